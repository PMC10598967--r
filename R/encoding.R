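# Window -> numeric channel matrices. Windows enter as character strings (or
# site_window objects); every encoder returns an L x C matrix with named
# channels. The pad symbol N encodes to all-zero channels under the lenient
# policy and errors under strict.

.ONEHOT <- rbind(A = c(1, 0, 0, 0), C = c(0, 1, 0, 0),
                 G = c(0, 0, 1, 0), U = c(0, 0, 0, 1),
                 N = c(0, 0, 0, 0))
colnames(.ONEHOT) <- c("A", "C", "G", "U")

# Nucleotide chemical property channels: ring structure (purine = 1),
# functional group (amino = 1: A and C), hydrogen-bond strength (strong = 1:
# A and U). The three rules make {A,C,G,U} a bijective 3-bit code.
.NCP <- rbind(A = c(1, 1, 1), C = c(0, 1, 0),
              G = c(1, 0, 0), U = c(0, 0, 1),
              N = c(0, 0, 0))
colnames(.NCP) <- c("ring", "amino", "hydrogen")

window_chars <- function(window, strict = TRUE) {
  if (inherits(window, "site_window")) window <- window$window
  window <- as.character(window)
  stopifnot(length(window) == 1L)
  ch <- strsplit(window, "", fixed = TRUE)[[1]]
  bad <- !(ch %in% c("A", "C", "G", "U", if (!strict) "N"))
  if (any(bad)) {
    stop("window contains unsupported symbol(s): ",
         paste(unique(ch[bad]), collapse = ", "))
  }
  ch
}

#' One-hot encode a window
#'
#' A, C, G, U map to the indicator vectors (1,0,0,0), (0,1,0,0), (0,0,1,0),
#' (0,0,0,1); a 41-nt window becomes a 41 x 4 matrix.
#'
#' @param window Character scalar or `site_window`.
#' @param strict Reject the pad symbol `N` (default); otherwise `N` encodes to
#'   an all-zero row.
#' @return L x 4 numeric matrix with channels `A`, `C`, `G`, `U`.
#' @examples
#' encode_onehot("ACGU")  # 4 x 4 identity
#' @export
encode_onehot <- function(window, strict = TRUE) {
  ch <- window_chars(window, strict)
  m <- .ONEHOT[ch, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Nucleotide chemical property (NCP) encoding
#'
#' Three binary channels per position: ring structure (purine A/G = 1,
#' pyrimidine C/U = 0), functional group (amino A/C = 1, keto G/U = 0) and
#' hydrogen-bond strength (strong pairing A/U = 1, weak G/C = 0). So
#' A = (1,1,1), C = (0,1,0), G = (1,0,0), U = (0,0,1).
#'
#' @inheritParams encode_onehot
#' @return L x 3 numeric matrix with channels `ring`, `amino`, `hydrogen`.
#' @export
encode_ncp <- function(window, strict = TRUE) {
  ch <- window_chars(window, strict)
  m <- .NCP[ch, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Nucleotide density (ND) encoding
#'
#' The density at position i is d_i = n / i where n counts occurrences of the
#' nucleotide at position i within the prefix 1..i (inclusive). Counting is
#' over the literal symbols of the input: in the worked example "AGTAUUCA"
#' the densities of A at positions 1, 4 and 8 are 1, 0.50 and 0.375, and of
#' U at positions 5 and 6 are 0.20 and 1/3 — values that require T and U to
#' be counted as distinct symbols. Unlike the other encoders, `T` is
#' therefore accepted here and counted separately from `U` (on normalized
#' RNA input, where no T occurs, this makes no difference).
#'
#' @inheritParams encode_onehot
#' @return L x 1 numeric matrix with channel `density`. Entries lie in (0, 1]
#'   and the first entry is always 1 (the pad symbol `N` is counted like any
#'   other symbol under `strict = FALSE`).
#' @export
encode_nd <- function(window, strict = TRUE) {
  if (inherits(window, "site_window")) window <- window$window
  window <- toupper(as.character(window))
  stopifnot(length(window) == 1L)
  ch <- strsplit(window, "", fixed = TRUE)[[1]]
  bad <- !(ch %in% c("A", "C", "G", "U", "T", if (!strict) "N"))
  if (any(bad)) {
    stop("window contains unsupported symbol(s): ",
         paste(unique(ch[bad]), collapse = ", "))
  }
  L <- length(ch)
  counts <- integer(L)
  seen <- integer(0)
  names(seen) <- character(0)
  d <- numeric(L)
  for (i in seq_len(L)) {
    key <- ch[i]
    seen[key] <- (if (is.na(seen[key])) 0L else seen[key]) + 1L
    d[i] <- seen[[key]] / i
  }
  matrix(d, ncol = 1L, dimnames = list(NULL, "density"))
}

#' Combined NCP + ND encoding
#'
#' Column-wise concatenation of the three chemical-property channels and the
#' density channel: each position becomes the 4-vector (ring, amino,
#' hydrogen, density), a 41-nt window a 41 x 4 matrix.
#'
#' @inheritParams encode_onehot
#' @return L x 4 numeric matrix.
#' @export
encode_ncp_nd <- function(window, strict = TRUE) {
  cbind(encode_ncp(window, strict), encode_nd(window, strict))
}

#' Concatenate encoding matrices channel-wise
#'
#' @param matrices List of L x C_j matrices sharing L.
#' @return Single matrix with the channels in argument order.
#' @export
concat_encodings <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  L <- vapply(matrices, nrow, integer(1))
  if (length(unique(L)) != 1L) {
    stop("encoding matrices disagree on window length: ",
         paste(unique(L), collapse = ", "))
  }
  do.call(cbind, matrices)
}

#' Flatten an encoding matrix to a row-major vector
#'
#' Position-major order: the C channels of position 1, then position 2, and
#' so on; a 41 x 4 matrix flattens to length 164. [unflatten_encoding()]
#' inverts.
#'
#' @param matrix L x C encoding matrix.
#' @return Numeric vector of length L*C.
#' @export
flatten_encoding <- function(matrix) {
  as.vector(t(matrix))
}

#' @rdname flatten_encoding
#' @param x Flattened vector.
#' @param n_channels Number of channels C.
#' @export
unflatten_encoding <- function(x, n_channels) {
  matrix(x, ncol = n_channels, byrow = TRUE)
}

#' Encode a batch of windows
#'
#' @param windows Character vector of windows (equal lengths) or a
#'   `site_dataset`.
#' @param encoding One of `"onehot"`, `"ncp_nd"`, `"onehot_ncp_nd"`.
#' @param flatten Return an n x (L*C) matrix of row-major flattened encodings
#'   instead of an n x L x C array.
#' @param strict Reject pad symbols.
#' @return Numeric array n x L x C (or matrix when `flatten = TRUE`) with
#'   channel names in the last dimension.
#' @export
encode_windows <- function(windows,
                           encoding = c("onehot", "ncp_nd", "onehot_ncp_nd"),
                           flatten = FALSE, strict = TRUE) {
  encoding <- match.arg(encoding)
  if (inherits(windows, "site_dataset")) windows <- windows$window
  windows <- as.character(windows)
  enc1 <- function(w) switch(encoding,
    onehot = encode_onehot(w, strict),
    ncp_nd = encode_ncp_nd(w, strict),
    onehot_ncp_nd = concat_encodings(list(encode_onehot(w, strict),
                                          encode_ncp(w, strict),
                                          encode_nd(w, strict))))
  if (length(windows) == 0L) {
    return(if (flatten) matrix(numeric(0), nrow = 0) else
             array(numeric(0), dim = c(0, 0, 0)))
  }
  mats <- lapply(windows, enc1)
  L <- nrow(mats[[1]]); C <- ncol(mats[[1]])
  if (flatten) {
    out <- do.call(rbind, lapply(mats, flatten_encoding))
    colnames(out) <- paste0(rep(seq_len(L), each = C), "_",
                            rep(colnames(mats[[1]]), L))
    return(out)
  }
  arr <- array(0, dim = c(length(windows), L, C),
               dimnames = list(NULL, NULL, colnames(mats[[1]])))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  arr
}

# Batch one-hot as the (B*L) x 4 layout the network layers use
# (position fastest within sample).
onehot_batch_matrix <- function(windows, strict = TRUE) {
  if (inherits(windows, "site_dataset")) windows <- windows$window
  windows <- as.character(windows)
  n <- length(windows)
  if (n == 0L) return(matrix(numeric(0), 0, 4))
  L <- nchar(windows[1])
  if (any(nchar(windows) != L)) stop("windows differ in length")
  ch <- unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE)
  bad <- !(ch %in% c("A", "C", "G", "U", if (!strict) "N"))
  if (any(bad)) stop("windows contain unsupported symbol(s): ",
                     paste(unique(ch[bad]), collapse = ", "))
  m <- .ONEHOT[ch, , drop = FALSE]
  rownames(m) <- NULL
  m
}
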