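#' Read RNA (or DNA) sequences from a FASTA file
#'
#' Sequences are uppercased and DNA thymine is normalized to uracil, so the
#' working alphabet downstream is always \{A, C, G, U\}. Under the default
#' `"strict"` policy any other character is an error; under `"lenient"` it is
#' replaced by the pad symbol `N` (which encodes to all-zero channels).
#'
#' @param path Path to a FASTA file.
#' @param alphabet_policy `"strict"` (default) or `"lenient"`.
#' @return A [Biostrings::BStringSet]-backed named character vector of
#'   normalized sequences (names are the FASTA record ids).
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "ACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, alphabet_policy = c("strict", "lenient")) {
  alphabet_policy <- match.arg(alphabet_policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  seqs <- toupper(as.character(set))
  ids <- names(set)
  ids[is.na(ids) | !nzchar(ids)] <- paste0("record_", which(is.na(ids) | !nzchar(ids)))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for FASTA record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  names(seqs) <- ids
  normalize_rna(seqs, alphabet_policy)
}

#' Normalize sequences to the RNA alphabet
#'
#' @param seqs Named or unnamed character vector.
#' @param alphabet_policy `"strict"` rejects characters outside \{A,C,G,U\}
#'   (after T to U mapping); `"lenient"` replaces them with `N`.
#' @return Character vector over \{A,C,G,U\} (plus `N` under `"lenient"`).
#' @export
normalize_rna <- function(seqs, alphabet_policy = c("strict", "lenient")) {
  alphabet_policy <- match.arg(alphabet_policy)
  out <- chartr("Tt", "UU", toupper(seqs))
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    if (alphabet_policy == "strict") {
      nm <- names(out)[bad]
      if (is.null(nm)) nm <- which(bad)
      stop("sequence(s) contain characters outside {A,C,G,U}: ",
           paste(utils::head(nm, 5), collapse = ", "),
           " (use alphabet_policy = \"lenient\" to pad with N)")
    }
    out[bad] <- gsub("[^ACGU]", "N", out[bad])
  }
  out
}

#' Write sequences to a FASTA file
#'
#' Round-trips losslessly with [read_fasta()] for sequences over \{A,C,G,U\}.
#'
#' @param records Named character vector of sequences (names become headers).
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  if (length(records) == 0) {
    ok <- file.create(path)
    if (!ok) stop("cannot write FASTA to: ", path)
    return(invisible(path))
  }
  ids <- names(records)
  if (is.null(ids)) ids <- paste0("record_", seq_along(records))
  set <- Biostrings::BStringSet(unname(as.character(records)))
  names(set) <- ids
  tryCatch(Biostrings::writeXStringSet(set, filepath = path),
           error = function(e) stop("cannot write FASTA to '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Extract a fixed-length window centered on a candidate adenosine
#'
#' Builds the (2*delta + 1)-nt fragment `sequence[center - delta, center +
#' delta]` (1-based, closed interval). The benchmark design uses delta = 20,
#' i.e. 41-nt windows.
#'
#' @param sequence A single sequence (character scalar over \{A,C,G,U\}).
#' @param center 1-based position of the candidate site.
#' @param delta Number of flanking nucleotides on each side.
#' @param pad_policy `"reject"` (default) errors when the window runs off the
#'   sequence ends; `"pad"` fills missing positions with `N`.
#' @param require_A Require the center nucleotide to be adenosine.
#' @param source_id Identifier recorded in the returned object.
#' @return A `site_window` object (list with `source_id`, `center`, `delta`,
#'   `window`, `label`).
#' @examples
#' extract_window("AGUACUGA", center = 4, delta = 2)$window  # "GUACU"
#' @export
extract_window <- function(sequence, center, delta, pad_policy = c("reject", "pad"),
                           require_A = TRUE, source_id = "seq") {
  pad_policy <- match.arg(pad_policy)
  sequence <- as.character(sequence)
  stopifnot(length(sequence) == 1L)
  n <- nchar(sequence)
  if (center < 1L || center > n) {
    stop("center position ", center, " out of range [1, ", n, "]")
  }
  ctr <- substr(sequence, center, center)
  if (require_A && ctr != "A") {
    stop("center nucleotide at position ", center, " is '", ctr,
         "', not 'A' (set require_A = FALSE to allow)")
  }
  lo <- center - delta
  hi <- center + delta
  if (lo < 1L || hi > n) {
    if (pad_policy == "reject") {
      stop("window [", lo, ", ", hi, "] exceeds sequence bounds [1, ", n,
           "]; use pad_policy = \"pad\" to pad with N")
    }
    left <- strrep("N", max(0L, 1L - lo))
    right <- strrep("N", max(0L, hi - n))
    core <- substr(sequence, max(1L, lo), min(n, hi))
    win <- paste0(left, core, right)
  } else {
    win <- substr(sequence, lo, hi)
  }
  structure(list(source_id = source_id, center = as.integer(center),
                 delta = as.integer(delta), window = win, label = "unlabeled"),
            class = "site_window")
}

#' @export
print.site_window <- function(x, ...) {
  cat(sprintf("<site_window> %s:%d (delta=%d, label=%s)\n  %s\n",
              x$source_id, x$center, x$delta, x$label, x$window))
  invisible(x)
}

#' Find candidate adenosine centers in a sequence
#'
#' Returns all 1-based positions carrying `A`. With `require_motif = TRUE`,
#' only adenosines in a BCA context are kept, interpreted as the
#' trinucleotide (B, C, A) ending at the candidate: position - 2 carries B
#' (one of C/G/U) and position - 1 carries C. The exact offsets are
#' configurable because the motif definition is not fully standardized.
#'
#' @param sequence Character scalar over \{A,C,G,U\}.
#' @param require_motif Apply the BCA context filter.
#' @param b_offset,c_offset Offsets (relative to the candidate A) of the B and
#'   C motif positions.
#' @return Integer vector of 1-based positions.
#' @export
find_candidate_centers <- function(sequence, require_motif = FALSE,
                                   b_offset = -2L, c_offset = -1L) {
  sequence <- as.character(sequence)
  stopifnot(length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pos <- which(chars == "A")
  if (!require_motif || length(pos) == 0) return(pos)
  keep <- vapply(pos, function(p) {
    bp <- p + b_offset
    cp <- p + c_offset
    bp >= 1L && cp >= 1L && bp <= length(chars) && cp <= length(chars) &&
      chars[bp] %in% c("C", "G", "U") && chars[cp] == "C"
  }, logical(1))
  pos[keep]
}

#' Construct a labeled window dataset
#'
#' The central container of the package: a data frame of fixed-length windows
#' with labels, carrying the shared `delta` as an attribute.
#'
#' @param windows Character vector of window sequences (all length
#'   2*delta+1).
#' @param label Character vector in `"positive"`/`"negative"`/`"unlabeled"`.
#' @param id Optional window identifiers.
#' @param delta Flank size; inferred from window length when `NULL`.
#' @return A `site_dataset` (data frame with columns `id`, `window`, `label`).
#' @export
site_dataset <- function(windows, label, id = NULL, delta = NULL) {
  windows <- as.character(windows)
  label <- as.character(label)
  stopifnot(length(windows) == length(label))
  if (!all(label %in% c("positive", "negative", "unlabeled"))) {
    stop("labels must be 'positive', 'negative' or 'unlabeled'")
  }
  lens <- nchar(windows)
  if (length(windows) > 0 && length(unique(lens)) != 1L) {
    stop("all windows must share the same length; saw lengths ",
         paste(unique(lens), collapse = ", "))
  }
  L <- if (length(windows) > 0) lens[1] else 2L * (delta %||% 20L) + 1L
  if (L %% 2L != 1L) stop("window length must be odd (2*delta + 1), got ", L)
  d <- (L - 1L) %/% 2L
  if (!is.null(delta) && delta != d) {
    stop("window length ", L, " inconsistent with delta = ", delta)
  }
  if (is.null(id)) id <- sprintf("w%05d", seq_along(windows))
  out <- data.frame(id = as.character(id), window = windows, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "delta") <- d
  class(out) <- c("site_dataset", "data.frame")
  out
}

#' @export
print.site_dataset <- function(x, ...) {
  cat(sprintf("<site_dataset> %d windows (delta=%d, length=%d): %d positive, %d negative, %d unlabeled\n",
              nrow(x), attr(x, "delta"), 2L * attr(x, "delta") + 1L,
              sum(x$label == "positive"), sum(x$label == "negative"),
              sum(x$label == "unlabeled")))
  invisible(x)
}

#' @export
`[.site_dataset` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("id", "window", "label") %in% names(out))) {
    attr(out, "delta") <- attr(x, "delta")
    class(out) <- c("site_dataset", "data.frame")
  }
  out
}

#' Number of positive / negative windows in a dataset
#' @param dataset A `site_dataset`.
#' @return Named integer vector with `n_pos` and `n_neg`.
#' @export
class_counts <- function(dataset) {
  c(n_pos = sum(dataset$label == "positive"),
    n_neg = sum(dataset$label == "negative"))
}

#' Binary label vector (positive = 1) of a dataset
#' @param dataset A `site_dataset`.
#' @return Numeric 0/1 vector (unlabeled windows are NA).
#' @export
dataset_labels <- function(dataset) {
  ifelse(dataset$label == "positive", 1,
         ifelse(dataset$label == "negative", 0, NA_real_))
}

#' Load a labeled window dataset from FASTA or a delimited table
#'
#' Two dialects are accepted and auto-sniffed: (1) FASTA whose headers carry a
#' `pos`/`neg` token (any position, case-insensitive, separated by
#' non-alphanumerics), (2) a delimited file (TSV or CSV, header row) with
#' columns `sequence` and `label` where label is `pos`/`neg`/`positive`/
#' `negative`/`1`/`0`.
#'
#' @param path Input file.
#' @param format `"auto"` (default), `"fasta"` or `"table"`.
#' @return A [site_dataset()].
#' @export
read_labeled_windows <- function(path, format = c("auto", "fasta", "table")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "table"
  }
  if (format == "fasta") {
    seqs <- read_fasta(path)
    toks <- tolower(names(seqs))
    lab <- ifelse(grepl("(^|[^a-z0-9])pos(itive)?([^a-z0-9]|$)", toks), "positive",
           ifelse(grepl("(^|[^a-z0-9])neg(ative)?([^a-z0-9]|$)", toks), "negative",
                  "unlabeled"))
    return(site_dataset(unname(seqs), lab, id = names(seqs)))
  }
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("sequence", "label") %in% names(tab))) {
    stop("labeled table must have 'sequence' and 'label' columns; found: ",
         paste(names(tab), collapse = ", "))
  }
  lab <- tolower(as.character(tab$label))
  lab <- ifelse(lab %in% c("pos", "positive", "1"), "positive",
         ifelse(lab %in% c("neg", "negative", "0"), "negative", "unlabeled"))
  site_dataset(normalize_rna(tab$sequence), lab,
               id = if ("id" %in% names(tab)) tab$id else NULL)
}

#' Write a labeled dataset as FASTA plus label-bearing headers
#' @param dataset A `site_dataset`.
#' @param path Output FASTA path.
#' @export
write_labeled_windows <- function(dataset, path) {
  tag <- ifelse(dataset$label == "positive", "pos",
                ifelse(dataset$label == "negative", "neg", "unk"))
  recs <- dataset$window
  names(recs) <- paste0(dataset$id, "|", tag)
  write_fasta(recs, path)
}
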