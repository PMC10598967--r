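# Positional nucleotide-composition comparison between positive and negative
# windows (two-sample-logo style analysis).

#' Positional nucleotide frequencies of a window set
#'
#' @param dataset A `site_dataset` (or character window vector).
#' @param label Which windows to tabulate: `"positive"`, `"negative"` or
#'   `"all"` (ignored for plain character input).
#' @return A `frequency_table`: list with `values` (L x 4 matrix of
#'   per-position base fractions, rows summing to 1) and `n` (window count).
#' @export
positional_frequencies <- function(dataset, label = c("all", "positive",
                                                      "negative")) {
  label <- match.arg(label)
  if (inherits(dataset, "site_dataset")) {
    windows <- if (label == "all") dataset$window else
      dataset$window[dataset$label == label]
  } else {
    windows <- as.character(dataset)
  }
  if (length(windows) == 0L) stop("no windows with label '", label, "'")
  L <- nchar(windows[1])
  if (any(nchar(windows) != L)) stop("windows differ in length")
  ch <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
               nrow = length(windows), byrow = TRUE)
  vals <- t(apply(ch, 2, function(col) {
    tab <- table(factor(col, levels = .BASES))
    as.numeric(tab) / length(col)
  }))
  colnames(vals) <- .BASES
  structure(list(values = vals, n = length(windows), L = L),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("<frequency_table> %d positions x 4 bases from %d windows\n",
              x$L, x$n))
  invisible(x)
}

#' Per-cell enrichment of positive over negative windows
#'
#' For every (position, base) cell, the difference in frequency and a
#' two-proportion z-test (pooled standard error); p-values are multiplicity
#' corrected over all L x 4 cells (Bonferroni by default). The forced central
#' adenosine is flagged as uninformative.
#'
#' @param pos,neg `frequency_table`s of the two classes (equal L).
#' @param alpha Family-wise significance level.
#' @param correction `"bonferroni"` or `"none"`.
#' @param center 1-based position of the fixed center; `NULL` takes the
#'   middle position when L is odd.
#' @return Data frame with columns `position`, `base`, `diff`, `p_value`,
#'   `p_adjusted`, `significant`, `uninformative`.
#' @export
enrichment_table <- function(pos, neg, alpha = 0.05,
                             correction = c("bonferroni", "none"),
                             center = NULL) {
  correction <- match.arg(correction)
  stopifnot(inherits(pos, "frequency_table"), inherits(neg, "frequency_table"))
  if (pos$L != neg$L) {
    stop("frequency tables disagree on window length: ", pos$L, " vs ", neg$L)
  }
  L <- pos$L
  if (is.null(center)) center <- if (L %% 2L == 1L) (L + 1L) %/% 2L else NA_integer_
  n1 <- pos$n; n2 <- neg$n
  grid <- expand.grid(position = seq_len(L), base = .BASES,
                      stringsAsFactors = FALSE)
  p1 <- pos$values[cbind(grid$position, match(grid$base, .BASES))]
  p2 <- neg$values[cbind(grid$position, match(grid$base, .BASES))]
  pooled <- (p1 * n1 + p2 * n2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- ifelse(se == 0, 0, (p1 - p2) / se)
  pval <- 2 * stats::pnorm(-abs(z))
  padj <- if (correction == "bonferroni") pmin(1, pval * nrow(grid)) else pval
  out <- data.frame(grid, diff = p1 - p2, z = z, p_value = pval,
                    p_adjusted = padj,
                    significant = padj < alpha,
                    uninformative = !is.na(center) & grid$position == center)
  out$significant[out$uninformative] <- FALSE
  out
}
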