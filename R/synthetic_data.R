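# Planted-motif generator for labeled fixed-length windows. The generator
# states a world in which positives carry a position-specific composition
# bias on a few offsets right of the central adenosine (G/C/U enriched),
# negatives are pure background, and the center is 'A' in both classes so it
# is uninformative -- mimicking the enrichment structure seen around real
# m6Am sites without simulating transcriptome context.

.BASES <- c("A", "C", "G", "U")

#' Position-specific motif model for the generator
#'
#' @param offsets Integer offsets relative to the central adenosine (offset 0
#'   is the center and is not allowed: the center is always `A`).
#' @param emission Matrix (length(offsets) x 4, columns A/C/G/U) of emission
#'   probabilities per offset; each row must sum to 1. A single vector is
#'   recycled across offsets.
#' @param effect Scalar in \[0, 1\]: positives draw motif positions from
#'   `(1 - effect) * background + effect * emission`. At `effect = 0`
#'   positives are distributionally identical to negatives.
#' @return A `motif_model`.
#' @export
motif_model <- function(offsets, emission, effect = 0.5) {
  offsets <- as.integer(offsets)
  if (any(offsets == 0L)) stop("offset 0 is the fixed central adenosine")
  if (is.null(dim(emission))) {
    emission <- matrix(emission, nrow = length(offsets), ncol = 4,
                       byrow = TRUE)
  }
  emission <- as.matrix(emission)
  if (nrow(emission) != length(offsets) || ncol(emission) != 4) {
    stop("emission must be length(offsets) x 4")
  }
  if (any(emission < 0) || any(abs(rowSums(emission) - 1) > 1e-8)) {
    stop("each emission row must be a probability vector summing to 1")
  }
  if (effect < 0 || effect > 1) stop("effect must lie in [0, 1]")
  colnames(emission) <- .BASES
  structure(list(offsets = offsets, emission = emission, effect = effect),
            class = "motif_model")
}

#' Default motif: G/C/U enrichment immediately right of the center
#'
#' Offsets +1..+5 favor the bases G, C, U, G, C with concentration
#' `strength` (remaining mass spread over the other three bases) --
#' a qualitative stand-in for the composition bias observed downstream of
#' genuine m6Am sites.
#'
#' @param effect Effect size passed to [motif_model()].
#' @param strength Emission probability of the favored base at each offset.
#' @return A `motif_model`.
#' @export
default_motif <- function(effect = 0.5, strength = 0.8) {
  favored <- c("G", "C", "U", "G", "C")
  em <- t(vapply(favored, function(b) {
    v <- rep((1 - strength) / 3, 4)
    names(v) <- .BASES
    v[b] <- strength
    v
  }, numeric(4)))
  motif_model(offsets = 1:5, emission = em, effect = effect)
}

#' Generate a labeled window dataset with a planted motif
#'
#' All windows have length `2*delta + 1` with the center forced to `A` in
#' both classes. Positive windows draw the motif offsets from the
#' effect-interpolated emissions and every other position from the
#' background; negative windows are background everywhere (except the fixed
#' center).
#'
#' @param n_pos,n_neg Class sizes (>= 0).
#' @param delta Flank size (window length 2*delta+1; default 20).
#' @param motif A [motif_model()] (default [default_motif()]).
#' @param background Probability vector over A/C/G/U (default uniform).
#' @param seed RNG seed; output is fully reproducible.
#' @param id_prefix Prefix for window ids.
#' @return A [site_dataset()].
#' @export
generate_dataset <- function(n_pos, n_neg, delta = 20L,
                             motif = default_motif(), background = rep(0.25, 4),
                             seed = 1L, id_prefix = "syn") {
  stopifnot(n_pos >= 0, n_neg >= 0)
  background <- as.numeric(background)
  if (length(background) != 4 || any(background < 0) ||
      abs(sum(background) - 1) > 1e-8) {
    stop("background must be a probability vector of length 4 summing to 1")
  }
  L <- 2L * as.integer(delta) + 1L
  center <- as.integer(delta) + 1L
  off_pos <- center + motif$offsets
  if (any(off_pos < 1L | off_pos > L)) {
    stop("motif offsets fall outside the window for delta = ", delta)
  }
  set.seed(seed)
  mix <- (1 - motif$effect) * matrix(background, nrow = length(motif$offsets),
                                     ncol = 4, byrow = TRUE) +
         motif$effect * motif$emission
  draw_class <- function(n, positive) {
    if (n == 0L) return(character(0))
    m <- matrix(sample(.BASES, n * L, replace = TRUE, prob = background),
                nrow = n)
    m[, center] <- "A"
    if (positive) {
      for (j in seq_along(motif$offsets)) {
        m[, off_pos[j]] <- sample(.BASES, n, replace = TRUE, prob = mix[j, ])
      }
    }
    apply(m, 1, paste, collapse = "")
  }
  pw <- draw_class(n_pos, TRUE)
  nw <- draw_class(n_neg, FALSE)
  site_dataset(c(pw, nw),
               c(rep("positive", n_pos), rep("negative", n_neg)),
               id = sprintf("%s_%s%05d", id_prefix,
                            c(rep("pos", n_pos), rep("neg", n_neg)),
                            c(seq_len(n_pos), seq_len(n_neg))))
}

#' Benchmark-shaped synthetic surrogate
#'
#' Emulates the benchmark's shape -- 1419/1419 training windows and 355/355
#' independent-test windows at delta = 20 -- with the default moderate-effect
#' multi-offset motif (effect 0.75, concentration 0.8 on offsets +1..+5).
#' This is a synthetic stand-in for the deposited benchmark, not a copy of
#' it; only the class counts and window length are taken from the benchmark
#' design.
#'
#' @param seed RNG seed (train and test use derived seeds).
#' @param effect Motif effect size (0 gives the null world).
#' @return List with `train` and `test` `site_dataset`s and the `motif` used.
#' @export
default_benchmark_surrogate <- function(seed = 1L, effect = 0.75) {
  motif <- default_motif(effect = effect, strength = 0.8)
  train <- generate_dataset(1419L, 1419L, delta = 20L, motif = motif,
                            seed = as.integer(seed), id_prefix = "train")
  test <- generate_dataset(355L, 355L, delta = 20L, motif = motif,
                           seed = as.integer(seed) + 524287L,
                           id_prefix = "test")
  list(train = train, test = test, motif = motif)
}
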