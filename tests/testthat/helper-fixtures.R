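# Shared fixtures: everything is generated in code, no files shipped.

BASES <- c("A", "C", "G", "U")

random_windows <- function(n, L = 41L, seed = 1L, center_A = TRUE) {
  set.seed(seed)
  w <- vapply(seq_len(n), function(i) {
    ch <- sample(BASES, L, replace = TRUE)
    if (center_A) ch[(L + 1L) %/% 2L] <- "A"
    paste(ch, collapse = "")
  }, character(1))
  w
}

# Fast training configuration for unit tests (compute knob only).
fast_cfg <- function(epochs = 2L, seed = 1L, batch_size = 16L,
                     learning_rate = 3e-3, dropout = 0) {
  train_config(epochs = epochs, batch_size = batch_size,
               learning_rate = learning_rate, early_stopping_patience = 50L,
               dropout_rate = dropout, seed = seed)
}

# Narrow-width variants of the three architectures for plumbing tests where
# only behaviour, not the full structural contract, is exercised.
tiny_spec <- function(arch, L = 41L) {
  hp <- switch(arch,
    densenet_senet = list(trunk_channels = 8L, growth = 4L,
                          layers_per_block = 2L, head_units = 8L),
    dcnn_bilstm = list(filters = 8L, lstm_units = 8L),
    msrn_bigru = list(block_channels = 16L, fusion_filters = 24L,
                      gru_units = 8L, n_msrb = 2L))
  base_model_spec(arch, L = L, hyperparameters = hp)
}

strong_dataset <- function(n_pos, n_neg, seed = 3L, effect = 1) {
  generate_dataset(n_pos, n_neg, delta = 20L,
                   motif = default_motif(effect = effect, strength = 0.8),
                   seed = seed)
}
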