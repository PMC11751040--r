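# Shared fixtures: tiny configurations and datasets built in code.

tiny_model_config <- function(dropout = 0, ...) {
  model_config(conv_channels = c(4L, 8L), kernel_sizes = c(3L, 3L), pool_size = 2L,
               lstm_hidden = 8L, attention_dim = 8L, fc_sizes = c(16L, 8L),
               dropout = dropout, ...)
}

# the scaled-down architecture used for the synthetic-recovery runs
small_model_config <- function(...) {
  model_config(conv_channels = c(8L, 16L), lstm_hidden = 16L, attention_dim = 16L,
               fc_sizes = c(32L, 16L), dropout = 0.3, ...)
}

tiny_dataset <- function(n_pos = 20, n_neg = 20, L = 15L, seed = 1L, ...) {
  generate_dataset(signal_spec(L = L, seed = seed, ...), n_pos, n_neg)
}

# windows whose class is decided by 'K' adjacent to the center: a linearly
# separable toy problem for the training contract
separable_toy <- function(n = 20, L = 9L, seed = 42L) {
  withr::with_seed(seed, {
    ctr <- (L + 1L) %/% 2L
    bg <- setdiff(strsplit("ACDEFGHILMNPQRSTVWY", "")[[1]], "K")
    seqs <- vapply(seq_len(n), function(i) {
      chars <- sample(bg, L, replace = TRUE)
      chars[ctr] <- "C"
      if (i <= n / 2) chars[ctr + sample(c(-1L, 1L), 1)] <- "K"
      paste(chars, collapse = "")
    }, character(1))
    window_dataset(data.frame(
      sequence = seqs, label = rep(c(1L, 0L), each = n / 2),
      protein_id = paste0("T", seq_len(n)), center_position = ctr))
  })
}
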