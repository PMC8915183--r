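# Shared fixtures, all generated in code.

# Random windows over the 20 letters (optionally with X pads at the ends).
rand_windows <- function(n, L, seed = 1, pad_prob = 0) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    chars <- sample(AA_ALPHABET, L, replace = TRUE)
    if (pad_prob > 0 && runif(1) < pad_prob) {
      npad <- sample.int(L %/% 2, 1)
      side <- sample(c("l", "r"), 1)
      if (side == "l") chars[seq_len(npad)] <- "X"
      else chars[(L - npad + 1):L] <- "X"
    }
    paste(chars, collapse = "")
  }, "")
}

# A trivially separable window set: positives carry a run of prolines
# right of centre, negatives are background.
toy_separable_dataset <- function(n_per_class = 25, flank = 5, seed = 1) {
  set.seed(seed)
  L <- 2 * flank + 1
  make <- function(positive) {
    vapply(seq_len(n_per_class), function(i) {
      chars <- sample(setdiff(AA_ALPHABET, "P"), L, replace = TRUE)
      chars[flank + 1] <- "S"
      if (positive) chars[(flank + 2):(flank + 4)] <- "P"
      paste(chars, collapse = "")
    }, "")
  }
  tibble::tibble(
    sequence = c(make(TRUE), make(FALSE)),
    label = rep(c("positive", "negative"), each = n_per_class),
    residue = "S",
    protein_id = sprintf("toy%03d", seq_len(2 * n_per_class)),
    position = flank + 1L,
    flank_n = as.integer(flank)
  )
}

# Small, fast CNN settings for tests that only need a working model.
quick_hp <- function(L, ...) {
  args <- modifyList(list(input_length = L, kernel_width = min(5L, L),
                          filters = 8L, hidden_dims = 8L, epochs = 10L,
                          batch_size = 16L, seed = 1L),
                     list(...))
  do.call(cnn_hyperparams, args)
}

# Model-free factory for split-scheme tests: scores by proline content.
proline_factory <- function(train) {
  function(test) {
    pmin(1, stringr::str_count(test$sequence, "P") /
           nchar(test$sequence) * 5)
  }
}

# A small synthetic world shared by several tests.
small_synth <- function(n_s = 120, seed = 7, n_proteins = 60,
                        length_range = c(100, 200), ...) {
  generate_synthetic(synthetic_spec(n_proteins = n_proteins,
                                    length_range = length_range,
                                    n_positive_sites = c(S = n_s),
                                    seed = seed, ...))
}
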