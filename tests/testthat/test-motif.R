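test_that("K = 1 clustering puts every window in one cluster", {
  w <- rand_windows(30, 11, seed = 1)
  res <- kmeans_windows(w, K_range = 1, seed = 2)
  expect_equal(res$K, 1L)
  expect_equal(unique(res$assignments), 1L)
  expect_error(kmeans_windows(w, K_range = c(2, 50)), "only")
})

test_that("duplicated windows receive identical cluster assignments", {
  w <- rand_windows(40, 9, seed = 3)
  doubled <- c(w, w)
  res <- kmeans_windows(doubled, K_range = 3, seed = 4)
  expect_equal(res$assignments[1:40], res$assignments[41:80])
})

test_that("clustering is reproducible and exposes the criterion curve", {
  w <- rand_windows(60, 9, seed = 5)
  r1 <- kmeans_windows(w, K_range = 1:4, seed = 6)
  r2 <- kmeans_windows(w, K_range = 1:4, seed = 6)
  expect_identical(r1$assignments, r2$assignments)
  expect_equal(nrow(r1$criterion), 4L)
  # mean within-cluster distance is non-increasing in K
  expect_true(all(diff(r1$criterion$mean_within) < 1e-8))
})

test_that("enrichment flags planted motif offsets with positive differences", {
  synth <- generate_synthetic(synthetic_spec(
    n_proteins = 250, length_range = c(150, 300),
    n_positive_sites = c(S = 500), seed = 42
  ))
  pos <- extract_windows(synth$proteins, synth$annotations, 10)
  neg_ann <- sample_negatives(synth$proteins, synth$annotations, "S",
                              flank_n = 10, seed = 1)
  neg <- extract_windows(synth$proteins, neg_ann, 10)
  prof <- position_enrichment(pos, neg, flank = 10)
  planted <- dplyr::filter(prof, residue == "P", offset %in% 1:4)
  expect_true(all(planted$significant))
  expect_true(all(planted$difference > 0))
  # per-position frequencies over the 21-symbol alphabet sum to 1
  sums <- prof |> dplyr::group_by(offset) |>
    dplyr::summarise(s = sum(freq_pos), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("enrichment differences are antisymmetric under set swap", {
  a <- rand_windows(50, 11, seed = 7)
  b <- rand_windows(50, 11, seed = 8)
  p1 <- position_enrichment(a, b, flank = 5)
  p2 <- position_enrichment(b, a, flank = 5)
  expect_equal(p1$difference, -p2$difference)
  expect_equal(p1$p_value, p2$p_value)
  expect_error(position_enrichment(a, b, flank = 9), "exceeds")
})

test_that("the null false-positive rate of the enrichment test is near alpha", {
  set.seed(99)
  fractions <- replicate(100, {
    pos <- rand_windows(150, 11, seed = sample.int(1e6, 1))
    neg <- rand_windows(150, 11, seed = sample.int(1e6, 1))
    mean(position_enrichment(pos, neg, flank = 5)$significant)
  })
  expect_lt(mean(fractions), 0.08)
})

test_that("a hand-set filter recovers its own motif as a PWM", {
  hp <- cnn_hyperparams(input_length = 15, kernel_width = 4, filters = 2,
                        hidden_dims = 4, epochs = 1, seed = 3)
  model <- build_cnn(hp)
  # filter 1 fires only on PPPP: strong positive weight on P at each
  # offset, strong negative elsewhere
  Wc <- matrix(-1, nrow = 80, ncol = 2)
  p_code <- which(AA_ALPHABET == "P")
  for (t in 1:4) Wc[(t - 1) * 20 + p_code, 1] <- 1
  model$params$Wc <- Wc
  model$params$bc <- c(0, 0)
  set.seed(10)
  wins <- vapply(1:50, function(i) {
    chars <- sample(setdiff(AA_ALPHABET, "P"), 15, replace = TRUE)
    if (i <= 10) chars[6:9] <- "P"
    paste(chars, collapse = "")
  }, "")
  res <- filter_activation_pwm(model, wins, activation_quantile = 0.95)
  pwm <- res$pwms[["filter_1"]]
  expect_false(is.null(pwm))
  argmax <- AA_ALPHABET[apply(pwm, 1, which.max)]
  expect_equal(argmax, c("P", "P", "P", "P"))
  expect_true(all(abs(rowSums(pwm) - 1) < 1e-9))
  expect_gte(attr(pwm, "support"), 1L)
  # activation-position profile covers the conv map
  expect_equal(nrow(res$activation_positions), 15 - 4 + 1)
  expect_equal(sum(res$activation_positions$fraction), 1)
})

test_that("PWM extraction is deterministic given weights and threshold", {
  ds <- toy_separable_dataset(n_per_class = 20, flank = 5, seed = 9)
  model <- train_cnn(build_cnn(quick_hp(11, epochs = 4L)), ds)
  r1 <- filter_activation_pwm(model, ds)
  r2 <- filter_activation_pwm(model, ds)
  expect_identical(r1$pwms, r2$pwms)
})

test_that("PWMs export in MEME minimal format", {
  pwm <- matrix(1 / 20, nrow = 3, ncol = 20,
                dimnames = list(NULL, AA_ALPHABET))
  attr(pwm, "support") <- 7L
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(motif_a = pwm), f)
  lines <- readLines(f)
  expect_equal(lines[1], "MEME version 4")
  expect_true(any(grepl("MOTIF motif_a", lines)))
  expect_true(any(grepl("w= 3 nsites= 7", lines)))
})

test_that("best-offset PWM/motif correlation behaves as a recovery score", {
  motif <- default_motif_model(proline_prob = 0.9)
  # perfect embedding at offset 2 of a wider PWM
  pwm <- matrix(1 / 20, nrow = 8, ncol = 20,
                dimnames = list(NULL, AA_ALPHABET))
  pwm[3:6, ] <- motif
  expect_gt(pwm_motif_correlation(pwm, motif), 0.99)
  # flat PWM carries no motif signal
  flat <- matrix(1 / 20, nrow = 8, ncol = 20)
  expect_lt(pwm_motif_correlation(flat, motif), 0.5)
})
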