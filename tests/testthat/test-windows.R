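test_that("window extraction pads termini with X and honours the geometry", {
  expect_equal(extract_window("MSTY", 2, 3), "XXMSTYX")
  long <- paste0(strrep("A", 149), "S", strrep("A", 150))
  expect_equal(nchar(extract_window(long, 150, 100)), 201L)
  expect_equal(extract_window("MSTY", 2, 0), "S")
  expect_error(extract_window("MSTY", 1, 2), "S/T/Y")
  expect_error(extract_window("MSTY", 9, 2), "out of range")
})

test_that("padding invariants hold under a random sweep", {
  set.seed(42)
  for (i in 1:500) {
    L <- sample(5:60, 1)
    chars <- sample(AA_ALPHABET, L, replace = TRUE)
    pos <- sample(L, 1)
    chars[pos] <- sample(c("S", "T", "Y"), 1)
    seqs <- paste(chars, collapse = "")
    n <- sample(0:30, 1)
    w <- extract_window(seqs, pos, n)
    expect_equal(nchar(w), 2L * n + 1L)
    expect_equal(substr(w, n + 1, n + 1), chars[pos])
    # X only as contiguous prefix/suffix, matching the overhang exactly
    left <- max(0L, n - (pos - 1L))
    right <- max(0L, n - (L - pos))
    expect_equal(w, paste0(strrep("X", left),
                           substr(seqs, max(1, pos - n), min(L, pos + n)),
                           strrep("X", right)))
  }
})

test_that("redundancy removal matches a brute-force all-pairs oracle", {
  # identity 0.6 pair survives at threshold 0.7; identical pair collapses
  a <- "ACDEFGHIKL"
  b <- "ACDEFGWWWW" # 6/10 matches
  expect_equal(window_identity(a, b), 0.6)
  expect_equal(nrow(remove_redundancy(tibble::tibble(sequence = c(a, b)))), 2L)
  expect_equal(length(remove_redundancy(c(a, a))), 1L)

  # survivor set is pairwise below threshold and every removed window has
  # a surviving representative at or above threshold (greedy invariant)
  w <- rand_windows(200, 12, seed = 8)
  # force some near-duplicates
  w[51:70] <- vapply(w[1:20], function(s) {
    chars <- strsplit(s, "")[[1]]
    chars[1:3] <- "W"
    paste(chars, collapse = "")
  }, "")
  surv <- remove_redundancy(w, identity_threshold = 0.7)
  ident <- function(x, y) window_identity(x, y)
  for (i in seq_along(surv)) {
    for (j in seq_len(i - 1L)) {
      expect_lt(ident(surv[i], surv[j]), 0.7)
    }
  }
  removed <- setdiff(w, surv)
  for (r in removed) {
    expect_true(any(vapply(surv, ident, 0, y = r) >= 0.7))
  }
})

test_that("redundancy removal is idempotent and rejects mixed lengths", {
  w <- rand_windows(100, 9, seed = 3)
  once <- remove_redundancy(w)
  twice <- remove_redundancy(once)
  expect_identical(as.character(once), as.character(twice))
  expect_error(remove_redundancy(c("AAA", "AAAA")), "equal length")
})

test_that("negative sampling is balanced, disjoint from positives and seeded", {
  synth <- small_synth(n_s = 50, seed = 13)
  neg1 <- sample_negatives(synth$proteins, synth$annotations, "S",
                           flank_n = 7, seed = 99)
  neg2 <- sample_negatives(synth$proteins, synth$annotations, "S",
                           flank_n = 7, seed = 99)
  expect_identical(neg1, neg2)
  pos_w <- remove_redundancy(extract_windows(synth$proteins,
                                             synth$annotations, 7))
  expect_equal(nrow(neg1), nrow(pos_w))
  # exhaustive disjointness on (protein, position) pairs
  expect_length(intersect(paste(neg1$protein_id, neg1$position),
                          paste(synth$annotations$protein_id,
                                synth$annotations$position)), 0L)
  # negatives sit on the requested residue type
  seqs <- setNames(synth$proteins$sequence, synth$proteins$id)
  expect_true(all(substr(seqs[neg1$protein_id], neg1$position,
                         neg1$position) == "S"))
})

test_that("built datasets are balanced, shuffled deterministically, and valid", {
  synth <- small_synth(n_s = 60, seed = 17)
  ds1 <- build_dataset(synth$proteins, synth$annotations, "S",
                       flank_n = 8, seed = 5)
  ds2 <- build_dataset(synth$proteins, synth$annotations, "S",
                       flank_n = 8, seed = 5)
  expect_identical(ds1$sequence, ds2$sequence)
  counts <- table(ds1$label)
  expect_equal(unname(counts["positive"]), unname(counts["negative"]))
  expect_true(all(nchar(ds1$sequence) == 17L))
  expect_false(any(duplicated(ds1$sequence[ds1$label == "positive"])))
  log <- attr(ds1, "build_log")
  expect_equal(log$total, log$positives_dedup + log$negatives)
})

test_that("dataset invariants hold across random configurations", {
  set.seed(31)
  for (rep in 1:15) {
    n_s <- sample(20:40, 1)
    flank <- sample(3:12, 1)
    synth <- small_synth(n_s = n_s, seed = 1000 + rep, n_proteins = 40,
                         length_range = c(80, 160))
    ds <- build_dataset(synth$proteins, synth$annotations, "S",
                        flank_n = flank, seed = rep)
    expect_true(all(nchar(ds$sequence) == 2L * flank + 1L))
    expect_equal(sum(ds$label == "positive"), sum(ds$label == "negative"))
    centre <- substr(ds$sequence, flank + 1, flank + 1)
    expect_true(all(centre == "S"))
    # X only as contiguous terminal blocks
    expect_false(any(grepl("X", gsub("^X+|X+$", "", ds$sequence))))
  }
})
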