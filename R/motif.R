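#' K-means clustering of peptide windows
#'
#' Clusters windows on their flattened one-hot vectors for each K in
#' `K_range`, recording the mean within-cluster squared distance as the
#' selection criterion. The optimal K is the elbow of the criterion
#' curve: the interior K with the maximum second difference (the point
#' where the improvement from adding a cluster collapses). The full
#' curve is returned so any other selection rule can be applied.
#'
#' @param windows Window tibble or character vector.
#' @param K_range Integer vector of candidate K (default 1:8).
#' @param seed Seed; centroids are reproducible.
#' @param nstart Random restarts per K (default 5).
#' @return A `cluster_result` list: `K` (selected), `assignments`
#'   (integer per window, for the selected K), `criterion` (tibble of K
#'   vs mean within-cluster distance), `all_assignments` (list by K).
#' @export
kmeans_windows <- function(windows, K_range = 1:8, seed = 1L, nstart = 5L) {
  seqs <- if (is.data.frame(windows)) windows$sequence else windows
  n <- length(seqs)
  if (max(K_range) > n) {
    abort(paste0("K_range includes K = ", max(K_range),
                 " but there are only ", n, " windows"))
  }
  x <- onehot_matrix(seqs)
  K_range <- sort(unique(as.integer(K_range)))
  set.seed(seed)
  fits <- lapply(K_range, function(K) {
    kmeans(x, centers = K, nstart = nstart, iter.max = 100L)
  })
  crit <- vapply(fits, function(f) f$tot.withinss / n, 0)
  K_sel <- select_elbow(K_range, crit)
  sel_fit <- fits[[match(K_sel, K_range)]]
  structure(list(
    K = K_sel,
    assignments = as.integer(sel_fit$cluster),
    criterion = tibble::tibble(K = K_range, mean_within = crit),
    all_assignments = setNames(lapply(fits, function(f) as.integer(f$cluster)),
                               K_range),
    centers = sel_fit$centers
  ), class = "cluster_result")
}

# Elbow = interior K maximizing the second difference of the criterion
# curve. With fewer than 3 points there is no interior: fall back to the
# smallest K whose criterion is within 1% of the minimum.
select_elbow <- function(K, crit) {
  if (length(K) < 3L) {
    return(K[which(crit <= min(crit) * 1.01)[1]])
  }
  d2 <- crit[-c(length(crit) - 1L, length(crit))] -
    2 * crit[-c(1L, length(crit))] + crit[-(1:2)]
  K[which.max(d2) + 1L]
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> selected K =", x$K, "\n")
  print(x$criterion)
  invisible(x)
}

#' Position-specific residue enrichment between positives and negatives
#'
#' For every position offset in `-flank..+flank` and every residue
#' symbol (20 amino acids plus `X`), compares the per-window occurrence
#' indicator between the positive and negative sets with a two-sample
#' Welch test on the Bernoulli indicators (a two-proportion test is
#' available via `test = "prop"`), reporting frequencies, their
#' difference, and the p-value; cells with p below `alpha` are flagged.
#' Windows are trimmed around their centre to length `2 * flank + 1`.
#'
#' @param positives,negatives Window tibbles or character vectors (equal
#'   window length within each set; flank of the windows must be >=
#'   `flank`).
#' @param flank Analysis flank (default 10, i.e. 21-residue segments).
#' @param test `"welch"` (default) or `"prop"`.
#' @param alpha Significance level (default 0.05).
#' @return An `enrichment_profile` tibble with columns `offset`,
#'   `residue`, `freq_pos`, `freq_neg`, `difference`, `p_value`,
#'   `significant`.
#' @export
position_enrichment <- function(positives, negatives, flank = 10L,
                                test = c("welch", "prop"), alpha = 0.05) {
  test <- match.arg(test)
  pos <- trim_to_flank(positives, flank)
  neg <- trim_to_flank(negatives, flank)
  if (!length(pos) || !length(neg)) abort("both sets must be non-empty")
  op <- ordinal_matrix(pos)
  on <- ordinal_matrix(neg)
  L <- 2L * flank + 1L
  n1 <- nrow(op); n2 <- nrow(on)
  out <- vector("list", L)
  symbols <- c("X", AA_ALPHABET)
  for (j in seq_len(L)) {
    cnt1 <- tabulate(op[, j] + 1L, nbins = 21L)
    cnt2 <- tabulate(on[, j] + 1L, nbins = 21L)
    f1 <- cnt1 / n1
    f2 <- cnt2 / n2
    p <- if (test == "welch") {
      welch_bernoulli_p(f1, n1, f2, n2)
    } else {
      two_prop_p(cnt1, n1, cnt2, n2)
    }
    out[[j]] <- tibble::tibble(
      offset = j - flank - 1L,
      residue = symbols,
      freq_pos = f1,
      freq_neg = f2,
      difference = f1 - f2,
      p_value = p
    )
  }
  res <- dplyr::bind_rows(out)
  res$significant <- !is.na(res$p_value) & res$p_value < alpha
  class(res) <- c("enrichment_profile", class(res))
  res
}

# Welch t on 0/1 indicators, vectorised over cells. Sample variance of a
# Bernoulli sample with mean f is n/(n-1) * f(1-f).
welch_bernoulli_p <- function(f1, n1, f2, n2) {
  v1 <- f1 * (1 - f1) * n1 / (n1 - 1)
  v2 <- f2 * (1 - f2) * n2 / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (f1 - f2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  # both samples constant: no evidence if equal, certainty if different
  degenerate <- se2 == 0
  p[degenerate & f1 == f2] <- 1
  p[degenerate & f1 != f2] <- 0
  p
}

two_prop_p <- function(cnt1, n1, cnt2, n2) {
  phat <- (cnt1 + cnt2) / (n1 + n2)
  se2 <- phat * (1 - phat) * (1 / n1 + 1 / n2)
  z <- (cnt1 / n1 - cnt2 / n2) / sqrt(se2)
  p <- 2 * stats::pnorm(-abs(z))
  p[se2 == 0] <- 1
  p
}

trim_to_flank <- function(windows, flank) {
  seqs <- if (is.data.frame(windows)) windows$sequence else windows
  if (!length(seqs)) return(character(0))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) abort("windows must have equal length")
  have <- (L - 1L) %/% 2L
  if (have < flank) {
    abort(paste0("requested flank ", flank, " exceeds window flank ", have))
  }
  centre <- have + 1L
  substr(seqs, centre - flank, centre + flank)
}

#' Extract motifs from convolution-filter activations
#'
#' For each filter of a trained CNN, collects the k-mer subsequences
#' whose rectified activation exceeds the per-filter
#' `activation_quantile`, stacks them (equal width, no gaps) and
#' converts the stack into a pseudocount-smoothed position weight
#' matrix. Also reports, per conv-map position, the fraction of filters
#' whose maximum activation over the dataset occurs there — the
#' "where do the motif detectors fire" profile.
#'
#' @param model Trained `phoscnn_model`.
#' @param windows Window tibble or character vector of model length.
#' @param activation_quantile Per-filter quantile above which a k-mer
#'   counts as activating (default 0.99).
#' @param pseudocount Added to every PWM cell before row normalisation
#'   (default 0.5).
#' @return A list of class `filter_pwms`: `pwms`, a named list of k x 20
#'   row-stochastic matrices with attribute `support`; and
#'   `activation_positions`, a tibble (`position`, `fraction`).
#' @export
filter_activation_pwm <- function(model, windows, activation_quantile = 0.99,
                                  pseudocount = 0.5) {
  seqs <- if (is.data.frame(windows)) windows$sequence else windows
  acts <- cnn_activations(model, seqs)
  A <- acts$act
  m <- acts$m
  n <- length(seqs)
  k <- model$hp$kernel_width
  F_ <- ncol(A)
  # k-mer content per (window, start): reuse the ordinal matrix
  ord <- ordinal_matrix(seqs)
  pos_of_row <- rep(seq_len(m), n)
  win_of_row <- rep(seq_len(n), each = m)
  pwms <- list()
  max_pos <- integer(F_)
  for (f in seq_len(F_)) {
    a <- A[, f]
    max_pos[f] <- pos_of_row[which.max(a)]
    thr <- quantile(a, activation_quantile, names = FALSE)
    sel <- which(a > thr & a > 0)
    if (!length(sel)) {
      message("filter ", f, ": no activations above threshold; PWM omitted")
      next
    }
    counts <- matrix(0, nrow = k, ncol = 20L,
                     dimnames = list(NULL, AA_ALPHABET))
    for (t in seq_len(k)) {
      codes <- ord[cbind(win_of_row[sel], pos_of_row[sel] + t - 1L)]
      tab <- tabulate(codes, nbins = 20L)
      counts[t, ] <- counts[t, ] + tab
    }
    pwm <- counts + pseudocount
    pwm <- pwm / rowSums(pwm)
    attr(pwm, "support") <- length(sel)
    pwms[[paste0("filter_", f)]] <- pwm
  }
  frac <- tabulate(max_pos, nbins = m) / F_
  structure(list(
    pwms = pwms,
    activation_positions = tibble::tibble(position = seq_len(m),
                                          fraction = frac)
  ), class = "filter_pwms")
}

#' @export
print.filter_pwms <- function(x, ...) {
  cat("<filter_pwms>", length(x$pwms), "motifs\n")
  invisible(x)
}

#' Best-alignment correlation between a learned PWM and a motif table
#'
#' Slides the (narrower) motif probability table along the PWM rows and
#' returns the maximum Pearson correlation over the overlapping cells —
#' a scale-free measure of motif recovery.
#'
#' @param pwm A k x 20 PWM (rows = motif positions).
#' @param motif An w x 20 probability table, `w <= k` (e.g.
#'   `spec$motif_model`).
#' @return The best-offset Pearson correlation.
#' @export
pwm_motif_correlation <- function(pwm, motif) {
  k <- nrow(pwm); w <- nrow(motif)
  if (w > k) return(pwm_motif_correlation(motif, pwm))
  best <- -1
  for (off in 0:(k - w)) {
    block <- pwm[(off + 1):(off + w), , drop = FALSE]
    r <- suppressWarnings(stats::cor(as.vector(block), as.vector(motif)))
    if (!is.na(r) && r > best) best <- r
  }
  best
}

#' Write PWMs in MEME minimal motif format
#'
#' @param pwms A `filter_pwms` object or named list of row-stochastic
#'   matrices.
#' @param path Output path.
#' @param background Background frequencies for the header.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path, background = background_frequencies()) {
  if (inherits(pwms, "filter_pwms")) pwms <- pwms$pwms
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c("MEME version 4", "",
             "ALPHABET= ACDEFGHIKLMNPQRSTVWY", "",
             "Background letter frequencies",
             paste(sprintf("%s %.5f", AA_ALPHABET, background),
                   collapse = " "), "")
  for (nm in names(pwms)) {
    p <- pwms[[nm]]
    lines <- c(lines,
               paste0("MOTIF ", nm),
               sprintf("letter-probability matrix: alength= 20 w= %d nsites= %d E= 0",
                       nrow(p), attr(p, "support") %||% nrow(p)),
               apply(p, 1, function(r) paste(sprintf("%.6f", r),
                                             collapse = " ")),
               "")
  }
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
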