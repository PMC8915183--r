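#' Background amino-acid frequencies
#'
#' Approximate residue frequencies of the human proteome, used as the
#' default background for synthetic sequence generation. Named by
#' one-letter code in the order of [AA_ALPHABET]; sums to 1.
#'
#' @return A named numeric vector of length 20.
#' @export
background_frequencies <- function() {
  f <- c(A = 8.3, C = 1.4, D = 5.5, E = 6.7, F = 3.9, G = 7.1, H = 2.3,
         I = 5.9, K = 5.8, L = 9.7, M = 2.4, N = 4.1, P = 4.7, Q = 3.9,
         R = 5.5, S = 6.6, T = 5.4, V = 6.9, W = 1.1, Y = 2.9)
  f <- f[AA_ALPHABET]
  f / sum(f)
}

#' Default planted phospho-motif model
#'
#' A per-offset residue-probability table emulating the proline-directed
#' signature of many kinases: Proline probability is elevated at offsets
#' +1..+4 downstream of the phosphosite, with the remaining mass spread
#' according to the background.
#'
#' @param proline_prob Probability of Proline at each motif offset.
#' @param offsets Integer offsets (relative to the site) carrying the motif.
#' @param background Background frequencies (defaults to
#'   [background_frequencies()]).
#' @return A numeric matrix with one row per offset (rownames are the
#'   offsets) and 20 columns in [AA_ALPHABET] order; each row sums to 1.
#' @export
default_motif_model <- function(proline_prob = 0.8, offsets = 1:4,
                                background = background_frequencies()) {
  stopifnot(proline_prob >= 0, proline_prob <= 1)
  rest <- background
  rest["P"] <- 0
  rest <- rest / sum(rest) * (1 - proline_prob)
  row <- rest
  row["P"] <- proline_prob
  m <- matrix(rep(row, length(offsets)), nrow = length(offsets), byrow = TRUE,
              dimnames = list(as.character(offsets), AA_ALPHABET))
  m
}

# Per-cluster flank fingerprint distributions: each latent cluster tilts
# flank composition toward its own residue triplet so clusters are
# recoverable from sequence alone.
cluster_profiles <- function(K, background = background_frequencies(),
                             strength = 0.6) {
  triplets <- list(c("A", "L", "V"), c("G", "E", "D"), c("K", "R", "Q"),
                   c("F", "W", "H"), c("N", "I", "M"))
  out <- matrix(0, nrow = K, ncol = 20,
                dimnames = list(NULL, AA_ALPHABET))
  for (c_id in seq_len(K)) {
    tri <- triplets[[(c_id - 1L) %% length(triplets) + 1L]]
    row <- (1 - strength) * background
    row[tri] <- row[tri] + strength / length(tri)
    out[c_id, ] <- row / sum(row)
  }
  out
}

#' Specify a synthetic proteome with planted phosphosites
#'
#' Defines the generative model used by [generate_synthetic()]: proteins
#' drawn from background residue frequencies; positive phosphosites
#' planted with a downstream-proline motif; each positive assigned to one
#' of `n_latent_clusters` latent clusters whose flank composition carries
#' a cluster-specific fingerprint (this emulates the sub-population
#' structure that cluster-stratified validation is designed for).
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer `c(min, max)` protein length.
#' @param n_positive_sites Named integer vector, positives per residue
#'   type, e.g. `c(S = 400, T = 150, Y = 150)`.
#' @param motif_model Offset-by-residue probability matrix as produced by
#'   [default_motif_model()]; rows must sum to 1.
#' @param n_latent_clusters Number of latent sample clusters (>= 1).
#' @param cluster_strength Mixing weight of the cluster fingerprint in
#'   flank positions (0 disables cluster structure).
#' @param background_frequencies Length-20 probability vector.
#' @param disease_class Class label written into the annotations.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return An object of class `synthetic_spec` (a list).
#' @export
synthetic_spec <- function(n_proteins = 150,
                           length_range = c(150L, 400L),
                           n_positive_sites = c(S = 400L, T = 150L, Y = 150L),
                           motif_model = default_motif_model(),
                           n_latent_clusters = 3L,
                           cluster_strength = 0.6,
                           background_frequencies = phoscnn::background_frequencies(),
                           disease_class = "synthetic",
                           seed = 1L) {
  if (n_latent_clusters < 1L) abort("n_latent_clusters must be >= 1")
  if (abs(sum(background_frequencies) - 1) > 1e-9) {
    abort("background_frequencies must sum to 1")
  }
  if (any(abs(rowSums(motif_model) - 1) > 1e-9)) {
    abort("every motif_model row must sum to 1 (within 1e-9)")
  }
  if (is.null(names(n_positive_sites)) ||
      !all(names(n_positive_sites) %in% c("S", "T", "Y"))) {
    abort("n_positive_sites must be named with S/T/Y")
  }
  structure(list(
    n_proteins = as.integer(n_proteins),
    length_range = as.integer(length_range),
    n_positive_sites = n_positive_sites,
    motif_model = motif_model,
    n_latent_clusters = as.integer(n_latent_clusters),
    cluster_strength = cluster_strength,
    background_frequencies = background_frequencies,
    disease_class = disease_class,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Generate a synthetic proteome with planted phosphosites
#'
#' Draws protein sequences from the background model, plants positive
#' S/T/Y sites carrying the motif and a latent-cluster fingerprint, and
#' returns proteins, positive-site annotations and a separate ground-truth
#' table (cluster ids never leak into the annotations). Unplanted S/T/Y
#' positions serve as the negative candidate pool downstream.
#'
#' @param spec A [synthetic_spec()].
#' @param max_retries Placement attempts per site before erroring.
#' @return A list with tibbles `proteins` (`id`, `sequence`),
#'   `annotations` (the five standard columns, all `label == "positive"`)
#'   and `truth` (`protein_id`, `position`, `residue`, `cluster`), plus
#'   the `spec`.
#' @export
generate_synthetic <- function(spec, max_retries = 200L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  margin <- max(10L, max(abs(as.integer(rownames(spec$motif_model)))))
  lens <- sample(seq(spec$length_range[1], spec$length_range[2]),
                 spec$n_proteins, replace = TRUE)
  chars <- lapply(lens, function(L) {
    sample(AA_ALPHABET, L, replace = TRUE, prob = spec$background_frequencies)
  })
  ids <- sprintf("synprot%04d", seq_len(spec$n_proteins))

  occupied <- lapply(lens, function(L) logical(L))
  profiles <- cluster_profiles(spec$n_latent_clusters,
                               spec$background_frequencies,
                               spec$cluster_strength)
  motif_offsets <- as.integer(rownames(spec$motif_model))
  flank_offsets <- setdiff(-margin:margin, c(0L, motif_offsets))
  eligible <- which(lens >= 2L * margin + 1L)
  if (!length(eligible)) abort("no protein long enough to host a site")

  rows <- list()
  for (res in names(spec$n_positive_sites)) {
    n_sites <- spec$n_positive_sites[[res]]
    for (s in seq_len(n_sites)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        pi <- sample(eligible, 1L)
        pos <- sample(seq(margin + 1L, lens[pi] - margin), 1L)
        win <- max(1L, pos - margin):min(lens[pi], pos + margin)
        if (!any(occupied[[pi]][win])) {
          occupied[[pi]][win] <- TRUE
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(paste0("could not place site ", s, " of type ", res,
                     " after ", max_retries, " retries; ",
                     "increase n_proteins or protein length"))
      }
      cl <- sample.int(spec$n_latent_clusters, 1L)
      chars[[pi]][pos] <- res
      for (o in motif_offsets) {
        chars[[pi]][pos + o] <- sample(AA_ALPHABET, 1L,
                                       prob = spec$motif_model[as.character(o), ])
      }
      draw <- sample(AA_ALPHABET, length(flank_offsets), replace = TRUE,
                     prob = profiles[cl, ])
      chars[[pi]][pos + flank_offsets] <- draw
      rows[[length(rows) + 1L]] <- list(protein_id = ids[pi],
                                        position = pos, residue = res,
                                        cluster = cl)
    }
  }
  truth <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  truth <- dplyr::arrange(truth, .data$protein_id, .data$position)
  proteins <- tibble::tibble(id = ids,
                             sequence = vapply(chars, paste, "", collapse = ""))
  annotations <- tibble::tibble(
    protein_id = truth$protein_id,
    position = truth$position,
    residue = truth$residue,
    label = "positive",
    disease_class = spec$disease_class
  )
  list(proteins = proteins, annotations = annotations,
       truth = truth, spec = spec)
}

#' Write a synthetic dataset to disk
#'
#' Emits `proteins.fasta`, `annotations.tsv` and `truth.tsv` (LF endings)
#' into `dir`.
#'
#' @param synth Result of [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(synth$proteins, file.path(dir, "proteins.fasta"))
  write_annotations(synth$annotations, file.path(dir, "annotations.tsv"))
  readr::write_tsv(synth$truth, file.path(dir, "truth.tsv"), eol = "\n")
  invisible(dir)
}
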