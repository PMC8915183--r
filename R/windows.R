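#' Extract a fixed-length peptide window around a site
#'
#' Returns the peptide of length `2 * flank_n + 1` centred on `position`,
#' padding positions that fall before residue 1 or beyond the terminus
#' with the dummy residue `"X"` so every window has identical length.
#'
#' @param sequence A protein sequence string.
#' @param position 1-based site position; the residue there must be one
#'   of S/T/Y (candidate-site contract).
#' @param flank_n Number of flanking residues on each side (>= 0).
#' @return The window string.
#' @export
#' @examples
#' extract_window("MSTY", 2, 3) # "XXMSTYX"
extract_window <- function(sequence, position, flank_n) {
  if (flank_n < 0) abort("flank_n must be >= 0")
  L <- nchar(sequence)
  if (position < 1 || position > L) {
    abort(paste0("position ", position, " out of range 1..", L))
  }
  centre <- substr(sequence, position, position)
  if (!centre %in% c("S", "T", "Y")) {
    abort(paste0("centre residue at position ", position, " is '", centre,
                 "', not one of S/T/Y"))
  }
  pad <- strrep("X", flank_n)
  substr(paste0(pad, sequence, pad), position, position + 2L * flank_n)
}

#' Extract windows for a table of annotated sites
#'
#' Vectorised [extract_window()] over an annotation tibble.
#'
#' @param proteins Tibble with `id`, `sequence`.
#' @param annotations Annotation tibble (`protein_id`, `position`,
#'   `residue`, `label`, `disease_class`).
#' @param flank_n Flank width; windows have length `2 * flank_n + 1`.
#' @return A window tibble with columns `sequence`, `label`, `residue`,
#'   `protein_id`, `position`, `flank_n`.
#' @export
extract_windows <- function(proteins, annotations, flank_n) {
  check_proteins(proteins)
  seqs <- setNames(proteins$sequence, proteins$id)
  unknown <- setdiff(annotations$protein_id, proteins$id)
  if (length(unknown)) {
    abort(paste0("annotations reference unknown protein(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  full <- seqs[annotations$protein_id]
  centre <- substr(full, annotations$position, annotations$position)
  bad <- !centre %in% c("S", "T", "Y")
  if (any(bad)) {
    abort(paste0("non-S/T/Y centre residue for annotation row(s): ",
                 paste(head(which(bad), 5), collapse = ", ")))
  }
  pad <- strrep("X", flank_n)
  win <- substr(paste0(pad, full, pad),
                annotations$position,
                annotations$position + 2L * flank_n)
  tibble::tibble(
    sequence = unname(win),
    label = annotations$label,
    residue = unname(centre),
    protein_id = annotations$protein_id,
    position = annotations$position,
    flank_n = as.integer(flank_n)
  )
}

#' Remove redundant windows by greedy identity clustering
#'
#' Greedy incremental clustering in input order, analogous to running
#' CD-HIT on equal-length peptides: a window joins the first retained
#' representative whose positionwise (Hamming) identity with it is at
#' least `identity_threshold`, otherwise it becomes a new representative.
#' Identity between equal-length windows is the fraction of matching
#' positions, with `X`-`X` counting as a match. Output order is preserved.
#'
#' @param windows A window tibble (from [extract_windows()]) or a
#'   character vector of equal-length window sequences.
#' @param identity_threshold Fraction in (0, 1]; default 0.7.
#' @return The surviving windows, same type as the input, with attribute
#'   `"n_removed"`.
#' @export
remove_redundancy <- function(windows, identity_threshold = 0.7) {
  seqs <- if (is.data.frame(windows)) windows$sequence else windows
  n <- length(seqs)
  if (n == 0L) return(windows)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) {
    abort("all windows must have equal length for redundancy removal")
  }
  keep <- greedy_identity_filter(seqs, L, identity_threshold)
  out <- if (is.data.frame(windows)) windows[keep, , drop = FALSE] else windows[keep]
  attr(out, "n_removed") <- n - sum(keep)
  out
}

# Greedy representative selection on the ordinal-encoded window matrix.
# Exact duplicates are collapsed first so the O(n_reps) scan only runs
# over distinct sequences.
greedy_identity_filter <- function(seqs, L, threshold) {
  n <- length(seqs)
  first_of_dup <- !duplicated(seqs)
  distinct_idx <- which(first_of_dup)
  mat <- ordinal_matrix(seqs[distinct_idx])
  m <- length(distinct_idx)
  keep_distinct <- logical(m)
  rep_rows <- matrix(0L, nrow = 0L, ncol = L)
  min_matches <- threshold * L
  for (i in seq_len(m)) {
    row <- mat[i, ]
    if (nrow(rep_rows) == 0L) {
      hit <- FALSE
    } else {
      matches <- rowSums(rep_rows == matrix(row, nrow = nrow(rep_rows),
                                            ncol = L, byrow = TRUE))
      hit <- any(matches >= min_matches)
    }
    if (!hit) {
      keep_distinct[i] <- TRUE
      rep_rows <- rbind(rep_rows, row)
    }
  }
  keep <- logical(n)
  keep[distinct_idx[keep_distinct]] <- TRUE
  keep
}

#' Pairwise window identity
#'
#' Positionwise identity between two equal-length windows (`X`-`X`
#' counts as a match).
#'
#' @param a,b Window strings of equal length.
#' @return Fraction of matching positions.
#' @export
window_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("windows must have equal length")
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}

#' Sample residue-type-matched negative sites
#'
#' Builds the negative candidate pool — every position of `residue_type`
#' on positive-bearing proteins that is not itself annotated — extracts
#' windows, removes redundancy within the pool, drops candidates whose
#' window duplicates a (deduplicated) positive window, then draws a
#' uniform random subset of size equal to the deduplicated positive
#' count.
#'
#' @param proteins Protein tibble.
#' @param positive_annotations Positive annotation tibble.
#' @param residue_type One of "S", "T", "Y".
#' @param flank_n Flank width used for window-level deduplication.
#' @param seed Integer seed; the draw is reproducible.
#' @param identity_threshold Dedup threshold (default 0.7).
#' @return An annotation tibble of negatives (`label == "negative"`),
#'   disjoint from the positive (protein, position) pairs.
#' @export
sample_negatives <- function(proteins, positive_annotations, residue_type,
                             flank_n, seed, identity_threshold = 0.7) {
  stopifnot(residue_type %in% c("S", "T", "Y"))
  pos <- dplyr::filter(positive_annotations, .data$residue == residue_type)
  if (!nrow(pos)) abort("no positive annotations of the requested residue type")
  pos_windows <- extract_windows(proteins, pos, flank_n)
  pos_dedup <- remove_redundancy(pos_windows, identity_threshold)
  n_needed <- nrow(pos_dedup)

  carriers <- dplyr::filter(proteins,
                            .data$id %in% unique(positive_annotations$protein_id))
  pool <- candidate_sites(carriers, residue_type)
  taken <- paste(positive_annotations$protein_id, positive_annotations$position)
  pool <- pool[!paste(pool$protein_id, pool$position) %in% taken, , drop = FALSE]
  if (!nrow(pool)) {
    abort("negative candidate pool is empty")
  }
  pool_windows <- extract_windows(carriers, pool, flank_n)
  pool_dedup <- remove_redundancy(pool_windows, identity_threshold)
  pool_dedup <- pool_dedup[!pool_dedup$sequence %in% pos_dedup$sequence, ,
                           drop = FALSE]
  if (nrow(pool_dedup) < n_needed) {
    abort(paste0("negative pool too small: need ", n_needed,
                 ", have ", nrow(pool_dedup), " after deduplication"))
  }
  set.seed(seed)
  pick <- sort(sample.int(nrow(pool_dedup), n_needed))
  sel <- pool_dedup[pick, , drop = FALSE]
  tibble::tibble(
    protein_id = sel$protein_id,
    position = sel$position,
    residue = residue_type,
    label = "negative",
    disease_class = if (nrow(positive_annotations)) positive_annotations$disease_class[1] else NA_character_
  )
}

# All positions of a residue type across proteins, as an annotation-shaped
# tibble with label "candidate".
candidate_sites <- function(proteins, residue_type) {
  hits <- stringr::str_locate_all(proteins$sequence,
                                  stringr::fixed(residue_type))
  n_per <- vapply(hits, nrow, 0L)
  tibble::tibble(
    protein_id = rep(proteins$id, n_per),
    position = as.integer(unlist(lapply(hits, function(h) h[, 1]))),
    residue = residue_type,
    label = "candidate",
    disease_class = NA_character_
  )
}

#' Build a balanced, deduplicated peptide-window dataset
#'
#' The full dataset-construction pipeline for one residue type and
#' disease class: extract positive windows, deduplicate them, sample an
#' equal number of deduplicated negatives, merge and shuffle.
#'
#' @param proteins Protein tibble.
#' @param annotations Annotation tibble (positives; extra labels/classes
#'   are filtered out).
#' @param residue_type "S", "T" or "Y".
#' @param disease_class Class to select (default: all classes present).
#' @param flank_n Flank width; windows have length `2 * flank_n + 1`.
#' @param seed Seed controlling negative sampling and the final shuffle.
#' @param identity_threshold Dedup threshold (default 0.7).
#' @return A window tibble with equal positive and negative counts,
#'   attributes `flank_n`, `residue_type`, `disease_class` and a
#'   `build_log` list of per-stage counts.
#' @export
build_dataset <- function(proteins, annotations, residue_type,
                          disease_class = NULL, flank_n = 20L, seed = 1L,
                          identity_threshold = 0.7) {
  pos_ann <- dplyr::filter(annotations, .data$label == "positive",
                           .data$residue == residue_type)
  if (!is.null(disease_class)) {
    pos_ann <- dplyr::filter(pos_ann, .data$disease_class == !!disease_class)
  }
  if (!nrow(pos_ann)) abort("no positive annotations after filtering")
  pos_w <- extract_windows(proteins, pos_ann, flank_n)
  pos_d <- remove_redundancy(pos_w, identity_threshold)
  neg_ann <- sample_negatives(proteins, pos_ann, residue_type, flank_n,
                              seed = seed,
                              identity_threshold = identity_threshold)
  neg_w <- extract_windows(proteins, neg_ann, flank_n)
  merged <- dplyr::bind_rows(pos_d, neg_w)
  set.seed(seed + 1L)
  merged <- merged[sample.int(nrow(merged)), , drop = FALSE]
  attr(merged, "flank_n") <- as.integer(flank_n)
  attr(merged, "residue_type") <- residue_type
  attr(merged, "disease_class") <- disease_class %||% pos_ann$disease_class[1]
  attr(merged, "build_log") <- list(
    positives_in = nrow(pos_w),
    positives_dedup = nrow(pos_d),
    negatives = nrow(neg_w),
    total = nrow(merged)
  )
  merged
}

#' Serialize a window dataset
#'
#' Writes the window tibble as TSV and, optionally, as FASTA with
#' structured headers `>{protein_id}|{position}|{label}`.
#'
#' @param dataset Window tibble.
#' @param path Output TSV path.
#' @param fasta Optional FASTA output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, fasta = NULL) {
  readr::write_tsv(dataset, path, eol = "\n")
  if (!is.null(fasta)) {
    recs <- tibble::tibble(
      id = paste(dataset$protein_id, dataset$position, dataset$label,
                 sep = "|"),
      sequence = dataset$sequence
    )
    write_fasta(recs, fasta)
  }
  invisible(path)
}
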