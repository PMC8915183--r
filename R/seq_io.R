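#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a tibble of protein records. Sequences are
#' upper-cased and any non-canonical letter (`B`, `Z`, `U`, `J`, `O`, `*`,
#' and anything else outside the 20 one-letter codes) is mapped to the
#' unknown/padding symbol `"X"`. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header) and `sequence`.
#' @seealso [write_fasta()], [read_annotations()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "MSTY", ">b", "PPSP"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  aa <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- toupper(as.character(aa))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate FASTA ids: ", paste(dup, collapse = ", ")))
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(paste0("empty sequence for record(s): ",
                 paste(ids[empty], collapse = ", ")))
  }
  seqs <- sanitize_sequence(seqs)
  tibble::tibble(id = unname(ids), sequence = unname(seqs))
}

#' Map non-canonical residue letters to 'X'
#'
#' @param x Character vector of amino-acid sequences.
#' @return The sequences with every character outside the 20 canonical
#'   one-letter codes replaced by `"X"`.
#' @export
sanitize_sequence <- function(x) {
  stringr::str_replace_all(toupper(x),
                           paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
                           "X")
}

#' Write protein records to a FASTA file
#'
#' Writes with LF line endings and no sequence wrapping, so that
#' `read_fasta(write_fasta(x, f))` round-trips sequences exactly.
#'
#' @param proteins Tibble with columns `id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  check_proteins(proteins)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0(">", proteins$id, "\n", proteins$sequence),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

check_proteins <- function(proteins) {
  if (!all(c("id", "sequence") %in% names(proteins))) {
    abort("`proteins` must have columns `id` and `sequence`")
  }
  invisible(proteins)
}

#' Read a site-annotation table
#'
#' Reads a TSV with columns `protein_id`, `position`, `residue`, `label`,
#' `disease_class` and validates each row against the protein sequences:
#' the position must be in range and the sequence character at that
#' position must equal `residue`. Invalid rows are dropped and reported.
#'
#' @param path Path to a tab-separated annotation file with a header.
#' @param proteins Optional tibble from [read_fasta()]; when supplied,
#'   rows are validated against the sequences.
#' @return A tibble of accepted annotations. The tibble of rejected rows
#'   (with a `reason` column) is attached as attribute `"rejected"`.
#' @export
read_annotations <- function(path, proteins = NULL) {
  if (!file.exists(path)) {
    abort(paste0("annotation file not found: ", path))
  }
  ann <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    position = readr::col_integer(),
    residue = readr::col_character(),
    label = readr::col_character(),
    disease_class = readr::col_character()
  ))
  required <- c("protein_id", "position", "residue", "label", "disease_class")
  missing <- setdiff(required, names(ann))
  if (length(missing)) {
    abort(paste0("annotation file lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad_res <- !ann$residue %in% c("S", "T", "Y")
  if (any(bad_res)) {
    abort(paste0("unknown residue code(s) in rows: ",
                 paste(which(bad_res), collapse = ", "),
                 " (must be S, T or Y)"))
  }
  if (is.null(proteins)) {
    return(ann)
  }
  validate_annotations(ann, proteins)
}

#' Validate annotations against protein sequences
#'
#' @param annotations Tibble with the five annotation columns.
#' @param proteins Tibble with `id`, `sequence`.
#' @return Accepted rows; rejected rows (with `reason`) as attribute
#'   `"rejected"`.
#' @export
validate_annotations <- function(annotations, proteins) {
  check_proteins(proteins)
  seqs <- setNames(proteins$sequence, proteins$id)
  len <- nchar(seqs)[annotations$protein_id]
  reason <- rep(NA_character_, nrow(annotations))
  unknown <- !annotations$protein_id %in% proteins$id
  reason[unknown] <- "unknown protein_id"
  oob <- !unknown & (annotations$position < 1L | annotations$position > len)
  reason[oob] <- "position out of range"
  ok_so_far <- is.na(reason)
  at <- rep(NA_character_, nrow(annotations))
  at[ok_so_far] <- substr(seqs[annotations$protein_id[ok_so_far]],
                          annotations$position[ok_so_far],
                          annotations$position[ok_so_far])
  mismatch <- ok_so_far & at != annotations$residue
  reason[mismatch] <- paste0("sequence has '", at[mismatch],
                             "' at position, not '",
                             annotations$residue[mismatch], "'")
  accepted <- annotations[is.na(reason), , drop = FALSE]
  rejected <- annotations[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  if (nrow(rejected)) {
    warn(paste0(nrow(rejected),
                " annotation row(s) rejected; see attr(x, \"rejected\")"))
  }
  attr(accepted, "rejected") <- rejected
  accepted
}

#' Write a site-annotation table
#'
#' @param annotations Annotation tibble.
#' @param path Output path; written as TSV with LF endings.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path, eol = "\n")
  invisible(path)
}
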