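#' One-hot encode a peptide window
#'
#' Encodes a window string as a 20-row binary matrix: row order is the
#' fixed alphabetical amino-acid ordering ([AA_ALPHABET]), one column per
#' window position. The padding symbol `"X"` yields an all-zero column,
#' keeping the convolution filter height at exactly 20.
#'
#' @param window A window string over the 20 letters and `"X"`.
#' @return A 20 x L matrix of 0/1 with rownames [AA_ALPHABET].
#' @seealso [onehot_decode()], [ordinal_encode()]
#' @export
onehot_encode <- function(window) {
  codes <- ordinal_encode(window)
  L <- length(codes)
  m <- matrix(0L, nrow = 20L, ncol = L, dimnames = list(AA_ALPHABET, NULL))
  hit <- codes > 0L
  m[cbind(codes[hit], which(hit))] <- 1L
  m
}

#' Decode a one-hot matrix back to a window string
#'
#' @param mat A 20 x L one-hot matrix (all-zero columns decode to `"X"`).
#' @return The window string.
#' @export
onehot_decode <- function(mat) {
  stopifnot(nrow(mat) == 20L)
  idx <- apply(mat, 2, function(col) {
    w <- which(col == 1L)
    if (length(w) == 0L) 0L else w[1]
  })
  ordinal_decode(idx)
}

#' Ordinal ("dictionary") encode a peptide window
#'
#' Maps each residue to an integer code: `"X"` to 0 and the 20 canonical
#' amino acids to 1..20 in alphabetical one-letter order (A=1, C=2, ...,
#' Y=20), yielding an L-dimensional vector. This is the feature
#' representation used by the classical machine-learning baselines.
#'
#' @param window A window string.
#' @return An integer vector of length `nchar(window)` with values 0..20.
#' @export
#' @examples
#' ordinal_encode("XXAXX") # 0 0 1 0 0
ordinal_encode <- function(window) {
  ch <- strsplit(window, "")[[1]]
  codes <- unname(.aa_code[ch])
  codes[is.na(codes)] <- 0L
  as.integer(codes)
}

#' Decode an ordinal vector back to a window string
#'
#' @param codes Integer vector with values 0..20.
#' @return The window string (0 decodes to `"X"`).
#' @export
ordinal_decode <- function(codes) {
  paste(c("X", AA_ALPHABET)[codes + 1L], collapse = "")
}

#' Ordinal-encode many windows into a matrix
#'
#' @param windows Character vector (or window tibble) of equal-length
#'   windows.
#' @return An n x L integer matrix, one row per window.
#' @export
ordinal_matrix <- function(windows) {
  seqs <- if (is.data.frame(windows)) windows$sequence else windows
  L <- unique(nchar(seqs))
  if (length(L) != 1L) abort("all windows must have equal length")
  ch <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs), byrow = TRUE)
  codes <- .aa_code[ch]
  codes[is.na(codes)] <- 0L
  matrix(as.integer(codes), nrow = length(seqs), ncol = L)
}

#' One-hot encode many windows into a flat matrix
#'
#' Flattens each window's 20 x L one-hot matrix column-major into a row
#' of length `20 * L` (position-major blocks of 20). This is the feature
#' representation used for K-means clustering of peptides.
#'
#' @param windows Character vector or window tibble.
#' @return An n x (20 * L) numeric matrix.
#' @export
onehot_matrix <- function(windows) {
  om <- ordinal_matrix(windows)
  n <- nrow(om)
  L <- ncol(om)
  out <- matrix(0, nrow = n, ncol = 20L * L)
  hit <- which(om > 0L, arr.ind = TRUE)
  cols <- (hit[, 2] - 1L) * 20L + om[hit]
  out[cbind(hit[, 1], cols)] <- 1
  out
}

#' The residue-to-code table
#'
#' @return A tibble with columns `letter` and `code` (X = 0, A..Y =
#'   1..20); the same table ships as a JSON asset in
#'   `system.file("extdata", "aa_index.json", package = "phoscnn")`.
#' @export
aa_index_table <- function() {
  tibble::tibble(letter = c("X", AA_ALPHABET), code = 0:20)
}
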