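#' Global percent identity between two protein sequences
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gap
#' penalties, reported as EMBOSS-style percent identity: identical aligned
#' positions divided by the full alignment length, gap columns included.
#'
#' @param seq_a,seq_b Amino-acid strings (standard alphabet; `X` tolerated).
#' @param gap_open,gap_extend Affine gap penalties (defaults 10 and 0.5,
#'   the usual protein-alignment defaults).
#' @return Percent identity in `[0, 100]`.
#' @export
#' @examples
#' global_identity("HEAGAWGHEE", "HEAGAWGHEE")  # 100
#' global_identity("AAAA", "CCCC")              # 0
global_identity <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.5) {
  for (s in list(seq_a, seq_b)) {
    if (!is.character(s) || length(s) != 1L || !nzchar(s))
      stop("sequences must be non-empty character scalars")
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", toupper(s)))
      stop("sequence contains non-amino-acid characters: ",
           gsub("[ACDEFGHIKLMNPQRSTVWYX]", "", toupper(s)))
  }
  al <- pairwiseAlignment(AAString(toupper(seq_a)), AAString(toupper(seq_b)),
                          substitutionMatrix = blosum62(),
                          gapOpening = gap_open, gapExtension = gap_extend,
                          type = "global")
  aln_len <- nchar(as.character(alignedPattern(al)))
  100 * nmatch(al) / aln_len
}

# BLOSUM62 matrix shipped with Biostrings, fetched once per session.
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Build the sequence-similarity descriptor block (P0)
#'
#' Each panel target is described by its global percent identity to every
#' reference sequence; for the HDAC panel against the eleven classical
#' isoforms this gives the 5 x 11 block.
#'
#' @param panel_seqs Named character vector, one amino-acid sequence per
#'   panel target.
#' @param reference_seqs Named character vector of reference sequences
#'   (columns of the block).
#' @param ... Passed to [global_identity()].
#' @return Numeric matrix (targets x references) of percent identities.
#' @export
build_p0 <- function(panel_seqs, reference_seqs, ...) {
  if (is.null(names(panel_seqs)) || is.null(names(reference_seqs)))
    stop("panel_seqs and reference_seqs must be named")
  if (any(!nzchar(panel_seqs)) || any(!nzchar(reference_seqs)))
    stop("missing (empty) sequence in input")
  if (anyDuplicated(names(reference_seqs)))
    warning("duplicate reference ids; all columns kept")
  out <- matrix(NA_real_, length(panel_seqs), length(reference_seqs),
                dimnames = list(names(panel_seqs), names(reference_seqs)))
  for (i in seq_along(panel_seqs))
    for (j in seq_along(reference_seqs))
      out[i, j] <- global_identity(panel_seqs[[i]], reference_seqs[[j]], ...)
  out
}

#' Read a protein similarity matrix from CSV
#'
#' Loads a rectangular similarity matrix with row and column headers (rows
#' are panel targets, columns reference entries).  For similarity scales
#' with a known self-similarity value (1 for structure-alignment fractions,
#' 100 for percent identity), the diagonal over shared ids is validated.
#'
#' @param path CSV file; first column holds the row ids.
#' @param self_value Expected self-similarity on shared row/column ids, or
#'   `NULL` to skip the check.
#' @param tol Tolerance for the self-similarity check.
#' @return Numeric matrix with row and column names.
#' @export
read_similarity_matrix <- function(path, self_value = NULL, tol = 1e-9) {
  if (!file.exists(path)) stop("similarity matrix file not found: ", path)
  raw <- read.csv(path, row.names = 1, check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(raw)
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "double")
    if (anyNA(m)) stop("non-numeric cell in similarity matrix ", path)
  }
  if (anyNA(m)) stop("missing value in similarity matrix ", path)
  if (any(m < 0)) stop("negative similarity value in ", path)
  if (!is.null(self_value)) {
    shared <- intersect(rownames(m), colnames(m))
    for (id in shared)
      if (abs(m[id, id] - self_value) > tol)
        stop("self-similarity of ", id, " is ", m[id, id],
             ", expected ", self_value)
  }
  m
}

#' Shipped HDAC sequence-similarity block (P0)
#'
#' The 5 x 11 percent-identity block for the modeled panel against all
#' eleven classical HDAC isoforms, as shipped with the package.
#'
#' @return 5 x 11 numeric matrix.
#' @export
hdac_p0 <- function() {
  read_similarity_matrix(
    system.file("extdata", "hdac_p0_identity.csv", package = "hdacpcm",
                mustWork = TRUE),
    self_value = 100, tol = 1e-9)
}

#' Shipped HDAC structure-similarity block (P1)
#'
#' The 5 x 5 pairwise structure-alignment similarity block for the modeled
#' panel.  Structure similarities are ingested, not computed: any user
#' matrix passing [read_similarity_matrix()] validation can substitute.
#'
#' @return 5 x 5 numeric matrix with unit diagonal.
#' @export
hdac_p1 <- function() {
  read_similarity_matrix(
    system.file("extdata", "hdac_p1_structure.csv", package = "hdacpcm",
                mustWork = TRUE),
    self_value = 1, tol = 1e-9)
}
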