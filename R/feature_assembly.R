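# Pair-level design-matrix assembly.
#
# A model specification names a protein block, a ligand block and a mode:
# the two blocks side by side ("P1-GD"), the blocks plus all multiplicative
# protein x ligand cross-terms ("P1-GD-C"), or the cross-terms alone
# ("C(P1,GD)").  Three protein blocks x two ligand blocks x three modes
# gives the canonical grid of 18 specifications.

.block_modes <- c("blocks_only", "blocks_plus_cross", "cross_only")

#' Construct a model specification
#'
#' @param protein Protein block label (conventionally `"P0"`, `"P1"`,
#'   `"P2"`; any label naming an entry of a block list is allowed).
#' @param ligand Ligand block label (conventionally `"GD"` or `"DLI"`).
#' @param mode One of `"blocks_only"`, `"blocks_plus_cross"`,
#'   `"cross_only"`.
#' @return An object of class `"pcm_spec"` with fields `protein`, `ligand`,
#'   `mode` and the rendered `name`.
#' @export
#' @examples
#' model_spec("P1", "GD", "blocks_plus_cross")$name  # "P1-GD-C"
model_spec <- function(protein, ligand, mode = .block_modes) {
  mode <- match.arg(mode)
  name <- switch(mode,
    blocks_only       = paste0(protein, "-", ligand),
    blocks_plus_cross = paste0(protein, "-", ligand, "-C"),
    cross_only        = paste0("C(", protein, ",", ligand, ")"))
  structure(list(name = name, protein = protein, ligand = ligand,
                 mode = mode), class = "pcm_spec")
}

#' Parse a model-specification name
#'
#' Accepts the rendered names produced by [model_spec()] (`"P1-GD"`,
#' `"P1-GD-C"`, `"C(P1,GD)"`) or an existing `pcm_spec`.
#'
#' @param x Name string or `pcm_spec`.
#' @return A `pcm_spec`.
#' @export
as_model_spec <- function(x) {
  if (inherits(x, "pcm_spec")) return(x)
  if (!is.character(x) || length(x) != 1L) stop("cannot parse model spec")
  if (grepl("^C\\(.+,.+\\)$", x)) {
    inner <- strsplit(sub("^C\\((.+)\\)$", "\\1", x), ",")[[1]]
    return(model_spec(trimws(inner[1]), trimws(inner[2]), "cross_only"))
  }
  parts <- strsplit(x, "-", fixed = TRUE)[[1]]
  if (length(parts) == 3 && parts[3] == "C")
    return(model_spec(parts[1], parts[2], "blocks_plus_cross"))
  if (length(parts) == 2)
    return(model_spec(parts[1], parts[2], "blocks_only"))
  stop("cannot parse model spec name: ", x)
}

#' @export
print.pcm_spec <- function(x, ...) {
  cat("PCM model spec:", x$name, "\n  protein block:", x$protein,
      "\n  ligand block: ", x$ligand, "\n  mode:         ", x$mode, "\n")
  invisible(x)
}

#' Enumerate the 18 canonical model specifications
#'
#' All combinations of the three protein blocks (P0, P1, P2), the two
#' ligand blocks (DLI, GD) and the three assembly modes.
#'
#' @return List of 18 `pcm_spec` objects, in a fixed deterministic order.
#' @export
model_specs <- function() {
  out <- list()
  for (mode in .block_modes)
    for (p in c("P0", "P1", "P2"))
      for (l in c("DLI", "GD"))
        out[[length(out) + 1L]] <- model_spec(p, l, mode)
  out
}

#' Center and scale descriptor columns
#'
#' Standardizes each column to zero mean and unit sample variance using
#' statistics from a fitting subset of rows (normally the training pairs).
#' Constant columns (sd below 1e-12) are centered only and flagged, so the
#' block dimensionality never changes.
#'
#' @param x Numeric matrix.
#' @param fit_rows Row indices on which the statistics are computed
#'   (default: all rows).
#' @return List with `values` (scaled matrix), `center`, `scale` and
#'   logical `constant` per column.
#' @export
center_scale <- function(x, fit_rows = seq_len(nrow(x))) {
  if (length(fit_rows) == 0L) stop("empty fitting subset")
  x <- as.matrix(x)
  ctr <- colMeans(x[fit_rows, , drop = FALSE])
  s <- apply(x[fit_rows, , drop = FALSE], 2, sd)
  if (length(fit_rows) == 1L) s <- rep(NA_real_, ncol(x))
  const <- !is.finite(s) | s < 1e-12
  s[const] <- 1
  values <- sweep(sweep(x, 2, ctr, "-"), 2, s, "/")
  list(values = values, center = ctr, scale = s, constant = const)
}

#' Protein-ligand cross-terms
#'
#' The flattened outer product of a (centered and scaled) protein
#' descriptor vector with a ligand descriptor vector, in protein-major
#' order: element `(i-1) * d_l + j` is `p_i * l_j`.  Matrix inputs are
#' processed row-wise.
#'
#' @param protein Numeric vector of length `d_p`, or matrix (n x `d_p`).
#' @param ligand Numeric vector of length `d_l`, or matrix (n x `d_l`)
#'   with matching row count.
#' @return Vector of length `d_p * d_l`, or matrix (n x `d_p * d_l`).
#' @export
#' @examples
#' make_crossterms(c(1, 2), c(3, 4))  # 3 4 6 8
make_crossterms <- function(protein, ligand) {
  if (is.matrix(protein) || is.matrix(ligand)) {
    protein <- as.matrix(protein); ligand <- as.matrix(ligand)
    if (nrow(protein) != nrow(ligand)) stop("row count mismatch")
    dp <- ncol(protein); dl <- ncol(ligand)
    out <- protein[, rep(seq_len(dp), each = dl), drop = FALSE] *
      ligand[, rep(seq_len(dl), times = dp), drop = FALSE]
    colnames(out) <- paste(rep(colnames(protein) %||% paste0("p", 1:dp),
                               each = dl),
                           rep(colnames(ligand) %||% paste0("l", 1:dl),
                               times = dp), sep = "x")
    return(out)
  }
  as.numeric(rep(protein, each = length(ligand)) *
               rep(ligand, length(protein)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the pair-level design matrix for a model specification
#'
#' Expands the protein and ligand descriptor blocks to one row per
#' compound-target pair, standardizes every column on the training pairs,
#' forms cross-terms from the standardized sections (cross-term columns
#' are not re-standardized), and concatenates the sections according to the
#' specification mode.
#'
#' @param spec A `pcm_spec` or spec name.
#' @param protein_block Numeric matrix, targets x d_p, row names =
#'   target ids.
#' @param ligand_block Numeric matrix, compounds x d_l, row names =
#'   compound ids.
#' @param records Record data frame with `compound_id`, `target_id` and a
#'   `split` column.
#' @param fit_on `"train"` (default) to fit column statistics on training
#'   pairs only, or `"all"` to fit on every pair.
#' @return Object of class `"pcm_features"`: list with `values`
#'   (n_pairs x D), `pair_index`, `block_slices`, `scaling` and `spec`.
#' @export
assemble_features <- function(spec, protein_block, ligand_block, records,
                              fit_on = c("train", "all")) {
  spec <- as_model_spec(spec)
  fit_on <- match.arg(fit_on)
  pi_ <- match(records$target_id, rownames(protein_block))
  li <- match(records$compound_id, rownames(ligand_block))
  if (anyNA(pi_))
    stop("missing protein descriptor row for pair ",
         records$compound_id[which(is.na(pi_))[1]], "/",
         records$target_id[which(is.na(pi_))[1]])
  if (anyNA(li))
    stop("missing ligand descriptor row for pair ",
         records$compound_id[which(is.na(li))[1]], "/",
         records$target_id[which(is.na(li))[1]])
  fit_rows <- if (fit_on == "train") which(records$split == "train")
              else seq_len(nrow(records))
  if (length(fit_rows) == 0L)
    stop("no training pairs to fit scaling on; split the records first ",
         "or use fit_on = 'all'")
  P <- as.matrix(protein_block)[pi_, , drop = FALSE]
  L <- as.matrix(ligand_block)[li, , drop = FALSE]
  colnames(P) <- colnames(protein_block) %||%
    paste0("p", seq_len(ncol(P)))
  colnames(L) <- colnames(ligand_block) %||%
    paste0("l", seq_len(ncol(L)))
  csP <- center_scale(P, fit_rows)
  csL <- center_scale(L, fit_rows)
  dp <- ncol(P); dl <- ncol(L)
  sections <- switch(spec$mode,
    blocks_only       = list(protein = csP$values, ligand = csL$values),
    blocks_plus_cross = list(protein = csP$values, ligand = csL$values,
                             cross = make_crossterms(csP$values,
                                                     csL$values)),
    cross_only        = list(cross = make_crossterms(csP$values,
                                                     csL$values)))
  values <- do.call(cbind, sections)
  slices <- list(); at <- 0L
  for (nm in names(sections)) {
    slices[[nm]] <- at + seq_len(ncol(sections[[nm]]))
    at <- at + ncol(sections[[nm]])
  }
  colnames(values) <- unlist(lapply(sections, colnames), use.names = FALSE)
  structure(list(
    values = values,
    pair_index = records[, c("compound_id", "target_id")],
    block_slices = slices,
    scaling = list(protein = csP[c("center", "scale", "constant")],
                   ligand = csL[c("center", "scale", "constant")]),
    d_p = dp, d_l = dl, spec = spec, fit_rows = fit_rows),
    class = "pcm_features")
}

# Apply a fitted feature scaling to new pairs (used at prediction time).
apply_feature_scaling <- function(features, protein_block, ligand_block,
                                  pairs) {
  spec <- features$spec
  pi_ <- match(pairs$target_id, rownames(protein_block))
  li <- match(pairs$compound_id, rownames(ligand_block))
  if (anyNA(pi_) || anyNA(li))
    stop("missing descriptor row for a requested pair")
  P <- as.matrix(protein_block)[pi_, , drop = FALSE]
  L <- as.matrix(ligand_block)[li, , drop = FALSE]
  sp <- features$scaling$protein; sl <- features$scaling$ligand
  P <- sweep(sweep(P, 2, sp$center, "-"), 2, sp$scale, "/")
  L <- sweep(sweep(L, 2, sl$center, "-"), 2, sl$scale, "/")
  switch(spec$mode,
    blocks_only       = cbind(P, L),
    blocks_plus_cross = cbind(P, L, make_crossterms(P, L)),
    cross_only        = make_crossterms(P, L))
}

#' @export
print.pcm_features <- function(x, ...) {
  cat("PCM feature matrix (", x$spec$name, "): ",
      nrow(x$values), " pairs x ", ncol(x$values), " features [",
      paste(names(x$block_slices), lengths(x$block_slices),
            sep = "=", collapse = ", "), "]\n", sep = "")
  invisible(x)
}
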