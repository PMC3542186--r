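#' The modeled HDAC panel
#'
#' The five classical HDAC isoforms with solved catalytic-domain crystal
#' structures that form the default modeling panel, with their class
#' assignment, PDB entry, NCBI protein accession and sequence length.
#'
#' @return A data frame with columns `target_id`, `hdac_class`
#'   (one of `"I"`, `"IIa"`, `"IIb"`, `"IV"`), `pdb_id`, `ncbi_entry`
#'   and `length_aa`.
#' @seealso [hdac_family()] for all eleven classical isoforms.
#' @export
#' @examples
#' hdac_panel()
hdac_panel <- function() {
  data.frame(
    target_id  = c("HDAC2", "HDAC4", "HDAC6", "HDAC7", "HDAC8"),
    hdac_class = c("I", "IIa", "IIb", "IIa", "I"),
    pdb_id     = c("3MAX", "2VQJ", "3C5K", "3C0Z", "1T69"),
    ncbi_entry = c("NP_001518", "NP_006028", "NP_006035", "NP_056216",
                   "NP_060956"),
    length_aa  = c(488L, 1084L, 1215L, 991L, 377L),
    stringsAsFactors = FALSE
  )
}

#' All eleven classical HDAC isoforms
#'
#' The full zinc-dependent HDAC family used as the reference set for the
#' sequence-similarity descriptor block (one column per isoform).
#'
#' @return A data frame with columns `target_id`, `hdac_class`,
#'   `ncbi_entry` and `length_aa`.
#' @export
hdac_family <- function() {
  data.frame(
    target_id  = paste0("HDAC", 1:11),
    hdac_class = c("I", "I", "I", "IIa", "IIa", "IIb", "IIa", "I", "IIa",
                   "IIb", "IV"),
    ncbi_entry = c("NP_004955", "NP_001518", "NP_003874", "NP_006028",
                   "NP_005465", "NP_006035", "NP_056216", "NP_060956",
                   "NP_478056", "NP_114408", "NP_079103"),
    length_aa  = c(482L, 488L, 428L, 1084L, 1122L, 1215L, 991L, 377L,
                   1011L, 669L, 347L),
    stringsAsFactors = FALSE
  )
}

#' Read a target-panel definition file
#'
#' @param path CSV file with columns `target_id`, `hdac_class` and
#'   optionally `pdb_id` and `fasta_path`.
#' @return A data frame with one row per target.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  pan <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("target_id", "hdac_class")
  if (!all(need %in% names(pan)))
    stop("panel file must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(pan$target_id))
    stop("duplicate target_id in panel file")
  pan
}

#' Convert IC50 in nanomolar to pIC50
#'
#' pIC50 is the negative decadic logarithm of the molar IC50, so an IC50
#' given in nanomolar maps to `9 - log10(ic50_nm)`: 1000 nM (1 uM) gives 6,
#' 1 nM gives 9.
#'
#' @param ic50_nm Numeric vector of IC50 values in nM; must be positive.
#' @return Numeric vector of pIC50 values.
#' @export
#' @examples
#' to_pic50(c(1000, 1, 50))
to_pic50 <- function(ic50_nm) {
  if (!is.numeric(ic50_nm)) stop("ic50_nm must be numeric")
  if (any(!is.finite(ic50_nm)) || any(ic50_nm <= 0))
    stop("ic50_nm must be finite and strictly positive")
  9 - log10(ic50_nm)
}

# Light-weight syntactic screen for SMILES strings: character set plus
# balanced () and [].  Chemical validity is checked later, when descriptors
# are computed.
smiles_plausible <- function(s) {
  ok <- !is.na(s) & nzchar(s) &
    grepl("^[A-Za-z0-9@+=#$%.:*/\\\\()\\[\\]-]+$", s, perl = TRUE)
  bal <- function(x, open, close) {
    v <- strsplit(x, "")[[1]]
    depth <- cumsum((v == open) - (v == close))
    all(depth >= 0) && depth[length(depth)] == 0
  }
  ok & vapply(ifelse(is.na(s), "", s), function(x) {
    nzchar(x) && bal(x, "(", ")") && bal(x, "[", "]")
  }, logical(1))
}

#' Load a compound-target activity table
#'
#' Reads a CSV with columns `compound_id`, `smiles`, `target_id`, `ic50_nm`
#' into a record table, dropping (and tallying) rows with non-positive or
#' missing IC50, syntactically implausible SMILES, or targets outside the
#' panel.  Duplicate (compound, target) pairs are an error, as each pair
#' must carry exactly one measured affinity.
#'
#' @param path CSV file path.
#' @param panel Character vector of admissible target ids, or a panel data
#'   frame with a `target_id` column.  Default: the built-in HDAC panel.
#' @param quiet If `TRUE`, suppress the rejection-tally message.
#' @return A data frame with columns `compound_id`, `smiles`, `target_id`,
#'   `ic50_nm`, `pic50`, `y_scaled` (NA until [scale_response()]) and
#'   `split` (`"unassigned"` until [stratified_split()]).  The rejection
#'   tally is attached as attribute `"rejections"`.
#' @export
read_activities <- function(path, panel = hdac_panel(), quiet = FALSE) {
  if (!file.exists(path)) stop("activity file not found: ", path)
  if (is.data.frame(panel)) panel <- panel$target_id
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "smiles", "target_id", "ic50_nm")
  if (!all(need %in% names(raw)))
    stop("activity file must contain columns: ", paste(need, collapse = ", "))
  raw$ic50_nm <- suppressWarnings(as.numeric(raw$ic50_nm))

  bad_ic50   <- is.na(raw$ic50_nm) | raw$ic50_nm <= 0
  bad_target <- !(raw$target_id %in% panel)
  bad_smiles <- !smiles_plausible(raw$smiles)
  keep <- !(bad_ic50 | bad_target | bad_smiles)
  rejections <- c(
    nonpositive_or_missing_ic50 = sum(bad_ic50),
    unknown_target              = sum(bad_target & !bad_ic50),
    implausible_smiles          = sum(bad_smiles & !bad_ic50 & !bad_target)
  )
  rec <- raw[keep, need]
  if (nrow(rec) == 0L) stop("no valid activity rows after filtering")
  dup <- duplicated(rec[, c("compound_id", "target_id")])
  if (any(dup))
    stop("duplicate (compound_id, target_id) rows, e.g. ",
         rec$compound_id[which(dup)[1]], " / ", rec$target_id[which(dup)[1]])
  rec$pic50 <- to_pic50(rec$ic50_nm)
  rec$y_scaled <- NA_real_
  rec$split <- "unassigned"
  rownames(rec) <- NULL
  if (!quiet && sum(rejections) > 0)
    message("dropped ", sum(rejections), " row(s): ",
            paste(names(rejections), rejections, sep = "=", collapse = ", "))
  attr(rec, "rejections") <- rejections
  rec
}

#' Stratified train/test split
#'
#' Assigns each record to the training or test set by stratified sampling
#' within each target: in a stratum of n pairs, exactly
#' `floor(fraction_train * n)` are labeled `"train"`, the rest `"test"`.
#' Membership is randomized by `seed`.
#'
#' @param records Record data frame (see [read_activities()]); all rows
#'   must be `"unassigned"`.
#' @param fraction_train Training fraction, strictly between 0 and 1
#'   (default 0.65).
#' @param seed Integer seed controlling stratum membership.
#' @return The records with the `split` column filled in; the per-target
#'   count table is attached as attribute `"split_summary"`.
#' @export
stratified_split <- function(records, fraction_train = 0.65, seed = 1) {
  if (!all(records$split == "unassigned"))
    stop("records already carry split labels")
  if (!is.numeric(fraction_train) || length(fraction_train) != 1L ||
      fraction_train <= 0 || fraction_train >= 1)
    stop("fraction_train must lie strictly between 0 and 1")
  set.seed(as.integer(seed))
  for (t in unique(records$target_id)) {
    idx <- which(records$target_id == t)
    n <- length(idx)
    if (n == 0L) {
      warning("empty stratum for target ", t, "; skipped")
      next
    }
    n_train <- floor(fraction_train * n)
    tr <- if (n_train > 0) sample(idx, n_train) else integer(0)
    records$split[idx] <- "test"
    records$split[tr] <- "train"
  }
  attr(records, "split_summary") <- split_summary(records)
  records
}

#' Per-target split counts
#'
#' @param records Record data frame with a `split` column.
#' @return Data frame with columns `target_id`, `total`, `n_train`,
#'   `n_test`.
#' @export
split_summary <- function(records) {
  tg <- sort(unique(records$target_id))
  out <- data.frame(
    target_id = tg,
    total   = vapply(tg, function(t) sum(records$target_id == t), integer(1)),
    n_train = vapply(tg, function(t)
      sum(records$target_id == t & records$split == "train"), integer(1)),
    n_test  = vapply(tg, function(t)
      sum(records$target_id == t & records$split == "test"), integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Center and scale the pIC50 response
#'
#' Standardizes pIC50 to zero mean and unit variance.  The mean and the
#' sample (n-1) standard deviation are estimated on the training subset by
#' default, so no test-set information leaks into the response scale;
#' `fit_on = "all"` uses every record.
#'
#' @param records Record data frame with `pic50` filled in.
#' @param fit_on `"train"` (default) or `"all"`: the subset on which the
#'   scaling parameters are estimated.
#' @return The records with `y_scaled` filled in; the parameters are
#'   attached as attribute `"response_scaling"` (named vector `mean`, `sd`).
#' @export
scale_response <- function(records, fit_on = c("train", "all")) {
  fit_on <- match.arg(fit_on)
  idx <- if (fit_on == "train") which(records$split == "train")
         else seq_len(nrow(records))
  if (length(idx) == 0L)
    stop("no records in the '", fit_on, "' fitting subset; ",
         "run stratified_split() first or use fit_on = 'all'")
  if (length(idx) < 2L) stop("need at least 2 records to fit the scaling")
  m <- mean(records$pic50[idx])
  s <- sd(records$pic50[idx])
  if (!is.finite(s) || s < 1e-12)
    stop("degenerate response scaling: pIC50 variance is zero in the ",
         "fitting subset")
  records$y_scaled <- (records$pic50 - m) / s
  attr(records, "response_scaling") <- c(mean = m, sd = s)
  records
}

#' Invert the response scaling
#'
#' @param y_scaled Numeric vector on the standardized scale.
#' @param scaling Named vector `c(mean =, sd =)` as returned in the
#'   `"response_scaling"` attribute of [scale_response()].
#' @return pIC50 values.
#' @export
unscale_response <- function(y_scaled, scaling) {
  y_scaled * scaling[["sd"]] + scaling[["mean"]]
}

#' Write a record table back to CSV
#'
#' Emits the same columns as the input activity table plus the `split`
#' label, so a split data set can be archived and reloaded.
#'
#' @param records Record data frame.
#' @param path Output CSV path.
#' @export
write_activities <- function(records, path) {
  cols <- intersect(c("compound_id", "smiles", "target_id", "ic50_nm",
                      "pic50", "split"), names(records))
  write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
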