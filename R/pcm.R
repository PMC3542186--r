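# The user-facing proteochemometric model: one fitting function returning
# a classed object with the usual modeling methods.

#' Fit a proteochemometric model
#'
#' Assembles the pair-level design matrix for a model specification from a
#' protein block and a ligand block, standardizes the response, and trains
#' an epsilon-insensitive support vector regression under the Pearson VII
#' kernel on the training pairs.  Goodness of fit (R2 on training pairs)
#' and external predictive ability (Q2 on test pairs, when a test split
#' exists) are computed immediately; fold cross-validation is available
#' through [cross_validate()].
#'
#' @param records Record data frame (see [read_activities()] or
#'   [generate_dataset()]).  If no split labels are present and
#'   `fraction_train` is given, a stratified split is drawn first.
#' @param protein_block Targets x d_p descriptor matrix (row names =
#'   target ids).
#' @param ligand_block Compounds x d_l descriptor matrix (row names =
#'   compound ids).
#' @param spec Model specification (name or [model_spec()]); default
#'   `"P1-GD"`.
#' @param puk Kernel parameters ([puk_params()]).
#' @param svr Regression parameters ([svr_params()]).
#' @param fraction_train Training fraction for the stratified split when
#'   the records are unassigned (default 0.65); ignored when split labels
#'   exist.
#' @param seed Seed for the stratified split.
#' @param scale_fit_on `"train"` (default) or `"all"`: subset used to fit
#'   the response and descriptor scaling.
#' @return Object of class `"pcm"` with `print`, `summary`, `predict`,
#'   `fitted`, `residuals`, `coef`, `plot` and `simulate` methods.
#' @export
#' @examples
#' syn <- generate_dataset(synth_config(seed = 7))
#' fit <- pcm(syn$records, syn$protein_block, syn$ligand_block,
#'            spec = model_spec("P", "L", "blocks_only"),
#'            puk = puk_params(sigma = "median", sigma_scale = 12),
#'            svr = svr_params(cost = 1000))
#' fit
pcm <- function(records, protein_block, ligand_block, spec = "P1-GD",
                puk = puk_params(), svr = svr_params(),
                fraction_train = 0.65, seed = 1,
                scale_fit_on = c("train", "all")) {
  spec <- as_model_spec(spec)
  scale_fit_on <- match.arg(scale_fit_on)
  if (all(records$split == "unassigned")) {
    if (!is.null(fraction_train) && fraction_train < 1) {
      records <- stratified_split(records, fraction_train, seed)
    } else {
      records$split <- "train"
    }
  }
  if (is.null(attr(records, "response_scaling")))
    records <- scale_response(records, fit_on = scale_fit_on)
  features <- assemble_features(spec, protein_block, ligand_block, records,
                                fit_on = scale_fit_on)
  tr <- which(records$split == "train")
  te <- which(records$split == "test")
  fit <- train_svr(features$values[tr, , drop = FALSE],
                   records$y_scaled[tr], puk, svr)
  pred <- rep(NA_real_, nrow(records))
  pred[tr] <- fit$fitted
  if (length(te))
    pred[te] <- predict(fit, features$values[te, , drop = FALSE])
  ytr_mean <- mean(records$y_scaled[tr])
  metrics <- list(
    r2_train = q_squared(records$y_scaled[tr], pred[tr], ytr_mean),
    q2_test = if (length(te) >= 2)
      q_squared(records$y_scaled[te], pred[te], ytr_mean) else NA_real_,
    q2_cv = NA_real_,
    n_train = length(tr), n_test = length(te))
  structure(list(
    spec = spec, model = fit, features = features,
    records = cbind(records, .pred = pred),
    response_scaling = attr(records, "response_scaling"),
    protein_block = protein_block, ligand_block = ligand_block,
    metrics = metrics, call = match.call()), class = "pcm")
}

#' PRESS-based predictive squared correlation
#'
#' `Q2 = 1 - sum((y_obs - y_pred)^2) / sum((y_obs - y_ref_mean)^2)`.  With
#' predictions on the training data and the training mean this is the
#' goodness of fit R2; with test-set predictions referenced to the
#' training mean it is Q2(test); pooled out-of-fold predictions referenced
#' to their fold-training means give Q2(cv).
#'
#' @param y_obs,y_pred Observed and predicted responses (length >= 2).
#' @param y_ref_mean Reference mean (training or fold-training mean).
#' @return Numeric scalar <= 1.
#' @export
#' @examples
#' q_squared(c(1, 2, 3), c(1, 2, 4), 2)  # 0.5
q_squared <- function(y_obs, y_pred, y_ref_mean) {
  if (length(y_obs) != length(y_pred) || length(y_obs) < 2)
    stop("y_obs and y_pred must have equal length >= 2")
  denom <- sum((y_obs - y_ref_mean)^2)
  if (denom <= 0) stop("degenerate Q2: zero reference variance")
  1 - sum((y_obs - y_pred)^2) / denom
}

#' k-fold cross-validated Q2
#'
#' Pairs are assigned to `k` random folds (by `seed`); each fold is
#' predicted by a model trained on the remaining folds, and the pooled
#' out-of-fold predictions give Q2(cv), each residual referenced to its
#' fold-training mean.
#'
#' @param x Training feature matrix, or a fitted `"pcm"` model (then the
#'   model's training pairs and parameters are reused).
#' @param y Response vector (matrix interface only).
#' @param puk,svr Kernel and regression parameters (matrix interface
#'   only).
#' @param k Number of folds (default 10); `k = n` is leave-one-out.
#' @param seed Fold-assignment seed.
#' @param ... Unused.
#' @return Q2(cv) as a numeric scalar, with the fold assignment in
#'   attribute `"folds"`.
#' @export
cross_validate <- function(x, ...) UseMethod("cross_validate")

#' @rdname cross_validate
#' @export
cross_validate.default <- function(x, y, puk = puk_params(),
                                   svr = svr_params(), k = 10, seed = 1,
                                   ...) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k must not exceed the number of rows")
  if (k < 2) stop("k must be at least 2")
  set.seed(as.integer(seed))
  folds <- sample(rep(seq_len(k), length.out = n))
  press <- 0; tot <- 0
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    fit <- train_svr(x[tr, , drop = FALSE], y[tr], puk, svr)
    pred <- predict(fit, x[te, , drop = FALSE])
    press <- press + sum((y[te] - pred)^2)
    tot <- tot + sum((y[te] - mean(y[tr]))^2)
  }
  out <- 1 - press / tot
  attr(out, "folds") <- folds
  out
}

#' @rdname cross_validate
#' @export
cross_validate.pcm <- function(x, k = 10, seed = 1, ...) {
  tr <- which(x$records$split == "train")
  cross_validate(x$features$values[tr, , drop = FALSE],
                 x$records$y_scaled[tr],
                 puk = x$model$puk, svr = x$model$svr, k = k, seed = seed)
}

#' @export
print.pcm <- function(x, ...) {
  m <- x$metrics
  cat("Proteochemometric model ", x$spec$name, " (Puk-kernel eps-SVR)\n",
      sep = "")
  cat("  pairs: ", m$n_train, " train / ", m$n_test, " test;  features: ",
      ncol(x$features$values), "\n", sep = "")
  cat("  R2(train) = ", round(m$r2_train, 4), sep = "")
  if (!is.na(m$q2_test)) cat(",  Q2(test) = ", round(m$q2_test, 4),
                             sep = "")
  if (!is.na(m$q2_cv)) cat(",  Q2(cv) = ", round(m$q2_cv, 4), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
summary.pcm <- function(object, ...) {
  out <- c(object$metrics,
           list(spec = object$spec$name,
                n_features = ncol(object$features$values),
                n_sv = length(object$model$dual),
                sigma = object$model$puk$sigma,
                omega = object$model$puk$omega,
                cost = object$model$svr$cost,
                epsilon = object$model$svr$epsilon,
                response_scaling = object$response_scaling))
  class(out) <- "summary.pcm"
  out
}

#' @export
print.summary.pcm <- function(x, ...) {
  cat("PCM model ", x$spec, ": ", x$n_features, " features, ", x$n_sv,
      " support vectors\n", sep = "")
  cat("  kernel: omega = ", x$omega, ", sigma = ", signif(x$sigma, 4),
      "; SVR: C = ", x$cost, ", epsilon = ", x$epsilon, "\n", sep = "")
  cat("  R2(train) = ", round(x$r2_train, 4),
      "  Q2(test) = ", round(x$q2_test, 4),
      "  Q2(cv) = ", round(x$q2_cv, 4), "\n", sep = "")
  cat("  response: pIC50 standardized with mean ",
      round(x$response_scaling[["mean"]], 3), ", sd ",
      round(x$response_scaling[["sd"]], 3), "\n", sep = "")
  invisible(x)
}

#' Predict affinities for compound-target pairs
#'
#' @param object Fitted `"pcm"` model.
#' @param pairs Data frame with `compound_id` and `target_id`; default:
#'   the model's own pairs.
#' @param protein_block,ligand_block Descriptor blocks to look pairs up
#'   in; default: the blocks stored in the model (supply a new ligand
#'   block to screen external compounds).
#' @param type `"scaled"` (standardized units, default) or `"pic50"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pcm <- function(object, pairs = NULL, protein_block = NULL,
                        ligand_block = NULL, type = c("scaled", "pic50"),
                        ...) {
  type <- match.arg(type)
  if (is.null(pairs)) {
    out <- object$records$.pred
  } else {
    X <- apply_feature_scaling(object$features,
                               protein_block %||% object$protein_block,
                               ligand_block %||% object$ligand_block,
                               pairs)
    out <- predict(object$model, X)
  }
  if (type == "pic50") out <- unscale_response(out,
                                               object$response_scaling)
  out
}

#' @export
fitted.pcm <- function(object, ...) {
  tr <- object$records$split == "train"
  setNames(object$records$.pred[tr],
           paste(object$records$compound_id[tr],
                 object$records$target_id[tr], sep = "/"))
}

#' @export
residuals.pcm <- function(object, ...) {
  tr <- object$records$split == "train"
  setNames(object$records$y_scaled[tr] - object$records$.pred[tr],
           paste(object$records$compound_id[tr],
                 object$records$target_id[tr], sep = "/"))
}

#' @export
coef.pcm <- function(object, ...) {
  list(dual = object$model$dual, bias = object$model$bias,
       support_pairs = if (length(object$model$dual))
         object$features$pair_index[
           which(object$records$split == "train")[object$model$sv_index], ]
       else NULL)
}

#' @export
plot.pcm <- function(x, ...) {
  r <- x$records
  tr <- r$split == "train"
  plot(r$y_scaled[tr], r$.pred[tr], pch = 16, col = "grey40",
       xlab = "observed (scaled pIC50)", ylab = "predicted",
       main = paste("PCM", x$spec$name), ...)
  if (any(!tr)) points(r$y_scaled[!tr], r$.pred[!tr], pch = 17,
                       col = "firebrick")
  abline(0, 1, lty = 2)
  if (any(!tr))
    legend("topleft", pch = c(16, 17), col = c("grey40", "firebrick"),
           legend = c("train", "test"), bty = "n")
  invisible(x)
}

#' @export
simulate.pcm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  tr <- object$records$split == "train"
  mu <- object$records$.pred[tr]
  s <- sd(object$records$y_scaled[tr] - mu)
  out <- as.data.frame(replicate(nsim, mu + rnorm(length(mu), sd = s)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Fit the full grid of model specifications
#'
#' Runs [pcm()] for each specification over a named list of descriptor
#' blocks and collects the validation metrics in a table mirroring the
#' usual model-grid layout (one row per model; columns R2, Q2_cv,
#' Q2_test).
#'
#' @param records Record data frame.
#' @param blocks Named list of descriptor matrices; each spec's `protein`
#'   and `ligand` labels must name entries (e.g.
#'   `list(P0 = ..., P1 = ..., P2 = ..., GD = ..., DLI = ...)`).
#' @param specs List of specs (default: all 18 from [model_specs()]).
#' @param cv If `TRUE`, also compute 10-fold Q2(cv) per model (slower).
#' @param ... Passed to [pcm()].
#' @return Data frame with columns `model`, `D`, `R2`, `Q2_cv`,
#'   `Q2_test`.
#' @export
pcm_grid <- function(records, blocks, specs = model_specs(), cv = FALSE,
                     ...) {
  rows <- lapply(specs, function(sp) {
    sp <- as_model_spec(sp)
    fit <- pcm(records, blocks[[sp$protein]], blocks[[sp$ligand]],
               spec = sp, ...)
    q2cv <- if (cv) as.numeric(cross_validate(fit)) else NA_real_
    data.frame(model = sp$name, D = ncol(fit$features$values),
               R2 = fit$metrics$r2_train, Q2_cv = q2cv,
               Q2_test = fit$metrics$q2_test, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
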