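# Epsilon-insensitive support vector regression in the Puk-kernel feature
# space.  The convex dual problem is solved by kernlab's SMO-type
# optimizer on a precomputed kernel matrix; the fitted machine is
# f(x) = sum_i alpha_i K(sv_i, x) + bias.

#' Support vector regression parameters
#'
#' @param cost Box constraint C on the dual coefficients, > 0 (default 1).
#' @param epsilon Half-width of the insensitive loss tube (default 0.001).
#' @param tolerance Optimizer termination tolerance (default 0.001).
#' @return Object of class `"svr_params"`.
#' @export
svr_params <- function(cost = 1, epsilon = 0.001, tolerance = 0.001) {
  if (!is.numeric(cost) || cost <= 0) stop("cost must be positive")
  if (!is.numeric(epsilon) || epsilon < 0)
    stop("epsilon must be non-negative")
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be positive")
  structure(list(cost = cost, epsilon = epsilon, tolerance = tolerance),
            class = "svr_params")
}

#' Train a Puk-kernel support vector regression
#'
#' @param x Training feature matrix (n x d), n >= 2, all finite.
#' @param y Numeric response vector (normally the standardized pIC50).
#' @param puk Kernel parameters ([puk_params()]); `sigma = "median"` is
#'   resolved against `x`.
#' @param svr Regression parameters ([svr_params()]).
#' @return Object of class `"puk_svr"`: support vectors, dual
#'   coefficients, bias, resolved kernel parameters and training fit.
#' @export
train_svr <- function(x, y, puk = puk_params(), svr = svr_params()) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 training rows")
  if (length(y) != nrow(x)) stop("length(y) must match nrow(x)")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in features or response")
  puk <- resolve_sigma(puk, x)

  if (diff(range(y)) <= 2 * svr$epsilon) {
    # every target inside one tube: the flat function at the mean is
    # optimal, all dual coefficients vanish
    fit <- structure(list(
      sv = x[0, , drop = FALSE], dual = numeric(0), bias = mean(y),
      puk = puk, svr = svr, n_train = nrow(x), d = ncol(x)),
      class = "puk_svr")
    fit$fitted <- predict(fit, x)
    fit$y <- y
    return(fit)
  }

  K <- gram_matrix(x, puk)
  m <- tryCatch(
    kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "eps-svr",
                  C = svr$cost, epsilon = svr$epsilon,
                  tol = svr$tolerance),
    error = function(e) stop("SVR solver failed: ", conditionMessage(e)))
  idx <- kernlab::SVindex(m)
  fit <- structure(list(
    sv = x[idx, , drop = FALSE],
    dual = as.numeric(unlist(kernlab::alpha(m))),
    bias = -kernlab::b(m),
    puk = puk, svr = svr, n_train = nrow(x), d = ncol(x),
    sv_index = idx), class = "puk_svr")
  fit$fitted <- as.numeric(K[, idx, drop = FALSE] %*% fit$dual + fit$bias)
  fit$y <- y
  fit
}

#' Predict from a fitted Puk-kernel SVR
#'
#' @param object A `"puk_svr"` fit.
#' @param newdata Feature matrix with the training dimensionality.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.puk_svr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d)
    stop("feature dimension mismatch: model expects ", object$d)
  if (length(object$dual) == 0L)
    return(rep(object$bias, nrow(newdata)))
  K <- gram_matrix(newdata, object$puk, object$sv)
  as.numeric(K %*% object$dual + object$bias)
}

#' @export
print.puk_svr <- function(x, ...) {
  cat("Puk-kernel eps-SVR: ", x$n_train, " training rows, ",
      length(x$dual), " support vectors\n", sep = "")
  cat("  omega = ", x$puk$omega, ", sigma = ", signif(x$puk$sigma, 4),
      ", C = ", x$svr$cost, ", epsilon = ", x$svr$epsilon, "\n", sep = "")
  invisible(x)
}

#' Karush-Kuhn-Tucker diagnostics for a fitted SVR
#'
#' Checks the dual box constraints (|alpha_i| <= C) and, for unbounded
#' support vectors, that the training residual lies within the epsilon
#' tube (complementary slackness), up to a numerical tolerance.
#'
#' @param fit A `"puk_svr"` object.
#' @param tol Numerical slack (default: 10 x the solver tolerance).
#' @return List with `box_ok`, `tube_ok`, `max_box_violation`,
#'   `max_tube_violation`.
#' @export
check_kkt <- function(fit, tol = 10 * fit$svr$tolerance) {
  if (length(fit$dual) == 0L)
    return(list(box_ok = TRUE, tube_ok = TRUE,
                max_box_violation = 0, max_tube_violation = 0))
  box_viol <- max(0, max(abs(fit$dual)) - fit$svr$cost)
  free <- abs(fit$dual) < fit$svr$cost - tol
  resid <- fit$y[fit$sv_index] - fit$fitted[fit$sv_index]
  tube_viol <- if (any(free))
    max(0, max(abs(resid[free])) - fit$svr$epsilon) else 0
  list(box_ok = box_viol <= tol, tube_ok = tube_viol <= tol,
       max_box_violation = box_viol, max_tube_violation = tube_viol)
}
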