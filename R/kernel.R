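# Pearson VII universal ("Puk") kernel.
#
# K(x, y) = 1 / [1 + (2 * ||x - y|| * sqrt(2^(1/omega) - 1) / sigma)^2]^omega
#
# omega is the tailing factor (omega = 1 gives a Lorentzian, large omega
# approaches a Gaussian); sigma is the width on the scale of the Euclidean
# distance between feature vectors.

#' Pearson VII kernel parameters
#'
#' @param omega Tailing factor, > 0 (default 1).
#' @param sigma Kernel width, > 0, or the string `"median"` to set the
#'   width from the median pairwise Euclidean distance of the training
#'   rows at fit time.
#' @param sigma_scale Multiplier applied to the median heuristic (ignored
#'   for numeric `sigma`).  Values well above 1 put the kernel in its wide,
#'   nearly linear regime.
#' @return Object of class `"puk_params"`.
#' @export
puk_params <- function(omega = 1, sigma = 1, sigma_scale = 1) {
  if (!is.numeric(omega) || omega <= 0) stop("omega must be positive")
  if (identical(sigma, "median")) {
    if (!is.numeric(sigma_scale) || sigma_scale <= 0)
      stop("sigma_scale must be positive")
  } else if (!is.numeric(sigma) || sigma <= 0) {
    stop("sigma must be positive or the string 'median'")
  }
  structure(list(omega = omega, sigma = sigma, sigma_scale = sigma_scale),
            class = "puk_params")
}

resolve_sigma <- function(params, X) {
  if (!identical(params$sigma, "median")) return(params)
  d <- dist(X)
  d <- d[d > 0]
  if (length(d) == 0L) stop("cannot resolve median kernel width: ",
                            "all training rows identical")
  params$sigma <- params$sigma_scale * median(d)
  params
}

#' Evaluate the Pearson VII kernel for two vectors
#'
#' @param x,y Numeric vectors of equal length.
#' @param params [puk_params()] with a numeric `sigma`.
#' @return Kernel value in (0, 1]; 1 exactly when `x == y`.
#' @export
#' @examples
#' puk_kernel(0, 0.5)  # omega = sigma = 1: 1 / (1 + 1^2) = 0.5
puk_kernel <- function(x, y, params = puk_params()) {
  if (length(x) != length(y)) stop("dimension mismatch")
  if (identical(params$sigma, "median"))
    stop("sigma = 'median' must be resolved against a training matrix")
  d <- sqrt(sum((x - y)^2))
  (1 + (2 * d * sqrt(2^(1 / params$omega) - 1) / params$sigma)^2)^
    (-params$omega)
}

#' Pearson VII Gram matrix
#'
#' Kernel matrix between the rows of `x` (and optionally the rows of `y`,
#' for prediction).  The square case has unit diagonal, is symmetric and
#' positive semidefinite.
#'
#' @param x Numeric matrix (n x d).
#' @param params [puk_params()] with numeric `sigma`.
#' @param y Optional second matrix (m x d); result is then n x m.
#' @return Kernel matrix.
#' @export
gram_matrix <- function(x, params = puk_params(), y = NULL) {
  x <- as.matrix(x)
  if (identical(params$sigma, "median"))
    stop("sigma = 'median' must be resolved against a training matrix")
  y2 <- if (is.null(y)) x else as.matrix(y)
  if (ncol(x) != ncol(y2)) stop("dimension mismatch")
  d2 <- outer(rowSums(x^2), rep(1, nrow(y2))) +
    outer(rep(1, nrow(x)), rowSums(y2^2)) - 2 * tcrossprod(x, y2)
  d2[d2 < 0] <- 0
  K <- (1 + 4 * d2 * (2^(1 / params$omega) - 1) / params$sigma^2)^
    (-params$omega)
  if (is.null(y)) {
    K <- (K + t(K)) / 2
    diag(K) <- 1
  }
  K
}
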