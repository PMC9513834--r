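# Exact Gaussian process regression with anisotropic squared-exponential or
# Matern 5/2 kernels plus white noise. Written in-package because the
# behavior-map interpolation (posterior mean + predictive sd on a dense
# grid, marginal likelihood for hyperparameter search) is the analytical
# core of the pipeline.

.sqdist <- function(X1, X2, ls) {
  X1 <- sweep(X1, 2L, ls, "/")
  X2 <- sweep(X2, 2L, ls, "/")
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  pmax(d2, 0)
}

#' Kernel matrix between two point sets
#'
#' @param X1,X2 numeric matrices (rows = points, columns = dimensions).
#' @param length_scales positive vector, one per dimension.
#' @param signal_var signal variance.
#' @param kernel `"se"` (squared exponential) or `"matern52"`.
#' @return covariance matrix.
#' @export
gp_kernel <- function(X1, X2, length_scales, signal_var = 1,
                      kernel = c("se", "matern52")) {
  kernel <- match.arg(kernel)
  d2 <- .sqdist(X1, X2, length_scales)
  if (kernel == "se") return(signal_var * exp(-0.5 * d2))
  r <- sqrt(5 * d2)
  signal_var * (1 + r + r^2 / 3) * exp(-r)
}

#' Condition a Gaussian process on training data
#'
#' Exact conditioning: Cholesky of `K + noise_var * I` (with escalating
#' jitter if numerically singular, logged via a message). The prior mean is
#' the training-label mean.
#'
#' @param X numeric matrix of training inputs.
#' @param y numeric vector of training labels.
#' @param length_scales,signal_var,noise_var hyperparameters.
#' @param kernel kernel family, see [gp_kernel()].
#' @return a `gp_fit` object.
#' @export
gp_fit <- function(X, y, length_scales, signal_var, noise_var,
                   kernel = "se") {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(length_scales > 0),
            signal_var > 0, noise_var >= 0)
  mu <- mean(y)
  K <- gp_kernel(X, X, length_scales, signal_var, kernel)
  jit <- 0
  for (j in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    L <- tryCatch(chol(K + diag(noise_var + j * signal_var, nrow(X))),
                  error = function(e) NULL)
    if (!is.null(L)) { jit <- j; break }
  }
  if (is.null(L)) stop("kernel matrix not positive definite even with jitter")
  if (jit > 0)
    message(sprintf("gp_fit: added jitter %.0e * signal_var for stability", jit))
  alpha <- backsolve(L, forwardsolve(t(L), y - mu))
  structure(list(X = X, y = y, mu = mu, L = L, alpha = alpha,
                 length_scales = length_scales, signal_var = signal_var,
                 noise_var = noise_var, kernel = kernel, jitter = jit),
            class = "gp_fit")
}

#' Posterior mean and predictive standard deviation
#'
#' @param fit a [gp_fit()].
#' @param Xnew matrix of prediction points.
#' @param chunk points processed per block (memory control on large grids).
#' @return list with `mean` and `sd` (predictive sd of the latent function).
#' @export
gp_predict <- function(fit, Xnew, chunk = 25000L) {
  Xnew <- as.matrix(Xnew)
  n <- nrow(Xnew)
  mean_out <- numeric(n); var_out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    Ks <- gp_kernel(Xnew[s:e, , drop = FALSE], fit$X,
                    fit$length_scales, fit$signal_var, fit$kernel)
    mean_out[s:e] <- fit$mu + Ks %*% fit$alpha
    v <- forwardsolve(t(fit$L), t(Ks))
    var_out[s:e] <- pmax(fit$signal_var - colSums(v^2), 0)
  }
  list(mean = mean_out, sd = sqrt(var_out))
}

#' Negative log marginal likelihood of a GP hyperparameter setting
#'
#' @inheritParams gp_fit
#' @return scalar negative log marginal likelihood (smaller is better);
#'   `1e10` for numerically infeasible settings.
#' @export
gp_nlml <- function(X, y, length_scales, signal_var, noise_var,
                    kernel = "se") {
  X <- as.matrix(X)
  n <- nrow(X)
  K <- gp_kernel(X, X, length_scales, signal_var, kernel)
  L <- tryCatch(chol(K + diag(noise_var + 1e-10 * signal_var, n)),
                error = function(e) NULL)
  if (is.null(L)) return(1e10)
  yc <- y - mean(y)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  as.numeric(0.5 * sum(yc * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi))
}
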