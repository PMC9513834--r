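#' Bayesian optimization with the expected-improvement acquisition
#'
#' Minimizes a black-box objective over a box. A GP surrogate (isotropic
#' squared-exponential on inputs rescaled to the unit cube) is refit after
#' every evaluation; the next point maximizes expected improvement (EI)
#' over a seeded random candidate set, trading off exploitation of low
#' predicted objective against exploration of high uncertainty.
#'
#' @param fn objective function of a numeric vector, returning a scalar to
#'   minimize.
#' @param lower,upper numeric bounds (same length).
#' @param n_init initial space-filling evaluations (stratified uniform).
#' @param n_iter EI-guided evaluations after the initial design.
#' @param n_candidates random candidates scored by EI per iteration.
#' @param seed integer seed; fixed seed gives an identical trace.
#' @param x0 optional matrix of points (rows) evaluated before the random
#'   design, e.g. informed starting guesses.
#' @return list with `par`, `value`, and `trace` (data.frame of iteration,
#'   evaluated point, objective, incumbent best).
#' @export
bayes_opt <- function(fn, lower, upper, n_init = 8L, n_iter = 30L,
                      n_candidates = 500L, seed = 1L, x0 = NULL) {
  stopifnot(length(lower) == length(upper), all(upper > lower),
            n_init >= 2L, n_iter >= 0L)
  d <- length(lower)
  span <- upper - lower
  unscale <- function(U) sweep(sweep(U, 2L, span, "*"), 2L, lower, "+")
  with_seed(seed, {
    # stratified (Latin-hypercube-style) initial design
    U <- sapply(seq_len(d), function(j)
      (sample(n_init) - stats::runif(n_init)) / n_init)
    if (!is.null(x0)) {
      x0 <- matrix(pmin(pmax(t(t(x0)), lower), upper), ncol = d)
      U <- rbind(sweep(sweep(x0, 2L, lower, "-"), 2L, span, "/"), U)
    }
    X <- unscale(U)
    y <- apply(X, 1L, fn)
    for (it in seq_len(n_iter)) {
      ys <- (y - mean(y)) / max(stats::sd(y), 1e-12)
      sur <- tryCatch(
        gp_fit(U, ys, length_scales = rep(0.2, d),
               signal_var = 1, noise_var = 1e-6),
        error = function(e) NULL)
      if (is.null(sur)) {
        cand_u <- matrix(stats::runif(d), 1L)
      } else {
        Uc <- matrix(stats::runif(n_candidates * d), n_candidates, d)
        pr <- gp_predict(sur, Uc)
        best <- min(ys)
        imp <- best - pr$mean
        zz <- imp / pmax(pr$sd, 1e-12)
        ei <- imp * stats::pnorm(zz) + pr$sd * stats::dnorm(zz)
        ei[pr$sd < 1e-12] <- 0
        cand_u <- Uc[which.max(ei), , drop = FALSE]
      }
      xn <- unscale(cand_u)
      yn <- fn(drop(xn))
      U <- rbind(U, cand_u); X <- rbind(X, xn); y <- c(y, yn)
    }
    inc <- cummin(y)
    trace <- data.frame(iteration = seq_along(y), objective = y,
                        incumbent = inc)
    trace <- cbind(trace, as.data.frame(X))
    names(trace)[-(1:3)] <- paste0("x", seq_len(d))
    best <- which.min(y)
    list(par = X[best, ], value = y[best], trace = trace)
  })
}
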