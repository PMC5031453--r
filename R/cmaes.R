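#' Covariance matrix adaptation evolution strategy
#'
#' Minimal (mu/mu_w, lambda) CMA-ES with cumulative step-size adaptation and
#' rank-one plus rank-mu covariance updates, following the standard
#' published parameterisation.  Used by the design pipeline for both the
#' posture search and the gain optimization; seeded and deterministic.
#'
#' @param fn Objective function of a numeric vector, to minimize.  When
#'   `lower` is given, candidates are clipped to the bound before
#'   evaluation and the clipped vector is reported.
#' @param x0 Initial mean.
#' @param sigma Initial step size (standard deviation).
#' @param lambda Population size (>= 2).
#' @param max_iter Maximum number of iterations.
#' @param seed Integer seed for the candidate sampling.
#' @param lower Optional lower bound (scalar or vector) enforced by
#'   clipping.
#' @param stop_fitness Optional target: stop once the best value is <= it.
#' @param tol_sigma Stop when `sigma * max(diag(C))^0.5` falls below this.
#' @return A list with `x` (best-ever solution, clipped), `value`, `trace`
#'   (best-so-far objective per iteration, nonincreasing), `iterations`.
#' @export
cmaes <- function(fn, x0, sigma, lambda = NULL, max_iter = 100, seed = 1L,
                  lower = NULL, stop_fitness = NULL, tol_sigma = 1e-12) {
  n <- length(x0)
  if (is.null(lambda)) lambda <- 4 + floor(3 * log(n))
  lambda <- max(2L, as.integer(lambda))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  clipv <- function(x) if (is.null(lower)) x else pmax(x, lower)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  xmean <- as.numeric(x0)
  ps <- numeric(n); pc <- numeric(n)
  C <- diag(n); B <- diag(n); D <- rep(1, n)
  best_x <- clipv(xmean)
  best_f <- fn(best_x)
  trace <- numeric(0)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    arz <- matrix(rnorm(n * lambda), n, lambda)
    ary <- B %*% (D * arz)
    arx <- xmean + sigma * ary
    fit <- apply(arx, 2, function(x) fn(clipv(x)))
    ord <- order(fit)
    if (fit[ord[1]] < best_f) {
      best_f <- fit[ord[1]]
      best_x <- clipv(arx[, ord[1]])
    }
    trace <- c(trace, best_f)
    sel <- ord[seq_len(mu)]
    xold <- xmean
    xmean <- drop(arx[, sel, drop = FALSE] %*% w)
    ymean <- (xmean - xold) / sigma
    zmean <- drop(arz[, sel, drop = FALSE] %*% w)
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * drop(B %*% zmean)
    hsig <- as.numeric(sqrt(sum(ps^2)) /
                         sqrt(1 - (1 - cs)^(2 * it)) / chiN < 1.4 + 2 / (n + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ymean
    artmp <- ary[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    C <- (C + t(C)) / 2
    eig <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eig$values, 1e-30))
    B <- eig$vectors
    if (!is.null(stop_fitness) && best_f <= stop_fitness) break
    if (sigma * max(D) < tol_sigma) break
  }
  list(x = best_x, value = best_f, trace = trace, iterations = it)
}
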