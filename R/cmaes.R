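# Covariance matrix adaptation evolution strategy (CMA-ES), the standard
# (mu/mu_w, lambda) formulation with rank-one and rank-mu covariance updates
# and cumulative step-size adaptation.  The objective is evaluated on the
# whole candidate population at once (fn takes an n x lambda matrix and
# returns lambda values), which lets callers vectorize over candidates.  Box
# constraints are handled by evaluating at the clipped point and adding a
# quadratic out-of-bounds penalty.  Written for the low-dimensional
# (d <= ~10) scalar-parameter fits this package performs.

cma_es_minimize <- function(fn, x0, sigma0 = 0.3, lower = -10, upper = 10,
                            max_evals = 1000L, stop_fitness = -Inf,
                            stagnation_iters = 30L, penalty = 1e6) {
  n <- length(x0)
  stopifnot(n >= 1L)
  lambda <- 4L + floor(3 * log(n))
  mu <- floor(lambda / 2)
  weights <- log(mu + 1 / 2) - log(seq_len(mu))
  weights <- weights / sum(weights)
  mueff <- sum(weights)^2 / sum(weights^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- pmin(pmax(x0, lower), upper)
  sigma <- sigma0
  pc <- ps <- numeric(n)
  B <- diag(n)
  D <- rep(1, n)
  C <- diag(n)

  best_f <- Inf
  best_x <- xmean
  evals <- 0L
  iter <- 0L
  last_improve <- 0L
  last_best <- Inf

  while (evals < max_evals) {
    iter <- iter + 1L
    arz <- matrix(rnorm(n * lambda), n, lambda)
    arx <- xmean + sigma * (B %*% (D * arz))
    xclip <- pmin(pmax(arx, lower), upper)
    fvals <- fn(xclip) + penalty * colSums((arx - xclip)^2)
    fvals[!is.finite(fvals)] <- 1e18
    evals <- evals + lambda
    if (!all(is.finite(xmean)) || !is.finite(sigma)) break
    k <- which.min(fvals)
    if (fvals[k] < best_f) {
      best_f <- fvals[k]
      best_x <- xclip[, k]
    }
    # Improvement counts only when meaningfully better than the previous
    # record, so slow drift in a hopeless basin triggers the stagnation stop.
    improve_margin <- if (is.finite(last_best))
      max(1e-12, 1e-8 * abs(last_best)) else 0
    if (best_f < last_best - improve_margin) {
      last_best <- best_f
      last_improve <- iter
    }
    if (best_f <= stop_fitness) break
    ord <- order(fvals)[seq_len(mu)]
    xold <- xmean
    xmean <- drop(arx[, ord, drop = FALSE] %*% weights)
    zmean <- drop(arz[, ord, drop = FALSE] %*% weights)
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * drop(B %*% zmean)
    hsig <- sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * evals / lambda)) / chiN < 1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc +
      hsig * sqrt(cc * (2 - cc) * mueff) * (xmean - xold) / sigma
    artmp <- (arx[, ord, drop = FALSE] - xold) / sigma
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (weights * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    C <- (C + t(C)) / 2
    eig <- eigen(C, symmetric = TRUE)
    if (any(eig$values <= 0) || !all(is.finite(eig$values))) break
    D <- sqrt(eig$values)
    B <- eig$vectors
    if (max(D) / min(D) > 1e7) break
    if (sigma * max(D) < 1e-12) break
    if (iter - last_improve > stagnation_iters) break
  }
  list(par = best_x, value = best_f, evals = evals, iterations = iter)
}
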