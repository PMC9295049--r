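## Independent numerical oracles used across the test files.  These never
## call the package's own density/Laplace code paths except where a test
## explicitly compares the two.

## Gauss-Hermite nodes/weights by Golub-Welsch (weight exp(-x^2))
gauss_hermite <- function(n) {
  i <- seq_len(n - 1L)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  o <- order(e$values)
  list(nodes = e$values[o], weights = (sqrt(pi) * e$vectors[1L, ]^2)[o])
}

## log of sum(exp(lx)) without overflow
lse <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

## ---- quadrature oracle for the marginal density, N = 1 ------------------
## One group: M iid N(mu, u) with u ~ IW_1(a, df) = InvGamma(df/2, a/2).
## Adaptive quadrature over u.
quad_marginal_1d <- function(xs, mu, a, df) {
  f <- function(u) vapply(u, function(uu) {
    exp(sum(stats::dnorm(xs, mu, sqrt(uu), log = TRUE)) +
          df / 2 * log(a / 2) - lgamma(df / 2) -
          (df / 2 + 1) * log(uu) - a / (2 * uu))
  }, 1)
  log(stats::integrate(f, 0, Inf, rel.tol = 1e-12)$value)
}

## ---- quadrature oracle for the marginal density, N = 2 ------------------
## One group: M iid N_2(mu, U) with U ~ IW_2(A, df).  Nested adaptive
## quadrature over the Cholesky factor U = L L', Jacobian 4 l11^2 l22.
quad_marginal_2d <- function(X, mu, A, df) {
  M <- ncol(X)
  ldetA <- determinant(A, logarithm = TRUE)$modulus
  lconst <- df / 2 * ldetA - df * log(2) - lmvgamma_test(df / 2, 2)
  integrand <- function(l11, l21, l22) {
    L <- matrix(c(l11, l21, 0, l22), 2, 2)
    U <- L %*% t(L)
    Ui <- chol2inv(chol(U))
    ldU <- 2 * (log(l11) + log(l22))
    Z <- X - mu
    llik <- -M * log(2 * pi) - M / 2 * ldU - 0.5 * sum(Z * (Ui %*% Z))
    liw <- lconst - (df + 3) / 2 * ldU - 0.5 * sum(diag(A %*% Ui))
    exp(llik + liw) * 4 * l11^2 * l22
  }
  inner <- function(l11, l21) {
    stats::integrate(function(v) vapply(v, function(l22)
      integrand(l11, l21, l22), 1), 0, Inf, rel.tol = 1e-10)$value
  }
  mid <- function(l11) {
    stats::integrate(function(v) vapply(v, function(l21)
      inner(l11, l21), 1), -Inf, Inf, rel.tol = 1e-9)$value
  }
  log(stats::integrate(function(v) vapply(v, mid, 1), 0, Inf,
                       rel.tol = 1e-8)$value)
}

lmvgamma_test <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

## ---- Gauss-Hermite marginal oracle for one configuration ----------------
## Integrates exp(log f(X,Y | mu(theta)) + log priors) over theta by a
## shifted/scaled product Gauss-Hermite rule centred on block means of the
## data with a data-driven scale (the latent posterior is much narrower
## than the prior, so quadrature at the prior scale would under-resolve).
## log f is evaluated through log_density_given_means; the object under
## test is the *Laplace* step, not the closed-form density (checked against
## adaptive quadrature elsewhere).
gh_config_marginal <- function(stats, partition, delta, hyper, n_nodes = 10) {
  K <- length(partition)
  act <- which(delta == 1)
  d <- K + length(act)
  nb <- lengths(partition)
  N <- length(stats$xbar)
  MX <- stats$MX; MY <- stats$MY; df <- hyper$df

  ## the integrand in rank-one form: the determinant lemma turns the
  ## determinant ratios of the (quadrature-validated) closed-form density
  ## into scalar quadratic forms, evaluable for all nodes at once
  A0 <- hyper$A + (MX - 1) * stats$S1
  B0 <- hyper$B + (MY - 1) * stats$T1
  A0i <- chol2inv(chol(A0))
  B0i <- chol2inv(chol(B0))
  Z <- matrix(0, N, K)
  for (k in seq_len(K)) Z[partition[[k]], k] <- 1
  W <- cbind(Z, Z[, act, drop = FALSE])
  GA <- t(Z) %*% A0i %*% Z
  GBW <- t(W) %*% B0i %*% W
  ax <- drop(t(Z) %*% A0i %*% stats$xbar)
  bw <- drop(t(W) %*% B0i %*% stats$ybar)
  q0X <- drop(stats$xbar %*% A0i %*% stats$xbar)
  q0Y <- drop(stats$ybar %*% B0i %*% stats$ybar)
  cX <- (df + MX) / 2; cY <- (df + MY) / 2
  pd_ld <- function(m) 2 * sum(log(diag(chol(m))))
  const <- -N * (MX + MY) / 2 * log(pi) +
    lmvgamma_test((df + MX) / 2, N) - lmvgamma_test(df / 2, N) +
    lmvgamma_test((df + MY) / 2, N) - lmvgamma_test(df / 2, N) +
    df / 2 * (pd_ld(hyper$A) + pd_ld(hyper$B)) -
    cX * pd_ld(A0) - cY * pd_ld(B0)

  ## shifted/scaled product rule centred at block means of the data (the
  ## latent posterior is much narrower than the prior); a null block's bump
  ## sits at its pooled mean, a shifted block's at its group-1 mean
  s2 <- mean(c(diag(as.matrix(stats$S1)), diag(as.matrix(stats$T1))))
  pooled <- (MX * stats$xbar + MY * stats$ybar) / (MX + MY)
  centers <- c(vapply(seq_len(K), function(k) {
                 b <- partition[[k]]
                 if (delta[k] == 1) mean(stats$xbar[b]) else mean(pooled[b])
               }, 1),
               vapply(partition[act],
                      function(b) mean(stats$ybar[b] - stats$xbar[b]), 1))
  scales <- c(1 / sqrt(1 / hyper$tau2 + (MX + MY) * nb / s2),
              1 / sqrt(1 / hyper$sigma2 + MY * nb[act] / s2))
  scales <- 2 * scales   # widen to cover both the bump and prior curvature
  gh <- gauss_hermite(n_nodes)
  idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(n_nodes)), d)))
  x <- matrix(gh$nodes[idx], nrow(idx), d)
  ## shifted GH: int F = sum_i w_i e^{x_i^2} sqrt(2) s F(c + sqrt(2) s x_i)
  lw <- rowSums(matrix((log(gh$weights) + gh$nodes^2)[idx],
                       nrow(idx), d)) + sum(log(sqrt(2) * scales))
  theta <- sweep(sweep(x, 2L, sqrt(2) * scales, `*`), 2L, centers, `+`)

  phi <- theta[, seq_len(K), drop = FALSE]
  qX <- q0X - 2 * drop(phi %*% ax) + rowSums((phi %*% GA) * phi)
  qY <- q0Y - 2 * drop(theta %*% bw) + rowSums((theta %*% GBW) * theta)
  lvals <- const - cX * log1p(MX * qX) - cY * log1p(MY * qY) +
    rowSums(matrix(stats::dnorm(phi, hyper$mu0, sqrt(hyper$tau2),
                                log = TRUE), nrow(theta), K))
  if (length(act)) {
    dv <- theta[, K + seq_along(act), drop = FALSE]
    lvals <- lvals +
      rowSums(matrix(stats::dnorm(dv, hyper$delta0, sqrt(hyper$sigma2),
                                  log = TRUE), nrow(theta), length(act)))
  }
  lse(lw + lvals)
}

## ---- latent-mean integration oracle for the toy system ------------------
## Each component's shared-mean incidence matrix Z has exactly one 1 per
## observation row, so the 4D integral over the latent means factorizes into
## independent 1D integrals (one per latent mean), each solved by adaptive
## quadrature over the standard-normal latent mean.
quad_toy_component <- function(z4, Z, sigma2) {
  sum(vapply(seq_len(ncol(Z)), function(c0) {
    obs <- z4[Z[, c0] == 1]
    f <- function(m) vapply(m, function(mu)
      exp(sum(stats::dnorm(obs, mu, sqrt(sigma2), log = TRUE)) +
            stats::dnorm(mu, log = TRUE)), 1)
    log(stats::integrate(f, -Inf, Inf, rel.tol = 1e-12)$value)
  }, 1))
}

## toy lfdr2 by full 4-component latent-mean integration
oracle_toy_lfdr2 <- function(x1, x2, y1, y2, params, ...) {
  Zs <- list(null_blocked = matrix(1, 4, 1),
             null_free = cbind(c(1, 0, 1, 0), c(0, 1, 0, 0), c(0, 0, 0, 1)),
             alt_blocked = cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)),
             alt_free = diag(4))
  p0 <- params$p0; pb <- params$p_block
  wts <- c(p0 * pb, p0 * (1 - pb), (1 - p0) * pb, (1 - p0) * (1 - pb))
  z4 <- c(x1, x2, y1, y2)
  ld <- vapply(Zs, function(Z) quad_toy_component(z4, Z, params$sigma2), 1)
  keep <- wts > 0
  num <- lse((log(wts) + ld)[keep & c(TRUE, TRUE, FALSE, FALSE)])
  den <- lse((log(wts) + ld)[keep])
  exp(num - den)
}

## largest-prefix TPR at a target empirical FDR (used in power comparisons)
tpr_at_fdr <- function(scores, truth, fdr = 0.05) {
  o <- order(scores)
  n <- length(scores)
  femp <- cumsum(truth[o]) / seq_len(n)
  ok <- which(femp <= fdr)
  if (!length(ok)) return(0)
  sum(!truth[o[seq_len(max(ok))]]) / sum(!truth)
}

## diagonal hyperparameters sized to an n-vertex subgraph
tiny_hyper <- function(n, df = n + 2, p0 = 0.5, tau2 = 1, sigma2 = 1,
                       mu0 = 0, delta0 = 0) {
  hyperparams(mu0 = mu0, tau2 = tau2, delta0 = delta0, sigma2 = sigma2,
              df = df, A = diag(n), B = diag(n), p0 = p0)
}
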