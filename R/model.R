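#' Two-group graph-associated data
#'
#' Bundles the two measurement matrices of an unpaired two-group comparison.
#' Rows are vertices of a graph (e.g. voxels), columns are replicate samples.
#'
#' @param x numeric matrix, `N` vertices x `M_X` group-1 samples.
#' @param y numeric matrix, `N` x `M_Y` group-2 samples.
#' @param dims optional lattice dimensions with `prod(dims) == N`, recorded
#'   for engines and plotting.
#' @return object of class `"two_group_data"`.
#' @export
two_group_data <- function(x, y, dims = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of rows")
  if (ncol(x) < 2L || ncol(y) < 2L)
    stop("at least 2 samples per group are required")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (!is.null(dims) && prod(dims) != nrow(x))
    stop("prod(dims) must equal the number of rows")
  structure(list(x = x, y = y, dims = if (!is.null(dims)) as.integer(dims)),
            class = "two_group_data")
}

#' @export
print.two_group_data <- function(x, ...) {
  cat(sprintf("two_group_data: N = %d vertices, M_X = %d, M_Y = %d samples%s\n",
              nrow(x$x), ncol(x$x), ncol(x$y),
              if (!is.null(x$dims))
                paste0(" (lattice ", paste(x$dims, collapse = "x"), ")")
              else ""))
  invisible(x)
}

#' Sufficient statistics of a two-group data set
#'
#' Column means and unbiased (divisor `M - 1`) sample covariance matrices of
#' each group.  The marginal predictive density depends on the data only
#' through these.
#'
#' @param data a [two_group_data()] object (or a list with matrices `x`, `y`).
#' @return list with `xbar`, `ybar` (length-`N` means), `S1`, `T1` (`N x N`
#'   covariances) and sample counts `MX`, `MY`.
#' @export
sufficient_stats <- function(data) {
  x <- as.matrix(data$x); y <- as.matrix(data$y)
  if (ncol(x) < 2L || ncol(y) < 2L)
    stop("at least 2 samples per group are required")
  list(xbar = rowMeans(x), ybar = rowMeans(y),
       S1 = stats::cov(t(x)), T1 = stats::cov(t(y)),
       MX = ncol(x), MY = ncol(y))
}

#' Model hyperparameters
#'
#' Global hyperparameters of the mixture model: Gaussian priors on block base
#' means (`mu0`, `tau2`) and on block shifts given non-null (`delta0`,
#' `sigma2`), inverse-Wishart priors `IW(A, df)` / `IW(B, df)` on the two
#' group covariance matrices of the local subgraph, and the per-block null
#' probability `p0`.
#'
#' @param mu0,tau2 prior mean and variance (> 0) of block base means.
#' @param delta0,sigma2 prior mean and variance (> 0) of non-null block shifts.
#' @param df inverse-Wishart degrees of freedom; must exceed `nrow(A) + 1`.
#' @param A,B positive-definite scale matrices sized to the full local window.
#' @param p0 probability in `[0, 1]` that a block is null.
#' @return object of class `"graphmm_hyper"`.
#' @export
hyperparams <- function(mu0 = 0, tau2 = 1, delta0 = 0, sigma2 = 1,
                        df, A, B, p0 = 0.8) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  if (!isTRUE(all.equal(dim(A), dim(B))))
    stop("A and B must have identical dimensions")
  if (tau2 <= 0 || sigma2 <= 0) stop("tau2 and sigma2 must be positive")
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  if (df <= n + 1) stop("df must exceed nrow(A) + 1")
  for (m in list(A, B))
    if (inherits(try(chol(m), silent = TRUE), "try-error"))
      stop("A and B must be positive definite")
  structure(list(mu0 = mu0, tau2 = tau2, delta0 = delta0, sigma2 = sigma2,
                 df = df, A = A, B = B, p0 = p0),
            class = "graphmm_hyper")
}

#' @export
print.graphmm_hyper <- function(x, ...) {
  cat(sprintf(paste0("graphmm hyperparameters: window %d, mu0 = %.4g, ",
                     "tau2 = %.4g, delta0 = %.4g, sigma2 = %.4g,\n  df = %.4g, ",
                     "p0 = %.4g\n"),
              nrow(x$A), x$mu0, x$tau2, x$delta0, x$sigma2, x$df, x$p0))
  invisible(x)
}

## restrict hyperparameters to a subset of window positions (principal
## submatrices of A and B); used for clipped border windows
subset_hyper <- function(hyper, idx) {
  hyper$A <- hyper$A[idx, idx, drop = FALSE]
  hyper$B <- hyper$B[idx, idx, drop = FALSE]
  hyper
}

#' Expand block-level means to per-vertex mean vectors
#'
#' Vertices in block `k` share the group-1 mean `phi[k]`; their group-2 mean
#' is `phi[k] + dvals[k]` when the block is flagged as shifted (`delta[k] ==
#' 1`) and `phi[k]` otherwise.
#'
#' @param partition list of blocks (see [as_partition()]).
#' @param delta binary vector, one indicator per block.
#' @param phi numeric vector of block base means, one per block.
#' @param dvals numeric shifts for the active (`delta == 1`) blocks, in block
#'   order.
#' @param n number of vertices (defaults to those covered by the partition).
#' @return list with per-vertex vectors `muX` and `muY`.
#' @export
expand_block_means <- function(partition, delta, phi, dvals = numeric(0),
                               n = sum(lengths(partition))) {
  cf <- canonicalize_config(partition, delta, phi, dvals)
  partition <- cf$partition; delta <- cf$delta
  phi <- cf$phi; dvals <- cf$dvals
  K <- length(partition)
  muX <- muY <- numeric(n)
  j <- 0L
  for (k in seq_len(K)) {
    b <- partition[[k]]
    muX[b] <- phi[k]
    if (delta[k] == 1) {
      j <- j + 1L
      muY[b] <- phi[k] + dvals[j]
    } else muY[b] <- phi[k]
  }
  list(muX = muX, muY = muY)
}

## bring a (partition, delta, phi, dvals) configuration into canonical block
## order, permuting the per-block vectors alongside the blocks
canonicalize_config <- function(partition, delta, phi = NULL,
                                dvals = NULL) {
  if (!is.list(partition)) partition <- as_partition(partition)
  blocks <- lapply(partition, function(b) sort(as.integer(b)))
  K <- length(blocks)
  if (length(delta) != K) stop("delta must have one entry per block")
  if (!is.null(phi) && length(phi) != K)
    stop("delta and phi must have one entry per block")
  if (!is.null(dvals) && length(dvals) != sum(delta == 1))
    stop("dvals must have one entry per active block")
  o <- order(vapply(blocks, min, 1L))
  dfull <- NULL
  if (!is.null(dvals)) {
    dfull <- numeric(K)
    dfull[delta == 1] <- dvals
    dfull <- dfull[o]
  }
  delta <- delta[o]
  list(partition = blocks[o], delta = delta,
       phi = if (!is.null(phi)) phi[o],
       dvals = if (!is.null(dfull)) dfull[delta == 1])
}

## log multivariate gamma function log Gamma_p(a)
lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

## log determinant of a symmetric positive-definite matrix, NA if not PD
pd_logdet <- function(m) {
  ch <- try(chol(m), silent = TRUE)
  if (inherits(ch, "try-error")) return(NA_real_)
  2 * sum(log(diag(ch)))
}

## ensure A + (M-1)*S1 is PD; if not, nudge with eps*I (eps = 1e-8 tr/N)
adjusted_scale <- function(A, S1, M) {
  A0 <- A + (M - 1) * S1
  if (is.na(pd_logdet(A0))) {
    eps <- 1e-8 * sum(diag(A0)) / nrow(A0)
    warning("adjusted scale matrix not positive definite; adding ",
            format(eps), " * I")
    A0 <- A0 + diag(eps, nrow(A0))
    if (is.na(pd_logdet(A0)))
      stop("adjusted scale matrix remains singular; ",
           "increase the prior scale matrix (A or B)")
  }
  A0
}

#' Log marginal density of the data given block-constant means
#'
#' The Gaussian sampling model with conjugate inverse-Wishart priors on the
#' two group covariance matrices integrates analytically to
#' \deqn{f(X, Y | \mu_X, \mu_Y) = C\,
#'   \frac{|A|^{df/2} |B|^{df/2}}
#'        {|\tilde A|^{(df+M_X)/2} |\tilde B|^{(df+M_Y)/2}},}
#' where \eqn{\tilde A = A + (M_X - 1) S_1 + M_X (\bar X - \mu_X)(\bar X -
#' \mu_X)^T} and \eqn{\tilde B} analogously.  The normalizing constant is
#' implemented in full,
#' \eqn{C = \prod_{g} \pi^{-N M_g / 2}\,
#'   \Gamma_N((df + M_g)/2) / \Gamma_N(df/2)}
#' (multivariate gamma), so the returned value is an absolute log density and
#' can be validated against numerical integration.
#'
#' @param stats output of [sufficient_stats()].
#' @param muX,muY per-vertex mean vectors.
#' @param hyper a [hyperparams()] object sized to `N`.
#' @return the log density (a single number).
#' @export
log_density_given_means <- function(stats, muX, muY, hyper) {
  N <- length(stats$xbar)
  if (nrow(hyper$A) != N) stop("hyperparameters not sized to the data")
  MX <- stats$MX; MY <- stats$MY; df <- hyper$df
  A0 <- adjusted_scale(hyper$A, stats$S1, MX)
  B0 <- adjusted_scale(hyper$B, stats$T1, MY)
  dx <- stats$xbar - muX
  dy <- stats$ybar - muY
  ldAt <- pd_logdet(A0 + MX * tcrossprod(dx))
  ldBt <- pd_logdet(B0 + MY * tcrossprod(dy))
  if (is.na(ldAt) || is.na(ldBt))
    stop("adjusted matrices not positive definite; regularize A/B")
  logC <- -N * (MX + MY) / 2 * log(pi) +
    lmvgamma((df + MX) / 2, N) - lmvgamma(df / 2, N) +
    lmvgamma((df + MY) / 2, N) - lmvgamma(df / 2, N)
  logC + df / 2 * (pd_logdet(hyper$A) + pd_logdet(hyper$B)) -
    (df + MX) / 2 * ldAt - (df + MY) / 2 * ldBt
}

## central-difference Hessian with per-coordinate step 1e-4 * (1 + |theta|)
num_hessian <- function(fn, theta) {
  d <- length(theta)
  hstep <- 1e-4 * (1 + abs(theta))
  H <- matrix(0, d, d)
  f0 <- fn(theta)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, hstep[i])
    H[i, i] <- (fn(theta + ei) - 2 * f0 + fn(theta - ei)) / hstep[i]^2
    if (i < d) for (j in seq((i + 1L), d)) {
      ej <- replace(numeric(d), j, hstep[j])
      H[i, j] <- H[j, i] <-
        (fn(theta + ei + ej) - fn(theta + ei - ej) -
           fn(theta - ei + ej) + fn(theta - ei - ej)) /
        (4 * hstep[i] * hstep[j])
    }
  }
  H
}

#' Laplace-approximated log marginal density of one model configuration
#'
#' For a fixed graph-respecting partition and block shift-indicator vector,
#' integrates the free means out of [log_density_given_means()]: block base
#' means \eqn{\varphi_k \sim N(\mu_0, \tau^2)} and, for the active blocks,
#' shifts \eqn{\delta_k \sim N(\delta_0, \sigma^2)}.  The integral is
#' approximated by Laplace's method around the posterior mode, found by
#' quasi-Newton (BFGS) search started from block means of the observed group
#' means; the Hessian uses central finite differences.
#'
#' @inheritParams log_density_given_means
#' @param partition list of blocks.
#' @param delta binary vector of per-block shift indicators.
#' @return approximate log of the marginal density `f(X, Y | delta, partition)`.
#' @export
laplace_log_marginal <- function(stats, partition, delta, hyper) {
  cf <- canonicalize_config(partition, delta)
  partition <- cf$partition; delta <- cf$delta
  K <- length(partition)
  act <- which(delta == 1)
  nact <- length(act)
  d <- K + nact
  n <- length(stats$xbar)

  h <- function(theta) {
    phi <- theta[seq_len(K)]
    dvals <- theta[K + seq_len(nact)]
    mu <- expand_block_means(partition, delta, phi, dvals, n)
    log_density_given_means(stats, mu$muX, mu$muY, hyper) +
      sum(stats::dnorm(phi, hyper$mu0, sqrt(hyper$tau2), log = TRUE)) +
      (if (nact) sum(stats::dnorm(dvals, hyper$delta0, sqrt(hyper$sigma2),
                                  log = TRUE)) else 0)
  }

  ## the objective can be bimodal in a null block's base mean (product of
  ## two t-forms, one per group): start null blocks at their pooled means
  ## (the natural estimate under no shift) and shifted blocks at their
  ## group-1 means, falling back to the prior mean on non-convergence
  wpool <- stats$MX / (stats$MX + stats$MY)
  pooled <- wpool * stats$xbar + (1 - wpool) * stats$ybar
  start_data <- c(vapply(seq_len(K), function(k) {
                    b <- partition[[k]]
                    if (delta[k] == 1) mean(stats$xbar[b])
                    else mean(pooled[b])
                  }, 1),
                  vapply(partition[act],
                         function(b) mean(stats$ybar[b] - stats$xbar[b]), 1))
  start_prior <- c(rep(hyper$mu0, K), rep(hyper$delta0, nact))
  opt <- NULL
  for (start in list(start_data, start_prior)) {
    opt <- tryCatch(
      stats::optim(start, function(t) -h(t), method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) && opt$convergence == 0) break
  }
  if (is.null(opt))
    stop("Laplace mode search failed for configuration with K = ", K,
         ", delta = ", paste(delta, collapse = ""))
  theta_hat <- opt$par
  H <- num_hessian(h, theta_hat)
  negH <- -(H + t(H)) / 2
  ld <- pd_logdet(negH)
  if (is.na(ld)) {  # mode Hessian numerically indefinite: tiny ridge
    ridge <- 1e-8 * max(1, max(abs(diag(negH))))
    ld <- pd_logdet(negH + diag(ridge, d))
    if (is.na(ld))
      stop("negative Hessian not positive definite at the mode (K = ", K, ")")
  }
  -opt$value + d / 2 * log(2 * pi) - ld / 2
}

#' Log prior mass of a model configuration
#'
#' Uniform over the enumerated graph-respecting partitions, and independent
#' Bernoulli block-state indicators with null probability `p0` (a block is
#' null, `delta == 0`, with probability `p0`).
#'
#' @param partition list of blocks.
#' @param delta binary indicator vector, one per block.
#' @param p0 per-block null probability.
#' @param n_partitions number of graph-respecting partitions of the graph.
#' @return log prior probability (can be `-Inf` at the `p0` limits).
#' @export
config_log_prior <- function(partition, delta, p0, n_partitions) {
  K <- length(as_partition(partition))
  if (length(delta) != K) stop("delta must have one entry per block")
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  terms <- ifelse(delta == 1, log1p(-p0), log(p0))
  -log(n_partitions) + sum(terms)
}

logsumexp <- function(lw) {
  m <- max(lw)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lw - m)))
}

#' Posterior over (partition, shift-state) configurations
#'
#' Enumerates every pair of a graph-respecting partition and a block
#' shift-indicator vector for a (small) graph, scores each with
#' `log prior + log marginal`, and normalizes by log-sum-exp.
#'
#' @param data a [two_group_data()] with rows matching `graph`.
#' @param graph connected [vgraph()] of small order.
#' @param hyper a [hyperparams()] sized to the graph.
#' @param engine `"r"` for the reference implementation
#'   ([laplace_log_marginal()] per configuration) or `"cpp"` for the compiled
#'   core used by [graphmm()]; the two agree to numerical accuracy.
#' @return object of class `"config_posterior"`: a data frame `table` with
#'   one row per configuration (partition id, delta bitmask, K, log prior,
#'   log marginal, normalized log weight) plus the partition list.
#' @export
posterior_over_configs <- function(data, graph, hyper,
                                   engine = c("r", "cpp")) {
  engine <- match.arg(engine)
  stopifnot(inherits(graph, "vgraph"))
  if (nrow(data$x) != graph$n) stop("data rows must match graph order")
  parts <- enumerate_partitions(graph)
  np <- length(parts)
  stats <- sufficient_stats(data)

  rows <- vector("list", 0L)
  if (engine == "cpp") {
    prep <- cpp_prepare(stats, hyper)
    for (ip in seq_len(np)) {
      p <- parts[[ip]]
      K <- length(p)
      memb <- partition_membership(p, graph$n)
      for (mask in 0:(2^K - 1)) {
        delta <- as.integer(intToBits(mask))[seq_len(K)]
        lm <- graphmm_config_logmarg(
          memb - 1L, delta, prep$xbar, prep$ybar,
          prep$A0inv, prep$B0inv, prep$cX, prep$cY,
          prep$MX, prep$MY, hyper$mu0, hyper$tau2,
          hyper$delta0, hyper$sigma2) + prep$const
        lp <- config_log_prior(p, delta, hyper$p0, np)
        rows[[length(rows) + 1L]] <-
          data.frame(partition = ip, mask = mask, K = K,
                     log_prior = lp, log_marginal = lm)
      }
    }
  } else {
    for (ip in seq_len(np)) {
      p <- parts[[ip]]
      K <- length(p)
      for (mask in 0:(2^K - 1)) {
        delta <- as.integer(intToBits(mask))[seq_len(K)]
        lm <- laplace_log_marginal(stats, p, delta, hyper)
        lp <- config_log_prior(p, delta, hyper$p0, np)
        rows[[length(rows) + 1L]] <-
          data.frame(partition = ip, mask = mask, K = K,
                     log_prior = lp, log_marginal = lm)
      }
    }
  }
  tab <- do.call(rbind, rows)
  lw <- tab$log_prior + tab$log_marginal
  tab$log_weight <- lw - logsumexp(lw)
  structure(list(table = tab, partitions = parts, n = graph$n),
            class = "config_posterior")
}

## shared pre-computation for the compiled per-configuration kernel
cpp_prepare <- function(stats, hyper) {
  N <- length(stats$xbar)
  MX <- stats$MX; MY <- stats$MY; df <- hyper$df
  A0 <- adjusted_scale(hyper$A, stats$S1, MX)
  B0 <- adjusted_scale(hyper$B, stats$T1, MY)
  ldA0 <- pd_logdet(A0); ldB0 <- pd_logdet(B0)
  logC <- -N * (MX + MY) / 2 * log(pi) +
    lmvgamma((df + MX) / 2, N) - lmvgamma(df / 2, N) +
    lmvgamma((df + MY) / 2, N) - lmvgamma(df / 2, N)
  cX <- (df + MX) / 2
  cY <- (df + MY) / 2
  list(xbar = stats$xbar, ybar = stats$ybar,
       A0inv = chol2inv(chol(A0)), B0inv = chol2inv(chol(B0)),
       cX = cX, cY = cY, MX = MX, MY = MY,
       const = logC + df / 2 * (pd_logdet(hyper$A) + pd_logdet(hyper$B)) -
         cX * ldA0 - cY * ldB0)
}

#' @export
print.config_posterior <- function(x, ...) {
  cat(sprintf("config_posterior: %d configurations over %d partitions of %d vertices\n",
              nrow(x$table), length(x$partitions), x$n))
  top <- x$table[order(-x$table$log_weight), ][1:min(5, nrow(x$table)), ]
  cat("top configurations (posterior weight):\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("  partition %d, delta mask %d (K = %d): %.4f\n",
                top$partition[i], top$mask[i], top$K[i],
                exp(top$log_weight[i])))
  invisible(x)
}

#' Local false discovery rate of a vertex
#'
#' Posterior probability that the vertex is null: the sum of posterior
#' configuration weights in which the block containing the vertex is
#' unshifted.
#'
#' @param post a [posterior_over_configs()] result.
#' @param vertex vertex id.
#' @return a probability in `[0, 1]`.
#' @export
local_fdr <- function(post, vertex) {
  vertex <- as.integer(vertex)
  if (vertex < 1L || vertex > post$n) stop("unknown vertex")
  tab <- post$table
  contrib <- vapply(seq_len(nrow(tab)), function(i) {
    p <- post$partitions[[tab$partition[i]]]
    k <- which(vapply(p, function(b) vertex %in% b, TRUE))
    delta_k <- bitwAnd(bitwShiftR(tab$mask[i], k - 1L), 1L)
    if (delta_k == 0L) exp(tab$log_weight[i]) else 0
  }, 1)
  min(1, max(0, sum(contrib)))
}

#' Write a configuration posterior to TSV (debugging aid)
#'
#' @param post a [posterior_over_configs()] result.
#' @param path output file.
#' @export
write_posterior_tsv <- function(post, path) {
  utils::write.table(post$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
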