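## ---- preprocessing transforms and empirical-Bayes hyperparameter estimation

#' Rank-based normal scores, per vertex
#'
#' Each row is replaced by normal quantiles of its midranks across the
#' combined samples: value `Phi^{-1}((rank - 0.5) / M)`.  Group membership of
#' the columns is unchanged, so the transform can be applied to
#' `cbind(x, y)` before splitting back.
#'
#' @param data numeric matrix, vertices x samples.
#' @return matrix of the same shape.
#' @export
normal_scores <- function(data) {
  data <- as.matrix(data)
  M <- ncol(data)
  const <- which(apply(data, 1L, function(r) max(r) == min(r)))
  if (length(const))
    warning(length(const), " constant rows; their normal scores are all zero")
  out <- t(apply(data, 1L, function(r) stats::qnorm((rank(r) - 0.5) / M)))
  dimnames(out) <- dimnames(data)
  out
}

#' Filter vertices with very low marginal standard deviation
#'
#' @param data numeric matrix, vertices x samples (both groups pooled).
#' @param quantile_threshold keep vertices whose pooled SD exceeds this
#'   quantile of all SDs; `0` keeps everything.
#' @return logical keep-mask over vertices.
#' @export
low_variance_filter <- function(data, quantile_threshold = 0.1) {
  if (quantile_threshold < 0 || quantile_threshold >= 1)
    stop("'quantile_threshold' must lie in [0, 1)")
  sds <- apply(as.matrix(data), 1L, stats::sd)
  if (quantile_threshold == 0) return(rep(TRUE, length(sds)))
  sds > stats::quantile(sds, quantile_threshold)
}

#' Storey estimator of the null proportion
#'
#' `p0 = #\{p > lambda\} / ((1 - lambda) n)`, clipped to `[1/n, 1]`.
#'
#' @param pvalues vector of p-values in `[0, 1]`.
#' @param lambda tuning constant, default 0.5.
#' @return estimate in `(0, 1]`.
#' @export
estimate_p0 <- function(pvalues, lambda = 0.5) {
  pvalues <- pvalues[!is.na(pvalues)]
  n <- length(pvalues)
  if (!n) stop("empty p-value vector")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  est <- sum(pvalues > lambda) / ((1 - lambda) * n)
  min(1, max(est, 1 / n))
}

row_vars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1L)
}

## vectorized Welch two-sample t-test p-values, one per vertex
welch_pvalues <- function(x, y) {
  MX <- ncol(x); MY <- ncol(y)
  vx <- row_vars(x); vy <- row_vars(y)
  se2 <- vx / MX + vy / MY
  bad <- se2 <= 0
  if (any(bad))
    warning(sum(bad), " zero-variance vertices; their p-values are set to 1")
  tt <- (rowMeans(x) - rowMeans(y)) / sqrt(se2)
  df <- se2^2 / ((vx / MX)^2 / (MX - 1) + (vy / MY)^2 / (MY - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[bad] <- 1
  p
}

#' Estimate model hyperparameters from whole-graph data
#'
#' Moment-based empirical-Bayes estimates computed across all vertices:
#' \itemize{
#' \item `mu0`, `tau2`: mean and variance over vertices of the pooled
#'   per-vertex sample means (`tau2` floored);
#' \item `delta0 = 0` (symmetric two-sided testing); `sigma2`: variance over
#'   vertices of the observed group differences minus their average sampling
#'   variance, rescaled by the estimated non-null fraction `1 - p0` (the
#'   model's `sigma2` is the shift variance given non-null) and floored;
#' \item `df = n_window + 2`, the smallest value giving the inverse-Wishart a
#'   finite mean, and `A = (df - n_window - 1) * Sigma_X` so the prior is
#'   centred on `Sigma_X`, the across-window average local sample covariance
#'   shrunk halfway toward its diagonal (`B` likewise from group 2);
#' \item `p0`: Storey estimate on per-vertex Welch t-test p-values.
#' }
#' Every choice (floors, Storey `lambda`, shrinkage fraction, `delta0`) is an
#' argument, so any sub-estimator can be overridden.
#'
#' @param data a [two_group_data()] with lattice `dims`.
#' @param nbhd neighbourhood kind defining the local window (see
#'   [local_subgraph()]).
#' @param shrink fraction by which the average window covariance is shrunk
#'   toward its diagonal.
#' @param lambda Storey tuning constant for `p0`.
#' @param floor_tau2,floor_sigma2 variance floors.
#' @param delta0 prior mean of non-null shifts.
#' @param max_windows cap on the number of (evenly spaced, full) windows
#'   averaged for the scale matrices.
#' @return list of class `"graphmm_estimation"` with elements `hyper` (a
#'   [hyperparams()] object) and `diagnostics`.
#' @export
estimate_hyperparams <- function(data, nbhd = c("lattice3x3", "star2d", "star3d"),
                                 shrink = 0.5, lambda = 0.5,
                                 floor_tau2 = 1e-6, floor_sigma2 = 1e-6,
                                 delta0 = 0, max_windows = 2000L) {
  nbhd <- match.arg(nbhd)
  if (is.null(data$dims)) stop("data must carry lattice dims")
  x <- data$x; y <- data$y
  N <- nrow(x); MX <- ncol(x); MY <- ncol(y)
  off <- nbhd_offsets(nbhd, length(data$dims))
  n_win <- nrow(off)

  wide <- N < 50L
  if (wide)
    warning("fewer than 50 vertices; falling back to wide default priors")

  pooled_means <- rowMeans(cbind(x, y))
  mu0 <- mean(pooled_means)
  tau2 <- if (wide) 1 else max(stats::var(pooled_means), floor_tau2)

  pvals <- welch_pvalues(x, y)
  ## cap below 1: a degenerate p0 = 1 would shut the mixture off entirely
  p0 <- min(estimate_p0(pvals, lambda), 0.999)

  ## sigma2 is the shift variance *given non-null*; the observed vertex
  ## differences mix null (no shift) and non-null vertices, so the raw
  ## moment  var(diffs) - sampling variance  estimates (1 - p0) * sigma2
  ## and is rescaled by the estimated non-null fraction
  diffs <- rowMeans(y) - rowMeans(x)
  sampvar <- mean(row_vars(x) / MX + row_vars(y) / MY)
  sigma2 <- if (wide) 1 else
    max((stats::var(diffs) - sampvar) / (1 - p0), floor_sigma2)

  df <- n_win + 2

  ## average local-window covariance at full (unclipped) windows
  full_idx <- which(vapply(seq_len(N), function(v)
    length(window_at(data$dims, v, off)$ids) == n_win, TRUE))
  if (length(full_idx) > max_windows)
    full_idx <- full_idx[round(seq(1L, length(full_idx),
                                   length.out = max_windows))]
  avg_cov <- function(m) {
    S <- matrix(0, n_win, n_win)
    for (v in full_idx) {
      rows <- window_at(data$dims, v, off)$ids
      S <- S + stats::cov(t(m[rows, , drop = FALSE]))
    }
    S <- S / length(full_idx)
    (1 - shrink) * S + shrink * diag(diag(S), n_win)
  }
  if (wide || !length(full_idx)) {
    SigX <- diag(mean(row_vars(x)), n_win)
    SigY <- diag(mean(row_vars(y)), n_win)
  } else {
    SigX <- avg_cov(x)
    SigY <- avg_cov(y)
  }
  A <- (df - n_win - 1) * SigX
  B <- (df - n_win - 1) * SigY

  hy <- hyperparams(mu0 = mu0, tau2 = tau2, delta0 = delta0, sigma2 = sigma2,
                    df = df, A = A, B = B, p0 = p0)
  structure(list(
    hyper = hy,
    diagnostics = list(
      method = c(mu0 = "mean of pooled vertex means",
                 tau2 = "variance of pooled vertex means",
                 sigma2 = "moment estimator on group differences",
                 A = "average window covariance, 50% diagonal shrinkage",
                 p0 = sprintf("Storey(lambda = %g) on Welch p-values", lambda)),
      n_windows = length(full_idx), n_vertices = N,
      sampling_variance = sampvar, wide_defaults = wide)),
    class = "graphmm_estimation")
}

#' @export
print.graphmm_estimation <- function(x, ...) {
  cat("Empirical-Bayes hyperparameter estimates",
      sprintf("(from %d vertices, %d windows):\n",
              x$diagnostics$n_vertices, x$diagnostics$n_windows))
  print(x$hyper)
  invisible(x)
}
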