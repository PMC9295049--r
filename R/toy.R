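## ---- two-pair toy system: the blocking phenomenon in closed form
##
## Units are pairs of variables measured under two conditions: (x1, x2) and
## (y1, y2).  The test concerns the first variable only (H0: mu_x1 = mu_y1,
## with marginal probability p0); with probability p_block the pair is
## "blocked" -- mu_x2 = mu_x1 and mu_y2 = mu_y1 -- in which case the second
## pair of observations carries information about H0.  Latent means are
## standard normal; observations add N(0, sigma2) noise.

#' Parameters of the toy two-pair system
#'
#' @param p0 marginal null probability.
#' @param p_block probability that a pair shares latent means across its two
#'   variables.
#' @param sigma2 observation noise variance.
#' @param n_pairs number of simulated unit pairs.
#' @param seed integer RNG seed (`NULL` to use the current RNG state).
#' @return list of class `"toy_params"`.
#' @export
toy_params <- function(p0 = 0.8, p_block = 0.5, sigma2 = 0.5,
                       n_pairs = 1e4, seed = NULL) {
  if (p0 < 0 || p0 > 1 || p_block < 0 || p_block > 1)
    stop("probabilities must lie in [0, 1]")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  structure(list(p0 = p0, p_block = p_block, sigma2 = sigma2,
                 n_pairs = as.integer(n_pairs), seed = seed),
            class = "toy_params")
}

#' Simulate the toy system
#'
#' Per unit pair: draw the null and blocking states independently, draw the
#' latent means from N(0, 1) subject to the implied equality constraints,
#' then add N(0, sigma2) observation noise.  The test is about the first
#' variable of each pair; `is_null` records its latent truth.
#'
#' @param params a [toy_params()] object.
#' @return data frame with columns `x1, x2, y1, y2, is_null, is_blocked`.
#' @export
toy_simulate <- function(params) {
  stopifnot(inherits(params, "toy_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_pairs
  s <- sqrt(params$sigma2)
  is_null <- stats::rbinom(n, 1, params$p0) == 1
  is_blocked <- stats::rbinom(n, 1, params$p_block) == 1
  mu_x1 <- stats::rnorm(n)
  mu_y1 <- ifelse(is_null, mu_x1, stats::rnorm(n))
  mu_x2 <- ifelse(is_blocked, mu_x1, stats::rnorm(n))
  mu_y2 <- ifelse(is_blocked, mu_y1, stats::rnorm(n))
  data.frame(x1 = mu_x1 + stats::rnorm(n, 0, s),
             x2 = mu_x2 + stats::rnorm(n, 0, s),
             y1 = mu_y1 + stats::rnorm(n, 0, s),
             y2 = mu_y2 + stats::rnorm(n, 0, s),
             is_null = is_null, is_blocked = is_blocked)
}

#' Single-pair local FDR
#'
#' `P(H0 | x1, y1)` for the toy system: a two-component mixture of the null
#' predictive `f` (bivariate normal, margins `N(0, 1 + sigma2)`, correlation
#' `1 / (1 + sigma2)`) and the independent non-null predictive `g(x1) g(y1)`.
#'
#' @param x1,y1 observed values (vectorized).
#' @param params a [toy_params()] object.
#' @return local FDR values in `[0, 1]`.
#' @export
toy_lfdr1 <- function(x1, y1, params) {
  s2 <- params$sigma2
  v <- 1 + s2
  ## joint null covariance [[v, 1], [1, v]]
  det2 <- v^2 - 1
  lf <- -log(2 * pi) - 0.5 * log(det2) -
    (v * x1^2 - 2 * x1 * y1 + v * y1^2) / (2 * det2)
  lg <- stats::dnorm(x1, 0, sqrt(v), log = TRUE) +
    stats::dnorm(y1, 0, sqrt(v), log = TRUE)
  post_odds <- log(params$p0) - log1p(-params$p0) + lf - lg
  if (params$p0 == 0) return(rep(0, length(x1)))
  if (params$p0 == 1) return(rep(1, length(x1)))
  stats::plogis(post_odds)
}

## shared-mean design matrices of the four (null, blocked) components,
## observation order (x1, x2, y1, y2); covariance = sigma2 I + Z Z'
toy_component_Z <- function() {
  list(
    null_blocked = matrix(1, 4, 1),
    null_free = cbind(c(1, 0, 1, 0), c(0, 1, 0, 0), c(0, 0, 0, 1)),
    alt_blocked = cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)),
    alt_free = diag(4))
}

## log density of rows of z4 under N(0, sigma2 I + Z Z')
ldmvnorm0 <- function(z4, Z, sigma2) {
  S <- sigma2 * diag(4) + tcrossprod(Z)
  ch <- chol(S)
  q <- colSums(backsolve(ch, t(z4), transpose = TRUE)^2)
  -2 * log(2 * pi) - sum(log(diag(ch))) - q / 2
}

#' Two-pair local FDR with blocking
#'
#' `P(H0 | x1, x2, y1, y2)`: the four-component mixture over the joint
#' (null, blocked) states.  Each component is a 4-variate normal whose
#' covariance `sigma2 I + Z Z'` is built from the component's shared-mean
#' incidence matrix `Z`.  Reduces exactly to [toy_lfdr1()] when
#' `p_block = 0`.
#'
#' @param x1,x2,y1,y2 observed values (vectorized).
#' @param params a [toy_params()] object.
#' @return local FDR values in `[0, 1]`.
#' @export
toy_lfdr2 <- function(x1, x2, y1, y2, params) {
  if (params$p0 == 0) return(rep(0, length(x1)))
  if (params$p0 == 1) return(rep(1, length(x1)))
  z4 <- cbind(x1, x2, y1, y2)
  Zs <- toy_component_Z()
  ld <- vapply(Zs, function(Z) ldmvnorm0(z4, Z, params$sigma2),
               numeric(nrow(z4)))
  if (is.null(dim(ld))) ld <- matrix(ld, nrow = 1)
  p0 <- params$p0; pb <- params$p_block
  lw <- log(c(p0 * pb, p0 * (1 - pb), (1 - p0) * pb, (1 - p0) * (1 - pb)))
  keep <- is.finite(lw)
  lnum <- apply(ld[, keep & c(TRUE, TRUE, FALSE, FALSE), drop = FALSE] +
                  rep(lw[keep & c(TRUE, TRUE, FALSE, FALSE)],
                      each = nrow(z4)), 1L, logsumexp_vec)
  lden <- apply(ld[, keep, drop = FALSE] +
                  rep(lw[keep], each = nrow(z4)), 1L, logsumexp_vec)
  out <- exp(lnum - lden)
  out[!is.finite(lnum)] <- 0
  pmin(1, pmax(0, out))
}

logsumexp_vec <- function(lw) {
  m <- max(lw)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lw - m)))
}

#' Empirical and score-based FDR along the ranked list
#'
#' Ranks units by score (ascending) and reports, at every prefix size, the
#' empirical FDR (mean of the true null indicators in the prefix) and the
#' score-based controlled FDR (mean of the scores in the prefix).  As the
#' list grows to the full system both approach the marginal null fraction.
#'
#' @param scores per-unit lfdr-type scores (small = more significant).
#' @param truth logical per-unit null indicators.
#' @return data frame with columns `size`, `fdr_empirical`, `fdr_controlled`.
#' @export
fdr_curve <- function(scores, truth) {
  if (length(scores) != length(truth)) stop("scores/truth length mismatch")
  o <- order(scores)
  n <- length(scores)
  data.frame(size = seq_len(n),
             fdr_empirical = cumsum(as.numeric(truth[o])) / seq_len(n),
             fdr_controlled = cumsum(scores[o]) / seq_len(n))
}

#' Effect of mis-specifying the blocking rate
#'
#' Simulates the toy system with one blocking rate and scores it with
#' [toy_lfdr2()] under another (possibly different) assumed rate.  Returns
#' the ranked-list curve of realized empirical FDR against the nominal
#' (score-implied) FDR.  Underestimating the blocking rate retains FDR
#' control; overestimating it (over-regularizing) loses control.
#'
#' @param gen_p_block blocking rate generating the data.
#' @param assumed_p_block blocking rate assumed by the analyst's score.
#' @param params remaining [toy_params()]; its `p_block` is ignored.
#' @return data frame from [fdr_curve()] with attribute `"sim"` holding the
#'   simulated units.
#' @export
misspecification_experiment <- function(gen_p_block, assumed_p_block,
                                        params = toy_params()) {
  gen <- params; gen$p_block <- gen_p_block
  sim <- toy_simulate(gen)
  assumed <- params; assumed$p_block <- assumed_p_block
  sc <- toy_lfdr2(sim$x1, sim$x2, sim$y1, sim$y2, assumed)
  out <- fdr_curve(sc, sim$is_null)
  attr(out, "sim") <- sim
  out
}
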