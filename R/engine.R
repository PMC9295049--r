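## ---- whole-lattice driver: per-vertex local-subgraph inference

## fast arithmetic window lookup on a row-major lattice (x fastest):
## returns original vertex ids of the window around v and which template
## offsets are present (clipped at borders)
window_at <- function(dims, v, off) {
  nd <- length(dims)
  v0 <- v - 1L
  cx <- v0 %% dims[1L] + 1L
  cy <- (v0 %/% dims[1L]) %% dims[2L] + 1L
  cc <- c(cx, cy, if (nd == 3L) v0 %/% (dims[1L] * dims[2L]) + 1L)
  cand <- sweep(off, 2L, cc, `+`)
  present <- rowSums(cand >= 1L & cand <= rep(dims, each = nrow(cand))) == nd
  cand <- cand[present, , drop = FALSE]
  ids <- cand[, 1L]
  mult <- 1L
  for (a in seq_len(nd)[-1L]) {
    mult <- mult * dims[a - 1L]
    ids <- ids + (cand[, a] - 1L) * mult
  }
  list(ids = as.integer(ids), template_idx = which(present))
}

## subgraph of the window in local labels, given the present template rows
window_graph <- function(off, template_idx, nbhd) {
  sub <- off[template_idx, , drop = FALSE]
  n <- nrow(sub)
  if (nbhd == "lattice3x3") {
    ed <- NULL
    for (i in seq_len(n)) for (j in seq_len(n))
      if (i < j && sum(abs(sub[i, ] - sub[j, ])) == 1L)
        ed <- rbind(ed, c(i, j))
  } else {
    cloc <- which(rowSums(abs(sub)) == 0L)
    ed <- if (n > 1L) cbind(cloc, setdiff(seq_len(n), cloc)) else NULL
  }
  vgraph(n, ed)
}

## membership matrix (n_sub x P, 0-based labels) of all graph-respecting
## partitions of a window subgraph
partition_membs <- function(graph) {
  parts <- enumerate_partitions(graph)
  membs <- vapply(parts, function(p) partition_membership(p, graph$n) - 1L,
                  integer(graph$n))
  matrix(membs, nrow = graph$n)
}

#' Fit the graph-based mixture model over a lattice
#'
#' For every vertex of a 2D or 3D lattice, extracts the local subgraph of the
#' chosen neighbourhood, restricts the data to its rows, enumerates all
#' (graph-respecting partition, block shift-state) configurations, and
#' reports the posterior probability that the centre vertex is null -- its
#' local false discovery rate.  Hyperparameters are shared across the lattice
#' and estimated from the whole data set unless supplied.  The scale matrices
#' `A`, `B` are estimated at the full window size and subset to principal
#' submatrices at clipped border windows.
#'
#' Vertices whose computation fails are scored conservatively with
#' `lfdr = 1` and recorded in the `failed` field.
#'
#' @param data a [two_group_data()], or a matrix for group 1.
#' @param y group-2 matrix when `data` is a matrix.
#' @param dims lattice dimensions (defaults to `data$dims`).
#' @param nbhd neighbourhood kind: in-slice `"lattice3x3"` window (default),
#'   `"star2d"` (4 in-slice neighbours) or `"star3d"` (6 neighbours).
#' @param hyper a [hyperparams()] object sized to the full window, or `NULL`
#'   to estimate via [estimate_hyperparams()].
#' @param threshold default local-FDR discovery threshold used by `summary`
#'   and [discoveries()].
#' @param verbose print progress every 500 vertices.
#' @return an object of class `"graphmm"` with components `lfdr` (per-vertex
#'   local FDR), `dims`, `nbhd`, `hyper`, `threshold`, `failed` and `call`.
#' @seealso [discoveries()], [controlled_fdr()], [empirical_fdr_tpr()],
#'   [ttest_bh()] for the standard baseline.
#' @examples
#' sc <- scenario_spec(dims = c(8, 8), M_X = 8, M_Y = 8, seed = 1)
#' sim <- simulate_scenario(sc)
#' fit <- graphmm(sim$data, nbhd = "star2d")
#' summary(fit)
#' @export
graphmm <- function(data, y = NULL, dims = NULL,
                    nbhd = c("lattice3x3", "star2d", "star3d"),
                    hyper = NULL, threshold = 0.05, verbose = FALSE) {
  cl <- match.call()
  nbhd <- match.arg(nbhd)
  if (!inherits(data, "two_group_data"))
    data <- two_group_data(data, y, dims = dims)
  if (is.null(dims)) dims <- data$dims
  if (is.null(dims)) stop("lattice 'dims' are required")
  dims <- as.integer(dims)
  if (prod(dims) != nrow(data$x)) stop("prod(dims) must match data rows")
  data$dims <- dims

  if (is.null(hyper)) hyper <- estimate_hyperparams(data, nbhd)$hyper
  if (!inherits(hyper, "graphmm_hyper")) stop("'hyper' must come from hyperparams()")
  off <- nbhd_offsets(nbhd, length(dims))
  if (nrow(hyper$A) != nrow(off))
    stop("hyper$A must be sized to the full ", nrow(off), "-vertex window")

  x <- data$x; y <- data$y
  N <- nrow(x); MX <- ncol(x); MY <- ncol(y)
  df <- hyper$df
  cX <- (df + MX) / 2; cY <- (df + MY) / 2

  shape_cache <- new.env(parent = emptyenv())
  lfdr <- rep(NA_real_, N)
  failed <- integer(0)
  for (v in seq_len(N)) {
    w <- window_at(dims, v, off)
    key <- paste(w$template_idx, collapse = ",")
    sh <- shape_cache[[key]]
    if (is.null(sh)) {
      g <- window_graph(off, w$template_idx, nbhd)
      sh <- list(membs = partition_membs(g),
                 center = match(which(rowSums(abs(off)) == 0L),
                                w$template_idx))
      shape_cache[[key]] <- sh
    }
    res <- tryCatch({
      xs <- x[w$ids, , drop = FALSE]
      ys <- y[w$ids, , drop = FALSE]
      Aw <- hyper$A[w$template_idx, w$template_idx, drop = FALSE]
      Bw <- hyper$B[w$template_idx, w$template_idx, drop = FALSE]
      A0 <- adjusted_scale(Aw, stats::cov(t(xs)), MX)
      B0 <- adjusted_scale(Bw, stats::cov(t(ys)), MY)
      graphmm_center_lfdr(sh$membs, sh$center - 1L, rowMeans(xs),
                          rowMeans(ys), chol2inv(chol(A0)),
                          chol2inv(chol(B0)), cX, cY, MX, MY,
                          hyper$mu0, hyper$tau2, hyper$delta0, hyper$sigma2,
                          hyper$p0)
    }, error = function(e) NA_real_)
    if (is.na(res)) {
      failed <- c(failed, v)
      res <- 1
    }
    lfdr[v] <- res
    if (verbose && v %% 500L == 0L)
      message("  vertex ", v, " / ", N)
  }
  if (length(failed))
    warning(length(failed), " vertices failed and were scored lfdr = 1")
  structure(list(lfdr = lfdr, dims = dims, nbhd = nbhd, hyper = hyper,
                 threshold = threshold, failed = failed, call = cl),
            class = "graphmm")
}

#' @export
print.graphmm <- function(x, ...) {
  cat("Graph-based mixture model local FDR fit\n")
  cat(sprintf("  lattice %s, neighbourhood %s, %d vertices\n",
              paste(x$dims, collapse = "x"), x$nbhd, length(x$lfdr)))
  cat(sprintf("  discoveries at lfdr <= %g: %d\n", x$threshold,
              length(discoveries(x, x$threshold))))
  invisible(x)
}

#' @export
summary.graphmm <- function(object, thresholds = c(0.01, 0.05, 0.1), ...) {
  rows <- lapply(thresholds, function(c0) {
    L <- discoveries(object, c0)
    data.frame(threshold = c0, n_discoveries = length(L),
               controlled_fdr = if (length(L))
                 controlled_fdr(object, L) else NA_real_)
  })
  out <- list(table = do.call(rbind, rows), nbhd = object$nbhd,
              dims = object$dims, n_failed = length(object$failed),
              lfdr_quartiles = stats::quantile(object$lfdr))
  class(out) <- "summary.graphmm"
  out
}

#' @export
print.summary.graphmm <- function(x, ...) {
  cat(sprintf("graphmm fit on a %s lattice (%s neighbourhood)\n",
              paste(x$dims, collapse = "x"), x$nbhd))
  cat("local FDR quartiles:\n")
  print(round(x$lfdr_quartiles, 4))
  cat("discoveries:\n")
  print(x$table, row.names = FALSE)
  if (x$n_failed) cat(x$n_failed, "vertices failed (scored 1)\n")
  invisible(x)
}

#' @export
fitted.graphmm <- function(object, ...) object$lfdr

#' @export
plot.graphmm <- function(x, slice = 1L, ...) {
  if (length(x$dims) == 2L) {
    m <- matrix(x$lfdr, x$dims[1L], x$dims[2L])
  } else {
    m <- array(x$lfdr, x$dims)[, , slice]
  }
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), 1 - m,
                  xlab = "x", ylab = "y", zlim = c(0, 1),
                  main = "1 - local FDR", ...)
  invisible(x)
}

#' @export
as.data.frame.graphmm <- function(x, row.names = NULL, optional = FALSE, ...) {
  co <- lattice_graph(x$dims)$coords
  d <- data.frame(vertex = seq_along(x$lfdr), co, lfdr = x$lfdr)
  d$discovered <- d$lfdr <= x$threshold
  d
}

#' Discovery list at a local-FDR threshold
#'
#' Vertices with `lfdr <= c`, ordered by increasing lfdr (ties by vertex id).
#'
#' @param fit a `"graphmm"` fit or a numeric lfdr vector.
#' @param c threshold in `[0, 1]`.
#' @return integer vertex ids.
#' @export
discoveries <- function(fit, c = 0.05) {
  l <- if (inherits(fit, "graphmm")) fit$lfdr else as.numeric(fit)
  if (c < 0 || c > 1) stop("'c' must lie in [0, 1]")
  v <- which(l <= c)
  v[order(l[v], v)]
}

#' Controlled (data-computable) FDR of a discovery list
#'
#' The mean of the local FDRs over the list: the conditional expected
#' type-I proportion given data.
#'
#' @inheritParams discoveries
#' @param list integer vertex ids.
#' @return a proportion.
#' @export
controlled_fdr <- function(fit, list) {
  l <- if (inherits(fit, "graphmm")) fit$lfdr else as.numeric(fit)
  if (!length(list)) stop("empty discovery list: controlled FDR undefined")
  mean(l[list])
}

#' Empirical FDR and TPR against known truth
#'
#' For synthetic data with known per-vertex null status, counts the realized
#' false-discovery proportion and true-positive rate of a list.
#'
#' @param list integer vertex ids (the discoveries).
#' @param null_true logical per-vertex null indicator.
#' @return list with `empirical_fdr`, `tpr`, `list_size` and `empty` flag
#'   (`empirical_fdr` is reported as 0 with `empty = TRUE` for empty lists).
#' @export
empirical_fdr_tpr <- function(list, null_true) {
  n_nonnull <- sum(!null_true)
  if (!length(list))
    return(list(empirical_fdr = 0, tpr = if (n_nonnull) 0 else NA_real_,
                list_size = 0L, empty = TRUE))
  list(empirical_fdr = mean(null_true[list]),
       tpr = if (n_nonnull) sum(!null_true[list]) / n_nonnull else NA_real_,
       list_size = length(list), empty = FALSE)
}

#' Welch t-tests with Benjamini-Hochberg adjustment
#'
#' The standard mass-univariate baseline: per-vertex Welch two-sample
#' t-tests, BH step-up adjustment, rejection at `alpha`.
#'
#' @param data a [two_group_data()].
#' @param alpha nominal FDR level.
#' @return list with `p`, `p_adjusted` and logical `reject`.
#' @export
ttest_bh <- function(data, alpha = 0.05) {
  p <- welch_pvalues(data$x, data$y)
  adj <- stats::p.adjust(p, method = "BH")
  list(p = p, p_adjusted = adj, reject = adj <= alpha)
}

#' Storey q-values
#'
#' `q_i = min_{p_j >= p_i} p0 n p_j / rank_j`, with the null proportion from
#' [estimate_p0()].
#'
#' @param pvalues p-values in `[0, 1]`.
#' @param lambda Storey tuning constant for the `p0` estimate.
#' @return q-values in the original order.
#' @export
storey_qvalues <- function(pvalues, lambda = 0.5) {
  n <- length(pvalues)
  p0 <- estimate_p0(pvalues, lambda)
  o <- order(pvalues)
  q <- p0 * n * pvalues[o] / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

#' Connected components of a discovery mask ("significant clusters")
#'
#' Post-hoc utility: groups the vertices discovered at a threshold into
#' connected components of the lattice.
#'
#' @param fit a `"graphmm"` fit.
#' @param c lfdr threshold.
#' @return list of integer vertex-id vectors, largest first.
#' @export
significant_clusters <- function(fit, c = 0.05) {
  disc <- sort(discoveries(fit, c))
  if (!length(disc)) return(list())
  g <- lattice_graph(fit$dims)
  inmask <- logical(g$n)
  inmask[disc] <- TRUE
  seen <- logical(g$n)
  comps <- list()
  for (v in disc) {
    if (seen[v]) next
    queue <- v
    seen[v] <- TRUE
    comp <- v
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      nb <- g$adj[[u]]
      nb <- nb[inmask[nb] & !seen[nb]]
      seen[nb] <- TRUE
      comp <- c(comp, nb)
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(-lengths(comps))]
}
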