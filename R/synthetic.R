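## ---- lattice scenario generator: blocked latent means with known truth

#' Specify a synthetic lattice scenario
#'
#' Describes a generative scenario on a 2D/3D lattice: contiguous latent
#' blocks drawn by seeded region growing, block-level group shifts, and
#' Gaussian noise.  Ground truth (the partition and per-vertex null status)
#' is retained so empirical FDR and TPR can be computed.
#'
#' Block-size laws: `"uniform12_14"` draws target sizes uniformly from
#' 12..14 (the large-block regime), `"mean4"` draws `1 + Poisson(3)` sizes
#' averaging 4 vertices, `"singleton"` makes every vertex its own block.
#'
#' @param dims lattice dimensions (default a single coronal-slice-sized 2D
#'   lattice is far larger than test runs need; pick small dims for speed).
#' @param block_size_law one of `"uniform12_14"`, `"mean4"`, `"singleton"`.
#' @param shift_fraction fraction of blocks shifted between groups.
#' @param shift_magnitude block shift in units of the noise SD (sign random).
#' @param noise `"independent"` or `"spatial"` (squared-exponential
#'   correlation with `noise_range` in voxels).
#' @param noise_sd noise standard deviation.
#' @param noise_range correlation range for spatial noise.
#' @param M_X,M_Y group sample sizes.
#' @param mu0,tau2 mean and variance of the latent block base means.
#' @param graph_respecting if `FALSE`, a fraction `reassign_fraction` of
#'   vertices is reassigned to non-adjacent blocks after growing, violating
#'   the contiguity assumption while keeping means clustered (robustness
#'   experiment).
#' @param reassign_fraction see `graph_respecting`.
#' @param seed integer RNG seed.
#' @return list of class `"scenario_spec"`.
#' @export
scenario_spec <- function(dims = c(70, 75),
                          block_size_law = c("uniform12_14", "mean4",
                                             "singleton"),
                          shift_fraction = 0.2, shift_magnitude = 1,
                          noise = c("independent", "spatial"),
                          noise_sd = 1, noise_range = 2,
                          M_X = 30, M_Y = 30, mu0 = 0, tau2 = 1,
                          graph_respecting = TRUE, reassign_fraction = 0.2,
                          seed = NULL) {
  block_size_law <- match.arg(block_size_law)
  noise <- match.arg(noise)
  if (shift_fraction < 0 || shift_fraction > 1)
    stop("'shift_fraction' must lie in [0, 1]")
  if (any(dims < 1)) stop("'dims' must be positive")
  structure(list(dims = as.integer(dims), block_size_law = block_size_law,
                 shift_fraction = shift_fraction,
                 shift_magnitude = shift_magnitude, noise = noise,
                 noise_sd = noise_sd, noise_range = noise_range,
                 M_X = as.integer(M_X), M_Y = as.integer(M_Y),
                 mu0 = mu0, tau2 = tau2,
                 graph_respecting = isTRUE(graph_respecting),
                 reassign_fraction = reassign_fraction, seed = seed),
            class = "scenario_spec")
}

## target block size, constrained so the remaining vertex count stays
## representable as a sum of law-range sizes (uniform law only)
sample_block_size <- function(law, remaining) {
  switch(law,
    uniform12_14 = {
      lo <- 12L; hi <- 14L
      feasible <- function(r) {
        r == 0L || (ceiling(r / hi) <= floor(r / lo))
      }
      cand <- lo:hi
      cand <- cand[cand <= remaining & vapply(cand, function(s)
        feasible(remaining - s), TRUE)]
      if (!length(cand)) return(min(remaining, hi))
      if (length(cand) == 1L) cand else sample(cand, 1L)
    },
    mean4 = max(1L, 1L + stats::rpois(1L, 3)),
    singleton = 1L)
}

#' Draw a contiguous blocked partition of a lattice
#'
#' Seeded region growing: the smallest unassigned vertex starts a region
#' which grows by uniform random frontier expansion to a target size drawn
#' from the block-size law; regions that run out of frontier below the law's
#' minimum are merged into an adjacent block.  With
#' `graph_respecting = FALSE` a fraction of vertices is afterwards
#' reassigned to random non-adjacent blocks.
#'
#' @param spec a [scenario_spec()].
#' @return a partition (canonical block list, see [as_partition()]).
#' @export
generate_blocked_partition <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  g <- lattice_graph(spec$dims)
  N <- g$n
  if (spec$block_size_law == "singleton" && spec$graph_respecting)
    return(as_partition(as.list(seq_len(N))))
  assigned <- integer(N)   # block label per vertex, 0 = unassigned
  nblocks <- 0L
  min_size <- if (spec$block_size_law == "uniform12_14") 12L else 1L
  while (any(assigned == 0L)) {
    remaining <- sum(assigned == 0L)
    seedv <- which.max(assigned == 0L)
    target <- sample_block_size(spec$block_size_law, remaining)
    region <- seedv
    assigned[seedv] <- -1L  # provisional
    frontier <- g$adj[[seedv]][assigned[g$adj[[seedv]]] == 0L]
    while (length(region) < target && length(frontier)) {
      ## prefer frontier vertices with the fewest unassigned neighbours
      ## (fills concave corners first, so growth rarely strands pockets),
      ## breaking ties at random
      holes <- vapply(frontier, function(v)
        sum(assigned[g$adj[[v]]] == 0L), 1L)
      cand <- frontier[holes == min(holes)]
      w <- if (length(cand) == 1L) cand else sample(cand, 1L)
      region <- c(region, w)
      assigned[w] <- -1L
      frontier <- unique(c(frontier, g$adj[[w]]))
      frontier <- frontier[assigned[frontier] == 0L]
    }
    if (length(region) < min_size && nblocks > 0L) {
      ## stuck pocket: merge into an adjacent existing block
      nb_blocks <- unique(assigned[unlist(g$adj[region])])
      nb_blocks <- nb_blocks[nb_blocks > 0L]
      tgt <- if (length(nb_blocks) == 1L) nb_blocks else sample(nb_blocks, 1L)
      assigned[region] <- tgt
    } else {
      nblocks <- nblocks + 1L
      assigned[region] <- nblocks
    }
  }
  if (!spec$graph_respecting && nblocks > 1L) {
    n_move <- round(spec$reassign_fraction * N)
    move <- sample(N, n_move)
    for (v in move) {
      others <- setdiff(seq_len(nblocks),
                        c(assigned[v], assigned[g$adj[[v]]]))
      if (length(others))
        assigned[v] <- if (length(others) == 1L) others else sample(others, 1L)
    }
    ## dropped labels are re-packed by as_partition
  }
  as_partition(assigned)
}

#' Generate two-group data from a blocked partition
#'
#' Block base means are drawn `N(mu0, tau2)` and shared by both groups;
#' shifted blocks (Bernoulli `shift_fraction`) move the group-2 mean by
#' `shift_magnitude * noise_sd` with random sign.  Samples add Gaussian
#' noise, independent or spatially correlated.  Truth is recorded per
#' vertex: null iff its block is unshifted.
#'
#' @param partition block list covering the lattice.
#' @param spec a [scenario_spec()].
#' @return list with `data` (a [two_group_data()]) and `truth` (list:
#'   `partition`, `shifted_blocks`, logical `null` per vertex, `mu_x`,
#'   `mu_y`).
#' @export
generate_scenario_data <- function(partition, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  N <- prod(spec$dims)
  partition <- as_partition(partition)
  if (sum(lengths(partition)) != N)
    stop("partition does not cover the lattice")
  K <- length(partition)
  phi <- stats::rnorm(K, spec$mu0, sqrt(spec$tau2))
  shifted <- stats::rbinom(K, 1, spec$shift_fraction) == 1
  delta <- ifelse(shifted,
                  spec$shift_magnitude * spec$noise_sd *
                    sample(c(-1, 1), K, replace = TRUE), 0)
  memb <- partition_membership(partition, N)
  mu_x <- phi[memb]
  mu_y <- (phi + delta)[memb]
  noise <- function(M) {
    if (spec$noise == "independent") {
      matrix(stats::rnorm(N * M, 0, spec$noise_sd), N, M)
    } else {
      co <- lattice_graph(spec$dims)$coords
      D2 <- as.matrix(stats::dist(co))^2
      S <- spec$noise_sd^2 * exp(-D2 / (2 * spec$noise_range^2))
      diag(S) <- diag(S) + 1e-8
      t(chol(S)) %*% matrix(stats::rnorm(N * M), N, M)
    }
  }
  x <- mu_x + noise(spec$M_X)
  y <- mu_y + noise(spec$M_Y)
  list(data = two_group_data(x, y, dims = spec$dims),
       truth = list(partition = partition,
                    shifted_blocks = which(shifted),
                    null = !shifted[memb],
                    mu_x = mu_x, mu_y = mu_y))
}

#' Simulate a full scenario (partition + data) in one call
#'
#' @param spec a [scenario_spec()].
#' @return as [generate_scenario_data()].
#' @export
simulate_scenario <- function(spec) {
  part <- generate_blocked_partition(spec)  # seeds the RNG from spec$seed
  generate_scenario_data(part, spec)
}

#' Permute sample labels
#'
#' Pools the columns of both groups and randomly re-splits them into groups
#' of the original sizes, destroying any true group difference while keeping
#' each sample's spatial structure intact.
#'
#' @param data a [two_group_data()].
#' @param seed integer RNG seed (`NULL`: current RNG state).
#' @return a [two_group_data()] of the same shape.
#' @export
permute_sample_labels <- function(data, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- cbind(data$x, data$y)
  MX <- ncol(data$x)
  o <- sample(ncol(pool))
  two_group_data(pool[, o[seq_len(MX)], drop = FALSE],
                 pool[, o[-seq_len(MX)], drop = FALSE], dims = data$dims)
}

#' Permute vertices
#'
#' Applies one random vertex permutation identically to every sample in both
#' groups: per-vertex marginals are preserved, spatial structure (of both
#' signal and noise) is destroyed.
#'
#' @inheritParams permute_sample_labels
#' @return list with the permuted [two_group_data()] and the permutation
#'   (`perm[new] = old`).
#' @export
permute_voxels <- function(data, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(data$x)
  perm <- sample(N)
  list(data = two_group_data(data$x[perm, , drop = FALSE],
                             data$y[perm, , drop = FALSE], dims = data$dims),
       perm = perm)
}
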