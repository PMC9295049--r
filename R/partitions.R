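#' Graph-respecting partitions
#'
#' A partition of a graph's vertex set is *graph respecting* when every block
#' induces a connected subgraph.  Constraining group means to be constant on
#' the blocks of such a partition is the dimension reduction that drives the
#' mixture model: the set of graph-respecting partitions is far smaller than
#' the set of all set partitions once the graph is sparse (1434 versus the 9th
#' Bell number 21147 for the 3x3 lattice).
#'
#' Partitions are represented as lists of integer vectors in canonical form:
#' vertices sorted within blocks, blocks ordered by their smallest member.
#'
#' @name partitions
NULL

#' Canonicalize a partition
#'
#' @param blocks list of integer vectors (or an integer membership vector,
#'   one block label per vertex).
#' @return list of sorted integer vectors, blocks ordered by smallest member.
#' @export
as_partition <- function(blocks) {
  if (!is.list(blocks)) {
    labels <- as.integer(blocks)
    blocks <- split(seq_along(labels), labels)
  }
  blocks <- lapply(blocks, function(b) sort(as.integer(b)))
  if (any(vapply(blocks, length, 1L) == 0L)) stop("blocks must be non-empty")
  blocks <- blocks[order(vapply(blocks, min, 1L))]
  names(blocks) <- NULL
  blocks
}

#' Membership vector of a partition
#'
#' @param partition list of blocks.
#' @param n vertex count (defaults to the number of partitioned vertices).
#' @return integer vector, `membership[v]` = index of the block holding `v`.
#' @export
partition_membership <- function(partition, n = sum(lengths(partition))) {
  m <- integer(n)
  for (k in seq_along(partition)) m[partition[[k]]] <- k
  m
}

## connectivity of an induced vertex subset, by breadth-first search
induced_connected <- function(vertices, adj) {
  nv <- length(vertices)
  if (nv <= 1L) return(TRUE)
  inset <- logical(length(adj))
  inset[vertices] <- TRUE
  seen <- logical(length(adj))
  queue <- vertices[1L]
  seen[queue] <- TRUE
  found <- 1L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    nb <- adj[[v]]
    nb <- nb[inset[nb] & !seen[nb]]
    seen[nb] <- TRUE
    found <- found + length(nb)
    queue <- c(queue, nb)
  }
  found == nv
}

#' Test whether a partition respects a graph
#'
#' @param partition list of blocks covering `1..graph$n` exactly once.
#' @param graph a [vgraph()].
#' @return `TRUE` iff every block induces a connected subgraph.
#' @examples
#' g <- lattice_graph(c(3, 1))             # path 1-2-3
#' is_graph_respecting(list(c(1, 3), 2), g)  # FALSE: {1,3} is disconnected
#' @export
is_graph_respecting <- function(partition, graph) {
  partition <- as_partition(partition)
  covered <- sort(unlist(partition))
  if (!identical(covered, seq_len(graph$n)))
    stop("partition must cover the graph's vertex set exactly once")
  all(vapply(partition, induced_connected, TRUE, adj = graph$adj))
}

## Enumerate all connected vertex subsets of `rem` (logical mask) that contain
## `v`, calling `emit(subset)` for each.  Standard frontier-expansion scheme:
## at each level, either stop (emit) or add one extension vertex; vertices
## popped from the extension list are forbidden in that branch, so every
## connected superset is produced exactly once.
connected_subsets_containing <- function(v, rem, adj, emit) {
  n <- length(rem)
  forb_base <- !rem
  forb_base[v] <- TRUE
  recurse <- function(set, ext, forb) {
    emit(set)
    while (length(ext)) {
      w <- ext[[1L]]
      ext <- ext[-1L]
      forb[w] <- TRUE
      nb <- adj[[w]]
      nb <- nb[!forb[nb]]
      forb2 <- forb
      forb2[nb] <- TRUE   # queued vertices must not be re-queued deeper
      forb2[ext] <- TRUE
      recurse(c(set, w), c(ext, nb), forb2)
    }
  }
  nb0 <- adj[[v]]
  nb0 <- nb0[!forb_base[nb0]]
  forb0 <- forb_base
  forb0[nb0] <- TRUE
  recurse(v, nb0, forb0)
  invisible(NULL)
}

## per-session cache of enumerations, keyed by graph shape
.partition_cache <- new.env(parent = emptyenv())

graph_key <- function(graph) {
  paste(graph$n, paste(t(graph$edges), collapse = ","), sep = ";")
}

#' Enumerate all graph-respecting partitions
#'
#' Exhaustive recursion: the block containing the smallest unassigned vertex is
#' grown over every connected subset of the remaining graph that contains it,
#' then the rest is partitioned recursively.  Each partition is produced once,
#' in canonical form.  Results are cached per graph shape for the session.
#'
#' @param graph a connected [vgraph()].
#' @param cap refuse graphs larger than this many vertices (enumeration is
#'   exponential; the model only ever needs small local subgraphs).
#' @return list of partitions (each a list of integer-vector blocks).
#' @examples
#' length(enumerate_partitions(lattice_graph(c(3, 3))))  # 1434
#' @export
enumerate_partitions <- function(graph, cap = 12L) {
  stopifnot(inherits(graph, "vgraph"))
  if (graph$n > cap)
    stop("graph order ", graph$n, " exceeds enumeration cap ", cap)
  key <- graph_key(graph)
  hit <- .partition_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- vector("list", 2048L)
  count <- 0L
  adj <- graph$adj
  recurse <- function(rem, acc) {
    if (!any(rem)) {
      count <<- count + 1L
      if (count > length(out)) length(out) <<- 2L * length(out)
      out[[count]] <<- acc
      return(invisible(NULL))
    }
    v <- which.max(rem)  # smallest remaining vertex
    connected_subsets_containing(v, rem, adj, function(set) {
      rem2 <- rem
      rem2[set] <- FALSE
      recurse(rem2, c(acc, list(sort(set))))
    })
  }
  recurse(rep(TRUE, graph$n), list())
  out <- out[seq_len(count)]
  .partition_cache[[key]] <- out
  out
}

#' Bell numbers
#'
#' Number of set partitions of `n` labelled objects, via the Bell triangle
#' recurrence.  Exact for `n <= 20` (values stay below 2^53).
#'
#' @param n integer in `0..20`.
#' @return the Bell number as a double.
#' @examples
#' bell_number(9)  # 21147
#' @export
bell_number <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 0L || n > 20L)
    stop("'n' must be a single integer in 0..20")
  if (n == 0L) return(1)
  row <- 1
  for (i in seq_len(n - 1L)) row <- cumsum(c(row[length(row)], row))
  row[length(row)]
}

#' Central-block statistics under the uniform partition law
#'
#' Under the uniform distribution over a supplied set of partitions, computes
#' the probability mass function of the size of the block containing a given
#' centre vertex, and the median number of blocks.  For the 1434
#' graph-respecting partitions of the 3x3 lattice with the centre vertex this
#' gives P(size <= 3) = 0.71 and a median of 4 blocks: the prior insulates the
#' vertex on test from data far away in the window.
#'
#' @param partitions list of partitions, e.g. from [enumerate_partitions()].
#' @param center vertex id.
#' @return list with `pmf` (named numeric, block-size distribution),
#'   `median_blocks` and `n_partitions`.
#' @export
central_block_stats <- function(partitions, center) {
  if (!length(partitions)) stop("empty partition list")
  center <- as.integer(center)
  sizes <- vapply(partitions, function(p) {
    for (b in p) if (center %in% b) return(length(b))
    stop("center vertex ", center, " not covered by a partition")
  }, 1L)
  ks <- vapply(partitions, length, 1L)
  pmf <- table(sizes) / length(sizes)
  pmf <- stats::setNames(as.numeric(pmf), names(pmf))
  list(pmf = pmf,
       median_blocks = stats::median(ks),
       n_partitions = length(partitions))
}
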