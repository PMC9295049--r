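#' Vertex graphs
#'
#' Lightweight undirected simple graph container used throughout the package.
#' Vertices are the integers `1..n`; edges are stored as a two-column integer
#' matrix with `edge[1] < edge[2]` in every row; `coords` optionally holds
#' integer lattice coordinates (one row per vertex, 2 or 3 columns).
#'
#' @param n number of vertices.
#' @param edges two-column integer matrix (or `NULL` for an edgeless graph).
#' @param coords optional integer matrix of lattice coordinates, `n` rows.
#' @return an object of class `"vgraph"` with fields `n`, `edges`, `adj`
#'   (adjacency list) and `coords`.
#' @examples
#' g <- vgraph(3, rbind(c(1, 2), c(2, 3)))
#' g$adj
#' @export
vgraph <- function(n, edges = NULL, coords = NULL) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("'n' must be a single positive integer")
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
  }
  if (any(is.na(edges)) || any(edges < 1L) || any(edges > n))
    stop("edge endpoints must be vertices in 1..n")
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-loops are not allowed")
  ## canonical order: u < v, rows sorted, duplicates dropped
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
  if (nrow(edges)) {
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  adj <- rep(list(integer(0)), n)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1L]; v <- edges[i, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  adj <- lapply(adj, sort)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "integer"
    if (nrow(coords) != n) stop("'coords' must have one row per vertex")
  }
  structure(list(n = n, edges = edges, adj = adj, coords = coords),
            class = "vgraph")
}

#' @export
print.vgraph <- function(x, ...) {
  cat(sprintf("vgraph: %d vertices, %d edges%s\n", x$n, nrow(x$edges),
              if (!is.null(x$coords))
                sprintf(", %dD lattice coordinates", ncol(x$coords))
              else ""))
  invisible(x)
}

#' Build a 2D or 3D lattice graph
#'
#' Vertices are the cells of a rectangular grid, connected when their integer
#' coordinates differ by 1 in exactly one axis (rook adjacency, L1 distance 1).
#' Vertex ids are row-major with the first coordinate varying fastest, so for
#' `dims = c(nx, ny)` vertex `v` sits at
#' `x = (v-1) %% nx + 1`, `y = (v-1) %/% nx + 1`.
#'
#' @param dims integer vector of 2 or 3 positive extents.
#' @return a [vgraph()] with populated `coords`.
#' @examples
#' g <- lattice_graph(c(3, 3))   # 9 vertices, 12 edges
#' nrow(g$edges)
#' @export
lattice_graph <- function(dims) {
  dims <- as.integer(dims)
  if (!length(dims) %in% c(2L, 3L) || any(is.na(dims)) || any(dims < 1L))
    stop("'dims' must be 2 or 3 positive integers")
  n <- prod(dims)
  coords <- as.matrix(do.call(expand.grid, lapply(dims, seq_len)))
  colnames(coords) <- c("x", "y", "z")[seq_along(dims)]
  ## edges: along each axis connect consecutive coordinates
  edges <- NULL
  id <- function(cc) {
    v <- cc[, 1L]
    mult <- 1L
    for (a in seq_along(dims)[-1L]) {
      mult <- mult * dims[a - 1L]
      v <- v + (cc[, a] - 1L) * mult
    }
    v
  }
  for (axis in seq_along(dims)) {
    keep <- coords[, axis] < dims[axis]
    if (!any(keep)) next
    from <- coords[keep, , drop = FALSE]
    to <- from
    to[, axis] <- to[, axis] + 1L
    edges <- rbind(edges, cbind(id(from), id(to)))
  }
  vgraph(n, edges, coords)
}

#' Read a graph from a whitespace-delimited edge list
#'
#' Expects two integer columns of 1-based vertex ids.  The vertex count is
#' `max(id)` unless given.
#'
#' @param path file path.
#' @param n optional vertex count.
#' @return a [vgraph()].
#' @export
read_edgelist <- function(path, n = NULL) {
  ed <- utils::read.table(path, header = FALSE)
  if (ncol(ed) < 2L) stop("edge list must have two integer columns")
  ed <- as.matrix(ed[, 1:2])
  if (is.null(n)) n <- max(ed)
  vgraph(n, ed)
}

## canonical in-slice window offsets for each neighborhood kind; the ordering
## here fixes how the full-window scale matrices A and B are indexed, so
## clipped border windows can take principal submatrices.
nbhd_offsets <- function(nbhd, ndim) {
  switch(nbhd,
    lattice3x3 = {
      off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))
      if (ndim == 3L) off <- cbind(off, dz = 0L)
      off
    },
    star2d = {
      off <- rbind(c(0, 0), c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
      if (ndim == 3L) off <- cbind(off, 0L)
      off
    },
    star3d = {
      if (ndim != 3L) stop("star3d requires a 3D lattice")
      rbind(c(0, 0, 0), c(-1, 0, 0), c(1, 0, 0),
            c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
    },
    stop("unknown neighborhood kind: ", nbhd))
}

#' Extract the local model subgraph around a vertex
#'
#' GraphMM runs its mixture model on a small subgraph centred on the vertex
#' under test.  Three neighbourhood kinds are supported: the in-slice 3x3
#' lattice window (`"lattice3x3"`), a 2D star of the 4 in-slice first-order
#' neighbours (`"star2d"`), and a 3D star of all 6 first-order neighbours
#' (`"star3d"`).  Windows are clipped at lattice borders, never padded; the
#' model runs on whatever connected subgraph results.
#'
#' @param graph a [vgraph()] with lattice coordinates.
#' @param center vertex id.
#' @param nbhd neighbourhood kind.
#' @return a list with components `graph` (the local [vgraph()], vertices
#'   relabelled `1..n_sub`), `vertices` (their original ids), `center` (local
#'   index of the centre) and `template_idx` (which rows of the canonical
#'   full-window offset template are present; used to subset scale matrices).
#' @examples
#' g <- lattice_graph(c(5, 5))
#' local_subgraph(g, 13, "lattice3x3")$graph   # interior: full 3x3 lattice
#' local_subgraph(g, 1, "lattice3x3")$graph    # corner: clipped 2x2
#' @export
local_subgraph <- function(graph, center,
                           nbhd = c("lattice3x3", "star2d", "star3d")) {
  nbhd <- match.arg(nbhd)
  if (is.null(graph$coords))
    stop("'graph' must carry lattice coordinates")
  center <- as.integer(center)
  if (center < 1L || center > graph$n) stop("'center' not in graph")
  ndim <- ncol(graph$coords)
  off <- nbhd_offsets(nbhd, ndim)
  cc <- graph$coords[center, ]
  cand <- sweep(off, 2L, cc, `+`)
  ## present = inside the lattice bounding box and an actual vertex
  key <- function(m) apply(m, 1L, paste, collapse = ",")
  all_keys <- key(graph$coords)
  idx <- match(key(cand), all_keys)
  present <- !is.na(idx)
  verts <- idx[present]
  template_idx <- which(present)
  nloc <- length(verts)
  loc_of <- match(seq_len(graph$n), verts)
  if (nbhd == "lattice3x3") {
    ## induced lattice edges within the window
    co <- graph$coords[verts, , drop = FALSE]
    ed <- NULL
    for (i in seq_len(nloc)) for (j in seq_len(nloc)) {
      if (i < j && sum(abs(co[i, ] - co[j, ])) == 1L)
        ed <- rbind(ed, c(i, j))
    }
  } else {
    cloc <- loc_of[center]
    ed <- cbind(cloc, setdiff(seq_len(nloc), cloc))
  }
  list(graph = vgraph(nloc, ed, graph$coords[verts, , drop = FALSE]),
       vertices = verts,
       center = loc_of[center],
       template_idx = template_idx)
}
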