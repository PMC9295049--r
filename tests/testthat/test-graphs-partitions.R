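test_that("lattice graphs have the right order, size and coordinates", {
  g <- lattice_graph(c(3, 3))
  expect_equal(g$n, 9L)
  expect_equal(nrow(g$edges), 12L)          # 2 * 3 * 2 rook edges
  expect_equal(lattice_graph(c(1, 1))$n, 1L)
  expect_equal(nrow(lattice_graph(c(1, 1))$edges), 0L)
  g3 <- lattice_graph(c(2, 2, 2))
  expect_equal(g3$n, 8L)
  expect_equal(nrow(g3$edges), 12L)         # brute-force L1-adjacency count
  ## edges really connect L1-distance-1 coordinate pairs
  d <- abs(g3$coords[g3$edges[, 1], ] - g3$coords[g3$edges[, 2], ])
  expect_true(all(rowSums(d) == 1))
  expect_error(lattice_graph(c(0, 3)), "positive")
  expect_error(vgraph(3, rbind(c(1, 1))), "self-loops")
})

test_that("local subgraphs clip at borders and keep the centre mapped", {
  g <- lattice_graph(c(5, 5))
  ## interior voxel: full 3x3 window
  s <- local_subgraph(g, 13, "lattice3x3")
  expect_equal(s$graph$n, 9L)
  expect_equal(nrow(s$graph$edges), 12L)
  expect_equal(s$vertices[s$center], 13L)
  ## corner: 2x2 window
  s2 <- local_subgraph(g, 1, "lattice3x3")
  expect_equal(s2$graph$n, 4L)
  expect_equal(nrow(s2$graph$edges), 4L)
  expect_equal(s2$vertices[s2$center], 1L)
  ## 2D star: centre + 4 neighbours, centre-leaf edges only
  s3 <- local_subgraph(g, 13, "star2d")
  expect_equal(s3$graph$n, 5L)
  expect_equal(nrow(s3$graph$edges), 4L)
  expect_true(all(s3$graph$edges == s3$center |
                    apply(s3$graph$edges, 1, function(e) s3$center %in% e)))
  ## 3D star on a volume: 7 vertices, 6 edges
  gv <- lattice_graph(c(3, 3, 3))
  s4 <- local_subgraph(gv, 14, "star3d")
  expect_equal(s4$graph$n, 7L)
  expect_equal(nrow(s4$graph$edges), 6L)
  expect_error(local_subgraph(vgraph(3, rbind(c(1, 2))), 1), "coordinates")
})

test_that("graph-respecting test agrees with brute-force connectivity", {
  path3 <- lattice_graph(c(3, 1))
  expect_true(is_graph_respecting(list(1:3), path3))
  expect_true(is_graph_respecting(as.list(1:3), path3))
  expect_false(is_graph_respecting(list(c(1, 3), 2), path3))
  expect_error(is_graph_respecting(list(c(1, 2)), path3), "cover")
  ## single all-vertex block: true iff the graph is connected
  disc <- vgraph(4, rbind(c(1, 2), c(3, 4)))
  expect_false(is_graph_respecting(list(1:4), disc))
})

test_that("enumeration counts match closed forms and the paper's lattice", {
  expect_length(enumerate_partitions(lattice_graph(c(3, 3))), 1434L)
  ## paths: 2^(n-1)
  for (n in 2:6)
    expect_length(enumerate_partitions(lattice_graph(c(n, 1))), 2^(n - 1))
  ## 4-leaf star: any leaf subset joins the centre, the rest are singletons
  star <- vgraph(5, cbind(1, 2:5))
  expect_length(enumerate_partitions(star), 16L)
  ## complete graphs: all set partitions
  for (n in 2:6) {
    Kn <- vgraph(n, t(utils::combn(n, 2)))
    expect_length(enumerate_partitions(Kn), bell_number(n))
  }
  expect_error(enumerate_partitions(lattice_graph(c(5, 3)), cap = 12L), "cap")
})

test_that("enumeration is exhaustive and exact against brute force", {
  ## all set partitions of n <= 5 vertices by restricted growth strings,
  ## filtered with is_graph_respecting, must equal the enumerated set
  all_partitions <- function(n) {
    out <- list()
    gen <- function(lab, mx) {
      if (length(lab) == n) {
        out[[length(out) + 1L]] <<- as_partition(lab)
        return(invisible(NULL))
      }
      for (l in seq_len(mx + 1L)) gen(c(lab, l), max(mx, l))
    }
    gen(1L, 1L)
    out
  }
  g <- lattice_graph(c(2, 2))   # 4-cycle
  brute <- Filter(function(p) is_graph_respecting(p, g), all_partitions(4))
  enum <- enumerate_partitions(g)
  key <- function(p) paste(vapply(p, paste, "", collapse = ","),
                           collapse = "|")
  expect_setequal(vapply(enum, key, ""), vapply(brute, key, ""))
  ## and on a path of 5
  g5 <- lattice_graph(c(5, 1))
  brute5 <- Filter(function(p) is_graph_respecting(p, g5), all_partitions(5))
  expect_length(enumerate_partitions(g5), length(brute5))
})

test_that("enumeration is invariant under vertex relabelling", {
  g <- lattice_graph(c(2, 3))
  perm <- c(4L, 2L, 6L, 1L, 3L, 5L)   # arbitrary relabelling
  ed <- matrix(perm[g$edges], ncol = 2)
  g2 <- vgraph(6, ed)
  p1 <- enumerate_partitions(g)
  p2 <- enumerate_partitions(g2)
  expect_length(p2, length(p1))
  profile <- function(ps) sort(vapply(ps, function(p)
    paste(sort(lengths(p)), collapse = ","), ""))
  expect_equal(profile(p1), profile(p2))
})

test_that("Bell numbers follow the triangle recurrence", {
  expect_equal(bell_number(0), 1)
  expect_equal(bell_number(1), 1)
  expect_equal(bell_number(3), 5)      # {123},{1|23},{2|13},{3|12},{1|2|3}
  expect_equal(bell_number(9), 21147)
  expect_error(bell_number(21), "0..20")
})

test_that("central-block statistics form a distribution", {
  ps <- enumerate_partitions(lattice_graph(c(3, 3)))
  st <- central_block_stats(ps, 5L)
  expect_equal(sum(st$pmf), 1)
  sizes <- as.integer(names(st$pmf))
  expect_true(all(sizes >= 1 & sizes <= 9))
  expect_equal(st$median_blocks, 4)
  expect_equal(st$n_partitions, 1434L)
  ## single-vertex graph: certain singleton
  expect_equal(central_block_stats(enumerate_partitions(vgraph(1)), 1L)$pmf,
               c("1" = 1))
  expect_error(central_block_stats(list(), 1L), "empty")
})

test_that("edge-list files round-trip", {
  g <- lattice_graph(c(2, 3))
  f <- tempfile(fileext = ".tsv")
  utils::write.table(g$edges, f, row.names = FALSE, col.names = FALSE)
  g2 <- read_edgelist(f)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$n, g$n)
  unlink(f)
})
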