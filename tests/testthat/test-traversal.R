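# Shared small fixture: the four-edge cycle motif has a 5-multiedge
# expansion with two distinct Eulerian traversals.
motif_setup <- function() {
  g <- motif_graph()
  tg <- first_tangle(g, min_len = 1000, frac = 0.2)
  a <- solve_multiplicities(tg, g, cov_u = 30)
  list(g = g, tg = tg, a = a, mg = build_multigraph(tg, a, g))
}

test_that("multigraph expansion has one multiedge per multiplicity unit", {
  s <- motif_setup()
  counts <- table(s$mg$me$edge_id)
  expect_equal(as.integer(counts[c("e1", "e2", "e3", "e4")]), c(1L, 1L, 2L, 1L))
  # degree balance: out - in is +1 at source, -1 at sink, 0 elsewhere
  verts <- unique(c(s$mg$me$from, s$mg$me$to))
  outd <- table(factor(s$mg$me$from, levels = verts))
  ind <- table(factor(s$mg$me$to, levels = verts))
  bal <- as.integer(outd) - as.integer(ind)
  sys <- tanglepatch:::tangle_flow_system(s$tg, s$g)
  expect_equal(sort(bal), c(-1L, 0L, 0L, 1L))
  expect_equal(bal[match(sys$start, verts)], 1L)
  expect_equal(bal[match(sys$end, verts)], -1L)
})

test_that("a self-loop of multiplicity 3 expands to 3 parallel multiedges", {
  g <- load_gfa(gfa_file(
    c(seg_line("X", 2000, 30), seg_line("in", 50, 30), seg_line("loop", 50, 90),
      seg_line("out", 50, 30), seg_line("Y", 2000, 30)),
    c(link_line("X", "+", "in", "+"), link_line("in", "+", "loop", "+"),
      link_line("loop", "+", "loop", "+"), link_line("loop", "+", "out", "+"),
      link_line("out", "+", "Y", "+"))
  ))
  g <- attach_coverage(to_edge_graph(g))
  tg <- manual_tangle(g, c("X+", "Y+"))
  a <- solve_multiplicities(tg, g, cov_u = 30)
  expect_equal(unname(a$mult["loop"]), 3L)
  mg <- build_multigraph(tg, a, g)
  expect_equal(sum(mg$me$edge_id == "loop"), 3L)
  p <- find_eulerian_path(mg, g, rng_seed = 1)
  expect_true(path_is_eulerian(p, mg))
})

test_that("a linear multigraph yields its unique Eulerian path", {
  g <- load_gfa(gfa_file(
    c(seg_line("X", 2000, 30), seg_line("a", 50, 30), seg_line("b", 50, 30),
      seg_line("Y", 2000, 30)),
    c(link_line("X", "+", "a", "+"), link_line("a", "+", "b", "+"),
      link_line("b", "+", "Y", "+"))
  ))
  g <- attach_coverage(to_edge_graph(g))
  tg <- manual_tangle(g, c("X+", "Y+"))
  a <- solve_multiplicities(tg, g)
  mg <- build_multigraph(tg, a, g)
  for (seed in 1:5) {
    p <- find_eulerian_path(mg, g, rng_seed = seed)
    expect_equal(paste0(p$edge_id, p$orient), c("X+", "a+", "b+", "Y+"))
  }
})

test_that("figure-eight loops admit exactly two orderings, both produced", {
  # two loop edges at one junction, each traversed once
  g <- load_gfa(gfa_file(
    c(seg_line("X", 2000, 30), seg_line("in", 50, 30),
      seg_line("p", 50, 30), seg_line("q", 50, 30),
      seg_line("out", 50, 30), seg_line("Y", 2000, 30)),
    c(link_line("X", "+", "in", "+"), link_line("in", "+", "p", "+"),
      link_line("in", "+", "q", "+"), link_line("p", "+", "p", "+"),
      link_line("p", "+", "q", "+"), link_line("q", "+", "p", "+"),
      link_line("q", "+", "q", "+"), link_line("p", "+", "out", "+"),
      link_line("q", "+", "out", "+"), link_line("out", "+", "Y", "+"))
  ))
  g <- attach_coverage(to_edge_graph(g))
  tg <- manual_tangle(g, c("X+", "Y+"))
  a <- solve_multiplicities(tg, g, cov_u = 30)
  expect_equal(unname(a$mult[c("p", "q")]), c(1L, 1L))
  mg <- build_multigraph(tg, a, g)
  seen <- unique(vapply(1:40, function(s) {
    paste(path_labels(find_eulerian_path(mg, g, rng_seed = s)), collapse = " ")
  }, character(1)))
  expect_length(seen, 2L)  # p-before-q and q-before-p
  sys <- tanglepatch:::tangle_flow_system(tg, g)
  oracle <- oracle_euler_paths(mg$me, sys$start[[1]], sys$end[[1]])
  expect_length(oracle, 2L)
})

test_that("every seeded Eulerian draw replays as a valid traversal", {
  for (seed in 1:10) {
    fx <- random_tangle_fixture(seed, n_internal = 4, walk_len = 7)
    a <- solve_multiplicities(fx$tangle, fx$graph, cov_u = fx$cov_u_true)
    mg <- build_multigraph(fx$tangle, a, fx$graph)
    for (s2 in 1:10) {
      p <- find_eulerian_path(mg, fx$graph, rng_seed = s2)
      expect_true(path_is_eulerian(p, mg))
    }
  }
})

test_that("swap enumeration matches a brute-force interval scan", {
  brute_swaps <- function(path) {
    n <- nrow(path)
    res <- NULL
    movable <- !path$fixed
    for (i1 in 1:n) for (j1 in i1:n) for (i2 in (j1 + 1):n) for (j2 in i2:n) {
      if (i2 > n || i2 <= j1 || j2 > n) next
      if (!all(movable[c(i1:j1, i2:j2)])) next
      if (path$from[[i1]] != path$from[[i2]]) next
      if (path$to[[j1]] != path$to[[j2]]) next
      res <- rbind(res, c(i1, j1, i2, j2))
    }
    res
  }
  # path with all distinct vertices: no swaps
  g <- load_gfa(gfa_file(
    c(seg_line("X", 2000, 30), seg_line("a", 50, 30), seg_line("b", 50, 30),
      seg_line("Y", 2000, 30)),
    c(link_line("X", "+", "a", "+"), link_line("a", "+", "b", "+"),
      link_line("b", "+", "Y", "+"))
  ))
  g <- attach_coverage(to_edge_graph(g))
  tg <- manual_tangle(g, c("X+", "Y+"))
  mg <- build_multigraph(tg, solve_multiplicities(tg, g), g)
  p <- find_eulerian_path(mg, g, rng_seed = 1)
  expect_equal(nrow(enumerate_swaps(p)), 0L)

  # A->B->A->B over two parallel edges twice: the two A->B steps swap
  s <- motif_setup()
  for (seed in 1:5) {
    fx <- random_tangle_fixture(seed + 300, n_internal = 3, walk_len = 6)
    a <- solve_multiplicities(fx$tangle, fx$graph, cov_u = fx$cov_u_true)
    mg2 <- build_multigraph(fx$tangle, a, fx$graph)
    p2 <- find_eulerian_path(mg2, fx$graph, rng_seed = seed)
    sw <- enumerate_swaps(p2)
    bs <- brute_swaps(p2)
    expect_equal(nrow(sw), if (is.null(bs)) 0L else nrow(bs))
    if (nrow(sw) > 0L) {
      expect_equal(unname(sw), unname(bs[order(bs[,1], bs[,2], bs[,3], bs[,4]), ,
                                         drop = FALSE]))
      for (r in seq_len(nrow(sw))) {
        p3 <- apply_swap(p2, sw[r, ])
        expect_true(path_is_eulerian(p3, mg2))
      }
    }
  }
})

test_that("swapping two identical subpaths leaves the path unchanged", {
  s <- motif_setup()
  p <- find_eulerian_path(s$mg, s$g, rng_seed = 3)
  sw <- enumerate_swaps(p)
  same <- which(apply(sw, 1, function(r) {
    identical(path_labels(p)[r[1]:r[2]], path_labels(p)[r[3]:r[4]])
  }))
  expect_gt(length(same), 0L)  # the two e3 steps are identical subpaths
  p2 <- apply_swap(p, sw[same[[1]], ])
  expect_equal(path_labels(p2), path_labels(p))
})

test_that("optimization returns the planted path when reads pin the order", {
  fx <- random_tangle_fixture(77, n_internal = 3, walk_len = 6)
  a <- solve_multiplicities(fx$tangle, fx$graph, cov_u = fx$cov_u_true)
  skip_if_not(all(a$mult[names(fx$mult_true)] == fx$mult_true))
  mg <- build_multigraph(fx$tangle, a, fx$graph)
  tl <- path_labels(fx$true_path)
  walks <- lapply(seq_len(nrow(fx$true_path) - 2L), function(i) {
    make_walk(fx$graph, tl[i:min(i + 3L, length(tl))], sprintf("r%02d", i))
  })
  init <- find_eulerian_path(mg, fx$graph, rng_seed = 5)
  opt <- optimize_path(init, walks, restarts = 10, rng_seed = 9)
  expect_equal(attr(opt, "score"), length(walks))
  expect_equal(path_labels(opt), tl)
})

test_that("with no walks the initial path is returned at score 0", {
  s <- motif_setup()
  init <- find_eulerian_path(s$mg, s$g, rng_seed = 2)
  opt <- optimize_path(init, list(), restarts = 3, rng_seed = 1)
  expect_equal(attr(opt, "score"), 0L)
  expect_true(path_is_eulerian(opt, s$mg))
})

test_that("identical inputs and seeds give identical optimized paths", {
  fx <- random_tangle_fixture(55, n_internal = 3, walk_len = 6)
  a <- solve_multiplicities(fx$tangle, fx$graph, cov_u = fx$cov_u_true)
  mg <- build_multigraph(fx$tangle, a, fx$graph)
  walks <- list(make_walk(fx$graph, path_labels(fx$true_path)[2:4], "r1"))
  init <- find_eulerian_path(mg, fx$graph, rng_seed = 11)
  o1 <- optimize_path(init, walks, restarts = 5, rng_seed = 123)
  o2 <- optimize_path(init, walks, restarts = 5, rng_seed = 123)
  expect_identical(path_labels(o1), path_labels(o2))
  expect_identical(attr(o1, "restart_scores"), attr(o2, "restart_scores"))
})

test_that("every Eulerian path pair is connected by prefix-extending swaps", {
  # figure-eight: exactly two paths, one swap apart
  g <- load_gfa(gfa_file(
    c(seg_line("X", 2000, 30), seg_line("in", 50, 30),
      seg_line("p", 50, 30), seg_line("q", 50, 30),
      seg_line("out", 50, 30), seg_line("Y", 2000, 30)),
    c(link_line("X", "+", "in", "+"), link_line("in", "+", "p", "+"),
      link_line("in", "+", "q", "+"), link_line("p", "+", "p", "+"),
      link_line("p", "+", "q", "+"), link_line("q", "+", "p", "+"),
      link_line("q", "+", "q", "+"), link_line("p", "+", "out", "+"),
      link_line("q", "+", "out", "+"), link_line("out", "+", "Y", "+"))
  ))
  g <- attach_coverage(to_edge_graph(g))
  tg <- manual_tangle(g, c("X+", "Y+"))
  mg <- build_multigraph(tg, solve_multiplicities(tg, g, cov_u = 30), g)
  cc <- check_swap_connectivity(mg, graph = g)
  expect_equal(cc$n_paths, 2L)
  expect_true(cc$connected)
  expect_equal(sort(cc$swap_lengths), c(0L, 0L, 1L, 1L))

  # random small multigraphs: all ordered pairs connected
  for (seed in 401:412) {
    fx <- random_tangle_fixture(seed, n_internal = 3, walk_len = 6)
    mg2 <- build_multigraph(fx$tangle,
                            planted_assignment(fx$mult_true, fx$cov_u_true),
                            fx$graph)
    if (nrow(mg2$me) > 8L) next
    cc2 <- check_swap_connectivity(mg2, graph = fx$graph)
    expect_true(cc2$connected, label = paste("seed", seed))
  }
})
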