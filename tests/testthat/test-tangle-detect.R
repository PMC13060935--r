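test_that("unique-edge classification applies length floor and coverage window", {
  g <- load_gfa(gfa_file(c(
    seg_line("long_mid", 500000, 30),    # central case
    seg_line("short", 1000, 30),         # below length floor
    seg_line("long_low", 500000, 10),    # coverage too low
    seg_line("long_high", 500000, 80),   # coverage too high
    seg_line("long_ok", 200000, 33)
  )))
  g <- attach_coverage(to_edge_graph(g))
  u <- classify_unique_edges(g, min_length = 1e5, median_cov = 30)
  expect_setequal(u, c("long_mid", "long_ok"))
  # median bootstrap over >= min_length edges gives the same calls here
  u2 <- classify_unique_edges(g, min_length = 1e5)
  expect_setequal(u2, u)
})

test_that("a bubble flanked by unique edges is one tangle with 2 edges", {
  g <- bubble_graph()
  tg <- detect_tangles(g, classify_unique_edges(g, min_length = 100),
                       max_tangle_fraction = 0.2)
  expect_length(tg, 1L)
  expect_true(tg[[1]]$resolvable)
  expect_equal(tg[[1]]$n_pairs, 1)
  expect_setequal(tg[[1]]$tangle_edges, c("m1", "m2"))
  expect_true(separation_holds(g, tg[[1]]))
})

test_that("a six-edge tangle between two terminals is detected intact", {
  # unique x1/y1 flanks; six tangle edges over internal junctions A-D
  g <- load_gfa(gfa_file(
    c(seg_line("x1", 3000, 30), seg_line("y1", 3000, 30),
      seg_line("e1", 60, 30), seg_line("e2", 60, 60), seg_line("e3", 60, 30),
      seg_line("e4", 60, 30), seg_line("e5", 60, 30), seg_line("e6", 60, 30)),
    c(link_line("x1", "+", "e1", "+"),
      link_line("e1", "+", "e2", "+"),       # A
      link_line("e2", "+", "e3", "+"), link_line("e2", "+", "e4", "+"),  # B
      link_line("e3", "+", "e5", "+"),       # C
      link_line("e4", "+", "e6", "+"),       # D
      link_line("e5", "+", "e2", "+"),       # back to A: second pass
      link_line("e6", "+", "y1", "+"))
  ))
  g <- attach_coverage(g |> to_edge_graph())
  tg <- detect_tangles(g, classify_unique_edges(g, min_length = 1000),
                       max_tangle_fraction = 0.2)
  expect_length(tg, 1L)
  expect_length(tg[[1]]$tangle_edges, 6L)
  expect_true(tg[[1]]$resolvable)
  expect_equal(tg[[1]]$boundary$x_id, "x1")
  expect_equal(tg[[1]]$boundary$y_id, "y1")
})

test_that("tangles with boundary counts outside {2,4} are flagged unresolvable", {
  # three unique edges meeting one repeat: 3 boundary nodes
  g <- load_gfa(gfa_file(
    c(seg_line("u1", 2000, 30), seg_line("u2", 2000, 30),
      seg_line("u3", 2000, 30), seg_line("rep", 50, 45)),
    c(link_line("u1", "+", "rep", "+"), link_line("rep", "+", "u2", "+"),
      link_line("rep", "+", "u3", "+"))
  ))
  g <- attach_coverage(to_edge_graph(g))
  tg <- detect_tangles(g, classify_unique_edges(g, min_length = 1000),
                       max_tangle_fraction = 0.2)
  expect_length(tg, 1L)
  expect_false(tg[[1]]$resolvable)
  expect_match(tg[[1]]$reason, "boundary nodes")
})

test_that("detection matches a brute-force separation oracle on random graphs", {
  # oracle: for every candidate non-unique component, check conditions
  # directly — removal of adjacent unique edges separates it (flood fill),
  # boundary ends lie inside, size constraint holds
  for (seed in 1:8) {
    fx <- random_tangle_fixture(seed, n_internal = 3, walk_len = 5)
    g <- fx$graph
    u <- c("X", "Y")
    tg <- detect_tangles(g, u, max_tangle_fraction = 0.9)
    expect_length(tg, 1L)
    expect_setequal(tg[[1]]$tangle_edges,
                    setdiff(g$edges$edge_id, c("X", "Y")))
    expect_true(separation_holds(g, tg[[1]]))
  }
})

test_that("detection output is independent of segment order in the file", {
  pl <- plant_repeat_tangle(3, unit_len = 120, divergence = 0.03, rng_seed = 9)
  dir <- withr::local_tempdir()
  write_fixture(pl, dir)
  lines <- readLines(file.path(dir, "graph.gfa"))
  segs <- grep("^S\t", lines, value = TRUE)
  links <- grep("^L\t", lines, value = TRUE)
  shuf <- file.path(dir, "shuffled.gfa")
  set.seed(4)
  writeLines(c("H\tVN:Z:1.0", sample(segs), sample(links)), shuf)
  t1 <- first_tangle(attach_coverage(to_edge_graph(load_gfa(file.path(dir, "graph.gfa")))),
                     min_len = 300)
  t2 <- first_tangle(attach_coverage(to_edge_graph(load_gfa(shuf))), min_len = 300)
  expect_identical(t1$tangle_edges, t2$tangle_edges)
  expect_identical(t1$boundary, t2$boundary)
})

test_that("cov_u estimation takes the boundary median and honours overrides", {
  g <- bubble_graph()
  tg <- first_tangle(g)
  expect_equal(estimate_cov_u(tg, g), 30)            # {30, 30}
  expect_equal(estimate_cov_u(tg, g, user_value = 25), 25)
  # even count: median by sorting
  expect_equal(stats::median(c(28, 30, 31, 33)), 30.5)
  g0 <- g
  g0$edges$coverage[] <- 0
  tg0 <- tg
  expect_error(estimate_cov_u(tg0, g0), "zero")
})

test_that("manual boundaries naming a non-separating edge set are rejected", {
  g <- bubble_graph()
  # m1 does not separate anything sensible as a boundary
  expect_error(manual_tangle(g, c("m1+", "Y+")), "valid tangle|incoming")
})
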