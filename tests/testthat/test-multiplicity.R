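test_that("reasonably covered edges use an inclusive 0.5 * cov_u threshold", {
  g <- bubble_graph(cov_m1 = 15, cov_m2 = 14.9)
  tg <- first_tangle(g)
  tg$cov_u <- 30
  expect_setequal(reasonably_covered(tg, g), "m1")   # 15 >= 15; 14.9 < 15
  g0 <- bubble_graph(cov_m1 = 0, cov_m2 = 0)
  tg0 <- first_tangle(g0)
  tg0$cov_u <- 30
  expect_length(reasonably_covered(tg0, g0), 0L)
})

test_that("a single tangle edge between boundaries is forced to mult 1", {
  g <- load_gfa(gfa_file(
    c(seg_line("X", 2000, 30), seg_line("e", 50, 30), seg_line("Y", 2000, 30)),
    c(link_line("X", "+", "e", "+"), link_line("e", "+", "Y", "+"))
  ))
  g <- attach_coverage(to_edge_graph(g))
  tg <- manual_tangle(g, c("X+", "Y+"))
  a <- solve_multiplicities(tg, g)
  expect_equal(unname(a$mult["e"]), 1L)
  expect_equal(a$objective_value, 0, tolerance = 1e-9)
  expect_false(a$relaxed)
})

test_that("parallel variants with a return edge follow the coverage signal", {
  # both near cov_u: two passes, each variant once
  g <- two_pass_graph(30, 30)
  tg <- first_tangle(g)
  a <- solve_multiplicities(tg, g, cov_u = 30)
  expect_equal(unname(a$mult[c("m1", "m2", "r")]), c(1L, 1L, 1L))
  expect_false(a$relaxed)
  # 1.8 / 0.3 x cov_u: low edge leaves E_rc, strong edge doubled
  g2 <- two_pass_graph(54, 9)
  tg2 <- first_tangle(g2)
  a2 <- solve_multiplicities(tg2, g2, cov_u = 30)
  expect_equal(unname(a2$mult[c("m1", "m2")]), c(2L, 0L))
  expect_false(a2$relaxed)
  # oracle agreement for both
  for (case in list(list(g, tg, a), list(g2, tg2, a2))) {
    bf <- brute_force_multiplicity(
      case[[2]], case[[1]], 30,
      reasonably_covered(case[[2]], case[[1]], cov_u = 30), bound = 4L)
    expect_equal(case[[3]]$objective_value, bf$obj, tolerance = 1e-9)
  }
})

test_that("the two-in-one-out coverage motif forces the outgoing edge to 2", {
  g <- motif_graph()
  tg <- first_tangle(g, min_len = 1000, frac = 0.2)
  a <- solve_multiplicities(tg, g, cov_u = 30)
  expect_false(a$relaxed)
  expect_equal(unname(a$mult[c("e1", "e2", "e3", "e4")]), c(1L, 1L, 2L, 1L))
  expect_equal(a$objective_value, 1, tolerance = 1e-9)
  bf <- brute_force_multiplicity(tg, g, 30, reasonably_covered(tg, g, cov_u = 30),
                                 bound = 4L)
  expect_equal(bf$obj, 1, tolerance = 1e-9)
})

test_that("infeasible strict problems fall back to the relaxed formulation", {
  # two reasonably covered parallel edges, but flow admits only one pass
  g <- bubble_graph(cov_m1 = 30, cov_m2 = 30)
  tg <- first_tangle(g)
  a <- solve_multiplicities(tg, g, cov_u = 30)
  expect_true(a$relaxed)
  expect_equal(sum(a$mult), 1L)  # exactly one variant traversed
  expect_equal(a$objective_value, 1, tolerance = 1e-9)
})

test_that("MILP objective equals brute force on random planted tangles", {
  for (seed in 1:30) {
    fx <- random_tangle_fixture(seed, n_internal = 3, walk_len = 5)
    tg <- fx$tangle
    cov_u <- fx$cov_u_true
    rc <- reasonably_covered(tg, fx$graph, cov_u = cov_u)
    a <- solve_multiplicities(tg, fx$graph, cov_u = cov_u)
    bound <- ceiling(2 * max(fx$graph$edges[tg$tangle_edges, "coverage"]) / cov_u)
    bf <- brute_force_multiplicity(tg, fx$graph, cov_u, rc, bound)
    if (is.null(bf)) {
      expect_true(a$relaxed)
      bf <- brute_force_multiplicity(tg, fx$graph, cov_u, character(0), bound)
    }
    expect_equal(a$objective_value, bf$obj, tolerance = 1e-9,
                 label = paste("seed", seed))
  }
})

test_that("scaling all coverages and cov_u together leaves the optimum unchanged", {
  fx <- random_tangle_fixture(101, walk_len = 6)
  a1 <- solve_multiplicities(fx$tangle, fx$graph, cov_u = fx$cov_u_true)
  g2 <- fx$graph
  g2$edges$coverage <- g2$edges$coverage * 7.5
  a2 <- solve_multiplicities(fx$tangle, g2, cov_u = fx$cov_u_true * 7.5)
  expect_identical(a1$mult, a2$mult)
})

test_that("planted multiplicities are recovered when they are the unique optimum", {
  recovered <- 0L; eligible <- 0L
  for (seed in 201:230) {
    fx <- random_tangle_fixture(seed, n_internal = 3, walk_len = 5)
    tg <- fx$tangle
    cov_u <- fx$cov_u_true
    rc <- reasonably_covered(tg, fx$graph, cov_u = cov_u)
    bound <- ceiling(2 * max(fx$graph$edges[tg$tangle_edges, "coverage"]) / cov_u)
    bf <- brute_force_multiplicity(tg, fx$graph, cov_u, rc, bound)
    if (is.null(bf) || nrow(bf$mults) != 1L) next  # optimum not unique
    planted <- fx$mult_true[colnames(bf$mults)]
    if (!all(bf$mults[1, ] == planted)) next       # noise moved the optimum
    eligible <- eligible + 1L
    a <- solve_multiplicities(tg, fx$graph, cov_u = cov_u)
    if (all(a$mult[names(planted)] == planted)) recovered <- recovered + 1L
  }
  expect_gt(eligible, 10L)
  expect_equal(recovered, eligible)
})

test_that("flow conservation and the objective are recomputable from the output", {
  for (seed in c(7, 42)) {
    fx <- random_tangle_fixture(seed, walk_len = 6)
    a <- solve_multiplicities(fx$tangle, fx$graph, cov_u = fx$cov_u_true)
    covs <- fx$graph$edges[names(a$mult), "coverage"]
    expect_equal(a$objective_value, sum(abs(covs / a$cov_u - a$mult)),
                 tolerance = 1e-6)
    # flow conservation: replayable as an Eulerian traversal
    mg <- build_multigraph(fx$tangle, a, fx$graph)
    p <- find_eulerian_path(mg, fx$graph, rng_seed = 1)
    expect_true(path_is_eulerian(p, mg))
  }
})
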