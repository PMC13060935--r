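#' Reasonably covered tangle edges
#'
#' Tangle edges with coverage at least `threshold_factor * cov_u` (default
#' 0.5) are considered real sequence rather than assembly noise, and the
#' strict multiplicity problem requires each of them to appear at least once
#' in the traversal.
#'
#' @param tangle a [tangle][detect_tangles] with `cov_u` set (or pass `cov_u`).
#' @param graph the [edge_graph][to_edge_graph].
#' @param threshold_factor fraction of `cov_u` (default 0.5).
#' @param cov_u optional override of `tangle$cov_u`.
#' @return character vector of edge ids (subset of the tangle edges).
#' @export
reasonably_covered <- function(tangle, graph, threshold_factor = 0.5,
                               cov_u = NULL) {
  cov_u <- cov_u %||% tangle$cov_u
  stopifnot(is.numeric(cov_u), cov_u > 0)
  covs <- graph$edges[tangle$tangle_edges, "coverage"]
  tangle$tangle_edges[covs >= threshold_factor * cov_u]
}

# --- the flow-constrained integer program ---------------------------------
#
# Variables: one non-negative integer multiplicity per tangle edge (bounded).
# Constraints: flow conservation at every tangle-internal oriented vertex,
# with the boundary edges contributing fixed multiplicity 1; optional lower
# bound 1 on reasonably covered edges. Objective: minimise
# sum_e |cov(e)/cov_u - mult(e)|.
#
# Solved exactly by spanning-tree decomposition of the flow constraints:
# the constraint matrix is a directed incidence matrix, so once the non-tree
# ("free") edges are fixed, every tree edge is forced by leaf elimination.
# The search enumerates free-edge values in increasing per-edge cost with
# branch-and-bound pruning against a per-edge lower-bound table. Exact on
# tangle-scale problems; a time limit returns the best incumbent found.

# Directed system of a tangle: per-edge from/to oriented vertices under the
# tangle's orientation frame, plus net boundary demand per vertex.
tangle_flow_system <- function(tangle, graph) {
  if (is.null(tangle$orient))
    stop("tangle has no orientation frame (unresolvable: ", tangle$reason, ")")
  eids <- tangle$tangle_edges
  rows <- oe_row(graph, paste0(eids, tangle$orient[eids]))
  bnd <- tangle$boundary
  xs <- oe_row(graph, paste0(bnd$x_id, bnd$x_orient))
  ys <- oe_row(graph, paste0(bnd$y_id, bnd$y_orient))
  verts <- sort(unique(c(rows$from, rows$to)))
  # demand d[v]: required (in - out) over tangle edges at v, i.e.
  # boundary-out minus boundary-in contributions.
  d <- stats::setNames(numeric(length(verts)), verts)
  for (v in xs$to) {
    if (!v %in% verts) stop("incoming boundary edge ends at a vertex with no tangle edge")
    d[[v]] <- d[[v]] - 1  # one unit arrives from outside; tangle must carry it out
  }
  for (v in ys$from) {
    if (!v %in% verts) stop("outgoing boundary edge starts at a vertex with no tangle edge")
    d[[v]] <- d[[v]] + 1  # one unit leaves outward; tangle must bring it in
  }
  list(edge_id = eids, from = rows$from, to = rows$to, vertices = verts,
       demand = d, start = xs$to, end = ys$from)
}

# Exact solver. target = cov/cov_u per edge; lb/ub integer bounds per edge.
# Returns list(mult, objective, feasible, timed_out).
solve_flow_ip <- function(sys, target, lb, ub, time_limit = Inf) {
  m <- length(sys$edge_id)
  verts <- sys$vertices
  nv <- length(verts)
  from_i <- match(sys$from, verts)
  to_i <- match(sys$to, verts)
  is_loop <- from_i == to_i

  # spanning forest over non-loop edges (loops drop out of flow constraints)
  uf <- uf_env(nv)
  tree <- logical(m)
  for (i in seq_len(m)) {
    if (is_loop[[i]]) next
    if (uf_root(uf, from_i[[i]]) != uf_root(uf, to_i[[i]])) {
      uf_union(uf, from_i[[i]], to_i[[i]])
      tree[[i]] <- TRUE
    }
  }
  free <- which(!tree)
  tree_idx <- which(tree)

  cost <- function(i, v) abs(target[[i]] - v)
  mincost <- vapply(seq_len(m), function(i) {
    v <- max(lb[[i]], min(ub[[i]], round(target[[i]])))
    cost(i, v)
  }, numeric(1))
  if (any(lb > ub)) return(list(feasible = FALSE, timed_out = FALSE))
  tree_min_total <- sum(mincost[tree_idx])
  # suffix sums of free-edge minimal costs, in search order
  free_ord <- free[order(-mincost[free])]  # most constrained (costly) first
  suffix_min <- rev(cumsum(rev(c(mincost[free_ord], 0))))[-1]

  # incidence lists for leaf elimination over tree edges
  inc_tree <- lapply(seq_len(nv), function(v) {
    tree_idx[from_i[tree_idx] == v | to_i[tree_idx] == v]
  })

  best <- new.env(parent = emptyenv())
  best$obj <- Inf
  best$mult <- NULL
  best$timed_out <- FALSE
  t0 <- Sys.time()
  nodes <- 0L

  # Given fixed free-edge values, force all tree edges by peeling leaves of
  # the spanning forest; returns mult vector or NULL if infeasible.
  solve_tree <- function(mult) {
    bal <- numeric(nv)  # in - out over assigned edges
    assigned <- !is.na(mult)
    for (i in which(assigned)) {
      bal[[to_i[[i]]]] <- bal[[to_i[[i]]]] + mult[[i]]
      bal[[from_i[[i]]]] <- bal[[from_i[[i]]]] - mult[[i]]
    }
    remaining <- vapply(seq_len(nv), function(v) sum(is.na(mult[inc_tree[[v]]])),
                        integer(1))
    queue <- which(remaining == 1L)
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (remaining[[v]] != 1L) next
      i <- inc_tree[[v]][is.na(mult[inc_tree[[v]]])][[1L]]
      val <- if (to_i[[i]] == v) sys$demand[[v]] - bal[[v]] else bal[[v]] - sys$demand[[v]]
      if (val < lb[[i]] || val > ub[[i]]) return(NULL)
      mult[[i]] <- val
      bal[[to_i[[i]]]] <- bal[[to_i[[i]]]] + val
      bal[[from_i[[i]]]] <- bal[[from_i[[i]]]] - val
      for (w in unique(c(from_i[[i]], to_i[[i]]))) {
        remaining[[w]] <- remaining[[w]] - 1L
        if (remaining[[w]] == 1L) queue <- c(queue, w)
      }
    }
    if (anyNA(mult)) return(NULL)            # cycle left unpeeled (cannot happen in a forest)
    if (any(abs(bal - sys$demand) > 1e-9)) return(NULL)
    mult
  }

  dfs <- function(pos, mult, acc) {
    nodes <<- nodes + 1L
    if (nodes %% 256L == 0L &&
        as.numeric(Sys.time() - t0, units = "secs") > time_limit) {
      best$timed_out <- TRUE
      return(invisible(NULL))
    }
    if (best$timed_out) return(invisible(NULL))
    if (pos > length(free_ord)) {
      full <- solve_tree(mult)
      if (!is.null(full)) {
        obj <- sum(abs(target - full))
        if (obj < best$obj - 1e-12) {
          best$obj <- obj
          best$mult <- full
        }
      }
      return(invisible(NULL))
    }
    i <- free_ord[[pos]]
    vals <- lb[[i]]:ub[[i]]
    vals <- vals[order(abs(target[[i]] - vals))]
    for (v in vals) {
      acc2 <- acc + cost(i, v)
      if (acc2 + suffix_min[[pos]] + tree_min_total >= best$obj - 1e-12) {
        # values are cost-ordered: nothing later in `vals` can do better
        break
      }
      mult[[i]] <- v
      dfs(pos + 1L, mult, acc2)
      mult[[i]] <- NA_real_
    }
    invisible(NULL)
  }
  dfs(1L, rep(NA_real_, m), 0)

  if (is.null(best$mult))
    return(list(feasible = FALSE, timed_out = best$timed_out))
  list(
    mult = stats::setNames(as.integer(round(best$mult)), sys$edge_id),
    objective = best$obj, feasible = TRUE, timed_out = best$timed_out
  )
}

#' Solve the tangle multiplicity problem
#'
#' Assigns an integer multiplicity to every tangle edge so that flow is
#' conserved at every tangle-internal vertex (boundary edges count as fixed
#' multiplicity 1), every reasonably covered edge is used at least once, and
#' the total absolute deviation `sum_e |cov(e)/cov_u - mult(e)|` is minimal.
#' The problem is solved exactly; if the strict problem is infeasible (e.g. a
#' boundary edge followed by two reasonably covered edges that cannot both be
#' traversed), the at-least-once requirement is dropped and the relaxed
#' problem is solved instead, flagged via `relaxed = TRUE`.
#'
#' Multiplicities are bounded above by `ceiling(4 * max(cov) / cov_u)` (at
#' least 2). With `tune_cov_u = TRUE` the solve is repeated over
#' `c(0.9, 1, 1.1) * cov_u` and the lowest-objective solution kept.
#'
#' @param tangle a resolvable [tangle][detect_tangles].
#' @param graph the [edge_graph][to_edge_graph].
#' @param e_rc reasonably covered edge ids; computed by
#'   [reasonably_covered()] when `NULL`.
#' @param cov_u unique traversal coverage; defaults to `tangle$cov_u`.
#' @param solver_time_limit seconds before the best incumbent is returned
#'   with a warning (default 300).
#' @param tune_cov_u re-solve over a small grid around `cov_u` (default off).
#' @param rc_threshold threshold factor handed to [reasonably_covered()].
#' @return an object of class `multiplicity_assignment`: list with `mult`
#'   (named integer vector over tangle edges), `objective_value`, `relaxed`,
#'   `cov_u` and `e_rc`.
#' @export
solve_multiplicities <- function(tangle, graph, e_rc = NULL, cov_u = NULL,
                                 solver_time_limit = 300, tune_cov_u = FALSE,
                                 rc_threshold = 0.5) {
  stopifnot(inherits(tangle, "tangle"))
  if (!tangle$resolvable)
    stop("tangle is not resolvable: ", tangle$reason)
  cov_u0 <- cov_u %||% tangle$cov_u
  stopifnot(is.numeric(cov_u0), cov_u0 > 0)
  grid <- if (tune_cov_u) c(0.9, 1, 1.1) * cov_u0 else cov_u0
  sys <- tangle_flow_system(tangle, graph)
  covs <- graph$edges[sys$edge_id, "coverage"]

  best <- NULL
  for (cu in grid) {
    rc <- e_rc %||% reasonably_covered(tangle, graph, rc_threshold, cov_u = cu)
    target <- covs / cu
    ub <- rep(max(2L, as.integer(ceiling(4 * max(covs) / cu))), length(covs))
    lb_strict <- ifelse(sys$edge_id %in% rc, 1L, 0L)
    sol <- solve_flow_ip(sys, target, lb_strict, ub, solver_time_limit)
    relaxed <- FALSE
    if (!sol$feasible) {
      sol <- solve_flow_ip(sys, target, rep(0L, length(covs)), ub,
                           solver_time_limit)
      relaxed <- TRUE
    }
    if (!sol$feasible) next
    if (sol$timed_out)
      warning("multiplicity solver hit the time limit for ", tangle$id,
              "; returning best incumbent")
    cand <- structure(list(
      mult = sol$mult, objective_value = sol$objective,
      relaxed = relaxed, cov_u = cu, e_rc = rc
    ), class = "multiplicity_assignment")
    if (is.null(best) || cand$objective_value < best$objective_value)
      best <- cand
  }
  if (is.null(best))
    stop("tangle ", tangle$id, " is unsolvable: no multiplicity assignment ",
         "satisfies flow conservation even after relaxation")
  best
}

#' @export
print.multiplicity_assignment <- function(x, ...) {
  cat("multiplicity assignment (cov_u =", format(x$cov_u, digits = 4),
      if (x$relaxed) ", relaxed" else "", "):\n")
  print(x$mult)
  cat("objective:", format(x$objective_value, digits = 6), "\n")
  invisible(x)
}
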