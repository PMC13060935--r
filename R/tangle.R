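#' Classify unique edges by length and coverage
#'
#' Boundary edges of a resolvable tangle must be *unique*: non-repetitive,
#' non-homozygous edges expected exactly once in the finished genome. Since
#' the finished genome is unknown, uniqueness is called from edge length and
#' coverage: an edge is unique when its length is at least `min_length` and
#' its coverage lies within `cov_window` times the median unique coverage.
#' When `median_cov` is not supplied it is bootstrapped as the median coverage
#' of all edges at least `min_length` long.
#'
#' @param graph an [edge_graph][to_edge_graph] with coverage attached.
#' @param min_length minimum edge length in bp (default 100 kbp).
#' @param cov_window numeric length-2, lower/upper multipliers of the median
#'   coverage (default `c(0.7, 1.3)`).
#' @param median_cov median coverage of unique edges; estimated when `NULL`.
#' @return character vector of unique edge ids, sorted.
#' @export
classify_unique_edges <- function(graph, min_length = 1e5,
                                  cov_window = c(0.7, 1.3),
                                  median_cov = NULL) {
  stopifnot(inherits(graph, "edge_graph"), length(cov_window) == 2L)
  e <- graph$edges
  if (anyNA(e$coverage))
    stop("coverage not attached; run attach_coverage() first")
  long <- e$length >= min_length
  if (is.null(median_cov)) {
    if (!any(long)) stop("no edge reaches min_length = ", min_length,
                         "; cannot bootstrap median coverage")
    median_cov <- stats::median(e$coverage[long])
  }
  if (median_cov <= 0) stop("median coverage must be positive")
  ok <- long & e$coverage >= cov_window[[1]] * median_cov &
    e$coverage <= cov_window[[2]] * median_cov
  sort(e$edge_id[ok])
}

# Undirected junction endpoints of a set of edges (uses the "+" oe rows).
edge_junctions <- function(graph, edge_ids) {
  rows <- oe_row(graph, paste0(edge_ids, "+"))
  data.frame(edge_id = edge_ids,
             jfrom = junction_of(graph, rows$from),
             jto = junction_of(graph, rows$to),
             stringsAsFactors = FALSE)
}

# Assign a consistent orientation frame to a connected set of tangle edges,
# starting from an oriented vertex known to be inside the tangle (the end of
# an incoming boundary edge). Each junction gets one side; each tangle edge
# one orientation. Returns NULL if the frame is inconsistent, i.e. some edge
# would have to be traversed in both orientations (an inverted repeat inside
# the tangle, which the simplified model does not support).
orient_tangle <- function(graph, tangle_edges, start_vertex) {
  ej <- edge_junctions(graph, tangle_edges)
  rows <- oe_row(graph, paste0(tangle_edges, "+"))
  side <- character()
  side[[junction_of(graph, start_vertex)]] <- start_vertex
  orient <- stats::setNames(rep(NA_character_, length(tangle_edges)), tangle_edges)
  # incidence lists junction -> edge indices
  inc <- split(rep(seq_along(tangle_edges), 2L), c(ej$jfrom, ej$jto))
  queue <- junction_of(graph, start_vertex)
  while (length(queue) > 0L) {
    j <- queue[[1L]]; queue <- queue[-1L]
    s <- side[[j]]
    for (i in unique(inc[[j]])) {
      f <- rows$from[[i]]; t <- rows$to[[i]]
      jf <- ej$jfrom[[i]]; jt <- ej$jto[[i]]
      # decide this edge's orientation as seen from junction j's side
      if (jf == j && s == f) {
        o <- "+"; other_j <- jt; other_s <- t
      } else if (jf == j && s == graph$mirror[[f]]) {
        o <- "-"; other_j <- jt; other_s <- graph$mirror[[t]]
      } else if (jt == j && s == t) {
        o <- "+"; other_j <- jf; other_s <- f
      } else if (jt == j && s == graph$mirror[[t]]) {
        o <- "-"; other_j <- jf; other_s <- graph$mirror[[f]]
      } else {
        return(NULL)  # side does not match either reading
      }
      if (!is.na(orient[[tangle_edges[[i]]]])) {
        if (orient[[tangle_edges[[i]]]] != o) return(NULL)
      } else {
        orient[[tangle_edges[[i]]]] <- o
      }
      if (!other_j %in% names(side)) {
        side[[other_j]] <- other_s
        queue <- c(queue, other_j)
      } else if (side[[other_j]] != other_s) {
        return(NULL)
      }
    }
  }
  if (anyNA(orient)) return(NULL)  # disconnected from start (should not happen)
  list(orient = orient, side = side)
}

# Build a tangle object from a candidate edge set plus its adjacent unique
# boundary edges; classifies boundary direction and orientation frame.
build_tangle <- function(graph, id, tangle_edges, boundary_edges,
                         component_len) {
  tangle_edges <- sort(tangle_edges)
  boundary_edges <- sort(boundary_edges)
  tj <- unique(unlist(edge_junctions(graph, tangle_edges)[c("jfrom", "jto")]))
  tangle_len <- sum(graph$edges[tangle_edges, "length"])
  out <- structure(list(
    id = id, tangle_edges = tangle_edges, boundary = NULL,
    n_pairs = length(boundary_edges) / 2, cov_u = NA_real_,
    orient = NULL, junctions = tj,
    tangle_len = tangle_len, component_len = component_len,
    resolvable = FALSE, reason = NA_character_
  ), class = "tangle")

  bj <- edge_junctions(graph, boundary_edges)
  touch_from <- bj$jfrom %in% tj
  touch_to <- bj$jto %in% tj
  if (any(touch_from & touch_to) || any(bj$jfrom == bj$jto)) {
    out$reason <- "boundary edge touches the tangle at both ends"
    return(out)
  }
  if (!length(boundary_edges) %in% c(2L, 4L)) {
    out$reason <- sprintf(
      "tangle has %d boundary nodes (only two or four are supported)",
      length(boundary_edges))
    return(out)
  }
  # First boundary edge (sorted) is taken incoming: orientation with its
  # `to` vertex inside the tangle defines the frame.
  b1 <- boundary_edges[[1L]]
  b1p <- oe_row(graph, paste0(b1, "+"))
  x1 <- if (junction_of(graph, b1p$to) %in% tj) {
    list(id = b1, orient = "+", end = b1p$to)
  } else {
    b1m <- oe_row(graph, paste0(b1, "-"))
    list(id = b1, orient = "-", end = b1m$to)
  }
  fr <- orient_tangle(graph, tangle_edges, x1$end)
  if (is.null(fr)) {
    out$reason <- "inconsistent orientation frame (inverted repeat inside tangle)"
    return(out)
  }
  out$orient <- fr$orient
  xs <- data.frame(id = x1$id, orient = x1$orient, stringsAsFactors = FALSE)
  ys <- data.frame(id = character(), orient = character(), stringsAsFactors = FALSE)
  for (b in boundary_edges[-1L]) {
    cls <- NULL
    for (o in c("+", "-")) {
      row <- oe_row(graph, paste0(b, o))
      jt <- junction_of(graph, row$to)
      jf <- junction_of(graph, row$from)
      if (jt %in% names(fr$side) && fr$side[[jt]] == row$to) {
        cls <- list(kind = "in", orient = o); break
      }
      if (jf %in% names(fr$side) && fr$side[[jf]] == row$from) {
        cls <- list(kind = "out", orient = o); break
      }
    }
    if (is.null(cls)) {
      out$reason <- "boundary edge not attached to the tangle orientation frame"
      return(out)
    }
    if (cls$kind == "in") {
      xs <- rbind(xs, data.frame(id = b, orient = cls$orient))
    } else {
      ys <- rbind(ys, data.frame(id = b, orient = cls$orient))
    }
  }
  if (nrow(xs) != nrow(ys)) {
    out$reason <- sprintf("unbalanced boundary: %d incoming vs %d outgoing",
                          nrow(xs), nrow(ys))
    return(out)
  }
  out$boundary <- data.frame(
    x_id = xs$id, x_orient = xs$orient,
    y_id = ys$id, y_orient = ys$orient, stringsAsFactors = FALSE
  )
  out$n_pairs <- nrow(out$boundary)
  out$resolvable <- TRUE
  out$cov_u <- tryCatch(estimate_cov_u(out, graph), error = function(e) NA_real_)
  out
}

#' @export
print.tangle <- function(x, ...) {
  cat("tangle", x$id, ":", length(x$tangle_edges), "tangle edges,",
      x$n_pairs, "boundary pair(s),",
      if (x$resolvable) "resolvable" else paste0("unresolvable (", x$reason, ")"),
      "\n")
  if (!is.null(x$boundary)) {
    for (i in seq_len(nrow(x$boundary)))
      cat("  pair", i, ":", paste0(x$boundary$x_id[[i]], x$boundary$x_orient[[i]]),
          "->", paste0(x$boundary$y_id[[i]], x$boundary$y_orient[[i]]), "\n")
  }
  if (!is.na(x$cov_u)) cat("  cov_u =", x$cov_u, "\n")
  invisible(x)
}

#' Detect tangles delimited by unique boundary edges
#'
#' A tangle is a small connected component of non-unique edges cut off from
#' the rest of its assembly-graph component by unique boundary edges: removing
#' the boundary edges disconnects it, the ends of incoming boundary edges and
#' the starts of outgoing ones lie inside it, and its total sequence length is
#' at most `max_tangle_fraction` of the component it came from. Candidates
#' are grown from non-unique edges, stopping at unique edges; the frontier
#' unique edges become the boundary. Tangles whose boundary does not consist
#' of exactly two or four unique edges (one or two incoming/outgoing pairs)
#' are returned flagged unresolvable rather than dropped.
#'
#' @param graph an [edge_graph][to_edge_graph] with coverage attached.
#' @param unique_edges character vector of unique edge ids, from
#'   [classify_unique_edges()].
#' @param max_tangle_fraction maximum fraction of the component's total edge
#'   length a tangle may occupy (default 0.2).
#' @return list of `tangle` objects (possibly empty), ordered by id.
#' @export
detect_tangles <- function(graph, unique_edges, max_tangle_fraction = 0.2) {
  stopifnot(inherits(graph, "edge_graph"))
  e <- graph$edges
  if (nrow(e) == 0L) return(list())
  ej <- edge_junctions(graph, sort(e$edge_id))

  # undirected components over junctions, all edges
  g_all <- igraph::graph_from_data_frame(
    ej[c("jfrom", "jto")], directed = FALSE,
    vertices = data.frame(name = graph$vertices)
  )
  comp_all <- igraph::components(g_all)$membership
  comp_of_edge <- comp_all[ej$jfrom]
  comp_len <- tapply(e[ej$edge_id, "length"], comp_of_edge, sum)

  nonuniq <- ej[!ej$edge_id %in% unique_edges, , drop = FALSE]
  if (nrow(nonuniq) == 0L) return(list())
  # components over junctions using only non-unique edges
  g_nu <- igraph::graph_from_data_frame(
    nonuniq[c("jfrom", "jto")], directed = FALSE,
    vertices = data.frame(name = graph$vertices)
  )
  memb <- igraph::components(g_nu)$membership
  groups <- split(nonuniq$edge_id, memb[nonuniq$jfrom])

  uniq_j <- edge_junctions(graph, intersect(sort(e$edge_id), unique_edges))
  tangles <- list()
  tid <- 0L
  for (grp in groups[order(vapply(groups, function(g) min(g), character(1)))]) {
    tj <- unique(c(ej$jfrom[ej$edge_id %in% grp], ej$jto[ej$edge_id %in% grp]))
    adj_uniq <- uniq_j$edge_id[uniq_j$jfrom %in% tj | uniq_j$jto %in% tj]
    if (length(adj_uniq) == 0L) next  # free-floating repeat component, no gap
    total <- comp_len[[as.character(comp_of_edge[[match(grp[[1]], ej$edge_id)]])]]
    tlen <- sum(e[grp, "length"])
    if (tlen > max_tangle_fraction * total) next  # not "significantly smaller"
    tid <- tid + 1L
    tangles[[tid]] <- build_tangle(graph, paste0("tangle", tid), grp, adj_uniq,
                                   total)
  }
  tangles
}

#' Estimate the unique traversal coverage of a tangle
#'
#' Every genomic path through a tangle is assumed to carry the same coverage
#' `Cov_u`, the normaliser for multiplicity estimation. Unless overridden by
#' the user it is estimated as the median coverage of the tangle's unique
#' boundary edges (incoming and outgoing alike).
#'
#' @param tangle a [tangle][detect_tangles] with at least one boundary pair.
#' @param graph the [edge_graph][to_edge_graph].
#' @param user_value optional positive override; returned as-is when given.
#' @return positive numeric scalar.
#' @export
estimate_cov_u <- function(tangle, graph, user_value = NULL) {
  if (!is.null(user_value)) {
    stopifnot(is.numeric(user_value), user_value > 0)
    return(user_value)
  }
  stopifnot(inherits(tangle, "tangle"))
  if (is.null(tangle$boundary) || nrow(tangle$boundary) < 1L)
    stop("tangle has no boundary pairs")
  ids <- c(tangle$boundary$x_id, tangle$boundary$y_id)
  covs <- graph$edges[ids, "coverage"]
  if (all(covs == 0)) stop("all boundary edge coverages are zero; cannot normalise")
  stats::median(covs)
}

#' Name a tangle manually by its boundary edges
#'
#' Bypasses structural detection: the caller supplies the oriented boundary
#' edges (incoming, outgoing, in pairs) and the tangle is taken to be the
#' connected set of non-boundary edges at the end of the first incoming edge.
#' The same separation and orientation checks as in [detect_tangles()] are
#' applied; a non-separating boundary is a validation error.
#'
#' @param graph an [edge_graph][to_edge_graph] with coverage attached.
#' @param boundary character vector of 2 or 4 oriented edge labels in the
#'   order `x1, y1[, x2, y2]`, e.g. `c("utg1+", "utg9-")`.
#' @return a resolvable `tangle` object.
#' @export
manual_tangle <- function(graph, boundary) {
  stopifnot(length(boundary) %in% c(2L, 4L))
  rows <- oe_row(graph, boundary)  # errors on unknown labels
  bids <- unique(rows$edge_id)
  if (length(bids) != length(boundary))
    stop("boundary edges must be distinct")
  e_rest <- setdiff(graph$edges$edge_id, bids)
  if (length(e_rest) == 0L) stop("no non-boundary edges left to form a tangle")
  ej <- edge_junctions(graph, sort(e_rest))
  g_rest <- igraph::graph_from_data_frame(
    ej[c("jfrom", "jto")], directed = FALSE,
    vertices = data.frame(name = graph$vertices)
  )
  memb <- igraph::components(g_rest)$membership
  x1_end_j <- junction_of(graph, rows$to[[1L]])
  inside <- names(memb)[memb == memb[[x1_end_j]]]
  tangle_edges <- ej$edge_id[ej$jfrom %in% inside | ej$jto %in% inside]
  if (length(tangle_edges) == 0L)
    stop("no tangle edges found at the end of ", boundary[[1L]])
  comp_len <- sum(graph$edges[c(tangle_edges, bids), "length"])
  tg <- build_tangle(graph, "manual", tangle_edges, bids, comp_len)
  if (!tg$resolvable)
    stop("boundary does not delimit a valid tangle: ", tg$reason)
  # honour the caller's stated incoming/outgoing pairing
  want_x <- sub("[+-]$", "", boundary[c(TRUE, FALSE)])
  if (!setequal(tg$boundary$x_id, want_x))
    stop("stated incoming edges (", paste(want_x, collapse = ","),
         ") disagree with graph structure (incoming: ",
         paste(tg$boundary$x_id, collapse = ","), ")")
  tg
}
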