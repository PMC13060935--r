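# Shared fixture builders and independent oracles. The oracles deliberately
# re-derive everything from first principles (incidence sums, sliding-window
# matching, recursive path enumeration) so that they never share code paths
# with the implementations they check.

dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

gfa_file <- function(segs, links = character()) {
  path <- withr::local_tempfile(fileext = ".gfa",
                                .local_envir = parent.frame())
  writeLines(c("H\tVN:Z:1.0", segs, links), path)
  path
}

seg_line <- function(name, len, cov = NULL, seq = NULL) {
  s <- seq %||% dna(len)
  paste0("S\t", name, "\t", s,
         if (!is.null(cov)) paste0("\tdp:f:", cov) else "")
}

link_line <- function(a, ao, b, bo, ov = 0L) {
  paste("L", a, ao, b, bo, paste0(ov, "M"), sep = "\t")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A bubble tangle: long unique X/Y flanks, two short parallel variants.
bubble_graph <- function(cov_m1 = 15, cov_m2 = 15) {
  p <- gfa_file(
    c(seg_line("X", 2000, 30), seg_line("m1", 50, cov_m1),
      seg_line("m2", 50, cov_m2), seg_line("Y", 2000, 30)),
    c(link_line("X", "+", "m1", "+"), link_line("X", "+", "m2", "+"),
      link_line("m1", "+", "Y", "+"), link_line("m2", "+", "Y", "+"))
  )
  attach_coverage(to_edge_graph(load_gfa(p)))
}

# Parallel variants plus a return edge, so the traversal can pass twice.
two_pass_graph <- function(cov_m1, cov_m2, cov_r = 30) {
  p <- gfa_file(
    c(seg_line("X", 2000, 30), seg_line("m1", 50, cov_m1),
      seg_line("m2", 50, cov_m2), seg_line("r", 50, cov_r),
      seg_line("Y", 2000, 30)),
    c(link_line("X", "+", "m1", "+"), link_line("X", "+", "m2", "+"),
      link_line("m1", "+", "Y", "+"), link_line("m2", "+", "Y", "+"),
      link_line("m1", "+", "r", "+"), link_line("m2", "+", "r", "+"),
      link_line("r", "+", "m1", "+"), link_line("r", "+", "m2", "+"))
  )
  attach_coverage(to_edge_graph(load_gfa(p)))
}

# The coverage-rounding infeasibility motif: a junction with two incoming
# and one outgoing edge, all coverages near cov_u, embedded in a cycle so a
# single traversal exists.
motif_graph <- function() {
  p <- gfa_file(
    c(seg_line("X", 2000, 30), seg_line("e1", 50, 30), seg_line("e2", 50, 30),
      seg_line("e3", 50, 30), seg_line("e4", 50, 30), seg_line("Y", 2000, 30)),
    c(link_line("X", "+", "e1", "+"), link_line("e1", "+", "e3", "+"),
      link_line("e2", "+", "e3", "+"), link_line("e3", "+", "e4", "+"),
      link_line("e4", "+", "e2", "+"), link_line("e3", "+", "Y", "+"))
  )
  attach_coverage(to_edge_graph(load_gfa(p)))
}

first_tangle <- function(graph, min_len = 100, frac = 0.6) {
  detect_tangles(graph, classify_unique_edges(graph, min_length = min_len),
                 max_tangle_fraction = frac)[[1]]
}

make_walk <- function(graph, labels, id = "r") {
  rows <- graph$oe[match(labels, rownames(graph$oe)), , drop = FALSE]
  list(read_id = id,
       steps = data.frame(edge_id = rows$edge_id, orient = rows$orient,
                          from = rows$from, to = rows$to,
                          stringsAsFactors = FALSE))
}

# ---- independent oracles --------------------------------------------------

# Brute-force minimum of the multiplicity objective: enumerate every vector
# with entries in 0..bound, keep those satisfying flow conservation (computed
# directly from incidence sums) and the at-least-once constraints, minimise
# the absolute deviation objective. Returns list(obj, mults) with all optima,
# or NULL if infeasible.
brute_force_multiplicity <- function(tangle, graph, cov_u, e_rc, bound) {
  eids <- tangle$tangle_edges
  m <- length(eids)
  rows <- graph$oe[match(paste0(eids, tangle$orient[eids]),
                         rownames(graph$oe)), , drop = FALSE]
  bnd <- tangle$boundary
  xs <- graph$oe[match(paste0(bnd$x_id, bnd$x_orient), rownames(graph$oe)), ]
  ys <- graph$oe[match(paste0(bnd$y_id, bnd$y_orient), rownames(graph$oe)), ]
  verts <- sort(unique(c(rows$from, rows$to)))
  A <- matrix(0L, length(verts), m)  # (in - out) incidence
  for (i in seq_len(m)) {
    A[match(rows$to[[i]], verts), i] <- A[match(rows$to[[i]], verts), i] + 1L
    A[match(rows$from[[i]], verts), i] <- A[match(rows$from[[i]], verts), i] - 1L
  }
  d <- integer(length(verts))
  for (v in xs$to) d[[match(v, verts)]] <- d[[match(v, verts)]] - 1L
  for (v in ys$from) d[[match(v, verts)]] <- d[[match(v, verts)]] + 1L
  M <- as.matrix(do.call(expand.grid, rep(list(0:bound), m)))
  colnames(M) <- eids
  feas <- colSums(abs(A %*% t(M) - d)) == 0
  if (length(e_rc) > 0L) {
    lowok <- rowSums(M[, eids %in% e_rc, drop = FALSE] >= 1L) == sum(eids %in% e_rc)
    feas <- feas & lowok
  }
  if (!any(feas)) return(NULL)
  Mf <- M[feas, , drop = FALSE]
  target <- graph$edges[eids, "coverage"] / cov_u
  obj <- rowSums(abs(sweep(Mf, 2, target)))
  best <- min(obj)
  list(obj = best, mults = Mf[abs(obj - best) < 1e-9, , drop = FALSE])
}

# Naive sliding-window substring check over label vectors.
naive_occurs <- function(pattern, text) {
  np <- length(pattern); nt <- length(text)
  if (np == 0L || np > nt) return(FALSE)
  for (i in seq_len(nt - np + 1L)) {
    if (all(text[i:(i + np - 1L)] == pattern)) return(TRUE)
  }
  FALSE
}

rc_labels <- function(labels) {
  id <- sub("[+-]$", "", labels)
  o <- substr(labels, nchar(labels), nchar(labels))
  rev(paste0(id, ifelse(o == "+", "-", "+")))
}

# Naive score: reads whose walk (either strand) occurs in any path.
naive_score <- function(paths, walks) {
  if (inherits(paths, "traversal_path")) paths <- list(paths)
  texts <- lapply(paths, function(p) paste0(p$edge_id, p$orient))
  supported <- vapply(walks, function(w) {
    lab <- paste0(w$steps$edge_id, w$steps$orient)
    any(vapply(texts, function(tx) {
      naive_occurs(lab, tx) || naive_occurs(rc_labels(lab), tx)
    }, logical(1)))
  }, logical(1))
  length(unique(vapply(walks[supported], `[[`, character(1), "read_id")))
}

# Independent recursive enumeration of Eulerian paths over a multiedge table
# (indices, deduplicated by label sequence at the end).
oracle_euler_paths <- function(me, start, end) {
  n <- nrow(me)
  out <- list()
  rec <- function(v, used, acc) {
    if (all(used)) {
      if (v == end) out[[length(out) + 1L]] <<- acc
      return(invisible(NULL))
    }
    for (i in which(!used & me$from == v)) {
      used[[i]] <- TRUE
      rec(me$to[[i]], used, c(acc, i))
      used[[i]] <- FALSE
    }
    invisible(NULL)
  }
  rec(start, rep(FALSE, n), integer(0))
  labs <- vapply(out, function(ix) paste(paste0(me$edge_id[ix], me$orient[ix]),
                                         collapse = " "), character(1))
  out[!duplicated(labs)]
}

# Flood-fill separation check: deleting the boundary edges must leave the
# tangle edges as exactly one undirected component.
separation_holds <- function(graph, tangle) {
  bids <- c(tangle$boundary$x_id, tangle$boundary$y_id)
  rest <- setdiff(graph$edges$edge_id, bids)
  rows <- graph$oe[match(paste0(rest, "+"), rownames(graph$oe)), ]
  jf <- unname(graph$junction[rows$from])
  jt <- unname(graph$junction[rows$to])
  # flood fill over junctions from the first tangle edge
  seed <- rest == tangle$tangle_edges[[1L]]
  reach <- unique(c(jf[seed], jt[seed]))
  repeat {
    hit <- jf %in% reach | jt %in% reach
    nreach <- unique(c(reach, jf[hit], jt[hit]))
    if (length(nreach) == length(reach)) break
    reach <- nreach
  }
  inside <- rest[jf %in% reach | jt %in% reach]
  setequal(inside, tangle$tangle_edges)
}

# Build a multiplicity_assignment object directly (for planted multigraphs).
planted_assignment <- function(mult, cov_u) {
  structure(list(mult = mult, objective_value = NA_real_, relaxed = FALSE,
                 cov_u = cov_u, e_rc = character(0)),
            class = "multiplicity_assignment")
}

# Replay check: a traversal path uses every multiedge exactly once, is
# vertex-consistent, and keeps its boundary endpoints.
path_is_eulerian <- function(path, mg) {
  inner <- path[!path$fixed, , drop = FALSE]
  lab_ok <- identical(sort(paste0(inner$edge_id, inner$orient)),
                      sort(paste0(mg$me$edge_id, mg$me$orient)))
  adj_ok <- nrow(path) < 2L ||
    all(path$to[-nrow(path)] == path$from[-1L])
  lab_ok && adj_ok
}
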