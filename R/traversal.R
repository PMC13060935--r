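#' Expand a multiplicity assignment into a multigraph
#'
#' Each tangle edge of multiplicity `n` is replaced by `n` parallel multiedges
#' carrying the same label; edges of multiplicity 0 are removed. Together with
#' the boundary edges (multiplicity 1) this multigraph admits an Eulerian
#' traversal whenever the positive-multiplicity edges are connected, which is
#' checked here.
#'
#' @param tangle a resolvable [tangle][detect_tangles].
#' @param assignment a [multiplicity_assignment][solve_multiplicities].
#' @param graph the [edge_graph][to_edge_graph].
#' @return an object of class `tangle_multigraph`: list with `me` (data.frame
#'   `edge_id`, `orient`, `from`, `to`, one row per multiedge), the `tangle`
#'   and the `assignment`.
#' @export
build_multigraph <- function(tangle, assignment, graph) {
  stopifnot(inherits(tangle, "tangle"),
            inherits(assignment, "multiplicity_assignment"))
  sys <- tangle_flow_system(tangle, graph)
  mult <- assignment$mult[sys$edge_id]
  reps <- rep(seq_along(sys$edge_id), pmax(mult, 0L))
  me <- data.frame(
    edge_id = sys$edge_id[reps],
    orient = unname(tangle$orient[sys$edge_id[reps]]),
    from = sys$from[reps], to = sys$to[reps],
    stringsAsFactors = FALSE
  )
  # connectivity over positive multiedges + boundary attachment vertices
  anchors <- unique(c(sys$start, sys$end))
  if (nrow(me) > 0L) {
    g <- igraph::graph_from_data_frame(
      me[c("from", "to")], directed = FALSE,
      vertices = data.frame(name = unique(c(me$from, me$to, anchors)))
    )
    memb <- igraph::components(g)$membership
    if (length(unique(memb[anchors])) > 1L || any(memb != memb[[1L]]))
      stop(errorCondition(
        paste0("multiplicity-positive edges of ", tangle$id,
               " are not connected; no Eulerian path exists"),
        class = "tanglepatch_no_eulerian_path"))
  }
  structure(list(me = me, tangle = tangle, assignment = assignment),
            class = "tangle_multigraph")
}

#' @export
print.tangle_multigraph <- function(x, ...) {
  cat("tangle multigraph:", nrow(x$me), "multiedges over",
      length(unique(x$me$edge_id)), "edges\n")
  invisible(x)
}

# Hierholzer's algorithm over a multiedge table, start/end oriented vertices.
# Random multiedge choice order is controlled by the caller's RNG state.
# Returns integer row indices into `me` or signals a no-Eulerian-path error.
euler_path_me <- function(me, start, end) {
  n <- nrow(me)
  if (n == 0L) {
    if (!identical(start, end))
      stop(errorCondition("empty multigraph with distinct endpoints",
                          class = "tanglepatch_no_eulerian_path"))
    return(integer(0))
  }
  verts <- unique(c(me$from, me$to, start, end))
  outd <- table(factor(me$from, levels = verts))
  ind <- table(factor(me$to, levels = verts))
  bal <- as.integer(outd) - as.integer(ind)
  names(bal) <- verts
  want <- stats::setNames(integer(length(verts)), verts)
  if (start != end) { want[[start]] <- 1L; want[[end]] <- -1L }
  if (!all(bal == want))
    stop(errorCondition("degree balance violated; no Eulerian path",
                        class = "tanglepatch_no_eulerian_path"))
  adj <- split(seq_len(n), factor(me$from, levels = verts))
  adj <- lapply(adj, function(ix) if (length(ix) > 1L) sample(ix) else ix)
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  stack_v <- start
  stack_e <- integer(0)   # edge taken to reach stack_v[i] (parallel, offset 1)
  path <- integer(0)
  while (length(stack_v) > 0L) {
    v <- stack_v[[length(stack_v)]]
    av <- adj[[v]]
    if (ptr[[v]] <= length(av)) {
      e <- av[[ptr[[v]]]]
      ptr[[v]] <- ptr[[v]] + 1L
      stack_v <- c(stack_v, me$to[[e]])
      stack_e <- c(stack_e, e)
    } else {
      stack_v <- stack_v[-length(stack_v)]
      if (length(stack_e) > 0L) {
        path <- c(path, stack_e[[length(stack_e)]])
        stack_e <- stack_e[-length(stack_e)]
      }
    }
  }
  path <- rev(path)
  if (length(path) != n)
    stop(errorCondition("multigraph is disconnected; no Eulerian path",
                        class = "tanglepatch_no_eulerian_path"))
  path
}

# Assemble a traversal_path data.frame. `context` lets optimize_path() draw
# fresh Eulerian restarts; it carries the multiedge table and the fixed
# boundary/sentinel step rows.
new_traversal_path <- function(steps, context = NULL, score = NA_integer_) {
  rownames(steps) <- NULL
  structure(steps, class = c("traversal_path", "data.frame"),
            context = context, score = score)
}

path_labels <- function(path) paste0(path$edge_id, path$orient)

#' @export
print.traversal_path <- function(x, ...) {
  lab <- path_labels(x)
  lab[x$fixed & x$edge_id == ".gap."] <- "|"
  cat("traversal path (", nrow(x), " steps):\n  ",
      paste(lab, collapse = ","), "\n", sep = "")
  s <- attr(x, "score")
  if (!is.na(s)) cat("  score:", s, "\n")
  invisible(x)
}

# Fixed boundary step row for an oriented boundary edge label.
boundary_step <- function(graph, label) {
  r <- oe_row(graph, label)
  data.frame(edge_id = r$edge_id, orient = r$orient, from = r$from, to = r$to,
             fixed = TRUE, stringsAsFactors = FALSE)
}

# Build the traversal context for a tangle: multiedge table plus fixed steps
# for the given boundary pairing (a permutation of the y rows). For two
# boundary pairs the two genomic paths are represented as one combined path
# joined by a sentinel step, so subpath swaps within and between the paths
# are a single mechanism.
traversal_context <- function(tangle, assignment, graph, pairing = NULL) {
  mg <- build_multigraph(tangle, assignment, graph)
  bnd <- tangle$boundary
  pairing <- pairing %||% seq_len(nrow(bnd))
  segs <- lapply(seq_len(nrow(bnd)), function(i) {
    x <- boundary_step(graph, paste0(bnd$x_id[[i]], bnd$x_orient[[i]]))
    y <- boundary_step(graph, paste0(bnd$y_id[[pairing[[i]]]],
                                     bnd$y_orient[[pairing[[i]]]]))
    list(x = x, y = y, sv = x$to, ev = y$from)
  })
  list(me = mg$me, segs = segs, tangle_id = tangle$id)
}

# Draw one random Eulerian traversal for a context (RNG from caller).
draw_traversal <- function(context) {
  me <- context$me
  segs <- context$segs
  if (length(segs) == 1L) {
    ix <- euler_path_me(me, segs[[1]]$sv, segs[[1]]$ev)
    steps <- rbind(
      segs[[1]]$x,
      if (length(ix)) cbind(me[ix, , drop = FALSE], fixed = FALSE),
      segs[[1]]$y
    )
    return(new_traversal_path(steps, context))
  }
  # two pairs: dummy multiedge closes pair 1's sink to pair 2's source
  dummy <- data.frame(edge_id = ".gap.", orient = "+",
                      from = segs[[1]]$ev, to = segs[[2]]$sv,
                      stringsAsFactors = FALSE)
  me2 <- rbind(me, dummy)
  ix <- euler_path_me(me2, segs[[1]]$sv, segs[[2]]$ev)
  d <- which(ix == nrow(me2))
  gap_step <- data.frame(edge_id = ".gap.", orient = "+",
                         from = segs[[1]]$y$to, to = segs[[2]]$x$from,
                         fixed = TRUE, stringsAsFactors = FALSE)
  first <- ix[seq_len(d - 1L)]
  second <- if (d < length(ix)) ix[(d + 1L):length(ix)] else integer(0)
  steps <- rbind(
    segs[[1]]$x,
    if (length(first)) cbind(me2[first, , drop = FALSE], fixed = FALSE),
    segs[[1]]$y,
    gap_step,
    segs[[2]]$x,
    if (length(second)) cbind(me2[second, , drop = FALSE], fixed = FALSE),
    segs[[2]]$y
  )
  new_traversal_path(steps, context)
}

#' Find an initial Eulerian traversal of a tangle multigraph
#'
#' Runs Hierholzer's algorithm on the expanded multigraph, starting with the
#' incoming boundary edge and ending with the outgoing one. The seed controls
#' the order in which parallel multiedges are taken, so different seeds give
#' different (equally valid) initial traversals.
#'
#' @param mg a [tangle_multigraph][build_multigraph].
#' @param graph the [edge_graph][to_edge_graph].
#' @param start,end oriented boundary edge labels (e.g. `"utg1+"`); default to
#'   the tangle's first boundary pair.
#' @param rng_seed integer seed for multiedge choice order.
#' @return a `traversal_path`: a data.frame of steps (`edge_id`, `orient`,
#'   `from`, `to`, `fixed`) whose first and last steps are the boundary edges,
#'   using every multiedge exactly once.
#' @export
find_eulerian_path <- function(mg, graph, start = NULL, end = NULL,
                               rng_seed = 42) {
  stopifnot(inherits(mg, "tangle_multigraph"))
  tangle <- mg$tangle
  bnd <- tangle$boundary
  start <- start %||% paste0(bnd$x_id[[1]], bnd$x_orient[[1]])
  end <- end %||% paste0(bnd$y_id[[1]], bnd$y_orient[[1]])
  if (nrow(bnd) == 1L) {
    ctx <- traversal_context(tangle, mg$assignment, graph)
  } else {
    yi <- match(sub("[+-]$", "", end), bnd$y_id)
    if (is.na(yi)) stop("end label is not an outgoing boundary edge: ", end)
    pairing <- if (yi == 1L) c(1L, 2L) else c(2L, 1L)
    ctx <- traversal_context(tangle, mg$assignment, graph, pairing)
  }
  with_seed(rng_seed, draw_traversal(ctx))
}

#' Enumerate subpath swaps of a traversal
#'
#' A swap exchanges two non-overlapping step intervals that start at the same
#' vertex A and end at the same vertex B — the move that reorders repeat units
#' while preserving edge multiplicities. Boundary (and sentinel) steps are
#' never moved. All valid descriptors are returned; applying any of them via
#' [apply_swap()] yields another Eulerian traversal of the same multigraph.
#'
#' @param path a `traversal_path`.
#' @return integer matrix with columns `i1, j1, i2, j2` (one swap per row;
#'   intervals `[i1,j1]` and `[i2,j2]`, `j1 < i2`).
#' @export
enumerate_swaps <- function(path) {
  n <- nrow(path)
  movable <- !path$fixed
  out <- matrix(integer(0), ncol = 4,
                dimnames = list(NULL, c("i1", "j1", "i2", "j2")))
  if (!any(movable)) return(out)
  # all intervals of consecutive movable steps
  iv_i <- integer(0); iv_j <- integer(0)
  runs <- rle(movable)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    a <- starts[[r]]; b <- ends[[r]]
    for (i in a:b) {
      iv_i <- c(iv_i, rep(i, b - i + 1L))
      iv_j <- c(iv_j, i:b)
    }
  }
  key <- paste0(path$from[iv_i], "|", path$to[iv_j])
  groups <- split(seq_along(key), key)
  res <- vector("list", length(groups))
  gi <- 0L
  for (grp in groups) {
    if (length(grp) < 2L) next
    a_i <- iv_i[grp]; a_j <- iv_j[grp]
    pair <- which(outer(a_j, a_i, `<`), arr.ind = TRUE)  # j of row < i of col
    if (nrow(pair) == 0L) next
    gi <- gi + 1L
    res[[gi]] <- cbind(i1 = a_i[pair[, 1L]], j1 = a_j[pair[, 1L]],
                       i2 = a_i[pair[, 2L]], j2 = a_j[pair[, 2L]])
  }
  if (gi == 0L) return(out)
  m <- do.call(rbind, res[seq_len(gi)])
  m[order(m[, 1L], m[, 2L], m[, 3L], m[, 4L]), , drop = FALSE]
}

#' Apply a swap to a traversal path
#'
#' @param path a `traversal_path`.
#' @param swap one row of [enumerate_swaps()] output (length-4 integer).
#' @return the rearranged `traversal_path`; the multiset of steps and all
#'   vertex adjacencies are preserved.
#' @export
apply_swap <- function(path, swap) {
  swap <- as.integer(swap)
  i1 <- swap[[1]]; j1 <- swap[[2]]; i2 <- swap[[3]]; j2 <- swap[[4]]
  n <- nrow(path)
  stopifnot(1L <= i1, i1 <= j1, j1 < i2, i2 <= j2, j2 <= n)
  if (path$from[[i1]] != path$from[[i2]] || path$to[[j1]] != path$to[[j2]])
    stop("swap intervals do not share endpoints")
  mid <- if (j1 + 1L <= i2 - 1L) (j1 + 1L):(i2 - 1L) else integer(0)
  post <- if (j2 < n) (j2 + 1L):n else integer(0)
  idx <- c(seq_len(i1 - 1L), i2:j2, mid, i1:j1, post)
  new_traversal_path(path[idx, , drop = FALSE], attr(path, "context"),
                     NA_integer_)
}

#' Optimize a traversal under swap moves to maximize read support
#'
#' Hill-climbing over the swap neighbourhood: swaps are scanned in random
#' order and the first strictly score-improving one is applied, until a full
#' scan finds none (a local optimum). The score of a path is the number of
#' reads whose walk occurs as an exact contiguous substring of the path in the
#' alphabet of oriented edge labels (either strand). Because local optima are
#' possible, the search restarts from fresh random Eulerian paths; the best
#' final path across restarts is returned, ties broken by the
#' lexicographically smallest label sequence.
#'
#' @param initial a `traversal_path` (used as the first restart's start).
#' @param walks list of [read walks][load_gaf].
#' @param restarts number of random restarts (default 10).
#' @param rng_seed integer; restart r uses a seed derived from
#'   `rng_seed` and `r`, so identical inputs give identical output.
#' @param max_accepts safety cap on accepted swaps per restart.
#' @return the best-scoring `traversal_path`, with `attr(, "score")` set and
#'   `attr(, "restart_scores")` recording each restart's final score.
#' @export
optimize_path <- function(initial, walks, restarts = 10, rng_seed = 42,
                          max_accepts = 10000) {
  stopifnot(inherits(initial, "traversal_path"), restarts >= 1)
  context <- attr(initial, "context")
  matcher <- build_read_matcher(walks)
  best <- NULL
  best_score <- -1L
  best_key <- NULL
  restart_scores <- integer(restarts)
  for (r in seq_len(restarts)) {
    res <- with_seed(derive_seed(rng_seed, r), {
      start_path <- if (r == 1L || is.null(context)) initial else draw_traversal(context)
      local_search_swaps(start_path, matcher, max_accepts)
    })
    restart_scores[[r]] <- res$score
    key <- paste(path_labels(res$path), collapse = "\r")
    if (res$score > best_score ||
        (res$score == best_score && key < best_key)) {
      best <- res$path
      best_score <- res$score
      best_key <- key
    }
  }
  attr(best, "score") <- best_score
  attr(best, "restart_scores") <- restart_scores
  best
}

# One hill-climb from `path` to a swap-local optimum. First-improvement rule
# over a randomly shuffled scan; incumbent score is non-decreasing.
local_search_swaps <- function(path, matcher, max_accepts = 10000) {
  cur <- path
  cur_score <- matcher_score(cur, matcher)
  accepts <- 0L
  repeat {
    sw <- enumerate_swaps(cur)
    if (nrow(sw) == 0L) break
    ord <- if (nrow(sw) > 1L) sample(nrow(sw)) else 1L
    improved <- FALSE
    for (k in ord) {
      cand <- apply_swap(cur, sw[k, ])
      s <- matcher_score(cand, matcher)
      if (s > cur_score) {
        cur <- cand
        cur_score <- s
        improved <- TRUE
        accepts <- accepts + 1L
        break
      }
    }
    if (!improved || accepts >= max_accepts) break
  }
  attr(cur, "score") <- cur_score
  list(path = cur, score = cur_score)
}

# --- Lemma-1 machinery -----------------------------------------------------

# Enumerate all Eulerian paths of a multiedge table between two vertices,
# as distinct label sequences (multiedges with equal labels are
# interchangeable). `limit` caps the enumeration as a safety valve.
enumerate_eulerian_labels <- function(me, start, end, limit = 50000L) {
  n <- nrow(me)
  if (n == 0L) return(list(character(0)))
  lab <- paste0(me$edge_id, me$orient)
  grp <- data.frame(lab = lab, from = me$from, to = me$to,
                    stringsAsFactors = FALSE)
  grp <- unique(grp)
  counts0 <- table(factor(lab, levels = grp$lab))
  out <- list()
  rec <- function(v, counts, acc) {
    if (length(out) >= limit) return(invisible(NULL))
    if (sum(counts) == 0L) {
      if (v == end) out[[length(out) + 1L]] <<- acc
      return(invisible(NULL))
    }
    for (g in which(grp$from == v & counts > 0L)) {
      counts[[g]] <- counts[[g]] - 1L
      rec(grp$to[[g]], counts, c(acc, grp$lab[[g]]))
      counts[[g]] <- counts[[g]] + 1L
    }
    invisible(NULL)
  }
  rec(start, as.integer(counts0), character(0))
  out
}

# Turn a label sequence back into a traversal_path (all steps movable).
labels_to_path <- function(labels, me) {
  lab <- paste0(me$edge_id, me$orient)
  idx <- match(labels, lab)
  new_traversal_path(cbind(me[idx, , drop = FALSE], fixed = FALSE))
}

#' Verify swap-connectivity of the Eulerian path space
#'
#' For every ordered pair of Eulerian paths of a small multigraph (same start
#' and end), finds an explicit swap sequence transforming one into the other
#' by iteratively extending their common prefix — the constructive argument
#' behind the guarantee that hill-climbing over swaps can, in principle,
#' reach any traversal. Intended for test-scale multigraphs.
#'
#' @param mg a [tangle_multigraph][build_multigraph], or a plain multiedge
#'   data.frame with columns `edge_id`, `orient`, `from`, `to`.
#' @param start,end oriented vertex ids delimiting the paths; default to the
#'   tangle's first boundary pair attachment vertices when `mg` is a
#'   `tangle_multigraph`.
#' @param graph required with a `tangle_multigraph` to resolve defaults.
#' @return list with `n_paths`, `n_pairs`, `connected` (logical), and
#'   `swap_lengths` (swap count per ordered pair, row-major).
#' @export
check_swap_connectivity <- function(mg, start = NULL, end = NULL,
                                    graph = NULL) {
  if (inherits(mg, "tangle_multigraph")) {
    stopifnot(!is.null(graph))
    sys <- tangle_flow_system(mg$tangle, graph)
    start <- start %||% sys$start[[1]]
    end <- end %||% sys$end[[1]]
    me <- mg$me
  } else {
    me <- mg
    stopifnot(!is.null(start), !is.null(end))
  }
  paths <- enumerate_eulerian_labels(me, start, end)
  np <- length(paths)
  swap_lengths <- integer(0)
  connected <- TRUE
  for (a in seq_len(np)) {
    for (b in seq_len(np)) {
      if (a == b) { swap_lengths <- c(swap_lengths, 0L); next }
      tr <- swap_transform(labels_to_path(paths[[a]], me), paths[[b]])
      if (is.null(tr)) {
        connected <- FALSE
        swap_lengths <- c(swap_lengths, NA_integer_)
      } else {
        swap_lengths <- c(swap_lengths, length(tr))
      }
    }
  }
  list(n_paths = np, n_pairs = np * np, connected = connected,
       swap_lengths = swap_lengths)
}

# Transform `path` into the label sequence `target` by greedy common-prefix
# extension; returns the list of applied swaps, or NULL if stuck (which the
# swap-connectivity lemma says cannot happen).
swap_transform <- function(path, target) {
  applied <- list()
  guard <- 0L
  repeat {
    lab <- path_labels(path)
    if (identical(lab, target)) return(applied)
    guard <- guard + 1L
    if (guard > length(target) + 5L) return(NULL)
    k <- which(lab != target)[[1L]]
    sw <- enumerate_swaps(path)
    if (nrow(sw) == 0L) return(NULL)
    best_cand <- NULL
    best_row <- NULL
    best_pref <- common_prefix_len(lab, target)
    for (r in seq_len(nrow(sw))) {
      if (sw[r, "i1"] != k) next  # only swaps at the mismatch can extend
      cand <- apply_swap(path, sw[r, ])
      p <- common_prefix_len(path_labels(cand), target)
      if (p > best_pref) {
        best_pref <- p
        best_cand <- cand
        best_row <- sw[r, ]
      }
    }
    if (is.null(best_cand)) return(NULL)
    applied[[length(applied) + 1L]] <- best_row
    path <- best_cand
  }
}

common_prefix_len <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  d <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(d) == 0L) n else d[[1L]] - 1L
}
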