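#' Convert a node-sequence graph to the edge-labeled representation
#'
#' Assembly graphs in GFA store sequence on nodes. Tangle resolution works on
#' the dual representation with sequence on *edges*: junctions become
#' vertices and each GFA segment becomes one edge (available in both
#' orientations). Two segment ends belong to the same junction if and only if
#' they are connected by a link, transitively closed. A segment end with no
#' link gets its own degree-one vertex.
#'
#' Because the graph is bidirected, every junction is represented by two
#' mirror-image oriented vertices (sides `a` and `b`); a traversal that is
#' legal forward is legal in reverse complement with all orientations flipped.
#' The unsigned junction set is exposed as `vertices`, and the oriented-edge
#' table `oe` carries the directed structure used for path finding.
#'
#' @param g a `gfa_graph` from [load_gfa()].
#' @return an object of class `edge_graph`: a list with
#'   \describe{
#'     \item{edges}{data.frame `edge_id`, `length`, `coverage`, `sequence`.}
#'     \item{oe}{data.frame `edge_id`, `orient`, `from`, `to` with one row per
#'       oriented edge, row names `<edge_id><orient>`; `from`/`to` are oriented
#'       vertex ids such as `"v3a"`.}
#'     \item{vertices}{character vector of unsigned junction ids (`"v1"` ...).}
#'     \item{junction}{named map oriented vertex -> junction id.}
#'     \item{mirror}{named map oriented vertex -> its mirror oriented vertex.}
#'     \item{links}{the link table (for round-tripping).}
#'     \item{overlaps}{named integer map `"<A><a>|<B><b>"` -> overlap bp for
#'       every legal consecutive step, both reading directions.}
#'   }
#' @export
to_edge_graph <- function(g) {
  stopifnot(inherits(g, "gfa_graph"))
  segs <- g$segments[order(g$segments$name), , drop = FALSE]
  links <- g$links
  n <- nrow(segs)
  edges <- data.frame(
    edge_id = segs$name, length = segs$length,
    coverage = segs$coverage, sequence = segs$sequence,
    stringsAsFactors = FALSE
  )
  rownames(edges) <- edges$edge_id

  if (n == 0L) {
    oe <- data.frame(edge_id = character(), orient = character(),
                     from = character(), to = character(),
                     stringsAsFactors = FALSE)
    return(structure(list(edges = edges, oe = oe, vertices = character(),
                          junction = character(), mirror = character(),
                          links = links, overlaps = integer()),
                     class = "edge_graph"))
  }

  # Ports: 4 per segment, (segment, orientation, end). Index layout keeps
  # arithmetic trivial: for segment i, ports 4i-3 .. 4i are (+,in), (+,out),
  # (-,in), (-,out). The mirror of (s,o,in) is (s,flip(o),out).
  port_index <- function(seg_i, orient, dir) {
    4L * (seg_i - 1L) + ifelse(orient == "+", 0L, 2L) + ifelse(dir == "in", 1L, 2L)
  }
  mirror_port <- function(p) {
    base <- ((p - 1L) %/% 4L) * 4L
    off <- p - base            # 1..4
    base + c(4L, 3L, 2L, 1L)[off]
  }
  seg_i <- stats::setNames(seq_len(n), edges$edge_id)
  uf <- uf_env(4L * n)
  if (nrow(links) > 0L) {
    for (r in seq_len(nrow(links))) {
      A <- seg_i[[links$from[[r]]]]; a <- links$from_orient[[r]]
      B <- seg_i[[links$to[[r]]]];   b <- links$to_orient[[r]]
      # A,a followed by B,b share a junction; the mirror reading is
      # B,flip(b) followed by A,flip(a).
      uf_union(uf, port_index(A, a, "out"), port_index(B, b, "in"))
      uf_union(uf, port_index(B, flip_orient(b), "out"),
               port_index(A, flip_orient(a), "in"))
    }
  }
  roots <- vapply(seq_len(4L * n), function(p) uf_root(uf, p), integer(1))
  class_ids <- sort(unique(roots))
  class_of <- match(roots, class_ids)           # per port, 1..K
  mirror_class <- class_of[vapply(match(class_ids, roots), mirror_port, integer(1))]

  # Junction = unordered pair {class, mirror(class)}; number junctions in
  # order of smallest involved class so labelling is deterministic.
  K <- length(class_ids)
  jkey <- pmin(seq_len(K), mirror_class)
  jlev <- sort(unique(jkey))
  jnum <- match(jkey, jlev)
  side <- ifelse(seq_len(K) == jkey, "a", "b")
  vclass <- paste0("v", jnum, side)             # oriented vertex id per class

  junction <- stats::setNames(paste0("v", jnum), vclass)
  mirror <- stats::setNames(vclass[mirror_class], vclass)
  vertices <- paste0("v", seq_along(jlev))

  pid <- function(orient, dir) {
    # vectorised over segments, fixed orient/dir
    4L * (seq_len(n) - 1L) + ifelse(orient == "+", 0L, 2L) +
      ifelse(dir == "in", 1L, 2L)
  }
  oe <- data.frame(
    edge_id = rep(edges$edge_id, 2L),
    orient = rep(c("+", "-"), each = n),
    from = c(vclass[class_of[pid("+", "in")]], vclass[class_of[pid("-", "in")]]),
    to = c(vclass[class_of[pid("+", "out")]], vclass[class_of[pid("-", "out")]]),
    stringsAsFactors = FALSE
  )
  rownames(oe) <- paste0(oe$edge_id, oe$orient)

  overlaps <- integer()
  if (nrow(links) > 0L) {
    k1 <- paste0(links$from, links$from_orient, "|", links$to, links$to_orient)
    k2 <- paste0(links$to, flip_orient(links$to_orient), "|",
                 links$from, flip_orient(links$from_orient))
    overlaps <- stats::setNames(c(links$overlap, links$overlap), c(k1, k2))
    overlaps <- overlaps[!duplicated(names(overlaps))]
  }

  structure(list(edges = edges, oe = oe, vertices = vertices,
                 junction = junction, mirror = mirror,
                 links = links, overlaps = overlaps),
            class = "edge_graph")
}

#' @export
print.edge_graph <- function(x, ...) {
  cat("edge_graph:", nrow(x$edges), "edges,", length(x$vertices),
      "junction vertices\n")
  if (nrow(x$edges) > 0L) {
    cov <- x$edges$coverage
    cat("  coverage set on", sum(!is.na(cov)), "/", nrow(x$edges), "edges\n")
  }
  invisible(x)
}

# --- oriented-edge helpers -------------------------------------------------

# Look up the oe row(s) for oriented labels like "e1+".
oe_row <- function(graph, labels) {
  idx <- match(labels, rownames(graph$oe))
  if (anyNA(idx)) stop("unknown oriented edge label(s): ",
                       paste(labels[is.na(idx)], collapse = ", "))
  graph$oe[idx, , drop = FALSE]
}

oriented_label <- function(edge_id, orient) paste0(edge_id, orient)

# Reverse of an oriented label: reverse(reverse(e)) == e.
reverse_label <- function(labels) {
  id <- sub("[+-]$", "", labels)
  o <- substr(labels, nchar(labels), nchar(labels))
  paste0(id, flip_orient(o))
}

# Junction (unsigned) of an oriented vertex id.
junction_of <- function(graph, v) unname(graph$junction[v])

# --- coverage --------------------------------------------------------------

#' Attach per-edge coverage to an edge graph
#'
#' Coverage comes either from a two-column tab-separated table
#' (`node<TAB>coverage`, a header line is auto-detected) or, when
#' `coverage_table` is `NULL`, from `dp:f:` tags already present in the GFA.
#' An explicit table overrides embedded tags. Edges absent from the table get
#' coverage 0 with a warning; negative values are a validation error.
#'
#' @param graph an [edge_graph][to_edge_graph].
#' @param coverage_table path to a TSV, or `NULL` to keep embedded tags.
#' @return the graph with `edges$coverage` fully populated.
#' @export
attach_coverage <- function(graph, coverage_table = NULL) {
  stopifnot(inherits(graph, "edge_graph"))
  if (is.null(coverage_table)) {
    missing <- is.na(graph$edges$coverage)
    if (any(missing)) {
      warning(sum(missing), " edge(s) without embedded coverage set to 0: ",
              paste(utils::head(graph$edges$edge_id[missing], 5L), collapse = ", "),
              if (sum(missing) > 5L) ", ..." else "")
      graph$edges$coverage[missing] <- 0
    }
  } else {
    tab <- utils::read.table(coverage_table, sep = "\t", header = FALSE,
                             colClasses = "character", comment.char = "#")
    if (ncol(tab) < 2L) stop("coverage table must have 2 columns: ", coverage_table)
    if (suppressWarnings(is.na(as.numeric(tab[1, 2])))) tab <- tab[-1, , drop = FALSE]
    ids <- tab[[1]]
    vals <- suppressWarnings(as.numeric(tab[[2]]))
    if (anyNA(vals)) stop("non-numeric coverage value(s) in ", coverage_table)
    if (any(vals < 0)) stop("negative coverage value(s) in ", coverage_table)
    idx <- match(graph$edges$edge_id, ids)
    if (anyNA(idx)) {
      miss <- graph$edges$edge_id[is.na(idx)]
      warning(length(miss), " edge(s) missing from coverage table set to 0: ",
              paste(utils::head(miss, 5L), collapse = ", "),
              if (length(miss) > 5L) ", ..." else "")
    }
    graph$edges$coverage <- ifelse(is.na(idx), 0, vals[idx])
  }
  graph
}
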