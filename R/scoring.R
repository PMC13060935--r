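#' Load read-to-graph alignments for a tangle
#'
#' Parses a GAF file (as written by sequence-to-graph aligners such as
#' GraphAligner), renders each alignment's path column as a sequence of
#' oriented edge labels, and clips it to the longest contiguous run lying
#' within the tangle plus its boundary edges. Records naming unknown segments
#' or with a malformed path column are skipped with a warning; walks shorter
#' than two labels constrain nothing and are dropped. Duplicate walks are
#' kept — scoring counts each read once by id.
#'
#' @param path path to a GAF file.
#' @param graph the [edge_graph][to_edge_graph].
#' @param tangle a [tangle][detect_tangles]; its tangle and boundary edges
#'   define the clipping universe.
#' @return list of read walks, each a list with `read_id` and `steps`
#'   (data.frame `edge_id`, `orient`, `from`, `to`).
#' @export
load_gaf <- function(path, graph, tangle) {
  stopifnot(inherits(graph, "edge_graph"), inherits(tangle, "tangle"))
  allowed <- c(tangle$tangle_edges,
               tangle$boundary$x_id, tangle$boundary$y_id)
  lines <- readLines(path, warn = FALSE)
  walks <- list()
  for (ln in lines) {
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) {
      warning("skipping malformed GAF record (fewer than 6 fields)")
      next
    }
    read_id <- f[[1]]
    pcol <- f[[6]]
    toks <- regmatches(pcol, gregexpr("[><][^><[:space:]]+", pcol))[[1]]
    if (length(toks) == 0L || nchar(paste(toks, collapse = "")) != nchar(pcol)) {
      warning("skipping GAF record ", read_id, ": malformed path column")
      next
    }
    ids <- substring(toks, 2L)
    orients <- ifelse(substring(toks, 1L, 1L) == ">", "+", "-")
    if (!all(ids %in% graph$edges$edge_id)) {
      warning("skipping GAF record ", read_id, ": unknown segment(s) ",
              paste(setdiff(ids, graph$edges$edge_id), collapse = ","))
      next
    }
    steps <- oe_row(graph, paste0(ids, orients))
    keep <- ids %in% allowed
    # break runs at non-adjacent consecutive steps too
    adj_ok <- c(TRUE, utils::head(steps$to, -1L) == steps$from[-1L])
    run_id <- cumsum(!keep | !adj_ok)
    runs <- split(which(keep), run_id[keep])
    if (length(runs) == 0L) next
    lens <- vapply(runs, length, integer(1))
    best <- runs[[which.max(lens)]]
    if (length(best) < 2L) next
    walks[[length(walks) + 1L]] <- list(
      read_id = read_id,
      steps = data.frame(edge_id = ids[best], orient = orients[best],
                         from = steps$from[best], to = steps$to[best],
                         stringsAsFactors = FALSE)
    )
  }
  walks
}

walk_labels <- function(walk) paste0(walk$steps$edge_id, walk$steps$orient)

walk_labels_rc <- function(walk) rev(reverse_label(walk_labels(walk)))

# --- Aho-Corasick over the edge-label alphabet -----------------------------
#
# Multi-pattern matching where the alphabet is oriented edge labels, not
# characters. Patterns are token vectors; the automaton reports which
# patterns occur in a token text. Standard goto/fail/output construction.

ac_build <- function(patterns) {
  children <- list(integer(0))   # named integer vectors, names = tokens
  fail <- 1L
  out <- list(integer(0))
  for (p in seq_along(patterns)) {
    node <- 1L
    for (tok in patterns[[p]]) {
      kids <- children[[node]]
      nxt <- kids[tok]
      if (is.na(nxt)) {
        children[[length(children) + 1L]] <- integer(0)
        fail[[length(children)]] <- 1L
        out[[length(children)]] <- integer(0)
        nxt <- length(children)
        kids[[tok]] <- nxt
        children[[node]] <- kids
      }
      node <- nxt
    }
    out[[node]] <- c(out[[node]], p)
  }
  # BFS failure links with output closure
  queue <- unname(children[[1L]])
  while (length(queue) > 0L) {
    u <- queue[[1L]]; queue <- queue[-1L]
    kids <- children[[u]]
    for (k in seq_along(kids)) {
      tok <- names(kids)[[k]]
      v <- kids[[k]]
      # follow fail links of u to find the fail node of v
      fnode <- fail[[u]]
      repeat {
        fkids <- children[[fnode]]
        nxt <- fkids[tok]
        if (!is.na(nxt)) { fail[[v]] <- nxt; break }
        if (fnode == 1L) { fail[[v]] <- 1L; break }
        fnode <- fail[[fnode]]
      }
      if (fail[[v]] == v) fail[[v]] <- 1L
      out[[v]] <- c(out[[v]], out[[fail[[v]]]])
      queue <- c(queue, v)
    }
  }
  list(children = children, fail = fail, out = out)
}

ac_match <- function(ac, text) {
  node <- 1L
  hits <- integer(0)
  for (tok in text) {
    repeat {
      kids <- ac$children[[node]]
      nxt <- kids[tok]
      if (!is.na(nxt)) { node <- nxt; break }
      if (node == 1L) break
      node <- ac$fail[[node]]
    }
    if (length(ac$out[[node]]) > 0L) hits <- c(hits, ac$out[[node]])
  }
  unique(hits)
}

# Matcher bundling the automaton with pattern -> read bookkeeping. Each walk
# contributes its forward and reverse-complement label sequences (read strand
# is unknown); a read is supported if either occurs.
build_read_matcher <- function(walks) {
  if (length(walks) == 0L) {
    return(list(ac = NULL, pattern_read = character(0),
                reads = character(0)))
  }
  patterns <- vector("list", 2L * length(walks))
  pattern_read <- character(2L * length(walks))
  for (i in seq_along(walks)) {
    patterns[[2L * i - 1L]] <- walk_labels(walks[[i]])
    patterns[[2L * i]] <- walk_labels_rc(walks[[i]])
    pattern_read[c(2L * i - 1L, 2L * i)] <- walks[[i]]$read_id
  }
  list(ac = ac_build(patterns), pattern_read = pattern_read,
       reads = unique(vapply(walks, `[[`, character(1), "read_id")))
}

# Read ids supported by a path (or list of paths) under a prebuilt matcher.
matcher_supported <- function(paths, matcher) {
  if (is.null(matcher$ac)) return(character(0))
  if (inherits(paths, "traversal_path")) paths <- list(paths)
  hits <- unlist(lapply(paths, function(p) ac_match(matcher$ac, path_labels(p))))
  unique(matcher$pattern_read[unique(hits)])
}

matcher_score <- function(paths, matcher) length(matcher_supported(paths, matcher))

#' Score a traversal path against read walks
#'
#' The score is the number of reads whose walk occurs as an exact contiguous
#' substring of the path in the alphabet of oriented edge labels. Matching is
#' orientation-sensitive but each walk is also tried reverse-complemented
#' (read strand is unknown); a read counts at most once however many times or
#' ways it matches. Implemented with an Aho-Corasick automaton over the edge
#' label alphabet.
#'
#' @param path a `traversal_path` (or list of them, for two-pair tangles —
#'   each read is then creditable to at most one path).
#' @param walks read walks from [load_gaf()].
#' @return integer score, with the supported read ids as
#'   `attr(, "supported")`.
#' @export
score_path <- function(path, walks) {
  matcher <- build_read_matcher(walks)
  supported <- matcher_supported(path, matcher)
  structure(length(supported), supported = supported)
}
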