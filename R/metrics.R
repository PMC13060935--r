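#' Coverage divergence of a multiplicity assignment
#'
#' The first reference-free quality metric: the divergence between
#' multiplicities and coverage, normalised by coverage and the number of
#' edges, `sum_e |cov(e)/cov_u - mult(e)| / |E|` over the tangle edges.
#' Higher values indicate tangles where the coverage-uniformity assumption
#' fits poorly; no pass/fail threshold is applied — the metric is reported,
#' never gated on.
#'
#' @param assignment a [multiplicity_assignment][solve_multiplicities].
#' @param tangle the [tangle][detect_tangles].
#' @param graph the [edge_graph][to_edge_graph].
#' @return non-negative numeric scalar.
#' @export
coverage_divergence <- function(assignment, tangle, graph) {
  eids <- tangle$tangle_edges
  stopifnot(length(eids) > 0L)
  covs <- graph$edges[eids, "coverage"]
  mean(abs(covs / assignment$cov_u - assignment$mult[eids]))
}

#' Fraction of read walks unsupported by the traversal
#'
#' The second reference-free metric: the fraction of read alignments in the
#' tangle that are *not* exact substrings of the output traversal(s) in the
#' alphabet of edge labels. For two-pair tangles a read is supported if it
#' matches either path. With no walks the fraction is defined as 0 and
#' flagged via `attr(, "no_alignments")`.
#'
#' @param paths a `traversal_path` or list of them.
#' @param walks read walks from [load_gaf()].
#' @return numeric in `[0, 1]`.
#' @export
unsupported_fraction <- function(paths, walks) {
  reads <- unique(vapply(walks, `[[`, character(1), "read_id"))
  if (length(reads) == 0L)
    return(structure(0, no_alignments = TRUE))
  matcher <- build_read_matcher(walks)
  supported <- matcher_supported(paths, matcher)
  1 - length(supported) / length(reads)
}

#' Emit the model sequence of a traversal
#'
#' Concatenates the step sequences of a traversal path, trimming each
#' junction's stored link overlap from the start of every step after the
#' first; reverse-oriented steps contribute their reverse complement. By
#' default the boundary edges are included in full so the patch carries its
#' anchors; `trim_boundary = TRUE` drops them. The model sequence is written
#' standalone — it is deliberately not patched into any scaffold, so that
#' incorporating a model sequence remains a conscious downstream decision.
#'
#' @param path a single-pair `traversal_path` (no sentinel steps).
#' @param graph the [edge_graph][to_edge_graph] with sequences present.
#' @param id sequence record id.
#' @param trim_boundary drop the first and last (boundary) steps.
#' @param description optional FASTA description text.
#' @return a [Biostrings::DNAStringSet] of length 1.
#' @export
emit_sequence <- function(path, graph, id = "model", trim_boundary = FALSE,
                          description = NULL) {
  stopifnot(inherits(path, "traversal_path"))
  if (any(path$edge_id == ".gap."))
    stop("emit_sequence() expects a single traversal; split two-pair paths first")
  steps <- path
  if (trim_boundary) {
    stopifnot(nrow(steps) > 2L)
    steps <- steps[-c(1L, nrow(steps)), , drop = FALSE]
  }
  seqs <- graph$edges[steps$edge_id, "sequence"]
  if (anyNA(seqs))
    stop("missing sequence on step(s): ",
         paste(unique(steps$edge_id[is.na(seqs)]), collapse = ", "))
  pieces <- character(nrow(steps))
  for (i in seq_len(nrow(steps))) {
    s <- if (steps$orient[[i]] == "-") revcomp(seqs[[i]]) else seqs[[i]]
    if (i > 1L) {
      key <- paste0(steps$edge_id[[i - 1L]], steps$orient[[i - 1L]], "|",
                    steps$edge_id[[i]], steps$orient[[i]])
      ov <- graph$overlaps[key]
      if (is.na(ov))
        stop("no link overlap recorded for step ", key)
      if (ov > 0L) s <- substring(s, ov + 1L)
    }
    pieces[[i]] <- s
  }
  out <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
  names(out) <- if (is.null(description)) id else paste(id, description)
  out
}

# Split a combined two-pair traversal at its sentinel step into the two
# genomic paths (each keeping its own boundary steps).
split_traversal <- function(path) {
  gaps <- which(path$edge_id == ".gap.")
  if (length(gaps) == 0L) return(list(path))
  stopifnot(length(gaps) == 1L)
  list(
    new_traversal_path(path[seq_len(gaps - 1L), , drop = FALSE]),
    new_traversal_path(path[(gaps + 1L):nrow(path), , drop = FALSE])
  )
}

#' Assemble the per-tangle report
#'
#' Bundles the reference-free metrics with traversal metadata into a list
#' that serialises losslessly to JSON.
#'
#' @param tangle the [tangle][detect_tangles].
#' @param assignment the [multiplicity_assignment][solve_multiplicities].
#' @param graph the [edge_graph][to_edge_graph].
#' @param paths list of final `traversal_path`s (one per boundary pair).
#' @param walks the read walks used for scoring.
#' @param restart_scores per-restart final scores from [optimize_path()].
#' @return a list of class `tangle_report`.
#' @export
tangle_report <- function(tangle, assignment, graph, paths, walks,
                          restart_scores = integer(0)) {
  score <- matcher_score(paths, build_read_matcher(walks))
  uf <- unsupported_fraction(paths, walks)
  path_len <- sum(vapply(paths, function(p) {
    sum(graph$edges[p$edge_id, "length"])
  }, numeric(1)))
  structure(list(
    tangle_id = tangle$id,
    n_pairs = tangle$n_pairs,
    n_tangle_edges = length(tangle$tangle_edges),
    cov_u = assignment$cov_u,
    relaxed_milp = assignment$relaxed,
    objective_value = assignment$objective_value,
    coverage_divergence = coverage_divergence(assignment, tangle, graph),
    score = score,
    n_reads = length(unique(vapply(walks, `[[`, character(1), "read_id"))),
    unsupported_read_fraction = as.numeric(uf),
    no_alignments = isTRUE(attr(uf, "no_alignments")),
    path_length_bp = path_len,
    restart_scores = as.integer(restart_scores),
    restarts_agreeing = if (length(restart_scores) > 0L)
      sum(restart_scores == max(restart_scores)) else 0L,
    paths = lapply(paths, function(p) paste0(p$edge_id, p$orient)),
    multiplicities = as.list(assignment$mult)
  ), class = "tangle_report")
}

#' @export
print.tangle_report <- function(x, ...) {
  cat("tangle report", x$tangle_id, "\n")
  cat("  pairs:", x$n_pairs, " edges:", x$n_tangle_edges,
      " cov_u:", format(x$cov_u, digits = 4),
      if (x$relaxed_milp) " (relaxed)" else "", "\n")
  cat("  coverage divergence:", format(x$coverage_divergence, digits = 4), "\n")
  cat("  unsupported read fraction:",
      format(x$unsupported_read_fraction, digits = 4),
      if (x$no_alignments) "(no alignments)" else "", "\n")
  cat("  score:", x$score, "/", x$n_reads, "reads;",
      x$restarts_agreeing, "restart(s) at the best score\n")
  invisible(x)
}

write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
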