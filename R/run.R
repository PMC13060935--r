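#' Resolve assembly-graph tangles end to end
#'
#' The full pipeline: load the GFA graph and coverage, detect tangles (or
#' accept manually named boundaries), estimate the unique traversal coverage,
#' solve the multiplicity program (with relaxation fallback), expand to a
#' multigraph, find an Eulerian traversal and optimise it against the read
#' walks, then emit the model sequence and the reference-free metrics. Each
#' tangle is processed in isolation: a failure at any stage is recorded with
#' the failing stage and never aborts the batch.
#'
#' Two-pair tangles are traversed by two genomic paths optimised jointly;
#' both source/sink pairings are tried and the better-scoring kept.
#'
#' @param graph path to a GFA file, or an [edge_graph][to_edge_graph].
#' @param coverage path to a coverage TSV, or `NULL` for embedded `dp:f:`
#'   tags.
#' @param alignments path to a GAF file of read-to-graph alignments, or
#'   `NULL` (traversals are then unscored).
#' @param out_dir output directory for per-tangle FASTA/JSON and a combined
#'   `paths.tsv`; `NULL` writes nothing.
#' @param boundary optional manual boundary labels (`c("x1+", "y1-", ...)`)
#'   bypassing detection.
#' @param min_unique_len,unique_cov_window,max_tangle_fraction detection
#'   parameters, see [classify_unique_edges()] and [detect_tangles()].
#' @param cov_u optional user override of the unique traversal coverage.
#' @param rc_threshold reasonably-covered threshold factor (default 0.5).
#' @param milp_time_limit solver time limit in seconds per tangle.
#' @param tune_cov_u re-solve over a small grid around the coverage estimate.
#' @param restarts,seed optimisation restarts and base seed.
#' @param trim_boundary drop boundary edges from emitted sequences.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list of per-tangle results; each is a list with
#'   `tangle_id`, `status` (`"resolved"`, `"failed"` or `"unsupported"`),
#'   and for resolved tangles `report`, `paths` and `sequences`.
#' @export
resolve_tangles <- function(graph, coverage = NULL, alignments = NULL,
                            out_dir = NULL, boundary = NULL,
                            min_unique_len = 1e5,
                            unique_cov_window = c(0.7, 1.3),
                            max_tangle_fraction = 0.2,
                            cov_u = NULL, rc_threshold = 0.5,
                            milp_time_limit = 300, tune_cov_u = FALSE,
                            restarts = 10, seed = 42,
                            trim_boundary = FALSE, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  if (is.character(graph)) {
    graph <- attach_coverage(to_edge_graph(load_gfa(graph)), coverage)
  } else if (!is.null(coverage)) {
    graph <- attach_coverage(graph, coverage)
  }
  stopifnot(inherits(graph, "edge_graph"))

  tangles <- if (!is.null(boundary)) {
    tryCatch(list(manual_tangle(graph, boundary)), error = function(e) {
      structure(list(list(tangle_id = "manual", status = "failed",
                          stage = "boundary", message = conditionMessage(e))),
                boundary_failed = TRUE)
    })
  } else {
    uniq <- classify_unique_edges(graph, min_unique_len, unique_cov_window)
    detect_tangles(graph, uniq, max_tangle_fraction)
  }
  if (isTRUE(attr(tangles, "boundary_failed"))) {
    say("manual boundary rejected: ", tangles[[1]]$message)
    return(invisible(unclass(tangles)))
  }
  say(length(tangles), " tangle(s) to process")
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- vector("list", length(tangles))
  path_lines <- character(0)
  for (ti in seq_along(tangles)) {
    tg <- tangles[[ti]]
    res <- resolve_one_tangle(tg, graph, alignments, cov_u, rc_threshold,
                              milp_time_limit, tune_cov_u, restarts,
                              derive_seed(seed, ti), trim_boundary)
    results[[ti]] <- res
    if (res$status == "resolved") {
      say(tg$id, ": resolved, score ", res$report$score, "/",
          res$report$n_reads, ", coverage divergence ",
          format(res$report$coverage_divergence, digits = 3))
      if (!is.null(out_dir)) {
        Biostrings::writeXStringSet(res$sequences,
                                    file.path(out_dir, paste0(tg$id, ".fasta")))
        write_report_json(res$report, file.path(out_dir, paste0(tg$id, ".json")))
        for (p in res$paths)
          path_lines <- c(path_lines,
                          paste(tg$id, paste(path_labels(p), collapse = ","),
                                sep = "\t"))
      }
    } else {
      say(tg$id, ": ", res$status, " at stage '", res$stage, "': ", res$message)
      if (!is.null(out_dir))
        jsonlite::write_json(res[c("tangle_id", "status", "stage", "message")],
                             file.path(out_dir, paste0(tg$id, ".json")),
                             auto_unbox = TRUE)
    }
  }
  if (!is.null(out_dir) && length(path_lines) > 0L)
    writeLines(path_lines, file.path(out_dir, "paths.tsv"))
  invisible(results)
}

# Resolve one tangle; never throws — failures are captured with their stage.
resolve_one_tangle <- function(tangle, graph, alignments, cov_u, rc_threshold,
                               milp_time_limit, tune_cov_u, restarts, seed,
                               trim_boundary) {
  stage <- "validate"
  out <- tryCatch({
    if (!tangle$resolvable)
      stop(errorCondition(tangle$reason, class = "tanglepatch_unsupported"))

    stage <- "cov_u"
    cu <- estimate_cov_u(tangle, graph, user_value = cov_u)
    tangle$cov_u <- cu

    stage <- "alignments"
    walks <- if (is.null(alignments)) list() else
      load_gaf(alignments, graph, tangle)

    stage <- "multiplicity"
    assignment <- solve_multiplicities(
      tangle, graph, cov_u = cu, solver_time_limit = milp_time_limit,
      tune_cov_u = tune_cov_u, rc_threshold = rc_threshold)

    stage <- "eulerian"
    pairings <- if (tangle$n_pairs == 2L) list(c(1L, 2L), c(2L, 1L)) else
      list(1L)
    contexts <- lapply(pairings, function(pr)
      traversal_context(tangle, assignment, graph, pr))

    stage <- "optimize"
    best <- NULL
    for (ci in seq_along(contexts)) {
      init <- with_seed(derive_seed(seed, 100 + ci),
                        draw_traversal(contexts[[ci]]))
      opt <- optimize_path(init, walks, restarts = restarts,
                           rng_seed = derive_seed(seed, ci))
      if (is.null(best) || attr(opt, "score") > attr(best, "score"))
        best <- opt
    }

    stage <- "emit"
    paths <- split_traversal(best)
    seqs <- do.call(c, lapply(seq_along(paths), function(i) {
      emit_sequence(paths[[i]], graph,
                    id = paste0(tangle$id, "_path", i),
                    trim_boundary = trim_boundary,
                    description = sprintf("pair=%d score=%d", i,
                                          attr(best, "score")))
    }))
    report <- tangle_report(tangle, assignment, graph, paths, walks,
                            attr(best, "restart_scores"))
    list(tangle_id = tangle$id, status = "resolved", report = report,
         paths = paths, sequences = seqs, assignment = assignment,
         walks = walks)
  }, error = function(e) {
    status <- if (inherits(e, "tanglepatch_unsupported")) "unsupported" else "failed"
    list(tangle_id = tangle$id, status = status, stage = stage,
         message = conditionMessage(e))
  })
  out
}
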