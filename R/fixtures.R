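# Synthetic ground-truth tangles: a repeat array flanked by unique sequence,
# collapsed into an assembly graph by exact k-mer collapse (a forward-strand
# de Bruijn graph compacted into unitigs), with coverage derived from the
# planted multiplicities. Emulates the collapsed repeat arrays (e.g.
# ampliconic gene clusters) that leave tangles in real assembly graphs;
# homogeneous arrays (low divergence) produce the most tangled graphs.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

mutate_seq <- function(seq, divergence) {
  if (divergence <= 0) return(list(seq = seq, pos = integer(0)))
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < divergence)
  for (i in hit) {
    chars[[i]] <- sample(setdiff(c("A", "C", "G", "T"), chars[[i]]), 1L)
  }
  list(seq = paste(chars, collapse = ""), pos = hit)
}

#' Plant a repeat-array tangle with known ground truth
#'
#' Builds a genome of `n_units` near-identical repeat units flanked by unique
#' random sequence, collapses it by exact k-mer collapse (forward-strand de
#' Bruijn graph compacted into unitigs) into an assembly graph, and derives
#' per-edge coverage from the true multiplicities with multiplicative uniform
#' noise. Higher `divergence` separates the unit copies and yields less
#' tangled graphs; `divergence = 0` collapses the array into a single repeat
#' edge of multiplicity `n_units`.
#'
#' @param n_units number of repeat units (>= 1).
#' @param unit_len unit length in bp (default 150).
#' @param divergence per-base point-mutation probability applied to each unit
#'   copy before collapse (default 0.02).
#' @param rng_seed integer seed; the same seed reproduces the fixture
#'   byte-for-byte.
#' @param k k-mer size of the collapse (default 21; toy scale).
#' @param flank_len length of each unique flank in bp (default 500).
#' @param cov_u_true coverage of one traversal (default 30).
#' @param noise multiplicative coverage noise half-width (default 0.1, i.e.
#'   cov = mult * cov_u * (1 + eps), eps ~ U(-0.1, 0.1)).
#' @return an object of class `planted_tangle`: list with `genome`, `units`
#'   (the mutated unit copies), `variants` (mutated-site context strings,
#'   k-flank each side), `graph` (an [edge_graph][to_edge_graph] with planted
#'   coverage), `true_path` (a `traversal_path` over the graph), `mult`
#'   (named true multiplicities), `cov_u_true`, `k`, and `noise`.
#' @export
plant_repeat_tangle <- function(n_units, unit_len = 150, divergence = 0.02,
                                rng_seed = 1, k = 21, flank_len = 500,
                                cov_u_true = 30, noise = 0.1) {
  stopifnot(n_units >= 1, unit_len > k, flank_len > k)
  with_seed(rng_seed, {
    flank_l <- rand_dna(flank_len)
    flank_r <- rand_dna(flank_len)
    unit <- rand_dna(unit_len)
    units <- vector("list", n_units)
    variant_pos <- list()
    offset <- flank_len
    for (i in seq_len(n_units)) {
      m <- mutate_seq(unit, divergence)
      units[[i]] <- m$seq
      if (length(m$pos) > 0L)
        variant_pos[[length(variant_pos) + 1L]] <- offset + m$pos
      offset <- offset + unit_len
    }
    genome <- paste0(flank_l, paste(unlist(units), collapse = ""), flank_r)
    gl <- nchar(genome)
    variants <- vapply(unlist(variant_pos) %||% integer(0), function(p) {
      substr(genome, max(1L, p - k), min(gl, p + k))
    }, character(1))

    db <- dbg_unitigs(genome, k)
    eps <- stats::runif(length(db$mult), -noise, noise)
    coverage <- db$mult * cov_u_true * (1 + eps)

    gfa <- structure(list(
      segments = data.frame(name = db$names, length = nchar(db$seqs),
                            coverage = coverage, sequence = db$seqs,
                            stringsAsFactors = FALSE),
      links = db$links
    ), class = "gfa_graph")
    graph <- to_edge_graph(gfa)

    steps <- oe_row(graph, paste0(db$walk, "+"))
    true_path <- new_traversal_path(data.frame(
      edge_id = steps$edge_id, orient = steps$orient,
      from = steps$from, to = steps$to,
      fixed = c(TRUE, rep(FALSE, max(0L, length(db$walk) - 2L)), TRUE),
      stringsAsFactors = FALSE
    ))

    structure(list(
      genome = genome, units = unlist(units), variants = variants,
      graph = graph, true_path = true_path,
      mult = stats::setNames(db$mult, db$names),
      cov_u_true = cov_u_true, k = k, noise = noise,
      flank_len = flank_len, rng_seed = rng_seed
    ), class = "planted_tangle")
  })
}

#' @export
print.planted_tangle <- function(x, ...) {
  cat("planted tangle:", nchar(x$genome), "bp genome,",
      nrow(x$graph$edges), "graph edges,",
      nrow(x$true_path), "true-path steps, cov_u =", x$cov_u_true, "\n")
  invisible(x)
}

# Forward-strand de Bruijn graph of one genome string, compacted to unitigs.
# Returns unitig names/sequences/multiplicities, the link table (k-1
# overlaps) and the genome's walk as a unitig name sequence.
dbg_unitigs <- function(genome, k) {
  L <- nchar(genome)
  nk <- L - k + 1L
  stopifnot(nk >= 2L)
  kmers <- substring(genome, seq_len(nk), seq_len(nk) + k - 1L)
  uk <- unique(kmers)
  kid <- match(kmers, uk)
  counts <- tabulate(kid, length(uk))
  pref <- substring(uk, 1L, k - 1L)
  suff <- substring(uk, 2L, k)
  nodes <- unique(c(pref, suff))
  pi <- match(pref, nodes)
  si <- match(suff, nodes)
  outdeg <- tabulate(pi, length(nodes))
  indeg <- tabulate(si, length(nodes))
  internal <- indeg == 1L & outdeg == 1L
  out_k <- split(seq_along(uk), pi)   # node index (as name) -> kmer ids out
  starts <- which(!internal[pi])
  if (length(starts) == 0L)
    stop("degenerate fixture: the collapse is a pure cycle; change the seed")
  unitig_of <- integer(length(uk))
  chains <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    e <- starts[[s]]
    chain <- e
    while (internal[si[[e]]]) {
      e <- out_k[[as.character(si[[e]])]][[1L]]
      chain <- c(chain, e)
    }
    chains[[s]] <- chain
    unitig_of[chain] <- s
  }
  if (any(unitig_of == 0L))
    stop("degenerate fixture: isolated k-mer cycle; change the seed")
  names_u <- sprintf("utg%03d", seq_along(chains))
  seqs <- vapply(chains, function(ch) {
    paste0(substring(uk[[ch[[1L]]]], 1L, k - 1L),
           paste(substring(uk[ch], k, k), collapse = ""))
  }, character(1))
  mult <- vapply(chains, function(ch) {
    cs <- counts[ch]
    if (length(unique(cs)) != 1L)
      stop("internal error: non-uniform k-mer counts inside a unitig")
    cs[[1L]]
  }, integer(1))
  # links from each unitig end to the unitigs starting at its suffix node
  lf <- character(0); lt <- character(0)
  for (s in seq_along(chains)) {
    last <- chains[[s]][[length(chains[[s]])]]
    nxt <- out_k[[as.character(si[[last]])]]
    if (!is.null(nxt) && !internal[si[[last]]]) {
      for (e2 in nxt) {
        lf <- c(lf, names_u[[s]])
        lt <- c(lt, names_u[[unitig_of[[e2]]]])
      }
    }
  }
  links <- data.frame(from = lf, from_orient = rep("+", length(lf)),
                      to = lt, to_orient = rep("+", length(lt)),
                      overlap = rep(k - 1L, length(lf)),
                      stringsAsFactors = FALSE)
  # genome walk through the unitigs
  walk <- character(0)
  p <- 1L
  while (p <= nk) {
    u <- unitig_of[[kid[[p]]]]
    if (chains[[u]][[1L]] != kid[[p]])
      stop("degenerate fixture: genome enters a unitig mid-way; change the seed")
    walk <- c(walk, names_u[[u]])
    p <- p + length(chains[[u]])
  }
  list(names = names_u, seqs = seqs, mult = mult, links = links, walk = walk)
}

#' Sample read walks from a planted tangle
#'
#' Draws uniform random subpaths of the true traversal, 2 to `max_len` steps
#' long, as read walks — the idealised output of a sequence-to-graph aligner
#' (walks are exact; base-level read errors are out of scope because the
#' pipeline consumes aligner output, not raw reads).
#'
#' @param planted a [planted_tangle][plant_repeat_tangle].
#' @param n_reads number of walks to draw.
#' @param min_len,max_len walk length bounds in steps (min 2).
#' @param rng_seed integer seed.
#' @return list of read walks as produced by [load_gaf()].
#' @export
sample_read_walks <- function(planted, n_reads, min_len = 2, max_len = 6,
                              rng_seed = 1) {
  stopifnot(inherits(planted, "planted_tangle"), min_len >= 2)
  tp <- planted$true_path
  n <- nrow(tp)
  stopifnot(n >= 2L)
  with_seed(rng_seed, {
    walks <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      len <- sample(min_len:min(max_len, n), 1L)
      start <- sample(seq_len(n - len + 1L), 1L)
      steps <- tp[start:(start + len - 1L),
                  c("edge_id", "orient", "from", "to"), drop = FALSE]
      rownames(steps) <- NULL
      walks[[i]] <- list(read_id = sprintf("read%05d", i),
                         steps = as.data.frame(steps))
    }
    walks
  })
}

#' Write a planted fixture to disk
#'
#' Writes `graph.gfa` (sequences plus embedded `dp:f:` coverage),
#' `coverage.tsv`, `reads.gaf` (when walks are given) and `truth.json` into a
#' directory, so the complete pipeline can be exercised from files. Output is
#' byte-deterministic for a given fixture.
#'
#' @param planted a [planted_tangle][plant_repeat_tangle].
#' @param dir output directory (created if needed).
#' @param walks optional read walks from [sample_read_walks()].
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(planted, dir, walks = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gfa(planted$graph, file.path(dir, "graph.gfa"))
  e <- planted$graph$edges
  writeLines(c("node\tcoverage",
               paste(e$edge_id, format(e$coverage, digits = 10, trim = TRUE),
                     sep = "\t")),
             file.path(dir, "coverage.tsv"))
  if (!is.null(walks))
    write_gaf_walks(walks, planted$graph, file.path(dir, "reads.gaf"))
  jsonlite::write_json(
    list(genome = planted$genome,
         true_path = paste0(planted$true_path$edge_id, planted$true_path$orient),
         mult = as.list(planted$mult),
         cov_u = planted$cov_u_true, k = planted$k,
         rng_seed = planted$rng_seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Generate a random small tangle with planted multiplicities
#'
#' Draws a random traversal through a handful of internal junctions and
#' realises it as an assembly graph: every traversed (junction, junction)
#' step either reuses an existing parallel edge (raising its multiplicity) or
#' creates a new one, so flow conservation holds by construction. Boundary
#' edges `X`/`Y` flank the tangle and coverage is planted as
#' `mult * cov_u * (1 + eps)`. Complements [plant_repeat_tangle()] with
#' arbitrary small topologies (parallel edges, loops) for property testing of
#' the multiplicity and traversal stages.
#'
#' @param rng_seed integer seed.
#' @param n_internal number of internal junctions (default 3).
#' @param walk_len number of internal steps in the planted traversal.
#' @param reuse_prob probability of reusing an existing parallel edge.
#' @param cov_u_true planted unique traversal coverage.
#' @param noise multiplicative coverage noise half-width.
#' @param seg_len tangle segment length in bp.
#' @param flank_len boundary segment length in bp.
#' @return list with `graph` (an [edge_graph][to_edge_graph]), `tangle` (via
#'   [manual_tangle()]), `mult_true` (named integer), `true_path` (a
#'   `traversal_path` including boundary steps) and `cov_u_true`.
#' @export
random_tangle_fixture <- function(rng_seed, n_internal = 3, walk_len = 5,
                                  reuse_prob = 0.6, cov_u_true = 30,
                                  noise = 0.1, seg_len = 50,
                                  flank_len = 400) {
  with_seed(rng_seed, {
    inner <- sample(paste0("I", seq_len(n_internal)), walk_len, replace = TRUE)
    vseq <- c("S", inner, "T")
    efrom <- character(0); eto <- character(0); emult <- integer(0)
    path_edges <- character(length(vseq) - 1L)
    for (s in seq_len(length(vseq) - 1L)) {
      u <- vseq[[s]]; v <- vseq[[s + 1L]]
      cand <- which(efrom == u & eto == v)
      if (length(cand) > 0L && stats::runif(1) < reuse_prob) {
        i <- cand[[1L]]
        emult[[i]] <- emult[[i]] + 1L
      } else {
        efrom <- c(efrom, u); eto <- c(eto, v); emult <- c(emult, 1L)
        i <- length(efrom)
      }
      path_edges[[s]] <- sprintf("e%02d", i)
    }
    enames <- sprintf("e%02d", seq_along(efrom))
    segs <- data.frame(
      name = c("X", "Y", enames),
      length = c(flank_len, flank_len, rep(seg_len, length(enames))),
      coverage = c(cov_u_true * (1 + stats::runif(2, -noise, noise)),
                   emult * cov_u_true * (1 + stats::runif(length(enames),
                                                          -noise, noise))),
      sequence = vapply(c(flank_len, flank_len,
                          rep(seg_len, length(enames))), rand_dna, character(1)),
      stringsAsFactors = FALSE
    )
    lf <- character(0); lt <- character(0)
    for (v in unique(c(efrom, eto, "S", "T"))) {
      ins <- c(enames[eto == v], if (v == "S") "X")
      outs <- c(enames[efrom == v], if (v == "T") "Y")
      for (a in ins) for (b in outs) { lf <- c(lf, a); lt <- c(lt, b) }
    }
    links <- data.frame(from = lf, from_orient = "+", to = lt, to_orient = "+",
                        overlap = 0L, stringsAsFactors = FALSE)
    gfa <- structure(list(segments = segs, links = links), class = "gfa_graph")
    graph <- to_edge_graph(gfa)
    tangle <- manual_tangle(graph, c("X+", "Y+"))
    steps <- oe_row(graph, paste0(c("X", path_edges, "Y"), "+"))
    true_path <- new_traversal_path(data.frame(
      edge_id = steps$edge_id, orient = steps$orient,
      from = steps$from, to = steps$to,
      fixed = c(TRUE, rep(FALSE, length(path_edges)), TRUE),
      stringsAsFactors = FALSE
    ))
    list(graph = graph, tangle = tangle,
         mult_true = stats::setNames(emult, enames),
         true_path = true_path, cov_u_true = cov_u_true)
  })
}

# Serialise read walks as GAF records (12 canonical columns).
write_gaf_walks <- function(walks, graph, path) {
  lines <- vapply(walks, function(w) {
    labs <- paste0(ifelse(w$steps$orient == "+", ">", "<"), w$steps$edge_id)
    lens <- graph$edges[w$steps$edge_id, "length"]
    ovs <- if (nrow(w$steps) > 1L) {
      keys <- paste0(w$steps$edge_id[-nrow(w$steps)],
                     w$steps$orient[-nrow(w$steps)], "|",
                     w$steps$edge_id[-1L], w$steps$orient[-1L])
      sum(graph$overlaps[keys])
    } else 0L
    plen <- sum(lens) - ovs
    paste(w$read_id, plen, 0L, plen, "+", paste(labs, collapse = ""),
          plen, 0L, plen, plen, plen, 60L, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
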