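#' Load a GFA 1.x assembly graph
#'
#' Reads segment (`S`) and link (`L`) lines of a GFA 1.x file into a
#' node-sequence graph, the representation emitted by de Bruijn / multiplex-DBG
#' assemblers where sequence lives on segments and links describe junction
#' overlaps. `P` and `W` lines are ignored with a message; `C` lines and
#' GFA 2.0 are unsupported.
#'
#' Per-segment coverage is picked up from a `dp:f:` tag when present, so graphs
#' that embed read depth need no separate coverage table (an explicit table
#' passed to [attach_coverage()] still takes precedence).
#'
#' @param path path to a GFA file.
#' @return an object of class `gfa_graph`: a list with `segments`
#'   (data.frame: `name`, `length`, `coverage`, `sequence`) and `links`
#'   (data.frame: `from`, `from_orient`, `to`, `to_orient`, `overlap` in bp).
#' @seealso [to_edge_graph()], [write_gfa()]
#' @export
load_gfa <- function(path) {
  if (!file.exists(path)) stop("GFA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  seg_name <- character()
  seg_seq <- character()
  seg_len <- integer()
  seg_cov <- numeric()
  lf <- character(); lfo <- character(); lt <- character(); lto <- character()
  lov <- integer()
  ignored <- 0L
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    rec <- f[[1]]
    if (rec == "S") {
      if (length(f) < 3L) stop("malformed S line at line ", i, " of ", path)
      seq <- f[[3]]
      tags <- if (length(f) > 3L) f[4:length(f)] else character()
      len <- if (seq == "*") {
        ln <- grep("^LN:i:", tags, value = TRUE)
        if (length(ln) == 0L)
          stop("segment without sequence or LN tag at line ", i, " of ", path)
        as.integer(sub("^LN:i:", "", ln[[1]]))
      } else nchar(seq)
      dp <- grep("^dp:f:", tags, value = TRUE)
      cov <- if (length(dp) > 0L) as.numeric(sub("^dp:f:", "", dp[[1]])) else NA_real_
      seg_name <- c(seg_name, f[[2]])
      seg_seq <- c(seg_seq, if (seq == "*") NA_character_ else seq)
      seg_len <- c(seg_len, len)
      seg_cov <- c(seg_cov, cov)
    } else if (rec == "L") {
      if (length(f) < 6L) stop("malformed L line at line ", i, " of ", path)
      if (!all(c(f[[3]], f[[5]]) %in% c("+", "-")))
        stop("malformed L line orientation at line ", i, " of ", path)
      cig <- f[[6]]
      ov <- if (cig == "*") 0L else if (grepl("^[0-9]+M$", cig)) {
        as.integer(sub("M$", "", cig))
      } else {
        stop("unsupported link CIGAR '", cig, "' at line ", i, " of ", path,
             " (only '<int>M' or '*' overlaps are supported)")
      }
      lf <- c(lf, f[[2]]); lfo <- c(lfo, f[[3]])
      lt <- c(lt, f[[4]]); lto <- c(lto, f[[5]])
      lov <- c(lov, ov)
    } else if (rec %in% c("P", "W")) {
      ignored <- ignored + 1L
    } else if (rec == "H") {
      next
    } else if (rec %in% c("C", "E", "G", "F", "O", "U")) {
      stop("unsupported GFA record type '", rec, "' at line ", i, " of ", path)
    } else {
      stop("malformed GFA line at line ", i, " of ", path)
    }
  }
  if (ignored > 0L) message("ignored ", ignored, " P/W path line(s) in ", path)
  segments <- data.frame(
    name = seg_name, length = seg_len, coverage = seg_cov,
    sequence = seg_seq, stringsAsFactors = FALSE
  )
  if (anyDuplicated(segments$name))
    stop("duplicate segment name(s) in ", path, ": ",
         paste(unique(segments$name[duplicated(segments$name)]), collapse = ", "))
  links <- data.frame(
    from = lf, from_orient = lfo, to = lt, to_orient = lto,
    overlap = lov, stringsAsFactors = FALSE
  )
  bad <- setdiff(unique(c(links$from, links$to)), segments$name)
  if (length(bad) > 0L)
    stop("link(s) reference unknown segment(s): ", paste(bad, collapse = ", "))
  structure(list(segments = segments, links = links), class = "gfa_graph")
}

#' @export
print.gfa_graph <- function(x, ...) {
  cat("gfa_graph:", nrow(x$segments), "segments,", nrow(x$links), "links\n")
  invisible(x)
}

#' Write a graph back to GFA 1.x
#'
#' Serialises either a `gfa_graph` or an [edge_graph][to_edge_graph] to GFA,
#' with per-segment coverage stored as a `dp:f:` tag. Used for fixtures and
#' debugging; [load_gfa()] of the output reproduces an isomorphic graph.
#'
#' @param graph a `gfa_graph` or `edge_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path) {
  if (inherits(graph, "edge_graph")) {
    segments <- data.frame(
      name = graph$edges$edge_id, length = graph$edges$length,
      coverage = graph$edges$coverage, sequence = graph$edges$sequence,
      stringsAsFactors = FALSE
    )
    links <- graph$links
  } else if (inherits(graph, "gfa_graph")) {
    segments <- graph$segments
    links <- graph$links
  } else {
    stop("write_gfa() expects a gfa_graph or edge_graph")
  }
  s_lines <- vapply(seq_len(nrow(segments)), function(i) {
    seq <- segments$sequence[[i]]
    base <- paste("S", segments$name[[i]],
                  if (is.na(seq)) "*" else seq, sep = "\t")
    if (is.na(seq)) base <- paste0(base, "\tLN:i:", segments$length[[i]])
    cov <- segments$coverage[[i]]
    if (!is.na(cov)) base <- paste0(base, "\tdp:f:", format(cov, digits = 10))
    base
  }, character(1))
  l_lines <- if (nrow(links) > 0L) {
    paste("L", links$from, links$from_orient, links$to, links$to_orient,
          paste0(links$overlap, "M"), sep = "\t")
  } else character()
  writeLines(c("H\tVN:Z:1.0", s_lines, l_lines), path)
  invisible(path)
}
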