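# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

flip_orient <- function(o) {
  stopifnot(all(o %in% c("+", "-")))
  ifelse(o == "+", "-", "+")
}

#' Reverse complement of a DNA string
#' @param x character scalar over the DNA alphabet (IUPAC codes allowed).
#' @return character scalar
#' @keywords internal
revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All randomized operations in the package route their seeds through this so
# that library code never clobbers the user's random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a child seed from a parent seed and an index, kept inside 32-bit
# integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483629)
}

# Union-find kept in an environment (plain vectors would be copied on every
# union).
uf_env <- function(n) {
  e <- new.env(parent = emptyenv())
  e$parent <- seq_len(n)
  e
}

uf_root <- function(e, i) {
  p <- e$parent
  root <- i
  while (p[root] != root) root <- p[root]
  # path compression
  while (p[i] != root) {
    nxt <- p[i]
    p[i] <- root
    i <- nxt
  }
  e$parent <- p
  root
}

uf_union <- function(e, i, j) {
  ri <- uf_root(e, i)
  rj <- uf_root(e, j)
  if (ri != rj) {
    p <- e$parent
    p[max(ri, rj)] <- min(ri, rj)
    e$parent <- p
  }
  invisible(NULL)
}
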