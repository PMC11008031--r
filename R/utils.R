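#' Reverse complement of a DNA string
#'
#' Plain-character convenience used throughout the package (sequences are
#' carried as character scalars, not `DNAString` objects).  `N` maps to `N`.
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(out, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Map any non-ACGTN character (other IUPAC ambiguity codes, gaps from sloppy
# inputs) to N after uppercasing.  Assemblies routinely contain ambiguity
# codes; N is neutral in every downstream count.
normalize_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

# Run `expr` under a temporary RNG state seeded with `seed`; restore the
# caller's RNG afterwards.  seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Draw a random DNA sequence of length n at the given GC content.
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# 0-based half-open substring of a character scalar.
substr0 <- function(x, start, end) {
  if (end <= start) return("")
  substr(x, start + 1L, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
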