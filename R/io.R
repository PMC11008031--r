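#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased and any IUPAC ambiguity code outside
#' `{A,C,G,T,N}` is mapped to `N`.  Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @param species_id optional short label attached to the result as the
#'   `species_id` attribute (one genome assembly per species is the working
#'   convention of the pipeline).
#' @return named character vector of sequences (names are the first
#'   whitespace-delimited token of each header), with attribute
#'   `species_id` when supplied.
#' @export
read_fasta <- function(path, species_id = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("FASTA parse error at line 1: empty file ", path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("FASTA parse error at line ", first, ": expected '>' header in ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA parse error: no records in ", path)
  seqs <- normalize_dna(as.character(set))
  if (any(!nzchar(seqs))) {
    bad <- which(!nzchar(seqs))[1L]
    stop("FASTA parse error: empty sequence for record '", names(set)[bad], "'")
  }
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (!is.null(species_id)) attr(seqs, "species_id") <- species_id
  seqs
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a table of genomic intervals
#'
#' The package-wide interval convention is 0-based half-open (BED-native);
#' 1-based coordinates appear only in human-readable reports.
#'
#' @param seq_id contig names.
#' @param start,end 0-based half-open bounds, `0 <= start < end`.
#' @param name feature names (default `iv1`, `iv2`, ...).
#' @param score numeric scores (BED column 5).
#' @param strand `"+"` or `"-"`.
#' @return data.frame with columns seq_id, start, end, name, score, strand.
#' @export
intervals <- function(seq_id, start, end, name = NULL, score = 0L, strand = "+") {
  n <- length(start)
  stopifnot(length(end) == n, all(start >= 0), all(end > start))
  if (n == 0L) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    seq_id = rep_len(as.character(seq_id), n),
    start = as.integer(start), end = as.integer(end),
    name = if (is.null(name)) paste0("iv", seq_len(n)) else rep_len(as.character(name), n),
    score = rep_len(score, n), strand = rep_len(strand, n),
    stringsAsFactors = FALSE
  )
}

#' Write intervals as BED6
#'
#' @param loci data.frame as returned by [intervals()] (extra columns are
#'   ignored).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(loci, path) {
  cols <- c("seq_id", "start", "end", "name", "score", "strand")
  if (nrow(loci) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  stopifnot(all(cols %in% names(loci)), all(loci$start >= 0), all(loci$end > loci$start))
  utils::write.table(loci[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path path to a BED file (0-based half-open, as always).
#' @return data.frame with columns seq_id, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L) return(intervals(character(0), integer(0), integer(0))[0, ])
  df <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("BED parse error: expected 6 columns, found ", ncol(df))
  names(df)[1:6] <- c("seq_id", "start", "end", "name", "score", "strand")
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$end <= df$start)) stop("BED parse error: end <= start")
  df[, 1:6]
}

#' Read a species tree in newick format
#'
#' @param path path to a newick file, or a newick string when `text` is
#'   used instead.
#' @param text optional newick string (bypasses `path`).
#' @return a \pkg{ape} `phylo` object; branch lengths retained
#'   when present.  Duplicate leaf labels are an error.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else {
    if (!file.exists(path)) stop("newick file not found: ", path)
    ape::read.tree(path)
  }
  if (is.null(tr)) stop("newick parse error")
  if (anyDuplicated(tr$tip.label))
    stop("newick error: duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}
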