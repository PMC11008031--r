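empty_hits <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), qstart = integer(0), qend = integer(0),
             score = integer(0), identity = numeric(0),
             aligned_length = integer(0), matches = integer(0),
             mismatches = integer(0), gapcols = integer(0),
             stringsAsFactors = FALSE)
}

#' Seed-and-extend local nucleotide search
#'
#' Finds local alignments of `query` in `genome` with the sensitive scoring
#' used for low-identity TE searches: exact `word_size` seeds on both
#' strands, ungapped X-drop triage, then banded gapped extension around the
#' seed diagonal.  Overlapping same-strand hits are merged to the best
#' scoring one.  Identity is matches over aligned columns excluding gap
#' columns; `N` positions count as mismatches and never seed.
#'
#' @param query DNA character scalar (the TE consensus or any probe).
#' @param genome named character vector of contig sequences (as from
#'   [read_fasta()]), or a bare character scalar (contig name `"seq1"`).
#' @param word_size exact seed length (default 7, the sensitive setting).
#' @param match,mismatch match reward / mismatch penalty (+4 / -5).
#' @param gap_open,gap_extend affine gap scores; a gap of length L scores
#'   `gap_open + L * gap_extend`.
#' @param min_score minimum alignment score to report.
#' @param xdrop ungapped extension termination threshold.
#' @param band half-width of the gapped extension band around the seed
#'   diagonal (alignments cannot drift more than `band` indel columns).
#' @param merge_overlap same-strand hits overlapping at least this fraction
#'   of the shorter hit are merged, best score wins.
#' @return data.frame of hits: seq_id, start, end (0-based half-open
#'   genomic), strand, qstart, qend (0-based half-open on the query in its
#'   input orientation), score, identity, aligned_length, matches,
#'   mismatches, gapcols.  Sorted by decreasing score.
#' @export
local_search <- function(query, genome, word_size = 7L, match = 4L,
                         mismatch = -5L, gap_open = -8L, gap_extend = -2L,
                         min_score = 100L, xdrop = 20L, band = 16L,
                         merge_overlap = 0.5) {
  stopifnot(is.character(query), length(query) == 1L)
  if (nchar(query) < word_size) stop("query shorter than word_size")
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  qlen <- nchar(query)
  # gapped extension only refines seeds whose ungapped extension already
  # reaches min_score; cheap, and loses nothing for substitution-dominated
  # alignments because hit regions are seed-dense
  trigger <- as.integer(min_score)
  out <- list()
  for (contig in names(genome)) {
    gseq <- genome[[contig]]
    if (nchar(gseq) < word_size) next
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else revcomp(query)
      raw <- cpp_local_search(q, gseq, as.integer(word_size),
                              as.integer(match), as.integer(mismatch),
                              as.integer(gap_open), as.integer(gap_extend),
                              as.integer(min_score), as.integer(xdrop),
                              as.integer(band), as.integer(trigger))
      if (nrow(raw) == 0L) next
      qs <- raw$qstart; qe <- raw$qend
      if (strand == "-") { tmp <- qs; qs <- qlen - qe; qe <- qlen - tmp }
      out[[length(out) + 1L]] <- data.frame(
        seq_id = contig, start = raw$gstart, end = raw$gend, strand = strand,
        qstart = qs, qend = qe, score = raw$score,
        identity = raw$matches / pmax(raw$matches + raw$mismatches, 1L),
        aligned_length = raw$matches + raw$mismatches + raw$gapcols,
        matches = raw$matches, mismatches = raw$mismatches,
        gapcols = raw$gapcols, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) return(empty_hits())
  hits <- do.call(rbind, out)
  merge_hits(hits, merge_overlap)
}

# Keep the best-scoring hit among same-contig same-strand hits whose
# genomic spans overlap by >= min_frac of the shorter span.
merge_hits <- function(hits, min_frac = 0.5) {
  if (nrow(hits) <= 1L) return(hits)
  hits <- hits[order(-hits$score, hits$seq_id, hits$start), , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    if (any(keep)) {
      k <- which(keep & hits$seq_id == hits$seq_id[i] &
                   hits$strand == hits$strand[i])
      if (length(k) > 0L) {
        ov <- pmin(hits$end[k], hits$end[i]) - pmax(hits$start[k], hits$start[i])
        len <- pmin(hits$end[k] - hits$start[k], hits$end[i] - hits$start[i])
        if (any(ov > min_frac * len)) ok <- FALSE
      }
    }
    keep[i] <- ok
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter hits to full-length TE candidates
#'
#' Applies the candidate cutoff used throughout the pipeline: at least
#' `min_identity` identity and `min_coverage` of the query covered.
#'
#' @param hits data.frame from [local_search()].
#' @param min_identity identity floor (default 0.75).
#' @param min_coverage query coverage floor, `(qend - qstart) / query_length`
#'   (default 0.90).
#' @param query_length length of the query the hits were produced from.
#' @return the surviving rows of `hits`.
#' @export
filter_candidates <- function(hits, query_length, min_identity = 0.75,
                              min_coverage = 0.90) {
  if (nrow(hits) == 0L) return(hits)
  keep <- hits$identity >= min_identity &
    (hits$qend - hits$qstart) / query_length >= min_coverage
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop short hits
#'
#' Removes hits whose genomic span is under `min_len` bp (the standard
#' cleaning step before locus extraction; 100 bp keeps the boundary).
#'
#' @param hits data.frame with `start` and `end` columns.
#' @param min_len minimum genomic span in bp to keep.
#' @return the surviving rows.
#' @export
clean_short_hits <- function(hits, min_len = 100L) {
  if (nrow(hits) == 0L) return(hits)
  out <- hits[hits$end - hits$start >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise identity matrix
#'
#' Identity between every pair of sequences from the best local alignment
#' under the search scoring scheme: matches over aligned columns, gap
#' columns excluded from the denominator.  Pairs with no alignment above
#' the score floor get 0.
#'
#' @param seqs named character vector of >= 2 DNA sequences.
#' @param min_score score floor for the best local alignment.
#' @param ... further arguments to [local_search()].
#' @return symmetric numeric matrix with unit diagonal, dimnames from
#'   `names(seqs)`.
#' @export
pairwise_identity_matrix <- function(seqs, min_score = 30L, ...) {
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  m <- diag(1, n)
  dimnames(m) <- list(names(seqs), names(seqs))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      h <- local_search(seqs[[i]], seqs[j], min_score = min_score, ...)
      m[i, j] <- m[j, i] <- if (nrow(h) == 0L) 0 else h$identity[1L]
    }
  }
  m
}
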