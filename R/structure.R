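# Global alignment under the package-wide scoring (match +4, mismatch -5,
# linear gap -6; N scores 0 against anything).  Returns the two aligned
# strings (equal length, '-' gaps).
align_global <- function(a, b, gap = -6L, match = 4L, mismatch = -5L) {
  cpp_global_align(a, b, as.integer(match), as.integer(mismatch),
                   as.integer(gap), 0L)
}

count_tir_mismatches <- function(left, right_rc) {
  l <- strsplit(left, "", fixed = TRUE)[[1]]
  r <- strsplit(right_rc, "", fixed = TRUE)[[1]]
  sum(l != r | l == "N" | r == "N")
}

#' Detect terminal inverted repeats
#'
#' Finds the longest `L` in `[min_tir_len, max_tir_len]` such that the
#' first `L` bases of the copy match the reverse complement of its last `L`
#' bases with at most `floor(max_mismatch_frac * L)` mismatches.  `N`
#' positions always count as mismatches.
#'
#' @param copy_seq DNA character scalar (a TE copy, termini included).
#' @param min_tir_len,max_tir_len search bounds in bp; hAT TIRs are ~15 bp,
#'   so the default window 10-30 brackets the canonical value.
#' @param max_mismatch_frac tolerated mismatch fraction within the TIR.
#' @return list (`TIRReport`): found, length, mismatches, left_arm,
#'   right_arm.  When found, `right_arm` is the reverse complement of
#'   `left_arm` up to `mismatches` positions.
#' @export
find_tirs <- function(copy_seq, min_tir_len = 10L, max_tir_len = 30L,
                      max_mismatch_frac = 0.2) {
  n <- nchar(copy_seq)
  if (n <= 2L * min_tir_len)
    stop("sequence too short for TIR search: ", n, " bp")
  max_tir_len <- min(max_tir_len, floor(n / 2))
  for (L in seq(max_tir_len, min_tir_len)) {
    left <- substr0(copy_seq, 0L, L)
    right <- substr0(copy_seq, n - L, n)
    mm <- count_tir_mismatches(left, revcomp(right))
    if (mm <= floor(max_mismatch_frac * L)) {
      return(list(found = TRUE, length = L, mismatches = mm,
                  left_arm = left, right_arm = right))
    }
  }
  list(found = FALSE, length = 0L, mismatches = NA_integer_,
       left_arm = "", right_arm = "")
}

#' Detect a target site duplication
#'
#' Finds the longest `k` in `[tsd_min, tsd_max]` for which the last `k`
#' bases of the left flank equal the first `k` bases of the right flank
#' exactly (longest wins on ties; k-mers containing `N` are not accepted).
#' hAT TSDs are ~8 bp; exact matching is the conservative reading of the
#' hallmark.
#'
#' @param left_flank,right_flank flanking sequences immediately adjacent to
#'   the copy, each at least `tsd_max` bp.
#' @param tsd_min,tsd_max search bounds in bp.
#' @return list (`TSDReport`): found, length, left_site, right_site.
#' @export
find_tsd <- function(left_flank, right_flank, tsd_min = 4L, tsd_max = 12L) {
  nl <- nchar(left_flank); nr <- nchar(right_flank)
  if (nl < tsd_max || nr < tsd_max)
    stop("flanks must be at least tsd_max (", tsd_max, ") bp")
  for (k in seq(tsd_max, tsd_min)) {
    ls <- substr0(left_flank, nl - k, nl)
    rs <- substr0(right_flank, 0L, k)
    if (ls == rs && !grepl("N", ls, fixed = TRUE)) {
      return(list(found = TRUE, length = k, left_site = ls, right_site = rs))
    }
  }
  list(found = FALSE, length = 0L, left_site = "", right_site = "")
}

#' Classify a TE copy as full-length or fragment
#'
#' A copy is full-length when it retains both structural hallmarks (TIRs
#' and a TSD) and covers at least `min_coverage` of the family consensus in
#' a global alignment; everything else is a fragment.  Consensus coverage
#' is the fraction of consensus positions paired with a copy base in the
#' global alignment.
#'
#' @param copy_seq the copy sequence (termini included).
#' @param left_flank,right_flank genomic flanks adjacent to the copy.
#' @param consensus the family consensus sequence.
#' @param min_coverage consensus coverage required for full-length status.
#' @param tir_args,tsd_args argument lists for [find_tirs()] / [find_tsd()].
#' @return list (`CopyClassification`): status (`"full_length"` or
#'   `"fragment"`), consensus_coverage, tir, tsd.
#' @export
classify_copy <- function(copy_seq, left_flank, right_flank, consensus,
                          min_coverage = 0.90, tir_args = list(),
                          tsd_args = list()) {
  stopifnot(nchar(consensus) > 0L)
  aln <- align_global(copy_seq, consensus)
  ca <- strsplit(aln$a, "", fixed = TRUE)[[1]]
  ka <- strsplit(aln$b, "", fixed = TRUE)[[1]]
  # consensus positions actually paired with a copy base; a span-based
  # measure is unstable when equal-scoring gap placements exist
  coverage <- sum(ca != "-" & ka != "-") / nchar(consensus)
  tir <- tryCatch(do.call(find_tirs, c(list(copy_seq), tir_args)),
                  error = function(e) list(found = FALSE, length = 0L,
                                           mismatches = NA_integer_,
                                           left_arm = "", right_arm = ""))
  tsd <- tryCatch(do.call(find_tsd, c(list(left_flank, right_flank), tsd_args)),
                  error = function(e) list(found = FALSE, length = 0L,
                                           left_site = "", right_site = ""))
  status <- if (tir$found && tsd$found && coverage >= min_coverage)
    "full_length" else "fragment"
  list(status = status, consensus_coverage = coverage, tir = tir, tsd = tsd)
}

#' Longest open reading frame, in amino acids
#'
#' Scans all six frames (three per strand).  An ORF runs from the first
#' `ATG` of a stop-to-stop segment (or from the segment start when
#' `require_atg = FALSE`) to the codon before the stop; the count excludes
#' the stop codon.  Copies with at least 600 aa are conventionally flagged
#' as coding-capable hAT transposase candidates.
#'
#' @param seq DNA character scalar.
#' @param require_atg must the ORF start with ATG?
#' @return longest ORF length in residues (0 if none).
#' @export
longest_orf_aa <- function(seq, require_atg = TRUE) {
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (s in c(seq, revcomp(seq))) {
    n <- nchar(s)
    for (frame in 0:2) {
      ncod <- (n - frame) %/% 3L
      if (ncod < 1L) next
      starts <- frame + seq(0L, by = 3L, length.out = ncod)
      codons <- substring(s, starts + 1L, starts + 3L)
      bounds <- c(0L, which(codons %in% stops), ncod + 1L)
      for (i in seq_len(length(bounds) - 1L)) {
        lo <- bounds[i] + 1L; hi <- bounds[i + 1L] - 1L
        if (hi < lo) next
        if (require_atg) {
          atg <- which(codons[lo:hi] == "ATG")
          if (length(atg) == 0L) next
          lo <- lo + atg[1L] - 1L
        }
        best <- max(best, hi - lo + 1L)
      }
    }
  }
  best
}
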