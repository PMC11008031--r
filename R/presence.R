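#' Extract insertion loci with extended flanks
#'
#' For each TE interval, takes `pad` bp of genomic flank on each side
#' (clipped at contig edges, with the clip recorded).  These flank-extended
#' loci are the units of the orthologous presence/absence test.
#'
#' @param genome named character vector of contigs.
#' @param te_intervals data.frame with seq_id, start, end (0-based
#'   half-open), e.g. cleaned hits from [clean_short_hits()].
#' @param pad flank length in bp on each side (default 1500).
#' @return list of loci; each locus is a list with locus_id, seq_id,
#'   te_start, te_end, te_len, left_flank, right_flank, pad, clipped.
#' @export
extract_loci <- function(genome, te_intervals, pad = 1500L) {
  stopifnot(pad > 0)
  if (nrow(te_intervals) == 0L) return(list())
  loci <- vector("list", nrow(te_intervals))
  for (i in seq_len(nrow(te_intervals))) {
    sid <- te_intervals$seq_id[i]
    if (!sid %in% names(genome)) stop("interval on unknown contig: ", sid)
    contig <- genome[[sid]]
    n <- nchar(contig)
    s <- te_intervals$start[i]; e <- te_intervals$end[i]
    if (s < 0 || e > n || e <= s)
      stop("interval off contig ", sid, ": [", s, ",", e, ")")
    ls <- max(0L, s - pad); re <- min(n, e + pad)
    loci[[i]] <- list(
      locus_id = if ("name" %in% names(te_intervals)) te_intervals$name[i]
                 else paste0("locus", i),
      seq_id = sid, te_start = s, te_end = e, te_len = e - s,
      left_flank = substr0(contig, ls, s),
      right_flank = substr0(contig, e, re),
      pad = pad, clipped = (ls > s - pad) || (re < e + pad)
    )
  }
  loci
}

# Projected junction position of a flank hit in the target genome:
# extrapolates the unaligned query tail so truncated alignments still
# point at the insertion junction.
project_junction <- function(hit, flank_len, side) {
  if (side == "left") {
    tail <- flank_len - hit$qend  # unaligned bases between alignment and junction
    if (hit$strand == "+") hit$end + tail else hit$start - tail
  } else {
    head <- hit$qstart
    if (hit$strand == "+") hit$start - head else hit$end + head
  }
}

#' Classify an insertion locus in a second genome
#'
#' Searches both flanks of the locus in the target genome and decides,
#' from the geometry of the best co-linear flank pair, whether the target
#' shares the insertion (inter-flank gap comparable to the TE length),
#' carries an empty orthologous site (flanks directly adjacent, up to
#' `empty_gap_max` bp apart; small negative gaps arise from the target
#' site duplication and are allowed), or is unresolved.
#'
#' @param locus one locus from [extract_loci()].
#' @param target_genome named character vector of target contigs.
#' @param min_flank minimum usable flank length after clipping.
#' @param min_hit_len minimum flank hit length (the standard 100 bp
#'   cleaning rule).
#' @param min_identity minimum flank hit identity.
#' @param empty_gap_max maximum gap (bp) for an empty-site call.
#' @param gap_lo,gap_hi shared-site gap window as multiples of the TE
#'   length.
#' @param min_score score floor for the flank searches.
#' @param search_args extra arguments to [local_search()].
#' @return list (`LocusCall`): locus_id, status (`"shared"`,
#'   `"absent_empty_site"` or `"unresolved"`), reason, target_seq_id,
#'   strand, left/right hit coordinates, gap.
#' @export
classify_locus <- function(locus, target_genome, min_flank = 200L,
                           min_hit_len = 100L, min_identity = 0.75,
                           empty_gap_max = 50L, gap_lo = 0.5, gap_hi = 1.5,
                           min_score = 40L, search_args = list()) {
  res <- list(locus_id = locus$locus_id, status = "unresolved", reason = "",
              target_seq_id = NA_character_, strand = NA_character_,
              left_start = NA_integer_, left_end = NA_integer_,
              right_start = NA_integer_, right_end = NA_integer_,
              gap = NA_integer_)
  if (nchar(locus$left_flank) < min_flank || nchar(locus$right_flank) < min_flank) {
    res$reason <- "flank_too_short"
    return(res)
  }
  search_one <- function(flank) {
    h <- do.call(local_search,
                 c(list(flank, target_genome, min_score = min_score), search_args))
    h <- clean_short_hits(h, min_hit_len)
    h[h$identity >= min_identity, , drop = FALSE]
  }
  hl <- search_one(locus$left_flank)
  hr <- search_one(locus$right_flank)
  if (nrow(hl) == 0L || nrow(hr) == 0L) {
    res$reason <- if (nrow(hl) == 0L && nrow(hr) == 0L) "flanks_not_found"
                  else "one_flank_missing"
    return(res)
  }
  pl <- nchar(locus$left_flank); pr <- nchar(locus$right_flank)
  te_len <- locus$te_len
  best <- NULL
  for (i in seq_len(nrow(hl))) {
    for (j in seq_len(nrow(hr))) {
      if (hl$seq_id[i] != hr$seq_id[j] || hl$strand[i] != hr$strand[j]) next
      jl <- project_junction(hl[i, ], pl, "left")
      jr <- project_junction(hr[j, ], pr, "right")
      gap <- if (hl$strand[i] == "+") jr - jl else jl - jr
      if (gap < -100 || gap > 3 * te_len) next  # rearranged or unrelated loci
      # prefer junction-anchored hits: the junction is determined by the
      # flank portions adjacent to the TE, so pairs needing the least
      # extrapolation across unaligned flank bases are the trustworthy
      # ones (a hit interrupted by a target-specific insertion would
      # otherwise overshoot the junction); score breaks ties
      over <- (pl - hl$qend[i]) + hr$qstart[j]
      sc <- hl$score[i] + hr$score[j]
      if (is.null(best) || over < best$over ||
          (over == best$over && sc > best$sc)) {
        best <- list(i = i, j = j, gap = gap, sc = sc, over = over)
      }
    }
  }
  if (is.null(best)) {
    res$reason <- "no_colinear_flank_pair"
    return(res)
  }
  i <- best$i; j <- best$j
  res$target_seq_id <- hl$seq_id[i]
  res$strand <- hl$strand[i]
  res$left_start <- hl$start[i]; res$left_end <- hl$end[i]
  res$right_start <- hr$start[j]; res$right_end <- hr$end[j]
  res$gap <- as.integer(round(best$gap))
  if (best$gap >= gap_lo * te_len && best$gap <= gap_hi * te_len) {
    res$status <- "shared"
  } else if (best$gap <= empty_gap_max) {
    res$status <- "absent_empty_site"
  } else {
    res$reason <- "gap_ambiguous"
  }
  res
}

#' Count shared insertions between two species
#'
#' Classifies every locus of the source species against the target genome
#' and counts `"shared"` calls; an orthologous insertion present in both
#' species predates their split, while empty sites mark insertions younger
#' than the split (the signature of independent invasion).
#'
#' @param loci list from [extract_loci()] (source species).
#' @param target_genome named character vector (target species).
#' @param ... passed to [classify_locus()].
#' @return list with `count` (shared calls) and `table` (one row per locus:
#'   locus_id, status, reason, target_seq_id, strand, coordinates, gap).
#' @export
shared_insertion_count <- function(loci, target_genome, ...) {
  rows <- lapply(loci, function(lc) {
    as.data.frame(classify_locus(lc, target_genome, ...),
                  stringsAsFactors = FALSE)
  })
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(locus_id = character(0), status = character(0),
               reason = character(0), target_seq_id = character(0),
               strand = character(0), left_start = integer(0),
               left_end = integer(0), right_start = integer(0),
               right_end = integer(0), gap = integer(0),
               stringsAsFactors = FALSE)
  list(count = sum(tab$status == "shared"), table = tab)
}
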