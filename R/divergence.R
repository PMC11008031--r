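#' Kimura 2-parameter distance between two aligned sequences
#'
#' Columns with a gap (`-`) or `N` in either sequence are excluded from the
#' comparable sites.  With transition proportion `P` and transversion
#' proportion `Q` over the comparable sites, the distance is
#' `K = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`.  When the log argument is
#' non-positive the distance is saturated and flagged undefined.
#'
#' @param aligned_a,aligned_b equal-length aligned strings (or equal-length
#'   character vectors of single bases).
#' @return list (`K2PResult`): P, Q, K, sites, undefined flag.
#' @export
k2p_distance <- function(aligned_a, aligned_b) {
  a <- if (length(aligned_a) == 1L) strsplit(aligned_a, "", fixed = TRUE)[[1]] else aligned_a
  b <- if (length(aligned_b) == 1L) strsplit(aligned_b, "", fixed = TRUE)[[1]] else aligned_b
  if (length(a) != length(b)) stop("aligned sequences differ in length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  sites <- length(a)
  if (sites == 0L) stop("no comparable sites")
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / sites
  Q <- sum(diff & !transition) / sites
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    return(list(P = P, Q = Q, K = NA_real_, sites = sites, undefined = TRUE))
  }
  K <- -0.5 * log(arg1 * sqrt(arg2))
  list(P = P, Q = Q, K = K, sites = sites, undefined = FALSE)
}

# Project a copy onto consensus coordinates through a global alignment:
# returns a character vector of length nchar(consensus) holding the copy
# base aligned to each consensus position ('-' where the copy has none).
# Copy insertions relative to the consensus are dropped.
project_to_consensus <- function(copy_seq, consensus) {
  # gap -16: under-penalized gaps would launder mismatches into indel
  # pairs and bias K2P downward for old copies
  aln <- align_global(copy_seq, consensus, gap = -16L)
  ca <- strsplit(aln$a, "", fixed = TRUE)[[1]]
  ka <- strsplit(aln$b, "", fixed = TRUE)[[1]]
  keep <- ka != "-"
  out <- ca[keep]
  out
}

# Fraction of the sequence explained by a short-period tandem structure:
# max over periods p <= period_max of the autocorrelation identity
# mean(s[i] == s[i + p]).  Perfect period-p tandem repeats score ~1;
# random sequence ~0.25.
simple_repeat_frac <- function(seq, period_max = 6L) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(x)
  if (n < period_max + 2L) return(0)
  best <- 0
  for (p in seq_len(period_max)) {
    m <- mean(x[seq_len(n - p)] == x[seq_len(n - p) + p])
    if (m > best) best <- m
  }
  best
}

#' Build a bp-weighted divergence landscape
#'
#' The repeat-age distribution of a TE family: each copy is aligned to the
#' family consensus, its K2P divergence (as %) places it in a bin, and it
#' contributes its aligned bp to that bin.  Copies that look like short
#' simple repeats are excluded when `exclude_simple` (a copy is
#' simple-repeat-like when its period-\eqn{\le}{<=}6 autocorrelation identity is at
#' least `simple_frac`).  Copies with a saturated (undefined) K are routed
#' to the top bin rather than dropped, so total bp is conserved; their
#' count is reported.
#'
#' @param copies named character vector of copy sequences.
#' @param consensus family consensus.
#' @param bin_width bin width in % divergence.
#' @param max_div top of the binned range in %.
#' @param exclude_simple drop simple-repeat-like copies?
#' @param simple_frac,simple_period_max simple-repeat rule parameters.
#' @param family label stored on the result.
#' @return list (`DivergenceLandscape`): `bins` data.frame (bin_lo, bin_hi,
#'   bp), `per_copy` data.frame (copy, K, aligned_bp, undefined, simple),
#'   `n_undefined`, `n_excluded_simple`, `family`, `bin_width`.
#' @export
build_landscape <- function(copies, consensus, bin_width = 1, max_div = 60,
                            exclude_simple = TRUE, simple_frac = 0.8,
                            simple_period_max = 6L, family = "TE") {
  if (length(copies) > 0L && is.null(names(copies)))
    names(copies) <- paste0("copy", seq_along(copies))
  breaks <- seq(0, max_div, by = bin_width)
  bins <- data.frame(bin_lo = breaks, bin_hi = breaks + bin_width, bp = 0)
  per <- data.frame(copy = character(0), K = numeric(0),
                    aligned_bp = integer(0), undefined = logical(0),
                    simple = logical(0), stringsAsFactors = FALSE)
  for (nm in names(copies)) {
    s <- copies[[nm]]
    simple <- simple_repeat_frac(s, simple_period_max) >= simple_frac
    if (simple && exclude_simple) {
      per <- rbind(per, data.frame(copy = nm, K = NA_real_, aligned_bp = 0L,
                                   undefined = FALSE, simple = TRUE))
      next
    }
    proj <- project_to_consensus(s, consensus)
    aligned_bp <- sum(proj != "-")
    cons <- strsplit(consensus, "", fixed = TRUE)[[1]]
    k2p <- k2p_distance(proj, cons)
    if (k2p$undefined) {
      bin_idx <- nrow(bins)
      Kpct <- NA_real_
    } else {
      Kpct <- 100 * k2p$K
      bin_idx <- min(nrow(bins), findInterval(Kpct, breaks))
      bin_idx <- max(bin_idx, 1L)
    }
    bins$bp[bin_idx] <- bins$bp[bin_idx] + aligned_bp
    per <- rbind(per, data.frame(copy = nm, K = Kpct, aligned_bp = aligned_bp,
                                 undefined = k2p$undefined, simple = simple))
  }
  list(bins = bins, per_copy = per,
       n_undefined = sum(per$undefined),
       n_excluded_simple = sum(per$simple & exclude_simple),
       family = family, bin_width = bin_width)
}

#' Detect peaks in a divergence landscape
#'
#' Local maxima of the binned bp series with topographic prominence at
#' least `min_prominence_bp`, reported in bin order.  Peaks mark bursts of
#' TE activity; a young peak below 1% divergence is the signature of a
#' recent invasion.
#'
#' @param landscape result of [build_landscape()].
#' @param min_prominence_bp minimum prominence in aligned bp.
#' @return data.frame: bin_lo, bin_hi, bp, prominence.
#' @export
detect_peaks <- function(landscape, min_prominence_bp = 1) {
  y <- landscape$bins$bp
  n <- length(y)
  if (n == 0L || all(y == 0)) {
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      bp = numeric(0), prominence = numeric(0)))
  }
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    if (y[i] <= 0) next
    left <- if (i == 1L) -Inf else y[i - 1L]
    right <- if (i == n) -Inf else y[i + 1L]
    if (y[i] > left && y[i] >= right) {
      # skip plateau repeats: only the first bin of a flat top counts
      if (i > 1L && y[i] == y[i - 1L]) next
      is_peak[i] <- TRUE
    }
  }
  idx <- which(is_peak)
  # topographic prominence: height above the higher of the two key saddles
  # (lowest point on the way to strictly higher terrain on each side); a
  # side with no higher terrain does not constrain the peak
  saddle <- function(i, step) {
    j <- i + step
    lo <- Inf
    while (j >= 1L && j <= n) {
      if (y[j] > y[i]) return(if (is.infinite(lo)) y[i] else lo)
      lo <- min(lo, y[j])
      j <- j + step
    }
    -Inf
  }
  prom <- vapply(idx, function(i) {
    s <- max(saddle(i, -1L), saddle(i, 1L))
    if (is.infinite(s)) y[i] else y[i] - s
  }, numeric(1))
  keep <- prom >= min_prominence_bp
  data.frame(bin_lo = landscape$bins$bin_lo[idx[keep]],
             bin_hi = landscape$bins$bin_hi[idx[keep]],
             bp = y[idx[keep]], prominence = prom[keep])
}
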