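#' K2P distance matrix from representative sequences
#'
#' Pairwise global alignments under the package scoring, then
#' [k2p_distance()] on each aligned pair.  Saturated (undefined) distances
#' are recorded as the maximum defined distance in the matrix and flagged.
#'
#' @param seqs named character vector of >= 3 alignable DNA sequences.
#' @return symmetric numeric matrix (zero diagonal) with attribute
#'   `undefined`: logical matrix marking saturated entries.
#' @export
te_distance_matrix <- function(seqs) {
  n <- length(seqs)
  if (n < 3L) stop("need at least 3 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  undef <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      aln <- align_global(seqs[[i]], seqs[[j]], gap = -16L)
      k <- k2p_distance(aln$a, aln$b)
      if (k$undefined) {
        undef[i, j] <- undef[j, i] <- TRUE
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- k$K
      }
    }
  }
  if (any(undef)) {
    mx <- suppressWarnings(max(d, na.rm = TRUE))
    if (!is.finite(mx)) mx <- 1
    d[is.na(d)] <- mx
  }
  attr(d, "undefined") <- undef
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining (via \pkg{ape}), deterministic for a given
#' matrix.  Distance trees are sufficient here because the downstream
#' discordance test uses topology only.
#'
#' @param d symmetric distance matrix with >= 3 labelled rows.
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 labels")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix must be symmetric")
  ape::nj(stats::as.dist(d))
}

#' Robinson-Foulds discordance between two trees
#'
#' Both trees are pruned to their shared leaf set and compared unrooted.
#' RF is the count of bipartitions present in exactly one tree, normalized
#' by `2 * (n - 3)` (the maximum for two unrooted binary trees on n
#' leaves).  Any RF above zero marks discordance.
#'
#' @param tree_a,tree_b `phylo` objects (e.g. TE tree and species tree).
#' @return list (`DiscordanceReport`): rf, rf_normalized, shared_leaves,
#'   discordant.
#' @export
rf_distance <- function(tree_a, tree_b) {
  shared <- intersect(tree_a$tip.label, tree_b$tip.label)
  if (length(shared) < 4L)
    stop("discordance undefined: fewer than 4 shared leaves")
  a <- ape::unroot(ape::keep.tip(tree_a, shared))
  b <- ape::unroot(ape::keep.tip(tree_b, shared))
  rf <- as.integer(phangorn::RF.dist(a, b, normalize = FALSE))
  max_rf <- 2L * (length(shared) - 3L)
  list(rf = rf,
       rf_normalized = if (max_rf > 0) rf / max_rf else 0,
       shared_leaves = length(shared),
       discordant = rf > 0)
}
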