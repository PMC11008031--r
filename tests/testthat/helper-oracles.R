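# Independent oracles, deliberately written as plain brute-force R so they
# share no code with the package implementations they check.

# Full Smith-Waterman score (affine gaps: a gap of length L costs
# open + L * ext), O(nm) over the whole DP matrix.
sw_oracle_score <- function(a, b, match = 4, mismatch = -5,
                            open = -8, ext = -2) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (x[i] == y[j] && x[i] %in% c("A", "C", "G", "T")) match else mismatch
      E[i + 1, j + 1] <- max(H[i + 1, j] + open + ext, E[i + 1, j] + ext)
      F[i + 1, j + 1] <- max(H[i, j + 1] + open + ext, F[i, j + 1] + ext)
      h <- max(0, H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
      H[i + 1, j + 1] <- h
      if (h > best) best <- h
    }
  }
  best
}

# Exhaustive 6-frame ORF scan: longest run of codons from ATG (or frame
# start) to just before a stop, scanning every frame of both strands.
orf_oracle <- function(seq, require_atg = TRUE) {
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  best <- 0
  for (s in c(seq, rc(seq))) {
    for (f in 0:2) {
      i <- f + 1
      run_start <- NA
      count <- 0
      while (i + 2 <= nchar(s)) {
        cod <- substr(s, i, i + 2)
        if (cod %in% stops) {
          run_start <- NA; count <- 0
        } else {
          if (is.na(run_start)) {
            if (!require_atg || cod == "ATG") { run_start <- i; count <- 1 }
          } else count <- count + 1
          if (!is.na(run_start)) best <- max(best, count)
        }
        i <- i + 3
      }
    }
  }
  best
}

# Brute-force TIR scan: try every arm length, count mismatches position by
# position against the reverse complement.
tir_oracle <- function(seq, min_len, max_len, max_frac) {
  rc <- function(s) paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
                          collapse = "")
  n <- nchar(seq)
  for (L in seq(min(max_len, floor(n / 2)), min_len)) {
    left <- strsplit(substr(seq, 1, L), "")[[1]]
    right <- strsplit(rc(substr(seq, n - L + 1, n)), "")[[1]]
    mm <- sum(left != right | left == "N" | right == "N")
    if (mm <= floor(max_frac * L)) return(list(found = TRUE, length = L, mm = mm))
  }
  list(found = FALSE, length = 0, mm = NA)
}

# Random DNA helper for fixtures built in code.
rand_dna <- function(n, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Two-species scenario used by several presence/absence tests: n_anc
# orthologous insertions above the root plus n_ind recent independent
# insertions in each species, no fragmentation.
two_species_scenario <- function(seed, n_anc = 10, n_ind = 10,
                                 split = 0.05, genome_length = 50000) {
  tree <- read_newick(text = sprintf("(A:%f,B:%f);", split, split))
  ev <- list(insertion_event("vertical", clade = c("A", "B"),
                             time = 2 * split, copies = n_anc))
  if (n_ind > 0) {
    ev <- c(ev,
            list(insertion_event("horizontal", species = "A", time = 0.005,
                                 copies = n_ind),
                 insertion_event("horizontal", species = "B", time = 0.005,
                                 copies = n_ind)))
  }
  sim_config(tree, events = ev, genome_length = genome_length,
             fragment_prob = 0, seed = seed)
}
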