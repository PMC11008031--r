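test_that("verbatim and reverse-complement plants are found exactly", {
  g <- rand_dna(4000, seed = 1)
  q <- rand_dna(150, seed = 2)
  ins <- insert_te(g, q, 2000, 8)
  h <- local_search(q, c(chr1 = ins$genome), min_score = 50)
  expect_gte(nrow(h), 1L)
  expect_identical(h$identity[1], 1)
  expect_identical(h$qstart[1], 0L)
  expect_identical(h$qend[1], 150L)
  expect_identical(h$start[1], unname(as.integer(ins$interval["start"])))
  expect_identical(h$end[1], unname(as.integer(ins$interval["end"])))
  expect_identical(h$strand[1], "+")

  ins2 <- insert_te(g, revcomp(q), 2500, 8)
  h2 <- local_search(q, c(chr1 = ins2$genome), min_score = 50)
  expect_identical(h2$strand[1], "-")
  expect_identical(h2$identity[1], 1)
  expect_identical(h2$qstart[1], 0L)
  expect_identical(h2$qend[1], 150L)

  expect_error(local_search("ACGT", c(chr1 = g), word_size = 7), "word_size")
})

test_that("top hit scores equal the exhaustive Smith-Waterman oracle", {
  for (s in 1:5) {
    g <- rand_dna(300, seed = 400 + s)
    q <- rand_dna(100, seed = 500 + s)
    planted <- evolve_seq(q, 0.1, seed = 600 + s)
    gen <- paste0(substr(g, 1, 150), planted, substr(g, 151, 300))
    h <- local_search(q, c(chr1 = gen), min_score = 30)
    expect_identical(h$score[1], as.integer(sw_oracle_score(q, gen)))
  }
})

test_that("strand invariance: searching the reverse-complemented genome mirrors hits", {
  g <- rand_dna(3000, seed = 9)
  q <- rand_dna(120, seed = 10)
  gen <- paste0(substr(g, 1, 1000), evolve_seq(q, 0.05, seed = 11),
                substr(g, 1001, 3000))
  fwd <- local_search(q, c(chr1 = gen), min_score = 50)
  rev <- local_search(q, c(chr1 = revcomp(gen)), min_score = 50)
  expect_identical(nrow(fwd), nrow(rev))
  expect_identical(sort(fwd$score), sort(rev$score))
  expect_identical(sort(fwd$identity), sort(rev$identity))
  top_f <- fwd[1, ]; top_r <- rev[rev$score == top_f$score, ][1, ]
  expect_false(top_f$strand == top_r$strand)
  expect_identical(nchar(gen) - top_f$end, top_r$start)
})

test_that("candidate filtering applies the 75% / 90% thresholds at their edges", {
  mk <- function(identity, qlen) {
    data.frame(seq_id = "c", start = 0L, end = 1000L, strand = "+",
               qstart = 0L, qend = as.integer(qlen), score = 100L,
               identity = identity, aligned_length = qlen,
               matches = 0L, mismatches = 0L, gapcols = 0L)
  }
  hits <- rbind(mk(0.74, 950), mk(0.75, 950), mk(0.80, 950), mk(0.80, 899),
                mk(0.80, 900), mk(1.00, 100))
  kept <- filter_candidates(hits, query_length = 1000)
  expect_identical(nrow(kept), 3L)
  expect_true(all(kept$identity >= 0.75))
  expect_true(all((kept$qend - kept$qstart) / 1000 >= 0.90))

  # monotonicity: tightening thresholds never gains hits
  set.seed(12)
  rnd <- do.call(rbind, lapply(1:50, function(i)
    mk(runif(1, 0.5, 1), sample(200:1000, 1))))
  n_prev <- Inf
  for (mi in c(0.5, 0.7, 0.9)) {
    n <- nrow(filter_candidates(rnd, 1000, min_identity = mi))
    expect_lte(n, n_prev); n_prev <- n
  }
  n_prev <- Inf
  for (mc in c(0.3, 0.6, 0.95)) {
    n <- nrow(filter_candidates(rnd, 1000, min_coverage = mc))
    expect_lte(n, n_prev); n_prev <- n
  }
})

test_that("short-hit cleaning keeps the 100 bp boundary", {
  mk <- function(len) data.frame(seq_id = "c", start = 1000L,
                                 end = 1000L + as.integer(len))
  hits <- do.call(rbind, lapply(c(20, 99, 100, 101, 500), mk))
  kept <- clean_short_hits(hits, 100)
  expect_identical(nrow(kept), 3L)
  expect_true(all(kept$end - kept$start >= 100))
  expect_identical(nrow(clean_short_hits(hits[0, ], 100)), 0L)
})

test_that("pairwise identity matrix is symmetric, unit-diagonal, and calibrated", {
  base <- rand_dna(2000, seed = 30)
  seqs <- c(a = base, b = base, c = evolve_seq(base, 0.05, seed = 31))
  m <- pairwise_identity_matrix(seqs)
  expect_identical(diag(m), c(a = 1, b = 1, c = 1))
  expect_identical(m, t(m))
  expect_identical(m["a", "b"], 1)
  # K2P at distance 0.05 (kappa 2) changes 4.82% of sites; the local
  # alignment trims a few terminal mismatches, nudging identity up slightly
  se <- sqrt(0.048 * 0.952 / 2000)
  expect_lt(abs(m["a", "c"] - 0.9518), 4 * se + 0.005)
  expect_error(pairwise_identity_matrix(seqs[1]), "at least 2")
})
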