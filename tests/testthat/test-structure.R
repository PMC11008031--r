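test_that("find_tirs recovers planted TIRs and matches a brute-force scan", {
  te <- make_te_consensus(400, tir_length = 15, seed = 11)
  rep <- find_tirs(te)
  expect_true(rep$found)
  expect_gte(rep$length, 15L)
  # the planted 15-mer arms must be mismatch-free
  expect_identical(count_mm <- sum(strsplit(substr(te, 1, 15), "")[[1]] !=
                                     strsplit(revcomp(substr(te, 386, 400)), "")[[1]]), 0L)

  # agreement with the independent oracle on random and planted sequences
  for (s in 1:30) {
    x <- if (s %% 2 == 0) rand_dna(300, seed = s)
         else make_te_consensus(300, tir_length = 15, seed = s)
    got <- find_tirs(x, 10, 30, 0.2)
    ora <- tir_oracle(x, 10, 30, 0.2)
    expect_identical(got$found, ora$found)
    expect_identical(got$length, as.integer(ora$length))
  }

  # random sequence with zero tolerance: no TIR call
  for (s in 1:20) {
    x <- rand_dna(1000, seed = 1000 + s)
    expect_false(find_tirs(x, 10, 30, 0)$found)
  }

  # perfect palindromic termini found at the maximum length
  core <- rand_dna(100, seed = 3)
  arm <- rand_dna(30, seed = 4)
  pal <- paste0(arm, core, revcomp(arm))
  expect_identical(find_tirs(pal, 10, 30, 0)$length, 30L)

  expect_error(find_tirs("ACGTACGT", 10, 30, 0.2), "too short")
})

test_that("find_tirs is strand-symmetric", {
  for (s in 1:10) {
    x <- make_te_consensus(250, tir_length = 12, seed = 40 + s)
    a <- find_tirs(x); b <- find_tirs(revcomp(x))
    expect_identical(a$found, b$found)
    expect_identical(a$length, b$length)
    expect_identical(a$mismatches, b$mismatches)
  }
})

test_that("find_tsd returns the longest exact duplication and errors on short flanks", {
  # flanks from a simulated insertion carry the planted 8 bp TSD
  g <- rand_dna(400, seed = 8)
  ins <- insert_te(g, make_te_consensus(100, 10, seed = 9), 200, tsd_length = 8)
  s <- ins$interval["start"]; e <- ins$interval["end"]
  left <- substr(ins$genome, s - 19, s)
  right <- substr(ins$genome, e + 1, e + 20)
  rep <- find_tsd(left, right)
  expect_true(rep$found)
  expect_identical(rep$length, 8L)
  expect_identical(rep$left_site, rep$right_site)

  expect_false(find_tsd(paste0(rand_dna(16, seed = 1), "AAAA"),
                        paste0("CCCC", rand_dna(16, seed = 2)))$found)

  # longest wins: a 10-mer duplication beats its embedded 8-mer
  dup <- "GATTACAGAT"
  expect_identical(find_tsd(paste0("CCCCCC", dup), paste0(dup, "GGGGGG"),
                            tsd_min = 4, tsd_max = 12)$length, 10L)

  expect_error(find_tsd("ACGT", "ACGTACGTACGTACGT"), "tsd_max")
})

test_that("find_tsd is symmetric under insertion orientation flip", {
  for (s in 1:10) {
    g <- rand_dna(300, seed = 70 + s)
    ins <- insert_te(g, rand_dna(60, seed = 90 + s), 150, tsd_length = 8)
    st <- ins$interval["start"]; e <- ins$interval["end"]
    left <- substr(ins$genome, st - 15, st)
    right <- substr(ins$genome, e + 1, e + 16)
    a <- find_tsd(left, right)
    b <- find_tsd(revcomp(right), revcomp(left))
    expect_identical(a$found, b$found)
    expect_identical(a$length, b$length)
  }
})

test_that("classify_copy requires both hallmarks plus 90% consensus coverage", {
  cons <- make_te_consensus(600, 15, seed = 14)
  g <- rand_dna(2000, seed = 15)
  ins <- insert_te(g, cons, 1000, tsd_length = 8)
  s <- ins$interval["start"]; e <- ins$interval["end"]
  copy <- substr(ins$genome, s + 1, e)
  left <- substr(ins$genome, s - 19, s)
  right <- substr(ins$genome, e + 1, e + 20)

  intact <- classify_copy(copy, left, right, cons)
  expect_identical(intact$status, "full_length")
  expect_gte(intact$consensus_coverage, 0.99)

  # mild divergence on the copy only: still full-length
  div <- classify_copy(evolve_seq(copy, 0.02, seed = 1), left, right, cons)
  expect_identical(div$status, "full_length")

  # 50% truncation: coverage collapses
  half <- classify_copy(substr(copy, 1, 300), left, right, cons)
  expect_identical(half$status, "fragment")
  expect_lt(half$consensus_coverage, 0.9)

  # hallmark loss alone demotes an intact copy
  shuffled <- classify_copy(copy, rand_dna(20, seed = 77),
                            rand_dna(20, seed = 78), cons)
  expect_identical(shuffled$status, "fragment")
  expect_gte(shuffled$consensus_coverage, 0.99)
})

test_that("TSD recovery is complete on intact young copies, absent on fragments", {
  # 40 insertions, copy (not flank) divergence up to 0.05
  cons <- make_te_consensus(300, 15, seed = 20)
  found <- 0L
  for (i in 1:40) {
    g <- rand_dna(600, seed = 200 + i)
    ins <- insert_te(g, evolve_seq(cons, 0.05 * (i %% 2), seed = i), 300, 8)
    s <- ins$interval["start"]; e <- ins$interval["end"]
    rep <- find_tsd(substr(ins$genome, s - 15, s),
                    substr(ins$genome, e + 1, e + 16))
    if (rep$found && rep$length == 8L) found <- found + 1L
  }
  expect_identical(found, 40L)
})

test_that("longest_orf_aa matches the exhaustive 6-frame oracle", {
  expect_identical(longest_orf_aa("ATGAAATAA"), 2L)
  for (s in 1:20) {
    x <- rand_dna(500, seed = 300 + s)
    expect_identical(longest_orf_aa(x), as.integer(orf_oracle(x)))
    expect_identical(longest_orf_aa(x, require_atg = FALSE),
                     as.integer(orf_oracle(x, require_atg = FALSE)))
  }
  # planted 1830 bp ORF: ATG + 609 non-stop codons + stop
  set.seed(6)
  codons <- c("ATG", sample(c("GCT", "GAA", "TGC", "AAA", "CGT"), 609,
                            replace = TRUE), "TAA")
  te <- paste0(rand_dna(50, seed = 31), paste(codons, collapse = ""),
               rand_dna(50, seed = 32))
  expect_gte(longest_orf_aa(te), 600L)
})
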