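test_that("locus extraction pads by 1500 bp and clips at contig edges", {
  g <- c(chr1 = rand_dna(20000, seed = 120))
  iv <- data.frame(seq_id = "chr1", start = 5000L, end = 7000L)
  loci <- extract_loci(g, iv, pad = 1500)
  expect_length(loci, 1L)
  lc <- loci[[1]]
  expect_identical(nchar(lc$left_flank), 1500L)
  expect_identical(nchar(lc$right_flank), 1500L)
  expect_identical(lc$left_flank, substr(g[[1]], 3501, 5000))
  expect_identical(lc$right_flank, substr(g[[1]], 7001, 8500))
  expect_false(lc$clipped)

  near_edge <- extract_loci(g, data.frame(seq_id = "chr1", start = 200L,
                                          end = 700L), pad = 1500)[[1]]
  expect_identical(nchar(near_edge$left_flank), 200L)
  expect_true(near_edge$clipped)

  expect_identical(extract_loci(g, iv[0, ]), list())
  expect_error(extract_loci(g, data.frame(seq_id = "chr1", start = 19000L,
                                          end = 21000L)), "off contig")
  expect_error(extract_loci(g, data.frame(seq_id = "chrX", start = 1L,
                                          end = 10L)), "unknown contig")
})

test_that("self-comparison calls every locus shared; foreign flanks stay unresolved", {
  cfg <- two_species_scenario(seed = 130, n_anc = 4, n_ind = 0,
                              genome_length = 20000)
  sim <- simulate_scenario(cfg)
  gA <- sim$genomes[["A"]]
  cp <- sim$copies[sim$copies$species == "A", ]
  loci <- extract_loci(gA, data.frame(seq_id = "chr1", start = cp$start,
                                      end = cp$end), pad = 1500)
  self <- shared_insertion_count(loci, gA)
  expect_identical(self$count, nrow(cp))
  expect_true(all(self$table$status == "shared"))

  alien <- c(chr1 = rand_dna(20000, seed = 131))
  none <- shared_insertion_count(loci, alien)
  expect_identical(none$count, 0L)
  expect_true(all(none$table$status == "unresolved"))
})

test_that("an insertion present in one species shows an empty site in the other", {
  # same background genome; TE inserted into A only
  bg <- rand_dna(20000, seed = 140)
  te <- make_te_consensus(2000, 15, seed = 141)
  ins <- insert_te(bg, te, 10000, 8)
  gA <- c(chr1 = ins$genome)
  gB <- c(chr1 = evolve_seq(bg, 0.05, seed = 142))  # diverged sister, no TE
  loci <- extract_loci(gA, data.frame(seq_id = "chr1",
                                      start = ins$interval["start"],
                                      end = ins$interval["end"]), pad = 1500)
  call <- classify_locus(loci[[1]], gB)
  expect_identical(call$status, "absent_empty_site")
  # the empty-site gap is tiny (TSD-sized overlap allowed), never TE-sized
  expect_lte(call$gap, 50L)
  expect_gte(call$gap, -100L)

  # and the same locus against a TE-bearing genome is shared with a TE-sized gap
  call2 <- classify_locus(loci[[1]], gA)
  expect_identical(call2$status, "shared")
  expect_gte(call2$gap, 0.5 * 2000)
  expect_lte(call2$gap, 1.5 * 2000)
})

test_that("widening the empty-gap tolerance never loses empty-site calls", {
  bg <- rand_dna(15000, seed = 150)
  te <- make_te_consensus(1500, 15, seed = 151)
  ins <- insert_te(bg, te, 7000, 8)
  gA <- c(chr1 = ins$genome)
  gB <- c(chr1 = bg)
  loci <- extract_loci(gA, data.frame(seq_id = "chr1",
                                      start = ins$interval["start"],
                                      end = ins$interval["end"]), pad = 1500)
  n_prev <- -1L
  for (egm in c(0, 10, 50, 200)) {
    n <- sum(vapply(loci, function(lc)
      classify_locus(lc, gB, empty_gap_max = egm)$status == "absent_empty_site",
      logical(1)))
    expect_gte(n, n_prev); n_prev <- n
  }
})

test_that("shared counts are symmetric between species on unfragmented loci", {
  cfg <- two_species_scenario(seed = 160, n_anc = 5, n_ind = 3,
                              genome_length = 30000)
  sim <- simulate_scenario(cfg)
  mkloci <- function(sp) {
    cp <- sim$copies[sim$copies$species == sp, ]
    extract_loci(sim$genomes[[sp]],
                 data.frame(seq_id = "chr1", start = cp$start, end = cp$end))
  }
  ab <- shared_insertion_count(mkloci("A"), sim$genomes[["B"]])
  ba <- shared_insertion_count(mkloci("B"), sim$genomes[["A"]])
  expect_lte(abs(ab$count - ba$count), 1L)
  expect_identical(ab$count, 5L)
})
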