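test_that("consensus termini are reverse-complement TIRs and generation is seeded", {
  te <- make_te_consensus(300, tir_length = 15, seed = 5)
  expect_identical(nchar(te), 300L)
  expect_identical(substr(te, 286, 300), revcomp(substr(te, 1, 15)))
  expect_identical(te, make_te_consensus(300, tir_length = 15, seed = 5))
  expect_false(te == make_te_consensus(300, tir_length = 15, seed = 6))
  # no terminal constraint when tir_length = 0 (just a valid random element)
  expect_identical(nchar(make_te_consensus(100, tir_length = 0, seed = 1)), 100L)
  expect_error(make_te_consensus(30, tir_length = 15), "exceed")
})

test_that("insert_te duplicates the target k-mer around the element", {
  g <- "AAAATTTTGGGG"
  ins <- insert_te(g, "CCCCC", 4, tsd_length = 2)
  expect_identical(nchar(ins$genome), nchar(g) + 5L + 2L)
  expect_identical(ins$tsd, "TT")
  s <- ins$interval["start"]; e <- ins$interval["end"]
  expect_identical(substr(ins$genome, s + 1, e), "CCCCC")
  expect_identical(substr(ins$genome, s - 1, s), "TT")   # left TSD
  expect_identical(substr(ins$genome, e + 1, e + 2), "TT")  # right TSD

  # tsd_length = 0: plain insertion, growth = |TE|
  ins0 <- insert_te(g, "CCCCC", 4, tsd_length = 0)
  expect_identical(nchar(ins0$genome), nchar(g) + 5L)

  # default-length 8 bp TSD: identical 8-mers flank the element
  g2 <- rand_dna(200, seed = 2)
  ins8 <- insert_te(g2, "GATTACA", 100, tsd_length = 8)
  s <- ins8$interval["start"]; e <- ins8$interval["end"]
  expect_identical(substr(ins8$genome, s - 7, s), substr(ins8$genome, e + 1, e + 8))

  expect_error(insert_te(g, "CC", 20, 8), "out of range")
})

test_that("evolve_seq is the generative twin of the K2P estimator", {
  s <- rand_dna(10000, seed = 3)
  expect_identical(evolve_seq(s, 0), s)
  expect_error(evolve_seq(s, -0.1), ">= 0")
  expect_identical(evolve_seq(s, 0.1, seed = 9), evolve_seq(s, 0.1, seed = 9))

  # moderate-replicate recovery check (the acceptance suite runs the full one)
  for (d in c(0.05, 0.2)) {
    ks <- vapply(1:30, function(i) {
      k2p_distance(s, evolve_seq(s, d, kappa = 2, seed = 100 + i))$K
    }, numeric(1))
    se <- sd(ks) / sqrt(length(ks))
    expect_lt(abs(mean(ks) - d), 3 * se)
  }

  # kappa -> large: transversions vanish
  set.seed(4)
  e <- evolve_seq(s, 0.2, kappa = 1000)
  k <- k2p_distance(s, e)
  expect_lt(k$Q * k$sites, 10)
  expect_gt(k$P * k$sites, 1000)
})

test_that("scenario simulation conserves length, is deterministic, and tracks orthology", {
  cfg <- vertical_scenario(seed = 7, genome_length = 20000, copies = 4,
                           fragment_prob = 0)
  sim <- simulate_scenario(cfg)
  # conservation: genome length = background + sum(te + tsd)
  for (sp in names(sim$genomes)) {
    cp <- sim$copies[sim$copies$species == sp, ]
    expect_identical(nchar(sim$genomes[[sp]][[1]]),
                     20000L + sum(cp$te_len + cp$tsd_len))
  }
  # determinism
  sim2 <- simulate_scenario(cfg)
  expect_identical(sim$genomes, sim2$genomes)
  expect_identical(sim$copies, sim2$copies)

  # vertical-only: orthologous copies at identical coordinates in every species
  byspecies <- split(sim$copies[, c("instance", "start", "end", "strand")],
                     sim$copies$species)
  for (sp in names(byspecies)[-1]) {
    a <- byspecies[[1]][order(byspecies[[1]]$instance), ]
    b <- byspecies[[sp]][order(byspecies[[sp]]$instance), ]
    expect_equal(a, b, ignore_attr = TRUE)
  }
  # true shared counts equal the burst size for every pair
  expect_true(all(sim$shared$n_shared == 4L))

  # events must resolve to branches
  tr <- cfg$species_tree
  expect_error(simulate_scenario(sim_config(tr, events = list(
    insertion_event("horizontal", species = "ZZ", time = 0.01)
  ), seed = 1)), "unknown recipient")
  expect_error(simulate_scenario(sim_config(tr, events = list(
    insertion_event("horizontal", species = "A", time = 0.09)
  ), seed = 1)), "does not fall on the branch")
  expect_error(simulate_scenario(sim_config(tr, events = list(
    insertion_event("vertical", clade = c("A", "C"), time = 0.05)
  ), seed = 1)), "not a clade")
})

test_that("horizontal transfer copies diverge by twice the event time, not host depth", {
  tree <- read_newick(text = "(A:0.10,B:0.10);")
  cfg <- sim_config(tree, events = list(
    insertion_event("horizontal", species = "A", time = 0.01, copies = 2),
    insertion_event("horizontal", species = "B", time = 0.01, copies = 2)
  ), genome_length = 20000, fragment_prob = 0, seed = 21)
  sim <- simulate_scenario(cfg)
  getcopy <- function(sp, i) {
    cp <- sim$copies[sim$copies$species == sp, ][i, ]
    s <- substr(sim$genomes[[sp]][[1]], cp$start + 1, cp$end)
    if (cp$strand == "-") revcomp(s) else s
  }
  k <- k2p_distance(getcopy("A", 1), getcopy("B", 1))  # same length: no indels
  # cross-species TE divergence ~ 2 * event_time despite 0.2 of host divergence
  se <- sqrt(0.02 / k$sites)
  expect_lt(abs(k$K - 0.02), 4 * se + 0.002)
  expect_true(all(sim$shared$n_shared == 0L))
})

test_that("full fragmentation leaves no copy classifiable as full-length", {
  tree <- read_newick(text = "(A:0.01,B:0.01);")
  cfg <- sim_config(tree, events = list(
    insertion_event("vertical", clade = c("A", "B"), time = 0.02, copies = 6)
  ), genome_length = 20000, fragment_prob = 1, seed = 13)
  sim <- simulate_scenario(cfg)
  expect_true(all(sim$copies$fragment))
  cp <- sim$copies[sim$copies$species == "A", ]
  g <- sim$genomes[["A"]][[1]]
  for (i in seq_len(nrow(cp))) {
    s <- substr(g, cp$start[i] + 1, cp$end[i])
    if (cp$strand[i] == "-") s <- revcomp(s)
    cls <- classify_copy(s,
                         left_flank = substr(g, cp$start[i] - 19, cp$start[i]),
                         right_flank = substr(g, cp$end[i] + 1, cp$end[i] + 20),
                         consensus = sim$consensus)
    expect_identical(cls$status, "fragment")
  }
})
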