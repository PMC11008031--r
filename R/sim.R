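#' Build a hAT-like TE consensus sequence
#'
#' The element carries the canonical hAT architecture: the last `tir_length`
#' bases are the reverse complement of the first `tir_length` bases
#' (terminal inverted repeats), with a random interior at the stated GC.
#'
#' @param te_length total element length in bp.
#' @param tir_length terminal inverted repeat length in bp (~15 for hATs;
#'   0 disables the terminal constraint).
#' @param gc_content GC fraction of the generated sequence.
#' @param seed optional integer seed; the same seed reproduces the same
#'   sequence.
#' @return DNA character scalar of length `te_length`.
#' @export
make_te_consensus <- function(te_length, tir_length = 15L, gc_content = 0.5,
                              seed = NULL) {
  te_length <- as.integer(te_length); tir_length <- as.integer(tir_length)
  if (tir_length < 0) stop("tir_length must be >= 0")
  if (te_length <= 2L * tir_length)
    stop("te_length must exceed 2 * tir_length")
  with_seed(seed, {
    head <- random_dna(te_length - tir_length, gc_content)
    if (tir_length == 0L) return(head)
    paste0(head, revcomp(substr0(head, 0L, tir_length)))
  })
}

#' Insert a TE into a genome sequence with a target site duplication
#'
#' The `tsd_length` bases starting at `position` are duplicated so the
#' inserted element ends up flanked by two identical copies of the target
#' k-mer, as a cut-and-paste transposase leaves them.  The genome grows by
#' `nchar(te_seq) + tsd_length`.
#'
#' @param genome DNA character scalar.
#' @param te_seq element sequence to insert (already oriented; pass the
#'   reverse complement for a minus-strand insertion).
#' @param position 0-based insertion point; the duplicated target k-mer is
#'   `genome[position, position + tsd_length)`.
#' @param tsd_length target site duplication length in bp (~8 for hATs;
#'   0 inserts without duplication).
#' @return list with `genome` (new sequence), `interval` (0-based half-open
#'   start/end of the TE itself, excluding the TSDs) and `tsd` (the
#'   duplicated k-mer).
#' @export
insert_te <- function(genome, te_seq, position, tsd_length = 8L) {
  stopifnot(is.character(genome), length(genome) == 1L)
  position <- as.integer(position); tsd_length <- as.integer(tsd_length)
  n <- nchar(genome)
  if (position < 0L || position + tsd_length > n)
    stop("insertion position out of range: ", position)
  tsd <- substr0(genome, position, position + tsd_length)
  new_genome <- paste0(
    substr0(genome, 0L, position + tsd_length), te_seq, tsd,
    substr0(genome, position + tsd_length, n)
  )
  start <- position + tsd_length
  list(genome = new_genome,
       interval = c(start = start, end = start + nchar(te_seq)),
       tsd = tsd)
}

# Kimura 2-parameter per-site event probabilities after evolving for
# `distance` expected substitutions/site with transition/transversion rate
# ratio kappa = alpha / (2 beta).  Returns P (transition) and q1 (each of
# the two transversion targets); kappa = 0.5 is the Jukes-Cantor limit.
k2p_event_probs <- function(distance, kappa) {
  bt <- distance / (2 * (kappa + 1))
  at <- distance * kappa / (kappa + 1)
  P <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  q1 <- 0.25 - 0.25 * exp(-4 * bt)
  c(P = P, q1 = q1)
}

#' Evolve a DNA sequence under the Kimura 2-parameter process
#'
#' Independent sites, no indels: each site is substituted according to the
#' exact K2P transition probabilities for the requested distance, so the
#' expected proportions of transitions and transversions match what the
#' [k2p_distance()] estimator inverts.  `N` sites are left untouched.
#'
#' @param seq DNA character scalar.
#' @param distance expected substitutions per site (>= 0).
#' @param kappa transition/transversion rate ratio alpha/(2 beta); 0.5 is
#'   the unbiased (Jukes-Cantor) limit.
#' @param seed optional integer seed.
#' @return evolved DNA character scalar of the same length.
#' @export
evolve_seq <- function(seq, distance, kappa = 2, seed = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (distance < 0) stop("distance must be >= 0")
  if (kappa <= 0) stop("kappa must be > 0")
  if (distance == 0 || nchar(seq) == 0L) return(seq)
  with_seed(seed, {
    pr <- k2p_event_probs(distance, kappa)
    x <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(x)
    u <- stats::runif(n)
    # target lookup per source base: transition, transversion 1, transversion 2
    ts <- c(A = "G", G = "A", C = "T", T = "C", N = "N")
    tv1 <- c(A = "C", G = "C", C = "A", T = "A", N = "N")
    tv2 <- c(A = "T", G = "T", C = "G", T = "G", N = "N")
    pick_ts <- u < pr["P"]
    pick_tv1 <- !pick_ts & u < pr["P"] + pr["q1"]
    pick_tv2 <- !pick_ts & !pick_tv1 & u < pr["P"] + 2 * pr["q1"]
    x[pick_ts] <- ts[x[pick_ts]]
    x[pick_tv1] <- tv1[x[pick_tv1]]
    x[pick_tv2] <- tv2[x[pick_tv2]]
    paste(x, collapse = "")
  })
}

#' Describe one TE insertion event for the simulator
#'
#' Vertical events attach to an internal branch (or above the root) and
#' their copies are inherited, as orthologous insertions, by every
#' descendant species.  Horizontal events attach to the terminal branch of
#' one recipient species at the stated time, modelling transfer from an
#' abstract external source.
#'
#' @param kind `"vertical"` or `"horizontal"`.
#' @param clade for vertical events: character vector of species labels
#'   whose most recent common ancestor's stem branch receives the event
#'   (all species = above the root).
#' @param species for horizontal events: the single recipient species.
#' @param time event time before present, in the tree's branch-length units
#'   (substitutions/site for clock-like trees).  Must fall on the chosen
#'   branch; a vertical event on all species may predate the root, in which
#'   case the element accrues the extra divergence before insertion.
#' @param copies number of copies inserted by the event.
#' @return an `insertion_event` list.
#' @export
insertion_event <- function(kind = c("vertical", "horizontal"), clade = NULL,
                            species = NULL, time, copies = 5L) {
  kind <- match.arg(kind)
  if (kind == "vertical" && is.null(clade))
    stop("vertical events need a clade")
  if (kind == "horizontal" && (is.null(species) || length(species) != 1L))
    stop("horizontal events need exactly one recipient species")
  stopifnot(time >= 0, copies >= 1)
  structure(list(kind = kind, clade = clade, species = species,
                 time = time, copies = as.integer(copies)),
            class = "insertion_event")
}

#' Simulation configuration
#'
#' Bundles the species tree, the genome model and the insertion history.
#' Branch lengths are substitutions/site and the tree must be clock-like
#' (ultrametric) so that event times before present are well defined;
#' divergence-time trees in MY must be rescaled by a substitution rate
#' before use.
#'
#' @param species_tree `phylo` species tree with branch lengths in
#'   substitutions/site (ultrametric).
#' @param events list of [insertion_event()]s.
#' @param genome_length background genome length per species, bp.
#' @param gc_content background GC fraction.
#' @param te_length element length, bp.
#' @param tir_length terminal inverted repeat length, bp.
#' @param tsd_length target site duplication length, bp.
#' @param copies_per_event default copy count for events that do not state
#'   one.
#' @param fragment_prob probability that an inserted copy is truncated
#'   (one end removed, uniform retained fraction in `[0.3, 0.9]`), which
#'   destroys its hallmarks on the truncated side; truncated copies are
#'   inserted without a target site duplication.
#' @param kappa transition/transversion rate ratio of the substitution
#'   process (see [evolve_seq()]).
#' @param edge_margin insertions are sampled uniformly at least this many
#'   bp from the contig ends, so every simulated locus keeps its full
#'   flanking context (mirrors excluding contig-terminal loci in practice).
#' @param insert_buffer insertions are also rejected within this many bp of
#'   an existing copy.  Nested and immediately adjacent (tandem) copies
#'   produce junction arrangements that no flank-geometry test can
#'   resolve, and are excluded for the same reason nesting is.
#' @param seed integer seed; the full scenario is a deterministic function
#'   of the configuration.
#' @return a `sim_config` list.
#' @export
sim_config <- function(species_tree, events, genome_length = 50000L,
                       gc_content = 0.42, te_length = 3000L,
                       tir_length = 15L, tsd_length = 8L,
                       copies_per_event = 5L, fragment_prob = 0.2,
                       kappa = 2, edge_margin = 1600L, insert_buffer = 150L,
                       seed = 1L) {
  stopifnot(inherits(species_tree, "phylo"))
  if (te_length <= 2 * tir_length) stop("te_length must exceed 2 * tir_length")
  if (fragment_prob < 0 || fragment_prob > 1) stop("fragment_prob must be in [0, 1]")
  if (kappa <= 0) stop("kappa must be > 0")
  structure(list(
    species_tree = species_tree, events = events,
    n_species = length(species_tree$tip.label),
    genome_length = as.integer(genome_length), gc_content = gc_content,
    te_length = as.integer(te_length), tir_length = as.integer(tir_length),
    tsd_length = as.integer(tsd_length),
    copies_per_event = as.integer(copies_per_event),
    fragment_prob = fragment_prob, kappa = kappa,
    edge_margin = as.integer(edge_margin),
    insert_buffer = as.integer(insert_buffer), seed = as.integer(seed)
  ), class = "sim_config")
}

# Insert one copy into a growing genome, updating previously placed copy
# coordinates.  Returns the new (seq, copies) pair.
#
# `registry` is a scenario-wide environment collecting every insertion's
# position in ancestral background coordinates.  Positions are rejected
# within insert_buffer of any previous insertion's background-homologous
# spot, in any species: independent insertions landing at (nearly) the
# same orthologous site are homoplasy that no flank-geometry test can
# resolve, and at realistic genome sizes such collisions are vanishingly
# rare -- at simulation scale they would be a small-genome artifact.
sim_insert_copy <- function(seq, copies, te_raw, meta, config,
                            registry = NULL) {
  frag <- stats::runif(1) < config$fragment_prob
  strand <- sample(c("+", "-"), 1L)
  te_use <- te_raw
  if (frag) {
    keep <- stats::runif(1, 0.3, 0.9)
    rl <- max(1L, as.integer(round(keep * nchar(te_raw))))
    te_use <- if (stats::runif(1) < 0.5) substr0(te_raw, 0L, rl)
              else substr0(te_raw, nchar(te_raw) - rl, nchar(te_raw))
  }
  if (strand == "-") te_use <- revcomp(te_use)
  k <- if (frag) 0L else config$tsd_length
  n <- nchar(seq)
  margin <- config$edge_margin
  if (n - 2L * margin < 1L) stop("genome too short for edge_margin")
  buf <- config$insert_buffer %||% 0L
  pos <- NA_integer_
  for (try in 1:1000) {
    p <- as.integer(floor(stats::runif(1, margin, n - margin)))
    if (nrow(copies) > 0L &&
        any(copies$start - buf < p + k & copies$end + buf > p)) next
    if (!is.null(registry)) {
      anchor <- p - sum((copies$te_len + copies$tsd_len)[copies$start < p])
      if (length(registry$anchors) > 0L &&
          any(abs(registry$anchors - anchor) < buf)) next
      registry$anchors <- c(registry$anchors, anchor)
    }
    pos <- p; break
  }
  if (is.na(pos)) stop("could not place insertion after 1000 tries; genome too crowded")
  ins <- insert_te(seq, te_use, pos, k)
  grow <- nchar(te_use) + k
  if (nrow(copies) > 0L) {
    shift <- copies$start >= pos
    copies$start[shift] <- copies$start[shift] + grow
    copies$end[shift] <- copies$end[shift] + grow
  }
  row <- data.frame(
    instance = meta$instance, event_id = meta$event_id, kind = meta$kind,
    start = unname(ins$interval["start"]), end = unname(ins$interval["end"]),
    strand = strand, fragment = frag, te_len = nchar(te_use),
    tsd_len = k, true_div = meta$time, stringsAsFactors = FALSE
  )
  list(seq = ins$genome, copies = rbind(copies, row))
}

#' Simulate genomes under a vertical / horizontal TE insertion history
#'
#' The ancestral background genome is generated at the root and evolved
#' down the species tree under the K2P substitution process (no indels
#' outside of TE insertions).  Vertical events insert pristine consensus
#' copies on their branch at the stated time; the copies then evolve with
#' the genome, producing orthologous insertions (identical flanking
#' context) in every descendant.  Horizontal events insert pristine
#' consensus copies into one recipient's terminal branch, so their
#' divergence from the consensus reflects only the time since transfer,
#' however distant the host species are.
#'
#' @param config a [sim_config()].
#' @return list with `genomes` (per-species named character vectors, single
#'   contig `chr1`), `copies` (truth table: one row per simulated copy with
#'   species, 0-based interval, strand, event, orthology instance id,
#'   fragmentation flag and true divergence), `shared` (per species pair,
#'   the true count of orthologous insertions present in both), and
#'   `consensus` (the TE consensus used).
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- config$species_tree
  ntip <- length(tree$tip.label)
  if (is.null(tree$edge.length)) stop("species tree needs branch lengths")
  if (!ape::is.ultrametric(tree, tol = 1e-6))
    stop("species tree must be ultrametric (clock-like) for the simulator")
  depths <- ape::node.depth.edgelength(tree)
  total_depth <- max(depths[seq_len(ntip)])
  root <- ntip + 1L

  # resolve each event to the child node of the edge it sits on
  events <- lapply(seq_along(config$events), function(i) {
    ev <- config$events[[i]]
    ev$event_id <- paste0("ev", i)
    ev$copies <- ev$copies %||% config$copies_per_event
    if (ev$kind == "vertical") {
      if (!all(ev$clade %in% tree$tip.label))
        stop("event clade contains unknown species: ",
             paste(setdiff(ev$clade, tree$tip.label), collapse = ", "))
      if (setequal(ev$clade, tree$tip.label)) {
        if (ev$time < total_depth - 1e-9)
          stop("a vertical event on all species must predate the root")
        ev$node <- root
      } else {
        node <- if (length(ev$clade) == 1L) match(ev$clade, tree$tip.label)
                else ape::getMRCA(tree, ev$clade)
        desc <- tree$tip.label[unlist(phangorn::Descendants(tree, node, "tips"))]
        if (!setequal(desc, ev$clade))
          stop("event clade is not a clade of the species tree: ",
               paste(ev$clade, collapse = ","))
        ev$node <- node
      }
    } else {
      ev$node <- match(ev$species, tree$tip.label)
      if (is.na(ev$node)) stop("unknown recipient species: ", ev$species)
    }
    if (ev$node != root) {
      d_ev <- total_depth - ev$time
      parent <- tree$edge[tree$edge[, 2] == ev$node, 1]
      if (d_ev < depths[parent] - 1e-9 || d_ev > depths[ev$node] + 1e-9)
        stop("event time ", ev$time, " does not fall on the branch to ",
             if (ev$node <= ntip) tree$tip.label[ev$node] else "the clade ancestor")
    }
    ev
  })

  with_seed(config$seed, {
    consensus <- make_te_consensus(config$te_length, config$tir_length,
                                   config$gc_content)
    empty_copies <- data.frame(
      instance = character(0), event_id = character(0), kind = character(0),
      start = integer(0), end = integer(0), strand = character(0),
      fragment = logical(0), te_len = integer(0), tsd_len = integer(0),
      true_div = numeric(0), stringsAsFactors = FALSE
    )
    seq0 <- random_dna(config$genome_length, config$gc_content)
    copies0 <- empty_copies
    registry <- new.env(parent = emptyenv())
    registry$anchors <- numeric(0)

    # events above the root: element diverges before it ever enters a genome
    root_events <- Filter(function(e) e$node == root, events)
    root_events <- root_events[order(vapply(root_events, `[[`, 0, "time"),
                                     decreasing = TRUE)]
    for (ev in root_events) {
      pre <- ev$time - total_depth
      for (j in seq_len(ev$copies)) {
        te0 <- if (pre > 0) evolve_seq(consensus, pre, config$kappa) else consensus
        st <- sim_insert_copy(seq0, copies0, te0,
                              list(instance = paste0(ev$event_id, ".", j),
                                   event_id = ev$event_id, kind = ev$kind,
                                   time = ev$time), config, registry)
        seq0 <- st$seq; copies0 <- st$copies
      }
    }

    leaves <- vector("list", ntip)
    descend <- function(node, seq, copies, cur_depth) {
      if (node <= ntip) {
        leaves[[node]] <<- list(seq = seq, copies = copies)
        return(invisible())
      }
      children <- tree$edge[tree$edge[, 1] == node, 2]
      for (child in children) {
        s <- seq; cp <- copies; cur <- cur_depth
        evs <- Filter(function(e) e$node == child, events)
        evs <- evs[order(vapply(evs, function(e) total_depth - e$time, 0))]
        for (ev in evs) {
          d_ev <- total_depth - ev$time
          if (d_ev > cur) {
            s <- evolve_seq(s, d_ev - cur, config$kappa)
            cur <- d_ev
          }
          for (j in seq_len(ev$copies)) {
            st <- sim_insert_copy(s, cp, consensus,
                                  list(instance = paste0(ev$event_id, ".", j),
                                       event_id = ev$event_id, kind = ev$kind,
                                       time = ev$time), config, registry)
            s <- st$seq; cp <- st$copies
          }
        }
        if (depths[child] > cur)
          s <- evolve_seq(s, depths[child] - cur, config$kappa)
        descend(child, s, cp, depths[child])
      }
    }
    descend(root, seq0, copies0, 0)

    genomes <- list()
    truth <- NULL
    for (i in seq_len(ntip)) {
      sp <- tree$tip.label[i]
      g <- c(chr1 = leaves[[i]]$seq)
      attr(g, "species_id") <- sp
      genomes[[sp]] <- g
      cp <- leaves[[i]]$copies
      if (nrow(cp) > 0L) {
        cp <- cbind(
          data.frame(species = sp, seq_id = "chr1",
                     copy_id = paste0(sp, ".", seq_len(nrow(cp))),
                     stringsAsFactors = FALSE),
          cp
        )
        truth <- rbind(truth, cp)
      }
    }
    if (is.null(truth)) truth <- cbind(
      data.frame(species = character(0), seq_id = character(0),
                 copy_id = character(0), stringsAsFactors = FALSE),
      empty_copies
    )

    sp <- tree$tip.label
    shared <- NULL
    if (length(sp) >= 2L) {
      pr <- utils::combn(sp, 2L)
      shared <- data.frame(
        species_a = pr[1, ], species_b = pr[2, ],
        n_shared = apply(pr, 2L, function(p) {
          length(intersect(truth$instance[truth$species == p[1]],
                           truth$instance[truth$species == p[2]]))
        }),
        stringsAsFactors = FALSE
      )
    }
    list(genomes = genomes, copies = truth, shared = shared,
         consensus = consensus, config = config)
  })
}

#' Built-in clock-like six-species tree
#'
#' A balanced ultrametric topology `((A,B),((C,D),(E,F)))` with root depth
#' 0.10 substitutions/site, used as the default host phylogeny for
#' simulated scenarios: sister pairs split at 0.04-0.06, the deepest splits
#' at 0.10, spanning the shallow-to-moderate host divergences over which
#' HTT detection is informative.
#'
#' @return a `phylo` object.
#' @export
default_species_tree <- function() {
  read_newick(text = paste0(
    "((A:0.04,B:0.04):0.06,",
    "((C:0.05,D:0.05):0.03,(E:0.06,F:0.06):0.02):0.02);"
  ))
}

#' Standard study scenarios: vertical inheritance and HTT
#'
#' `vertical_scenario()` places one insertion burst above the root so every
#' species inherits the same orthologous copies.  `htt_scenario()` adds, on
#' top of an optional old vertical background (the realistic case: genomes
#' already carry ancient relatives of the family), a recent independent
#' horizontal transfer into each of two non-sister recipient species.
#'
#' @param seed integer seed (drives genome generation, substitution noise
#'   and, for `htt_scenario`, the recipient pair draw).
#' @param tree host species tree (default [default_species_tree()]).
#' @param time vertical insertion time before present (substitutions/site).
#' @param htt_time horizontal transfer time before present; the default
#'   0.005 yields copies under 1% diverged from the consensus, the
#'   signature of a recent transfer.
#' @param background_time age of the vertical background burst in
#'   `htt_scenario` (`NULL` for a pure-HTT scenario with no background).
#' @param recipients two non-sister species labels, or `NULL` to draw a
#'   random non-sister pair.
#' @param copies copies per event.
#' @param ... passed to [sim_config()] (genome length, fragment_prob, ...).
#' @return a `sim_config`; for `htt_scenario` the drawn recipients are in
#'   `attr(, "recipients")`.
#' @export
vertical_scenario <- function(seed = 1L, tree = default_species_tree(),
                              time = 0.15, copies = 5L, ...) {
  sim_config(tree, events = list(
    insertion_event("vertical", clade = tree$tip.label, time = time,
                    copies = copies)
  ), seed = seed, ...)
}

#' @rdname vertical_scenario
#' @export
htt_scenario <- function(seed = 1L, tree = default_species_tree(),
                         htt_time = 0.005, background_time = 0.15,
                         recipients = NULL, copies = 5L, ...) {
  if (is.null(recipients)) {
    recipients <- with_seed(seed + 7901L, {
      repeat {
        r <- sample(tree$tip.label, 2L)
        mrca <- ape::getMRCA(tree, r)
        desc <- unlist(phangorn::Descendants(tree, mrca, "tips"))
        if (length(desc) > 2L) break  # not a cherry: non-sister pair
      }
      sort(r)
    })
  }
  events <- list()
  if (!is.null(background_time))
    events <- list(insertion_event("vertical", clade = tree$tip.label,
                                   time = background_time, copies = copies))
  for (r in recipients)
    events <- c(events, list(insertion_event("horizontal", species = r,
                                             time = htt_time, copies = copies)))
  cfg <- sim_config(tree, events = events, seed = seed, ...)
  attr(cfg, "recipients") <- recipients
  cfg
}
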