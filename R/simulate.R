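# -------------------------------------------------------------------------
# Simulation of species trees, HGT-perturbed gene histories and K80
# sequence data, with recorded truth.
#
# All randomness is driven by integer seeds; named substreams derived from
# a master seed keep the stages (tree, per-replicate data) independently
# reproducible. Gene sets are partitioned deterministically between the
# two histories of a planted reticulation in proportion gamma.
# -------------------------------------------------------------------------

#' Derive a reproducible substream seed
#'
#' Hashes a master seed together with string/number labels into a new
#' seed below 2^31, so that each stage (trees, sequences, replicates)
#' draws from its own reproducible stream.
#'
#' @param seed Master integer seed.
#' @param ... Labels (strings or numbers) identifying the substream.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  s <- 0
  for (code in utf8ToInt(lab)) s <- (s * 31 + code) %% 2147483629
  as.integer(s %% 2147483629) + 1L
}

with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Simulate a species tree
#'
#' Either a deterministic caterpillar (fully unbalanced) tree with
#' configurable pendant and internal branch lengths, or a seeded
#' birth-death tree (via [ape::rphylo], ultrametric).
#'
#' @param ntaxa Number of taxa (`>= 3`). Taxa are labelled `t1..tN`, with
#'   the cherry `(t1, t2)` at the bottom of the caterpillar.
#' @param shape `"caterpillar"` (default) or `"birth_death"`.
#' @param pendant,internal Branch lengths for the caterpillar
#'   (substitutions/site).
#' @param birth,death Rates for the birth-death shape.
#' @param seed Seed for the birth-death draw (ignored for caterpillars).
#' @return An [ape::phylo] tree.
#' @export
make_species_tree <- function(ntaxa, shape = c("caterpillar", "birth_death"),
                              pendant = 0.25, internal = 0.25,
                              birth = 1, death = 0, seed = NULL) {
  if (ntaxa < 3) stop("need at least 3 taxa")
  shape <- match.arg(shape)
  if (shape == "caterpillar") {
    nwk <- sprintf("(t1:%g,t2:%g)", pendant, pendant)
    for (k in 3:ntaxa) {
      nwk <- sprintf("(%s:%g,t%d:%g)", nwk, internal, k, pendant)
    }
    ape::read.tree(text = paste0(nwk, ";"))
  } else {
    with_seed_(seed, {
      tr <- ape::rphylo(ntaxa, birth = birth, death = death)
      tr$tip.label <- sprintf("t%d", seq_len(ntaxa))
      tr
    })
  }
}

#' Gene tree induced by a horizontal transfer
#'
#' Returns the gene tree carried by genes that cross the reticulation:
#' the SPR of the species tree in which the recipient subtree is pruned
#' and regrafted next to the donor attachment point. It equals, by
#' construction, the non-base displayed tree of the single-reticulation
#' network built on the same edge pair.
#'
#' @param tree Species tree ([ape::phylo]).
#' @param donor,recipient Edge ids on `as_phylo_network(tree)` (see
#'   [pendant_edge()]).
#' @return An [ape::phylo] gene tree.
#' @export
apply_hgt <- function(tree, donor, recipient) {
  net <- add_reticulation(as_phylo_network(tree), donor, recipient,
                          gamma = 0.5)
  transferred_tree(net)
}

# the displayed tree using every transfer arc (for single-reticulation
# networks: the non-base tree T'); base_tree: the one using none
displayed_by_arcs <- function(net, use_arcs) {
  combos <- display_combos(net, hash = "none")
  eid <- network_edge_ids(net)
  arcs <- eid[net$transfer]
  pick <- vapply(combos, function(cb) {
    used <- intersect(cb$choice, arcs)
    if (use_arcs) setequal(used, arcs) else length(used) == 0L
  }, TRUE)
  dtree_to_phylo(combos[[which(pick)[1]]]$tree)
}

#' Base and transferred displayed trees of a planted network
#'
#' For networks built by planting transfer arcs on a species tree,
#' `base_tree()` returns the displayed tree using no transfer arc (the
#' species-tree history) and `transferred_tree()` the one using every
#' transfer arc (the fully horizontal history).
#'
#' @param net A `phylo_network` with flagged transfer arcs.
#' @return An [ape::phylo] tree.
#' @export
transferred_tree <- function(net) displayed_by_arcs(net, TRUE)

#' @rdname transferred_tree
#' @export
base_tree <- function(net) displayed_by_arcs(net, FALSE)

#' Deterministic gene partition between two histories
#'
#' Splits a genome of `k` genes so that a fraction `gamma` evolves on the
#' transferred history and `1 - gamma` on the base (species-tree) history;
#' the transferred count is `round(gamma * k)` (half-up).
#'
#' @param k Genome size (number of genes), `k >= 1`.
#' @param gamma Inheritance probability in (0, 1).
#' @return Named integer vector `c(base = , transferred = )`.
#' @export
partition_genes <- function(k, gamma) {
  stopifnot(k >= 1, gamma > 0, gamma < 1)
  m <- as.integer(floor(gamma * k + 0.5))
  c(base = as.integer(k) - m, transferred = m)
}

#' Simulate a gene alignment on a tree under K80
#'
#' The root sequence is drawn uniformly over `{A, C, G, T}` (the K80
#' stationary distribution) and states evolve edge by edge with
#' closed-form K80 transition probabilities.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param sites Number of sites (`>= 1`).
#' @param tstv Transition/transversion ratio (default 2).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A character matrix (taxa x sites) of bases.
#' @export
simulate_alignment <- function(tree, sites, tstv = 2, seed = NULL) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  stopifnot(sites >= 1)
  with_seed_(seed, {
    bases <- c("A", "C", "G", "T")
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    eo <- ape::reorder.phylo(tree, "cladewise")  # root-to-tip order
    states <- matrix(0L, nnode, sites)
    states[ntip + 1L, ] <- sample.int(4L, sites, replace = TRUE)
    pv <- k80_probs(eo$edge.length, tstv)
    for (e in seq_len(nrow(eo$edge))) {
      p <- eo$edge[e, 1]; ch <- eo$edge[e, 2]
      ps <- pv[e, 1]; pi_ <- pv[e, 2]; pvv <- pv[e, 3]
      u <- stats::runif(sites)
      par <- states[p, ]
      # transition partner under base coding A=1,C=2,G=3,T=4:
      # A<->G (1<->3), C<->T (2<->4)
      partner <- c(3L, 4L, 1L, 2L)[par]
      others <- matrix(0L, 2, sites)
      for (s in 1:4) {
        sel <- par == s
        oth <- setdiff(1:4, c(s, c(3L, 4L, 1L, 2L)[s]))
        others[1, sel] <- oth[1]; others[2, sel] <- oth[2]
      }
      child_state <- ifelse(u < ps, par,
                     ifelse(u < ps + pi_, partner,
                     ifelse(u < ps + pi_ + pvv, others[1, ], others[2, ])))
      states[ch, ] <- child_state
    }
    m <- matrix(bases[states[seq_len(ntip), , drop = FALSE]], ntip, sites)
    rownames(m) <- tree$tip.label
    m
  })
}

# recipient leaf achieving a given diameter on the default caterpillar
# (pendants = internals = 0.25, donor on t3's pendant edge): the
# attachment-midpoint path to leaf k >= 4 is 0.25 (k - 2); to t2 it is 0.5
default_recipient <- function(diameter) {
  map <- c("0.5" = "t2", "1" = "t6", "1.5" = "t8")
  key <- as.character(diameter)
  if (!key %in% names(map)) {
    stop("no default recipient for diameter ", diameter,
         "; supply donor/recipient edges explicitly")
  }
  map[[key]]
}

#' Simulate a multi-gene data set with one planted reticulation
#'
#' Builds the study species tree (16-taxon caterpillar, all branch
#' lengths 0.25), plants a single HGT arc of the requested diameter
#' (donor on taxon `t3`'s pendant edge; recipients `t2`/`t6`/`t8` give
#' diameters 0.5/1.0/1.5 between attachment midpoints, all with equal
#' height), partitions `k` genes deterministically in proportion `gamma`,
#' and simulates 100-site K80 alignments down the two histories.
#'
#' @param diameter Planted reticulation diameter (0.5, 1.0 or 1.5 on the
#'   default tree; other values require explicit `donor`/`recipient`).
#' @param gamma True inheritance probability in (0, 1).
#' @param k Genome size (number of genes).
#' @param sites Sites per gene (default 100).
#' @param tstv Transition/transversion ratio (default 2).
#' @param ntaxa Number of taxa (default 16).
#' @param seed Integer seed (drives the sequence simulation).
#' @param donor,recipient Optional explicit attachment taxa (pendant
#'   edges are used).
#' @return A list with components `genes` (a `gene_alignments`),
#'   `species_tree`, `network` (the planted `phylo_network`), `arc` (the
#'   transfer-arc edge id), `transferred_tree` (the true horizontal
#'   history `T_i`), and `truth` (one-row tibble: donor/recipient
#'   attachments, gamma, diameter, height, transferred gene indices).
#' @export
simulate_hgt_dataset <- function(diameter = 0.5, gamma = 0.3, k = 10,
                                 sites = 100, tstv = 2, ntaxa = 16,
                                 seed = NULL, donor = "t3",
                                 recipient = NULL) {
  tree <- make_species_tree(ntaxa)
  if (is.null(recipient)) recipient <- default_recipient(diameter)
  net0 <- as_phylo_network(tree)
  e_d <- pendant_edge(net0, donor)
  e_r <- pendant_edge(net0, recipient)
  net <- add_reticulation(net0, e_d, e_r, gamma = gamma)
  arc <- network_edge_ids(net)[net$transfer]
  geom <- reticulation_geometry(net, arc)
  t_base <- base_tree(net)
  t_alt <- transferred_tree(net)
  counts <- partition_genes(k, gamma)
  assign_alt <- c(rep(FALSE, counts["base"]), rep(TRUE, counts["transferred"]))
  mats <- lapply(seq_len(k), function(i) {
    simulate_alignment(if (assign_alt[i]) t_alt else t_base, sites, tstv,
                       seed = if (is.null(seed)) NULL else
                         substream_seed(seed, "gene", i))
  })
  list(genes = gene_alignments(mats),
       species_tree = tree,
       network = net,
       arc = arc,
       transferred_tree = t_alt,
       truth = tibble::tibble(
         donor_attach = e_d, recipient_attach = e_r, gamma = gamma,
         diameter = geom$diameter, height = geom$height,
         k = as.integer(k), n_transferred = counts[["transferred"]],
         transferred_genes = list(which(assign_alt)),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
}

#' Simulate a reticulation-free multi-gene data set
#'
#' All `k` genes evolve down the same caterpillar species tree; used for
#' the model-selection (true h = 0) experiments.
#'
#' @inheritParams simulate_hgt_dataset
#' @return A list with `genes` and `species_tree`.
#' @export
simulate_null_dataset <- function(k = 10, sites = 100, tstv = 2,
                                  ntaxa = 16, seed = NULL) {
  tree <- make_species_tree(ntaxa)
  mats <- lapply(seq_len(k), function(i) {
    simulate_alignment(tree, sites, tstv,
                       seed = if (is.null(seed)) NULL else
                         substream_seed(seed, "gene", i))
  })
  list(genes = gene_alignments(mats), species_tree = tree)
}

#' Factorial experiment grid of simulation conditions
#'
#' Full factorial of diameters, inheritance probabilities, genome sizes
#' and replicates, each row with its own derived seed; rows are the
#' configurations consumed by the evaluation drivers.
#'
#' @param diameters,gammas,genome_sizes Condition vectors (defaults:
#'   the study grid 0.5/1.0/1.5, 0.1/0.3/0.5, 10/20/40/80).
#' @param replicates Replicates per cell (default 50).
#' @param seed Master seed.
#' @return Tibble with columns `diameter`, `gamma`, `k`, `rep`, `seed`.
#' @export
make_experiment_grid <- function(diameters = c(0.5, 1, 1.5),
                                 gammas = c(0.1, 0.3, 0.5),
                                 genome_sizes = c(10, 20, 40, 80),
                                 replicates = 50, seed = 1) {
  g <- expand.grid(rep = seq_len(replicates), k = genome_sizes,
                   gamma = gammas, diameter = diameters,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("diameter", "gamma", "k", "rep")]
  g$seed <- mapply(function(d, ga, k, r)
    substream_seed(seed, "bundle", d, ga, k, r),
    g$diameter, g$gamma, g$k, g$rep)
  tibble::as_tibble(g)
}

#' Simulate the data set for one experiment-grid row
#'
#' @param row One row of [make_experiment_grid()].
#' @param sites,tstv,ntaxa Passed to [simulate_hgt_dataset()].
#' @return See [simulate_hgt_dataset()].
#' @export
simulate_bundle <- function(row, sites = 100, tstv = 2, ntaxa = 16) {
  simulate_hgt_dataset(diameter = row$diameter, gamma = row$gamma,
                       k = row$k, sites = sites, tstv = tstv,
                       ntaxa = ntaxa, seed = row$seed)
}
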