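test_that("pruning matches stationary and exhaustive-summation baselines", {
  # two identical states on zero-length branches: stationary frequency
  aln <- matrix(c("A", "A"), 2, 1, dimnames = list(c("a", "b"), NULL))
  tr <- ape::read.tree(text = "(a:0,b:0);")
  expect_equal(tree_log_likelihood(tr, aln), log(0.25), tolerance = 1e-12)
  # exhaustive ancestral-state summation on trees up to 4 taxa, 4 sites
  set.seed(7)
  for (rep in 1:8) {
    n <- sample(3:4, 1)
    tree <- ape::rtree(n, tip.label = sprintf("t%d", 1:n))
    aln <- random_alignment(tree$tip.label, sites = sample(1:4, 1),
                            seed = rep)
    net <- as_phylo_network(tree)
    tr_el <- list(parent = net$parent, child = net$child,
                  length = net$length, root = net$root)
    expect_equal(tree_log_likelihood(tree, aln),
                 oracle_tree_likelihood(tr_el, aln), tolerance = 1e-12)
  }
})

test_that("missing data and ambiguity codes act as marginalization", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.1,c:0.3);")
  full <- matrix(c("A", "C", "G"), 3, 1, dimnames = list(letters[1:3], NULL))
  miss <- full; miss["c", 1] <- "N"
  # all-missing column contributes zero log-likelihood
  allmiss <- matrix("N", 3, 1, dimnames = list(letters[1:3], NULL))
  expect_equal(tree_log_likelihood(tr, allmiss), 0, tolerance = 1e-12)
  # N marginalizes: equals the sum of likelihoods over c's four states
  states <- c("A", "C", "G", "T")
  tot <- sum(vapply(states, function(s) {
    m <- full; m["c", 1] <- s
    exp(tree_log_likelihood(tr, m))
  }, 0))
  expect_equal(exp(tree_log_likelihood(tr, miss)), tot, tolerance = 1e-12)
  # R = A or G
  amb <- full; amb["c", 1] <- "R"
  tot2 <- sum(vapply(c("A", "G"), function(s) {
    m <- full; m["c", 1] <- s
    exp(tree_log_likelihood(tr, m))
  }, 0))
  expect_equal(exp(tree_log_likelihood(tr, amb)), tot2, tolerance = 1e-12)
})

test_that("likelihood is invariant to rerooting along a branch", {
  # same unrooted metric tree rooted at two different points
  r1 <- ape::read.tree(text = "((a:0.1,b:0.2):0.15,(c:0.3,d:0.1):0.05);")
  r2 <- ape::read.tree(text = "(a:0.02,(b:0.2,(c:0.3,d:0.1):0.2):0.08);")
  aln <- random_alignment(letters[1:4], 20, seed = 3)
  expect_equal(tree_log_likelihood(r1, aln), tree_log_likelihood(r2, aln),
               tolerance = 1e-10)
})

test_that("branch-length optimization never worsens the likelihood", {
  tree <- ape::rtree(5, tip.label = sprintf("t%d", 1:5))
  aln <- simulate_alignment(tree, 200, seed = 4)
  fixed <- tree_log_likelihood(tree, aln)
  opt <- tree_log_likelihood(tree, aln, optimize_branches = TRUE)
  expect_gte(opt, fixed)
})

test_that("network likelihood reduces to the tree likelihood at h = 0 and
           matches full enumeration with reticulations", {
  tree <- make_species_tree(4)
  genes <- lapply(1:2, function(i)
    simulate_alignment(tree, 3, seed = i))
  ga <- gene_alignments(genes)
  ll_net <- network_log_likelihood(as_phylo_network(tree), ga)
  ll_sum <- sum(vapply(genes, function(g) tree_log_likelihood(tree, g), 0))
  expect_equal(as.numeric(ll_net), ll_sum, tolerance = 1e-12)
  # reticulate fixtures up to h = 3 on 4 taxa vs brute-force oracle
  for (h in 1:3) {
    net <- random_network(ntaxa = 4, h = h, seed = 20 + h)
    ll <- network_log_likelihood(net, ga)
    expect_equal(as.numeric(ll), oracle_network_loglik(net, genes),
                 tolerance = 1e-10)
  }
})

test_that("single-reticulation change in likelihood is linear in gamma", {
  # P(S|N,gamma) - P(S|T) = gamma [P(S|T') - P(S|T)] for one alignment
  net0 <- as_phylo_network(make_species_tree(6))
  for (seed in 1:5) {
    net <- add_reticulation(net0, pendant_edge(net0, "t3"),
                            pendant_edge(net0, sample(c("t2", "t5"), 1)),
                            gamma = runif(1, 0.1, 0.9))
    g <- net$gamma[net$transfer]
    aln <- simulate_alignment(base_tree(net), 30, seed = seed)
    ga <- gene_alignments(list(aln))
    pT <- exp(tree_log_likelihood(base_tree(net), ga))
    pTp <- exp(tree_log_likelihood(transferred_tree(net), ga))
    pN <- exp(as.numeric(network_log_likelihood(net, ga)))
    expect_equal(pN - pT, g * (pTp - pT), tolerance = 1e-10)
  }
})

test_that("per-gene mixture log-likelihood lies within displayed-tree bounds", {
  ds <- simulate_hgt_dataset(diameter = 1.0, gamma = 0.3, k = 6,
                             sites = 50, ntaxa = 8, seed = 9)
  lt <- vapply(seq_len(ds$genes$k), function(i)
    tree_log_likelihood(base_tree(ds$network), ds$genes[i]), 0)
  la <- vapply(seq_len(ds$genes$k), function(i)
    tree_log_likelihood(transferred_tree(ds$network), ds$genes[i]), 0)
  ln <- attr(network_log_likelihood(ds$network, ds$genes), "by_gene")
  expect_true(all(ln >= pmin(lt, la) - 1e-9))
  expect_true(all(ln <= pmax(lt, la) + 1e-9))
})

test_that("gamma grid search recovers boundary and balanced mixtures", {
  net0 <- as_phylo_network(make_species_tree(8))
  net <- add_reticulation(net0, pendant_edge(net0, "t3"),
                          pendant_edge(net0, "t6"), gamma = 0.25)
  arc <- network_edge_ids(net)[net$transfer]
  tb <- base_tree(net); ta <- transferred_tree(net)
  sim_genes <- function(n_base, n_alt, seed) {
    mats <- c(lapply(seq_len(n_base), function(i)
                simulate_alignment(tb, 100, seed = seed * 100 + i)),
              lapply(seq_len(n_alt), function(i)
                simulate_alignment(ta, 100, seed = seed * 100 + 50 + i)))
    gene_alignments(mats)
  }
  # all genes on the transferred history: grid maximum
  fit <- optimize_new_gamma(net, arc, sim_genes(0, 20, 1))
  expect_equal(fit$gamma, 0.5)
  # all genes on the base history: grid minimum
  fit <- optimize_new_gamma(net, arc, sim_genes(20, 0, 2))
  expect_equal(fit$gamma, 0.05)
  # balanced: maximum at the 0.5 end of the grid
  fit <- optimize_new_gamma(net, arc, sim_genes(10, 10, 3))
  expect_equal(fit$gamma, 0.5)
  expect_error(optimize_new_gamma(net, arc, sim_genes(1, 1, 4),
                                  grid = numeric(0)), "empty")
})

test_that("augmenting a network never decreases the optimized likelihood", {
  ds <- simulate_hgt_dataset(diameter = 0.5, gamma = 0.3, k = 5,
                             sites = 60, ntaxa = 6, seed = 31)
  cache <- likelihood_cache()
  # fixed-length objective
  ll0 <- as.numeric(network_log_likelihood(
    as_phylo_network(ds$species_tree), ds$genes, cache = cache))
  step <- best_augmentation(ds$species_tree, ds$genes, cache = cache,
                            refine_top = 0)
  expect_gte(step$loglik, ll0)
  # refined (per-gene optimized) objective
  ll0_opt <- as.numeric(network_log_likelihood(
    as_phylo_network(ds$species_tree), ds$genes, cache = cache,
    optimize_branches = TRUE))
  step_r <- best_augmentation(ds$species_tree, ds$genes, cache = cache)
  expect_gte(step_r$loglik, ll0_opt)
})
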