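test_that("candidate enumeration matches an independent validity oracle", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  net <- as_phylo_network(tree)
  cand <- enumerate_additions(net)
  eid <- network_edge_ids(net)
  # oracle: explicit subdivision + igraph DAG check + sibling exclusion
  valid <- 0L
  for (i in seq_along(eid)) {
    for (j in seq_along(eid)) {
      if (i == j) next
      if (net$parent[i] == net$parent[j]) next
      df <- data.frame(
        from = c(net$parent[-c(i, j)], net$parent[i], "X1",
                 net$parent[j], "X2", "X1"),
        to = c(net$child[-c(i, j)], "X1", net$child[i],
               "X2", net$child[j], "X2"))
      if (igraph::is_dag(igraph::graph_from_data_frame(df))) {
        valid <- valid + 1L
        expect_true(any(cand$donor == eid[i] & cand$recipient == eid[j]))
      }
    }
  }
  expect_equal(nrow(cand), valid)
  expect_false(any(cand$donor == cand$recipient))
  # the two root-child edges are siblings and never paired
  rc <- eid[net$parent == net$root]
  expect_false(any(cand$donor == rc[1] & cand$recipient == rc[2]))
  expect_false(any(cand$donor == rc[2] & cand$recipient == rc[1]))
})

test_that("information-criterion arithmetic is exact", {
  sc <- model_score(loglik = -100, K = 10, n = 1000, h = 0)
  expect_equal(sc$AIC, 220)
  expect_equal(sc$BIC, 10 * log(1000) + 200)
})

test_that("sequential threshold selection follows the derived rules", {
  mk <- function(deltas, n) {
    list(scores = tibble::tibble(
      h = seq(0, length(deltas)), K = 10 + seq(0, length(deltas)),
      loglik = cumsum(c(-500, deltas)),
      delta_loglik = c(NA, deltas)), n = n)
  }
  # AIC accepts iff delta lnL > 1
  expect_equal(select_model(mk(c(1.5, 0.4), 400), "aic"), 1L)
  # BIC threshold ln(400)/2 ~ 2.996: both 3.0 and 3.2 pass
  expect_equal(select_model(mk(c(3.0, 3.2), 400), "bic"), 2L)
  # nothing passes either
  expect_equal(select_model(mk(c(0.5, 0.2, 0.1), 400), "aic"), 0L)
  expect_equal(select_model(mk(c(0.5, 0.2, 0.1), 400), "bic"), 0L)
  # boundaries are strict
  expect_equal(select_model(mk(c(1.0), 400), "aic"), 0L)
  expect_equal(select_model(mk(c(log(400) / 2), 400), "bic"), 0L)
  # a later passing step is unreachable after a failure
  expect_equal(select_model(mk(c(5, 0.1, 6), 400), "aic"), 1L)
  # BIC is never less conservative than AIC once ln(n)/2 >= 1
  set.seed(1)
  for (i in 1:20) {
    tr <- mk(runif(4, 0, 4), n = sample(8:5000, 1))
    expect_lte(select_model(tr, "bic"), select_model(tr, "aic"))
  }
  # global-minimum mode agrees on monotone-decay trajectories
  expect_equal(select_model(mk(c(3, 0.2), 400), "bic", mode = "global"),
               select_model(mk(c(3, 0.2), 400), "bic"))
})

test_that("best augmentation equals exhaustive (candidate, gamma) argmax", {
  ds <- simulate_hgt_dataset(diameter = 0.5, gamma = 0.5, k = 2,
                             sites = 40, ntaxa = 4, seed = 5,
                             donor = "t3", recipient = "t2")
  net <- as_phylo_network(ds$species_tree)
  grid <- gamma_grid()
  # independent driver: loop candidates x grid through the public
  # network likelihood, skipping unidentifiable (topology-neutral)
  # additions via the independent topology key
  oracle_argmax <- function(optimize) {
    cand <- enumerate_additions(net)
    base_key <- oracle_topo_key_phylo(ds$species_tree)
    best_ll <- -Inf; best_pair <- NULL; best_g <- NA
    for (ci in seq_len(nrow(cand))) {
      n2 <- add_reticulation(net, cand$donor[ci], cand$recipient[ci],
                             gamma = 0.25)
      if (oracle_topo_key_phylo(transferred_tree(n2)) == base_key) next
      for (g in grid) {
        n2 <- add_reticulation(net, cand$donor[ci], cand$recipient[ci],
                               gamma = g)
        ll <- as.numeric(network_log_likelihood(
          n2, ds$genes, optimize_branches = optimize))
        if (ll > best_ll) {
          best_ll <- ll; best_pair <- cand[ci, ]; best_g <- g
        }
      }
    }
    list(ll = best_ll, pair = best_pair, g = best_g)
  }
  # fixed-length pass: deterministic, must agree exactly
  step0 <- best_augmentation(net, ds$genes, grid = grid, refine_top = 0)
  or0 <- oracle_argmax(optimize = FALSE)
  expect_equal(step0$loglik, or0$ll, tolerance = 1e-9)
  expect_equal(step0$donor, or0$pair$donor)
  expect_equal(step0$recipient, or0$pair$recipient)
  expect_equal(step0$gamma, or0$g)
  # refined pass: scores defined up to the branch optimizer's
  # convergence tolerance, so the achieved maxima must agree within it
  # (distinct candidates can tie at that resolution)
  step1 <- best_augmentation(net, ds$genes, grid = grid, refine_top = Inf)
  or1 <- oracle_argmax(optimize = TRUE)
  expect_equal(step1$loglik, or1$ll, tolerance = 1e-4)
})

test_that("forward search trajectories are monotone and selectable", {
  ds <- simulate_hgt_dataset(diameter = 0.5, gamma = 0.5, k = 4,
                             sites = 60, ntaxa = 6, seed = 8,
                             donor = "t3", recipient = "t2")
  # h_max = 0: just the start tree
  fit0 <- forward_search(ds$species_tree, ds$genes, h_max = 0)
  expect_equal(nrow(fit0$scores), 1L)
  expect_equal(fit0$selected$bic, 0L)
  fit <- forward_search(ds$species_tree, ds$genes, h_max = 2)
  # the first, signal-bearing step must improve the fit; later steps can
  # dip very slightly below zero because the inheritance-probability
  # grid is bounded away from 0 (an unwanted edge cannot be switched off
  # entirely)
  expect_gt(fit$scores$delta_loglik[2], 0)
  expect_true(all(diff(fit$scores$loglik) >= -1))
  expect_equal(fit$scores$K, c(10, 13, 16))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1L)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  # searches are reproducible: same data, same trajectory
  fit2 <- forward_search(ds$species_tree, ds$genes, h_max = 2)
  expect_identical(tidy(fit), tidy(fit2))
})
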