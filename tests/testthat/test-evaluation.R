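# Simulated data in this file is kept small (few taxa/genes) so the
# drivers' logic is exercised quickly; the full study conditions run in
# test-acceptance.R.

test_that("falsely postulated reticulations lose likelihood with diameter", {
  ser <- diameter_series()
  mats <- lapply(1:60, function(i)
    simulate_alignment(ser$tree, 100, seed = 1000 + i))
  genes <- gene_alignments(mats)
  # a diameter-0 "variant" (the true tree itself) scores exactly zero
  variants <- c(list(list(tree = ser$tree, diameter = 0, height = 0)),
                ser$variants)
  res <- diameter_effect_study(ser$tree, variants, genes)
  expect_equal(res$mean_delta[1], 0, tolerance = 1e-12)
  expect_true(all(res$mean_delta[-1] < 0))
  # mean delta lnL strictly decreases as the diameter grows
  expect_true(all(diff(res$mean_delta) < 0))
})

test_that("height affects the likelihood much less than diameter", {
  # same-diameter transfers at different depths of the caterpillar:
  # the event height varies, the diameter stays fixed at two internal
  # branches; compare against the diameter series on the same tree
  tree <- make_species_tree(16, pendant = 0.05, internal = 0.1)
  net <- as_phylo_network(tree)
  # edge into the caterpillar node whose clade is {t1..tk}
  spine_edge <- function(k) {
    kids <- split(net$child, net$parent)
    clade <- function(v) {
      if (!v %in% names(kids)) return(v)
      sort(unlist(lapply(kids[[v]], clade)))
    }
    nodes <- unique(net$parent)
    hit <- nodes[vapply(nodes, function(v)
      identical(clade(v), sort(sprintf("t%d", 1:k))), TRUE)]
    network_edge_ids(net)[net$child == hit]
  }
  heights <- lapply(c(4, 7, 10, 13), function(k) {
    hgt_variant(tree, spine_edge(k), spine_edge(k - 2))
  })
  expect_equal(length(unique(vapply(heights, `[[`, 0, "diameter"))), 1L)
  hh <- vapply(heights, `[[`, 0, "height")
  expect_true(all(diff(hh) != 0))
  mats <- lapply(1:60, function(i)
    simulate_alignment(tree, 100, seed = 2000 + i))
  genes <- gene_alignments(mats)
  hres <- height_effect_study(tree, heights, genes)
  expect_true(all(hres$mean_delta < 0))
  ser <- diameter_series()
  dres <- diameter_effect_study(tree, ser$variants, genes)
  # spread attributable to height is small next to the diameter effect
  expect_lt(diff(range(hres$mean_delta)), diff(range(dres$mean_delta)) / 2)
})

test_that("placement driver recovers a strongly supported transfer", {
  ds <- simulate_hgt_dataset(diameter = 0.5, gamma = 0.5, k = 8,
                             sites = 100, ntaxa = 8, seed = 41,
                             donor = "t3", recipient = "t2")
  res <- placement_experiment(ds)
  expect_equal(res$rf, 0L)
  expect_false(res$degenerate)
  expect_true(res$gamma_hat %in% gamma_grid())
  expect_true(res$rf %% 2 == 0)
})

test_that("gamma estimation with fixed placement tracks the gene partition", {
  ds <- simulate_hgt_dataset(diameter = 1.5, gamma = 0.3, k = 20,
                             sites = 100, ntaxa = 10, seed = 42,
                             donor = "t3", recipient = "t8")
  est <- gamma_estimation_experiment(ds)
  expect_true(abs(est$gamma_hat - 0.3) <= 0.1)
  # no reticulate signal at all: estimate collapses to the grid minimum
  null <- simulate_null_dataset(k = 10, sites = 100, ntaxa = 10, seed = 43)
  net0 <- as_phylo_network(null$species_tree)
  net <- add_reticulation(net0, pendant_edge(net0, "t3"),
                          pendant_edge(net0, "t8"), gamma = 0.3)
  fit <- optimize_new_gamma(net, network_edge_ids(net)[net$transfer],
                            null$genes)
  expect_equal(fit$gamma, 0.05)
})

test_that("model-selection driver tabulates improvements per replicate", {
  res <- model_selection_experiment(k = 4, replicates = 2, h_max = 2,
                                    seed = 7, sites = 50, ntaxa = 6)
  expect_equal(nrow(res), 2L)
  expect_equal(res$true_h, c(0L, 0L))
  expect_true(all(lengths(res$delta_loglik) == 2L))
  expect_true(all(res$h_bic <= res$h_aic))
  # a strongly supported planted reticulation is retained by BIC
  res1 <- model_selection_experiment(k = 8, replicates = 2, h_max = 2,
                                     seed = 7, diameter = 1.0, gamma = 0.5,
                                     sites = 100, ntaxa = 10)
  expect_equal(res1$true_h, c(1L, 1L))
  expect_true(all(res1$h_bic >= 1L))
  expect_true(all(res1$h_aic >= res1$h_bic))
})

test_that("the pipeline wrapper produces self-describing run directories", {
  dir <- withr::local_tempdir()
  run_pipeline("simulate",
               list(diameter = 0.5, gamma = 0.3, k = 3, sites = 30,
                    ntaxa = 6, seed = 5),
               file.path(dir, "sim"))
  expect_true(file.exists(file.path(dir, "sim", "config.json")))
  expect_true(file.exists(file.path(dir, "sim", "genes", "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "sim", "truth.tsv")))
  run_pipeline("search",
               list(tree = file.path(dir, "sim", "species_tree.nwk"),
                    genes = file.path(dir, "sim", "genes", "manifest.tsv"),
                    h_max = 1, seed = 5),
               file.path(dir, "run"))
  traj <- jsonlite::read_json(file.path(dir, "run", "trajectory.json"))
  expect_length(traj$scores, 2L)
  expect_true(file.exists(file.path(dir, "run", "network_h1.enwk")))
  net <- read_phylogeny(file.path(dir, "run", "network_h1.enwk"))
  expect_identical(validate_network(net), character(0))
  # reruns are byte-identical
  run_pipeline("simulate",
               list(diameter = 0.5, gamma = 0.3, k = 3, sites = 30,
                    ntaxa = 6, seed = 5),
               file.path(dir, "sim2"))
  f1 <- readLines(file.path(dir, "sim", "genes", "gene1.fasta"))
  f2 <- readLines(file.path(dir, "sim2", "genes", "gene1.fasta"))
  expect_identical(f1, f2)
  expect_error(run_pipeline("evaluate", list(study = "bogus"),
                            file.path(dir, "bad")),
               "unknown study")
})
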