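# -------------------------------------------------------------------------
# Experiment drivers: placement accuracy (RF between true and inferred
# transferred gene trees), inheritance-probability recovery with the
# placement fixed, model selection on reticulation-free data, and the
# effect of reticulation diameter/height on falsely postulated events.
# -------------------------------------------------------------------------

#' Placement accuracy for one simulated data set
#'
#' Runs one forward-selection step ([best_augmentation()]) from the true
#' species tree on a data set with a single planted reticulation, and
#' quantifies placement accuracy as the Robinson-Foulds distance between
#' the alternate tree displayed by the inferred network and the true
#' transferred gene tree; 0 means the placement was recovered. The
#' estimated inheritance probability of the inferred edge is recorded
#' too. If the inferred network displays only one distinct topology
#' (degenerate attachment), the RF is computed against the base tree and
#' the result flagged.
#'
#' @param dataset Output of [simulate_hgt_dataset()] /
#'   [simulate_bundle()].
#' @param grid Inheritance-probability grid.
#' @param tstv Transition/transversion ratio.
#' @param cache Optional [likelihood_cache()].
#' @param fit_lengths Fit the species tree's branch lengths on the
#'   pooled genes before the search step (default `TRUE`; see
#'   [fit_branch_lengths()]).
#' @return One-row tibble: `rf`, `gamma_hat`, `donor`, `recipient`,
#'   `loglik`, `degenerate`.
#' @export
placement_experiment <- function(dataset, grid = gamma_grid(), tstv = 2,
                                 cache = likelihood_cache(),
                                 fit_lengths = TRUE) {
  start <- dataset$species_tree
  if (fit_lengths) start <- fit_branch_lengths(start, dataset$genes, tstv)
  step <- best_augmentation(start, dataset$genes, grid, tstv, cache)
  alt <- transferred_tree(step$network)
  base <- base_tree(step$network)
  degenerate <- rf_distance(alt, base) == 0
  cmp <- if (degenerate) base else alt
  tibble::tibble(
    rf = rf_distance(cmp, dataset$transferred_tree),
    gamma_hat = step$gamma,
    donor = step$donor, recipient = step$recipient,
    loglik = step$loglik,
    degenerate = degenerate)
}

#' Inheritance-probability estimation with the placement fixed
#'
#' Assumes the correct placement of the planted reticulation edge and
#' infers only its inheritance probability by grid search on the network
#' likelihood.
#'
#' @inheritParams placement_experiment
#' @return One-row tibble with `gamma_hat` and `loglik`.
#' @export
gamma_estimation_experiment <- function(dataset, grid = gamma_grid(),
                                        tstv = 2,
                                        cache = likelihood_cache()) {
  fit <- optimize_new_gamma(dataset$network, dataset$arc, dataset$genes,
                            grid, tstv, cache)
  tibble::tibble(gamma_hat = fit$gamma, loglik = fit$loglik)
}

#' Placement study over replicates
#'
#' Simulates `replicates` data sets at one (diameter, gamma, genome size)
#' condition and runs [placement_experiment()] on each.
#'
#' @param diameter,gamma,k Condition (see [simulate_hgt_dataset()]).
#' @param replicates Number of replicates.
#' @param seed Master seed (per-replicate seeds are derived substreams).
#' @param sites,tstv,ntaxa Simulation parameters.
#' @param grid Inheritance-probability grid.
#' @return Tibble with one row per replicate (`rep`, condition columns,
#'   and the [placement_experiment()] outputs).
#' @export
run_placement_study <- function(diameter, gamma, k, replicates = 20,
                                seed = 1, sites = 100, tstv = 2,
                                ntaxa = 16, grid = gamma_grid()) {
  rows <- lapply(seq_len(replicates), function(r) {
    ds <- simulate_hgt_dataset(diameter, gamma, k, sites, tstv, ntaxa,
                               seed = substream_seed(seed, "placement",
                                                     diameter, gamma, k, r))
    out <- placement_experiment(ds, grid, tstv)
    out$rep <- r
    out
  })
  res <- do.call(rbind, rows)
  res$diameter <- diameter; res$gamma <- gamma; res$k <- as.integer(k)
  res[, c("rep", "diameter", "gamma", "k", "rf", "gamma_hat", "donor",
          "recipient", "loglik", "degenerate")]
}

#' Inheritance-probability study over replicates
#'
#' As [run_placement_study()] but with the true placement fixed
#' ([gamma_estimation_experiment()]); only gamma is estimated.
#'
#' @inheritParams run_placement_study
#' @return Tibble with one row per replicate.
#' @export
run_gamma_study <- function(diameter, gamma, k, replicates = 20, seed = 1,
                            sites = 100, tstv = 2, ntaxa = 16,
                            grid = gamma_grid()) {
  rows <- lapply(seq_len(replicates), function(r) {
    ds <- simulate_hgt_dataset(diameter, gamma, k, sites, tstv, ntaxa,
                               seed = substream_seed(seed, "gammafix",
                                                     diameter, gamma, k, r))
    out <- gamma_estimation_experiment(ds, grid, tstv)
    out$rep <- r
    out
  })
  res <- do.call(rbind, rows)
  res$diameter <- diameter; res$gamma <- gamma; res$k <- as.integer(k)
  res[, c("rep", "diameter", "gamma", "k", "gamma_hat", "loglik")]
}

#' Model selection on data with a known number of reticulations
#'
#' Simulates data sets with a known true reticulation count (0 by
#' default, or 1 when a planted `diameter`/`gamma` is given), runs the
#' forward search to `h_max`, and tabulates the reticulation number
#' selected under AIC and BIC together with the per-step log-likelihood
#' improvements.
#'
#' @param k Genome size (number of genes) per replicate.
#' @param replicates Number of replicates.
#' @param h_max Levels searched (default 4).
#' @param seed Master seed.
#' @param diameter,gamma When non-`NULL`, each replicate carries one
#'   planted reticulation with these parameters (true h = 1); otherwise
#'   the data are reticulation-free (true h = 0).
#' @param sites,tstv,ntaxa Simulation parameters.
#' @param grid Inheritance-probability grid.
#' @return Tibble with one row per replicate: `true_h`, `h_aic`,
#'   `h_bic`, and `delta_loglik` (list column of per-step improvements).
#' @export
model_selection_experiment <- function(k, replicates = 20, h_max = 4,
                                       seed = 1, diameter = NULL,
                                       gamma = NULL, sites = 100, tstv = 2,
                                       ntaxa = 16, grid = gamma_grid()) {
  planted <- !is.null(diameter)
  rows <- lapply(seq_len(replicates), function(r) {
    ds <- if (planted) {
      simulate_hgt_dataset(diameter, gamma, k, sites, tstv, ntaxa,
                           seed = substream_seed(seed, "sel1", diameter,
                                                 gamma, k, r))
    } else {
      simulate_null_dataset(k, sites, tstv, ntaxa,
                            seed = substream_seed(seed, "null", k, r))
    }
    fit <- forward_search(ds$species_tree, ds$genes, h_max = h_max,
                          grid = grid, tstv = tstv)
    tibble::tibble(rep = r, k = as.integer(k),
                   true_h = as.integer(planted),
                   h_aic = fit$selected$aic, h_bic = fit$selected$bic,
                   delta_loglik = list(fit$scores$delta_loglik[-1]))
  })
  do.call(rbind, rows)
}

#' Single-reticulation variant tree of a species tree
#'
#' Builds the gene tree that a falsely postulated reticulation between
#' two edges would imply (the alternate displayed tree of the
#' single-reticulation network on that edge pair), recording the event's
#' diameter and height.
#'
#' @param tree Species tree ([ape::phylo]).
#' @param donor,recipient Edge ids on `as_phylo_network(tree)`.
#' @return A list with `tree` ([ape::phylo]), `diameter`, `height`.
#' @export
hgt_variant <- function(tree, donor, recipient) {
  net <- add_reticulation(as_phylo_network(tree), donor, recipient,
                          gamma = 0.5)
  arc <- network_edge_ids(net)[net$transfer]
  geom <- reticulation_geometry(net, arc)
  list(tree = transferred_tree(net), diameter = geom$diameter,
       height = geom$height)
}

#' Effect of a falsely postulated reticulation on the likelihood
#'
#' For genes simulated on the true tree, computes the mean over genes of
#' `ln P(S_i | T') - ln P(S_i | T)` for each variant tree `T'` implying a
#' single reticulation event, with the event's diameter and height
#' attached. Negative means the variant explains the data worse than the
#' truth; the decline steepens with the event's diameter.
#'
#' @param tree The true species tree the genes evolved on.
#' @param variants List of [hgt_variant()] results.
#' @param genes A `gene_alignments` simulated on `tree`.
#' @param tstv Transition/transversion ratio.
#' @return Tibble with one row per variant: `diameter`, `height`,
#'   `mean_delta` (mean per-gene log-likelihood difference).
#' @export
diameter_effect_study <- function(tree, variants, genes, tstv = 2) {
  ll_true <- dtree_gene_loglik(phylo_to_dtree(tree), genes, tstv)
  rows <- lapply(variants, function(v) {
    ll_var <- dtree_gene_loglik(phylo_to_dtree(v$tree), genes, tstv)
    tibble::tibble(diameter = v$diameter, height = v$height,
                   mean_delta = mean(ll_var - ll_true))
  })
  do.call(rbind, rows)
}

#' @rdname diameter_effect_study
#' @export
height_effect_study <- diameter_effect_study

#' Diameter-series variants on the diameter-study caterpillar
#'
#' The 16-taxon caterpillar used for the diameter study (pendant branches
#' 0.05, internal branches 0.1) with the fixed-donor series: HGT edges
#' from taxon `t1` to taxa `t3..t8`, whose diameters are exactly
#' 0.15, 0.25, ..., 0.65.
#'
#' @param ntaxa Number of taxa (default 16).
#' @param donor Donor taxon (default `"t1"`).
#' @param recipients Recipient taxa (default `t3..t8`).
#' @return A list with `tree` (the species tree) and `variants` (list of
#'   [hgt_variant()] results, in recipient order).
#' @export
diameter_series <- function(ntaxa = 16, donor = "t1",
                            recipients = sprintf("t%d", 3:8)) {
  tree <- make_species_tree(ntaxa, pendant = 0.05, internal = 0.1)
  net <- as_phylo_network(tree)
  variants <- lapply(recipients, function(r)
    hgt_variant(tree, pendant_edge(net, donor), pendant_edge(net, r)))
  list(tree = tree, variants = variants)
}
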