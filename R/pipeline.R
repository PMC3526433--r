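# -------------------------------------------------------------------------
# Run-level plumbing: a reproducible pipeline wrapper used by the
# command-line script (inst/cli/phynetml). Every run directory is
# self-describing: the configuration (with its master seed) is echoed as
# JSON next to the outputs, so any stage can be reproduced byte-for-byte.
# -------------------------------------------------------------------------

#' Run a simulate / search / evaluate pipeline stage
#'
#' A thin reproducibility wrapper over the package functions. Supported
#' stages:
#' \describe{
#'   \item{`simulate`}{writes per-gene FASTA files, a manifest TSV, the
#'     species tree (Newick), the planted network (eNewick) and the truth
#'     table of a seeded HGT data set into `out_dir`.}
#'   \item{`likelihood`}{reads a tree or network and a gene manifest and
#'     writes the per-gene displayed-tree log-likelihood table
#'     (`gene_id`, `tree_id`, `lnL`) plus a JSON summary with the total
#'     network log-likelihood.}
#'   \item{`search`}{reads a start tree and a gene manifest, runs
#'     [forward_search()], and writes the trajectory (JSON + TSV) and the
#'     per-h networks (eNewick).}
#'   \item{`evaluate`}{runs one of the study drivers (`placement`,
#'     `gamma`, `selection`, `diameter`) and writes its table as TSV.}
#' }
#'
#' @param stage One of `"simulate"`, `"search"`, `"evaluate"`.
#' @param config Named list of stage parameters (see the stage functions
#'   for names; e.g. `diameter`, `gamma`, `k`, `seed` for `simulate`;
#'   `tree`, `genes`, `h_max`, `criterion` for `search`; `study` plus the
#'   study's parameters for `evaluate`).
#' @param out_dir Output directory (created).
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(stage = c("simulate", "likelihood", "search",
                                   "evaluate"),
                         config = list(), out_dir) {
  stage <- match.arg(stage)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- c(list(stage = stage), config)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  get_ <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  if (stage == "simulate") {
    ds <- simulate_hgt_dataset(
      diameter = get_("diameter", 0.5), gamma = get_("gamma", 0.3),
      k = get_("k", 10), sites = get_("sites", 100),
      tstv = get_("tstv", 2), ntaxa = get_("ntaxa", 16),
      seed = get_("seed", 1))
    write_gene_alignments(ds$genes, file.path(out_dir, "genes"))
    ape::write.tree(ds$species_tree, file.path(out_dir, "species_tree.nwk"))
    write_network(ds$network, file.path(out_dir, "network.enwk"))
    ape::write.tree(ds$transferred_tree,
                    file.path(out_dir, "transferred_tree.nwk"))
    truth <- ds$truth
    truth$transferred_genes <- vapply(truth$transferred_genes,
                                      paste, "", collapse = ",")
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else if (stage == "likelihood") {
    obj <- read_phylogeny(config$tree)
    net <- as_phylo_network(obj)
    genes <- read_gene_alignments(config$genes)
    dt <- displayed_trees(net)
    rows <- do.call(rbind, lapply(seq_len(nrow(dt)), function(i) {
      lnl <- vapply(seq_len(genes$k), function(g)
        tree_log_likelihood(dt$tree[[i]], genes[g], tstv = get_("tstv", 2)),
        0)
      data.frame(gene_id = genes$gene_names,
                 tree_id = sprintf("T%d", i), lnL = lnl)
    }))
    utils::write.table(rows, file.path(out_dir, "likelihoods.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(network_loglik =
             as.numeric(network_log_likelihood(net, genes,
                                               tstv = get_("tstv", 2))),
           displayed_trees = nrow(dt), n = genes$n, k = genes$k),
      file.path(out_dir, "likelihood_summary.json"),
      auto_unbox = TRUE, digits = NA)
  } else if (stage == "search") {
    tree <- read_phylogeny(config$tree)
    genes <- read_gene_alignments(config$genes)
    fit <- forward_search(tree, genes, h_max = get_("h_max", 1),
                          grid = get_("grid", gamma_grid()),
                          tstv = get_("tstv", 2))
    utils::write.table(tidy(fit), file.path(out_dir, "trajectory.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(seed = get_("seed", NULL), n = fit$n,
           scores = tidy(fit), selected = fit$selected),
      file.path(out_dir, "trajectory.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    for (i in seq_along(fit$networks)) {
      write_network(fit$networks[[i]],
                    file.path(out_dir, sprintf("network_h%d.enwk", i - 1L)))
    }
  } else {
    study <- get_("study", "placement")
    res <- switch(study,
      placement = run_placement_study(
        get_("diameter", 0.5), get_("gamma", 0.3), get_("k", 10),
        replicates = get_("replicates", 20), seed = get_("seed", 1)),
      gamma = run_gamma_study(
        get_("diameter", 1.5), get_("gamma", 0.3), get_("k", 10),
        replicates = get_("replicates", 20), seed = get_("seed", 1)),
      selection = model_selection_experiment(
        get_("k", 10), replicates = get_("replicates", 20),
        h_max = get_("h_max", 4), seed = get_("seed", 1)),
      diameter = {
        ser <- diameter_series()
        seed <- get_("seed", 1)
        mats <- lapply(seq_len(get_("k", 100)), function(i)
          simulate_alignment(ser$tree, get_("sites", 100),
                             seed = substream_seed(seed, "diamgene", i)))
        diameter_effect_study(ser$tree, ser$variants, gene_alignments(mats))
      },
      stop("unknown study '", study, "'"))
    if ("delta_loglik" %in% names(res)) {
      res$delta_loglik <- vapply(res$delta_loglik, paste, "",
                                 collapse = ",")
    }
    utils::write.table(res, file.path(out_dir, paste0(study, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
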