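# -------------------------------------------------------------------------
# Tree and network likelihoods.
#
# The network likelihood is the mixture over displayed trees
#   L(N, gamma | S) = prod_i sum_{T in T(N)} P(S_i | T) P(T | N, gamma),
# evaluated per gene on the log scale with log-sum-exp. P(S_i | T) is the
# Felsenstein pruning likelihood under K80 with uniform root frequencies;
# by default branch lengths are the ones induced from the network (merged
# subdivision halves sum), with an optional per-branch ML optimization
# mode (Brent sweeps) emulating dnaml-style re-estimation.
#
# Per-gene tree log-likelihoods are cached by (tree hash, model,
# alignment id); candidate networks examined during the search share most
# of their displayed trees, which makes the cache the main cost saver.
# -------------------------------------------------------------------------

# convert a dtree (character-id edge lists) to integer arrays for the
# C kernel, relative to a fixed taxa ordering (rows of the pattern matrix)
dtree_arrays <- function(tr, taxa) {
  nodes <- unique(c(tr$root, tr$parent, tr$child))
  nid <- stats::setNames(seq_along(nodes), nodes)
  parent_i <- nid[tr$parent]; child_i <- nid[tr$child]
  nnode <- length(nodes)
  tiprow <- integer(nnode)
  leaf <- setdiff(tr$child, tr$parent)
  tiprow[nid[leaf]] <- match(leaf, taxa)
  if (anyNA(tiprow[nid[leaf]])) stop("tree taxa not found in alignment")
  # postorder edge ordering (recursive; trees are small)
  kids <- split(seq_along(tr$parent), parent_i)
  order <- integer(0)
  rec <- function(v) {
    ks <- kids[[as.character(v)]]
    if (is.null(ks)) return(invisible())
    for (e in ks) {
      rec(child_i[[e]])
      order[[length(order) + 1L]] <<- e
    }
  }
  rec(nid[[tr$root]])
  list(edge = cbind(parent_i[order], child_i[order]),
       lengths = tr$length[order],
       nnode = nnode, tiprow = tiprow, root = nid[[tr$root]])
}

# per-gene log-likelihood vector for one displayed tree over a
# gene_alignments object (all genes in one C call)
dtree_gene_loglik <- function(tr, genes, tstv = 2) {
  arr <- dtree_arrays(tr, genes$taxa)
  pv <- k80_probs(arr$lengths, tstv)
  logs <- pruning_pattern_loglik(arr$edge, pv, arr$nnode, arr$tiprow,
                                 genes$patT, arr$root)
  as.numeric(rowsum(logs[genes$w_pat] * genes$w_cnt, genes$w_gene,
                    reorder = TRUE))
}

#' Likelihood cache
#'
#' Creates an empty cache for per-gene tree log-likelihoods, keyed by
#' tree hash, substitution-model parameters and alignment fingerprint.
#' Pass the same cache to repeated [network_log_likelihood()] /
#' [forward_search()] calls on the same data to re-use displayed-tree
#' scores across candidate networks.
#'
#' @return An environment usable as the `cache` argument of the
#'   likelihood and search functions.
#' @export
likelihood_cache <- function() new.env(parent = emptyenv())

cached_tree_loglik <- function(tr, hash, genes, tstv, cache,
                               optimize_branches = FALSE) {
  key <- paste0(if (optimize_branches)
    dtree_hash(tr, with_lengths = FALSE, rooted = FALSE) else hash,
    "|", tstv, "|", optimize_branches, "|", genes$id)
  if (!is.null(cache)) {
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  val <- if (optimize_branches) {
    dtree_gene_loglik_opt(tr, genes, tstv)
  } else {
    dtree_gene_loglik(tr, genes, tstv)
  }
  if (!is.null(cache)) cache[[key]] <- val
  val
}

# pattern-row indices and multiplicities of one gene within the global
# pattern table
gene_pattern_sel <- function(genes, g) {
  i <- genes$w_gene == g
  list(sel = genes$w_pat[i], wt = genes$w_cnt[i])
}

# per-branch ML optimization (C coordinate ascent with partial-likelihood
# profiling) of one tree on one gene; returns loglik and fitted lengths
optimize_dtree_branches <- function(tr, gene, tstv = 2, max_sweeps = 4,
                                    iters = 18) {
  arr <- dtree_arrays(tr, gene$taxa)
  r <- k80_rates(tstv)
  ps <- gene_pattern_sel(gene, 1L)
  pruning_optimize_branches(arr$edge, arr$lengths, arr$nnode, arr$tiprow,
                            gene$patT, ps$sel, ps$wt, arr$root,
                            r$alpha, r$beta, max_sweeps, iters)
}

# per-gene branch-length-optimized log-likelihoods of one tree (the
# dnaml-style tree score: every gene re-fits every branch)
dtree_gene_loglik_opt <- function(tr, genes, tstv = 2, sweeps = 2,
                                  iters = 14) {
  arr <- dtree_arrays(tr, genes$taxa)
  r <- k80_rates(tstv)
  vapply(seq_len(genes$k), function(g) {
    ps <- gene_pattern_sel(genes, g)
    pruning_optimize_branches(arr$edge, arr$lengths, arr$nnode,
                              arr$tiprow, genes$patT, ps$sel, ps$wt,
                              arr$root, r$alpha, r$beta, sweeps,
                              iters)$loglik
  }, 0)
}

#' Tree log-likelihood under K80
#'
#' Felsenstein-pruning log-likelihood `ln P(S | T)` of a single gene
#' alignment on a rooted binary tree, with uniform root base frequencies.
#' Ambiguous bases and gaps contribute all-ones partial likelihoods
#' (missing data). With `optimize_branches = TRUE` the branch lengths are
#' re-estimated by per-branch Brent sweeps before scoring.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param alignment A single gene: character matrix, named character
#'   vector, or a `gene_alignments` object with `k = 1`.
#' @param tstv Transition/transversion ratio (default 2).
#' @param optimize_branches Re-estimate branch lengths by maximum
#'   likelihood before scoring (default `FALSE`).
#' @return Log-likelihood in nats (a single number).
#' @export
tree_log_likelihood <- function(tree, alignment, tstv = 2,
                                optimize_branches = FALSE) {
  if (!inherits(alignment, "gene_alignments")) {
    alignment <- gene_alignments(list(alignment))
  }
  if (alignment$k != 1L) stop("supply a single gene (use network_log_likelihood for sets)")
  tr <- if (inherits(tree, "phylo")) phylo_to_dtree(tree) else tree
  if (!setequal(setdiff(tr$child, tr$parent), alignment$taxa)) {
    stop("alignment taxa do not match tree leaves", call. = FALSE)
  }
  if (optimize_branches) {
    optimize_dtree_branches(tr, alignment, tstv)$loglik
  } else {
    sum(dtree_gene_loglik(tr, alignment, tstv))
  }
}

#' Fit branch lengths of a tree by maximum likelihood
#'
#' Optimizes every branch length of a fixed topology on the concatenated
#' gene data (all sites pooled) by per-branch Brent sweeps under K80.
#' This is the standard preparation of a start tree whose input lengths
#' are not trusted: the forward network search scores candidates at
#' lengths induced from its start tree, so fitting them first ensures no
#' candidate can profit from branch-length misfit instead of reticulate
#' signal.
#'
#' @param tree An [ape::phylo] tree with (initial) branch lengths.
#' @param genes A `gene_alignments` object on the tree's taxa.
#' @param tstv Transition/transversion ratio (default 2).
#' @param max_sweeps Maximum coordinate-ascent passes over all branches
#'   (default 10; sweeps stop early once a pass gains under 0.001 nats).
#' @return The tree with optimized branch lengths.
#' @export
fit_branch_lengths <- function(tree, genes, tstv = 2, max_sweeps = 10) {
  if (!inherits(genes, "gene_alignments")) genes <- gene_alignments(genes)
  tr <- phylo_to_dtree(tree)
  arr <- dtree_arrays(tr, genes$taxa)
  # pooled per-pattern weights over all genes
  wtot <- numeric(nrow(genes$patT))
  agg <- rowsum(genes$w_cnt, genes$w_pat)
  wtot[as.integer(rownames(agg))] <- agg[, 1]
  r <- k80_rates(tstv)
  fit <- pruning_optimize_branches(arr$edge, arr$lengths, arr$nnode,
                                   arr$tiprow, genes$patT,
                                   seq_len(nrow(genes$patT)), wtot,
                                   arr$root, r$alpha, r$beta,
                                   max_sweeps, 25L)
  lens <- fit$lengths
  # write the fitted lengths back onto the phylo edges
  out <- tree
  net <- as_phylo_network(tree)
  key_fit <- paste(arr$edge[, 1], arr$edge[, 2])
  # map phylo edges -> dtree edges via node ids
  nodes <- unique(c(tr$root, tr$parent, tr$child))
  nid <- stats::setNames(seq_along(nodes), nodes)
  key_net <- paste(nid[net$parent], nid[net$child])
  m <- match(key_net, key_fit)
  fitted <- lens[m]
  # as_phylo_network preserves the phylo edge order
  out$edge.length <- fitted
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Network log-likelihood
#'
#' Evaluates the mixture likelihood of a phylogenetic network over a
#' multi-gene alignment set: for every gene, the displayed-tree
#' likelihoods are combined with weights `P(T | N, gamma)` via
#' log-sum-exp, and the per-gene log-likelihoods are summed.
#'
#' @param net A `phylo_network` (or a tree).
#' @param genes A `gene_alignments` object.
#' @param tstv Transition/transversion ratio (default 2).
#' @param cache Optional [likelihood_cache()] shared across calls.
#' @param optimize_branches Re-estimate branch lengths of every displayed
#'   tree per gene (slow; default `FALSE` uses the lengths induced from
#'   the network).
#' @return Total log-likelihood (nats), with attribute `by_gene` holding
#'   the per-gene log-likelihood vector.
#' @export
network_log_likelihood <- function(net, genes, tstv = 2, cache = NULL,
                                   optimize_branches = FALSE) {
  net <- as_phylo_network(net)
  stop_if_invalid(net)
  if (!inherits(genes, "gene_alignments")) genes <- gene_alignments(genes)
  if (!setequal(network_leaves(net), genes$taxa)) {
    stop("alignment taxa do not match network leaves", call. = FALSE)
  }
  combos <- display_combos(net)
  mix_loglik(combos, vapply(combos, `[[`, 0, "weight"), genes, tstv, cache,
             optimize_branches)
}

# shared mixture evaluation: combos (with trees + hashes), weights
mix_loglik <- function(combos, weights, genes, tstv, cache,
                       optimize_branches = FALSE) {
  if (all(weights <= 0)) stop("all displayed-tree probabilities are zero")
  ll <- matrix(-Inf, nrow = genes$k, ncol = length(combos))
  for (j in seq_along(combos)) {
    if (weights[j] <= 0) next
    ll[, j] <- cached_tree_loglik(combos[[j]]$tree, combos[[j]]$hash_topo,
                                  genes, tstv, cache, optimize_branches)
  }
  lw <- log(weights)
  per_gene <- vapply(seq_len(genes$k), function(i) {
    logsumexp(ll[i, ] + lw)
  }, 0)
  structure(sum(per_gene), by_gene = per_gene)
}

#' Optimize the inheritance probability of one reticulation edge
#'
#' Grid search over candidate inheritance probabilities for a single
#' reticulation arc, holding the rest of the network (including the gamma
#' values of any other reticulation edges) fixed, as in the incremental
#' forward-selection step. Ties are broken toward the smaller gamma.
#'
#' @param net A `phylo_network` containing the arc.
#' @param arc Edge id of the reticulation arc whose gamma is optimized.
#' @param genes A `gene_alignments` object.
#' @param grid Ascending vector of candidate probabilities
#'   (default [gamma_grid()]).
#' @param tstv Transition/transversion ratio.
#' @param cache Optional [likelihood_cache()].
#' @param optimize_branches Passed to the tree likelihoods.
#' @return A list with `gamma` (the maximizer), `loglik`, and
#'   `profile` (a tibble of the grid and its log-likelihoods).
#' @export
optimize_new_gamma <- function(net, arc, genes, grid = gamma_grid(),
                               tstv = 2, cache = NULL,
                               optimize_branches = FALSE) {
  if (!length(grid)) stop("empty gamma grid", call. = FALSE)
  net <- as_phylo_network(net)
  i <- edge_index(net, arc)
  if (!is_reticulation_edge(net)[i]) {
    stop("'", arc, "' is not a reticulation edge", call. = FALSE)
  }
  rnode <- net$child[i]
  partner <- setdiff(which(net$child == rnode), i)
  combos <- display_combos(net)
  arc_id <- network_edge_ids(net)[i]
  uses_arc <- vapply(combos, function(cb) arc_id %in% cb$choice, TRUE)
  # weight of the other reticulation choices (divide out this node's factor)
  g0 <- net$gamma[i]; g0p <- net$gamma[partner]
  base_w <- vapply(seq_along(combos), function(j)
    combos[[j]]$weight / (if (uses_arc[j]) g0 else g0p), 0)
  lls <- vapply(grid, function(g) {
    w <- base_w * ifelse(uses_arc, g, 1 - g)
    as.numeric(mix_loglik(combos, w, genes, tstv, cache, optimize_branches))
  }, 0)
  best <- which.max(lls)  # first maximum = smallest gamma on ties
  list(gamma = grid[best], loglik = lls[best],
       profile = tibble::tibble(gamma = grid, loglik = lls))
}
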