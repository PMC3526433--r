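# -------------------------------------------------------------------------
# Forward-selection search over phylogenetic networks.
#
# Starting from a species tree, each round scores every valid way of
# adding one reticulation edge (both directions over all ordered pairs of
# tree edges, excluding identical edges, sibling edges and pairs that
# would create a directed cycle) at every inheritance probability on the
# grid, and keeps the argmax. Model complexity is controlled afterwards
# with AIC/BIC: an i-th reticulation is accepted when the log-likelihood
# improvement exceeds 1 (AIC) or ln(n)/2 (BIC), the thresholds obtained
# from the criteria when one parameter is added per reticulation.
# -------------------------------------------------------------------------

#' Candidate reticulation attachments of a network
#'
#' Enumerates the ordered pairs of tree edges (donor, recipient) to which
#' a new reticulation edge may be attached: identical edges, sibling edges
#' (two tree edges emanating from the same node) and pairs whose arc would
#' close a directed cycle are excluded. The order is deterministic
#' (lexicographic in the edge ids, which are themselves derived from
#' descendant-taxon sets), so tie-breaking is reproducible.
#'
#' @param net A `phylo_network` or tree.
#' @return A [tibble][tibble::tibble] with columns `donor` and
#'   `recipient` (edge ids).
#' @export
enumerate_additions <- function(net) {
  net <- as_phylo_network(net)
  tree_e <- which(!is_reticulation_edge(net))
  eid <- network_edge_ids(net)
  ord <- tree_e[order(eid[tree_e])]
  anc <- ancestor_sets(net)
  out_d <- character(0); out_r <- character(0)
  for (i in ord) {
    for (j in ord) {
      if (i == j) next
      if (identical(net$parent[i], net$parent[j])) next  # sibling edges
      if (net$child[j] %in% anc[[net$parent[i]]]) next   # cycle
      out_d <- c(out_d, eid[i]); out_r <- c(out_r, eid[j])
    }
  }
  tibble::tibble(donor = out_d, recipient = out_r)
}

#' AIC/BIC score of a fitted network
#'
#' Computes the information criteria from the log-likelihood, the number
#' of branches of the network (the parameter count `K`) and the total
#' number of sites `n`: `AIC = 2K - 2 lnL`, `BIC = K ln(n) - 2 lnL`.
#'
#' @param loglik Log-likelihood (nats).
#' @param K Parameter count: the number of branches of the network.
#' @param n Sample size: total sites over all genes.
#' @param h Number of reticulation nodes (bookkeeping).
#' @return One-row tibble with columns `h`, `loglik`, `K`, `n`, `AIC`,
#'   `BIC`.
#' @export
model_score <- function(loglik, K, n, h = NA_integer_) {
  stopifnot(n > 0, K > 0)
  tibble::tibble(h = as.integer(h), loglik = loglik, K = as.integer(K),
                 n = as.integer(n),
                 AIC = 2 * K - 2 * loglik,
                 BIC = K * log(n) - 2 * loglik)
}

#' Best single-reticulation augmentation of a network
#'
#' Implements one forward-selection step: evaluates the network likelihood
#' of every candidate attachment from [enumerate_additions()] at every
#' inheritance probability on `grid`, holding the gamma values of existing
#' reticulation edges fixed, and returns the maximizing augmented network.
#' Ties are broken by the deterministic candidate order, then toward the
#' smaller gamma.
#'
#' Candidates that change no displayed topology (the recipient subtree
#' regrafted adjacent to its own attachment point) are skipped: such an
#' addition carries no reticulate signal — its mixture components share
#' one unrooted topology and differ only in branch lengths, so under
#' per-tree branch-length optimization it can never improve the
#' likelihood, while under fixed network-induced lengths it would act as
#' a spurious branch-length tweak rather than as a reticulation.
#'
#' Scoring is two-pass. All candidates are first ranked with the fast
#' fixed-length likelihood (displayed trees keep the lengths induced
#' from the network). The `refine_top` best are then re-scored with
#' dnaml-style tree likelihoods — every displayed tree's branch lengths
#' re-optimized per gene — and the refined score decides the winner and
#' is the score reported for the augmented network. The refinement is
#' what makes log-likelihood improvements comparable with the AIC/BIC
#' thresholds: at fixed lengths a topology-changing candidate can still
#' harvest residual branch-length misfit and inflate the improvement.
#'
#' @param net A `phylo_network` or starting tree.
#' @param genes A `gene_alignments` object.
#' @param grid Inheritance-probability grid (default [gamma_grid()]).
#' @param tstv Transition/transversion ratio.
#' @param cache A [likelihood_cache()]; strongly recommended across
#'   rounds.
#' @param refine_top Number of top fixed-length candidates re-scored
#'   with per-gene branch-length-optimized tree likelihoods (default 3;
#'   `0` disables refinement and returns the fixed-length argmax;
#'   `Inf` refines every candidate).
#' @param optimize_branches Use per-gene optimized tree likelihoods for
#'   the first pass as well (very slow; default `FALSE`).
#' @return A list: `network` (the augmented `phylo_network`), `donor`,
#'   `recipient`, `gamma`, `arc` (new edge id), `loglik`, and `score`
#'   (a [model_score()] row).
#' @export
best_augmentation <- function(net, genes, grid = gamma_grid(), tstv = 2,
                              cache = likelihood_cache(), refine_top = 3,
                              optimize_branches = FALSE) {
  net <- as_phylo_network(net)
  stop_if_invalid(net)
  cand <- enumerate_additions(net)
  if (!nrow(cand)) stop("no valid reticulation attachment exists")
  # Displayed trees of candidate networks split into two halves: combos
  # that do not use the new arc reproduce the base network's displayed
  # trees exactly (arc removal + midpoint suppression is the identity),
  # so their likelihoods are computed once per round; per candidate only
  # the arc-using combos (one per induction choice of the old
  # reticulations) are new.
  base_combos <- display_combos(net)
  base_w <- vapply(base_combos, `[[`, 0, "weight")
  base_ll <- matrix(NA_real_, nrow = genes$k, ncol = length(base_combos))
  for (j in seq_along(base_combos)) {
    base_ll[, j] <- cached_tree_loglik(base_combos[[j]]$tree,
                                       base_combos[[j]]$hash_topo,
                                       genes, tstv, cache, optimize_branches)
  }
  base_keys <- unique(vapply(base_combos, function(cb)
    dtree_hash(cb$tree, with_lengths = FALSE, rooted = FALSE), ""))
  # one candidate evaluation: returns per-gamma total log-likelihoods
  # (NULL for an unidentifiable, length-only addition)
  eval_candidate <- function(ci, optimize) {
    net2 <- add_reticulation(net, cand$donor[ci], cand$recipient[ci],
                             gamma = grid[1], check = FALSE)
    hnew <- setdiff(reticulation_nodes(net2), reticulation_nodes(net))
    arc <- network_edge_ids(net2)[which(net2$child == hnew &
                                          net2$transfer)]
    arc_combos <- display_combos(net2, hash = "none",
                                 fix = stats::setNames(arc, hnew))
    # cheap neutrality pre-filter: the move can only reproduce the base
    # topologies when the donor edge is incident, in the unrooted sense,
    # to the recipient edge's attachment node a = parent(recipient):
    # the parent edge of a; the other root edge when a's parent is the
    # root (the root vanishes unrooted); or, when a is the root itself
    # (whose unrooted attachment is the other root child s), the child
    # edges of s. Flagged pairs are verified by topology hashing.
    d_i <- edge_index(net, cand$donor[ci])
    r_i <- edge_index(net, cand$recipient[ci])
    a <- net$parent[r_i]
    a_parent <- net$parent[net$child == a]
    maybe_neutral <- identical(net$child[d_i], a) ||
      (length(a_parent) == 1L && identical(a_parent, net$root) &&
         identical(net$parent[d_i], net$root))
    if (!maybe_neutral && identical(a, net$root)) {
      other <- setdiff(net$child[net$parent == net$root], net$child[r_i])
      maybe_neutral <- net$parent[d_i] %in% other
    }
    if (maybe_neutral) {
      arc_keys <- vapply(arc_combos, function(cb)
        dtree_hash(cb$tree, with_lengths = FALSE, rooted = FALSE), "")
      if (all(arc_keys %in% base_keys)) return(NULL)
    }
    arc_w <- vapply(arc_combos, `[[`, 0, "weight") / grid[1]
    arc_ll <- matrix(NA_real_, nrow = genes$k, ncol = length(arc_combos))
    for (j in seq_along(arc_combos)) {
      arc_ll[, j] <- if (optimize) {
        cached_tree_loglik(arc_combos[[j]]$tree, NULL, genes, tstv, cache,
                           optimize_branches = TRUE)
      } else {
        dtree_gene_loglik(arc_combos[[j]]$tree, genes, tstv)
      }
    }
    bl <- if (optimize) base_opt_ll() else base_ll
    ll <- cbind(bl, arc_ll)
    m <- apply(ll, 1, max)
    A <- exp(ll - m)
    W <- rbind(base_w %o% (1 - grid), arc_w %o% grid)
    list(tot = colSums(log(A %*% W)) + sum(m), arc = arc)
  }
  base_opt_cache <- NULL
  base_opt_ll <- function() {
    if (is.null(base_opt_cache)) {
      m <- matrix(NA_real_, nrow = genes$k, ncol = length(base_combos))
      for (j in seq_along(base_combos)) {
        m[, j] <- cached_tree_loglik(base_combos[[j]]$tree, NULL, genes,
                                     tstv, cache, optimize_branches = TRUE)
      }
      base_opt_cache <<- m
    }
    base_opt_cache
  }
  # pass 1: rank all candidates at fixed (network-induced) lengths
  fixed_best <- rep(-Inf, nrow(cand))
  fixed_gi <- rep(NA_integer_, nrow(cand))
  arcs <- rep(NA_character_, nrow(cand))
  for (ci in seq_len(nrow(cand))) {
    ev <- eval_candidate(ci, optimize = optimize_branches)
    if (is.null(ev)) next
    gi <- which.max(ev$tot)  # first max: smallest gamma on ties
    fixed_best[ci] <- ev$tot[gi]
    fixed_gi[ci] <- gi
    arcs[ci] <- ev$arc
  }
  if (!any(is.finite(fixed_best))) {
    stop("no identifiable reticulation attachment: every candidate ",
         "leaves the displayed topologies unchanged", call. = FALSE)
  }
  # pass 2: re-score the leaders with per-gene optimized tree
  # likelihoods. The refinement pool holds the strongest candidates
  # overall plus the most nearly inert ones (fixed-length score closest
  # to the unaugmented network's): on tree-like data the re-optimized
  # argmax is typically a near-inert short-range candidate, which the
  # fixed-length ranking systematically under-ranks.
  refine_top <- min(refine_top, sum(is.finite(fixed_best)))
  if (refine_top > 0 && !optimize_branches) {
    ll0_fixed <- {
      lw <- log(base_w)
      sum(vapply(seq_len(genes$k), function(i)
        logsumexp(base_ll[i, ] + lw), 0))
    }
    top <- order(-fixed_best)[seq_len(refine_top)]
    inert <- order(abs(fixed_best - ll0_fixed))[seq_len(refine_top)]
    top <- union(top, inert[is.finite(fixed_best[inert])])
    best <- NULL
    for (ci in sort(top)) {
      ev <- eval_candidate(ci, optimize = TRUE)
      gi <- which.max(ev$tot)
      if (is.null(best) || ev$tot[gi] > best$loglik) {
        best <- list(donor = cand$donor[ci], recipient = cand$recipient[ci],
                     gamma = grid[gi], loglik = ev$tot[gi], arc = ev$arc)
      }
    }
  } else {
    ci <- which.max(fixed_best)
    best <- list(donor = cand$donor[ci], recipient = cand$recipient[ci],
                 gamma = grid[fixed_gi[ci]], loglik = fixed_best[ci],
                 arc = arcs[ci])
  }
  net_best <- add_reticulation(net, best$donor, best$recipient,
                               gamma = best$gamma)
  best$network <- net_best
  best$score <- model_score(best$loglik, K = length(net_best$parent),
                            n = genes$n, h = n_reticulations(net_best))
  best
}

#' Forward search over networks of increasing reticulation number
#'
#' Runs the forward-selection heuristic: starting from a species tree,
#' repeatedly adds the best-scoring reticulation edge (see
#' [best_augmentation()]) up to `h_max` reticulations, recording the
#' optimal network and its [model_score()] at every level, and applies
#' AIC/BIC model selection to the trajectory.
#'
#' @param start_tree An [ape::phylo] species tree with branch lengths (or
#'   a `phylo_network`).
#' @param genes A `gene_alignments` object.
#' @param h_max Maximum number of reticulations to add (`>= 0`).
#' @param grid Inheritance-probability grid.
#' @param tstv Transition/transversion ratio.
#' @param cache A [likelihood_cache()] (created if not supplied).
#' @param fit_lengths Fit the start tree's branch lengths by maximum
#'   likelihood on the pooled data before searching (default `TRUE` for
#'   tree input; see [fit_branch_lengths()]). Candidate networks inherit
#'   these fitted lengths, so no candidate can gain likelihood from
#'   branch-length misfit instead of reticulate signal.
#' @param refine_top See [best_augmentation()]; when refinement is
#'   enabled (the default) every score in the trajectory, including the
#'   h = 0 start score, uses per-gene branch-length-optimized tree
#'   likelihoods, so the per-step improvements compared against the
#'   AIC/BIC thresholds are on the dnaml-style likelihood scale.
#' @param optimize_branches See [best_augmentation()].
#' @param verbose Print per-round progress.
#' @return An object of class `net_search`: list with `networks` (one per
#'   h), `scores` (tibble with per-h `loglik`, `K`, `n`, `AIC`, `BIC`,
#'   `delta_loglik`, chosen `donor`/`recipient`/`gamma`), and `selected`
#'   (list with the h chosen under `aic` and `bic`). Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
forward_search <- function(start_tree, genes, h_max = 1,
                           grid = gamma_grid(), tstv = 2,
                           cache = likelihood_cache(), fit_lengths = TRUE,
                           refine_top = 3, optimize_branches = FALSE,
                           verbose = FALSE) {
  stopifnot(h_max >= 0)
  if (fit_lengths && inherits(start_tree, "phylo") && !optimize_branches) {
    start_tree <- fit_branch_lengths(start_tree, genes, tstv)
  }
  net <- as_phylo_network(start_tree)
  stop_if_invalid(net)
  # the h = 0 score on the same likelihood scale as the search scores
  ll0 <- as.numeric(network_log_likelihood(
    net, genes, tstv, cache,
    optimize_branches = optimize_branches || refine_top > 0))
  scores <- model_score(ll0, K = length(net$parent), n = genes$n, h = 0L)
  scores$delta_loglik <- NA_real_
  scores$donor <- NA_character_; scores$recipient <- NA_character_
  scores$gamma <- NA_real_
  networks <- list(net)
  h <- 0L
  while (h < h_max) {
    step <- best_augmentation(net, genes, grid, tstv, cache,
                              refine_top = refine_top,
                              optimize_branches = optimize_branches)
    h <- h + 1L
    if (verbose) {
      message(sprintf("h=%d: %s => %s  gamma=%.2f  lnL=%.3f", h,
                      step$donor, step$recipient, step$gamma, step$loglik))
    }
    row <- step$score
    row$delta_loglik <- step$loglik - scores$loglik[nrow(scores)]
    row$donor <- step$donor; row$recipient <- step$recipient
    row$gamma <- step$gamma
    scores <- rbind(scores, row)
    networks[[h + 1L]] <- step$network
    net <- step$network
  }
  out <- structure(list(networks = networks, scores = scores, n = genes$n),
                   class = "net_search")
  out$selected <- list(aic = select_model(out, "aic"),
                       bic = select_model(out, "bic"))
  out
}

#' Select the number of reticulations with an information criterion
#'
#' Sequential-stopping rule derived from AIC/BIC with one parameter added
#' per reticulation: the i-th reticulation is accepted iff
#' `lnL(i) - lnL(i-1) > 1` (AIC) or `> ln(n)/2` (BIC); the selected h is
#' the largest level reachable through consecutively accepted steps. A
#' `mode = "global"` variant instead returns the h minimizing the
#' penalized score `pen * (K0 + h) - 2 lnL(h)` over the whole trajectory.
#'
#' @param trajectory A `net_search` object from [forward_search()].
#' @param criterion `"aic"` or `"bic"`.
#' @param mode `"sequential"` (default) or `"global"`.
#' @return Selected number of reticulations (integer).
#' @export
select_model <- function(trajectory, criterion = c("bic", "aic"),
                         mode = c("sequential", "global")) {
  criterion <- match.arg(tolower(criterion), c("bic", "aic"))
  mode <- match.arg(mode)
  sc <- trajectory$scores
  n <- trajectory$n
  pen <- if (criterion == "aic") 2 else log(n)
  if (mode == "sequential") {
    d <- sc$delta_loglik[-1]
    if (!length(d)) return(0L)
    pass <- d > pen / 2
    fail <- which(!pass)
    if (!length(fail)) length(pass) else fail[1] - 1L
  } else {
    crit <- pen * (sc$K[1] + sc$h) - 2 * sc$loglik
    which.min(crit) - 1L
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a network search trajectory
#'
#' @param x A `net_search` object.
#' @param ... Unused.
#' @return The per-h score tibble (`h`, `loglik`, `K`, `n`, `AIC`, `BIC`,
#'   `delta_loglik`, `donor`, `recipient`, `gamma`).
#' @export
tidy.net_search <- function(x, ...) x$scores

#' One-row summary of a network search
#'
#' @param x A `net_search` object.
#' @param ... Unused.
#' @return Tibble with the selected reticulation numbers under AIC and
#'   BIC, the final log-likelihood and the sample size.
#' @export
glance.net_search <- function(x, ...) {
  tibble::tibble(h_max = max(x$scores$h),
                 h_aic = x$selected$aic,
                 h_bic = x$selected$bic,
                 loglik_max = max(x$scores$loglik),
                 n = x$n)
}

#' @export
print.net_search <- function(x, ...) {
  cat("Forward network search\n")
  print(x$scores)
  cat(sprintf("Selected h: AIC = %d, BIC = %d\n",
              x$selected$aic, x$selected$bic))
  invisible(x)
}

#' Plot a search trajectory
#'
#' Log-likelihood, AIC and BIC against the number of reticulations.
#'
#' @param object A `net_search` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.net_search <- function(object, ...) {
  sc <- object$scores
  df <- rbind(
    data.frame(h = sc$h, value = -2 * sc$loglik, metric = "-2 lnL"),
    data.frame(h = sc$h, value = sc$AIC, metric = "AIC"),
    data.frame(h = sc$h, value = sc$BIC, metric = "BIC"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "reticulations (h)", y = "score", colour = NULL)
}

#' @importFrom ggplot2 .data
NULL
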