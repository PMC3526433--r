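# -------------------------------------------------------------------------
# Displayed (contained) trees of a network.
#
# Every choice of one incoming edge per reticulation node (an "induction
# choice") yields a tree after suppressing the degree-2 nodes left behind;
# merged edges sum their lengths so path lengths are preserved. The
# probability of observing a displayed tree T is
#     P(T | N, gamma) = sum over induction sets yielding T of
#                       prod over kept reticulation edges of gamma(e).
#
# Internally displayed trees are light lists ("dtree"): parent/child/length
# character edge vectors plus the root, with a canonical recursive hash used
# for grouping identical topologies and for likelihood caching.
# -------------------------------------------------------------------------

# dtree: list(parent, child, length, root)

dtree_hash <- function(tr, with_lengths = TRUE, rooted = TRUE) {
  kids <- split(seq_along(tr$parent), tr$parent)
  rec <- function(v) {
    ks <- kids[[v]]
    if (is.null(ks)) return(v)
    subs <- vapply(ks, function(e) {
      s <- rec(tr$child[e])
      if (with_lengths) paste0(s, ":", sprintf("%.12g", tr$length[e]))
      else s
    }, "")
    paste0("(", paste(sort(subs), collapse = ","), ")")
  }
  key <- rec(tr$root)
  if (!rooted) {
    # canonical unrooted form: hash the sorted set of non-trivial splits
    paste(sort(dtree_splits(tr)), collapse = ";")
  } else key
}

# sorted non-trivial splits of the unrooted topology, used by the
# unrooted hash; each split is written as the taxon-index subset on the
# side away from the first taxon (the standard canonical side)
dtree_splits <- function(tr) {
  leaf <- setdiff(tr$child, tr$parent)
  taxa <- sort(leaf)
  nt <- length(taxa)
  kids <- split(seq_along(tr$parent), tr$parent)
  acc <- character(0)
  rec <- function(v) {
    ks <- kids[[v]]
    if (is.null(ks)) return(match(v, taxa))
    s <- sort(unlist(lapply(ks, function(e) rec(tr$child[e]))))
    n <- length(s)
    if (n > 1L && n < nt - 1L) {
      side <- if (s[1] == 1L) setdiff(seq_len(nt), s) else s
      acc[[length(acc) + 1L]] <<- paste(side, collapse = ",")
    }
    s
  }
  rec(tr$root)
  unique(acc)
}

dtree_to_newick <- function(tr, digits = 12) {
  kids <- split(seq_along(tr$parent), tr$parent)
  rec <- function(v) {
    ks <- kids[[v]]
    if (is.null(ks)) return(v)
    subs <- vapply(ks, function(e) {
      paste0(rec(tr$child[e]), ":", sprintf("%.*g", digits, tr$length[e]))
    }, "")
    paste0("(", paste(sort(subs), collapse = ","), ")")
  }
  paste0(rec(tr$root), ";")
}

dtree_to_phylo <- function(tr) {
  ape::read.tree(text = dtree_to_newick(tr))
}

phylo_to_dtree <- function(tree) {
  net <- as_phylo_network(tree)
  list(parent = net$parent, child = net$child, length = net$length,
       root = net$root)
}

# Enumerate all 2^h induction choices of a network. Returns a list of
# combos: list(tree = dtree, weight, choice (named chr: retic node ->
# kept incoming edge id), hash_topo (rooted, with lengths), and -- only
# when hash = "both" -- hash_unrooted (topology-only grouping key).
display_combos <- function(net, hash = c("topo", "both", "none"),
                           fix = NULL) {
  hash <- match.arg(hash)
  stopifnot(inherits(net, "phylo_network"))
  ret <- reticulation_nodes(net)
  h <- length(ret)
  eid <- network_edge_ids(net)
  incoming <- lapply(ret, function(v) sort(which(net$child == v)))
  names(incoming) <- ret
  # forced choices (named: retic node -> kept incoming edge id)
  forced <- integer(0)
  if (!is.null(fix)) {
    forced <- vapply(names(fix), function(v) {
      j <- match(fix[[v]], eid[incoming[[v]]])
      if (is.na(j)) stop("fix: '", fix[[v]], "' is not incoming to ", v)
      j
    }, 0L)
  }
  free <- setdiff(ret, names(forced))
  hf <- length(free)
  idx <- lapply(seq_len(2^hf) - 1L, function(b) {
    full <- integer(h); names(full) <- ret
    if (hf) full[free] <- bitwAnd(b %/% 2L^(seq_len(hf) - 1L), 1L) + 1L
    full[names(forced)] <- forced
    full
  })
  taxa <- network_leaves(net)
  lapply(idx, function(pick) {
    kept <- if (h) mapply(function(inc, j) inc[j], incoming, pick) else integer(0)
    drop <- if (h) mapply(function(inc, j) inc[3L - j], incoming, pick) else integer(0)
    keep <- setdiff(seq_along(net$parent), drop)
    sup <- suppress_degree_two(net$parent[keep], net$child[keep],
                               net$length[keep], net$gamma[keep],
                               net$transfer[keep], net$root, leaves = taxa)
    tr <- list(parent = sup$parent, child = sup$child, length = sup$length,
               root = sup$root)
    w <- if (h) prod(net$gamma[kept]) else 1
    list(tree = tr,
         weight = w,
         choice = if (h) stats::setNames(eid[kept], ret) else
           stats::setNames(character(0), character(0)),
         hash_topo = if (hash != "none") dtree_hash(tr, with_lengths = TRUE)
           else NULL,
         hash_unrooted = if (hash == "both")
           dtree_hash(tr, with_lengths = FALSE, rooted = FALSE) else NULL)
  })
}

#' Displayed trees of a phylogenetic network
#'
#' Enumerates all `2^h` induction choices (keep one incoming edge per
#' reticulation node, suppress the degree-2 nodes that remain, summing
#' merged branch lengths) and groups the resulting trees by unrooted
#' topology, adding the inheritance-probability products of induction
#' choices that yield the same topology. The probabilities over all
#' displayed trees always sum to 1.
#'
#' @param net A `phylo_network` (or tree coercible with
#'   [as_phylo_network()]).
#' @return A [tibble][tibble::tibble] with one row per distinct displayed
#'   topology: `tree` (list column of [ape::phylo] objects), `prob`
#'   (P(T | N, gamma)), and `n_inductions` (number of induction sets
#'   yielding the topology).
#' @export
displayed_trees <- function(net) {
  net <- as_phylo_network(net)
  stop_if_invalid(net)
  combos <- display_combos(net, hash = "both")
  keys <- vapply(combos, `[[`, "", "hash_unrooted")
  groups <- split(seq_along(combos), keys)
  # deterministic order: by first occurrence
  groups <- groups[order(vapply(groups, min, 0L))]
  tibble::tibble(
    tree = lapply(groups, function(g) dtree_to_phylo(combos[[g[1]]]$tree)),
    prob = vapply(groups, function(g)
      sum(vapply(combos[g], `[[`, 0, "weight")), 0),
    n_inductions = lengths(groups))
}

#' Probability of a tree under a network
#'
#' Computes `P(T | N, gamma)`: the sum over all induction sets of the
#' network that display the tree's (unrooted) topology of the product of
#' the kept reticulation edges' inheritance probabilities. Returns 0 for a
#' tree the network does not display.
#'
#' @param net A `phylo_network`.
#' @param tree An [ape::phylo] tree on the same taxon set.
#' @return Probability in \[0, 1\].
#' @export
tree_probability <- function(net, tree) {
  net <- as_phylo_network(net)
  stop_if_invalid(net)
  if (!setequal(network_leaves(net), tree$tip.label)) {
    stop("tree and network are on different taxon sets", call. = FALSE)
  }
  target <- dtree_hash(phylo_to_dtree(tree), with_lengths = FALSE,
                       rooted = FALSE)
  combos <- display_combos(net, hash = "both")
  keys <- vapply(combos, `[[`, "", "hash_unrooted")
  sum(vapply(combos[keys == target], `[[`, 0, "weight"))
}
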