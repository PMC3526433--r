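#' @useDynLib phynetml, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# -------------------------------------------------------------------------
# phylo_network: rooted binary phylogenetic network as a flat edge list.
#
# Fields (parallel vectors, one element per directed edge parent -> child):
#   parent, child : character node ids (leaves carry their taxon name)
#   length        : branch length, expected substitutions/site, >= 0
#   gamma         : inheritance probability for reticulation edges (edges
#                   whose head has in-degree 2); NA for tree edges
#   transfer      : TRUE for the "horizontal" arc of a reticulation (the
#                   edge removed to recover the underlying species tree)
#   root          : id of the root node
#
# Node classes are implicit: the root has in-degree 0; leaves have
# out-degree 0; reticulation nodes have in-degree 2; all other nodes are
# internal tree nodes. Internal node ids are assigned deterministically
# (ranked by the sorted set of descendant taxa) so that enumeration order,
# edge ids and tie-breaking are reproducible.
# -------------------------------------------------------------------------

new_phylo_network <- function(parent, child, length, gamma, transfer, root) {
  structure(
    list(parent = as.character(parent), child = as.character(child),
         length = as.numeric(length), gamma = as.numeric(gamma),
         transfer = as.logical(transfer), root = as.character(root)),
    class = "phylo_network")
}

#' Nodes, leaves and edges of a phylogenetic network
#'
#' Small accessors for the `phylo_network` edge-list representation. Edge
#' ids are strings of the form `"parent->child"` and are stable across
#' operations that do not touch the edge.
#'
#' @param net A `phylo_network` object.
#' @return `network_nodes()`/`network_leaves()` return character vectors of
#'   node ids; `network_edge_ids()` returns the edge id of every edge;
#'   `reticulation_nodes()` the ids of nodes with in-degree 2.
#' @export
network_nodes <- function(net) unique(c(net$root, net$parent, net$child))

#' @rdname network_nodes
#' @export
network_leaves <- function(net) {
  sort(setdiff(net$child, net$parent))
}

#' @rdname network_nodes
#' @export
network_edge_ids <- function(net) paste0(net$parent, "->", net$child)

#' @rdname network_nodes
#' @export
reticulation_nodes <- function(net) {
  tab <- table(net$child)
  sort(names(tab)[tab == 2L])
}

n_reticulations <- function(net) length(reticulation_nodes(net))

# logical vector over edges: head is a reticulation node
is_reticulation_edge <- function(net) net$child %in% reticulation_nodes(net)

edge_index <- function(net, edge_id) {
  i <- match(edge_id, network_edge_ids(net))
  if (anyNA(i)) {
    stop("unknown edge id(s): ",
         paste(edge_id[is.na(i)], collapse = ", "), call. = FALSE)
  }
  i
}

#' Pendant edge of a taxon
#'
#' Convenience lookup of the edge id of the terminal (pendant) branch
#' leading to a leaf, the usual attachment point for planted HGT events.
#'
#' @param net A `phylo_network`.
#' @param taxon Taxon name (leaf label).
#' @return Edge id string `"parent->taxon"`.
#' @export
pendant_edge <- function(net, taxon) {
  i <- which(net$child == taxon)
  if (length(i) != 1L) stop("no pendant edge for taxon '", taxon, "'")
  network_edge_ids(net)[i]
}

# ancestor sets (inclusive of the node itself) for every node; list keyed
# by node id. Used for cycle exclusion when attaching reticulations.
ancestor_sets <- function(net) {
  nodes <- network_nodes(net)
  anc <- stats::setNames(vector("list", length(nodes)), nodes)
  # process in topological order: repeatedly resolve nodes whose parents
  # are all resolved (the graph is small; simple fixed-point loop)
  parents_of <- split(net$parent, net$child)
  anc[[net$root]] <- net$root
  pending <- setdiff(nodes, net$root)
  while (length(pending)) {
    resolved_any <- FALSE
    for (v in pending) {
      ps <- parents_of[[v]]
      if (all(ps %in% names(anc)[!vapply(anc, is.null, TRUE)])) {
        anc[[v]] <- unique(c(v, unlist(anc[ps], use.names = FALSE)))
        resolved_any <- TRUE
      }
    }
    pending <- setdiff(pending, names(anc)[!vapply(anc, is.null, TRUE)])
    if (!resolved_any && length(pending)) {
      # cycle: leave unresolved entries as their own id
      for (v in pending) anc[[v]] <- v
      break
    }
  }
  anc
}

#' Validate a phylogenetic network
#'
#' Checks the structural invariants of a rooted binary phylogenetic
#' network: degree constraints (root in 0/out 2, leaves in 1/out 0,
#' internal tree nodes in 1/out 2, reticulation nodes in 2/out 1),
#' acyclicity, non-negative branch lengths, inheritance probabilities
#' summing to one at every reticulation node, and uniqueness of leaf
#' labels. Diagnostics are returned, not raised, so the function can be
#' used to explain why a hand-built or parsed network is rejected.
#'
#' @param net A `phylo_network` object.
#' @return Character vector of human-readable violations; `character(0)`
#'   if the network is valid.
#' @export
validate_network <- function(net) {
  bad <- character(0)
  eid <- network_edge_ids(net)
  if (anyDuplicated(eid)) {
    bad <- c(bad, paste0("duplicated edge: ",
                         paste(unique(eid[duplicated(eid)]), collapse = ", ")))
  }
  nodes <- network_nodes(net)
  indeg <- table(factor(net$child, levels = nodes))
  outdeg <- table(factor(net$parent, levels = nodes))
  for (v in nodes) {
    i <- indeg[[v]]; o <- outdeg[[v]]
    ok <- (i == 0L && o == 2L && v == net$root) ||  # root
      (i == 1L && o == 0L) ||                       # leaf
      (i == 1L && o == 2L) ||                       # internal tree node
      (i == 2L && o == 1L)                          # reticulation node
    if (!ok) {
      bad <- c(bad, sprintf("node '%s' has in-degree %d and out-degree %d",
                            v, i, o))
    }
  }
  if (any(net$length < 0, na.rm = TRUE)) {
    bad <- c(bad, paste0("negative branch length on edge ",
                         paste(eid[which(net$length < 0)], collapse = ", ")))
  }
  # cycles: count nodes reachable in a topological peeling; leftover => cycle
  if (has_cycle(net)) bad <- c(bad, "cycle: directed cycle present")
  # gamma constraints
  ret <- reticulation_nodes(net)
  for (v in ret) {
    i <- which(net$child == v)
    g <- net$gamma[i]
    if (anyNA(g)) {
      bad <- c(bad, sprintf(
        "reticulation node '%s': missing inheritance probability", v))
    } else if (abs(sum(g) - 1) > 1e-9) {
      bad <- c(bad, sprintf(
        "reticulation node '%s': inheritance probabilities do not sum to 1 (%g + %g)",
        v, g[1], g[2]))
    } else if (any(g < 0 | g > 1)) {
      bad <- c(bad, sprintf(
        "reticulation node '%s': inheritance probability outside [0,1]", v))
    }
  }
  tree_edge <- !is_reticulation_edge(net)
  if (any(!is.na(net$gamma[tree_edge]))) {
    bad <- c(bad, "inheritance probability set on a tree edge")
  }
  bad
}

# Kahn-style peeling; TRUE if a directed cycle exists
has_cycle <- function(net) {
  nodes <- network_nodes(net)
  indeg <- table(factor(net$child, levels = nodes))
  active <- rep(TRUE, length(net$parent))
  indeg <- as.integer(indeg); names(indeg) <- nodes
  queue <- nodes[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    out <- which(active & net$parent == v)
    for (e in out) {
      active[e] <- FALSE
      w <- net$child[e]
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  seen < length(nodes)
}

stop_if_invalid <- function(net) {
  v <- validate_network(net)
  if (length(v)) {
    stop("invalid phylogenetic network:\n  ", paste(v, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(net)
}

#' Convert a phylo tree to a phylogenetic network
#'
#' A phylogenetic tree is a phylogenetic network without reticulation
#' nodes. Internal node ids are assigned deterministically by ranking the
#' sorted descendant-taxon sets, so the same topology always yields the
#' same ids regardless of input edge order.
#'
#' @param x An [ape::phylo] object with branch lengths (rooted, binary).
#' @param ... Unused.
#' @return A `phylo_network` with no reticulation nodes.
#' @export
as_phylo_network <- function(x, ...) UseMethod("as_phylo_network")

#' @export
as_phylo_network.phylo_network <- function(x, ...) x

#' @export
as_phylo_network.phylo <- function(x, ...) {
  if (is.null(x$edge.length)) stop("tree must have branch lengths")
  if (!ape::is.rooted(x)) stop("tree must be rooted")
  if (!ape::is.binary(x)) stop("tree must be binary")
  ntip <- length(x$tip.label)
  nnode <- ntip + x$Nnode
  # descendant taxa per node
  clade <- vector("list", nnode)
  for (i in seq_len(ntip)) clade[[i]] <- x$tip.label[i]
  eo <- ape::reorder.phylo(x, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; c_ <- eo$edge[k, 2]
    clade[[p]] <- c(clade[[p]], clade[[c_]])
  }
  key <- vapply(clade, function(s) paste(sort(s), collapse = "|"), "")
  internal <- (ntip + 1):nnode
  rank <- match(key[internal], sort(key[internal]))
  id <- character(nnode)
  id[seq_len(ntip)] <- x$tip.label
  id[internal] <- sprintf("n%d", rank)
  root <- id[ntip + 1L]
  new_phylo_network(parent = id[x$edge[, 1]], child = id[x$edge[, 2]],
                    length = x$edge.length,
                    gamma = rep(NA_real_, nrow(x$edge)),
                    transfer = rep(FALSE, nrow(x$edge)),
                    root = root)
}

#' @export
print.phylo_network <- function(x, ...) {
  h <- n_reticulations(x)
  taxa <- network_leaves(x)
  cat(sprintf(
    "Phylogenetic network: %d taxa, %d reticulation%s, %d edges\n",
    length(taxa), h, if (h == 1) "" else "s", length(x$parent)))
  cat("Taxa:", paste(utils::head(taxa, 10), collapse = ", "),
      if (length(taxa) > 10) "..." else "", "\n")
  if (h > 0) {
    ret <- reticulation_nodes(x)
    for (v in ret) {
      i <- which(x$child == v)
      cat(sprintf("  %s: %s (gamma=%.3g), %s (gamma=%.3g)\n", v,
                  network_edge_ids(x)[i[1]], x$gamma[i[1]],
                  network_edge_ids(x)[i[2]], x$gamma[i[2]]))
    }
  }
  invisible(x)
}

#' Add a reticulation edge to a network
#'
#' Attaches a new reticulation between two tree edges: each edge is
#' subdivided at its midpoint into two halves of equal length, and a
#' horizontal arc is added from the midpoint of `donor` to the midpoint of
#' `recipient`. The recipient midpoint becomes the new reticulation node;
#' its incoming arc receives inheritance probability `gamma` and the
#' subdivided vertical edge the complement `1 - gamma`. Pairs that would
#' create a directed cycle, sibling edges (two tree edges emanating from
#' the same node) and identical edges are rejected.
#'
#' @param net A `phylo_network` (a tree converted with
#'   [as_phylo_network()] works too).
#' @param donor,recipient Edge ids (see [network_edge_ids()]) of the two
#'   tree edges to attach to; the arc points donor -> recipient.
#' @param gamma Inheritance probability of the new arc, in (0, 1).
#' @param length Length of the new arc itself; defaults to 0
#'   (instantaneous horizontal transfer).
#' @param check Run the cycle/sibling/tree-edge validity checks (default
#'   `TRUE`); callers that pre-validated the pair (the search loop) skip
#'   them.
#' @return A new `phylo_network` with one more reticulation node.
#' @export
add_reticulation <- function(net, donor, recipient, gamma, length = 0,
                             check = TRUE) {
  net <- as_phylo_network(net)
  if (identical(donor, recipient)) stop("identical edges", call. = FALSE)
  i1 <- edge_index(net, donor)
  i2 <- edge_index(net, recipient)
  if (!is.numeric(gamma) || gamma <= 0 || gamma >= 1) {
    stop("gamma must lie strictly in (0, 1)", call. = FALSE)
  }
  u1 <- net$parent[i1]; v1 <- net$child[i1]
  u2 <- net$parent[i2]; v2 <- net$child[i2]
  if (check) {
    if (any(is_reticulation_edge(net)[c(i1, i2)])) {
      stop("attachment edges must be tree edges", call. = FALSE)
    }
    if (identical(u1, u2)) stop("sibling edges", call. = FALSE)
    # arc x1 -> x2 closes a cycle iff v2 is an ancestor of (or equals) u1
    anc <- ancestor_sets(net)
    if (v2 %in% anc[[u1]]) stop("would create cycle", call. = FALSE)
  }
  k <- n_reticulations(net) + 1L
  x1 <- sprintf("x%d", k)
  hx <- sprintf("#H%d", k)
  while (x1 %in% network_nodes(net)) { k <- k + 1L; x1 <- sprintf("x%d", k); hx <- sprintf("#H%d", k) }
  keep <- setdiff(seq_along(net$parent), c(i1, i2))
  new_phylo_network(
    parent  = c(net$parent[keep], u1, x1, u2, hx, x1),
    child   = c(net$child[keep],  x1, v1, hx, v2, hx),
    length  = c(net$length[keep], net$length[i1] / 2, net$length[i1] / 2,
                net$length[i2] / 2, net$length[i2] / 2, length),
    gamma   = c(net$gamma[keep], NA, NA, 1 - gamma, NA, gamma),
    transfer = c(net$transfer[keep], FALSE, FALSE, FALSE, FALSE, TRUE),
    root = net$root)
}

#' Remove a reticulation arc, suppressing its attachment points
#'
#' Inverse of [add_reticulation()]: deletes the horizontal arc, then
#' suppresses the two midpoint nodes by merging the edge halves (lengths
#' are summed). Applied to the arc just added, it recovers the input
#' network exactly.
#'
#' @param net A `phylo_network`.
#' @param arc Edge id of the reticulation arc to remove.
#' @return A `phylo_network` with one fewer reticulation node.
#' @export
remove_reticulation <- function(net, arc) {
  i <- edge_index(net, arc)
  if (!is_reticulation_edge(net)[i]) {
    stop("'", arc, "' is not a reticulation edge", call. = FALSE)
  }
  keep <- setdiff(seq_along(net$parent), i)
  p <- net$parent[keep]; ch <- net$child[keep]; len <- net$length[keep]
  g <- net$gamma[keep]; tr <- net$transfer[keep]
  # the former reticulation node now has in-degree 1: clear gamma on the
  # surviving incoming edge
  g[ch == net$child[i]] <- NA_real_
  sup <- suppress_degree_two(p, ch, len, g, tr, net$root,
                             leaves = network_leaves(net))
  new_phylo_network(sup$parent, sup$child, sup$length, sup$gamma,
                    sup$transfer, sup$root)
}

# Merge nodes of in-degree 1 / out-degree 1 (summing lengths), and contract
# the root while it has a single child. gamma/transfer of a merged chain is
# inherited from its bottom-most constituent (the edge nearest the child),
# so a reticulation edge keeps its annotation when its tail is suppressed.
suppress_degree_two <- function(parent, child, length, gamma, transfer, root,
                                leaves = NULL) {
  nodes <- unique(c(root, parent, child))
  pi <- match(parent, nodes); ci <- match(child, nodes)
  ri <- match(root, nodes)
  keep <- rep(TRUE, length(pi))
  nn <- length(nodes)
  is_leaf <- if (is.null(leaves)) !(nodes %in% parent) else nodes %in% leaves
  repeat {
    outd <- tabulate(pi[keep], nn); ind <- tabulate(ci[keep], nn)
    # prune dangling internal nodes (no surviving children, not a taxon)
    dead <- which(outd == 0L & !is_leaf & ind > 0L)
    if (length(dead)) {
      keep[keep & ci %in% dead] <- FALSE
      next
    }
    if (outd[ri] == 1L && ind[ri] == 0L) {
      e <- which(keep & pi == ri)
      keep[e] <- FALSE
      ri <- ci[e]
      next
    }
    mid <- which(ind == 1L & outd == 1L)
    mid <- mid[mid != ri]
    if (!length(mid)) break
    for (u in mid) {
      ein <- which(keep & ci == u); eout <- which(keep & pi == u)
      pi[eout] <- pi[ein]
      length[eout] <- length[eout] + length[ein]
      keep[ein] <- FALSE
    }
  }
  list(parent = nodes[pi[keep]], child = nodes[ci[keep]],
       length = length[keep], gamma = gamma[keep],
       transfer = transfer[keep], root = nodes[ri])
}

#' Diameter and height of a reticulation event
#'
#' The diameter of a reticulation arc is the length of the path along the
#' underlying species tree (the network with all horizontal transfer arcs
#' removed) between the donor and recipient attachment points. The height
#' is the sum of the lengths of the paths from the donor and the recipient
#' down to their respective farthest descendant leaves.
#'
#' @param net A `phylo_network`.
#' @param arc Edge id of a reticulation arc (an edge flagged as the
#'   horizontal transfer arc, e.g. as created by [add_reticulation()] or
#'   read from the `#H` reference occurrence in extended Newick).
#' @return A list with elements `diameter` and `height` (both in expected
#'   substitutions/site).
#' @export
reticulation_geometry <- function(net, arc) {
  i <- edge_index(net, arc)
  if (!is_reticulation_edge(net)[i] || !isTRUE(net$transfer[i])) {
    stop("'", arc, "' is not a reticulation transfer arc", call. = FALSE)
  }
  donor <- net$parent[i]; recipient <- net$child[i]
  keep <- !net$transfer
  p <- net$parent[keep]; ch <- net$child[keep]; len <- net$length[keep]
  # path to root with cumulative lengths, on the underlying tree
  path_up <- function(v) {
    nodes <- v; dist <- 0
    while (v != net$root) {
      e <- which(ch == v)
      if (length(e) != 1L) stop("underlying tree is not well formed")
      dist <- c(dist, dist[length(dist)] + len[e])
      v <- p[e]
      nodes <- c(nodes, v)
    }
    stats::setNames(dist, nodes)
  }
  d1 <- path_up(donor); d2 <- path_up(recipient)
  common <- intersect(names(d1), names(d2))
  diameter <- min(d1[common] + d2[common])
  # farthest descendant leaf below a node, on the underlying tree
  depth_below <- function(v) {
    out <- which(p == v)
    if (!length(out)) return(0)
    max(vapply(out, function(e) len[e] + depth_below(ch[e]), 0))
  }
  list(diameter = unname(diameter),
       height = depth_below(donor) + depth_below(recipient))
}

#' Robinson-Foulds distance between two trees
#'
#' Unnormalized symmetric-difference count of non-trivial bipartitions,
#' computed on the unrooted topologies (the standard convention).
#'
#' @param tree1,tree2 [ape::phylo] trees on the same taxon set.
#' @return Non-negative integer RF distance.
#' @export
rf_distance <- function(tree1, tree2) {
  if (!setequal(tree1$tip.label, tree2$tip.label)) {
    stop("trees are on different taxon sets", call. = FALSE)
  }
  as.integer(phangorn::RF.dist(ape::unroot(tree1), ape::unroot(tree2),
                               check.labels = TRUE))
}
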