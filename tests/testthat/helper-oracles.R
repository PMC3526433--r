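# Independent oracles used to check the package's core computations.
# These deliberately re-derive everything from first principles (igraph
# graph surgery, exhaustive ancestral-state summation, brute-force
# bipartitions) and never call the code paths they verify.

# ---- graph oracles ------------------------------------------------------

# cycle detection by igraph
oracle_has_cycle <- function(net) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$parent, to = net$child), directed = TRUE)
  !igraph::is_dag(g)
}

# displayed trees by explicit graph surgery: for one induction choice
# (kept incoming edge index per reticulation node, in sorted node order),
# drop the other incoming edges, drop everything unreachable from the
# root, contract degree-2 chains summing lengths, drop single-child
# roots. Returns list(parent, child, length, root).
oracle_displayed <- function(net, choice) {
  ret <- sort(names(which(table(net$child) == 2)))
  drop <- integer(0)
  for (i in seq_along(ret)) {
    inc <- sort(which(net$child == ret[i]))
    drop <- c(drop, inc[3 - choice[i]])
  }
  keep <- setdiff(seq_along(net$parent), drop)
  p <- net$parent[keep]; ch <- net$child[keep]; len <- net$length[keep]
  g <- igraph::graph_from_data_frame(
    data.frame(from = p, to = ch, weight = len), directed = TRUE)
  reach <- igraph::subcomponent(g, net$root, mode = "out")
  g <- igraph::induced_subgraph(g, reach)
  taxa <- net$child[!(net$child %in% net$parent)]
  repeat {
    deg_in <- igraph::degree(g, mode = "in")
    deg_out <- igraph::degree(g, mode = "out")
    nm <- igraph::V(g)$name
    dangling <- nm[deg_out == 0 & !(nm %in% taxa)]
    if (length(dangling)) { g <- igraph::delete_vertices(g, dangling); next }
    root <- nm[deg_in == 0]
    if (length(root) == 1 && deg_out[root] == 1) {
      g <- igraph::delete_vertices(g, root); next
    }
    mid <- nm[deg_in == 1 & deg_out == 1]
    if (!length(mid)) break
    v <- mid[1]
    ein <- igraph::incident(g, v, "in"); eout <- igraph::incident(g, v, "out")
    up <- igraph::tail_of(g, ein)$name
    down <- igraph::head_of(g, eout)$name
    w <- ein$weight + eout$weight
    g <- igraph::delete_vertices(g, v)
    g <- igraph::add_edges(g, c(up, down), attr = list(weight = w))
  }
  el <- igraph::as_data_frame(g)
  nm <- igraph::V(g)$name
  list(parent = el$from, child = el$to, length = el$weight,
       root = nm[igraph::degree(g, mode = "in")[nm] == 0])
}

# all induction choices of a network (rows: one index in {1,2} per
# reticulation node, sorted node order)
oracle_choices <- function(net) {
  h <- sum(table(net$child) == 2)
  if (h == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  as.matrix(expand.grid(rep(list(1:2), h)))
}

# product of kept-edge gammas for one choice
oracle_choice_weight <- function(net, choice) {
  ret <- sort(names(which(table(net$child) == 2)))
  w <- 1
  for (i in seq_along(ret)) {
    inc <- sort(which(net$child == ret[i]))
    w <- w * net$gamma[inc[choice[i]]]
  }
  w
}

# unrooted-topology key of an edge-list tree: sorted non-trivial splits
oracle_topo_key <- function(tr) {
  taxa <- sort(setdiff(tr$child, tr$parent))
  desc <- function(v) {
    out <- which(tr$parent == v)
    if (!length(out)) return(v)
    sort(unlist(lapply(tr$child[out], desc)))
  }
  splits <- character(0)
  for (v in unique(tr$parent)) {
    s <- desc(v)
    if (length(s) <= 1 || length(s) >= length(taxa) - 1) next
    o <- setdiff(taxa, s)
    side <- if (paste(s, collapse = ",") < paste(o, collapse = ",")) s else o
    splits <- c(splits, paste(side, collapse = ","))
  }
  paste(sort(unique(splits)), collapse = ";")
}

oracle_topo_key_phylo <- function(tree) {
  net <- as_phylo_network(tree)
  oracle_topo_key(list(parent = net$parent, child = net$child))
}

# P(T | N, gamma) by full enumeration
oracle_tree_probability <- function(net, tree) {
  key <- oracle_topo_key_phylo(tree)
  ch <- oracle_choices(net)
  tot <- 0
  for (r in seq_len(nrow(ch))) {
    dt <- oracle_displayed(net, ch[r, ])
    if (oracle_topo_key(dt) == key) {
      tot <- tot + oracle_choice_weight(net, ch[r, ])
    }
  }
  tot
}

# ---- likelihood oracles -------------------------------------------------

# exhaustive tree likelihood: sum over all ancestral state assignments;
# tr: edge-list tree; aln: character matrix taxa x sites
oracle_tree_likelihood <- function(tr, aln, tstv = 2) {
  bases <- c("A", "C", "G", "T")
  internal <- unique(tr$parent)
  taxa <- setdiff(tr$child, tr$parent)
  P <- lapply(seq_along(tr$parent),
              function(e) k80_transition_matrix(tr$length[e], tstv))
  lik <- 1
  for (s in seq_len(ncol(aln))) {
    tot <- 0
    grid <- expand.grid(rep(list(1:4), length(internal)))
    for (r in seq_len(nrow(grid))) {
      st <- stats::setNames(as.integer(grid[r, ]), internal)
      pr <- 0.25
      ok <- TRUE
      for (e in seq_along(tr$parent)) {
        a <- st[[tr$parent[e]]]
        child <- tr$child[e]
        if (child %in% taxa) {
          obs <- aln[child, s]
          if (obs %in% bases) {
            pr <- pr * P[[e]][a, match(obs, bases)]
          } # missing: sums to 1, multiply by 1
        } else {
          pr <- pr * P[[e]][a, st[[child]]]
        }
      }
      tot <- tot + pr
    }
    lik <- lik * tot
  }
  log(lik)
}

# network likelihood by full enumeration over induction sets and
# exhaustive tree likelihoods; genes: list of character matrices
oracle_network_loglik <- function(net, genes, tstv = 2) {
  ch <- oracle_choices(net)
  trees <- lapply(seq_len(nrow(ch)), function(r) oracle_displayed(net, ch[r, ]))
  ws <- vapply(seq_len(nrow(ch)), function(r)
    oracle_choice_weight(net, ch[r, ]), 0)
  tot <- 0
  for (g in genes) {
    liks <- vapply(trees, function(tr)
      exp(oracle_tree_likelihood(tr, g, tstv)), 0)
    tot <- tot + log(sum(ws * liks))
  }
  tot
}

# brute-force RF: symmetric difference of non-trivial bipartitions
oracle_rf <- function(t1, t2) {
  s1 <- strsplit(oracle_topo_key_phylo(t1), ";")[[1]]
  s2 <- strsplit(oracle_topo_key_phylo(t2), ";")[[1]]
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# ---- fixture builders ---------------------------------------------------

# random valid network: seeded random tree plus h random reticulations
random_network <- function(ntaxa = 6, h = 1, seed = 1) {
  set.seed(seed)
  tree <- ape::rtree(ntaxa, tip.label = sprintf("t%d", seq_len(ntaxa)))
  net <- as_phylo_network(tree)
  for (i in seq_len(h)) {
    cand <- enumerate_additions(net)
    if (!nrow(cand)) break
    j <- sample.int(nrow(cand), 1)
    g <- sample(seq(0.1, 0.9, by = 0.1), 1)
    net <- add_reticulation(net, cand$donor[j], cand$recipient[j], gamma = g)
  }
  net
}

random_alignment <- function(taxa, sites, seed = 1) {
  set.seed(seed)
  matrix(sample(c("A", "C", "G", "T"), length(taxa) * sites, replace = TRUE),
         nrow = length(taxa), dimnames = list(taxa, NULL))
}
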