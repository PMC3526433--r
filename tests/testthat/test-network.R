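test_that("a plain binary tree is a valid network and trees round-trip", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):2);")
  net <- as_phylo_network(tree)
  expect_identical(validate_network(net), character(0))
  expect_identical(network_leaves(net), c("A", "B", "C", "D"))
  dt <- displayed_trees(net)
  expect_equal(nrow(dt), 1L)
  expect_equal(dt$prob, 1.0, ignore_attr = TRUE)
  expect_equal(oracle_rf(dt$tree[[1]], tree), 0)
})

test_that("validate_network reports gamma, degree and cycle violations", {
  tree <- make_species_tree(4)
  net <- as_phylo_network(tree)
  net2 <- add_reticulation(net, pendant_edge(net, "t3"),
                           pendant_edge(net, "t2"), gamma = 0.3)
  # corrupt the gamma pair
  bad <- net2
  bad$gamma[which(!is.na(bad$gamma))[1]] <- 0.6
  v <- validate_network(bad)
  expect_match(v, "do not sum to 1", all = FALSE)
  # a back-edge creating a directed cycle
  cyc <- net
  cyc$parent <- c(cyc$parent, "t4", "n3")
  cyc$child <- c(cyc$child, "n3", "t4x")
  cyc$length <- c(cyc$length, 0.1, 0.1)
  cyc$gamma <- c(cyc$gamma, NA, NA)
  cyc$transfer <- c(cyc$transfer, FALSE, FALSE)
  # t4 -> n3 while n3 is an ancestor of t4: cycle
  expect_true(oracle_has_cycle(cyc))
  expect_match(validate_network(cyc), "cycle", all = FALSE)
})

test_that("displayed trees of reticulate networks match enumeration", {
  net0 <- as_phylo_network(make_species_tree(8))
  # single reticulation: probabilities gamma and 1 - gamma
  net1 <- add_reticulation(net0, pendant_edge(net0, "t3"),
                           pendant_edge(net0, "t2"), gamma = 0.3)
  dt1 <- displayed_trees(net1)
  expect_equal(sort(dt1$prob), c(0.3, 0.7), ignore_attr = TRUE)
  expect_equal(sum(dt1$prob), 1)
  # two well-separated reticulations, gammas 0.2 and 0.4: four distinct
  # topologies with product probabilities
  net2 <- add_reticulation(net1, pendant_edge(net1, "t7"),
                           pendant_edge(net1, "t6"), gamma = 0.4)
  dt2 <- displayed_trees(net2)
  expect_equal(nrow(dt2), 4L)
  g1 <- 0.3; g2 <- 0.4
  expect_equal(sort(dt2$prob),
               sort(c((1 - g1) * (1 - g2), g1 * (1 - g2),
                      (1 - g1) * g2, g1 * g2)),
               ignore_attr = TRUE)
  expect_equal(sum(dt2$prob), 1)
  # against the independent graph-surgery oracle, topology by topology
  for (i in seq_len(nrow(dt2))) {
    expect_equal(tree_probability(net2, dt2$tree[[i]]),
                 oracle_tree_probability(net2, dt2$tree[[i]]))
  }
})

test_that("tree_probability handles undisplayed trees and merged inductions", {
  net0 <- as_phylo_network(make_species_tree(6))
  net1 <- add_reticulation(net0, pendant_edge(net0, "t3"),
                           pendant_edge(net0, "t2"), gamma = 0.3)
  other <- ape::read.tree(text = paste0(
    "(((t1:1,t6:1):1,(t2:1,t5:1):1):1,(t3:1,t4:1):2);"))
  expect_equal(tree_probability(net1, other), 0)
  expect_error(tree_probability(net1, ape::rtree(4)), "taxon set")
  # a topology-neutral reticulation (recipient regrafted onto the edge
  # directly above its parent): both induction choices give the same
  # unrooted topology, so their weights add
  eid <- network_edge_ids(net0)
  net_neutral <- add_reticulation(net0, "n3->n2", pendant_edge(net0, "t3"),
                                  gamma = 0.3)
  dtn <- displayed_trees(net_neutral)
  expect_equal(nrow(dtn), 1L)
  expect_equal(dtn$n_inductions, 2L, ignore_attr = TRUE)
  expect_equal(dtn$prob, 1, ignore_attr = TRUE)
  expect_equal(tree_probability(net_neutral, dtn$tree[[1]]),
               oracle_tree_probability(net_neutral, dtn$tree[[1]]))
})

test_that("probabilities over displayed trees sum to one on random networks", {
  for (seed in 1:25) {
    net <- random_network(ntaxa = 5 + seed %% 4, h = 1 + seed %% 3,
                          seed = seed)
    expect_equal(sum(displayed_trees(net)$prob), 1, tolerance = 1e-12)
  }
})

test_that("add_reticulation subdivides at midpoints and rejects bad pairs", {
  tree <- ape::read.tree(text = "(((A:0.4,B:0.3):0.2,C:0.5):0.1,D:0.6);")
  net <- as_phylo_network(tree)
  eA <- pendant_edge(net, "A")   # length 0.4
  eC <- pendant_edge(net, "C")
  net2 <- add_reticulation(net, eA, eC, gamma = 0.2)
  # pendant edge of A (0.4) split into equal halves of 0.2
  expect_equal(net2$length[net2$child == "A"], 0.2)
  expect_equal(net2$length[grepl("^x", net2$parent) & net2$child == "A"], 0.2)
  expect_equal(net2$length[net2$parent == "n1" & grepl("^x", net2$child)], 0.2)
  # underlying-tree length is conserved (arc has length 0)
  expect_equal(sum(net2$length[!net2$transfer]), sum(net$length))
  expect_error(add_reticulation(net, eA, eA, gamma = 0.5), "identical")
  eB <- pendant_edge(net, "B")
  expect_error(add_reticulation(net, eA, eB, gamma = 0.5), "sibling")
  # arc into an ancestor edge of the donor edge's tail closes a cycle
  expect_error(add_reticulation(net2, pendant_edge(net2, "B"),
                                pendant_edge(net2, "B"), gamma = 0.5),
               "identical")
  anc_edge <- "n3->n2"
  expect_error(add_reticulation(net, "n2->n1", anc_edge, gamma = 0.5),
               "cycle")
  # removing the arc again recovers the network exactly
  arc <- network_edge_ids(net2)[net2$transfer]
  expect_identical(write_network(remove_reticulation(net2, arc)),
                   write_network(net))
})

test_that("reticulation geometry matches the study trees and a path oracle", {
  # diameter-study caterpillar: pendants 0.05, internals 0.1; donor t1
  ser <- diameter_series()
  expect_equal(vapply(ser$variants, `[[`, 0, "diameter"),
               seq(0.15, 0.65, by = 0.1))
  # placement-study caterpillar: pendants/internals 0.25, donor t3
  net <- as_phylo_network(make_species_tree(16))
  for (cfg in list(list(r = "t2", d = 0.5), list(r = "t6", d = 1.0),
                   list(r = "t8", d = 1.5))) {
    net2 <- add_reticulation(net, pendant_edge(net, "t3"),
                             pendant_edge(net, cfg$r), gamma = 0.3)
    g <- reticulation_geometry(net2, network_edge_ids(net2)[net2$transfer])
    expect_equal(g$diameter, cfg$d)
    # both attachments halve pendant 0.25 edges
    expect_equal(g$height, 0.25)
    # independent all-pairs path oracle on the underlying tree
    und <- net2
    keep <- !und$transfer
    gg <- igraph::graph_from_data_frame(
      data.frame(from = und$parent[keep], to = und$child[keep],
                 weight = und$length[keep]), directed = FALSE)
    arc <- which(net2$transfer)
    d_or <- igraph::distances(gg, v = net2$parent[arc],
                              to = net2$child[arc])[1, 1]
    expect_equal(g$diameter, unname(d_or))
  }
  expect_error(reticulation_geometry(net, network_edge_ids(net)[1]),
               "not a reticulation")
})

test_that("rf_distance agrees with brute-force bipartitions", {
  t1 <- ape::read.tree(text = "((((A:1,B:1):1,C:1):1,D:1):1,E:1);")
  expect_equal(rf_distance(t1, t1), 0L)
  # one NNI away: distance 2
  t2 <- ape::read.tree(text = "((((A:1,C:1):1,B:1):1,D:1):1,E:1);")
  expect_equal(rf_distance(t1, t2), 2L)
  expect_equal(rf_distance(t1, t2), oracle_rf(t1, t2))
  set.seed(42)
  for (i in 1:10) {
    a <- ape::rtree(7); b <- ape::rtree(7)
    expect_equal(rf_distance(a, b), oracle_rf(a, b))
    expect_equal(rf_distance(a, b), rf_distance(b, a))
  }
  expect_error(rf_distance(t1, ape::rtree(4)), "taxon")
})
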