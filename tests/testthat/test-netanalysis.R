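triangle <- function() igraph::make_graph(c("a","b","b","c","c","a"),
                                          directed = FALSE)
path4 <- function() igraph::make_graph(c("a","b","b","c","c","d"),
                                       directed = FALSE)
star4 <- function() igraph::make_graph(c("hub","l1","hub","l2","hub","l3"),
                                       directed = FALSE)

test_that("global properties match closed forms", {
  gp <- global_properties(triangle())
  expect_equal(gp$density, 1)
  expect_equal(gp$average_clustering_coefficient, 1)
  expect_equal(gp$average_degree, 2)

  gp2 <- global_properties(path4())
  expect_equal(gp2$average_path_length, 10 / 6)
  expect_equal(gp2$n_components, 1)

  gp3 <- global_properties(star4())
  expect_equal(gp3$average_clustering_coefficient, 0)
  expect_equal(gp3$density, 0.5)
})

test_that("centralities on the star match hand enumeration", {
  ct <- node_centralities(star4())
  hub <- ct[ct$node == "hub", ]
  expect_equal(hub$betweenness, 3)
  expect_equal(hub$stress, 3)
  leaf <- ct[ct$node == "l1", ]
  expect_equal(leaf$betweenness, 0)
  expect_equal(leaf$stress, 0)
})

test_that("betweenness and stress equal exhaustive path enumeration", {
  for (s in 1:25) {
    n <- sample(5:12, 1)
    g <- random_ugraph(n, stats::runif(1, 0.2, 0.6), seed = 40 + s)
    ct <- node_centralities(g)
    oracle <- enumerate_centralities(as_mn_graph(g))
    expect_equal(stats::setNames(ct$betweenness, ct$node),
                 oracle$betweenness[ct$node], tolerance = 1e-9)
    expect_equal(stats::setNames(ct$stress, ct$node),
                 oracle$stress[ct$node])
  }
})

test_that("module detection recovers planted cliques deterministically", {
  cl1 <- t(combn(paste0("a", 1:5), 2))
  cl2 <- t(combn(paste0("b", 1:5), 2))
  el <- rbind(cl1, cl2, c("a1", "b1"))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  p <- detect_modules(g)
  expect_equal(p$n_modules, 2)
  memb <- p$membership
  expect_equal(length(unique(memb[paste0("a", 1:5)])), 1)
  expect_equal(length(unique(memb[paste0("b", 1:5)])), 1)
  expect_gt(p$modularity, 0)
  expect_identical(detect_modules(g)$membership, memb)

  single <- igraph::graph_from_edgelist(cl1, directed = FALSE)
  expect_equal(detect_modules(single)$n_modules, 1)
  empty <- igraph::make_empty_graph(10, directed = FALSE)
  expect_error(detect_modules(empty), "edge")
})

test_that("zi-Pi closed forms and role assignment", {
  # all edges inside own module -> P = 0
  cl <- igraph::graph_from_edgelist(t(combn(paste0("a", 1:4), 2)),
                                    directed = FALSE)
  zp <- zi_pi(cl)
  expect_true(all(zp$P_i == 0))

  # degree 4 split 2/2 across two modules -> P = 0.5
  el <- rbind(c("v", "m1a"), c("v", "m1b"), c("v", "m2a"), c("v", "m2b"),
              c("m1a", "m1b"), c("m2a", "m2b"))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  part <- structure(list(membership = c(v = 1L, m1a = 1L, m1b = 1L,
                                        m2a = 2L, m2b = 2L),
                         modularity = 0, n_modules = 2L),
                    class = "module_partition")
  zp2 <- zi_pi(g, part)
  expect_equal(zp2$P_i[zp2$node == "v"], 0.5)

  # planted hub: star K1,12 in one module -> z > 2.5, all edges internal
  star <- igraph::graph_from_edgelist(
    cbind("hub", paste0("l", 1:12)), directed = FALSE)
  part2 <- structure(list(membership = stats::setNames(
    rep(1L, 13), c("hub", paste0("l", 1:12))),
    modularity = 0, n_modules = 1L), class = "module_partition")
  zp3 <- zi_pi(star, part2)
  hub <- zp3[zp3$node == "hub", ]
  expect_gt(hub$z_i, 2.5)
  expect_equal(hub$P_i, 0)
  expect_equal(hub$role, "module hub")
  expect_true(all(zp3$role[zp3$node != "hub"] == "peripheral"))
})

test_that("zi-Pi invariants on random graphs", {
  for (s in 1:10) {
    g <- random_ugraph(15, 0.3, seed = 70 + s)
    g <- as_mn_graph(g)
    comp <- igraph::components(g)
    if (max(comp$csize) < 3) next
    part <- detect_modules(igraph::induced_subgraph(
      g, which(comp$membership == which.max(comp$csize))))
    sub <- igraph::induced_subgraph(g, names(part$membership))
    zp <- zi_pi(sub, part)
    M <- part$n_modules
    expect_true(all(zp$P_i >= -1e-12))
    expect_true(all(zp$P_i <= 1 - 1 / M + 1e-12))
    # within-module degree fractions sum to 1 for k > 0
    A <- as.matrix(igraph::as_adjacency_matrix(sub))
    for (v in zp$node[zp$degree > 0]) {
      fr <- vapply(seq_len(M), function(mm) {
        sum(A[v, names(part$membership)[part$membership == mm]])
      }, 0) / zp$degree[zp$node == v]
      expect_equal(sum(fr), 1)
    }
  }
})

test_that("merge_attributes joins by node with suffixes and dropped taxonomy", {
  g <- as_mn_graph(path4() + igraph::vertices("e"))
  ct <- node_centralities(igraph::add_edges(g, c("d", "e")))
  zp <- zi_pi(igraph::add_edges(g, c("d", "e")))
  tax <- data.frame(id = c("a", "b", "zzz"), taxon = c("T1", "T2", "T3"))
  expect_message(out <- merge_attributes(ct, zp, tax), "dropped 1")
  expect_equal(nrow(out), 5)
  expect_equal(sum(is.na(out$taxon)), 3)
  expect_true("clustering_coefficient" %in% names(out))

  bad <- rbind(ct, ct[1, ])
  expect_error(merge_attributes(bad, zp), "duplicate")
})

test_that("network intersection is idempotent, commutative, bounded", {
  g1 <- igraph::graph_from_edgelist(rbind(c("a","b"), c("b","c"), c("c","d")),
                                    directed = FALSE)
  g2 <- igraph::graph_from_edgelist(rbind(c("b","a"), c("c","b"), c("d","e")),
                                    directed = FALSE)
  self <- intersect_networks(g1, g1)
  expect_equal(igraph::ecount(self$graph), igraph::ecount(g1))
  i12 <- intersect_networks(g1, g2)
  i21 <- intersect_networks(g2, g1)
  expect_equal(i12$edge_list, i21$edge_list)
  expect_equal(nrow(i12$edge_list), 2)  # a-b and b-c (direction-free)
  expect_lte(igraph::ecount(i12$graph),
             min(igraph::ecount(g1), igraph::ecount(g2)))
  # nodes are endpoints of kept edges only
  expect_setequal(igraph::V(i12$graph)$name, c("a", "b", "c"))

  g3 <- igraph::graph_from_edgelist(rbind(c("x","y")), directed = FALSE)
  expect_warning(empty <- intersect_networks(g1, g3), "no edge")
  expect_equal(igraph::ecount(empty$graph), 0)
})
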