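test_that("metabolite graph has substrate->product edges, reversibility, no self-loops", {
  g <- build_metabolite_graph(make_toy_model(c("a -> b", "b -> c")))
  el <- igraph::as_edgelist(g)
  expect_setequal(paste(el[, 1], el[, 2]), c("a b", "b c"))

  g2 <- build_metabolite_graph(make_toy_model("a <-> b"))
  el2 <- igraph::as_edgelist(g2)
  expect_setequal(paste(el2[, 1], el2[, 2]), c("a b", "b a"))

  g3 <- build_metabolite_graph(make_toy_model("R: a + b -> c"))
  el3 <- igraph::as_edgelist(g3)
  expect_setequal(paste(el3[, 1], el3[, 2]), c("a c", "b c"))

  # compartment-merged substrate==product drops the self-loop
  g4 <- build_metabolite_graph(make_toy_model("T: g_e -> g_c"))
  expect_equal(igraph::ecount(g4), 0)
  # but with identity rule the transport edge survives
  g5 <- build_metabolite_graph(make_toy_model("T: g_e -> g_c"), rule = "identity")
  expect_equal(igraph::ecount(g5), 1)
})

test_that("boundary species and exchange reactions contribute no edges", {
  m <- make_toy_model(c("EX_g: g ->", "R1: g -> x"))
  g <- build_metabolite_graph(m)
  el <- igraph::as_edgelist(g)
  expect_equal(paste(el[, 1], el[, 2]), "g x")
  m$metabolites$boundary[m$metabolites$full_id == "g"] <- TRUE
  g2 <- build_metabolite_graph(m)
  expect_false("g" %in% igraph::V(g2)$name)
})

test_that("SCCs match brute-force mutual reachability on random graphs", {
  for (s in 1:25) {
    n <- sample(4:30, 1)
    g <- random_digraph(n, stats::runif(1, 0.05, 0.3), seed = 100 + s)
    got <- compute_sccs(g)
    # oracle: mutual reachability classes from transitive closure
    A <- matrix(FALSE, n, n)
    el <- igraph::as_edgelist(g, names = FALSE)
    if (nrow(el)) A[el] <- TRUE
    R <- A | diag(TRUE, n)
    for (k in seq_len(ceiling(log2(n)) + 1)) R <- (R %*% R) > 0
    mutual <- R & t(R)
    nm <- igraph::V(g)$name
    oracle_comp <- unique(apply(mutual, 1, function(row) paste(sort(nm[row]), collapse = ",")))
    got_comp <- vapply(got$components, function(cc) paste(sort(cc), collapse = ","), "")
    expect_setequal(got_comp, oracle_comp)
  }
})

test_that("hand-worked seed fixtures", {
  # chain a->b->c: a is the only seed
  s <- detect_seed_set(build_metabolite_graph(make_toy_model(c("a -> b", "b -> c"))))
  expect_equal(s$seeds, c(a = 1))
  expect_equal(s$nonseeds, c("b", "c"))

  # cycle a<->b feeding c: the cycle is the seed component, C = 1/2 each
  s2 <- detect_seed_set(build_metabolite_graph(make_toy_model(c("a <-> b", "b -> c"))))
  expect_equal(s2$seeds, c(a = 0.5, b = 0.5))
  expect_equal(s2$nonseeds, "c")

  # 6-cycle source component above MaxCC=5: members become nonseeds
  cyc6 <- make_toy_model(c("m1 -> m2", "m2 -> m3", "m3 -> m4", "m4 -> m5",
                           "m5 -> m6", "m6 -> m1", "m1 -> out"))
  expect_message(
    s3 <- detect_seed_set(build_metabolite_graph(cyc6), max_cc = 5),
    "above MaxCC")
  expect_equal(length(s3$seeds), 0)
  expect_setequal(s3$nonseeds, c(sprintf("m%d", 1:6), "out"))
  # with max_cc = 6 the component qualifies, C = 1/6
  s4 <- detect_seed_set(build_metabolite_graph(cyc6), max_cc = 6)
  expect_equal(unname(s4$seeds), rep(1 / 6, 6))

  expect_error(detect_seed_set(build_metabolite_graph(cyc6), max_cc = 0),
               "max_cc")
})

test_that("oracle agrees and handles the complete bidirectional triangle", {
  g <- igraph::make_graph(c("a", "b", "b", "a", "b", "c", "c", "b",
                            "a", "c", "c", "a"), directed = TRUE)
  o <- brute_force_seed_oracle(g, max_cc = 5)
  expect_equal(sort(names(o$seeds)), c("a", "b", "c"))
  expect_equal(unname(o$seeds), rep(1 / 3, 3))
  big <- random_digraph(51, 0.1, seed = 1)
  expect_error(brute_force_seed_oracle(big), "refuses")
})

test_that("detect_seed_set matches the oracle on random graphs", {
  for (s in 1:50) {
    n <- sample(4:30, 1)
    g <- random_digraph(n, stats::runif(1, 0.03, 0.25), seed = 500 + s)
    a <- detect_seed_set(g, max_cc = 5)
    b <- brute_force_seed_oracle(g, max_cc = 5)
    expect_equal(a$seeds, b$seeds)
    expect_equal(a$nonseeds, b$nonseeds)
  }
})

test_that("seed-set invariants hold", {
  # per-component confidences sum to 1 exactly
  g <- random_digraph(20, 0.15, seed = 9)
  s <- detect_seed_set(g, max_cc = 20)
  if (length(s$seeds)) {
    scc <- compute_sccs(g)
    for (cc in scc$components) {
      inseed <- intersect(cc, names(s$seeds))
      if (length(inseed)) expect_equal(sum(s$seeds[inseed]), 1)
    }
  }

  # adding an edge into a seed component from a non-member removes it
  m <- make_toy_model(c("a <-> b", "b -> c"))
  s1 <- detect_seed_set(build_metabolite_graph(m))
  expect_true("a" %in% names(s1$seeds))
  m2 <- make_toy_model(c("a <-> b", "b -> c", "z -> a"))
  s2 <- detect_seed_set(build_metabolite_graph(m2))
  expect_false("a" %in% names(s2$seeds))
  expect_equal(s2$seeds, c(z = 1))

  # seeds invariant to reaction order
  rx <- c("a -> b", "b -> c", "c <-> d", "a -> d")
  sa <- detect_seed_set(build_metabolite_graph(make_toy_model(rx)))
  sb <- detect_seed_set(build_metabolite_graph(make_toy_model(rev(rx))))
  expect_equal(sa$seeds, sb$seeds)
})

test_that("seed set table exports model/metabolite/confidence rows", {
  ss <- chain_seedsets()
  df <- seed_set_table(ss)
  expect_equal(nrow(df), 6)  # 3 metabolites per model
  expect_equal(df$confidence[df$model_id == "A" & df$metabolite == "a"], 1)
  expect_true(all(df$confidence[!df$is_seed] == 0))
})
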