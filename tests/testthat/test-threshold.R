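test_that("unfolding yields unit mean spacing and collapses duplicates", {
  # equally spaced spectrum: unfolded spacings all ~ 1
  u <- unfold_eigenvalues(seq(0, 5, length.out = 50))
  expect_equal(mean(diff(u)), 50 / 49, tolerance = 1e-6)
  expect_lt(max(abs(diff(u) - 1)), 0.05)

  # GOE spectrum n = 200: mean spacing within 5% of 1
  set.seed(3)
  X <- matrix(stats::rnorm(200 * 200), 200)
  ev <- eigen((X + t(X)) / sqrt(400), symmetric = TRUE, only.values = TRUE)$values
  u2 <- unfold_eigenvalues(ev)
  expect_gte(mean(diff(u2)), 0.95)
  expect_lte(mean(diff(u2)), 1.05)

  # duplicates collapsed before unfolding
  ev3 <- c(rep(1, 5), seq(2, 12, length.out = 11))
  u3 <- unfold_eigenvalues(ev3)
  expect_equal(length(u3), 12)

  expect_error(unfold_eigenvalues(1:5), "insufficient")
})

test_that("spacing tests accept Exp(1) and reject Wigner-surmise samples", {
  pois <- sample_spacings(2000, "poisson", seed = 17)
  wig <- sample_spacings(2000, "wigner", seed = 17)
  expect_gt(poisson_spacing_test(pois, "chisq")$p_value, 0.05)
  expect_gt(poisson_spacing_test(pois, "ks")$p_value, 0.05)
  expect_lt(poisson_spacing_test(wig, "chisq")$p_value, 0.01)
  expect_lt(poisson_spacing_test(wig, "ks")$p_value, 0.01)
  expect_error(poisson_spacing_test(numeric(0), "ks"), ">= 10")
})

test_that("z-score fixture {1,2,3,4,100} reproduces both printed formulas", {
  x <- c(1, 2, 3, 4, 100)
  expect_warning(zs <- zscore_outliers(x, method = "standard", cutoff = 2.698),
                 "no value exceeds")
  # mean 22, sample sd sqrt(7610/4)
  expect_equal(zs$center, 22)
  expect_equal(zs$scale, sqrt(7610 / 4))
  expect_equal(zs$table$z[5], (100 - 22) / sqrt(7610 / 4))
  expect_equal(round(zs$table$z[5], 3), 1.788)
  expect_false(zs$table$flagged[5])
  expect_true(is.na(zs$implied_value_threshold))

  zm <- zscore_outliers(x, method = "modified", cutoff = 2.698)
  # median 3, MAD 1
  expect_equal(zm$table$z[5], 0.6745 * 97)
  expect_true(zm$table$flagged[5])
  expect_equal(zm$implied_value_threshold, 100)
})

test_that("z-score structural identities and degenerate errors", {
  set.seed(21)
  x <- stats::rnorm(200)
  zs <- suppressWarnings(zscore_outliers(x, "standard", cutoff = 10))
  expect_lt(abs(mean(zs$table$z)), 1e-12)
  # modified z of the median value is exactly 0
  xm <- c(x, stats::median(x))
  zm <- suppressWarnings(zscore_outliers(xm, "modified", cutoff = 10))
  expect_equal(0.6745 * (stats::median(xm) - zm$center) / zm$scale, 0)

  expect_error(zscore_outliers(rep(1, 10), "standard"), "identical")
  expect_error(zscore_outliers(c(1, 1, 1, 1, 9), "modified"), "standard")
  expect_error(zscore_outliers(c(1, 2), "standard"), ">= 5")
})

test_that("standard and modified flag similar fractions on large normal samples", {
  set.seed(5)
  x <- stats::rnorm(1e5)
  fs <- mean(abs(zscore_outliers(x, "standard", 2.698)$table$flagged))
  fm <- mean(abs(zscore_outliers(x, "modified", 2.698)$table$flagged))
  # 0.6745 calibrates MAD to sd for normal data
  expect_lt(abs(fs - fm), 0.002)
})

test_that("matrix input uses the upper triangle with pair labels", {
  M <- make_planted_matrix(n_blocks = 2, block_size = 4, seed = 3)
  z <- suppressWarnings(zscore_outliers(M, "standard", cutoff = 10))
  expect_equal(nrow(z$table), 28)  # 8*7/2
  expect_true(all(c("A", "B") %in% names(z$table)))
})

test_that("distance_to_similarity is an order-reversing affine map onto [0,1]", {
  set.seed(2)
  n <- 6
  D <- as.matrix(stats::dist(matrix(stats::rnorm(n * 3), n)))
  dimnames(D) <- list(letters[1:n], letters[1:n])
  dm <- index_matrix(D, kind = "distance", symmetric = TRUE)
  s <- distance_to_similarity(dm)
  off <- upper.tri(D)
  expect_equal(s$values[off][which.min(D[off])], 1)
  expect_equal(s$values[off][which.max(D[off])], 0)
  expect_equal(order(s$values[off]), rev(order(D[off])))
  expect_equal(unname(diag(s$values)), rep(0, n))

  same <- index_matrix(matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3])) -
                         diag(3), kind = "distance", symmetric = TRUE)
  expect_error(distance_to_similarity(same), "equal")
})

test_that("apply_threshold builds the expected adjacency", {
  M <- make_planted_matrix(seed = 4)
  # at an in-gap threshold all retained edges are within-block
  nw <- apply_threshold(M, 0.6)
  block <- rep(1:4, each = 10)
  names(block) <- M$ids
  el <- igraph::as_edgelist(nw$graph)
  within <- block[el[, 1]] == block[el[, 2]]
  expect_gte(mean(within), 0.95)
  expect_equal(igraph::ecount(nw$graph), 4 * choose(10, 2))

  # threshold 0 -> complete graph
  full <- suppressMessages(apply_threshold(M, 0))
  expect_equal(igraph::ecount(full$graph), choose(40, 2))
  # threshold above max -> zero-edge error
  expect_error(apply_threshold(M, 1 + 1e-9), "zero edges")
  # weighted adjacency keeps values
  w <- apply_threshold(M, 0.6, weighted = TRUE)
  expect_true(all(igraph::E(w$graph)$weight >= 0.6))
})

test_that("rmt_scan validates input and is deterministic with monotone edges", {
  rec <- data.frame(A = c("x", "x", "y", "y"), B = c("x", "y", "x", "y"),
                    MI_complementarity = c(0, 0.3, 0.7, 0),
                    MI_competition = 0)
  asym <- to_matrix(rec, "complementarity", "asymmetric")
  expect_error(rmt_scan(asym), "symmetric")

  bad <- make_planted_matrix(n_blocks = 2, block_size = 6, seed = 1)
  bad$values <- bad$values * 3
  expect_error(rmt_scan(bad), "distance_to_similarity|normalized")

  M <- make_planted_matrix(seed = 8)
  s1 <- rmt_scan(M, "chisq")
  s2 <- rmt_scan(M, "chisq")
  expect_identical(s1$table, s2$table)
  expect_true(all(diff(s1$table$n_edges) <= 0))
  expect_true(is.na(s1$chosen_threshold) ||
                s1$chosen_threshold %in% s1$table$threshold)
})
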