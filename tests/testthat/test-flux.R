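test_that("FBA solves the hand-worked uptake-limited model", {
  r <- fba(uptake_model(), "Growth")
  expect_equal(r$status, "optimal")
  expect_equal(r$objective_value, 10, tolerance = 1e-6)
  # steady state for every internal metabolite
  m <- uptake_model()
  for (met in m$metabolites$full_id) {
    bal <- sum(vapply(m$reactions, function(rx) {
      if (met %in% names(rx$stoich)) rx$stoich[[met]] * r$fluxes[[rx$id]] else 0
    }, 0))
    expect_lt(abs(bal), 1e-6)
  }
  # bounds respected
  for (rx in m$reactions) {
    expect_gte(r$fluxes[[rx$id]], rx$lower_bound - 1e-6)
    expect_lte(r$fluxes[[rx$id]], rx$upper_bound + 1e-6)
  }
})

test_that("FBA error and degenerate cases", {
  m <- uptake_model()
  expect_error(fba(m, "Biomass"), "candidate biomass-like")
  # blocked model: no uptake -> zero flux, still optimal
  blocked <- make_toy_model(c("R1: g -> x", "Growth: x ->"),
                            objective = "Growth")
  r <- fba(blocked, "Growth")
  expect_equal(r$status, "optimal")
  expect_equal(r$objective_value, 0, tolerance = 1e-9)
})

test_that("pFBA routes through the short pathway and matches the LP oracle", {
  pb <- pfba(branched_model(), "Growth")
  expect_equal(pb$status, "optimal")
  # independent oracle: the optimal face is the 1-parameter family
  #   t = flux through the two-step route, t in [0, 10]
  #   v = (EX=-10, P1=10-t, P2a=t, P2b=t, Growth=10), sum|v| = 30 + t
  ts <- seq(0, 10, by = 0.01)
  oracle_min <- min(10 + (10 - ts) + 2 * ts + 10)
  expect_equal(pb$total_flux, oracle_min, tolerance = 1e-6)
  expect_equal(oracle_min, 30)
  expect_equal(unname(pb$fluxes["P2a"]), 0, tolerance = 1e-6)
  expect_equal(unname(pb$fluxes["P1"]), 10, tolerance = 1e-6)
  # objective preserved within 1e-9 relative
  r1 <- fba(branched_model(), "Growth")
  expect_lt(abs(pb$objective_value - r1$objective_value) /
              abs(r1$objective_value), 1e-9)
})

test_that("pFBA equals FBA on a chain with a unique optimum, and is deterministic", {
  m <- uptake_model()
  r <- fba(m, "Growth")
  p1 <- pfba(m, "Growth")
  p2 <- pfba(m, "Growth")
  expect_equal(p1$fluxes, r$fluxes, tolerance = 1e-6)
  expect_identical(p1$fluxes, p2$fluxes)
  expect_error(pfba(m, "Growth",
                    fba_result = structure(list(status = "infeasible"),
                                           class = "fba_result")),
               "stage-1")
})

test_that("flux table retains the union of nonzero reactions with zero fill", {
  mk <- function(id, fl) structure(
    list(model_id = id, fluxes = fl, status = "optimal"), class = "fba_result")
  r1 <- mk("m1", c(R1 = 10, R2 = 0, R3 = 5))
  r2 <- mk("m2", c(R1 = 1e-12, R4 = 2))
  tab <- build_flux_table(list(r1, r2))
  expect_setequal(tab$reaction_ids, c("R1", "R3", "R4"))
  expect_equal(tab$values["m2", "R1"], 0)   # below threshold -> kept as stored
  expect_equal(tab$values["m2", "R3"], 0)   # absent -> zero fill
  expect_equal(tab$values["m1", "R4"], 0)
  expect_true(all(apply(abs(tab$values), 2, max) > 1e-9))
  expect_error(build_flux_table(list(r1)), ">= 2")
})

test_that("euclidean distances match hand arithmetic and are column-order invariant", {
  vals <- rbind(m1 = c(10, 10, 0), m2 = c(10, 0, 10))
  colnames(vals) <- c("R1", "R2", "R3")
  tab <- structure(list(model_ids = rownames(vals), reaction_ids = colnames(vals),
                        values = vals), class = "flux_table")
  d <- euclidean_distances(tab)
  expect_equal(d$values["m1", "m2"], sqrt(200))
  perm <- tab; perm$values <- perm$values[, c(3, 1, 2)]
  expect_equal(euclidean_distances(perm)$values, d$values)
})

test_that("standardized distances: n=2 closed form, scale invariance, degenerate error", {
  # 2 models, m non-constant columns: each contributes (sqrt(2))^2 with the
  # sample-sd convention, so distance = sqrt(2 m)
  vals <- rbind(m1 = c(1, 5, 7, 3), m2 = c(2, 0, 7, 4))
  colnames(vals) <- sprintf("R%d", 1:4)
  tab <- structure(list(model_ids = rownames(vals), reaction_ids = colnames(vals),
                        values = vals), class = "flux_table")
  expect_message(d <- standardized_distances(tab), "zero-variance")
  m_nonconst <- 3
  expect_equal(d$values["m1", "m2"], sqrt(2 * m_nonconst))

  # scaling any column by 1000 leaves the standardized distance unchanged
  tab2 <- tab; tab2$values[, "R2"] <- tab2$values[, "R2"] * 1000
  expect_message(d2 <- standardized_distances(tab2), "zero-variance")
  expect_equal(d2$values, d$values)

  same <- tab; same$values <- rbind(m1 = c(1, 2), m2 = c(1, 2))
  expect_error(standardized_distances(same), "identical")
})

test_that("metabolic_distance produces consistent matrices and long table", {
  models <- make_demo_models(3, seed = 11)
  d <- suppressMessages(metabolic_distance(models))
  expect_equal(dim(d$raw$values), c(3, 3))
  expect_equal(nrow(d$long_table), 3)
  expect_equal(unname(diag(d$raw$values)), rep(0, 3))
  # raw matrix and long table agree entry-wise
  for (i in seq_len(nrow(d$long_table))) {
    row <- d$long_table[i, ]
    expect_equal(d$raw$values[row$model_A, row$model_B],
                 row$euclidean_distance)
  }
  # metric axioms
  expect_true(isSymmetric(unname(d$raw$values)))
  ids <- d$raw$ids
  for (i in ids) for (j in ids) for (k in ids) {
    expect_lte(d$raw$values[i, j],
               d$raw$values[i, k] + d$raw$values[k, j] + 1e-6)
  }
  # determinism across runs
  d2 <- suppressMessages(metabolic_distance(models))
  expect_identical(d$raw$values, d2$raw$values)
})

test_that("models without the objective are excluded, not fatal", {
  models <- make_demo_models(3, seed = 5)
  rx <- models[[3]]$reactions
  rx[[length(rx)]]$id <- "NotGrowth"
  models[[3]]$reactions <- rx
  expect_warning(d <- suppressMessages(metabolic_distance(models)),
                 "excluding model")
  expect_equal(length(d$raw$ids), 2)
  expect_equal(d$excluded, "demo03")
  # fewer than 2 usable models is fatal
  expect_error(
    suppressWarnings(metabolic_distance(models[c(3, 3)])), "fewer than 2")
})
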