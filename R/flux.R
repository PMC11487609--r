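# Flux balance analysis (FBA), parsimonious FBA and pFBA-based metabolic
# distances.
#
# FBA: max c.v  s.t.  S.v = 0, lb <= v <= ub   (S over internal metabolites)
# pFBA: each reaction split into non-negative forward/backward parts,
#   min sum(v+ + v-)  s.t.  S(v+ - v-) = 0, c.(v+ - v-) fixed at the FBA
#   optimum (within a small tolerance), split-variable bounds from lb/ub.
# Distances: pFBA flux vectors over the union of reactions carrying flux in
# at least one model, then Euclidean (raw) and per-reaction standardized
# Euclidean distance.

stoich_triplets <- function(model) {
  met <- model$metabolites
  internal <- met$full_id[!met$boundary]
  row_of <- stats::setNames(seq_along(internal), internal)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(model$reactions)) {
    s <- model$reactions[[k]]$stoich
    keep <- names(s) %in% internal
    if (!any(keep)) next
    i <- c(i, row_of[names(s)[keep]])
    j <- c(j, rep(k, sum(keep)))
    x <- c(x, unname(s[keep]))
  }
  list(i = i, j = j, x = x, nrow = length(internal),
       ncol = length(model$reactions), metabolites = internal)
}

resolve_objective <- function(model, objective) {
  rids <- reaction_ids(model)
  if (is.null(objective)) {
    oc <- vapply(model$reactions, function(r) r$objective_coefficient, 0)
    if (all(oc == 0)) mn_stop("model '", model$model_id,
                              "' declares no objective")
    return(stats::setNames(oc, rids))
  }
  if (!objective %in% rids) {
    cand <- rids[grepl("growth|biomass|bm", rids, ignore.case = TRUE)]
    mn_stop("objective reaction '", objective, "' not found in model '",
            model$model_id, "'",
            if (length(cand)) paste0("; candidate biomass-like reactions: ",
                                     paste(cand, collapse = ", "))
            else "")
  }
  stats::setNames(as.numeric(rids == objective), rids)
}

fba_problem <- function(model, objective = "Growth") {
  oc <- resolve_objective(model, objective)
  st <- stoich_triplets(model)
  list(c = unname(oc), sense = "max",
       A_eq = as_triplets(st$i, st$j, st$x, st$nrow, st$ncol),
       b_eq = rep(0, st$nrow),
       lb = vapply(model$reactions, `[[`, 0, "lower_bound"),
       ub = vapply(model$reactions, `[[`, 0, "upper_bound"))
}

new_fba_result <- function(model, oc, res) {
  rids <- reaction_ids(model)
  obj_id <- paste(rids[oc != 0], collapse = "+")
  fluxes <- if (identical(res$status, "optimal")) {
    stats::setNames(as.numeric(res$x), rids)
  } else stats::setNames(rep(NA_real_, length(rids)), rids)
  structure(list(model_id = model$model_id, objective_id = obj_id,
                 objective_value = res$objective %||% NA_real_,
                 fluxes = fluxes, status = res$status),
            class = "fba_result")
}

#' @export
print.fba_result <- function(x, ...) {
  cat(sprintf("<fba_result> %s: %s, objective(%s) = %s\n", x$model_id,
              x$status, x$objective_id, format(x$objective_value)))
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes the objective reaction flux subject to steady state and flux
#' bounds. A model with no route to the objective is still optimal with
#' objective 0 (the zero flux vector is always feasible).
#'
#' @param model A `gsmm`.
#' @param objective Objective reaction id (default `"Growth"`, the
#'   conventional biomass reaction name in automatically reconstructed
#'   models); `NULL` uses the model's own declared objective coefficients.
#' @return An `fba_result` with `status` in optimal / infeasible /
#'   unbounded.
#' @export
fba <- function(model, objective = "Growth") {
  oc <- resolve_objective(model, objective)
  res <- solve_lp_batch(list(fba_problem(model, objective)))[[1]]
  new_fba_result(model, oc, res)
}

pfba_problem <- function(model, objective, opt, fix_tolerance) {
  oc <- unname(resolve_objective(model, objective))
  st <- stoich_triplets(model)
  n <- st$ncol
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  # S (v+ - v-) = 0
  A_eq <- as_triplets(c(st$i, st$i), c(st$j, st$j + n), c(st$x, -st$x),
                      st$nrow, 2 * n)
  coef <- c(oc, -oc)
  nz <- which(coef != 0)
  prob <- list(c = rep(1, 2 * n), sense = "min",
               lb = c(pmax(lb, 0), pmax(-ub, 0)),
               ub = c(pmax(ub, 0), pmax(-lb, 0)))
  if (is.null(fix_tolerance)) {
    # exact fixing: append c.v = opt as an equality row (basic solutions
    # satisfy it to machine precision, preserving the objective within
    # 1e-9 relative with margin)
    prob$A_eq <- as_triplets(c(A_eq$i, rep(st$nrow + 1L, length(nz))),
                             c(A_eq$j, nz), c(A_eq$x, coef[nz]),
                             st$nrow + 1L, 2 * n)
    prob$b_eq <- c(rep(0, st$nrow), opt)
  } else {
    slack <- max(abs(opt) * fix_tolerance, fix_tolerance)
    prob$A_eq <- A_eq
    prob$b_eq <- rep(0, st$nrow)
    prob$A_ub <- as_triplets(c(rep(1, length(nz)), rep(2, length(nz))),
                             c(nz, nz), c(-coef[nz], coef[nz]), 2, 2 * n)
    prob$b_ub <- c(-(opt - slack), opt + slack)
  }
  prob
}

pfba_from_opt <- function(model, objective, opt, fix_tolerance) {
  n <- length(model$reactions)
  # exact equality fixing first; fall back to slack constraints on
  # numerical infeasibility, then relax the slack tenfold, then error
  for (tol in list(NULL, fix_tolerance, fix_tolerance * 10)) {
    res <- solve_lp_batch(list(pfba_problem(model, objective, opt, tol)))[[1]]
    if (identical(res$status, "optimal")) {
      v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
      oc <- resolve_objective(model, objective)
      out <- new_fba_result(model, oc,
                            list(status = "optimal",
                                 objective = sum(unname(oc) * v), x = v))
      out$total_flux <- sum(abs(v))
      return(out)
    }
  }
  mn_stop("pFBA stage-2 infeasible for model '", model$model_id,
          "' even after relaxing fix_tolerance to ", fix_tolerance * 10)
}

#' Parsimonious flux balance analysis
#'
#' Fixes the FBA-optimal objective flux and minimizes the total absolute
#' flux, yielding the most economical flux distribution achieving maximal
#' growth. The objective is fixed exactly (equality constraint); on
#' numerical stage-2 infeasibility the fix is relaxed to a slack of
#' `fix_tolerance`, then tenfold more, then an error is raised.
#'
#' @inheritParams fba
#' @param fix_tolerance Relative tolerance on the fixed objective value.
#' @param fba_result Optional precomputed stage-1 [fba()] result.
#' @return An `fba_result` with an extra `total_flux` field (sum |v|).
#' @export
pfba <- function(model, objective = "Growth", fix_tolerance = 1e-9,
                 fba_result = NULL) {
  if (is.null(fba_result)) fba_result <- fba(model, objective)
  if (!identical(fba_result$status, "optimal")) {
    mn_stop("cannot run pFBA: stage-1 FBA status is ", fba_result$status)
  }
  pfba_from_opt(model, objective, fba_result$objective_value, fix_tolerance)
}

#' Assemble flux vectors across models
#'
#' Retains the union of reactions whose absolute flux exceeds
#' `zero_threshold` in at least one model; reactions absent from a model
#' contribute 0.
#'
#' @param results List of optimal `fba_result`s (>= 2).
#' @param zero_threshold Magnitude below which a flux counts as zero.
#' @return Object of class `flux_table`: `model_ids`, `reaction_ids`,
#'   `values` (model x reaction matrix).
#' @export
build_flux_table <- function(results, zero_threshold = 1e-9) {
  ok <- vapply(results, function(r) identical(r$status, "optimal"), TRUE)
  results <- results[ok]
  if (length(results) < 2) mn_stop("need >= 2 models with optimal flux states")
  ids <- vapply(results, `[[`, "", "model_id")
  if (anyDuplicated(ids)) mn_stop("duplicate model ids in flux results")
  keep <- sort(unique(unlist(lapply(results, function(r) {
    names(r$fluxes)[abs(r$fluxes) > zero_threshold]
  }))))
  if (length(keep) == 0) mn_stop("no reaction carries flux in any model")
  vals <- matrix(0, length(results), length(keep), dimnames = list(ids, keep))
  for (k in seq_along(results)) {
    f <- results[[k]]$fluxes
    common <- intersect(names(f), keep)
    vals[k, common] <- f[common]
  }
  structure(list(model_ids = ids, reaction_ids = keep, values = vals),
            class = "flux_table")
}

#' Euclidean metabolic distances
#'
#' @param table A `flux_table`.
#' @return `index_matrix` of kind `distance` (symmetric, zero diagonal).
#' @export
euclidean_distances <- function(table) {
  d <- as.matrix(stats::dist(table$values, method = "euclidean"))
  index_matrix(d, kind = "distance", symmetric = TRUE)
}

#' Standardized Euclidean metabolic distances
#'
#' Each reaction column is standardized across models to mean 0 and unit
#' sample standard deviation (value - mean) / sd before computing Euclidean
#' distances; this removes order-of-magnitude differences between flux
#' scales. Zero-variance columns carry no information and are dropped (the
#' count is logged).
#'
#' @param table A `flux_table` with >= 2 models.
#' @return `index_matrix` of kind `distance`.
#' @export
standardized_distances <- function(table) {
  if (nrow(table$values) < 2) mn_stop("need >= 2 models")
  sds <- apply(table$values, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) {
    mn_stop("all flux columns have zero variance: ",
            "models are metabolically identical")
  }
  if (any(!keep)) {
    mn_log(sprintf("standardized distances: dropped %d zero-variance column(s)",
                   sum(!keep)))
  }
  z <- scale(table$values[, keep, drop = FALSE])
  d <- as.matrix(stats::dist(z, method = "euclidean"))
  index_matrix(d, kind = "distance", symmetric = TRUE)
}

#' Pairwise metabolic distances for a model set
#'
#' Runs FBA then pFBA on every model (batched through the LP backend),
#' assembles the flux table and returns the raw and standardized distance
#' matrices plus a three-column long table of raw distances. Models whose
#' FBA is infeasible/unbounded or that lack the objective reaction are
#' excluded with a logged list rather than failing the run.
#'
#' @param models List of `gsmm` objects.
#' @param objective Objective reaction id (default `"Growth"`).
#' @param zero_threshold Flux-zero threshold for column retention.
#' @param fix_tolerance pFBA objective-fixing tolerance.
#' @return Object of class `distance_result`: `raw`, `standardized`
#'   (`index_matrix`), `long_table` (model_A, model_B,
#'   euclidean_distance), `excluded` (model ids).
#' @export
metabolic_distance <- function(models, objective = "Growth",
                               zero_threshold = 1e-9, fix_tolerance = 1e-9) {
  ids <- vapply(models, `[[`, "", "model_id")
  models <- models[order(ids)]
  usable <- logical(length(models))
  problems <- vector("list", length(models))
  for (k in seq_along(models)) {
    pr <- tryCatch(fba_problem(models[[k]], objective), error = function(e) e)
    if (inherits(pr, "error")) {
      mn_warn("excluding model '", models[[k]]$model_id, "': ",
              conditionMessage(pr))
    } else {
      problems[[k]] <- pr
      usable[k] <- TRUE
    }
  }
  stage1 <- solve_lp_batch(problems[usable])
  kept <- list()
  excluded <- unname(vapply(models[!usable], `[[`, "", "model_id"))
  idx <- which(usable)
  for (k in seq_along(idx)) {
    m <- models[[idx[k]]]
    r1 <- stage1[[k]]
    if (!identical(r1$status, "optimal")) {
      mn_warn("excluding model '", m$model_id, "': FBA status ", r1$status)
      excluded <- c(excluded, m$model_id)
      next
    }
    kept[[length(kept) + 1]] <- pfba_from_opt(m, objective, r1$objective,
                                              fix_tolerance)
  }
  if (length(kept) < 2) mn_stop("fewer than 2 models usable for distances")
  table <- build_flux_table(kept, zero_threshold)
  raw <- euclidean_distances(table)
  std <- standardized_distances(table)
  n <- length(raw$ids)
  pairs <- which(upper.tri(raw$values), arr.ind = TRUE)
  long <- data.frame(model_A = raw$ids[pairs[, 1]],
                     model_B = raw$ids[pairs[, 2]],
                     euclidean_distance = raw$values[pairs],
                     stringsAsFactors = FALSE)
  long <- long[order(long$model_A, long$model_B), ]
  rownames(long) <- NULL
  structure(list(raw = raw, standardized = std, long_table = long,
                 flux_table = table, excluded = excluded),
            class = "distance_result")
}
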