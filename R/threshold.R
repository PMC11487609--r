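# Network threshold selection.
#
# RMT route: for each candidate cutoff, entries below it are zeroed, the
# nearest-neighbor spacing distribution (NNSD) of the unfolded eigenvalues
# of the remaining symmetric matrix is tested against the Poisson law
# P(s) = exp(-s). Uncorrelated (noise-dominated) systems show GOE-like
# level repulsion; as the cutoff removes noise the NNSD transitions to
# Poisson, and the smallest cutoff statistically consistent with Poisson is
# selected.
#
# Z-score route: standard ((x - mean)/sd) or modified
# (0.6745 (x - median)/MAD) scores on the pairwise values; pairs with
# |z| above the cutoff are outliers, and the smallest flagged |value| is
# the implied network threshold.

#' Unfold a spectrum to unit mean spacing
#'
#' Fits a smooth strictly increasing approximation to the cumulative
#' spectral count (monotone cubic interpolation through quantile knots) and
#' maps each eigenvalue to `n * F(lambda)`, so that nearest-neighbor
#' spacings have mean ~1 regardless of the local eigenvalue density.
#' Eigenvalues closer than `dedup_tol` are collapsed first.
#'
#' @param eigenvalues Numeric vector.
#' @param dedup_tol Collapse tolerance for (near-)duplicate eigenvalues.
#' @return Sorted numeric vector of unfolded eigenvalues.
#' @export
unfold_eigenvalues <- function(eigenvalues, dedup_tol = 1e-8) {
  ev <- sort(eigenvalues)
  if (length(ev) > 1) {
    keep <- c(TRUE, diff(ev) > dedup_tol)
    ev <- ev[keep]
  }
  n <- length(ev)
  if (n < 10) {
    mn_stop("insufficient spectrum: need >= 10 distinct eigenvalues, got ", n)
  }
  # knot count calibrated on reference ensembles: GOE spectra must be
  # rejected and superposed independent spectra accepted by the spacing
  # tests at alpha = 0.05 (see the methods vignette)
  k <- max(5, floor(n / 4))
  probs <- seq(0, 1, length.out = k + 2)
  xs <- stats::quantile(ev, probs, names = FALSE, type = 7)
  keep <- !duplicated(xs)
  f <- stats::splinefun(xs[keep], probs[keep], method = "hyman")
  n * f(ev)
}

#' Test spacings against the Poisson law
#'
#' One-sample test of nearest-neighbor spacings against Exp(1)
#' (`P(s) = exp(-s)`): either a Pearson chi-square test on
#' `ceiling(sqrt(n))` equal-probability bins (df = bins - 1) or a
#' one-sample Kolmogorov-Smirnov test.
#'
#' @param spacings Positive numeric vector (>= 10 values).
#' @param test `"chisq"` or `"ks"`.
#' @return List with `p_value` and `statistic`.
#' @export
poisson_spacing_test <- function(spacings, test = c("chisq", "ks")) {
  test <- match.arg(test)
  if (length(spacings) < 10) mn_stop("need >= 10 spacings, got ",
                                     length(spacings))
  if (test == "chisq") {
    n <- length(spacings)
    nb <- ceiling(sqrt(n))
    breaks <- stats::qexp(seq(0, 1, length.out = nb + 1))
    obs <- tabulate(findInterval(spacings, breaks,
                                 rightmost.closed = TRUE, all.inside = TRUE),
                    nbins = nb)
    expd <- n / nb
    stat <- sum((obs - expd)^2 / expd)
    list(p_value = stats::pchisq(stat, df = nb - 1, lower.tail = FALSE),
         statistic = stat)
  } else {
    kt <- suppressWarnings(stats::ks.test(spacings, stats::pexp, rate = 1))
    list(p_value = unname(kt$p.value), statistic = unname(kt$statistic))
  }
}

#' RMT threshold scan
#'
#' Scans an ascending threshold grid over a symmetric matrix normalized to
#' `[0, 1]`; at each candidate, entries below it are zeroed, isolated nodes
#' dropped, and the NNSD of the remaining spectrum tested against Poisson.
#' The chosen cutoff is the smallest threshold whose p-value is `>= alpha`
#' and remains so for the next `stability` available grid steps; the scan
#' stops once fewer than 10 non-isolated nodes (or 10 distinct eigenvalues)
#' remain.
#'
#' @param matrix A symmetric `index_matrix` with off-diagonal entries in
#'   `[0, 1]` (use [to_matrix()] max-symmetrization for directed indices and
#'   [distance_to_similarity()] for distance matrices).
#' @param test `"chisq"` or `"ks"` spacing test.
#' @param t_min,t_max,step Threshold grid.
#' @param alpha Significance level for Poisson consistency.
#' @param stability Number of subsequent grid steps that must also be
#'   consistent.
#' @param dedup_tol Eigenvalue collapse tolerance.
#' @return Object of class `threshold_scan`: `test`, `alpha`, `table`
#'   (threshold, n_nodes, n_edges, statistic, p_value, chosen),
#'   `chosen_threshold` (NA when no threshold qualifies).
#' @export
rmt_scan <- function(matrix, test = c("chisq", "ks"), t_min = 0.01,
                     t_max = 0.99, step = 0.01, alpha = 0.05,
                     stability = 2, dedup_tol = 1e-8) {
  test <- match.arg(test)
  if (inherits(matrix, "index_matrix")) {
    if (!matrix$symmetric) {
      mn_stop("RMT scan needs a symmetric matrix; use to_matrix(..., ",
              "mode = 'max_symmetric') to symmetrize directed indices")
    }
    M <- matrix$values
  } else {
    M <- matrix
    if (!isSymmetric(unname(M))) mn_stop("RMT scan needs a symmetric matrix")
  }
  off <- M[upper.tri(M)]
  if (any(off < 0) || any(off > 1)) {
    mn_stop("matrix values must be normalized to [0, 1]; for distance ",
            "matrices apply distance_to_similarity() first")
  }
  grid <- seq(t_min, t_max, by = step)
  rows <- list()
  for (t in grid) {
    W <- M
    W[W < t] <- 0
    diag(W) <- 0
    keep <- rowSums(W > 0) > 0
    n_nodes <- sum(keep)
    if (n_nodes < 10) break
    W <- W[keep, keep, drop = FALSE]
    n_edges <- sum(W[upper.tri(W)] > 0)
    ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
    p <- tryCatch({
      unf <- unfold_eigenvalues(ev, dedup_tol)
      poisson_spacing_test(diff(unf), test)
    }, error = function(e) NULL)
    if (is.null(p)) break
    rows[[length(rows) + 1]] <- data.frame(
      threshold = t, n_nodes = n_nodes, n_edges = n_edges,
      statistic = p$statistic, p_value = p$p_value)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(threshold = numeric(0), n_nodes = integer(0),
               n_edges = integer(0), statistic = numeric(0),
               p_value = numeric(0))
  chosen <- NA_real_
  if (nrow(tab)) {
    ok <- tab$p_value >= alpha
    for (i in which(ok)) {
      ahead <- seq(i + 1, min(i + stability, nrow(tab)))
      if (i == nrow(tab) || all(ok[ahead])) {
        chosen <- tab$threshold[i]
        break
      }
    }
  }
  tab$chosen <- !is.na(chosen) & tab$threshold == chosen
  structure(list(test = test, alpha = alpha, table = tab,
                 chosen_threshold = chosen),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("<threshold_scan> %s test, alpha=%g: chosen threshold = %s (%d candidates)\n",
              x$test, x$alpha,
              if (is.na(x$chosen_threshold)) "none" else
                format(x$chosen_threshold), nrow(x$table)))
  invisible(x)
}

#' Z-score outlier detection on pairwise values
#'
#' Standard scores use the sample mean and standard deviation; modified
#' scores use the median and the (raw) median absolute deviation with the
#' 0.6745 normal-consistency constant, making them robust to the outliers
#' being detected. Values with `|z|` above the cutoff are flagged, and the
#' smallest flagged `|value|` is reported as the implied network threshold.
#'
#' @param matrix A symmetric `index_matrix` (upper triangle used) or a
#'   numeric vector of values (>= 5).
#' @param method `"modified"` (default) or `"standard"`.
#' @param cutoff Absolute z-score cutoff; 2.698 and 3.5 are the two
#'   commonly used conventions.
#' @return Object of class `outlier_result`: `method`, `cutoff`, `center`,
#'   `scale`, `table` (value, z, flagged, plus A/B for matrix input),
#'   `implied_value_threshold`.
#' @export
zscore_outliers <- function(matrix, method = c("modified", "standard"),
                            cutoff = 2.698) {
  method <- match.arg(method)
  pairs <- NULL
  if (inherits(matrix, "index_matrix")) {
    if (!matrix$symmetric) mn_stop("matrix must be symmetric (upper triangle is used)")
    ut <- which(upper.tri(matrix$values), arr.ind = TRUE)
    pairs <- data.frame(A = matrix$ids[ut[, 1]], B = matrix$ids[ut[, 2]],
                        stringsAsFactors = FALSE)
    x <- matrix$values[ut]
  } else {
    x <- as.numeric(matrix)
  }
  if (length(x) < 5) mn_stop("need >= 5 values for outlier detection")
  if (method == "standard") {
    center <- mean(x)
    scale <- stats::sd(x)
    if (scale == 0) mn_stop("all values identical: standard deviation is 0")
    z <- (x - center) / scale
  } else {
    center <- stats::median(x)
    scale <- stats::median(abs(x - center))
    if (scale == 0) {
      mn_stop("median absolute deviation is 0; use method = 'standard'")
    }
    z <- 0.6745 * (x - center) / scale
  }
  flagged <- abs(z) > cutoff
  tab <- data.frame(value = x, z = z, flagged = flagged)
  if (!is.null(pairs)) tab <- cbind(pairs, tab)
  ivt <- if (any(flagged)) min(abs(x[flagged])) else NA_real_
  if (!any(flagged)) mn_warn("no value exceeds |z| = ", cutoff)
  structure(list(method = method, cutoff = cutoff, center = center,
                 scale = scale, table = tab,
                 implied_value_threshold = ivt),
            class = "outlier_result")
}

#' @export
print.outlier_result <- function(x, ...) {
  cat(sprintf("<outlier_result> %s z-score, cutoff %g: %d/%d flagged, implied threshold %s\n",
              x$method, x$cutoff, sum(x$table$flagged), nrow(x$table),
              format(x$implied_value_threshold)))
  invisible(x)
}

#' Convert a distance matrix to a similarity matrix in [0, 1]
#'
#' Affine inversion over the off-diagonal entries:
#' `s = 1 - (d - min) / (max - min)`, so the closest pair maps to 1 and the
#' farthest to 0; the diagonal stays 0. Bridges distance outputs to the
#' RMT scan's normalization requirement.
#'
#' @param matrix A symmetric non-negative `index_matrix` of kind distance.
#' @return An `index_matrix` of kind similarity.
#' @export
distance_to_similarity <- function(matrix) {
  stopifnot(inherits(matrix, "index_matrix"))
  if (!matrix$symmetric) mn_stop("distance matrix must be symmetric")
  M <- matrix$values
  off <- M[upper.tri(M)]
  if (any(off < 0)) mn_stop("distances must be non-negative")
  lo <- min(off); hi <- max(off)
  if (hi == lo) mn_stop("all off-diagonal distances equal; cannot rescale")
  S <- 1 - (M - lo) / (hi - lo)
  diag(S) <- 0
  index_matrix(S, kind = "similarity", symmetric = TRUE)
}

#' Build the final network adjacency from a threshold
#'
#' @param matrix A symmetric `index_matrix`.
#' @param threshold Cutoff from [rmt_scan()], [zscore_outliers()]
#'   (`implied_value_threshold`), or user supplied.
#' @param direction `"ge"`: edge when value >= threshold (similarity-like
#'   matrices); `"le"`: edge when value <= threshold (distance matrices;
#'   the zero diagonal is always excluded).
#' @param weighted Keep matrix values as edge weights (default: 1/0).
#' @return Object of class `mi_network`: `graph` (undirected igraph),
#'   `adjacency`, `dropped` (isolated node ids), `threshold`, `direction`.
#' @export
apply_threshold <- function(matrix, threshold, direction = c("ge", "le"),
                            weighted = FALSE) {
  direction <- match.arg(direction)
  stopifnot(inherits(matrix, "index_matrix"))
  if (!matrix$symmetric) {
    mn_stop("adjacency construction needs a symmetric matrix; ",
            "use max-symmetrization")
  }
  M <- matrix$values
  keep <- if (direction == "ge") M >= threshold else M <= threshold
  diag(keep) <- FALSE
  A <- ifelse(keep, if (weighted) M else 1, 0)
  dimnames(A) <- dimnames(M)
  isolated <- rowSums(A != 0) == 0
  if (all(isolated)) {
    mn_stop("threshold ", format(threshold), " retains zero edges")
  }
  if (any(isolated)) {
    mn_log(sprintf("dropping %d isolated node(s): %s", sum(isolated),
                   paste(rownames(A)[isolated], collapse = ", ")))
  }
  A <- A[!isolated, !isolated, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = if (weighted) TRUE else NULL,
                                           diag = FALSE)
  structure(list(graph = g, adjacency = A,
                 dropped = names(isolated)[isolated],
                 threshold = threshold, direction = direction),
            class = "mi_network")
}

#' @export
print.mi_network <- function(x, ...) {
  cat(sprintf("<mi_network> %d nodes, %d edges (threshold %s, %s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              format(x$threshold), x$direction))
  invisible(x)
}

# ---- benchmark generators --------------------------------------------------

#' Planted-block benchmark matrix
#'
#' Symmetric matrix with `n_blocks` diagonal blocks of `block_size` nodes:
#' within-block entries uniform on `signal`, between-block entries uniform
#' on `noise`. With the default separation, thresholds inside the
#' (noise_max, signal_min] gap isolate the planted modules.
#'
#' @param n_blocks,block_size Block structure.
#' @param signal,noise Ranges `c(lo, hi)` for within/between-block values.
#' @param seed Integer seed.
#' @return A symmetric `index_matrix` of kind similarity.
#' @export
make_planted_matrix <- function(n_blocks = 4, block_size = 10,
                                signal = c(0.8, 1.0), noise = c(0, 0.5),
                                seed = 1) {
  n <- n_blocks * block_size
  block <- rep(seq_len(n_blocks), each = block_size)
  with_seed(seed, {
    M <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        rng <- if (block[i] == block[j]) signal else noise
        M[i, j] <- M[j, i] <- stats::runif(1, rng[1], rng[2])
      }
    }
    dimnames(M) <- list(sprintf("n%03d", seq_len(n)), sprintf("n%03d", seq_len(n)))
    index_matrix(M, kind = "similarity", symmetric = TRUE)
  })
}

#' Sample nearest-neighbor spacings
#'
#' Draws from the Poisson spacing law Exp(1) or from the Wigner surmise
#' `P(s) = (pi s / 2) exp(-pi s^2 / 4)` (via its inverse CDF), the two
#' reference NNSDs of uncorrelated and GOE-correlated spectra.
#'
#' @param n Number of draws.
#' @param law `"poisson"` or `"wigner"`.
#' @param seed Integer seed.
#' @return Numeric vector of spacings.
#' @export
sample_spacings <- function(n, law = c("poisson", "wigner"), seed = 1) {
  law <- match.arg(law)
  with_seed(seed, {
    u <- stats::runif(n)
    if (law == "poisson") -log(1 - u) else sqrt(-4 * log(1 - u) / pi)
  })
}
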