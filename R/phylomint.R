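# Pairwise metabolic interaction indices between seed sets.
#
# For models A and B:
#   competition(A,B)     = sum of A's confidences over seeds(A) n seeds(B)
#                          / sum of A's confidences          -- weighted
#   complementarity(A,B) = |seeds(A) n nonseeds(B)|
#                          / |seeds(A) n metabolites(B)|     -- unweighted
# Both live in [0,1] and are asymmetric. The two formulas deliberately
# differ in weighting (confidence-weighted vs. plain cardinality); they are
# kept exactly as printed, not harmonized.

#' Metabolic competition index
#'
#' Fraction of A's seed-set confidence mass that is shared with B's seed
#' set: the baseline metabolic niche overlap of the two models.
#'
#' @param seed_a,seed_b `seed_set` objects (A is the focal model).
#' @return Value in `[0, 1]`. An empty seed set for A yields 0 with a
#'   warning (the ratio is undefined; 0 keeps matrices total).
#' @export
mi_competition <- function(seed_a, seed_b) {
  if (length(seed_a$seeds) == 0) {
    mn_warn("mi_competition(", seed_a$model_id, ",", seed_b$model_id,
            "): focal model has an empty seed set; returning 0")
    return(0)
  }
  shared <- intersect(names(seed_a$seeds), names(seed_b$seeds))
  sum(seed_a$seeds[shared]) / sum(seed_a$seeds)
}

#' Metabolic complementarity index
#'
#' Fraction of A's seed metabolites, among those present in B at all, that
#' B can itself produce (B's non-seed set): the potential for A to utilize
#' B's metabolic output.
#'
#' @inheritParams mi_competition
#' @return Value in `[0, 1]`. A zero denominator (A's seeds share no
#'   metabolite with B) yields 0 with a warning.
#' @export
mi_complementarity <- function(seed_a, seed_b) {
  if (length(seed_a$seeds) == 0) {
    mn_warn("mi_complementarity(", seed_a$model_id, ",", seed_b$model_id,
            "): focal model has an empty seed set; returning 0")
    return(0)
  }
  num <- length(intersect(names(seed_a$seeds), seed_b$nonseeds))
  den <- length(intersect(names(seed_a$seeds), seed_b$all_metabolites))
  if (den == 0) {
    mn_warn("mi_complementarity(", seed_a$model_id, ",", seed_b$model_id,
            "): seed sets share no metabolite with partner; returning 0")
    return(0)
  }
  num / den
}

#' All pairwise interaction indices
#'
#' Computes both indices for every ordered model pair including self-pairs
#' (n^2 records), in lexicographic order of (A, B).
#'
#' @param seedsets List of `seed_set` objects with unique model ids.
#' @return Data frame with columns `A`, `B`, `MI_competition`,
#'   `MI_complementarity`.
#' @export
all_pairwise <- function(seedsets) {
  ids <- vapply(seedsets, `[[`, "", "model_id")
  if (length(ids) < 2) mn_stop("need at least 2 models")
  if (anyDuplicated(ids)) mn_stop("duplicate model ids: ",
                                  paste(ids[duplicated(ids)], collapse = ", "))
  names(seedsets) <- ids
  ids <- sort(unname(ids))
  grid <- expand.grid(B = ids, A = ids, stringsAsFactors = FALSE)[, c("A", "B")]
  grid$MI_competition <- mapply(function(a, b) {
    mi_competition(seedsets[[a]], seedsets[[b]])
  }, grid$A, grid$B)
  grid$MI_complementarity <- mapply(function(a, b) {
    mi_complementarity(seedsets[[a]], seedsets[[b]])
  }, grid$A, grid$B)
  rownames(grid) <- NULL
  grid
}

#' Potentially transferable metabolites
#'
#' A metabolite is potentially transferable from donor B to receptor A when
#' it is in A's seed set (A needs it) and in B's non-seed set (B can make
#' it). One record per ordered pair and metabolite.
#'
#' @param seedsets List of `seed_set` objects.
#' @param names Optional named character vector mapping metabolite base ids
#'   to display names (e.g. from SBML species names via
#'   [metabolite_names()]).
#' @return Data frame with columns `donor`, `receptor`, `metabolite`,
#'   `name`, lexicographically ordered.
#' @export
find_ptms <- function(seedsets, names = character(0)) {
  ids <- sort(vapply(seedsets, `[[`, "", "model_id"))
  if (length(ids) < 2) mn_stop("need at least 2 models")
  seedsets <- stats::setNames(seedsets[order(vapply(seedsets, `[[`, "", "model_id"))], ids)
  rows <- list()
  for (a in ids) {           # receptor
    for (b in ids) {         # donor
      if (a == b) next
      mets <- sort(intersect(base::names(seedsets[[a]]$seeds),
                             seedsets[[b]]$nonseeds))
      if (length(mets) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        donor = b, receptor = a, metabolite = mets,
        name = ifelse(mets %in% base::names(names), names[mets], ""),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(donor = character(0), receptor = character(0),
                      metabolite = character(0), name = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$donor, df$receptor, df$metabolite), ]
  rownames(df) <- NULL
  df
}

#' Metabolite display names across a model set
#'
#' @param models List of `gsmm` objects.
#' @param rule ID normalization rule.
#' @return Named character vector base_id -> first non-empty SBML name.
#' @export
metabolite_names <- function(models, rule = "strip_compartment") {
  out <- character(0)
  for (m in models) {
    met <- m$metabolites
    base <- normalize_metabolite_id(met$full_id, rule)
    keep <- nzchar(met$name) & !(base %in% names(out))
    out[base[keep]] <- met$name[keep]
  }
  out
}

# ---- labeled square index matrices ----------------------------------------

#' Construct an index matrix
#'
#' @param values Square numeric matrix with identical row/column dimnames.
#' @param kind One of `complementarity`, `competition`, `distance`,
#'   `similarity`.
#' @param symmetric Whether the matrix is exactly symmetric.
#' @return Object of class `index_matrix`.
#' @export
index_matrix <- function(values, kind = c("complementarity", "competition",
                                          "distance", "similarity"),
                         symmetric = isSymmetric(unname(values))) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    mn_stop("values must be a square matrix")
  }
  if (is.null(rownames(values)) ||
      !identical(rownames(values), colnames(values))) {
    mn_stop("values must carry identical row and column names")
  }
  if (symmetric && !isSymmetric(unname(values))) {
    mn_stop("symmetric flag set but matrix is not symmetric")
  }
  structure(list(ids = rownames(values), values = values,
                 symmetric = symmetric, kind = kind),
            class = "index_matrix")
}

#' @export
print.index_matrix <- function(x, ...) {
  cat(sprintf("<index_matrix> %s, %d x %d, %s\n", x$kind, length(x$ids),
              length(x$ids), if (x$symmetric) "symmetric" else "asymmetric"))
  invisible(x)
}

#' Convert a pairwise record table to an index matrix
#'
#' @param records Data frame from [all_pairwise()] (columns A, B and the
#'   index columns).
#' @param index Which index to tabulate: `"complementarity"` or
#'   `"competition"`.
#' @param mode `"max_symmetric"` (default, recommended for undirected
#'   network construction): entry (i,j) = (j,i) = max of the two directed
#'   values; `"asymmetric"`: keep original directed values.
#' @return An `index_matrix` with zero diagonal.
#' @export
to_matrix <- function(records, index = c("complementarity", "competition"),
                      mode = c("max_symmetric", "asymmetric")) {
  index <- match.arg(index)
  mode <- match.arg(mode)
  col <- paste0("MI_", index)
  if (!all(c("A", "B", col) %in% names(records))) {
    mn_stop("records must have columns A, B, ", col)
  }
  ids <- sort(unique(c(records$A, records$B)))
  key <- paste(records$A, records$B, sep = "\r")
  need <- expand.grid(a = ids, b = ids, stringsAsFactors = FALSE)
  missing <- setdiff(paste(need$a, need$b, sep = "\r"), key)
  # self-pairs may legitimately be absent from user-supplied tables
  missing <- missing[vapply(strsplit(missing, "\r"), function(p) p[1] != p[2], TRUE)]
  if (length(missing)) {
    mn_stop("records do not cover all ordered pairs; missing ",
            length(missing), " pair(s), e.g. ",
            gsub("\r", " -> ", missing[1]))
  }
  M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  M[cbind(records$A, records$B)] <- records[[col]]
  if (mode == "max_symmetric") M <- pmax(M, t(M))
  diag(M) <- 0
  index_matrix(M, kind = index, symmetric = mode == "max_symmetric")
}

#' Write / read an index matrix as TSV
#'
#' First row and first column hold the model ids.
#' @param mat An `index_matrix`.
#' @param path File path.
#' @return `path` invisibly (write); an `index_matrix` (read).
#' @export
write_index_matrix <- function(mat, path) {
  df <- data.frame(id = mat$ids, mat$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_index_matrix
#' @param kind Matrix kind for the object read back.
#' @export
read_index_matrix <- function(path, kind = "similarity") {
  df <- read_tsv(path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  storage.mode(vals) <- "double"
  index_matrix(vals, kind = kind, symmetric = isSymmetric(unname(vals)))
}
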