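# Seed-set detection. The seed set of a metabolic network is the minimal
# set of compounds the organism cannot synthesize endogenously and must
# acquire from its environment. On the directed metabolite graph
# (substrate -> product for every reaction, both directions for reversible
# ones) seed components are the source strongly connected components (SCCs)
# of the condensation, capped at MaxCC members; every member metabolite
# gets confidence C = 1 / (SCC size).

#' Build the directed metabolite graph of a model
#'
#' One edge from every substrate to every product of each reaction, with
#' reverse edges for reversible reactions. Boundary species are excluded,
#' and exchange-style reactions (all metabolites on one side) contribute no
#' edges, so seeds reflect endogenous synthesis capability only. Self-loops
#' arising when a substrate equals a product after ID normalization are
#' dropped.
#'
#' @param model A `gsmm`.
#' @param rule ID normalization passed to [normalize_metabolite_id()];
#'   `"strip_compartment"` merges compartment instances of a compound.
#' @param ignore Optional character vector of base ids (e.g. currency
#'   metabolites) to exclude from the graph.
#' @return An `igraph` directed graph with a `model_id` attribute.
#' @export
build_metabolite_graph <- function(model, rule = c("strip_compartment", "identity"),
                                   ignore = character(0)) {
  rule <- match.arg(rule)
  met <- model$metabolites
  id_map <- stats::setNames(normalize_metabolite_id(met$full_id, rule), met$full_id)
  keep <- !met$boundary & !(id_map[met$full_id] %in% ignore)
  nodes <- sort(unique(unname(id_map[met$full_id[keep]])))
  if (length(nodes) == 0) {
    mn_stop("model '", model$model_id, "' has no internal metabolites")
  }
  allowed <- stats::setNames(rep(FALSE, nrow(met)), met$full_id)
  allowed[met$full_id[keep]] <- TRUE

  from <- character(0); to <- character(0)
  for (r in model$reactions) {
    subs <- names(r$stoich)[r$stoich < 0]
    prods <- names(r$stoich)[r$stoich > 0]
    subs <- subs[allowed[subs]]
    prods <- prods[allowed[prods]]
    if (length(subs) == 0 || length(prods) == 0) next
    pairs <- expand.grid(s = id_map[subs], p = id_map[prods],
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$s != pairs$p, , drop = FALSE]
    from <- c(from, pairs$s)
    to <- c(to, pairs$p)
    if (is_reversible(r)) {
      from <- c(from, pairs$p)
      to <- c(to, pairs$s)
    }
  }
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(nodes)
  if (length(from)) {
    el <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
    g <- igraph::add_edges(g, rbind(el$from, el$to))
  }
  g <- igraph::set_graph_attr(g, "model_id", model$model_id)
  g
}

#' Strongly connected components of a metabolite graph
#'
#' @param graph Directed `igraph`.
#' @return List with `components` (list of node-name sets, in topological
#'   order of the condensation) and `component_of` (named integer vector).
#' @export
compute_sccs <- function(graph) {
  if (igraph::vcount(graph) == 0) mn_stop("empty graph")
  sc <- igraph::components(graph, mode = "strong")
  nm <- igraph::V(graph)$name
  comps <- split(nm, sc$membership)
  list(components = unname(comps),
       component_of = stats::setNames(as.integer(sc$membership), nm))
}

#' Detect the seed set of a metabolite graph
#'
#' Seed components are SCCs with no incoming edges in the condensation and
#' at most `max_cc` members; each member gets confidence `1/size`. Source
#' SCCs larger than `max_cc` are excluded from the seeds and assigned to the
#' non-seed set (logged), the conservative reading of the MaxCC cap.
#'
#' @param graph Directed metabolite graph from [build_metabolite_graph()].
#' @param max_cc Maximum SCC size for a seed component (default 5, the
#'   recommended setting).
#' @return Object of class `seed_set`: `model_id`, `seeds` (named numeric of
#'   confidences), `nonseeds`, `all_metabolites`, `max_cc`.
#' @export
detect_seed_set <- function(graph, max_cc = 5) {
  if (max_cc < 1) mn_stop("max_cc must be >= 1")
  scc <- compute_sccs(graph)
  memb <- scc$component_of
  # does component k receive any edge from outside itself?
  el <- igraph::as_edgelist(graph, names = TRUE)
  has_in <- logical(length(scc$components))
  if (nrow(el)) {
    cross <- memb[el[, 1]] != memb[el[, 2]]
    has_in[unique(memb[el[cross, 2]])] <- TRUE
  }
  sizes <- lengths(scc$components)
  is_seed_comp <- !has_in & sizes <= max_cc
  n_capped <- sum(!has_in & sizes > max_cc)
  if (n_capped > 0) {
    mn_log(sprintf("model %s: %d source SCC(s) above MaxCC=%d moved to nonseeds",
                   igraph::graph_attr(graph, "model_id") %||% "?",
                   n_capped, max_cc))
  }
  seeds <- numeric(0)
  for (k in which(is_seed_comp)) {
    members <- scc$components[[k]]
    seeds[members] <- 1 / length(members)
  }
  all_mets <- names(memb)
  new_seed_set(igraph::graph_attr(graph, "model_id") %||% "model",
               seeds, setdiff(all_mets, names(seeds)), all_mets, max_cc)
}

new_seed_set <- function(model_id, seeds, nonseeds, all_metabolites, max_cc) {
  if (length(seeds)) seeds <- seeds[order(names(seeds))]
  else seeds <- stats::setNames(numeric(0), character(0))
  structure(list(model_id = model_id,
                 seeds = seeds,
                 nonseeds = sort(nonseeds),
                 all_metabolites = sort(all_metabolites),
                 max_cc = max_cc),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %s: %d seeds / %d metabolites (MaxCC=%d)\n",
              x$model_id, length(x$seeds), length(x$all_metabolites), x$max_cc))
  invisible(x)
}

#' Brute-force seed-set oracle
#'
#' Independent reference implementation via explicit reachability: the
#' transitive closure is computed by iterated boolean matrix products; a
#' node belongs to a seed component iff no node outside its
#' mutual-reachability class reaches it. Same contract as
#' [detect_seed_set()], but O(n^3) and refused above 50 nodes.
#'
#' @inheritParams detect_seed_set
#' @return A `seed_set`.
#' @export
brute_force_seed_oracle <- function(graph, max_cc = 5) {
  n <- igraph::vcount(graph)
  if (n > 50) mn_stop("oracle refuses graphs with more than 50 nodes")
  if (max_cc < 1) mn_stop("max_cc must be >= 1")
  nm <- igraph::V(graph)$name
  A <- matrix(FALSE, n, n, dimnames = list(nm, nm))
  el <- igraph::as_edgelist(graph, names = TRUE)
  if (nrow(el)) A[el] <- TRUE
  R <- A | diag(TRUE, n)  # reflexive closure
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  mutual <- R & t(R)
  seeds <- numeric(0)
  for (i in seq_len(n)) {
    class_i <- which(mutual[i, ])
    reachers <- which(R[, i])
    if (length(setdiff(reachers, class_i)) == 0 && length(class_i) <= max_cc) {
      seeds[nm[i]] <- 1 / length(class_i)
    }
  }
  new_seed_set(igraph::graph_attr(graph, "model_id") %||% "model",
               seeds, setdiff(nm, names(seeds)), nm, max_cc)
}

#' Seed sets for a set of models
#'
#' @param models List of `gsmm` objects.
#' @param max_cc Seed component size cap.
#' @param rule ID normalization rule.
#' @param ignore Base ids to exclude from all graphs.
#' @return Named list of `seed_set` objects.
#' @export
seed_sets <- function(models, max_cc = 5,
                      rule = c("strip_compartment", "identity"),
                      ignore = character(0)) {
  rule <- match.arg(rule)
  res <- lapply(models, function(m) {
    detect_seed_set(build_metabolite_graph(m, rule, ignore), max_cc)
  })
  stats::setNames(res, vapply(res, `[[`, "", "model_id"))
}

#' Export seed sets as a long table
#'
#' @param seedsets List of `seed_set`.
#' @param path Optional TSV output path.
#' @return Data frame with columns model_id, metabolite, confidence, is_seed.
#' @export
seed_set_table <- function(seedsets, path = NULL) {
  rows <- lapply(seedsets, function(s) {
    data.frame(model_id = s$model_id,
               metabolite = s$all_metabolites,
               confidence = ifelse(s$all_metabolites %in% names(s$seeds),
                                   unname(s$seeds[s$all_metabolites]), 0),
               is_seed = s$all_metabolites %in% names(s$seeds),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(path)) write_tsv(df, path)
  df
}
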