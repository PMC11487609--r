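# Visualization-oriented exports: the directed bipartite microbe-metabolite
# network of potentially transferable metabolites, and clustered heatmap
# data for the metabolic distance matrix. Canonical outputs are plain-text
# tables so the pipeline stays testable headlessly.

#' Bipartite microbe-metabolite network of PTMs
#'
#' Each retained (donor, receptor, metabolite) record contributes two
#' directed edges, donor -> metabolite -> receptor; the metabolite node ids
#' are prefixed with `met:` so the two node classes can never collide even
#' when a model is named like a compound. When a network is supplied, only
#' PTMs whose donor-receptor pair is one of its edges are kept.
#'
#' @param ptms Data frame from [find_ptms()].
#' @param net Optional `mi_network`/igraph filter; `NULL` exports all PTMs.
#' @return Object of class `bipartite_network`: `graph` (directed igraph),
#'   `edge_list` (source, target, edge_type), `nodes` (id, type, name).
#' @export
ptm_bipartite <- function(ptms, net = NULL) {
  stopifnot(all(c("donor", "receptor", "metabolite") %in% names(ptms)))
  if (!is.null(net)) {
    g <- as_mn_graph(net)
    el <- igraph::as_edgelist(g, names = TRUE)
    ekey <- if (nrow(el)) paste(pmin(el[, 1], el[, 2]),
                                pmax(el[, 1], el[, 2]), sep = "\r") else character(0)
    pkey <- paste(pmin(ptms$donor, ptms$receptor),
                  pmax(ptms$donor, ptms$receptor), sep = "\r")
    ptms <- ptms[pkey %in% ekey, , drop = FALSE]
  }
  ptms <- unique(ptms[, intersect(c("donor", "receptor", "metabolite", "name"),
                                  names(ptms))])
  if (nrow(ptms) == 0) {
    mn_warn("no PTMs retained; bipartite network is empty")
    return(structure(list(graph = igraph::make_empty_graph(directed = TRUE),
                          edge_list = data.frame(source = character(0),
                                                 target = character(0),
                                                 edge_type = character(0)),
                          nodes = data.frame(id = character(0),
                                             type = character(0),
                                             name = character(0))),
                     class = "bipartite_network"))
  }
  met_id <- paste0("met:", ptms$metabolite)
  el <- unique(rbind(
    data.frame(source = ptms$donor, target = met_id,
               edge_type = "production", stringsAsFactors = FALSE),
    data.frame(source = met_id, target = ptms$receptor,
               edge_type = "uptake", stringsAsFactors = FALSE)))
  el <- el[order(el$source, el$target), ]
  rownames(el) <- NULL
  microbes <- sort(unique(c(ptms$donor, ptms$receptor)))
  mets <- sort(unique(ptms$metabolite))
  met_names <- if ("name" %in% names(ptms)) {
    nm <- ptms$name[match(mets, ptms$metabolite)]
    ifelse(is.na(nm), "", nm)
  } else rep("", length(mets))
  nodes <- rbind(
    data.frame(id = microbes, type = "microbe", name = microbes,
               stringsAsFactors = FALSE),
    data.frame(id = paste0("met:", mets), type = "metabolite",
               name = met_names, stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(el[, 1:2], directed = TRUE,
                                     vertices = nodes)
  structure(list(graph = g, edge_list = el, nodes = nodes),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network> %d microbes, %d metabolites, %d directed edges\n",
              sum(x$nodes$type == "microbe"),
              sum(x$nodes$type == "metabolite"), nrow(x$edge_list)))
  invisible(x)
}

#' Ordered heatmap data for a distance matrix
#'
#' Reorders a symmetric distance matrix by average-linkage hierarchical
#' clustering so related models sit together; with fewer than 3 models the
#' input order is kept (with a notice).
#'
#' @param matrix A symmetric `index_matrix` of kind distance.
#' @param order `"cluster"` (default) or `"input"`.
#' @return List with `matrix` (reordered values), `leaf_order` (ids) and
#'   `hclust` (the tree, or NULL).
#' @export
heatmap_data <- function(matrix, order = c("cluster", "input")) {
  order <- match.arg(order)
  stopifnot(inherits(matrix, "index_matrix"))
  if (!matrix$symmetric) mn_stop("heatmap needs a symmetric distance matrix")
  M <- matrix$values
  if (order == "input" || nrow(M) < 3) {
    if (order == "cluster" && nrow(M) < 3) {
      mn_log("fewer than 3 models: keeping input order")
    }
    return(list(matrix = M, leaf_order = rownames(M), hclust = NULL))
  }
  hc <- stats::hclust(stats::as.dist(M), method = "average")
  ord <- hc$order
  list(matrix = M[ord, ord], leaf_order = rownames(M)[ord], hclust = hc)
}

#' Export a graph as GraphML
#'
#' @param net `mi_network`, `bipartite_network`, or igraph.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- if (inherits(net, c("mi_network", "bipartite_network"))) net$graph else net
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export an edge list as TSV
#'
#' @param net `mi_network` or igraph (undirected edges as from/to columns).
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_edge_list <- function(net, path) {
  g <- if (inherits(net, "mi_network")) net$graph else net
  el <- igraph::as_edgelist(g, names = TRUE)
  df <- data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
  if ("weight" %in% igraph::edge_attr_names(g)) {
    df$weight <- igraph::E(g)$weight
  }
  write_tsv(df, path)
}
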