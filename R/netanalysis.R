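# Topological analysis of the thresholded metabolic interaction network.
# Topology is computed on the binarized graph; edge weights, when present,
# are carried only as annotation.

#' Coerce to a canonical undirected analysis graph
#'
#' Accepts an `mi_network` or igraph, collapses direction and multi-edges,
#' removes self-loops, and sorts vertices by name so that all downstream
#' computations are independent of construction order.
#'
#' @param net `mi_network` or igraph.
#' @return Undirected simple igraph with named vertices.
#' @export
as_mn_graph <- function(net) {
  g <- if (inherits(net, "mi_network")) net$graph else net
  if (!igraph::is_igraph(g)) mn_stop("expected an mi_network or igraph object")
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (is.null(igraph::V(g)$name)) {
    g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(igraph::vcount(g))))
  }
  # deterministic vertex order regardless of construction history
  igraph::permute(g, order(order(igraph::V(g)$name)))
}

#' Global network properties
#'
#' Node/edge counts, average degree, density, average (local) clustering
#' coefficient with degree<2 nodes counted as 0, average shortest path
#' length within the largest connected component, component count, and the
#' modularity of the greedy module partition.
#'
#' @param net An `mi_network` or undirected igraph.
#' @return One-row data frame of global properties.
#' @export
global_properties <- function(net) {
  g <- as_mn_graph(net)
  n <- igraph::vcount(g)
  if (n < 2) mn_stop("need >= 2 nodes")
  m <- igraph::ecount(g)
  comps <- igraph::components(g)
  largest <- igraph::induced_subgraph(
    g, which(comps$membership == which.max(comps$csize)))
  apl <- if (igraph::vcount(largest) > 1) {
    igraph::mean_distance(largest, directed = FALSE)
  } else NA_real_
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  mod <- if (m > 0) {
    part <- detect_modules(g)
    part$modularity
  } else NA_real_
  data.frame(n_nodes = n, n_edges = m,
             average_degree = 2 * m / n,
             density = 2 * m / (n * (n - 1)),
             average_clustering_coefficient = mean(cc),
             average_path_length = apl,
             n_components = comps$no,
             modularity = mod)
}

# shortest-path counts from each source (BFS + DP)
sp_counts <- function(g) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  d <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    sigma[s, s] <- 1
    frontier <- s
    dist <- 0
    while (length(frontier)) {
      dist <- dist + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(d[s, w])) {
            if (!(w %in% nxt)) nxt <- c(nxt, w)
            sigma[s, w] <- sigma[s, w] + sigma[s, v]
          } else if (d[s, w] == dist) {
            sigma[s, w] <- sigma[s, w] + sigma[s, v]
          }
        }
      }
      d[s, nxt] <- dist
      frontier <- nxt
    }
  }
  list(d = d, sigma = sigma)
}

#' Node centralities
#'
#' Degree, betweenness (sum over unordered pairs of the fraction of
#' shortest paths through the node), stress (the raw count of shortest
#' paths through the node), and the local clustering coefficient.
#' Centralities are reported unnormalized; set `normalized = TRUE` to
#' divide betweenness by `(n-1)(n-2)/2`.
#'
#' @param net An `mi_network` or undirected igraph.
#' @param normalized Normalize betweenness.
#' @return Data frame: node, degree, betweenness, stress,
#'   clustering_coefficient.
#' @export
node_centralities <- function(net, normalized = FALSE) {
  g <- as_mn_graph(net)
  n <- igraph::vcount(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = normalized)
  sp <- sp_counts(g)
  stress <- numeric(n)
  if (n >= 3) {
    for (v in seq_len(n)) {
      for (s in seq_len(n - 1)) {
        if (s == v) next
        for (t in seq(s + 1, n)) {
          if (t == v || is.infinite(sp$d[s, t])) next
          if (sp$d[s, v] + sp$d[v, t] == sp$d[s, t]) {
            stress[v] <- stress[v] + sp$sigma[s, v] * sp$sigma[t, v]
          }
        }
      }
    }
  }
  data.frame(node = igraph::V(g)$name,
             degree = unname(igraph::degree(g)),
             betweenness = unname(btw),
             stress = stress,
             clustering_coefficient =
               igraph::transitivity(g, type = "local", isolates = "zero"),
             stringsAsFactors = FALSE)
}

#' Detect network modules
#'
#' Greedy modularity maximization (deterministic; ties broken by the fixed
#' vertex order, which [as_mn_graph()] sorts by node id). The `seed`
#' argument is accepted for interface stability and recorded, but the
#' algorithm involves no randomness.
#'
#' @param net An `mi_network` or undirected igraph.
#' @param seed Integer; recorded only.
#' @return Object of class `module_partition`: `membership` (named integer),
#'   `modularity`, `n_modules`.
#' @export
detect_modules <- function(net, seed = 1) {
  g <- as_mn_graph(net)
  if (igraph::ecount(g) == 0) mn_stop("need >= 1 edge for module detection")
  cl <- igraph::cluster_fast_greedy(g)
  # the greedy merge path can stop one step early on zero-gain merges
  # (floating error); re-evaluate every cut and keep the max-modularity
  # partition, ties broken toward fewer modules
  memb <- igraph::membership(cl)
  bestQ <- igraph::modularity(g, memb)
  for (k in rev(seq_len(max(1, length(memb) - 1)))) {
    mk <- tryCatch(igraph::cut_at(cl, no = k), error = function(e) NULL)
    if (is.null(mk)) next
    qk <- igraph::modularity(g, mk)
    if (qk > bestQ + 1e-12 ||
        (qk > bestQ - 1e-12 && length(unique(mk)) < length(unique(memb)))) {
      memb <- mk
      bestQ <- qk
    }
  }
  memb <- stats::setNames(as.integer(memb), igraph::V(g)$name)
  structure(list(membership = memb,
                 modularity = igraph::modularity(g, memb),
                 n_modules = length(unique(memb)),
                 seed = seed),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d modules, Q = %.4f\n",
              x$n_modules, x$modularity))
  invisible(x)
}

#' Within-module degree and participation coefficient
#'
#' For node i in module s: `z_i = (k_is - mean_s) / sd_s` over the
#' within-module degrees of module s (sample sd; 0 when sd is 0), and
#' `P_i = 1 - sum_s (k_is / k_i)^2` over all modules. Roles follow the
#' standard z-P plane partition: module hub (z > z_cut, P <= p_cut),
#' connector (z <= z_cut, P > p_cut), network hub (both), peripheral
#' otherwise; defaults z_cut = 2.5, p_cut = 0.62.
#'
#' @param net An `mi_network` or undirected igraph.
#' @param partition A `module_partition` covering all nodes (default:
#'   computed by [detect_modules()]).
#' @param z_cut,p_cut Role thresholds.
#' @return Data frame: node, module, degree, z_i, P_i, role.
#' @export
zi_pi <- function(net, partition = NULL, z_cut = 2.5, p_cut = 0.62) {
  g <- as_mn_graph(net)
  if (is.null(partition)) partition <- detect_modules(g)
  memb <- partition$membership
  nodes <- igraph::V(g)$name
  if (!all(nodes %in% names(memb))) {
    mn_stop("partition does not cover all nodes")
  }
  memb <- memb[nodes]
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  k <- rowSums(A)
  mods <- sort(unique(memb))
  # k_is: node x module within-degree
  kis <- vapply(mods, function(s) rowSums(A[, memb == s, drop = FALSE]), numeric(length(nodes)))
  if (length(nodes) == 1) kis <- matrix(kis, nrow = 1)
  own <- match(memb, mods)
  k_in <- kis[cbind(seq_along(nodes), own)]
  z <- numeric(length(nodes))
  for (s in seq_along(mods)) {
    idx <- which(own == s)
    mu <- mean(k_in[idx])
    sdev <- stats::sd(k_in[idx])
    z[idx] <- if (is.na(sdev) || sdev == 0) 0 else (k_in[idx] - mu) / sdev
  }
  P <- ifelse(k > 0, 1 - rowSums((kis / pmax(k, 1))^2), 0)
  role <- ifelse(z > z_cut & P > p_cut, "network hub",
          ifelse(z > z_cut, "module hub",
          ifelse(P > p_cut, "connector", "peripheral")))
  data.frame(node = nodes, module = memb, degree = unname(k),
             z_i = z, P_i = unname(P), role = role,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Merge node attribute tables
#'
#' Left-joins the centrality table, the zi-Pi table and an optional
#' taxonomy table (first column = node ids) on node id. Taxonomy rows with
#' no matching node are dropped with a logged count; clashing column names
#' get `.zipi` / `.tax` suffixes.
#'
#' @param centralities Data frame from [node_centralities()].
#' @param zipi Data frame from [zi_pi()].
#' @param taxonomy Optional data frame or TSV path; first column node ids.
#' @return Merged data frame, one row per network node.
#' @export
merge_attributes <- function(centralities, zipi, taxonomy = NULL) {
  for (df in list(centralities, zipi)) {
    if (anyDuplicated(df$node)) mn_stop("duplicate node ids in input table")
  }
  zipi2 <- zipi[, setdiff(names(zipi), "degree"), drop = FALSE]
  clash <- setdiff(intersect(names(centralities), names(zipi2)), "node")
  if (length(clash)) {
    names(zipi2)[match(clash, names(zipi2))] <- paste0(clash, ".zipi")
  }
  out <- merge(centralities, zipi2, by = "node", all.x = TRUE, sort = TRUE)
  if (!is.null(taxonomy)) {
    if (is.character(taxonomy)) taxonomy <- read_tsv(taxonomy)
    names(taxonomy)[1] <- "node"
    if (anyDuplicated(taxonomy$node)) mn_stop("duplicate node ids in taxonomy")
    clash <- setdiff(intersect(names(out), names(taxonomy)), "node")
    if (length(clash)) {
      names(taxonomy)[match(clash, names(taxonomy))] <- paste0(clash, ".tax")
    }
    unmatched <- sum(!taxonomy$node %in% out$node)
    if (unmatched > 0) {
      mn_log(sprintf("merge_attributes: dropped %d unmatched taxonomy row(s)",
                     unmatched))
    }
    out <- merge(out, taxonomy, by = "node", all.x = TRUE, sort = TRUE)
  }
  rownames(out) <- NULL
  out
}

#' Intersect two networks
#'
#' The common-edge subnetwork: edge set is the intersection of the two
#' edge sets (by node-id pairs), nodes are the endpoints of kept edges.
#'
#' @param a,b `mi_network` or igraph objects with comparable node ids.
#' @return List with `graph` (igraph), `edge_list` (data.frame from/to) and
#'   `adjacency`; the graph is empty (with a warning) when no edge is
#'   shared.
#' @export
intersect_networks <- function(a, b) {
  ga <- as_mn_graph(a); gb <- as_mn_graph(b)
  ekey <- function(g) {
    el <- igraph::as_edgelist(g, names = TRUE)
    if (nrow(el) == 0) return(character(0))
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
  }
  common <- sort(intersect(ekey(ga), ekey(gb)))
  if (length(common) == 0) {
    mn_warn("networks share no edge; returning empty network")
    g <- igraph::make_empty_graph(directed = FALSE)
    return(list(graph = g,
                edge_list = data.frame(from = character(0), to = character(0)),
                adjacency = matrix(0, 0, 0)))
  }
  parts <- do.call(rbind, strsplit(common, "\r", fixed = TRUE))
  el <- data.frame(from = parts[, 1], to = parts[, 2], stringsAsFactors = FALSE)
  nodes <- sort(unique(c(el$from, el$to)))
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  list(graph = g, edge_list = el, adjacency = A)
}
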