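# Shared fixtures. Everything is generated in code at test time; no stored
# binary data.

# two-model chain fixture: A needs a (makes b, c), B needs c (makes d, a)
chain_models <- function() {
  list(A = make_toy_model(c("a -> b", "b -> c"), model_id = "A"),
       B = make_toy_model(c("c -> d", "d -> a"), model_id = "B"))
}

chain_seedsets <- function() seed_sets(chain_models())

# branched pFBA fixture: direct route P1 vs two-step route P2a+P2b
branched_model <- function() {
  make_toy_model(
    c("EX_g: g ->", "P1: g -> x", "P2a: g -> y", "P2b: y -> x",
      "Growth: x ->"),
    model_id = "branched", bounds = list(EX_g = c(-10, 1000)),
    objective = "Growth")
}

# minimal growing model: uptake bound 10 is the only constraint
uptake_model <- function() {
  make_toy_model(c("EX_g: g ->", "R1: g -> x", "Growth: x ->"),
                 model_id = "uptake", bounds = list(EX_g = c(-10, 1000)),
                 objective = "Growth")
}

# random directed graph with named vertices (for SCC / seed property tests)
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n) < p, n, n)
  diag(A) <- FALSE
  nm <- sprintf("v%02d", seq_len(n))
  dimnames(A) <- list(nm, nm)
  igraph::graph_from_adjacency_matrix(A, mode = "directed")
}

# random undirected graph for centrality oracle tests
random_ugraph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p, directed = FALSE)
  igraph::set_vertex_attr(g, "name", value = sprintf("u%02d", seq_len(n)))
}

# zip a set of models flat (or under a folder) using python's zipfile,
# since no zip binary ships with the environment
zip_models <- function(models, zippath, folder = NULL) {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- write_model_set(models, d)
  arc <- basename(paths)
  if (!is.null(folder)) arc <- file.path(folder, arc)
  spec <- jsonlite::toJSON(
    list(zip = zippath, files = unname(paths), arcnames = unname(arc)),
    auto_unbox = TRUE)
  script <- paste(
    "import json, sys, zipfile",
    "spec = json.loads(sys.argv[1])",
    "with zipfile.ZipFile(spec['zip'], 'w') as z:",
    "    for f, a in zip(spec['files'], spec['arcnames']):",
    "        z.write(f, a)", sep = "\n")
  status <- system2("python", c("-c", shQuote(script), shQuote(spec)))
  stopifnot(status == 0)
  zippath
}

# brute-force betweenness/stress oracle by explicit enumeration of all
# shortest paths (igraph::all_shortest_paths), independent of the package's
# BFS counting implementation
enumerate_centralities <- function(g) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  btw <- stats::setNames(numeric(n), nm)
  stress <- stats::setNames(numeric(n), nm)
  if (n >= 3) {
    for (s in seq_len(n - 1)) {
      for (t in seq(s + 1, n)) {
        paths <- suppressWarnings(
          igraph::all_shortest_paths(g, from = s, to = t)$vpaths)
        if (length(paths) == 0) next
        through <- table(unlist(lapply(paths, function(p) {
          v <- as.integer(p)
          v[-c(1, length(v))]
        })))
        if (length(through)) {
          idx <- as.integer(names(through))
          stress[idx] <- stress[idx] + as.numeric(through)
          btw[idx] <- btw[idx] + as.numeric(through) / length(paths)
        }
      }
    }
  }
  list(betweenness = btw, stress = stress)
}
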