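# End-to-end pipeline: models -> seed sets -> pairwise indices -> matrices
# -> (optional) pFBA distances -> threshold -> network -> topology ->
# exports. Every stage persists its output as TSV under the output
# directory; a provenance JSON records the configuration and chosen
# threshold so reruns with the same config are byte-identical.

#' Default pipeline configuration
#'
#' @param ... Overrides for any configuration field.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    input_dir = NULL,         # directory of SBML files
    input_zip = NULL,         # or a zipped model set
    n_demo_models = NULL,     # or: generate a demo community of this size
    out_dir = "mintnet_out",
    seed = 1,
    max_cc = 5,
    id_rule = "strip_compartment",
    index = "complementarity",        # index used for the network
    symmetrization = "max_symmetric",
    run_flux = TRUE,
    objective = "Growth",
    threshold_method = "zscore",      # zscore | rmt_chisq | rmt_ks | fixed
    threshold = NA_real_,             # for method = fixed
    zscore_method = "modified",
    zscore_cutoff = 2.698,
    rmt_alpha = 0.05,
    rmt_step = 0.01,
    taxonomy = NULL,
    log_level = "INFO")
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) mn_stop("unknown config field(s): ",
                               paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

#' Read a plain-text key=value configuration file
#'
#' @param path File with one `key = value` pair per line; `#` comments and
#'   blank lines allowed.
#' @return Configuration list via [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  args <- stats::setNames(
    lapply(kv, function(p) {
      v <- trimws(paste(p[-1], collapse = "="))
      if (grepl("^-?[0-9.]+$", v)) as.numeric(v)
      else if (v %in% c("TRUE", "FALSE")) as.logical(v)
      else if (v == "NULL") NULL
      else v
    }),
    vapply(kv, function(p) trimws(p[1]), ""))
  do.call(pipeline_config, args)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    mn_stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full metabolic interaction network pipeline
#'
#' Executes model loading/generation, seed-set detection, pairwise index
#' calculation, matrix construction, optional pFBA metabolic distances,
#' threshold selection, network construction, topological analysis, and
#' visualization exports, persisting each stage's outputs as TSV files
#' under `config$out_dir`. Reruns with the same configuration produce
#' byte-identical outputs.
#'
#' @param config List from [pipeline_config()] or a path to a key=value
#'   config file.
#' @return The output directory, invisibly; the `provenance.json` file
#'   there records the configuration and chosen threshold.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  o <- function(f) file.path(out, f)

  models <- run_stage("load_models", {
    if (!is.null(config$input_zip)) {
      read_model_archive(config$input_zip)
    } else if (!is.null(config$input_dir)) {
      files <- sort(list.files(config$input_dir, "\\.(xml|sbml)$",
                               full.names = TRUE))
      if (length(files) == 0) mn_stop("no SBML files in ", config$input_dir)
      stats::setNames(lapply(files, read_sbml),
                      tools::file_path_sans_ext(basename(files)))
    } else if (!is.null(config$n_demo_models)) {
      m <- make_demo_models(config$n_demo_models, seed = config$seed)
      write_model_set(m, o("models"))
      m
    } else {
      mn_stop("config must set input_dir, input_zip or n_demo_models")
    }
  })

  ss <- run_stage("seedset", {
    s <- seed_sets(models, max_cc = config$max_cc, rule = config$id_rule)
    seed_set_table(s, o("seed_sets.tsv"))
    s
  })

  records <- run_stage("phylomint", {
    r <- all_pairwise(ss)
    write_tsv(r, o("phylomint_records.tsv"))
    r
  })

  mats <- run_stage("matrix", {
    m <- list(
      competition = to_matrix(records, "competition", config$symmetrization),
      complementarity = to_matrix(records, "complementarity",
                                  config$symmetrization))
    write_index_matrix(m$competition, o("matrix_competition.tsv"))
    write_index_matrix(m$complementarity, o("matrix_complementarity.tsv"))
    m
  })

  ptms <- run_stage("ptm", {
    p <- find_ptms(ss, names = metabolite_names(models))
    write_tsv(p, o("ptms.tsv"))
    p
  })

  dist_res <- NULL
  if (isTRUE(config$run_flux)) {
    dist_res <- run_stage("distance", {
      d <- metabolic_distance(models, objective = config$objective)
      write_index_matrix(d$raw, o("distance_raw.tsv"))
      write_index_matrix(d$standardized, o("distance_standardized.tsv"))
      write_tsv(d$long_table, o("distance_long.tsv"))
      d
    })
  }

  net_matrix <- mats[[config$index]]
  chosen <- run_stage("threshold", {
    switch(config$threshold_method,
      fixed = {
        if (is.na(config$threshold)) mn_stop("method 'fixed' needs a threshold")
        config$threshold
      },
      zscore = {
        zr <- zscore_outliers(net_matrix, method = config$zscore_method,
                              cutoff = config$zscore_cutoff)
        write_tsv(zr$table, o("zscore_outliers.tsv"))
        if (is.na(zr$implied_value_threshold)) {
          mn_stop("z-score method flagged no outlier; supply a fixed threshold")
        }
        zr$implied_value_threshold
      },
      rmt_chisq = ,
      rmt_ks = {
        scan <- rmt_scan(net_matrix,
                         test = sub("rmt_", "", config$threshold_method),
                         step = config$rmt_step, alpha = config$rmt_alpha)
        write_tsv(scan$table, o("threshold_scan.tsv"))
        if (is.na(scan$chosen_threshold)) {
          mn_stop("RMT scan selected no threshold; inspect threshold_scan.tsv")
        }
        scan$chosen_threshold
      },
      mn_stop("unknown threshold_method '", config$threshold_method, "'"))
  })

  net <- run_stage("build_network", {
    nw <- apply_threshold(net_matrix, chosen, direction = "ge")
    utils::write.table(
      data.frame(id = rownames(nw$adjacency), nw$adjacency,
                 check.names = FALSE),
      o("network_adjacency.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_edge_list(nw, o("network_edges.tsv"))
    nw
  })

  run_stage("analysis", {
    write_tsv(global_properties(net), o("global_properties.tsv"))
    cen <- node_centralities(net)
    write_tsv(cen, o("node_attributes.tsv"))
    part <- detect_modules(net, seed = config$seed)
    write_tsv(data.frame(node = names(part$membership),
                         module = unname(part$membership)),
              o("modules.tsv"))
    zp <- zi_pi(net, part)
    write_tsv(zp, o("zipi.tsv"))
    write_tsv(merge_attributes(cen, zp, config$taxonomy),
              o("merged_attributes.tsv"))
  })

  run_stage("export", {
    bp <- suppressWarnings(ptm_bipartite(ptms, net = net))
    write_tsv(bp$edge_list, o("ptm_network_edges.tsv"))
    write_tsv(bp$nodes, o("ptm_network_nodes.tsv"))
    if (!is.null(dist_res)) {
      hd <- heatmap_data(dist_res$raw)
      utils::write.table(
        data.frame(id = rownames(hd$matrix), hd$matrix, check.names = FALSE),
        o("heatmap_matrix.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      write_tsv(data.frame(leaf_order = hd$leaf_order), o("heatmap_order.tsv"))
    }
  })

  # out_dir is excluded so reruns into different directories stay
  # byte-identical; no timestamps are recorded for the same reason
  prov_cfg <- config[setdiff(names(config), "out_dir")]
  prov <- list(tool = "mintnet",
               version = as.character(utils::packageVersion("mintnet")),
               config = prov_cfg[!vapply(prov_cfg, is.null, TRUE)],
               chosen_threshold = chosen,
               n_models = length(models))
  jsonlite::write_json(prov, o("provenance.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out)
}
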