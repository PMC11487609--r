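# SBML Level 3 + FBC v2 I/O, restricted to the subset emitted by automated
# reconstruction tools (CarveMe-style): compartments, species (with
# boundaryCondition), global bound parameters, reactions with
# fbc:lowerFluxBound / fbc:upperFluxBound, and an active fbc objective.
# Events, rules and other full-SBML constructs are ignored with a warning.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Read a genome-scale metabolic model from SBML
#'
#' Parses SBML Level 3 with FBC v2 flux bounds and objective. When a
#' reaction carries no FBC bounds, defaults are assigned from its
#' `reversible` attribute: (-1000, 1000) mmol/gDW/h when reversible,
#' (0, 1000) otherwise.
#'
#' @param path Path to an `.xml`/`.sbml` file.
#' @param model_id Model id; defaults to the filename stem.
#' @return A `gsmm`.
#' @export
read_sbml <- function(path, model_id = NULL) {
  if (!file.exists(path)) mn_stop("no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) mn_stop("cannot parse SBML file '", path,
                                              "': ", conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing")) {
    # tolerate SBML files with other level/version namespaces
    model_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  }
  if (inherits(model_node, "xml_missing")) {
    mn_stop("file '", path, "' contains no SBML <model> element")
  }
  ignored <- intersect(xml2::xml_name(xml2::xml_children(model_node)),
                       c("listOfEvents", "listOfRules", "listOfConstraints"))
  if (length(ignored)) {
    mn_warn("ignoring unsupported SBML constructs in '", path, "': ",
            paste(ignored, collapse = ", "))
  }
  if (is.null(model_id)) {
    model_id <- xml2::xml_attr(model_node, "id")
    if (is.na(model_id) || !nzchar(model_id)) {
      model_id <- tools::file_path_sans_ext(basename(path))
    }
  }

  # global parameters (flux bound values)
  params <- xml2::xml_find_all(model_node, ".//*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  sp_nodes <- xml2::xml_find_all(model_node, ".//*[local-name()='species']")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_name <- xml2::xml_attr(sp_nodes, "name")
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  sp_bnd <- xml2::xml_attr(sp_nodes, "boundaryCondition")
  sp_name[is.na(sp_name)] <- ""
  sp_comp[is.na(sp_comp) | sp_comp == "default"] <- ""
  mets <- data.frame(full_id = sp_id,
                     base_id = normalize_metabolite_id(sp_id),
                     compartment = sp_comp,
                     name = sp_name,
                     boundary = !is.na(sp_bnd) & sp_bnd == "true",
                     stringsAsFactors = FALSE)

  # active objective
  active_obj <- character(0)
  obj_list <- xml2::xml_find_first(model_node, ".//*[local-name()='listOfObjectives']")
  if (!inherits(obj_list, "xml_missing")) {
    active <- xml2::xml_attr(obj_list, "activeObjective")
    objs <- xml2::xml_find_all(obj_list, ".//*[local-name()='objective']")
    pick <- if (!is.na(active)) {
      objs[xml2::xml_attr(objs, "id") == active]
    } else objs
    if (length(pick)) {
      fo <- xml2::xml_find_all(pick[[1]], ".//*[local-name()='fluxObjective']")
      active_obj <- stats::setNames(
        as.numeric(xml2::xml_attr(fo, "coefficient")),
        xml2::xml_attr(fo, "reaction"))
    }
  }

  rx_nodes <- xml2::xml_find_all(model_node, ".//*[local-name()='reaction']")
  if (length(rx_nodes) == 0) mn_stop("model in '", path, "' has zero reactions")
  rxns <- lapply(rx_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    rname <- xml2::xml_attr(node, "name")
    if (is.na(rname)) rname <- rid
    refs <- function(tag, sign) {
      sr <- xml2::xml_find_all(
        node, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']", tag))
      if (length(sr) == 0) return(numeric(0))
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      coef[is.na(coef)] <- 1
      stats::setNames(sign * coef, xml2::xml_attr(sr, "species"))
    }
    stoich <- c(refs("listOfReactants", -1), refs("listOfProducts", 1))
    stoich <- c(tapply(stoich, names(stoich), sum))
    stoich <- stoich[stoich != 0]
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    rev_attr <- xml2::xml_attr(node, "reversible")
    reversible <- !is.na(rev_attr) && rev_attr == "true"
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pval)) pval[[lb_ref]] else
      if (reversible) DEFAULT_LB else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) pval[[ub_ref]] else DEFAULT_UB
    oc <- if (rid %in% names(active_obj)) active_obj[[rid]] else 0
    list(id = rid, name = rname, stoich = stoich,
         lower_bound = lb, upper_bound = ub, objective_coefficient = oc)
  })

  # species referenced by reactions but missing from listOfSpecies: add bare
  used <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  extra <- setdiff(used, mets$full_id)
  if (length(extra)) {
    mets <- rbind(mets, make_metabolite_table(extra))
  }
  new_gsmm(model_id, mets, rxns)
}

#' Write a model as SBML Level 3 + FBC v2
#'
#' Inverse of [read_sbml()]: `read_sbml(write_sbml(m, f))` reproduces `m`
#' up to element ordering.
#'
#' @param model A `gsmm`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_gsmm(model)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">'), SBML_NS, FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$model_id)))

  comps <- unique(model$metabolites$compartment)
  comps[!nzchar(comps)] <- "default"
  out <- c(out, "    <listOfCompartments>",
           sprintf('      <compartment id="%s" constant="true"/>', unique(comps)),
           "    </listOfCompartments>")

  met <- model$metabolites
  comp_attr <- ifelse(nzchar(met$compartment), met$compartment, "default")
  out <- c(out, "    <listOfSpecies>",
           sprintf(paste0('      <species id="%s" name="%s" compartment="%s" ',
                          'boundaryCondition="%s" hasOnlySubstanceUnits="false" ',
                          'constant="false"/>'),
                   esc(met$full_id), esc(met$name), comp_attr,
                   ifelse(met$boundary, "true", "false")),
           "    </listOfSpecies>")

  # one shared parameter per distinct bound value
  bvals <- sort(unique(unlist(lapply(model$reactions, function(r)
    c(r$lower_bound, r$upper_bound)))))
  pid <- stats::setNames(sprintf("fb_%d", seq_along(bvals)),
                         vapply(bvals, format, "", digits = 17))
  out <- c(out, "    <listOfParameters>",
           sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                   pid, names(pid)),
           "    </listOfParameters>")

  ref_block <- function(stoich, keep, tag) {
    sel <- stoich[keep(stoich)]
    if (length(sel) == 0) return(character(0))
    c(sprintf("        <listOf%s>", tag),
      sprintf(paste0('          <speciesReference species="%s" ',
                     'stoichiometry="%s" constant="true"/>'),
              esc(names(sel)), format(abs(unname(sel)), digits = 17)),
      sprintf("        </listOf%s>", tag))
  }
  out <- c(out, "    <listOfReactions>")
  for (r in model$reactions) {
    out <- c(out,
             sprintf(paste0('      <reaction id="%s" name="%s" reversible="%s" ',
                            'fast="false" fbc:lowerFluxBound="%s" ',
                            'fbc:upperFluxBound="%s">'),
                     esc(r$id), esc(r$name),
                     if (is_reversible(r)) "true" else "false",
                     pid[[format(r$lower_bound, digits = 17)]],
                     pid[[format(r$upper_bound, digits = 17)]]),
             ref_block(r$stoich, function(s) s < 0, "Reactants"),
             ref_block(r$stoich, function(s) s > 0, "Products"),
             "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>")

  obj <- objective_ids(model)
  if (length(obj)) {
    oc <- vapply(model$reactions, function(r) r$objective_coefficient, 0)
    oc <- oc[oc != 0]
    out <- c(out,
             '    <fbc:listOfObjectives fbc:activeObjective="obj">',
             '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
             "        <fbc:listOfFluxObjectives>",
             sprintf(paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
                            'fbc:coefficient="%s"/>'),
                     esc(obj), format(oc, digits = 17)),
             "        </fbc:listOfFluxObjectives>",
             "      </fbc:objective>",
             "    </fbc:listOfObjectives>")
  }
  out <- c(out, "  </model>", "</sbml>")
  con <- tryCatch(file(path, "w"),
                  error = function(e) mn_stop("cannot write '", path, "': ",
                                              conditionMessage(e)))
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read a zipped set of models
#'
#' The archive must contain model files directly (not inside folders), one
#' model per file; model ids are taken from filename stems and returned in
#' lexicographic order.
#'
#' @param path Path to a `.zip` archive of SBML files.
#' @return Named list of `gsmm` objects.
#' @export
read_model_archive <- function(path) {
  if (!file.exists(path)) mn_stop("no such archive: ", path)
  entries <- utils::unzip(path, list = TRUE)
  files <- entries$Name
  if (any(grepl("/", files))) {
    mn_stop("archive '", path, "' contains a folder; ",
            "make sure all model files are directly zipped")
  }
  if (length(files) > 300) {
    mn_warn("archive holds ", length(files),
            " models, above the 300 commonly used as a platform cap; ",
            "expect long runtimes")
  }
  stems <- tools::file_path_sans_ext(files)
  if (anyDuplicated(stems)) {
    mn_stop("duplicate model ids (filename stems) in archive: ",
            paste(unique(stems[duplicated(stems)]), collapse = ", "))
  }
  tmp <- tempfile("mintnet_zip_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  utils::unzip(path, exdir = tmp)
  ord <- order(files)
  models <- lapply(ord, function(i) {
    read_sbml(file.path(tmp, files[i]), model_id = stems[i])
  })
  stats::setNames(models, stems[ord])
}

#' Write a set of models to a directory
#'
#' Helper for assembling pipeline inputs: one SBML file per model, named
#' `<model_id>.xml`.
#'
#' @param models List of `gsmm` objects.
#' @param dir Output directory (created if missing).
#' @return Character vector of file paths, invisibly.
#' @export
write_model_set <- function(models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(models, function(m) {
    p <- file.path(dir, paste0(m$model_id, ".xml"))
    write_sbml(m, p)
    p
  }, "")
  invisible(paths)
}
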