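# Genome-scale metabolic model (GSMM) container and synthetic model
# generators. A GSMM holds metabolites (with compartments and an optional
# boundary flag), stoichiometric reactions with flux bounds, and an
# objective given by per-reaction objective coefficients.

# Compartment codes recognized by the default metabolite-ID normalization
# (BiGG-style single/double letter suffixes).
KNOWN_COMPARTMENTS <- c("c", "e", "p", "m", "x", "r", "v", "n", "g", "h",
                        "u", "l", "i", "f", "s", "w", "y", "cx",
                        "cm", "im", "um")

DEFAULT_UB <- 1000
DEFAULT_LB <- -1000

#' Construct a genome-scale metabolic model
#'
#' @param model_id Model identifier; non-empty, no whitespace.
#' @param metabolites Data frame with columns `full_id`, `base_id`,
#'   `compartment`, `name`, `boundary` (logical).
#' @param reactions List of reactions, each a list with elements `id`,
#'   `name`, `stoich` (named numeric, names are metabolite `full_id`s,
#'   negative = substrate, positive = product), `lower_bound`,
#'   `upper_bound`, `objective_coefficient`.
#' @return An object of class `gsmm`.
#' @export
new_gsmm <- function(model_id, metabolites, reactions) {
  # canonical stoichiometry order (by metabolite id) so that equality is
  # insensitive to construction history and SBML round trips are identities
  reactions <- lapply(reactions, function(r) {
    r$stoich <- r$stoich[order(names(r$stoich))]
    r
  })
  m <- structure(list(model_id = model_id,
                      metabolites = metabolites,
                      reactions = reactions),
                 class = "gsmm")
  validate_gsmm(m)
}

validate_gsmm <- function(m) {
  if (!nzchar(m$model_id) || grepl("\\s", m$model_id)) {
    mn_stop("invalid model_id '", m$model_id,
            "': must be non-empty with no whitespace")
  }
  met <- m$metabolites
  need <- c("full_id", "base_id", "compartment", "name", "boundary")
  if (!all(need %in% names(met))) {
    mn_stop("metabolite table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(met$full_id)) {
    mn_stop("duplicate metabolite full_id in model '", m$model_id, "'")
  }
  if (length(m$reactions) == 0) {
    mn_stop("model '", m$model_id, "' has zero reactions")
  }
  rids <- vapply(m$reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) mn_stop("duplicate reaction ids in '", m$model_id, "'")
  for (r in m$reactions) {
    if (r$lower_bound > r$upper_bound) {
      mn_stop("reaction '", r$id, "': lower_bound > upper_bound")
    }
    if (length(r$stoich) && any(r$stoich == 0)) {
      mn_stop("reaction '", r$id, "': zero stoichiometric coefficient stored")
    }
    missing_met <- setdiff(names(r$stoich), met$full_id)
    if (length(missing_met)) {
      mn_stop("reaction '", r$id, "' references unknown metabolite(s): ",
              paste(missing_met, collapse = ", "))
    }
  }
  m
}

#' @export
print.gsmm <- function(x, ...) {
  cat(sprintf("<gsmm> %s: %d metabolites, %d reactions\n",
              x$model_id, nrow(x$metabolites), length(x$reactions)))
  obj <- objective_ids(x)
  if (length(obj)) cat("  objective:", paste(obj, collapse = ", "), "\n")
  invisible(x)
}

reaction_ids <- function(model) vapply(model$reactions, `[[`, "", "id")

objective_ids <- function(model) {
  oc <- vapply(model$reactions, function(r) r$objective_coefficient, 0)
  reaction_ids(model)[oc != 0]
}

is_reversible <- function(r) r$lower_bound < 0 && r$upper_bound > 0

#' Normalize a metabolite identifier
#'
#' Strips a trailing compartment suffix (`_c`, `_e`, ...) from a BiGG-style
#' metabolite id, so that the same compound can be matched across models and
#' compartments. Unrecognized suffixes are left intact.
#'
#' @param full_id Character vector of metabolite ids.
#' @param rule `"strip_compartment"` (default) or `"identity"`.
#' @param compartments Compartment codes recognized by the stripping rule.
#' @return Character vector of base ids.
#' @examples
#' normalize_metabolite_id(c("glc__D_e", "atp_c", "weird"))
#' @export
normalize_metabolite_id <- function(full_id,
                                    rule = c("strip_compartment", "identity"),
                                    compartments = KNOWN_COMPARTMENTS) {
  rule <- match.arg(rule)
  if (rule == "identity") return(full_id)
  vapply(full_id, function(id) {
    if (!nzchar(id)) return(id)
    pos <- regexpr("_([A-Za-z]{1,2})$", id)
    if (pos > 0) {
      suffix <- substr(id, pos + 1L, nchar(id))
      if (suffix %in% compartments && pos > 1L) {
        return(substr(id, 1L, pos - 1L))
      }
    }
    id
  }, "", USE.NAMES = FALSE)
}

split_compartment <- function(full_id, compartments = KNOWN_COMPARTMENTS) {
  base <- normalize_metabolite_id(full_id, compartments = compartments)
  comp <- ifelse(base == full_id, "",
                 substr(full_id, nchar(base) + 2L, nchar(full_id)))
  data.frame(full_id = full_id, base_id = base, compartment = comp,
             stringsAsFactors = FALSE)
}

make_metabolite_table <- function(full_ids, names = NULL, boundary = NULL) {
  sc <- split_compartment(full_ids)
  sc$name <- if (is.null(names)) rep("", length(full_ids)) else names
  sc$boundary <- if (is.null(boundary)) rep(FALSE, length(full_ids)) else boundary
  sc
}

# ---- declarative toy-model construction -----------------------------------

parse_side <- function(txt) {
  txt <- trimws(txt)
  if (!nzchar(txt)) return(numeric(0))
  parts <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  coefs <- numeric(0)
  add <- function(met, k) {
    cur <- if (met %in% names(coefs)) coefs[[met]] else 0
    coefs[[met]] <<- cur + k
  }
  for (p in parts) {
    if (!nzchar(p)) mn_stop("malformed reaction side: '", txt, "'")
    toks <- strsplit(p, "\\s+")[[1]]
    if (length(toks) == 1) {
      add(toks[1], 1)
    } else if (length(toks) == 2 && !is.na(suppressWarnings(as.numeric(toks[1])))) {
      add(toks[2], as.numeric(toks[1]))
    } else {
      mn_stop("cannot parse stoichiometric term '", p, "'")
    }
  }
  coefs
}

parse_reaction_string <- function(s, default_id) {
  raw <- s
  id <- default_id
  if (grepl(":", s, fixed = TRUE)) {
    bits <- strsplit(s, ":", fixed = TRUE)[[1]]
    id <- trimws(bits[1])
    s <- paste(bits[-1], collapse = ":")
  }
  reversible <- grepl("<->", s, fixed = TRUE)
  arrow <- if (reversible) "<->" else "->"
  if (!grepl(arrow, s, fixed = TRUE)) {
    mn_stop("malformed reaction string '", raw, "': no '->' or '<->' arrow")
  }
  sides <- strsplit(s, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1) sides <- c(sides, "")
  if (length(sides) != 2) mn_stop("malformed reaction string '", raw, "'")
  lhs <- parse_side(sides[1])
  rhs <- parse_side(sides[2])
  if (length(lhs) == 0 && length(rhs) == 0) {
    mn_stop("reaction '", raw, "' has no metabolites")
  }
  stoich <- c(-lhs, rhs)
  # merge duplicates across sides (a -> a would cancel; disallow zero)
  stoich <- c(tapply(stoich, names(stoich), sum))
  stoich <- stoich[stoich != 0]
  list(id = id, stoich = stoich, reversible = reversible)
}

#' Build a toy model from reaction strings
#'
#' A declarative fixture generator: each reaction is a string such as
#' `"R1: g + 2 atp -> x"`, `"a <-> b"` (reversible), or `"g ->"` (exchange /
#' sink). Default bounds follow the constraint-based modeling convention of
#' -1000/1000 mmol/gDW/h for reversible reactions and 0/1000 for
#' irreversible ones.
#'
#' @param reactions Character vector of reaction strings; ids default to
#'   `R1..Rn` when not given as an `"id:"` prefix.
#' @param model_id Model identifier.
#' @param bounds Named list: reaction id -> `c(lower, upper)` overriding the
#'   defaults.
#' @param objective Reaction id (coefficient 1) or named numeric vector of
#'   objective coefficients.
#' @param names Optional named character vector of metabolite display names
#'   keyed by full id.
#' @return A `gsmm`.
#' @examples
#' make_toy_model(c("EX_g: g ->", "R1: g -> x", "Growth: x ->"),
#'                bounds = list(EX_g = c(-10, 1000)), objective = "Growth")
#' @export
make_toy_model <- function(reactions, model_id = "toy", bounds = list(),
                           objective = NULL, names = NULL) {
  if (length(reactions) == 0) mn_stop("empty reaction list")
  parsed <- lapply(seq_along(reactions), function(i) {
    parse_reaction_string(reactions[[i]], sprintf("R%d", i))
  })
  mets <- sort(unique(unlist(lapply(parsed, function(p) names(p$stoich)))))
  obj_coef <- function(id) {
    if (is.null(objective)) return(0)
    if (is.character(objective)) return(as.numeric(id %in% objective))
    if (id %in% names(objective)) return(unname(objective[[id]]))
    0
  }
  rxns <- lapply(parsed, function(p) {
    b <- bounds[[p$id]]
    if (is.null(b)) b <- if (p$reversible) c(DEFAULT_LB, DEFAULT_UB) else c(0, DEFAULT_UB)
    list(id = p$id, name = p$id, stoich = p$stoich,
         lower_bound = b[1], upper_bound = b[2],
         objective_coefficient = obj_coef(p$id))
  })
  met_names <- if (is.null(names)) NULL else {
    unname(ifelse(mets %in% base::names(names), names[mets], ""))
  }
  new_gsmm(model_id, make_metabolite_table(mets, names = met_names), rxns)
}

#' Generate a random model
#'
#' Property-test input generator: `n_reactions` reactions each connecting
#' 1-2 random substrates to 1-2 random products, with the given probability
#' of being reversible. Reproducible for a fixed seed; connectivity is not
#' guaranteed (isolated metabolites may occur).
#'
#' @param n_metabolites Number of metabolites (>= 2).
#' @param n_reactions Number of reactions (>= 1).
#' @param seed Integer seed.
#' @param reversibility_prob Probability a reaction is reversible.
#' @param model_id Model identifier.
#' @return A `gsmm`.
#' @export
make_random_model <- function(n_metabolites, n_reactions, seed,
                              reversibility_prob = 0.2,
                              model_id = sprintf("rand_%d", seed)) {
  if (n_metabolites < 2) mn_stop("need at least 2 metabolites")
  with_seed(seed, {
    mets <- sprintf("m%02d_c", seq_len(n_metabolites))
    rxns <- lapply(seq_len(n_reactions), function(i) {
      ns <- sample(1:2, 1)
      np <- sample(1:2, 1)
      subs <- sample(mets, ns)
      prods <- sample(setdiff(mets, subs), min(np, n_metabolites - ns))
      stoich <- c(stats::setNames(rep(-1, length(subs)), subs),
                  stats::setNames(rep(1, length(prods)), prods))
      rev <- stats::runif(1) < reversibility_prob
      list(id = sprintf("R%03d", i), name = sprintf("R%03d", i),
           stoich = stoich,
           lower_bound = if (rev) DEFAULT_LB else 0,
           upper_bound = DEFAULT_UB,
           objective_coefficient = 0)
    })
    new_gsmm(model_id, make_metabolite_table(mets), rxns)
  })
}

#' Generate a growth-capable demo community
#'
#' Builds `n` structurally distinct toy organisms drawing on a shared pool
#' of environmental nutrients. Each model imports 2-3 nutrients through
#' exchange and transport reactions, converts them through a short random
#' chain of cytosolic intermediates into a biomass precursor, and maximizes
#' a `Growth` sink on that precursor; some models secrete a byproduct that
#' others can import, creating genuine complementarity between seed sets.
#' Uptake bounds are 10 mmol/gDW/h, the conventional default.
#'
#' @param n Number of models.
#' @param seed Integer seed; the set is fully reproducible.
#' @return List of `gsmm` objects, names = model ids.
#' @export
make_demo_models <- function(n = 7, seed = 42) {
  pool <- sprintf("nut%d", 1:8)
  with_seed(seed, {
    models <- vector("list", n)
    for (i in seq_len(n)) {
      nuts <- sample(pool, sample(2:3, 1))
      byprod <- sample(setdiff(pool, nuts), 1)
      rx <- character(0)
      bounds <- list()
      for (nu in nuts) {
        ex <- sprintf("EX_%s_e", nu)
        rx <- c(rx,
                sprintf("%s: %s_e ->", ex, nu),
                sprintf("T_%s: %s_e -> %s_c", nu, nu, nu))
        bounds[[ex]] <- c(-10, DEFAULT_UB)
      }
      # conversion chain: nutrients -> intermediates -> biomass precursor
      n_int <- sample(1:3, 1)
      ints <- sprintf("x%d_c", seq_len(n_int))
      chain_in <- paste(sprintf("%s_c", nuts), collapse = " + ")
      rx <- c(rx, sprintf("CV1: %s -> %s", chain_in, ints[1]))
      if (n_int > 1) {
        for (k in 2:n_int) {
          rx <- c(rx, sprintf("CV%d: %s -> %s", k, ints[k - 1], ints[k]))
        }
      }
      rx <- c(rx, sprintf("BM: %s -> bm_c + %s_c", ints[n_int], byprod),
              sprintf("SEC_%s: %s_c -> %s_e", byprod, byprod, byprod),
              sprintf("EX_%s_e: %s_e ->", byprod, byprod),
              "Growth: bm_c ->")
      bounds[[sprintf("EX_%s_e", byprod)]] <- c(0, DEFAULT_UB)
      models[[i]] <- make_toy_model(rx, model_id = sprintf("demo%02d", i),
                                    bounds = bounds, objective = "Growth")
    }
    stats::setNames(models, vapply(models, `[[`, "", "model_id"))
  })
}
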