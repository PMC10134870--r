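# Constraint-based model container, community-JSON I/O, FBA, flux splits.
#
# A metabolic_model is a plain list: a metabolite table, a named list of
# reactions (each with a named stoichiometry vector; negative = consumed),
# a gene id vector and the id of the biomass objective reaction. Exchange
# reactions follow the community sign convention: negative flux = uptake.

PATHWAY_TAGS <- c("glycolysis", "TCA", "PPP", "fatty_acids", "amino_acids",
                  "anaplerotic", "transport", "exchange", "biomass", "other")

STEADY_STATE_TOL <- 1e-6

#' Construct a reaction
#'
#' @param id reaction id.
#' @param stoich named numeric vector, metabolite id -> signed coefficient
#'   (negative = consumed).
#' @param lower_bound,upper_bound flux bounds in mmol/gDW/h.
#' @param gpr optional GPR rule string.
#' @param pathway optional pathway tag (see `PATHWAY_TAGS`); defaults to
#'   "other" ("exchange" for boundary reactions).
#' @param name human-readable name.
#' @return list of class passed through into a model.
#' @export
reaction <- function(id, stoich, lower_bound = -1000, upper_bound = 1000,
                     gpr = NA_character_, pathway = NULL, name = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stoich <- stoich[stoich != 0]
  if (!length(stoich) || is.null(names(stoich)) || any(!nzchar(names(stoich)))) {
    stop("reaction '", id, "': stoichiometry must be a named numeric vector")
  }
  if (lower_bound > upper_bound) {
    stop("reaction '", id, "': lower_bound exceeds upper_bound")
  }
  is_exchange <- length(stoich) == 1L
  if (is.null(pathway)) pathway <- if (is_exchange) "exchange" else "other"
  pathway <- match.arg(pathway, PATHWAY_TAGS)
  list(id = id, name = name, stoich = stoich,
       lower_bound = as.numeric(lower_bound),
       upper_bound = as.numeric(upper_bound),
       gpr = gpr, pathway = pathway, is_exchange = is_exchange)
}

#' Construct a metabolic model
#'
#' @param metabolites data.frame with columns id, name, compartment
#'   ("c" cytosol, "e" extracellular).
#' @param reactions list of [reaction()] objects.
#' @param genes character vector of gene ids.
#' @param objective_id id of the objective (biomass) reaction.
#' @param id model identifier.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, genes = character(0),
                            objective_id, id = "model") {
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  m <- structure(list(id = id,
                      metabolites = metabolites,
                      reactions = reactions,
                      genes = genes,
                      objective_id = objective_id),
                 class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate model invariants
#'
#' Checks id uniqueness, stoichiometry references, bound ordering, GPR gene
#' coverage, and objective presence. Errors name the offending record.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly.
#' @export
validate_model <- function(model) {
  met <- model$metabolites
  if (!all(c("id", "name", "compartment") %in% names(met))) {
    stop("metabolite table must have columns id, name, compartment")
  }
  if (anyDuplicated(met$id)) {
    stop("duplicate metabolite id: ", met$id[duplicated(met$id)][1])
  }
  if (any(!nzchar(met$compartment))) {
    stop("metabolite '", met$id[!nzchar(met$compartment)][1], "': empty compartment")
  }
  if (!length(model$reactions)) stop("model has no reactions")
  rid <- names(model$reactions)
  if (anyDuplicated(rid)) stop("duplicate reaction id: ", rid[duplicated(rid)][1])
  for (r in model$reactions) {
    unknown <- setdiff(names(r$stoich), met$id)
    if (length(unknown)) {
      stop("reaction '", r$id, "' references unknown metabolite '", unknown[1], "'")
    }
    if (r$lower_bound > r$upper_bound) {
      stop("reaction '", r$id, "': lower_bound exceeds upper_bound")
    }
    if (r$is_exchange && length(r$stoich) != 1L) {
      stop("reaction '", r$id, "': exchange reactions must touch exactly one metabolite")
    }
    gg <- gpr_genes(r$gpr)
    missing_g <- setdiff(gg, model$genes)
    if (length(missing_g)) {
      stop("reaction '", r$id, "': GPR gene '", missing_g[1], "' not in model genes")
    }
  }
  if (is.null(model$objective_id) || !model$objective_id %in% rid) {
    stop("objective reaction '", model$objective_id, "' not present in model")
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, ": ",
      nrow(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions, ",
      length(x$genes), " genes; objective = ", x$objective_id, "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#' @param model a `metabolic_model`.
#' @return dense matrix, metabolites x reactions.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), length(model$reactions),
              dimnames = list(model$metabolites$id, names(model$reactions)))
  for (r in model$reactions) S[names(r$stoich), r$id] <- r$stoich
  S
}

#' Exchange reaction ids of a model
#' @param model a `metabolic_model`.
#' @export
exchange_ids <- function(model) {
  names(model$reactions)[vapply(model$reactions, `[[`, logical(1), "is_exchange")]
}

#' Read a model from the community constraint-based JSON schema
#'
#' Expects the standard fields: `metabolites` (id, name, compartment),
#' `reactions` (id, metabolites map, lower_bound, upper_bound,
#' gene_reaction_rule, subsystem, objective_coefficient), `genes`.
#' The pathway tag is taken from `subsystem` (unknown tags become "other");
#' the objective is the reaction with nonzero `objective_coefficient`.
#'
#' @param path path to a JSON model file.
#' @return a validated `metabolic_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("metabolites", "reactions", "genes")) {
    if (is.null(j[[f]])) stop("malformed model file: missing field '", f, "'")
  }
  mets <- do.call(rbind, lapply(j$metabolites, function(m) {
    if (is.null(m$id)) stop("malformed metabolite record: missing id")
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = if (is.null(m$compartment)) "c" else m$compartment,
               stringsAsFactors = FALSE)
  }))
  objective_id <- if (!is.null(j$objective)) j$objective else NULL
  rxns <- lapply(j$reactions, function(r) {
    if (is.null(r$id)) stop("malformed reaction record: missing id")
    if (is.null(r$metabolites) || !length(r$metabolites)) {
      stop("reaction '", r$id, "': missing stoichiometry")
    }
    stoich <- unlist(r$metabolites)
    subsystem <- if (is.null(r$subsystem)) NULL else r$subsystem
    if (!is.null(subsystem) && !subsystem %in% PATHWAY_TAGS) subsystem <- "other"
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0) {
      objective_id <<- r$id
    }
    reaction(id = r$id,
             stoich = stoich,
             lower_bound = if (is.null(r$lower_bound)) -1000 else r$lower_bound,
             upper_bound = if (is.null(r$upper_bound)) 1000 else r$upper_bound,
             gpr = if (is.null(r$gene_reaction_rule) || !nzchar(r$gene_reaction_rule))
               NA_character_ else r$gene_reaction_rule,
             pathway = subsystem,
             name = if (is.null(r$name)) r$id else r$name)
  })
  genes <- vapply(j$genes, function(g) if (is.list(g)) g$id else g, character(1))
  if (is.null(objective_id)) {
    stop("model file '", path, "' declares no objective reaction")
  }
  metabolic_model(mets, rxns, genes, objective_id,
                  id = if (is.null(j$id)) basename(path) else j$id)
}

#' Write a model to the community constraint-based JSON schema
#'
#' Round-trips losslessly through [read_model()] for all supported fields.
#'
#' @param model a valid `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  validate_model(model)
  j <- list(
    id = model$id,
    objective = model$objective_id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      as.list(model$metabolites[i, c("id", "name", "compartment")])
    }),
    reactions = unname(lapply(model$reactions, function(r) {
      list(id = r$id, name = r$name,
           metabolites = as.list(r$stoich),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           gene_reaction_rule = if (is.na(r$gpr)) "" else r$gpr,
           subsystem = r$pathway,
           objective_coefficient = if (r$id == model$objective_id) 1 else 0)
    })),
    genes = lapply(model$genes, function(g) list(id = g))
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Exchanges kept open for uptake regardless of the configured carbon sources:
# inorganic medium components (water, protons, O2, CO2, phosphate, ammonium,
# sulfate). Matched on the exchanged metabolite id minus compartment suffix.
FREE_EXCHANGE_METS <- c("h2o", "h", "o2", "co2", "pi", "nh4", "so4")

#' Apply measured uptake rates as condition bounds
#'
#' Sets each listed exchange's lower bound to minus the uptake magnitude
#' (negative flux = uptake) and closes uptake (lower bound 0) on every other
#' exchange except the configured free exchanges (water, ions, O2, CO2,
#' phosphate, ammonium, sulfate by default). Secretion bounds are untouched.
#'
#' @param model a `metabolic_model`.
#' @param uptakes named numeric vector, exchange reaction id -> uptake
#'   magnitude (mmol/gDW/h, >= 0).
#' @param free_exchanges exchange reaction ids left open for uptake; `NULL`
#'   auto-detects from `FREE_EXCHANGE_METS`.
#' @return modified copy of the model.
#' @export
apply_condition_bounds <- function(model, uptakes, free_exchanges = NULL) {
  ex <- exchange_ids(model)
  if (length(uptakes)) {
    bad <- setdiff(names(uptakes), ex)
    if (length(bad)) stop("'", bad[1], "' is not an exchange reaction")
    if (any(uptakes < 0)) stop("uptake magnitudes must be >= 0")
  }
  if (is.null(free_exchanges)) {
    free_exchanges <- ex[vapply(ex, function(e) {
      met <- names(model$reactions[[e]]$stoich)
      sub("_[a-z]+$", "", met) %in% FREE_EXCHANGE_METS
    }, logical(1))]
  }
  for (e in ex) {
    if (e %in% names(uptakes)) {
      model$reactions[[e]]$lower_bound <- -as.numeric(uptakes[[e]])
    } else if (!e %in% free_exchanges) {
      model$reactions[[e]]$lower_bound <- max(0, model$reactions[[e]]$lower_bound)
    }
  }
  model
}

#' Flux balance analysis
#'
#' Maximizes the objective flux subject to steady state (`S v = 0`) and the
#' model's flux bounds. Infeasibility and unboundedness are reported in the
#' `status` field rather than raised, so callers keep the context.
#'
#' @param model a `metabolic_model`.
#' @param objective_id reaction to maximize; default the model objective.
#' @return object of class `flux_distribution`: list with `status`,
#'   `fluxes` (named vector, mmol/gDW/h) and `objective_value`.
#' @export
fba <- function(model, objective_id = NULL) {
  if (is.null(objective_id)) objective_id <- model$objective_id
  if (!objective_id %in% names(model$reactions)) {
    stop("objective reaction '", objective_id, "' not in model")
  }
  S <- stoich_matrix(model)
  n <- ncol(S)
  lbv <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  ubv <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  lbv <- pmax(lbv, -1e6)        # guard against Inf bounds from foreign files
  ubv <- pmin(ubv, 1e6)
  obj <- as.numeric(colnames(S) == objective_id)
  sol <- solve_lp(obj, A_eq = S, b_eq = numeric(nrow(S)),
                  lb = lbv, ub = ubv, maximize = TRUE)
  fluxes <- if (sol$status == "optimal") stats::setNames(sol$x, colnames(S)) else NULL
  structure(list(status = sol$status,
                 fluxes = fluxes,
                 objective_value = if (sol$status == "optimal") sol$objective else NA_real_,
                 objective_id = objective_id),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> status:", x$status,
      " objective(", x$objective_id, ") =", format(x$objective_value), "\n")
  invisible(x)
}

#' Production/consumption flux split for one metabolite
#'
#' Decomposes the steady-state turnover of a metabolite into per-reaction
#' production and consumption fractions: the production contribution of
#' reaction r is `max(0, s_mr * v_r)` and fractions are contributions over
#' total production (consumption symmetric). A zero-turnover metabolite
#' yields empty fraction maps with `total_production = 0`.
#'
#' @param model a `metabolic_model`.
#' @param flux a `flux_distribution` (or named flux vector) at steady state.
#' @param metabolite_id metabolite to split.
#' @return list with `metabolite_id`, `production_fractions`,
#'   `consumption_fractions` (named, each summing to 1 when active) and
#'   `total_production`.
#' @export
flux_splits <- function(model, flux, metabolite_id) {
  if (!metabolite_id %in% model$metabolites$id) {
    stop("unknown metabolite '", metabolite_id, "'")
  }
  v <- if (inherits(flux, "flux_distribution")) flux$fluxes else flux
  contrib <- vapply(model$reactions, function(r) {
    s <- r$stoich[metabolite_id]
    if (is.na(s)) 0 else unname(s * v[[r$id]])
  }, numeric(1))
  prod <- pmax(contrib, 0)
  cons <- pmax(-contrib, 0)
  tp <- sum(prod)
  tc <- sum(cons)
  if (abs(tp - tc) > STEADY_STATE_TOL) {
    stop("flux vector is not at steady state for '", metabolite_id,
         "' (production ", format(tp), " vs consumption ", format(tc), ")")
  }
  if (tp <= STEADY_STATE_TOL) {
    return(list(metabolite_id = metabolite_id,
                production_fractions = stats::setNames(numeric(0), character(0)),
                consumption_fractions = stats::setNames(numeric(0), character(0)),
                total_production = 0))
  }
  list(metabolite_id = metabolite_id,
       production_fractions = prod[prod > 0] / tp,
       consumption_fractions = cons[cons > 0] / tc,
       total_production = tp)
}
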