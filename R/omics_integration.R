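# Integration of relative expression and metabolite fold changes into a
# paired two-condition flux model, and consistency-score maximization.
#
# The paired model duplicates the irreversible-split network into condition
# A (cold) and condition B (warm) copies, each with its own uptake bounds
# and a biomass floor. Every regulated reaction or metabolite contributes
# one indicator-guarded candidate constraint: for an "up" candidate with
# capped ratio rho_hat and indicator z,
#     z = 1  =>  flux_B(target) >= rho_hat * flux_A(target),
#                flux_A(target) >= epsilon,
# with flux(r) the forward+backward component sum of a reaction and
# flux(m) the total production of a metabolite; "down" is symmetric.
# Because deactivating a candidate simply removes its rows, infeasibility
# is monotone in the active set, and the maximum consistency score (MCS,
# the largest number of simultaneously satisfiable candidates) is found by
# branch-and-bound over candidate subsets with hard-constraint LP
# feasibility checks - no big-M numerics. The theoretical maximum (TMCS)
# is the number of mappable candidates.

#' Select regulated genes or metabolites from fold changes
#'
#' Up-regulated: ids within the top `ceiling(top_frac * n)` by fold change
#' whose linear FC also reaches `fc_cutoff`; down symmetric with
#' FC <= 1/fc_cutoff (stored as the magnitude 1/FC). Ties are broken by id
#' lexicographic order for determinism.
#'
#' @param values named numeric vector of linear fold changes (B vs A).
#' @param top_frac fraction selected per tail (default 0.03).
#' @param fc_cutoff minimal linear fold change (default 2).
#' @return list with named numeric vectors `up` and `down` (values are
#'   fold-change magnitudes, all >= `fc_cutoff`).
#' @export
select_regulated <- function(values, top_frac = 0.03, fc_cutoff = 2) {
  if (!length(values)) return(list(up = stats::setNames(numeric(0), character(0)),
                                   down = stats::setNames(numeric(0), character(0))))
  if (top_frac <= 0 || top_frac >= 0.5) stop("top_frac must be in (0, 0.5)")
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("fold changes must be finite and positive")
  }
  n <- length(values)
  k <- ceiling(top_frac * n)
  ids <- names(values)
  ord_up <- order(-values, ids)
  ord_dn <- order(values, ids)
  up_ids <- ids[ord_up][seq_len(k)]
  dn_ids <- ids[ord_dn][seq_len(k)]
  up <- values[up_ids][values[up_ids] >= fc_cutoff]
  down <- values[dn_ids][values[dn_ids] <= 1 / fc_cutoff]
  down <- stats::setNames(1 / down, names(down))
  list(up = up, down = down)
}

#' Map gene fold changes to reaction-level ratios through GPRs
#'
#' Evaluates each reaction's GPR on the gene fold changes with AND -> min
#' (complexes limited by their scarcest subunit) and OR -> max (isozymes).
#' Reactions with no measured gene are omitted.
#'
#' @param model a `metabolic_model`.
#' @param gene_fcs named numeric vector of per-gene (linear) fold changes.
#' @return named numeric vector, reaction id -> ratio.
#' @export
reaction_expression_ratio <- function(model, gene_fcs) {
  out <- vapply(model$reactions, function(r) {
    tryCatch(eval_gpr(r$gpr, gene_fcs),
             error = function(e) stop("reaction '", r$id, "': ", conditionMessage(e)))
  }, numeric(1))
  out[!is.na(out)]
}

# Irreversible split layout of a model: one forward column per reaction,
# plus a backward column for reactions reversible in the base model.
split_layout <- function(model) {
  cols <- list()
  for (r in model$reactions) {
    cols[[length(cols) + 1L]] <- list(rxn = r$id, dir = 1)
    if (r$lower_bound < 0) cols[[length(cols) + 1L]] <- list(rxn = r$id, dir = -1)
  }
  data.frame(rxn = vapply(cols, `[[`, character(1), "rxn"),
             dir = vapply(cols, `[[`, numeric(1), "dir"))
}

split_bounds <- function(model, layout) {
  lb <- numeric(nrow(layout))
  ub <- numeric(nrow(layout))
  for (i in seq_len(nrow(layout))) {
    r <- model$reactions[[layout$rxn[i]]]
    if (layout$dir[i] > 0) {
      lb[i] <- max(0, r$lower_bound); ub[i] <- max(0, r$upper_bound)
    } else {
      lb[i] <- max(0, -r$upper_bound); ub[i] <- max(0, -r$lower_bound)
    }
  }
  list(lb = lb, ub = pmin(ub, 1e6))
}

split_stoich <- function(model, layout) {
  S <- stoich_matrix(model)
  Ssp <- S[, layout$rxn, drop = FALSE]
  sweep(Ssp, 2L, layout$dir, `*`)
}

#' Build a paired two-condition contrast model
#'
#' Splits reversible reactions, duplicates the network into condition A
#' and B copies with their respective uptake bounds, adds per-condition
#' biomass floors (`biomass_floor_frac` x the condition's FBA optimum) and
#' creates one indicator-guarded candidate constraint per regulated
#' reaction (mapped from genes through [reaction_expression_ratio()]) and
#' per regulated metabolite found in the model. Regulated entries that map
#' to no reaction or metabolite are dropped and logged (excluded from the
#' TMCS); a target regulated in both directions is dropped as a conflict.
#'
#' @param model a `metabolic_model`.
#' @param regulation list with `up_genes`, `down_genes`, `up_metabolites`,
#'   `down_metabolites` (named fold-change magnitude vectors, as produced
#'   by [select_regulated()]).
#' @param uptakes_A,uptakes_B named uptake magnitudes per condition
#'   (see [apply_condition_bounds()]).
#' @param biomass_floor_frac fraction of each condition's FBA optimum
#'   imposed as a biomass lower bound (default 0.1).
#' @param fc_cutoff minimal ratio for a reaction-level candidate.
#' @param rho_max cap on candidate ratios (keeps constraint numerics tame).
#' @param epsilon minimal reference flux for a ratio to be meaningful
#'   (mmol/gDW/h).
#' @param free_exchanges passed to [apply_condition_bounds()].
#' @return object of class `contrast_model`.
#' @export
build_contrast_model <- function(model, regulation, uptakes_A, uptakes_B,
                                 biomass_floor_frac = 0.1, fc_cutoff = 2,
                                 rho_max = 10, epsilon = 1e-3,
                                 free_exchanges = NULL) {
  mA <- apply_condition_bounds(model, uptakes_A, free_exchanges)
  mB <- apply_condition_bounds(model, uptakes_B, free_exchanges)
  fba_A <- fba(mA)
  fba_B <- fba(mB)
  if (fba_A$status != "optimal" || fba_B$status != "optimal") {
    stop("condition model infeasible before integration (A: ", fba_A$status,
         ", B: ", fba_B$status, ")")
  }
  layout <- split_layout(model)
  nS <- nrow(layout)
  bA <- split_bounds(mA, layout)
  bB <- split_bounds(mB, layout)
  Ssp <- split_stoich(model, layout)
  nm <- nrow(Ssp)

  # candidate constraints -----------------------------------------------
  rxn_up <- reaction_expression_ratio(model, regulation$up_genes)
  rxn_dn <- reaction_expression_ratio(model, regulation$down_genes)
  rxn_up <- rxn_up[rxn_up >= fc_cutoff]
  rxn_dn <- rxn_dn[rxn_dn >= fc_cutoff]
  conflict <- intersect(names(rxn_up), names(rxn_dn))
  if (length(conflict)) {
    message("dropping ", length(conflict),
            " reaction(s) regulated in both directions: ",
            paste(conflict, collapse = ", "))
    rxn_up <- rxn_up[setdiff(names(rxn_up), conflict)]
    rxn_dn <- rxn_dn[setdiff(names(rxn_dn), conflict)]
  }
  mets_in <- model$metabolites$id
  met_up <- regulation$up_metabolites
  met_dn <- regulation$down_metabolites
  dropped <- c(setdiff(names(met_up), mets_in), setdiff(names(met_dn), mets_in))
  mapped_genes <- unique(unlist(lapply(model$reactions, function(r) gpr_genes(r$gpr))))
  dropped <- c(dropped,
               setdiff(names(regulation$up_genes), mapped_genes),
               setdiff(names(regulation$down_genes), mapped_genes))
  met_up <- met_up[names(met_up) %in% mets_in]
  met_dn <- met_dn[names(met_dn) %in% mets_in]

  cand <- rbind(
    if (length(rxn_up)) data.frame(kind = "reaction", target = names(rxn_up),
                                   direction = "up", rho = unname(rxn_up)),
    if (length(rxn_dn)) data.frame(kind = "reaction", target = names(rxn_dn),
                                   direction = "down", rho = unname(rxn_dn)),
    if (length(met_up)) data.frame(kind = "metabolite", target = names(met_up),
                                   direction = "up", rho = unname(met_up)),
    if (length(met_dn)) data.frame(kind = "metabolite", target = names(met_dn),
                                   direction = "down", rho = unname(met_dn))
  )
  if (is.null(cand)) {
    cand <- data.frame(kind = character(0), target = character(0),
                       direction = character(0), rho = numeric(0))
  }
  cand <- cand[order(cand$kind, cand$target, cand$direction), , drop = FALSE]
  cand$rho_hat <- pmin(cand$rho, rho_max)
  cand$id <- paste(substr(cand$kind, 1, 3), cand$direction, cand$target, sep = ":")
  rownames(cand) <- NULL
  K <- nrow(cand)

  # variable layout: [x_A (nS), x_B (nS)] --------------------------------
  ntot <- 2L * nS
  lb <- c(bA$lb, bB$lb)
  ub <- c(bA$ub, bB$ub)
  A_eq <- matrix(0, 2L * nm, ntot)
  A_eq[seq_len(nm), seq_len(nS)] <- Ssp
  A_eq[nm + seq_len(nm), nS + seq_len(nS)] <- Ssp
  b_eq <- numeric(2L * nm)

  # target flux coefficient vector over one condition's split columns
  target_coef <- function(kind, target) {
    cf <- numeric(nS)
    if (kind == "reaction") {
      cf[layout$rxn == target] <- 1
    } else {
      cf <- pmax(Ssp[target, ], 0)    # total production of the metabolite
    }
    cf
  }

  floor_A <- biomass_floor_frac * fba_A$objective_value
  floor_B <- biomass_floor_frac * fba_B$objective_value
  bm_fwd <- which(layout$rxn == model$objective_id & layout$dir > 0)

  A_le <- matrix(0, 2L, ntot)
  b_le <- numeric(2L)
  A_le[1L, bm_fwd] <- -1;      b_le[1L] <- -floor_A
  A_le[2L, nS + bm_fwd] <- -1; b_le[2L] <- -floor_B

  # two hard rows per candidate, activated when the candidate is selected:
  # up:   rho_hat * f_A - f_B <= 0   and   -f_A <= -epsilon
  # down: rho_hat * f_B - f_A <= 0   and   -f_B <= -epsilon
  cand_rows <- lapply(seq_len(K), function(k) {
    cf <- target_coef(cand$kind[k], cand$target[k])
    R <- matrix(0, 2L, ntot)
    if (cand$direction[k] == "up") {
      R[1L, seq_len(nS)] <- cand$rho_hat[k] * cf
      R[1L, nS + seq_len(nS)] <- -cf
      R[2L, seq_len(nS)] <- -cf
    } else {
      R[1L, nS + seq_len(nS)] <- cand$rho_hat[k] * cf
      R[1L, seq_len(nS)] <- -cf
      R[2L, nS + seq_len(nS)] <- -cf
    }
    list(A = R, b = c(0, -epsilon))
  })

  structure(list(model = model, layout = layout,
                 A_eq = A_eq, b_eq = b_eq, A_le = A_le, b_le = b_le,
                 lb = lb, ub = ub, n_split = nS,
                 bm_cols = c(bm_fwd, nS + bm_fwd),
                 candidates = cand, cand_rows = cand_rows,
                 tmcs = K, dropped = dropped,
                 epsilon = epsilon, rho_max = rho_max,
                 biomass_floors = c(A = floor_A, B = floor_B),
                 fba_opt = c(A = fba_A$objective_value, B = fba_B$objective_value)),
            class = "contrast_model")
}

#' @export
print.contrast_model <- function(x, ...) {
  cat("<contrast_model> ", x$n_split, " split columns x 2 conditions, TMCS = ",
      x$tmcs, " (", length(x$dropped), " unmappable dropped)\n", sep = "")
  invisible(x)
}

#' Maximize the consistency score of a contrast model
#'
#' Finds the largest simultaneously satisfiable set of candidate
#' constraints (the MCS) by depth-first branch-and-bound over candidate
#' subsets: a candidate's constraints are either present as hard rows or
#' absent, infeasibility is monotone in the active set (pruning whole
#' subtrees), and the remaining-candidate count bounds the search.
#' Candidates individually infeasible against the base model are excluded
#' up front. With the optimal active set fixed, representative condition
#' fluxes are selected by maximizing the summed biomass and then
#' minimizing total absolute flux (parsimonious tie-break); fluxes are
#' mapped back to net values on the unsplit network. Each active
#' constraint is re-checked post hoc against the returned fluxes.
#'
#' @param cm a `contrast_model`.
#' @return object of class `consistency_result`: list with `status`, `mcs`,
#'   `tmcs`, `active_ids`, `flux_A`, `flux_B`.
#' @export
maximize_consistency <- function(cm) {
  nS <- cm$n_split
  K <- cm$tmcs
  ntot <- 2L * nS

  with_rows <- function(idx) {
    if (!length(idx)) return(list(A = cm$A_le, b = cm$b_le))
    list(A = do.call(rbind, c(list(cm$A_le), lapply(cm$cand_rows[idx], `[[`, "A"))),
         b = c(cm$b_le, unlist(lapply(cm$cand_rows[idx], `[[`, "b"))))
  }
  feasible <- function(idx) {
    rows <- with_rows(idx)
    solve_lp(numeric(ntot), cm$A_eq, cm$b_eq, rows$A, rows$b,
             cm$lb, cm$ub)$status == "optimal"
  }

  if (!feasible(integer(0))) {
    stop("contrast model infeasible with all candidate constraints off: ",
         "check uptake bounds and biomass floors")
  }

  active_idx <- integer(0)
  if (K) {
    # candidates that cannot hold even alone can never be in the MCS
    viable <- which(vapply(seq_len(K), function(k) feasible(k), logical(1)))
    best <- integer(0)
    # depth-first over viable candidates, include-first so large active
    # sets are reached early and the cardinality bound prunes hard
    rec <- function(pos, in_set) {
      if (length(in_set) + (length(viable) - pos + 1L) <= length(best)) return()
      if (pos > length(viable)) {
        if (length(in_set) > length(best)) best <<- in_set
        return()
      }
      k <- viable[pos]
      trial <- c(in_set, k)
      if (feasible(trial)) rec(pos + 1L, trial)   # monotone: prune on failure
      rec(pos + 1L, in_set)
    }
    rec(1L, integer(0))
    active_idx <- best
  }
  mcs <- length(active_idx)
  active <- cm$candidates$id[active_idx]

  # representative fluxes: fix the active set, maximize biomass, then pFBA
  rows <- with_rows(active_idx)
  obj_bm <- numeric(ntot)
  obj_bm[cm$bm_cols] <- 1
  s1 <- solve_lp(obj_bm, cm$A_eq, cm$b_eq, rows$A, rows$b, cm$lb, cm$ub,
                 maximize = TRUE)
  if (s1$status != "optimal") stop("flux selection LP failed: ", s1$status)
  A_le2 <- rbind(rows$A, -obj_bm)
  b_le2 <- c(rows$b, -(s1$objective - 1e-7))
  obj_p <- rep(1, ntot)
  s2 <- solve_lp(obj_p, cm$A_eq, cm$b_eq, A_le2, b_le2, cm$lb, cm$ub,
                 maximize = FALSE)
  x <- if (s2$status == "optimal") s2$x else s1$x

  net_flux <- function(offset) {
    v <- stats::setNames(numeric(length(cm$model$reactions)),
                         names(cm$model$reactions))
    for (i in seq_len(nS)) {
      v[cm$layout$rxn[i]] <- v[cm$layout$rxn[i]] +
        cm$layout$dir[i] * x[offset + i]
    }
    v
  }
  vA <- net_flux(0L)
  vB <- net_flux(nS)
  fd <- function(v) {
    structure(list(status = "optimal", fluxes = v,
                   objective_value = unname(v[cm$model$objective_id]),
                   objective_id = cm$model$objective_id),
              class = "flux_distribution")
  }
  res <- structure(list(status = "optimal", mcs = mcs, tmcs = cm$tmcs,
                        active_ids = active,
                        flux_A = fd(vA), flux_B = fd(vB),
                        dropped = cm$dropped),
                   class = "consistency_result")
  viol <- check_active_constraints(cm, res, x)
  if (length(viol)) {
    warning("active constraints violated post hoc: ", paste(viol, collapse = ", "))
  }
  res
}

# Post-hoc re-check of the active candidate constraints on the split
# solution vector; returns ids of violated constraints (tolerance 1e-6).
check_active_constraints <- function(cm, res, x, tol = 1e-6) {
  if (!nrow(cm$candidates)) return(character(0))
  nS <- cm$n_split
  viol <- character(0)
  for (k in seq_len(nrow(cm$candidates))) {
    if (!cm$candidates$id[k] %in% res$active_ids) next
    cf <- numeric(nS)
    if (cm$candidates$kind[k] == "reaction") {
      cf[cm$layout$rxn == cm$candidates$target[k]] <- 1
    } else {
      cf <- pmax(split_stoich(cm$model, cm$layout)[cm$candidates$target[k], ], 0)
    }
    fA <- sum(cf * x[seq_len(nS)])
    fB <- sum(cf * x[nS + seq_len(nS)])
    ok <- if (cm$candidates$direction[k] == "up") {
      fB >= cm$candidates$rho_hat[k] * fA - tol && fA >= cm$epsilon - tol
    } else {
      fA >= cm$candidates$rho_hat[k] * fB - tol && fB >= cm$epsilon - tol
    }
    if (!ok) viol <- c(viol, cm$candidates$id[k])
  }
  viol
}

#' @export
print.consistency_result <- function(x, ...) {
  cat("<consistency_result> MCS =", x$mcs, "/ TMCS =", x$tmcs, "\n")
  invisible(x)
}

#' Consistency ratio MCS / TMCS
#'
#' @param result a `consistency_result`.
#' @return fraction in \[0, 1\]; `NA` with a warning when TMCS = 0.
#' @export
consistency_ratio <- function(result) {
  if (result$tmcs == 0) {
    warning("TMCS is zero; consistency ratio undefined")
    return(NA_real_)
  }
  result$mcs / result$tmcs
}
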