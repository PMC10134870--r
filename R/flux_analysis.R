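# Downstream comparison of the two condition flux distributions:
# flux-split based metabolite change prediction, simple matching
# coefficient scoring, pathway activity contrasts and node reports.

#' Predicted metabolite log2 fold changes from flux splits
#'
#' The "predicted internal concentration" of a metabolite in a condition is
#' proxied by its total production flux (from [flux_splits()]); the
#' predicted change is `log2(P_B / P_A)`. If both productions are below
#' `zero_tol` the prediction is 0 (unchanged); if exactly one is, the
#' prediction is +/-`cap` and flagged.
#'
#' @param model a `metabolic_model`.
#' @param flux_A,flux_B steady-state `flux_distribution`s on the model.
#' @param metabolite_ids metabolites to predict.
#' @param zero_tol flux below which production counts as zero.
#' @param cap absolute cap replacing infinite log-ratios (default 10).
#' @return data.frame metabolite_id, production_A, production_B,
#'   predicted_log2fc, capped.
#' @export
predicted_metabolite_log2fc <- function(model, flux_A, flux_B, metabolite_ids,
                                        zero_tol = 1e-9, cap = 10) {
  rows <- lapply(metabolite_ids, function(m) {
    pA <- flux_splits(model, flux_A, m)$total_production
    pB <- flux_splits(model, flux_B, m)$total_production
    capped <- FALSE
    if (pA < zero_tol && pB < zero_tol) {
      fc <- 0
    } else if (pA < zero_tol) {
      fc <- cap; capped <- TRUE
    } else if (pB < zero_tol) {
      fc <- -cap; capped <- TRUE
    } else {
      fc <- log2(pB / pA)
    }
    data.frame(metabolite_id = m, production_A = pA, production_B = pB,
               predicted_log2fc = fc, capped = capped)
  })
  do.call(rbind, rows)
}

change_category <- function(x, delta = 0) {
  ifelse(x > delta, "up", ifelse(x < -delta, "down", "unchanged"))
}

#' Simple matching coefficient between predicted and measured changes
#'
#' Categorizes each shared metabolite's predicted and measured log2FC as
#' up / down / unchanged (zero band `delta`) and scores the fraction of
#' matching categories. Also reports the Spearman correlation restricted
#' to metabolites with |measured log2FC| >= 1 (the strongly changing
#' subset).
#'
#' @param predicted,measured named numeric vectors (or the data.frame from
#'   [predicted_metabolite_log2fc()]) of log2 fold changes.
#' @param delta half-width of the "unchanged" band (default 0).
#' @return list with `smc`, `n_scored`, `table` (per-metabolite categories
#'   and match), `spearman_r`, `spearman_p`, `n_strong`.
#' @export
smc <- function(predicted, measured, delta = 0) {
  if (is.data.frame(predicted)) {
    predicted <- stats::setNames(predicted$predicted_log2fc, predicted$metabolite_id)
  }
  shared <- intersect(names(predicted), names(measured))
  if (!length(shared)) stop("no shared metabolites between predicted and measured")
  p <- predicted[shared]
  m <- measured[shared]
  pc <- change_category(p, delta)
  mc <- change_category(m, delta)
  tab <- data.frame(metabolite_id = shared,
                    predicted_log2fc = unname(p), measured_log2fc = unname(m),
                    predicted_category = pc, measured_category = mc,
                    match = pc == mc)
  strong <- shared[abs(m) >= 1]
  sp_r <- NA_real_; sp_p <- NA_real_
  if (length(strong) >= 3) {
    st <- spearman_test(p[strong], m[strong])
    sp_r <- st$rho; sp_p <- st$p
  }
  list(smc = mean(tab$match), n_scored = nrow(tab), table = tab,
       spearman_r = sp_r, spearman_p = sp_p, n_strong = length(strong))
}

#' Pathway-level flux activity comparison between conditions
#'
#' Per pathway, reactions inactive in both conditions (|flux| below
#' `zero_tol`) or changing direction between conditions are excluded;
#' over the remainder, the mean absolute flux per condition is compared
#' with a two-sample two-sided Kolmogorov-Smirnov test (exact for
#' `n_used` <= `exact_n`, asymptotic above).
#'
#' @param model a `metabolic_model`.
#' @param flux_A,flux_B `flux_distribution`s (or named flux vectors).
#' @param pathways pathway tags to compare; default all tagged pathways
#'   except exchange/transport/biomass bookkeeping.
#' @param zero_tol inactivity threshold on |flux|.
#' @param exact_n exact KS p-value up to this per-sample size.
#' @return data.frame pathway, n_total, n_used, excluded_zero_both,
#'   excluded_sign_change, mean_abs_flux_A, mean_abs_flux_B,
#'   ks_statistic, ks_p (NA when undefined).
#' @export
pathway_activity_compare <- function(model, flux_A, flux_B, pathways = NULL,
                                     zero_tol = 1e-9, exact_n = 10) {
  vA <- if (inherits(flux_A, "flux_distribution")) flux_A$fluxes else flux_A
  vB <- if (inherits(flux_B, "flux_distribution")) flux_B$fluxes else flux_B
  tags <- vapply(model$reactions, `[[`, character(1), "pathway")
  if (is.null(pathways)) {
    pathways <- setdiff(sort(unique(tags)),
                        c("exchange", "transport", "biomass", "other"))
  }
  rows <- lapply(pathways, function(pw) {
    rids <- names(tags)[tags == pw]
    a <- vA[rids]; b <- vB[rids]
    zero_both <- abs(a) < zero_tol & abs(b) < zero_tol
    sign_change <- !zero_both & (a * b < 0)
    keep <- !zero_both & !sign_change
    n_used <- sum(keep)
    ks_s <- NA_real_; ks_p <- NA_real_
    mA <- NA_real_; mB <- NA_real_
    if (n_used >= 1) {
      mA <- mean(abs(a[keep])); mB <- mean(abs(b[keep]))
      ks <- suppressWarnings(
        stats::ks.test(abs(a[keep]), abs(b[keep]), exact = n_used <= exact_n))
      ks_s <- unname(ks$statistic); ks_p <- ks$p.value
    }
    data.frame(pathway = pw, n_total = length(rids), n_used = n_used,
               excluded_zero_both = sum(zero_both),
               excluded_sign_change = sum(sign_change),
               mean_abs_flux_A = mA, mean_abs_flux_B = mB,
               ks_statistic = ks_s, ks_p = ks_p)
  })
  do.call(rbind, rows)
}

#' Flux report around a metabolite node
#'
#' All reactions touching the metabolite, with stoichiometric coefficient,
#' condition fluxes, their difference and the production/consumption role
#' per condition, sorted by |delta| descending.
#'
#' @param model a `metabolic_model`.
#' @param flux_A,flux_B `flux_distribution`s (or named flux vectors).
#' @param metabolite_id node metabolite.
#' @return data.frame reaction_id, pathway, coef, flux_A, flux_B, delta,
#'   role_A, role_B.
#' @export
node_flux_report <- function(model, flux_A, flux_B, metabolite_id) {
  if (!metabolite_id %in% model$metabolites$id) {
    stop("unknown metabolite '", metabolite_id, "'")
  }
  vA <- if (inherits(flux_A, "flux_distribution")) flux_A$fluxes else flux_A
  vB <- if (inherits(flux_B, "flux_distribution")) flux_B$fluxes else flux_B
  role <- function(s, v) {
    contrib <- s * v
    ifelse(abs(contrib) < 1e-9, "inactive",
           ifelse(contrib > 0, "producer", "consumer"))
  }
  rows <- lapply(model$reactions, function(r) {
    s <- r$stoich[metabolite_id]
    if (is.na(s)) return(NULL)
    a <- unname(vA[r$id]); b <- unname(vB[r$id])
    data.frame(reaction_id = r$id, pathway = r$pathway, coef = unname(s),
               flux_A = a, flux_B = b, delta = b - a,
               role_A = role(unname(s), a), role_B = role(unname(s), b))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-abs(out$delta)), ]
}
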