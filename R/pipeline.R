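# Pipeline orchestration: simulate (or load) inputs, run kinetics ->
# metabolome -> expression -> integration -> flux analysis, write stage
# outputs and a summary report.

#' Default pipeline configuration
#'
#' All thresholds of the analysis in one validated list. Values mirror the
#' analysis defaults: DEG thresholds |log2FC| >= 1 and adjusted p < 0.05,
#' 3% regulated tails with a 2-fold cutoff, ratio cap 10, minimum
#' reference flux 1e-3 mmol/gDW/h, biomass floor 10% of the FBA optimum.
#'
#' @param ... named overrides of any default.
#' @return validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    simulate = TRUE,
    seed = 1,
    lfc_threshold = 1,
    alpha = 0.05,
    top_frac = 0.03,
    fc_cutoff = 2,
    rho_max = 10,
    epsilon = 1e-3,
    biomass_floor_frac = 0.1,
    category_delta = 0,
    contrast_time_index = 2,
    uptake_window = c(2L, 4L),          # T1..T3 sampling indices
    condition_ref = "0C",
    condition_alt = "15C",
    od_factors = c("15C" = 0.74, "0C" = 0.66),
    n_background_genes = 400,
    replicates = 3,
    outdir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  if (cfg$top_frac <= 0 || cfg$top_frac >= 0.5) stop("top_frac must be in (0, 0.5)")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (cfg$lfc_threshold < 0) stop("lfc_threshold must be >= 0")
  if (cfg$fc_cutoff < 1) stop("fc_cutoff must be >= 1")
  if (cfg$rho_max < cfg$fc_cutoff) stop("rho_max must be >= fc_cutoff")
  if (cfg$epsilon <= 0) stop("epsilon must be > 0")
  if (cfg$biomass_floor_frac < 0 || cfg$biomass_floor_frac >= 1) {
    stop("biomass_floor_frac must be in [0, 1)")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with flat key: value entries.
#' @return `pipeline_config` with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

write_stage_table <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# generated by coldflux v", GENERATOR_VERSION,
                    " seed=", seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' With `simulate = TRUE` (the default), generates the toy model and all
#' omics tables from the configured seed, then runs every stage: growth and
#' uptake kinetics, metabolome robustness statistics, DEG summarization,
#' consistency-score integration and downstream flux analysis. Writes
#' stage tables plus `summary.json` under `outdir` (if set) and returns
#' the report invisibly-printable list.
#'
#' @param config a `pipeline_config` (default: all defaults, seed 1).
#' @return list of class `pipeline_report` with per-stage results and a
#'   `summary` list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_config(config)
  t_start <- Sys.time()
  if (!isTRUE(config$simulate)) {
    stop("external-input mode requires the input paths to be set; ",
         "this build drives all stages from the synthetic generator")
  }
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0, stage) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  # --- simulate ---------------------------------------------------------
  t0 <- tic()
  truth <- make_synthetic_truth(config$seed)
  model <- truth$model
  growth <- lapply(c("0C", "15C"), function(cc) {
    simulate_growth_experiment(truth, cc, replicates = config$replicates)
  })
  names(growth) <- c("0C", "15C")
  metabolome <- simulate_metabolome(truth, replicates = config$replicates)
  expression <- simulate_expression(truth, n_background = config$n_background_genes)
  toc(t0, "simulate")

  # --- kinetics ---------------------------------------------------------
  t0 <- tic()
  kin <- lapply(c("0C", "15C"), function(cc) {
    od <- growth[[cc]]$od
    sub <- growth[[cc]]$substrate
    tt <- sort(unique(od$time_h))
    w <- tt[config$uptake_window]
    mu <- growth_rate(od, w[1], w[2])
    upt <- lapply(c("glutamate", "gluconate"), function(s) {
      uptake_rate(od, sub, s, w[1], w[2], factors = config$od_factors)
    })
    names(upt) <- c("glutamate", "gluconate")
    list(condition = cc, mu = mu, uptake = upt)
  })
  names(kin) <- c("0C", "15C")
  toc(t0, "kinetics")

  # --- metabolome -------------------------------------------------------
  t0 <- tic()
  norm <- normalize_trajectory(metabolome)
  mets <- sort(unique(metabolome$metabolite_id))
  trends <- lapply(mets, function(m) {
    tc <- trend_correlation(
      norm[norm$metabolite_id == m & norm$condition == "0C", ],
      norm[norm$metabolite_id == m & norm$condition == "15C", ])
    data.frame(metabolite_id = m, pearson_r = tc$pearson_r,
               spearman_rho = tc$spearman_rho, spearman_p = tc$spearman_p,
               defined = tc$defined)
  })
  trends <- do.call(rbind, trends)
  frac_pos <- mean(trends$pearson_r > 0, na.rm = TRUE)
  cm0 <- correlation_matrix(norm, "0C")
  cm15 <- correlation_matrix(norm, "15C")
  mat_cmp <- compare_matrices(cm0, cm15)
  mean_tests <- mean_difference_tests(metabolome, alpha = config$alpha)
  contrast <- contrast_log2fc(metabolome, time_index = config$contrast_time_index,
                              condition_ref = config$condition_ref,
                              condition_alt = config$condition_alt,
                              lfc_threshold = config$lfc_threshold,
                              alpha = config$alpha)
  toc(t0, "metabolome")

  # --- expression -------------------------------------------------------
  t0 <- tic()
  degs <- call_degs(expression, config$lfc_threshold, config$alpha)
  enr_up <- cog_enrichment(degs$up, expression, "up", config$alpha)
  enr_dn <- cog_enrichment(degs$down, expression, "down", config$alpha)
  pw_frac <- pathway_deg_fractions(degs$up, degs$down, expression)
  toc(t0, "expression")

  # --- integration ------------------------------------------------------
  t0 <- tic()
  gene_fc <- stats::setNames(2^expression$log2fc, expression$gene_id)
  reg_genes <- select_regulated(gene_fc, config$top_frac, config$fc_cutoff)
  met_fc <- stats::setNames(2^contrast$log2fc, contrast$metabolite_id)
  map <- truth$block_spec$model_id
  names(met_fc) <- ifelse(names(met_fc) %in% names(map),
                          map[names(met_fc)], names(met_fc))
  reg_mets <- select_regulated(met_fc, config$top_frac, config$fc_cutoff)
  regulation <- list(up_genes = reg_genes$up, down_genes = reg_genes$down,
                     up_metabolites = reg_mets$up, down_metabolites = reg_mets$down)
  uptakes <- lapply(kin, function(k) {
    c(EX_glu_e = k$uptake$glutamate$uptake, EX_glcn_e = k$uptake$gluconate$uptake)
  })
  cm <- build_contrast_model(model, regulation,
                             uptakes_A = uptakes[["0C"]], uptakes_B = uptakes[["15C"]],
                             biomass_floor_frac = config$biomass_floor_frac,
                             fc_cutoff = config$fc_cutoff, rho_max = config$rho_max,
                             epsilon = config$epsilon)
  cons <- maximize_consistency(cm)
  toc(t0, "integration")

  # --- flux analysis ----------------------------------------------------
  t0 <- tic()
  mapped <- map[names(map) %in% contrast$metabolite_id]
  pred <- predicted_metabolite_log2fc(model, cons$flux_A, cons$flux_B,
                                      unname(mapped))
  measured <- stats::setNames(contrast$log2fc, contrast$metabolite_id)
  # measured values keyed by model metabolite id where mapped, measured
  # name otherwise (unmapped metabolites predict "unchanged")
  measured_model <- measured
  names(measured_model) <- ifelse(names(measured) %in% names(map),
                                  map[names(measured)], names(measured))
  pred_all <- stats::setNames(rep(0, length(measured_model)), names(measured_model))
  pred_all[pred$metabolite_id] <- pred$predicted_log2fc
  assessment <- smc(pred_all, measured_model, delta = config$category_delta)
  pw_cmp <- pathway_activity_compare(model, cons$flux_A, cons$flux_B)
  pep_node <- node_flux_report(model, cons$flux_A, cons$flux_B, "pep_c")
  toc(t0, "flux_analysis")

  summary <- list(
    seed = config$seed,
    mu = list("0C" = kin[["0C"]]$mu$mu, "15C" = kin[["15C"]]$mu$mu),
    uptake = list(
      "0C" = vapply(kin[["0C"]]$uptake, `[[`, numeric(1), "uptake"),
      "15C" = vapply(kin[["15C"]]$uptake, `[[`, numeric(1), "uptake")),
    metabolome = list(
      fraction_positive_trend = frac_pos,
      matrix_comparison_p = mat_cmp$p,
      n_significant_raw = sum(mean_tests$significant_raw),
      n_significant_bonferroni = sum(mean_tests$significant),
      n_contrast_flagged = attr(contrast, "n_flagged"),
      pct_below_threshold = attr(contrast, "pct_below")),
    expression = list(
      n_up = length(degs$up), n_down = length(degs$down),
      n_deg = length(degs$up) + length(degs$down),
      metabolic_deg_pct = attr(pw_frac, "metabolic_deg_pct")),
    integration = list(
      mcs = cons$mcs, tmcs = cons$tmcs,
      consistency_ratio = consistency_ratio(cons),
      biomass_A = cons$flux_A$objective_value,
      biomass_B = cons$flux_B$objective_value),
    flux_analysis = list(
      smc = assessment$smc,
      spearman_strong = assessment$spearman_r,
      pathway_ks_p = stats::setNames(pw_cmp$ks_p, pw_cmp$pathway)),
    timings_s = timings)

  report <- structure(list(truth = truth, config = config,
                           kinetics = kin, trends = trends,
                           matrix_comparison = mat_cmp,
                           mean_tests = mean_tests, contrast = contrast,
                           degs = degs, enrichment = rbind(enr_up, enr_dn),
                           pathway_fractions = pw_frac,
                           regulation = regulation,
                           consistency = cons, prediction = assessment,
                           pathway_comparison = pw_cmp, pep_node = pep_node,
                           summary = summary),
                      class = "pipeline_report")

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outdir, f)
    write_model(model, out("model.json"))
    write_stage_table(growth[["0C"]]$od, out("growth_0C.tsv"), config$seed)
    write_stage_table(growth[["15C"]]$od, out("growth_15C.tsv"), config$seed)
    write_stage_table(rbind(growth[["0C"]]$substrate, growth[["15C"]]$substrate),
                      out("substrates.tsv"), config$seed)
    write_stage_table(metabolome, out("metabolome.tsv"), config$seed)
    write_stage_table(expression, out("expression.tsv"), config$seed)
    write_stage_table(trends, out("trend_correlations.tsv"), config$seed)
    write_stage_table(mean_tests, out("mean_difference_tests.tsv"), config$seed)
    write_stage_table(contrast, out("metabolite_contrast.tsv"), config$seed)
    write_stage_table(report$enrichment, out("cog_enrichment.tsv"), config$seed)
    write_stage_table(pw_frac, out("pathway_deg_fractions.tsv"), config$seed)
    write_stage_table(assessment$table, out("prediction_assessment.tsv"), config$seed)
    write_stage_table(pw_cmp, out("pathway_flux_comparison.tsv"), config$seed)
    write_stage_table(pep_node, out("pep_node_report.tsv"), config$seed)
    flux_tab <- data.frame(reaction_id = names(cons$flux_A$fluxes),
                           flux_A = unname(cons$flux_A$fluxes),
                           flux_B = unname(cons$flux_B$fluxes),
                           pathway = vapply(model$reactions, `[[`, character(1),
                                            "pathway"))
    write_stage_table(flux_tab, out("condition_fluxes.tsv"), config$seed)
    cfg_out <- config
    cfg_out$outdir <- NULL            # path-independent, rerun byte-identical
    cfg_out$od_factors <- as.list(cfg_out$od_factors)
    summary_out <- summary[setdiff(names(summary), "timings_s")]  # reruns byte-identical
    jsonlite::write_json(list(config = unclass(cfg_out), summary = summary_out),
                         out("summary.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_report> seed", s$seed, "\n")
  cat(sprintf("  mu: 0C %.4f h-1, 15C %.4f h-1\n", s$mu[["0C"]], s$mu[["15C"]]))
  cat(sprintf("  metabolome: %d%% below |log2FC| 1, %.0f%% positive trends\n",
              s$metabolome$pct_below_threshold,
              100 * s$metabolome$fraction_positive_trend))
  cat(sprintf("  DEGs: %d up, %d down (metabolic %.2f%%)\n",
              s$expression$n_up, s$expression$n_down,
              s$expression$metabolic_deg_pct))
  cat(sprintf("  consistency: MCS %d / TMCS %d\n",
              s$integration$mcs, s$integration$tmcs))
  cat(sprintf("  SMC %.2f\n", s$flux_analysis$smc))
  invisible(x)
}
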