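# Synthetic study generator: a toy central-carbon model for a bacterium
# growing on glutamate + gluconate, plus growth, metabolome and expression
# tables with planted ground truth for recovery testing.
#
# The generator emulates the two-temperature study design: a cold condition
# ("0C", exponential growth rate ~0.027 h^-1, uptakes 0.10/0.08 mmol/gDW/h
# for glutamate/gluconate) and a warm condition ("15C", ~0.27 h^-1,
# 0.47/0.62), five sampling times per curve, three replicates, a
# two-block metabolome (amino-acid-like rising, central-intermediate-like
# falling) nearly identical across conditions except a small contrast set,
# and expression fold changes consistent with planted pathway flux
# differences (PPP up in the warm condition, fatty acids up in the cold).

GENERATOR_VERSION <- "1"

#' Build the toy central-carbon metabolic model
#'
#' A ~32-reaction, ~25-metabolite network: glutamate and gluconate uptake,
#' a gluconate -> pentose phosphate entry with a ribose-5-P branch, lower
#' glycolysis through PEP / pyruvate / acetyl-CoA, a TCA loop with malate
#' and oxaloacetate, the PEP-pyruvate-oxaloacetate anaplerotic node
#' (malate dehydrogenase, PEP carboxykinase, PEP synthetase, pyruvate
#' kinase, PEP carboxylase, citrate synthase), a lumped fatty-acid branch
#' from acetyl-CoA, a lumped amino-acid branch from 2-oxoglutarate,
#' acetate overflow, and a biomass reaction drawing acetyl-CoA,
#' oxaloacetate, 2-oxoglutarate, ribose-5-P, PEP and ATP. Every reaction
#' is pathway-tagged; GPRs are one-gene except an AND complex (pyruvate
#' dehydrogenase) and an OR isozyme pair (2-oxoglutarate dehydrogenase).
#'
#' @param default_bound magnitude used for unconstrained bounds.
#' @return a validated `metabolic_model`.
#' @export
make_toy_model <- function(default_bound = 1000) {
  B <- default_bound
  met <- function(id, name, comp) data.frame(id = id, name = name, compartment = comp)
  mets <- rbind(
    met("glu_e", "L-glutamate", "e"), met("glcn_e", "D-gluconate", "e"),
    met("o2_e", "oxygen", "e"), met("co2_e", "carbon dioxide", "e"),
    met("nh4_e", "ammonium", "e"),
    met("glu_c", "L-glutamate", "c"), met("glcn_c", "D-gluconate", "c"),
    met("p6g_c", "6-phospho-gluconate", "c"), met("r5p_c", "ribose-5-phosphate", "c"),
    met("g3p_c", "glyceraldehyde-3-phosphate", "c"),
    met("ppp1_c", "PPP intermediate 1 (lumped)", "c"),
    met("ppp2_c", "PPP intermediate 2 (lumped)", "c"),
    met("pep_c", "phosphoenolpyruvate", "c"), met("pyr_c", "pyruvate", "c"),
    met("accoa_c", "acetyl-CoA", "c"), met("malcoa_c", "malonyl-CoA", "c"),
    met("fa1_c", "acyl intermediate 1 (lumped)", "c"),
    met("fa2_c", "acyl intermediate 2 (lumped)", "c"),
    met("cit_c", "citrate", "c"), met("akg_c", "2-oxoglutarate", "c"),
    met("succ_c", "succinate", "c"), met("mal_c", "L-malate", "c"),
    met("oaa_c", "oxaloacetate", "c"), met("atp_c", "ATP", "c"),
    met("nh4_c", "ammonium", "c"), met("o2_c", "oxygen", "c"),
    met("co2_c", "carbon dioxide", "c"), met("ac_c", "acetate", "c"),
    met("aa_c", "amino acids (lumped)", "c"), met("fa_c", "fatty acids (lumped)", "c")
  )
  rx <- list(
    reaction("EX_glu_e", c(glu_e = -1), -10, B, pathway = "exchange"),
    reaction("EX_glcn_e", c(glcn_e = -1), -10, B, pathway = "exchange"),
    reaction("EX_o2_e", c(o2_e = -1), -B, B, pathway = "exchange"),
    reaction("EX_co2_e", c(co2_e = -1), -B, B, pathway = "exchange"),
    reaction("EX_nh4_e", c(nh4_e = -1), -B, B, pathway = "exchange"),
    reaction("SK_ac_c", c(ac_c = -1), 0, B, pathway = "exchange"),
    reaction("SK_aa_c", c(aa_c = -1), 0, B, pathway = "exchange"),
    reaction("SK_fa_c", c(fa_c = -1), 0, B, pathway = "exchange"),
    reaction("GLUt", c(glu_e = -1, glu_c = 1), 0, B, gpr = "gT1", pathway = "transport"),
    reaction("GLCNt", c(glcn_e = -1, glcn_c = 1), 0, B, gpr = "gT2", pathway = "transport"),
    reaction("O2t", c(o2_e = -1, o2_c = 1), 0, B, pathway = "transport"),
    reaction("CO2t", c(co2_c = -1, co2_e = 1), -B, B, pathway = "transport"),
    reaction("NH4t", c(nh4_e = -1, nh4_c = 1), -B, B, pathway = "transport"),
    reaction("GDH", c(glu_c = -1, akg_c = 1, nh4_c = 1), 0, B,
             gpr = "g01", pathway = "amino_acids",
             name = "glutamate dehydrogenase"),
    reaction("GNK", c(glcn_c = -1, atp_c = -1, p6g_c = 1), 0, B,
             gpr = "g02", pathway = "PPP", name = "gluconokinase"),
    reaction("GND", c(p6g_c = -1, ppp1_c = 1, co2_c = 1), 0, B,
             gpr = "g03", pathway = "PPP",
             name = "6-phosphogluconate dehydrogenase (oxidative PPP)"),
    reaction("PPP2", c(ppp1_c = -1, ppp2_c = 1), 0, B,
             gpr = "g23", pathway = "PPP", name = "pentose interconversion 1 (lumped)"),
    reaction("PPP3", c(ppp2_c = -1, r5p_c = 1), 0, B,
             gpr = "g24", pathway = "PPP", name = "pentose interconversion 2 (lumped)"),
    reaction("TKT", c(r5p_c = -1, g3p_c = 1), -B, B,
             gpr = "g04", pathway = "PPP",
             name = "transketolase (lumped non-oxidative PPP)"),
    reaction("ENO", c(g3p_c = -1, pep_c = 1), -B, B,
             gpr = "g05", pathway = "glycolysis", name = "enolase (lumped)"),
    reaction("PYK", c(pep_c = -1, pyr_c = 1, atp_c = 1), 0, B,
             gpr = "g06", pathway = "glycolysis", name = "pyruvate kinase"),
    reaction("PDH", c(pyr_c = -1, accoa_c = 1, co2_c = 1), 0, B,
             gpr = "g07 and g08", pathway = "glycolysis",
             name = "pyruvate dehydrogenase complex"),
    reaction("PTA", c(accoa_c = -1, ac_c = 1, atp_c = 1), 0, B,
             gpr = "g22", pathway = "other", name = "acetate overflow (lumped)"),
    reaction("CS", c(accoa_c = -1, oaa_c = -1, cit_c = 1), 0, B,
             gpr = "g09", pathway = "TCA", name = "citrate synthase"),
    reaction("IDH", c(cit_c = -1, akg_c = 1, co2_c = 1), 0, B,
             gpr = "g10", pathway = "TCA", name = "isocitrate dehydrogenase (lumped)"),
    reaction("AKGDH", c(akg_c = -1, succ_c = 1, co2_c = 1, atp_c = 1), 0, B,
             gpr = "g11 or g12", pathway = "TCA",
             name = "2-oxoglutarate dehydrogenase (isozymes)"),
    reaction("SDH", c(succ_c = -1, mal_c = 1), 0, B,
             gpr = "g13", pathway = "TCA", name = "succinate -> malate (lumped)"),
    reaction("MDH", c(mal_c = -1, oaa_c = 1), -B, B,
             gpr = "g14", pathway = "TCA", name = "malate dehydrogenase"),
    reaction("PEPCK", c(oaa_c = -1, atp_c = -1, pep_c = 1, co2_c = 1), 0, B,
             gpr = "g15", pathway = "anaplerotic",
             name = "PEP carboxykinase (oxaloacetate -> PEP)"),
    reaction("PPS", c(pyr_c = -1, atp_c = -2, pep_c = 1), 0, B,
             gpr = "g16", pathway = "anaplerotic",
             name = "PEP synthetase (pyruvate -> PEP)"),
    reaction("PPC", c(pep_c = -1, co2_c = -1, oaa_c = 1), 0, B,
             gpr = "g17", pathway = "anaplerotic", name = "PEP carboxylase"),
    reaction("RESP", c(accoa_c = -1, o2_c = -2, co2_c = 2, atp_c = 4), 0, B,
             gpr = "g18", pathway = "other", name = "respiration (lumped)"),
    reaction("ACC", c(accoa_c = -1, atp_c = -1, malcoa_c = 1), 0, B,
             gpr = "g19", pathway = "fatty_acids", name = "acetyl-CoA carboxylase"),
    reaction("FA2", c(malcoa_c = -1, fa1_c = 1), 0, B,
             gpr = "g25", pathway = "fatty_acids", name = "acyl elongation 1 (lumped)"),
    reaction("FA3", c(fa1_c = -1, fa2_c = 1), 0, B,
             gpr = "g26", pathway = "fatty_acids", name = "acyl elongation 2 (lumped)"),
    reaction("FAS", c(accoa_c = -1, fa2_c = -2, fa_c = 1), 0, B,
             gpr = "g20", pathway = "fatty_acids", name = "fatty-acid synthase (lumped)"),
    reaction("AADH", c(akg_c = -1, nh4_c = -1, aa_c = 1), 0, B,
             gpr = "g21", pathway = "amino_acids",
             name = "amino-acid biosynthesis (lumped)"),
    reaction("BIOMASS", c(accoa_c = -0.6, oaa_c = -0.4, akg_c = -0.4,
                          r5p_c = -0.2, pep_c = -0.2, atp_c = -5),
             0, B, pathway = "biomass", name = "biomass assembly")
  )
  genes <- c("gT1", "gT2", sprintf("g%02d", 1:26))
  metabolic_model(mets, rx, genes, "BIOMASS", id = "toy_central_carbon")
}

#' Assemble the planted ground truth for a synthetic study
#'
#' Fixes the condition parameters (growth rates, uptake rates), constructs
#' the planted flux pair by FBA on the per-condition toy model with
#' pathway-forcing bounds (fatty-acid flux doubled in the cold condition A,
#' PEP carboxykinase rerouting in A; the warm condition B carries the
#' higher pentose-phosphate flux through its larger gluconate uptake), and
#' derives the regulated truth (reactions whose flux magnitudes differ at
#' least 2-fold). Generation aborts if the planted pair violates steady
#' state or bounds.
#'
#' @param seed master seed for all downstream randomness.
#' @param noise list with `od_cv`, `met_cv`, `expr_sd` (defaults 0.05,
#'   0.15, 0.25).
#' @return object of class `synthetic_truth`.
#' @export
make_synthetic_truth <- function(seed = 1,
                                 noise = list(od_cv = 0.05, met_cv = 0.15,
                                              expr_sd = 0.25)) {
  model <- make_toy_model()
  uptake_A <- c(EX_glu_e = 0.10, EX_glcn_e = 0.08)
  uptake_B <- c(EX_glu_e = 0.47, EX_glcn_e = 0.62)
  force_A <- list(SK_fa_c = c(0.05, 0.05), PEPCK = c(0.05, 1000))
  force_B <- list(SK_fa_c = c(0.02, 0.02), PEPCK = c(0, 0.01))
  planted_fba <- function(uptakes, forcing) {
    m <- apply_condition_bounds(model, uptakes)
    for (rid in names(forcing)) {
      m$reactions[[rid]]$lower_bound <- forcing[[rid]][1]
      m$reactions[[rid]]$upper_bound <- forcing[[rid]][2]
    }
    sol <- fba(m)
    if (sol$status != "optimal" || sol$objective_value <= 0) {
      stop("planted flux construction failed (status ", sol$status, ")")
    }
    verify_flux(model, sol$fluxes, uptakes, forcing)
    sol
  }
  flux_A <- planted_fba(uptake_A, force_A)
  flux_B <- planted_fba(uptake_B, force_B)

  ratios <- planted_reaction_ratios(model, flux_A$fluxes, flux_B$fluxes)
  reg_up <- ratios[ratios >= 2]
  reg_dn <- ratios[ratios <= 0.5]

  structure(list(seed = seed, model = model,
                 conditions = c(A = "0C", B = "15C"),
                 mu = c("0C" = 0.027, "15C" = 0.27),
                 uptakes = list("0C" = uptake_A, "15C" = uptake_B),
                 times = list("0C" = c(70, 141, 179, 190, 240),
                              "15C" = c(6, 14, 20, 25, 39)),
                 od_factors = c("15C" = 0.74, "0C" = 0.66),
                 flux_A = flux_A, flux_B = flux_B,
                 regulated_truth = list(up = reg_up, down = reg_dn),
                 block_spec = metabolome_block_spec(),
                 noise = noise,
                 generator_version = GENERATOR_VERSION),
            class = "synthetic_truth")
}

# Steady state and bound verification for a planted flux vector; aborts on
# violation so no data can be emitted from an invalid truth.
verify_flux <- function(model, v, uptakes, forcing, tol = 1e-6) {
  S <- stoich_matrix(model)
  resid <- max(abs(S %*% v[colnames(S)]))
  if (resid > tol) stop("planted flux violates steady state (residual ", resid, ")")
  m <- apply_condition_bounds(model, uptakes)
  for (rid in names(forcing)) {
    m$reactions[[rid]]$lower_bound <- forcing[[rid]][1]
    m$reactions[[rid]]$upper_bound <- forcing[[rid]][2]
  }
  for (r in m$reactions) {
    if (v[r$id] < r$lower_bound - tol || v[r$id] > r$upper_bound + tol) {
      stop("planted flux violates bounds on '", r$id, "'")
    }
  }
  invisible(TRUE)
}

# Per-reaction flux-magnitude ratios B/A over reactions active in BOTH
# conditions (so every derived relative constraint is satisfied, reference
# flux included, by the planted pair itself).
planted_reaction_ratios <- function(model, vA, vB, floor = 1e-3) {
  ids <- names(model$reactions)
  ids <- ids[!vapply(model$reactions, `[[`, logical(1), "is_exchange")]
  a <- abs(vA[ids]); b <- abs(vB[ids])
  keep <- a >= floor & b >= floor
  (b / a)[keep]
}

# The simulated metabolome: 34 metabolites in two anti-correlated blocks,
# with an 8-metabolite contrast set shifted at T1 in the warm condition
# (2 up, 6 down), mirroring the study design it emulates. `model_id` maps
# measured names into the toy model where a counterpart exists.
metabolome_block_spec <- function() {
  rising <- c("alanine", "aspartate", "glutamate", "glutamine", "glycine",
              "isoleucine", "leucine", "lysine", "methionine", "phenylalanine",
              "proline", "serine", "threonine", "tryptophan", "tyrosine", "valine")
  falling <- c("malate", "citrate", "succinate", "fumarate", "oxoglutarate",
               "pyruvate", "pep", "ribose", "gluconate", "acetate", "nadx",
               "nadpx", "amp", "uracil", "udp_glcnac", "thymidine",
               "methylnicotinamide", "ethanol")
  map <- c(glutamate = "glu_c", malate = "mal_c", citrate = "cit_c",
           succinate = "succ_c", oxoglutarate = "akg_c", pyruvate = "pyr_c",
           pep = "pep_c", ribose = "r5p_c", gluconate = "glcn_c",
           acetate = "ac_c")
  list(rising = rising, falling = falling,
       contrast_up = c("nadx", "gluconate"),
       contrast_down = c("pep", "succinate", "udp_glcnac", "thymidine",
                         "acetate", "methylnicotinamide"),
       contrast_shift_log2 = 1.5,
       model_id = map)
}

#' Simulate a growth + substrate-drawdown experiment
#'
#' Exponential OD600 growth at the condition's planted rate, capped when
#' the substrates run out; substrate drawdown is consistent with the
#' planted uptake rate (exhaustion lands near the fourth sampling point).
#' Measurements carry multiplicative lognormal noise; replicates are
#' independent given the seed.
#'
#' @param truth a `synthetic_truth`.
#' @param condition condition label ("0C" or "15C").
#' @param replicates number of biological replicates (default 3).
#' @return list with data.frames `od` (condition, time_h, replicate,
#'   od600) and `substrate` (condition, time_h, replicate, substrate_id,
#'   concentration, units).
#' @export
simulate_growth_experiment <- function(truth, condition, replicates = 3) {
  set.seed(truth$seed + 11 + 101 * match(condition, names(truth$mu)))
  times <- truth$times[[condition]]
  mu <- truth$mu[[condition]]
  od0 <- 0.2
  # Substrates run out at the 4th sampled time, right at the end of the
  # uptake-estimation window, so the window sees nearly the whole drawdown
  # (pure exponential growth otherwise back-loads consumption and buries
  # the early-window signal under measurement noise).
  t_exh <- times[4]
  od_det <- function(t) od0 * exp(mu * pmin(t, t_exh))
  factor <- truth$od_factors[[condition]]
  uptk <- truth$uptakes[[condition]]
  subs <- c(EX_glu_e = "glutamate", EX_glcn_e = "gluconate")
  cv <- truth$noise$od_cv
  lnoise <- function(n, cv) exp(stats::rnorm(n, -log(1 + cv^2) / 2, sqrt(log(1 + cv^2))))

  od <- do.call(rbind, lapply(seq_len(replicates), function(rr) {
    data.frame(condition = condition, time_h = times, replicate = rr,
               od600 = od_det(times) * lnoise(length(times), cv))
  }))
  substrate <- do.call(rbind, lapply(names(subs), function(ex) {
    q <- uptk[[ex]]                         # mmol/gDW/h
    lambda <- 1000 * mu / q                 # g biomass per mol substrate
    s0 <- (od_det(t_exh) - od0) * factor / lambda   # mol/L, exhausted at T4
    conc <- pmax(0, s0 - (od_det(times) - od0) * factor / lambda)
    do.call(rbind, lapply(seq_len(replicates), function(rr) {
      data.frame(condition = condition, time_h = times, replicate = rr,
                 substrate_id = subs[[ex]],
                 concentration = conc * lnoise(length(times), cv),
                 units = "mol/L")
    }))
  }))
  list(od = od, substrate = substrate)
}

#' Simulate the two-condition metabolome
#'
#' Shared latent block trajectories (rising amino-acid-like block, falling
#' central-intermediate block) drive both conditions, so non-contrast
#' metabolites correlate positively across conditions; the contrast subset
#' receives a condition-specific multiplicative shift at the first
#' sampling point (up contrast: higher in the warm condition; down:
#' lower). Replicate noise is lognormal at the configured CV.
#'
#' @param truth a `synthetic_truth`.
#' @param replicates replicates per time point (default 3).
#' @param met_cv override for the metabolite noise CV.
#' @return long-format data.frame metabolite_id, condition, time_h,
#'   replicate, value.
#' @export
simulate_metabolome <- function(truth, replicates = 3, met_cv = NULL) {
  set.seed(truth$seed + 23)
  bs <- truth$block_spec
  cv <- if (is.null(met_cv)) truth$noise$met_cv else met_cv
  sigma <- sqrt(log(1 + cv^2))
  shift <- bs$contrast_shift_log2
  mets <- c(bs$rising, bs$falling)
  base_level <- stats::setNames(exp(stats::runif(length(mets), 0, 2)), mets)
  rows <- list()
  for (cond in names(truth$times)) {
    times <- truth$times[[cond]]
    # latent trends advance with the sampling stage (the two curves were
    # sampled at matched physiological points, not matched absolute times)
    frac <- (seq_along(times) - 1) / (length(times) - 1)
    for (m in mets) {
      latent <- if (m %in% bs$rising) 1 + 1.5 * frac else 2.5 - 1.5 * frac
      mult <- rep(1, length(times))
      if (cond == "15C") {    # contrast applied at T1 (2nd sampling point)
        if (m %in% bs$contrast_up) mult[2] <- 2^shift
        if (m %in% bs$contrast_down) mult[2] <- 2^(-shift)
      }
      for (rr in seq_len(replicates)) {
        noise <- exp(stats::rnorm(length(times), -sigma^2 / 2, sigma))
        rows[[length(rows) + 1L]] <- data.frame(
          metabolite_id = m, condition = cond, time_h = times, replicate = rr,
          value = base_level[[m]] * latent * mult * noise)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a gene-expression table from the planted flux pair
#'
#' Genes of reactions whose planted flux magnitudes differ at least 2-fold
#' between conditions receive a log2 fold change reflecting the ratio
#' (warm over cold, Gaussian noise, small adjusted p); background genes
#' get null fold changes and uniform adjusted p. Counts are negative
#' binomial around a lognormal baseline; COG letters and pathway tags are
#' derived from the reactions a gene participates in.
#'
#' @param truth a `synthetic_truth`.
#' @param n_background number of non-model background genes (default 400).
#' @param expr_sd override for the log2FC noise s.d.
#' @return gene data.frame: gene_id, length_nt, count_* (3 samples per
#'   condition), tpm_0C, tpm_15C, log2fc, padj, cog, pathways, is_metabolic.
#' @export
simulate_expression <- function(truth, n_background = 400, expr_sd = NULL) {
  set.seed(truth$seed + 37)
  model <- truth$model
  sd_fc <- if (is.null(expr_sd)) truth$noise$expr_sd else expr_sd
  vA <- truth$flux_A$fluxes
  vB <- truth$flux_B$fluxes
  cog_map <- c(glycolysis = "C", TCA = "C", PPP = "G", fatty_acids = "I",
               amino_acids = "E", anaplerotic = "C", transport = "P",
               other = "C", exchange = "R", biomass = "R")
  gene_rxns <- lapply(model$genes, function(g) {
    names(model$reactions)[vapply(model$reactions, function(r) {
      g %in% gpr_genes(r$gpr)
    }, logical(1))]
  })
  names(gene_rxns) <- model$genes
  floor_ <- 1e-3
  gene_rows <- lapply(model$genes, function(g) {
    rids <- gene_rxns[[g]]
    pw <- unique(vapply(model$reactions[rids], `[[`, character(1), "pathway"))
    a <- max(abs(vA[rids])); b <- max(abs(vB[rids]))
    ratio <- (b + floor_) / (a + floor_)
    planted <- max(a, b) >= floor_ && (ratio >= 2 || ratio <= 0.5)
    lfc <- if (planted) log2(ratio) + stats::rnorm(1, 0, sd_fc) else stats::rnorm(1, 0, sd_fc)
    padj <- if (planted) stats::runif(1, 1e-8, 0.01) else stats::runif(1, 0.05, 1)
    data.frame(gene_id = g, log2fc = lfc, padj = padj,
               cog = cog_map[[pw[1]]],
               pathways = paste(sort(pw), collapse = ";"),
               is_metabolic = TRUE)
  })
  bg_letters <- c("J", "K", "L", "M", "N", "O", "T", "U", "V", "D")
  bg_rows <- data.frame(
    gene_id = sprintf("bg%04d", seq_len(n_background)),
    log2fc = stats::rnorm(n_background, 0, sd_fc),
    padj = stats::runif(n_background, 0, 1),
    cog = sample(bg_letters, n_background, replace = TRUE),
    pathways = NA_character_,
    is_metabolic = FALSE)
  tab <- rbind(do.call(rbind, gene_rows), bg_rows)
  n <- nrow(tab)
  tab$length_nt <- round(stats::runif(n, 300, 3000))
  base_expr <- exp(stats::rnorm(n, 5, 1))
  mu0 <- base_expr * tab$length_nt / 1000
  mu15 <- mu0 * 2^tab$log2fc
  for (rr in 1:3) {
    tab[[paste0("count_0C_r", rr)]] <- stats::rnbinom(n, mu = mu0, size = 10)
    tab[[paste0("count_15C_r", rr)]] <- stats::rnbinom(n, mu = mu15, size = 10)
  }
  c0 <- rowMeans(tab[paste0("count_0C_r", 1:3)])
  c15 <- rowMeans(tab[paste0("count_15C_r", 1:3)])
  tab$tpm_0C <- compute_tpm(c0, tab$length_nt)
  tab$tpm_15C <- compute_tpm(c15, tab$length_nt)
  rownames(tab) <- NULL
  tab
}
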