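# A fixed two-route network for prediction tests: B is made from A by R1
# and drained by BM; steady-state flux vectors are written by hand.
pred_model <- function() {
  mets <- data.frame(id = c("a_e", "a_c", "b_c"), name = c("A", "A", "B"),
                     compartment = c("e", "c", "c"))
  metabolic_model(mets, list(
    reaction("EX_a", c(a_e = -1), -100, 1000),
    reaction("TA", c(a_e = -1, a_c = 1), 0, 1000),
    reaction("R1", c(a_c = -1, b_c = 1), 0, 1000),
    reaction("BM", c(b_c = -1), 0, 1000, pathway = "biomass")),
    objective_id = "BM")
}
flux_at <- function(v) c(EX_a = -v, TA = v, R1 = v, BM = v)

test_that("predicted metabolite changes follow production-flux ratios", {
  m <- pred_model()
  pr <- predicted_metabolite_log2fc(m, flux_at(2), flux_at(4), "b_c")
  expect_equal(pr$predicted_log2fc, 1)
  expect_false(pr$capped)

  # both productions zero: unchanged
  pr0 <- predicted_metabolite_log2fc(m, flux_at(0), flux_at(0), "b_c")
  expect_equal(pr0$predicted_log2fc, 0)
  # production only in B: capped at +10 and flagged
  prc <- predicted_metabolite_log2fc(m, flux_at(0), flux_at(1), "b_c")
  expect_equal(prc$predicted_log2fc, 10)
  expect_true(prc$capped)
  expect_error(predicted_metabolite_log2fc(m, flux_at(1), flux_at(1), "nope"),
               "unknown metabolite")
})

test_that("predicted changes are antisymmetric under condition swap", {
  m <- pred_model()
  cases <- list(c(2, 4), c(3, 3), c(0, 1), c(0, 0), c(5, 1))
  for (cs in cases) {
    fwd <- predicted_metabolite_log2fc(m, flux_at(cs[1]), flux_at(cs[2]), "b_c")
    rev <- predicted_metabolite_log2fc(m, flux_at(cs[2]), flux_at(cs[1]), "b_c")
    expect_equal(fwd$predicted_log2fc, -rev$predicted_log2fc)
  }
})

test_that("SMC counts category matches and its Spearman subset", {
  p <- c(m1 = 0.5, m2 = 0.3, m3 = -0.2)
  m <- c(m1 = 1.2, m2 = -1.4, m3 = -2.0)
  res <- smc(p, m)
  expect_equal(res$smc, 2 / 3)
  expect_equal(res$n_scored, 3)
  expect_equal(res$n_strong, 3)        # all |measured| >= 1
  expect_equal(smc(p, p)$smc, 1)
  # invariant under metabolite reordering
  res2 <- smc(p[c(3, 1, 2)], m)
  expect_equal(res2$smc, res$smc)
  expect_error(smc(c(x = 1), c(y = 1)), "no shared metabolites")
})

test_that("pathway comparison applies the stated exclusion rules", {
  mets <- data.frame(id = "a_c", name = "A", compartment = "c")
  m <- metabolic_model(mets, list(
    reaction("r1", c(a_c = 1), -1000, 1000, pathway = "TCA"),
    reaction("r2", c(a_c = 1), -1000, 1000, pathway = "TCA"),
    reaction("r3", c(a_c = 1), -1000, 1000, pathway = "TCA"),
    reaction("BM", c(a_c = -1), 0, 1000, pathway = "biomass")),
    objective_id = "BM")
  vA <- c(r1 = 0, r2 = 2, r3 = 4, BM = 0)
  vB <- c(r1 = 0, r2 = -3, r3 = 2, BM = 0)
  pc <- pathway_activity_compare(m, vA, vB, pathways = "TCA")
  expect_equal(pc$n_total, 3)
  expect_equal(pc$excluded_zero_both, 1)   # r1
  expect_equal(pc$excluded_sign_change, 1) # r2
  expect_equal(pc$n_used, 1)               # r3 only
  expect_equal(pc$n_total, pc$n_used + pc$excluded_zero_both +
                 pc$excluded_sign_change)
  expect_equal(pc$mean_abs_flux_A, 4)
  expect_equal(pc$mean_abs_flux_B, 2)

  # identical flux samples: KS statistic 0, p = 1
  pc2 <- pathway_activity_compare(m, vA, vA, pathways = "TCA")
  expect_equal(pc2$ks_statistic, 0)
  expect_equal(pc2$ks_p, 1)

  # nothing left after exclusions: undefined, not an error
  pc3 <- pathway_activity_compare(m, c(r1 = 1, r2 = 0, r3 = 0, BM = 0),
                                  c(r1 = -1, r2 = 0, r3 = 0, BM = 0),
                                  pathways = "TCA")
  expect_equal(pc3$n_used, 0)
  expect_true(is.na(pc3$ks_p))
})

test_that("node report lists the PEP neighborhood sorted by flux change", {
  truth <- shared_truth()
  rep_ <- node_flux_report(truth$model, truth$flux_A$fluxes,
                           truth$flux_B$fluxes, "pep_c")
  touching <- names(truth$model$reactions)[vapply(truth$model$reactions,
    function(r) "pep_c" %in% names(r$stoich), logical(1))]
  expect_setequal(rep_$reaction_id, touching)
  expect_true(all(diff(abs(rep_$delta)) <= 1e-12))  # sorted descending
  # the planted cold-condition rerouting: PEP carboxykinase favors A
  pepck <- rep_[rep_$reaction_id == "PEPCK", ]
  expect_lt(pepck$delta, 0)
  expect_equal(pepck$role_A, "producer")

  # roles agree with the flux-split decomposition
  fsA <- flux_splits(truth$model, truth$flux_A, "pep_c")
  producers_A <- rep_$reaction_id[rep_$role_A == "producer"]
  expect_setequal(producers_A, names(fsA$production_fractions))

  # zero-turnover node: all roles inactive
  closed <- apply_condition_bounds(truth$model, c(EX_glu_e = 0, EX_glcn_e = 0))
  v0 <- fba(closed)$fluxes
  rep0 <- node_flux_report(truth$model, v0, v0, "pep_c")
  expect_true(all(rep0$role_A == "inactive"))
})
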