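test_that("regulated selection takes 3% tails above the fold-change cutoff", {
  set.seed(6)
  # 100 genes; the top three carry FCs above 2, the bottom three below 1/2
  fc <- setNames(runif(100, 0.8, 1.2), sprintf("g%03d", 1:100))
  fc[c("g001", "g002", "g003")] <- c(8, 4, 2.5)
  fc[c("g098", "g099", "g100")] <- c(1 / 8, 1 / 4, 1 / 2.5)
  reg <- select_regulated(fc, top_frac = 0.03, fc_cutoff = 2)
  expect_setequal(names(reg$up), c("g001", "g002", "g003"))
  expect_setequal(names(reg$down), c("g098", "g099", "g100"))
  expect_true(all(reg$up >= 2))
  expect_true(all(reg$down >= 2))    # stored as magnitudes

  # a top-ranked gene below the cutoff is excluded
  fc2 <- setNames(c(3, 1.5, rep(1, 98)), sprintf("g%03d", 1:100))
  reg2 <- select_regulated(fc2)
  expect_setequal(names(reg2$up), "g001")

  # all-equal fold changes select nothing
  reg3 <- select_regulated(setNames(rep(1, 50), sprintf("g%02d", 1:50)))
  expect_length(reg3$up, 0)
  expect_length(reg3$down, 0)

  # deterministic lexicographic tie-break
  fc4 <- setNames(rep(c(4, 1), c(5, 95)), sprintf("g%03d", c(5:1, 6:100)))
  reg4 <- select_regulated(fc4, top_frac = 0.03)
  expect_equal(names(reg4$up), c("g001", "g002", "g003"))

  expect_error(select_regulated(fc, top_frac = 0.6), "top_frac")
})

test_that("gene fold changes map to reactions through GPRs", {
  model <- make_toy_model()
  fcs <- c(g07 = 4, g08 = 2, g11 = 4, g12 = 2, g06 = 3)
  rr <- reaction_expression_ratio(model, fcs)
  expect_equal(rr[["PDH"]], 2)      # complex: min over subunits
  expect_equal(rr[["AKGDH"]], 4)    # isozymes: max
  expect_equal(rr[["PYK"]], 3)
  expect_false("CS" %in% names(rr)) # no measured gene -> omitted
})

test_that("contrast model counts mappable candidates as the TMCS", {
  model <- make_toy_model()
  upA <- c(EX_glu_e = 0.10, EX_glcn_e = 0.08)
  upB <- c(EX_glu_e = 0.47, EX_glcn_e = 0.62)
  reg1 <- list(up_genes = c(g06 = 4), down_genes = c(),
               up_metabolites = c(), down_metabolites = c())
  cm1 <- build_contrast_model(model, reg1, upA, upB)
  expect_equal(cm1$tmcs, 1L)
  expect_equal(cm1$candidates$target, "PYK")

  # a regulated gene in no GPR and an unknown metabolite are dropped
  reg2 <- list(up_genes = c(g06 = 4, ghost = 9), down_genes = c(),
               up_metabolites = c(unknown_met = 3), down_metabolites = c())
  cm2 <- build_contrast_model(model, reg2, upA, upB)
  expect_equal(cm2$tmcs, 1L)
  expect_setequal(cm2$dropped, c("ghost", "unknown_met"))

  # a reaction pushed both ways is dropped as a conflict
  reg3 <- list(up_genes = c(g06 = 4), down_genes = c(g06 = 4),
               up_metabolites = c(), down_metabolites = c())
  expect_message(cm3 <- build_contrast_model(model, reg3, upA, upB),
                 "both directions")
  expect_equal(cm3$tmcs, 0L)
})

test_that("reversible reactions split into nonnegative components", {
  m <- reversible_model(5)
  layout <- coldflux:::split_layout(m)
  expect_equal(sum(layout$rxn == "RX"), 2L)   # forward + backward column
  b <- coldflux:::split_bounds(m, layout)
  expect_true(all(b$lb >= 0))
  # net -3 on RX is representable as forward 0 / backward 3
  bwd <- which(layout$rxn == "RX" & layout$dir < 0)
  expect_gte(b$ub[bwd], 3)
})

test_that("opposite mandatory-direction candidates cap the MCS at one", {
  # chain forces flux through R1 equally in both conditions; demanding both
  # a 2x increase and a 2x decrease on R1 is jointly unsatisfiable
  mets <- data.frame(id = c("a_e", "a_c", "b_c"), name = c("A", "A", "B"),
                     compartment = c("e", "c", "c"))
  m <- metabolic_model(mets, list(
    reaction("EX_a", c(a_e = -1), -10, 1000),
    reaction("TA", c(a_e = -1, a_c = 1), 0, 1000, gpr = "gt"),
    reaction("R1", c(a_c = -1, b_c = 1), 0, 1000, gpr = "g1"),
    reaction("BM", c(b_c = -1), 0, 1000, pathway = "biomass")),
    genes = c("gt", "g1"), objective_id = "BM")
  reg <- list(up_genes = c(gt = 2.5), down_genes = c(g1 = 2.5),
              up_metabolites = c(), down_metabolites = c())
  # the biomass floor forces TA = R1 = BM >= 0.5 in both conditions, so
  # each candidate is satisfiable alone but b >= 2.5a and a >= 2.5b is not
  cm <- build_contrast_model(m, reg, c(EX_a = 5), c(EX_a = 5),
                             biomass_floor_frac = 0.1)
  expect_equal(cm$tmcs, 2L)
  res <- maximize_consistency(cm)
  expect_equal(res$mcs, 1L)
  expect_equal(res$mcs, mcs_brute(cm))
  expect_length(res$active_ids, 1L)

  # no candidates: MCS = TMCS = 0 and fluxes reach the FBA optimum
  reg0 <- list(up_genes = c(), down_genes = c(),
               up_metabolites = c(), down_metabolites = c())
  cm0 <- build_contrast_model(m, reg0, c(EX_a = 5), c(EX_a = 5))
  res0 <- maximize_consistency(cm0)
  expect_equal(res0$mcs, 0L)
  expect_equal(res0$tmcs, 0L)
  expect_equal(res0$flux_A$objective_value, 5, tolerance = 1e-6)
  expect_equal(res0$flux_B$objective_value, 5, tolerance = 1e-6)
})

test_that("MCS is monotone non-increasing in the fold-change cutoff", {
  truth <- shared_truth()
  set.seed(31)
  reg_full <- planted_regulation(truth, n_up = 5, n_down = 3, n_met = 2,
                                 expr_sd = 0.4)
  prev <- Inf
  for (cutoff in c(2, 4, 8)) {
    filt <- function(v) v[v >= cutoff]
    reg <- list(up_genes = filt(reg_full$up_genes),
                down_genes = filt(reg_full$down_genes),
                up_metabolites = filt(reg_full$up_metabolites),
                down_metabolites = filt(reg_full$down_metabolites))
    cm <- build_contrast_model(truth$model, reg,
                               truth$uptakes[["0C"]], truth$uptakes[["15C"]],
                               fc_cutoff = cutoff)
    res <- maximize_consistency(cm)
    expect_lte(res$mcs, prev)
    prev <- res$mcs
  }
})

test_that("returned fluxes satisfy every active constraint exactly", {
  truth <- shared_truth()
  reg <- planted_regulation(truth, n_up = 4, n_down = 2, n_met = 2)
  cm <- build_contrast_model(truth$model, reg,
                             truth$uptakes[["0C"]], truth$uptakes[["15C"]])
  # the solver re-checks all active constraints on the split components
  # and warns on any violation
  expect_no_warning(res <- maximize_consistency(cm))
  for (k in seq_len(nrow(cm$candidates))) {
    if (!cm$candidates$id[k] %in% res$active_ids) next
    tgt <- cm$candidates$target[k]
    if (cm$candidates$kind[k] == "reaction" &&
        cm$model$reactions[[tgt]]$lower_bound < 0) next   # net understates components
    fl <- function(fd) {
      if (cm$candidates$kind[k] == "reaction") abs(fd$fluxes[[tgt]])
      else flux_splits(cm$model, fd, tgt)$total_production
    }
    fA <- fl(res$flux_A)
    fB <- fl(res$flux_B)
    if (cm$candidates$direction[k] == "up") {
      expect_gte(fB, cm$candidates$rho_hat[k] * fA - 1e-6)
      expect_gte(fA, cm$epsilon - 1e-6)
    } else {
      expect_gte(fA, cm$candidates$rho_hat[k] * fB - 1e-6)
      expect_gte(fB, cm$epsilon - 1e-6)
    }
  }
})

test_that("consistency ratio is MCS over TMCS", {
  expect_equal(consistency_ratio(list(mcs = 7, tmcs = 10)), 0.7)
  expect_equal(consistency_ratio(list(mcs = 5, tmcs = 5)), 1)
  expect_warning(r <- consistency_ratio(list(mcs = 0, tmcs = 0)), "undefined")
  expect_true(is.na(r))
})
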