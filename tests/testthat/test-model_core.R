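test_that("model JSON round-trips losslessly and validates on read", {
  model <- make_toy_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$metabolites, model$metabolites)
  expect_equal(names(back$reactions), names(model$reactions))
  expect_equal(back$objective_id, model$objective_id)
  expect_equal(back$genes, model$genes)
  for (rid in names(model$reactions)) {
    expect_equal(back$reactions[[rid]]$stoich, model$reactions[[rid]]$stoich)
    expect_equal(back$reactions[[rid]]$lower_bound, model$reactions[[rid]]$lower_bound)
    expect_equal(back$reactions[[rid]]$gpr, model$reactions[[rid]]$gpr)
    expect_equal(back$reactions[[rid]]$pathway, model$reactions[[rid]]$pathway)
  }
  # idempotence: a second round trip writes the identical file
  path2 <- withr::local_tempfile(fileext = ".json")
  write_model(back, path2)
  expect_identical(readLines(path), readLines(path2))
  # composite GPR strings survive verbatim
  expect_equal(back$reactions[["AKGDH"]]$gpr, "g11 or g12")
  expect_equal(back$reactions[["PDH"]]$gpr, "g07 and g08")
})

test_that("model validation names the offending record", {
  mets <- data.frame(id = "a_c", name = "A", compartment = "c")
  expect_error(
    metabolic_model(mets, list(reaction("R1", c(X = -1), 0, 1)), objective_id = "R1"),
    "unknown metabolite 'X'")
  expect_error(
    metabolic_model(mets, list(reaction("R1", c(a_c = -1), 0, 1)),
                    objective_id = "nope"),
    "'nope' not present")
  expect_error(reaction("R1", c(a_c = -1), 2, 1), "lower_bound exceeds")
  expect_error(
    metabolic_model(mets, list(), objective_id = "R1"), "no reactions")
  # missing objective in a file is a validation error
  j <- list(metabolites = list(list(id = "a_c", compartment = "c")),
            reactions = list(list(id = "R1", metabolites = list(a_c = -1),
                                  lower_bound = 0, upper_bound = 1)),
            genes = list())
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(j, path, auto_unbox = TRUE)
  expect_error(read_model(path), "no objective")
})

test_that("condition bounds follow the uptake-negative convention", {
  model <- make_toy_model()
  m <- apply_condition_bounds(model, c(EX_glu_e = 0.10, EX_glcn_e = 0.08))
  expect_equal(m$reactions[["EX_glu_e"]]$lower_bound, -0.10)
  expect_equal(m$reactions[["EX_glcn_e"]]$lower_bound, -0.08)
  # free exchanges (O2, CO2, ammonium) stay open for uptake
  expect_lt(m$reactions[["EX_o2_e"]]$lower_bound, 0)
  expect_lt(m$reactions[["EX_nh4_e"]]$lower_bound, 0)
  # unlisted carbon sinks are closed for uptake but not secretion
  m2 <- apply_condition_bounds(model, c(EX_glu_e = 1))
  expect_equal(m2$reactions[["EX_glcn_e"]]$lower_bound, 0)
  # zero magnitude closes uptake
  m3 <- apply_condition_bounds(model, c(EX_glu_e = 0))
  expect_equal(m3$reactions[["EX_glu_e"]]$lower_bound, 0)
  expect_error(apply_condition_bounds(model, c(EX_glu_e = -1)), ">= 0")
  expect_error(apply_condition_bounds(model, c(PYK = 1)), "not an exchange")
})

test_that("FBA solves chain and branched toy networks to the known optimum", {
  expect_equal(fba(chain_model(10))$objective_value, 10, tolerance = 1e-9)
  sol <- fba(branched_model(10))
  expect_equal(sol$objective_value, 20, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["R1"]), 10, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["R2"]), 0, tolerance = 1e-9)
  # no carbon, no growth
  closed <- apply_condition_bounds(make_toy_model(),
                                   c(EX_glu_e = 0, EX_glcn_e = 0))
  expect_equal(fba(closed)$objective_value, 0, tolerance = 1e-6)
})

test_that("FBA optimum equals brute-force vertex enumeration", {
  for (m in list(chain_model(7), branched_model(4), reversible_model(5))) {
    expect_equal(fba(m)$objective_value, fba_brute(m), tolerance = 1e-6)
  }
})

test_that("biomass optimum scales linearly with uptake bounds", {
  model <- make_toy_model()
  base <- fba(apply_condition_bounds(model, c(EX_glu_e = 0.2, EX_glcn_e = 0.1)))
  for (k in c(0.5, 2, 3.5)) {
    scaled <- fba(apply_condition_bounds(model,
                                         c(EX_glu_e = 0.2 * k, EX_glcn_e = 0.1 * k)))
    expect_equal(scaled$objective_value, k * base$objective_value,
                 tolerance = 1e-6)
  }
})

test_that("flux splits decompose production and consumption correctly", {
  # B made by R1 (flux 6) and R2 (flux 4), drained by BM (10)
  mets <- data.frame(id = c("a_e", "a_c", "b_c"), name = c("A", "A", "B"),
                     compartment = c("e", "c", "c"))
  m <- metabolic_model(mets, list(
    reaction("EX_a", c(a_e = -1), -10, 1000),
    reaction("TA", c(a_e = -1, a_c = 1), 0, 1000),
    reaction("R1", c(a_c = -1, b_c = 1), 0, 6),
    reaction("R2", c(a_c = -1, b_c = 1), 0, 1000),
    reaction("BM", c(b_c = -1), 0, 1000, pathway = "biomass")),
    objective_id = "BM")
  v <- c(EX_a = -10, TA = 10, R1 = 6, R2 = 4, BM = 10)
  fs <- flux_splits(m, v, "b_c")
  expect_equal(fs$production_fractions[["R1"]], 0.6)
  expect_equal(fs$production_fractions[["R2"]], 0.4)
  expect_equal(fs$consumption_fractions[["BM"]], 1)
  expect_equal(fs$total_production, 10)

  # reversible reaction with negative flux appears as producer via the sign rule
  mr <- reversible_model(5)
  sol <- fba(mr)
  expect_lt(sol$fluxes[["RX"]], 0)           # runs a_c -> b_c, i.e. backwards
  fsr <- flux_splits(mr, sol, "b_c")
  expect_equal(fsr$production_fractions[["RX"]], 1)

  # zero-turnover metabolite: empty maps, not an error
  closed <- apply_condition_bounds(make_toy_model(),
                                   c(EX_glu_e = 0, EX_glcn_e = 0))
  fs0 <- flux_splits(closed, fba(closed), "pep_c")
  expect_equal(fs0$total_production, 0)
  expect_length(fs0$production_fractions, 0)
  expect_error(flux_splits(mr, sol, "nope"), "unknown metabolite")
})

test_that("flux-split fractions sum to one at every active metabolite", {
  model <- make_toy_model()
  sol <- fba(apply_condition_bounds(model, c(EX_glu_e = 0.10, EX_glcn_e = 0.08)))
  for (mid in model$metabolites$id) {
    fs <- flux_splits(model, sol, mid)
    if (fs$total_production > 1e-9) {
      expect_equal(sum(fs$production_fractions), 1, tolerance = 1e-9)
      expect_equal(sum(fs$consumption_fractions), 1, tolerance = 1e-9)
    }
  }
})
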