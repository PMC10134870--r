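# Tiny fixture networks and independent brute-force oracles.

# Linear chain: uptake of A (<= `uptake`) -> transport -> A->B -> biomass.
chain_model <- function(uptake = 10) {
  mets <- data.frame(id = c("a_e", "a_c", "b_c"),
                     name = c("A", "A", "B"),
                     compartment = c("e", "c", "c"))
  rxns <- list(
    reaction("EX_a", c(a_e = -1), -uptake, 1000),
    reaction("TA", c(a_e = -1, a_c = 1), 0, 1000),
    reaction("R1", c(a_c = -1, b_c = 1), 0, 1000),
    reaction("BM", c(b_c = -1), 0, 1000, pathway = "biomass"))
  metabolic_model(mets, rxns, character(0), "BM", id = "chain")
}

# Branched network: A feeds two routes of different yield (R1: A -> 2B,
# R2: A -> B); the optimum sends everything through R1.
branched_model <- function(uptake = 10) {
  mets <- data.frame(id = c("a_e", "a_c", "b_c"),
                     name = c("A", "A", "B"),
                     compartment = c("e", "c", "c"))
  rxns <- list(
    reaction("EX_a", c(a_e = -1), -uptake, 1000),
    reaction("TA", c(a_e = -1, a_c = 1), 0, 1000),
    reaction("R1", c(a_c = -1, b_c = 2), 0, 1000),
    reaction("R2", c(a_c = -1, b_c = 1), 0, 1000),
    reaction("BM", c(b_c = -1), 0, 1000, pathway = "biomass"))
  metabolic_model(mets, rxns, character(0), "BM", id = "branched")
}

# Network with a reversible interconversion, for split/sign conventions.
reversible_model <- function(uptake = 5) {
  mets <- data.frame(id = c("a_e", "a_c", "b_c"),
                     name = c("A", "A", "B"),
                     compartment = c("e", "c", "c"))
  rxns <- list(
    reaction("EX_a", c(a_e = -1), -uptake, 1000),
    reaction("TA", c(a_e = -1, a_c = 1), 0, 1000),
    reaction("RX", c(b_c = -1, a_c = 1), -1000, 1000),  # runs backwards A -> B
    reaction("BM", c(b_c = -1), 0, 1000, pathway = "biomass"))
  metabolic_model(mets, rxns, character(0), "BM", id = "reversible")
}

# Brute-force FBA by vertex enumeration: at a vertex of the flux polytope,
# n - rank(S) fluxes sit at a bound; enumerate all such bases and keep the
# best feasible objective. Independent of the simplex implementation.
fba_brute <- function(model, objective_id = NULL) {
  if (is.null(objective_id)) objective_id <- model$objective_id
  S <- stoich_matrix(model)
  n <- ncol(S)
  lb <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  obj <- as.numeric(colnames(S) == objective_id)
  nf <- n - qr(S)$rank
  best <- -Inf
  subsets <- if (nf == 0) list(integer(0)) else utils::combn(n, nf, simplify = FALSE)
  for (cols in subsets) {
    free <- setdiff(seq_len(n), cols)
    Sf <- S[, free, drop = FALSE]
    if (length(free) && qr(Sf)$rank < length(free)) next
    grid <- if (length(cols)) {
      as.matrix(expand.grid(rep(list(1:2), length(cols))))
    } else matrix(0, 1, 0)
    for (g in seq_len(nrow(grid))) {
      vfix <- ifelse(grid[g, ] == 1, lb[cols], ub[cols])
      if (any(!is.finite(vfix))) next
      rhs <- if (length(cols)) -S[, cols, drop = FALSE] %*% vfix else matrix(0, nrow(S), 1)
      v <- tryCatch(qr.coef(qr(Sf), rhs), error = function(e) NULL)
      if (is.null(v) || anyNA(v)) next
      if (max(abs(Sf %*% v - rhs)) > 1e-8) next
      full <- numeric(n)
      full[cols] <- vfix
      full[free] <- v
      if (any(full < lb - 1e-8 | full > ub + 1e-8)) next
      best <- max(best, sum(obj * full))
    }
  }
  best
}

# Brute-force MCS: enumerate every subset of candidate constraints and keep
# the largest whose hard rows leave the paired model feasible.
mcs_brute <- function(cm) {
  K <- cm$tmcs
  best <- 0L
  for (mask in seq_len(2^K) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(K) - 1L)) > 0)
    if (length(idx) <= best) next
    A <- do.call(rbind, c(list(cm$A_le), lapply(cm$cand_rows[idx], `[[`, "A")))
    b <- c(cm$b_le, unlist(lapply(cm$cand_rows[idx], `[[`, "b")))
    st <- coldflux:::solve_lp(numeric(length(cm$lb)), cm$A_eq, cm$b_eq,
                              A, b, cm$lb, cm$ub)$status
    if (st == "optimal") best <- length(idx)
  }
  best
}

# Two-sided Fisher p by direct hypergeometric enumeration.
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# Shared synthetic truth (seed 1), built once per test run.
shared_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_synthetic_truth(1)
    cache
  }
})

# Regulation derived noise-free from the planted flux pair: reaction-level
# gene fold changes plus metabolite production-ratio fold changes. Up and
# down candidates are selected per direction (strongest ratios first).
planted_regulation <- function(truth, n_up = 8, n_down = 5, n_met = 2,
                               expr_sd = 0) {
  reg <- truth$regulated_truth   # linear B/A ratios: up >= 2, down <= 1/2
  up <- reg$up[order(-reg$up, names(reg$up))]
  dn <- reg$down[order(reg$down, names(reg$down))]
  ratios <- c(up[seq_len(min(n_up, length(up)))],
              dn[seq_len(min(n_down, length(dn)))])
  if (expr_sd > 0) {
    ratios <- 2^(log2(ratios) + stats::rnorm(length(ratios), 0, expr_sd))
  }
  # one representative gene per reaction (GPRs are mostly single-gene)
  gene_fc <- c()
  for (rid in names(ratios)) {
    gg <- gpr_genes(truth$model$reactions[[rid]]$gpr)
    if (length(gg)) gene_fc[gg] <- ratios[[rid]]
  }
  up_g <- gene_fc[gene_fc >= 2]
  dn_g <- 1 / gene_fc[gene_fc <= 0.5]
  # metabolite candidates from planted production ratios
  prod_ratio <- function(m) {
    pA <- flux_splits(truth$model, truth$flux_A, m)$total_production
    pB <- flux_splits(truth$model, truth$flux_B, m)$total_production
    if (pA < 1e-9 || pB < 1e-9) return(NA_real_)
    pB / pA
  }
  pr <- vapply(c("glcn_c", "p6g_c", "mal_c", "akg_c"), prod_ratio, numeric(1))
  pr <- pr[!is.na(pr)]
  up_m <- pr[pr >= 2]
  dn_m <- 1 / pr[pr <= 0.5]
  up_m <- up_m[seq_len(min(n_met, length(up_m)))]
  dn_m <- dn_m[seq_len(min(n_met, length(dn_m)))]
  list(up_genes = up_g, down_genes = dn_g,
       up_metabolites = up_m, down_metabolites = dn_m)
}
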