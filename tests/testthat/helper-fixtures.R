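# Shared fixtures. Heavy simulations are computed once per test run and
# cached; every fixture is generated in code (no stored data).

.fx <- new.env(parent = emptyenv())

fx_cached <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

# single 400 mg oral solution, 48 h, all observables
fx_single_400 <- function() fx_cached("single400", {
  prot <- study_protocol(
    dose_event("carbamazepine", 400, 0, "solution"),
    sampling_times_h = c(0.25, 0.5, 1, 2, 4, 6, 8, 12, 24, 36, 48),
    analytes = rbind(
      data.frame(drug = "carbamazepine",
                 matrix = c("plasma", "saliva", "urine_fe")),
      data.frame(drug = "carbamazepine-10,11-epoxide", matrix = "plasma")))
  simulate_study(prot)
})

# 400 mg tid, 14 days (acceptance mass-balance / autoinduction fixture)
fx_tid14 <- function() fx_cached("tid14", {
  prot <- study_protocol(
    dosing_regimen("carbamazepine", 400, n_doses = 42, interval_h = 8,
                   formulation = "solution"),
    sampling_times_h = seq(0, 14 * 24, by = 4),
    analytes = data.frame(drug = "carbamazepine", matrix = "plasma"))
  simulate_study(prot)
})

# 400 mg bid, 14 days (superposition-failure fixture)
fx_bid14 <- function() fx_cached("bid14", {
  prot <- study_protocol(
    dosing_regimen("carbamazepine", 400, n_doses = 28, interval_h = 12,
                   formulation = "solution"),
    sampling_times_h = seq(0, 14 * 24, by = 1),
    analytes = data.frame(drug = "carbamazepine", matrix = "plasma"))
  simulate_study(prot)
})

# single 400 mg followed two weeks, for AUC(0-inf)
fx_single_long <- function() fx_cached("single_long", {
  prot <- study_protocol(
    dose_event("carbamazepine", 400, 0, "solution"),
    sampling_times_h = seq(0, 336, by = 2),
    analytes = data.frame(drug = "carbamazepine", matrix = "plasma"))
  simulate_study(prot)
})

auc_inf_single <- function() fx_cached("aucinf", {
  s <- analyte_series(fx_single_long(), "carbamazepine")
  tail_pts <- s[s$time_h >= 200, ]
  kz <- -stats::coef(stats::lm(log(value) ~ time_h, tail_pts))[[2]]
  auc_last(s$time_h, s$value) + s$value[nrow(s)] / kz
})

# strong synthetic interaction models for direction tests (not literature)
fx_strong_inhibitor <- function(mode = c("mbi", "competitive")) {
  mode <- match.arg(mode)
  drug_parameters(
    name = "inhibitor_synthetic", molecular_weight = 500,
    lipophilicity = 2, solubility = 5000, fraction_unbound = 0.5,
    intestinal_permeability = 1e-3,
    processes = list(process_hepatic_cl(0.002)),
    interactions = if (mode == "mbi")
      list(action_mbi("CYP3A4", K_I = 5, k_inact = 0.02)) else
      list(action_competitive_inhibition("CYP3A4", K_i = 0.5)))
}

fx_victim_protocol <- function(drug = "carbamazepine", amount = 200,
                               t_end = 24) {
  study_protocol(
    dose_event(drug, amount, 0, "solution"),
    sampling_times_h = c(seq(0.5, min(12, t_end), by = 0.5),
                         if (t_end > 12) seq(14, t_end, by = 2)),
    analytes = data.frame(drug = drug, matrix = "plasma"))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}

# closed-form matrix exponential of a diagonalizable 2x2 (test oracle)
expm_2x2 <- function(A) {
  ev <- eigen(A)
  Re(ev$vectors %*% diag(exp(ev$values)) %*% solve(ev$vectors))
}
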