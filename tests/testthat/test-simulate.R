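# Study simulation, observables and non-compartmental metrics.

test_that("metabolite peaks later than the parent after a single dose", {
  sim <- fx_single_400()
  s_p <- analyte_series(sim, "carbamazepine")
  s_m <- analyte_series(sim, "carbamazepine-10,11-epoxide")
  expect_gt(s_m$time_h[which.max(s_m$value)],
            s_p$time_h[which.max(s_p$value)])
  expect_true(all(s_p$value >= 0))
  expect_true(all(s_m$value >= 0))
})

test_that("autoinduction: liver CYP3A4 exceeds baseline at day 14", {
  sim <- fx_tid14()
  cyp <- sim$enzymes[["CYP3A4@liver"]]
  expect_gt(tail(cyp, 1), 1.5)
  # induced enzymes rise monotonically toward steady state early on
  expect_gt(cyp[which.min(abs(sim$enzymes$time_h - 96))],
            cyp[which.min(abs(sim$enzymes$time_h - 24))])
  # EPHX1 is induced as well
  expect_gt(tail(sim$enzymes[["EPHX1@liver"]], 1), 1.2)
})

test_that("superposition failure: steady-state interval AUC falls below the
           single-dose AUC(0-inf) benchmark", {
  s <- analyte_series(fx_bid14(), "carbamazepine")
  d14 <- s[s$time_h >= 312 & s$time_h <= 324, ]
  auc14 <- auc_last(d14$time_h, d14$value)
  expect_lt(auc14, auc_inf_single())
})

test_that("saliva observable is fu times plasma at every point", {
  sim <- fx_single_400()
  pl <- analyte_series(sim, "carbamazepine", "plasma")
  sa <- analyte_series(sim, "carbamazepine", "saliva")
  expect_equal(sa$value, 0.25 * pl$value, tolerance = 1e-12)
  expect_equal(saliva_profile(c(0, 4, 8), 1), c(0, 4, 8))
  expect_equal(saliva_profile(numeric(3), 0.25), numeric(3))
  expect_error(saliva_profile(1, 0), "fu")
})

test_that("urinary excretion: nondecreasing, bounded, zero without GFR", {
  sim <- fx_single_400()
  fe <- fraction_excreted_urine(sim, "carbamazepine")
  expect_true(all(diff(fe$fe) >= -1e-12))
  expect_lt(tail(fe$fe, 1), 1)
  expect_gt(tail(fe$fe, 1), 0)
  # matches the urine_fe analyte series
  fe2 <- analyte_series(sim, "carbamazepine", "urine_fe")
  expect_equal(fe2$value, fe$fe, tolerance = 1e-12)
  # gfr_fraction = 0 gives identically zero fe
  cbz0 <- carbamazepine_model()
  cbz0$processes <- lapply(cbz0$processes, function(p) {
    if (p$kind == "gfr") p$gfr_fraction <- 0
    p
  })
  prot <- study_protocol(
    dose_event("carbamazepine", 100, 0, "solution"),
    sampling_times_h = c(6, 24),
    analytes = data.frame(drug = "carbamazepine", matrix = "plasma"))
  sim0 <- simulate_study(prot, drugs = list(cbz0,
                                            carbamazepine_epoxide_model()))
  fe0 <- fraction_excreted_urine(sim0, "carbamazepine")
  expect_true(all(fe0$fe == 0))
  expect_error(fraction_excreted_urine(sim0, "carbamazepine-10,11-epoxide"),
               "no dose")
})

test_that("fe is dose-invariant in the linear range", {
  # single first-order pathway far below Km: doubling the dose must leave
  # the fraction excreted unchanged
  cbz_lin <- carbamazepine_model()
  cbz_lin$processes <- list(
    process_mm("CYP3A4", K_m = 1e6, k_cat = 100, label = "linear"),
    process_gfr(0.03))
  cbz_lin$interactions <- list()
  run <- function(mg) {
    prot <- study_protocol(
      dose_event("carbamazepine", mg, 0, "solution"),
      sampling_times_h = c(12, 48, 96),
      analytes = data.frame(drug = "carbamazepine", matrix = "plasma"))
    fraction_excreted_urine(simulate_study(prot, drugs = list(cbz_lin)),
                            "carbamazepine")$fe
  }
  expect_equal(run(100), run(200), tolerance = 1e-5)
})

test_that("oral tablet: later tmax and fed state slows gastric emptying", {
  run <- function(formulation, food = NA_character_) {
    prot <- study_protocol(
      dose_event("carbamazepine", 400, 0, formulation, food_state = food),
      sampling_times_h = seq(0.25, 24, by = 0.25),
      analytes = data.frame(drug = "carbamazepine", matrix = "plasma"))
    analyte_series(simulate_study(prot), "carbamazepine")
  }
  sol <- run("solution")
  ir <- run("tablet_ir")
  xr <- run("tablet_xr")
  tmax <- function(s) s$time_h[which.max(s$value)]
  expect_lt(tmax(sol), tmax(ir))
  expect_lt(tmax(ir), tmax(xr))
})

test_that("NCA primitives: trapezoid, Cmax, ratios", {
  expect_equal(auc_last(c(0, 1), c(1, 1)), 1)
  expect_equal(auc_last(c(0, 1, 2), c(0, 2, 0)), 2)
  tt <- sort(runif(20, 0, 10)); cc <- runif(20)
  expect_equal(auc_last(tt, 3 * cc), 3 * auc_last(tt, cc))
  expect_error(auc_last(1, 1), "2 matched")
  expect_error(auc_last(c(1, 0), c(1, 1)), "nondecreasing")
  expect_equal(cmax(c(1, 3, 2)), 3)
  expect_equal(cmax(rep(4, 5)), 4)
  expect_equal(cmax(5 * c(1, 3, 2)), 5 * cmax(c(1, 3, 2)))
  expect_error(cmax(numeric(0)), "empty")
  expect_equal(ddi_auc_ratio(2, 4), 0.5)
  expect_equal(ddi_auc_ratio(3, 3), 1)
  expect_equal(ddi_auc_ratio(7 * 2, 7 * 4), ddi_auc_ratio(2, 4))
  expect_error(ddi_auc_ratio(1, 0), "auc_without")
  expect_equal(ddi_cmax_ratio(1.5, 3), 0.5)
  expect_error(ddi_cmax_ratio(1, 0), "cmax_without")
})

test_that("simulation output carries both concentration units", {
  sim <- fx_single_400()
  ob <- sim$observations
  pl <- ob[ob$analyte == "carbamazepine" & ob$matrix == "plasma", ]
  expect_equal(pl$concentration_mg_per_L,
               pl$concentration_umol_per_L * 236.27 / 1000,
               tolerance = 1e-12)
})

test_that("protocol validation", {
  expect_error(dose_event("carbamazepine", -1), "amount")
  ev <- dose_event("carbamazepine", 100)
  expect_error(study_protocol(ev, numeric(0)), "sampling")
  expect_error(study_protocol(ev, c(-1, 2)), "sampling")
  expect_error(study_protocol(ev, 1, analytes = data.frame(
    drug = "carbamazepine", matrix = "csf")), "matrix")
  reg <- dosing_regimen("carbamazepine", 200, n_doses = 5, interval_h = 8)
  expect_equal(nrow(reg), 5L)
  expect_equal(reg$time_h, seq(0, 32, by = 8))
})

test_that("protocol JSON round trip", {
  prot <- study_protocol(
    rbind(dose_event("carbamazepine", 400, 0, "tablet_ir", "fed"),
          dose_event("carbamazepine", 400, 12, "tablet_ir", "fed")),
    sampling_times_h = c(1, 2, 4),
    analytes = data.frame(drug = "carbamazepine", matrix = "plasma"))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    events = lapply(seq_len(nrow(prot$events)), function(i)
      as.list(prot$events[i, ])),
    sampling_times_h = prot$sampling_times_h,
    analytes = lapply(seq_len(nrow(prot$analytes)), function(i)
      as.list(prot$analytes[i, ]))), path, auto_unbox = TRUE)
  back <- load_protocol_config(path)
  expect_equal(back$events$amount, prot$events$amount)
  expect_equal(back$events$food_state, prot$events$food_state)
  expect_equal(back$sampling_times_h, prot$sampling_times_h)
  unlink(path)
})

test_that("profile CSV export carries the documented schema", {
  path <- tempfile(fileext = ".csv")
  write_profiles_csv(fx_single_400(), path)
  back <- utils::read.csv(path)
  expect_equal(names(back),
               c("time_h", "analyte", "matrix",
                 "concentration_umol_per_L", "concentration_mg_per_L"))
  expect_gt(nrow(back), 100)
  unlink(path)
})
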