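# Parameter estimation. Fitting problems here use the cheap
# epoxide-only configuration so the suite stays fast; the expensive
# parent-model recoveries (k_cat, E_max) live in test-acceptance.R.

fx_fit_dataset <- function(seed = 1, sigma = 0,
                           samp = c(1, 2, 4, 8, 12, 24)) {
  prot <- study_protocol(
    dose_event("carbamazepine-10,11-epoxide", 100, 0, "solution"),
    sampling_times_h = samp,
    analytes = data.frame(drug = "carbamazepine-10,11-epoxide",
                          matrix = "plasma"))
  ds <- generate_observed_dataset(prot, list(carbamazepine_epoxide_model()),
                                  noise_model(sigma, seed = seed))
  list(protocol = prot,
       observed = ds$observed[, c("analyte", "matrix", "time_h", "value")])
}

test_that("objective: zero at truth, closed-form shift, empty data error", {
  ds <- fx_fit_dataset()
  par <- fit_param("carbamazepine-10,11-epoxide",
                   list("processes", 1, "CL_spec"), 1e-4, 1, name = "cl")
  spec <- fit_spec(list(par), list(ds),
                   drugs = list(carbamazepine_epoxide_model()),
                   n_starts = 1, rtol = 1e-6)
  expect_lt(fit_objective(0.01, spec), 1e-6)
  # scaling all observations by 10 adds n * 1^2 to the loss at the truth
  ds10 <- ds; ds10$observed$value <- 10 * ds10$observed$value
  spec10 <- fit_spec(list(par), list(ds10),
                     drugs = list(carbamazepine_epoxide_model()),
                     n_starts = 1, rtol = 1e-6)
  n <- nrow(ds$observed)
  expect_equal(fit_objective(0.01, spec10), n, tolerance = 1e-3)
  # out-of-model parameter values hit the penalty path, not an abort
  expect_equal(fit_objective(-5, spec), 1e6)
  ds_empty <- ds; ds_empty$observed <- ds$observed[0, ]
  expect_error(fit_spec(list(par), list(ds_empty),
                        drugs = list(carbamazepine_epoxide_model())),
               "observed")
})

test_that("identifiability guard refuses joint E_max / EC_50 fits", {
  ds <- fx_fit_dataset()
  p1 <- fit_param("carbamazepine", list("interactions", 1, "E_max"), 1, 30)
  p2 <- fit_param("carbamazepine", list("interactions", 1, "EC_50"), 1, 100)
  expect_error(fit_spec(list(p1, p2), list(ds)), "identifiability")
})

test_that("starting at the truth converges immediately", {
  ds <- fx_fit_dataset()
  par <- fit_param("carbamazepine-10,11-epoxide",
                   list("processes", 1, "CL_spec"), 1e-3, 0.1, name = "cl")
  spec <- fit_spec(list(par), list(ds),
                   drugs = list(carbamazepine_epoxide_model()),
                   n_starts = 1, rtol = 1e-6)
  fit <- fit_parameters(spec, maxit = 2)
  expect_lt(fit$objective, 1e-4)
  expect_lte(fit$starts$iterations[1], 2L)
  expect_equal(unname(fit$estimates["cl"]), 0.01, tolerance = 0.01)
})

test_that("noise-free recovery: EPHX1 CL_spec and GFR fraction within 5%", {
  ds <- fx_fit_dataset(samp = c(1, 2, 4, 8, 12, 24, 36, 48))
  # start from a deliberately wrong model
  wrong <- carbamazepine_epoxide_model()
  wrong$processes[[1]]$CL_spec <- 0.03
  par <- fit_param("carbamazepine-10,11-epoxide",
                   list("processes", 1, "CL_spec"), 1e-3, 0.1,
                   name = "CL_spec(EPHX1)")
  spec <- fit_spec(list(par), list(ds), drugs = list(wrong),
                   n_starts = 1, rtol = 1e-6)
  fit <- fit_parameters(spec)
  expect_rel_equal(unname(fit$estimates[1]), 0.01, 0.05)

  # GFR fraction from the urinary-excretion observable
  prot_u <- study_protocol(
    dose_event("carbamazepine-10,11-epoxide", 100, 0, "solution"),
    sampling_times_h = c(4, 12, 24, 48),
    analytes = data.frame(drug = "carbamazepine-10,11-epoxide",
                          matrix = c("plasma", "urine_fe")))
  ds_u <- generate_observed_dataset(prot_u,
                                    list(carbamazepine_epoxide_model()),
                                    noise_model(0, seed = 1))
  wrong2 <- carbamazepine_epoxide_model()
  wrong2$processes[[2]]$gfr_fraction <- 0.5
  par2 <- fit_param("carbamazepine-10,11-epoxide",
                    list("processes", 2, "gfr_fraction"), 0.01, 1,
                    name = "GFR fraction")
  spec2 <- fit_spec(list(par2), list(list(
    protocol = prot_u,
    observed = ds_u$observed[, c("analyte", "matrix", "time_h",
                                 "value")])),
    drugs = list(wrong2), n_starts = 1, rtol = 1e-6)
  fit2 <- fit_parameters(spec2)
  expect_rel_equal(unname(fit2$estimates[1]), 0.21, 0.05)
})

test_that("seeded noisy recovery with replicate studies lands within 25%", {
  # 15% multiplicative noise ~ 0.0607 log10 units, three replicates
  reps <- lapply(1:3, function(s)
    fx_fit_dataset(seed = s, sigma = log10(1.15)))
  wrong <- carbamazepine_epoxide_model()
  wrong$processes[[1]]$CL_spec <- 0.025
  par <- fit_param("carbamazepine-10,11-epoxide",
                   list("processes", 1, "CL_spec"), 1e-3, 0.1,
                   name = "CL_spec(EPHX1)")
  spec <- fit_spec(list(par), reps, drugs = list(wrong), n_starts = 1,
                   seed = 17, rtol = 1e-5)
  fit <- fit_parameters(spec)
  expect_rel_equal(unname(fit$estimates[1]), 0.01, 0.25)
})

test_that("objective is invariant to dataset order; multistart is seeded", {
  d1 <- fx_fit_dataset(seed = 1, sigma = 0.1)
  d2 <- fx_fit_dataset(seed = 2, sigma = 0.1)
  par <- fit_param("carbamazepine-10,11-epoxide",
                   list("processes", 1, "CL_spec"), 1e-3, 0.1)
  s12 <- fit_spec(list(par), list(d1, d2),
                  drugs = list(carbamazepine_epoxide_model()),
                  n_starts = 1, rtol = 1e-6)
  s21 <- fit_spec(list(par), list(d2, d1),
                  drugs = list(carbamazepine_epoxide_model()),
                  n_starts = 1, rtol = 1e-6)
  expect_equal(fit_objective(0.012, s12), fit_objective(0.012, s21))
  # Monte-Carlo starts reproduce with the seed
  draw <- function() pbpkddi:::.with_seed(9, runif(5))
  expect_identical(draw(), draw())
})

test_that("best objective is no worse than any start's final objective", {
  ds <- fx_fit_dataset()
  par <- fit_param("carbamazepine-10,11-epoxide",
                   list("processes", 1, "CL_spec"), 1e-3, 0.1)
  spec <- fit_spec(list(par), list(ds),
                   drugs = list(carbamazepine_epoxide_model()),
                   n_starts = 3, seed = 23, rtol = 1e-5)
  fit <- fit_parameters(spec, maxit = 6)
  expect_true(all(fit$objective <= fit$starts$objective + 1e-12))
})

test_that("one-at-a-time sensitivity utility has the right signs", {
  prot <- study_protocol(
    dose_event("carbamazepine-10,11-epoxide", 100, 0, "solution"),
    sampling_times_h = c(2, 8, 24),
    analytes = data.frame(drug = "carbamazepine-10,11-epoxide",
                          matrix = "plasma"))
  sens <- sensitivity_analysis(
    prot,
    list(fit_param("carbamazepine-10,11-epoxide",
                   list("processes", 1, "CL_spec"), 1e-3, 0.5,
                   name = "CL_spec")),
    drugs = list(carbamazepine_epoxide_model()),
    analyte = "carbamazepine-10,11-epoxide", perturbation = 10)
  expect_lt(sens$sensitivity[1], 0)   # more clearance, less exposure
})
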