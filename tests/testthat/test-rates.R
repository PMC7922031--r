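test_that("Michaelis-Menten rate law: identities and validation", {
  # half saturation with the packaged CYP3A4 -> epoxide k_cat
  expect_equal(mm_rate(1, 0.75, 248, 248), 0.375)
  expect_equal(mm_rate(2, 0.5, 0, 100), 0)
  expect_equal(mm_rate(1, 1, 1000, 100), 10 / 11)
  expect_equal(mm_rate(3, 0.2, 50, 100), 3 * 0.2 * 50 / 150)
  expect_error(mm_rate(-1, 0.75, 10, 248), "E_amount")
  expect_error(mm_rate(1, 0.75, -10, 248), "S_conc")
})

test_that("specific clearance rate: linearity in enzyme and substrate", {
  expect_equal(specific_cl_rate(1, 0.01, 10), 0.1)
  expect_equal(specific_cl_rate(0, 0.01, 10), 0)
  expect_equal(specific_cl_rate(2, 0.01, 10),
               2 * specific_cl_rate(1, 0.01, 10))
  expect_error(specific_cl_rate(1, -0.01, 10), "CL_spec")
})

test_that("Emax induction factor: bounds, monotonicity, Table-1 values", {
  expect_equal(induction_factor(0, 20, 6), 1)
  expect_equal(induction_factor(20, 20, 6), 4)          # 1 + Emax/2
  expect_equal(induction_factor(1e12, 20, 17), 18, tolerance = 1e-9)
  cc <- seq(0, 200, by = 5)
  f <- induction_factor(cc, 20, 6)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 1 & f <= 7))
  expect_error(induction_factor(1, 0, 6), "EC_50")
})

test_that("enzyme turnover: steady states match the closed form", {
  expect_equal(enzyme_turnover_rhs(10, 10, 1e-3, 1, 0), 0)
  # dE/dt = 0  =>  E_ss = E0 * f_ind
  f <- 3.5; k <- 3.2e-4
  e_ss <- 10 * f
  expect_equal(enzyme_turnover_rhs(e_ss, 10, k, f, 0), 0, tolerance = 1e-15)
  # with inactivation r: E_ss = E0 * k/(k+r)  (solve linear ODE at dE/dt=0)
  r <- 2e-3
  expect_equal(enzyme_turnover_rhs(10 * k / (k + r), 10, k, 1, r), 0,
               tolerance = 1e-15)
  expect_error(enzyme_turnover_rhs(1, 1, 0), "k_deg")
})

test_that("clamped-inducer turnover converges to closed form within 0.5%", {
  # integrate dE/dt with constant f_ind for 10 degradation half-lives
  k <- log(2) / (36 * 60); f <- 3.2; E0 <- 7.78
  rhs <- function(t, y) enzyme_turnover_rhs(y, E0, k, f, 0)
  t10 <- 10 * 36 * 60
  tr <- ode_solve(rhs, E0, c(0, t10 / 2, t10), rtol = 1e-8, atol = 1e-12)
  target <- E0 * f
  expect_lt(abs(tr[3, 1] - target) / target, 0.005)
  # and against the analytic transient at the midpoint
  analytic <- target + (E0 - target) * exp(-k * t10 / 2)
  expect_rel_equal(tr[2, 1], analytic, 1e-6)
})

test_that("mechanism-based inactivation and competitive Km shift", {
  expect_equal(mbi_inactivation_rate(0, 10, 0.05), 0)
  expect_equal(mbi_inactivation_rate(10, 10, 0.05), 0.025)
  expect_equal(mbi_inactivation_rate(1e9, 10, 0.05), 0.05, tolerance = 1e-7)
  expect_equal(competitive_km(100, 0, 5), 100)
  expect_equal(competitive_km(100, 5, 5), 200)
  expect_equal(competitive_km(100, 15, 5), 400)
  expect_error(competitive_km(100, 1, 0), "K_i")
})

test_that("GFR filtration rate is the product of its factors", {
  expect_equal(gfr_filtration_rate(40, 0.25, 0.12, 0.03), 0.036)
  expect_equal(gfr_filtration_rate(40, 0.25, 0.12, 0), 0)
  expect_equal(gfr_filtration_rate(10, 1, 0.12, 1), 1.2)
  expect_error(gfr_filtration_rate(10, 1, 0.12, 1.5), "gfr_fraction")
})

test_that("Weibull release: t50 convention and first-order limit", {
  wb <- formulation_weibull("f", t_50 = 60, shape = 1.3, lag = 10)
  expect_equal(weibull_release(10, wb), 0)
  expect_equal(weibull_release(0, wb), 0)
  expect_equal(weibull_release(70, wb), 0.5)
  tt <- seq(0, 600, by = 5)
  rel <- weibull_release(tt, wb)
  expect_true(all(diff(rel) >= 0))
  expect_lt(1 - weibull_release(6000, wb), 1e-6)
  # shape 1: exactly first order with rate ln 2 / t50 on a grid
  wb1 <- formulation_weibull("f1", t_50 = 120, shape = 1, lag = 0)
  expect_equal(weibull_release(tt, wb1), 1 - exp(-log(2) / 120 * tt),
               tolerance = 1e-12)
  expect_error(weibull_release(-1, wb), "t")
  expect_error(formulation_weibull("bad", t_50 = -5, shape = 1), "t_50")
})

test_that("Rodgers-Rowland Kp matches an independent transcription", {
  # straight-line oracle of the neutral-species composition equations
  kp_oracle <- function(fu, logp, f, adipose = FALSE) {
    P <- if (adipose) 10^(1.115 * logp - 1.35) else 10^logp
    fu * (f$f_ew + f$f_iw + P * f$f_nl + (0.3 * P + 0.7) * f$f_np)
  }
  ind <- create_individual()
  cbz <- carbamazepine_model()
  muscle <- as.list(ind$organs[ind$organs$name == "muscle", ])
  expect_equal(rodgers_rowland_kp(cbz, muscle),
               kp_oracle(0.25, 2.00, muscle), tolerance = 1e-12)
  adi <- as.list(ind$organs[ind$organs$name == "adipose", ])
  expect_equal(rodgers_rowland_kp(cbz, adi),
               kp_oracle(0.25, 2.00, adi, adipose = TRUE),
               tolerance = 1e-12)
  cbze <- carbamazepine_epoxide_model()
  liver <- as.list(ind$organs[ind$organs$name == "liver", ])
  expect_equal(rodgers_rowland_kp(cbze, liver),
               kp_oracle(0.518, 1.00, liver), tolerance = 1e-12)
})

test_that("Rodgers-Rowland limit cases", {
  # organ that is pure water, unit membrane affinity drug
  pure_water <- list(name = "x", f_ew = 0.2, f_iw = 0.8, f_nl = 0,
                     f_np = 0)
  expect_equal(rodgers_rowland_kp(list(lipophilicity = 0), pure_water,
                                  fu = 1), 1)
  # fu = 1, organ that is fractionally water: Kp equals the water fraction
  half_water <- list(name = "x", f_ew = 0.3, f_iw = 0.4, f_nl = 0,
                     f_np = 0)
  expect_equal(rodgers_rowland_kp(list(lipophilicity = -20), half_water,
                                  fu = 1), 0.7, tolerance = 1e-6)
  expect_error(rodgers_rowland_kp(list(lipophilicity = 1),
                                  list(name = "x", f_ew = 0.1), fu = 0.5),
               "composition")
  expect_error(rodgers_rowland_kp(carbamazepine_model(), pure_water,
                                  fu = 0), "fu")
})

test_that("kcat from microsomal Vmax and content", {
  expect_equal(kcat_from_vmax(0.79, 82.9), 0.79 / 82.9)
  expect_equal(kcat_from_vmax(5, 5), 1)
  expect_error(kcat_from_vmax(0.79, 0), "enzyme_content")
  expect_error(kcat_from_vmax(0, 82.9), "v_max")
})
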