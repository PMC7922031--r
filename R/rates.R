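# Elementary kinetic laws of the engine. All rates are in umol/min, amounts
# in umol, concentrations in umol/L (uM), time in min.

.check_nonneg <- function(...) {
  vals <- list(...)
  for (nm in names(vals))
    if (any(!is.finite(vals[[nm]])) || any(vals[[nm]] < 0))
      stop("validation error: '", nm, "' must be finite and >= 0",
           call. = FALSE)
  invisible(TRUE)
}

#' Michaelis-Menten metabolic rate
#'
#' v = E * k_cat * S / (K_m + S), the saturable enzymatic rate used for all
#' carbamazepine metabolic pathways.
#'
#' @param E_amount Enzyme amount, umol.
#' @param k_cat Catalytic rate constant, 1/min.
#' @param S_conc Unbound substrate concentration at the enzyme site, uM.
#' @param K_m Michaelis-Menten constant, uM.
#' @return Rate, umol/min.
#' @export
#' @examples
#' mm_rate(1, 0.75, 248, 248) # half saturation: E*k_cat/2
mm_rate <- function(E_amount, k_cat, S_conc, K_m) {
  .check_nonneg(E_amount = E_amount, k_cat = k_cat, S_conc = S_conc,
                K_m = K_m)
  E_amount * k_cat * S_conc / (K_m + S_conc)
}

#' First-order specific enzymatic clearance rate
#'
#' v = E_rel * CL_spec * S, the linear clearance law used for the EPHX1
#' metabolism of carbamazepine-10,11-epoxide. `E_rel` is the enzyme amount
#' relative to its baseline, so at baseline expression v = CL_spec * S and
#' induction scales the rate proportionally.
#'
#' @param E_rel Enzyme amount relative to baseline (1 at baseline).
#' @param CL_spec Specific clearance, 1/min.
#' @param S_amount Unbound substrate amount at the enzyme site, umol.
#' @return Rate, umol/min.
#' @export
specific_cl_rate <- function(E_rel, CL_spec, S_amount) {
  .check_nonneg(E_rel = E_rel, CL_spec = CL_spec, S_amount = S_amount)
  E_rel * CL_spec * S_amount
}

#' Emax induction multiplier on enzyme synthesis
#'
#' f = 1 + E_max * C_u / (EC_50 + C_u); ranges from 1 (no inducer) to
#' 1 + E_max (saturating inducer concentration), monotone in `C_u`.
#'
#' @param C_u Unbound inducer concentration at the enzyme site, uM.
#' @param EC_50 Half-maximal effective concentration, uM.
#' @param E_max Maximum fold-increase of the synthesis rate (dimensionless).
#' @return Synthesis multiplier in `[1, 1 + E_max]`.
#' @export
induction_factor <- function(C_u, EC_50, E_max) {
  .check_nonneg(C_u = C_u, EC_50 = EC_50, E_max = E_max)
  if (any(EC_50 <= 0))
    stop("validation error: 'EC_50' must be > 0", call. = FALSE)
  1 + E_max * C_u / (EC_50 + C_u)
}

#' Enzyme turnover with induction and inactivation
#'
#' dE/dt = k_deg * E_0 * f_ind - (k_deg + inact_rate) * E. At baseline
#' (f_ind = 1, no inactivation) the pool is at steady state E = E_0; under a
#' clamped induction multiplier it converges to E_0 * f_ind.
#'
#' @param E Current enzyme amount, umol.
#' @param E_0 Baseline enzyme amount, umol.
#' @param k_deg First-order degradation rate constant, 1/min.
#' @param f_ind Synthesis multiplier from [induction_factor()].
#' @param inact_rate Additional first-order inactivation from
#'   [mbi_inactivation_rate()], 1/min.
#' @return dE/dt, umol/min.
#' @export
enzyme_turnover_rhs <- function(E, E_0, k_deg, f_ind = 1, inact_rate = 0) {
  .check_nonneg(E = E, E_0 = E_0)
  if (any(k_deg <= 0))
    stop("validation error: 'k_deg' must be > 0", call. = FALSE)
  k_deg * E_0 * f_ind - (k_deg + inact_rate) * E
}

#' Mechanism-based inactivation rate
#'
#' r = k_inact * I_u / (K_I + I_u), the irreversible enzyme-inactivation
#' hazard added to natural degradation (e.g. CYP3A4 inactivation by
#' erythromycin).
#'
#' @param I_u Unbound inhibitor concentration at the enzyme site, uM.
#' @param K_I Inhibitor concentration at half-maximal inactivation, uM.
#' @param k_inact Maximum inactivation rate constant, 1/min.
#' @return Inactivation rate, 1/min.
#' @export
mbi_inactivation_rate <- function(I_u, K_I, k_inact) {
  .check_nonneg(I_u = I_u, K_I = K_I, k_inact = k_inact)
  k_inact * I_u / (K_I + I_u)
}

#' Apparent Km under competitive inhibition
#'
#' K_m,app = K_m * (1 + I_u / K_i).
#'
#' @param K_m Uninhibited Michaelis constant, uM.
#' @param I_u Unbound inhibitor concentration, uM.
#' @param K_i Competitive inhibition constant, uM.
#' @return Apparent K_m, uM.
#' @export
competitive_km <- function(K_m, I_u, K_i) {
  .check_nonneg(K_m = K_m, I_u = I_u, K_i = K_i)
  if (any(K_i <= 0))
    stop("validation error: 'K_i' must be > 0", call. = FALSE)
  K_m * (1 + I_u / K_i)
}

#' Renal filtration rate with a GFR fraction
#'
#' rate = gfr_fraction * GFR * fu * C_plasma. The GFR fraction < 1 lumps
#' passive tubular reabsorption into glomerular filtration of unbound drug.
#'
#' @param C_plasma Plasma concentration, uM.
#' @param fu Fraction unbound in plasma.
#' @param GFR Glomerular filtration rate, L/min.
#' @param gfr_fraction Net filtration fraction in `[0, 1]`.
#' @return Urinary excretion rate, umol/min.
#' @export
gfr_filtration_rate <- function(C_plasma, fu, GFR, gfr_fraction) {
  .check_nonneg(C_plasma = C_plasma, fu = fu, GFR = GFR,
                gfr_fraction = gfr_fraction)
  if (any(gfr_fraction > 1))
    stop("validation error: 'gfr_fraction' must be <= 1", call. = FALSE)
  gfr_fraction * GFR * fu * C_plasma
}

#' Cumulative Weibull release
#'
#' Fraction of a solid dose released by time `t`:
#' 0 for t <= lag, then 1 - exp(-ln(2) * ((t - lag)/t_50)^shape), so that
#' exactly half the dose is released at `lag + t_50`. With shape = 1 the
#' release is first order with rate ln(2)/t_50.
#'
#' @param t Time since administration, min (vectorized).
#' @param spec A `formulation` from [formulation_weibull()].
#' @return Cumulative released fraction in `[0, 1]`.
#' @export
weibull_release <- function(t, spec) {
  if (!inherits(spec, "formulation") || spec$kind != "weibull")
    stop("validation error: 'spec' must be a weibull formulation",
         call. = FALSE)
  if (any(!is.finite(t) | t < 0))
    stop("validation error: 't' must be finite and >= 0", call. = FALSE)
  te <- pmax(t - spec$lag, 0)
  1 - exp(-log(2) * (te / spec$t_50)^spec$shape)
}

# Release hazard (instantaneous release rate per remaining solid fraction) of
# a Weibull formulation at time t since dosing; exact first-order limit at
# shape = 1. Used by the lumen ODE.
.weibull_hazard <- function(t, spec) {
  te <- t - spec$lag
  if (te <= 0) return(0)
  log(2) * spec$shape * (te / spec$t_50)^(spec$shape - 1) / spec$t_50
}

#' Tissue:plasma partition coefficient (Rodgers-Rowland, neutral species)
#'
#' Implements the neutral-compound tissue-composition partition equations:
#' Kpu = f_EW + f_IW + P * f_NL + (0.3 P + 0.7) * f_NP with P = 10^logP,
#' and Kp = fu * Kpu. Both packaged compounds are neutral at physiological
#' pH (no pKa), so no ionization or acidic-phospholipid terms enter. For
#' adipose tissue the neutral-lipid affinity uses the vegetable-oil:water
#' coefficient via the standard correlation log(Dvo) = 1.115 logP - 1.35,
#' as octanol overestimates partitioning into storage fat.
#'
#' @param drug A `drug_parameters` object (uses `lipophilicity` and, when
#'   `fu` is missing, `fraction_unbound`).
#' @param organ One row of an individual's organ table (list or data.frame
#'   row with composition fractions `f_ew`, `f_iw`, `f_nl`, `f_np`).
#' @param fu Fraction unbound in plasma, in (0, 1].
#' @param hematocrit Unused by the neutral equations; accepted for interface
#'   stability.
#' @return Kp > 0 (tissue:plasma).
#' @export
rodgers_rowland_kp <- function(drug, organ, fu = drug$fraction_unbound,
                               hematocrit = 0.45) {
  if (!is.numeric(fu) || fu <= 0 || fu > 1)
    stop("validation error: 'fu' must be in (0, 1]", call. = FALSE)
  logp <- if (is.list(drug) || is.environment(drug)) drug$lipophilicity
          else drug
  if (!is.numeric(logp) || !is.finite(logp))
    stop("validation error: lipophilicity must be finite", call. = FALSE)
  need <- c("f_ew", "f_iw", "f_nl", "f_np")
  if (!all(need %in% names(organ)) ||
      any(vapply(need, function(k) is.null(organ[[k]]) || !is.finite(organ[[k]]),
                 logical(1))))
    stop("configuration error: organ composition fractions ",
         paste(need, collapse = ", "), " are required", call. = FALSE)
  P <- 10^logp
  if (identical(organ$name, "adipose")) P <- 10^(1.115 * logp - 1.35)
  kpu <- organ$f_ew + organ$f_iw + P * organ$f_nl +
    (0.3 * P + 0.7) * organ$f_np
  fu * kpu
}

#' Derive k_cat from microsomal Vmax and enzyme content
#'
#' k_cat = V_max / enzyme content, both referenced to mg microsomal protein;
#' used to translate in vitro microsomal assay results (e.g. the UGT2B7
#' pathway: 0.79 / 82.9 = 9.53e-3 1/min).
#'
#' @param v_max Maximum reaction velocity, pmol/min/mg microsomal protein.
#' @param enzyme_content Enzyme content, pmol/mg microsomal protein.
#' @return k_cat, 1/min.
#' @export
kcat_from_vmax <- function(v_max, enzyme_content) {
  if (!is.numeric(v_max) || v_max <= 0)
    stop("validation error: 'v_max' must be > 0", call. = FALSE)
  if (!is.numeric(enzyme_content) || enzyme_content <= 0)
    stop("validation error: 'enzyme_content' must be > 0", call. = FALSE)
  v_max / enzyme_content
}
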