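# Study simulation and observables.

#' Packaged parent-metabolite drug set
#'
#' The carbamazepine model together with its linked
#' carbamazepine-10,11-epoxide model.
#'
#' @return Named list of two `drug_parameters` objects.
#' @export
default_drug_set <- function() {
  drugs <- list(carbamazepine_model(), carbamazepine_epoxide_model())
  names(drugs) <- vapply(drugs, `[[`, character(1), "name")
  drugs
}

# dense output grid: sampling times plus >= `pts` points per dosing interval
.output_grid <- function(events_min, sampling_min, pts = 200) {
  t_end <- max(sampling_min)
  dt <- unique(sort(events_min))
  interval <- if (length(dt) > 1) min(diff(dt)) else t_end
  step <- max(interval / pts, t_end / 2e4, 1e-3)
  grid <- sort(unique(c(seq(0, t_end, by = step), sampling_min, dt[dt <= t_end])))
  grid[grid <= t_end]
}

#' Simulate a clinical study protocol
#'
#' Assembles the ODE system for the protocol's individual and drug set,
#' integrates it with dose-event restarts, and extracts the requested
#' observables (venous plasma, saliva, cumulative fraction excreted in
#' urine) for every analyte. Parent and linked metabolite are always
#' co-simulated. Deterministic: no randomness enters the simulation.
#'
#' @param protocol A [study_protocol()].
#' @param drugs List of drug models (default: the packaged
#'   carbamazepine / carbamazepine-10,11-epoxide pair).
#' @param options Engine option overrides (see [build_system()]).
#' @param rtol,atol Solver tolerances (default from options / engine
#'   defaults).
#' @param grid_points Minimum output points per dosing interval.
#' @return A `simulation_result` with elements `time_h`, `observations`
#'   (long data frame: `time_h`, `analyte`, `matrix`,
#'   `concentration_umol_per_L`, `concentration_mg_per_L`; urine rows carry
#'   the dimensionless fe in the concentration columns), `enzymes`
#'   (relative amounts per expression site), and the raw trajectory.
#' @export
simulate_study <- function(protocol, drugs = default_drug_set(),
                           options = list(), rtol = NULL, atol = NULL,
                           grid_points = 200) {
  stopifnot(inherits(protocol, "study_protocol"))
  if (inherits(drugs, "drug_parameters")) drugs <- list(drugs)
  names(drugs) <- vapply(drugs, `[[`, character(1), "name")

  sched <- data.frame(drug = protocol$events$drug,
                      time = protocol$events$time_h * 60,
                      amount = protocol$events$amount,
                      formulation = protocol$events$formulation,
                      food_state = protocol$events$food_state,
                      stringsAsFactors = FALSE)
  sched <- sched[sched$amount > 0, , drop = FALSE]
  sys <- build_system(protocol$individual, drugs,
                      schedule = if (nrow(sched)) sched else NULL,
                      options = options)
  samp_min <- protocol$sampling_times_h * 60
  grid <- .output_grid(sched$time, samp_min, pts = grid_points)
  traj <- integrate_system(sys, grid,
                           rtol = rtol %||% sys$opts$rtol,
                           atol = atol %||% sys$opts$atol)
  .result_from_traj(traj, protocol, sys, time_offset_min = 0)
}

# dose totals [umol] per drug in a schedule
.molar_dose <- function(sys, drug) {
  sched <- sys$schedule
  if (is.null(sched)) return(0)
  rows <- sched$drug == drug
  sum(sched$amount[rows]) / sys$drugs[[drug]]$molecular_weight * 1000
}

.result_from_traj <- function(traj, protocol, sys, time_offset_min = 0) {
  times_min <- attr(traj, "times") - time_offset_min
  keep_drugs <- unique(protocol$analytes$drug)
  obs <- list()
  for (k in seq_len(nrow(protocol$analytes))) {
    drg <- protocol$analytes$drug[k]
    mat <- protocol$analytes$matrix[k]
    if (!drg %in% names(sys$drugs))
      stop("analyte drug not simulated: ", drg, call. = FALSE)
    plasma <- .plasma_series(traj, drg)
    val <- switch(mat,
      plasma = plasma,
      saliva = saliva_profile(plasma, sys$drugs[[drg]]$fraction_unbound),
      urine_fe = {
        o <- .drug_offset(sys, drg)
        dose <- .molar_dose(sys, drg)
        if (dose <= 0)
          stop("urine_fe requires a nonzero dose of ", drg, call. = FALSE)
        traj[, o + .IDX$urine] / dose
      })
    mw <- sys$drugs[[drg]]$molecular_weight
    obs[[k]] <- data.frame(
      time_h = times_min / 60, analyte = drg, matrix = mat,
      concentration_umol_per_L = val,
      concentration_mg_per_L = if (mat == "urine_fe") val else
        val * mw / 1000,
      stringsAsFactors = FALSE)
  }
  nd <- length(sys$drugs)
  enz <- do.call(cbind, lapply(seq_along(sys$sites), function(s)
    traj[, nd * .N_DRUG_STATES + s]))
  colnames(enz) <- vapply(sys$sites, function(s)
    paste0(s$enzyme, "@", sys$individual$organs$name[s$organ]),
    character(1))
  structure(list(time_h = times_min / 60,
                 observations = do.call(rbind, obs),
                 enzymes = data.frame(time_h = times_min / 60, enz,
                                      check.names = FALSE),
                 trajectory = traj, protocol = protocol, system = sys,
                 time_offset_min = time_offset_min),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %d time points to %g h | analytes: %s\n",
    length(x$time_h), max(x$time_h),
    paste(unique(paste0(x$observations$analyte, "/",
                        x$observations$matrix)), collapse = ", ")))
  invisible(x)
}

#' Extract one analyte series from a simulation result
#'
#' @param result A `simulation_result`.
#' @param drug Analyte drug name.
#' @param matrix `"plasma"`, `"saliva"` or `"urine_fe"`.
#' @param at_sampling If `TRUE`, restrict to the protocol sampling times.
#' @return Data frame `time_h`, `value` (uM, or fe for urine).
#' @export
analyte_series <- function(result, drug, matrix = "plasma",
                           at_sampling = FALSE) {
  ob <- result$observations
  ob <- ob[ob$analyte == drug & ob$matrix == matrix, , drop = FALSE]
  if (!nrow(ob)) stop("no such analyte in result: ", drug, "/", matrix,
                      call. = FALSE)
  out <- data.frame(time_h = ob$time_h,
                    value = ob$concentration_umol_per_L)
  if (at_sampling) {
    st <- result$protocol$sampling_times_h -
      (result$time_offset_min %||% 0) / 60
    out <- out[match(round(st, 9), round(out$time_h, 9)), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Simulate a drug-drug interaction protocol
#'
#' Runs the victim protocol twice on identical sampling grids: once alone
#' and once with the perpetrator event list added (the full model set,
#' including the perpetrator drug, is loaded in both arms so the arms
#' differ only in perpetrator dosing). Profiles are re-zeroed to the
#' victim's first dose.
#'
#' @param ddi A [ddi_protocol()].
#' @param drugs List of all drug models involved (victim(s), metabolites,
#'   perpetrator).
#' @param options,rtol,atol,grid_points As in [simulate_study()].
#' @return A `ddi_result`: list with `without`, `with`
#'   (`simulation_result`s) and the protocol.
#' @export
simulate_ddi <- function(ddi, drugs = default_drug_set(), options = list(),
                         rtol = NULL, atol = NULL, grid_points = 200) {
  stopifnot(inherits(ddi, "ddi_protocol"))
  names(drugs) <- vapply(drugs, `[[`, character(1), "name")
  perp_names <- unique(ddi$perpetrator_events$drug)
  missing <- setdiff(perp_names, names(drugs))
  if (length(missing))
    stop("perpetrator model(s) not loaded: ",
         paste(missing, collapse = ", "), call. = FALSE)
  n_int <- sum(vapply(drugs, function(d) length(d$interactions),
                      integer(1)))
  if (n_int == 0)
    warning("no interaction declared by any loaded drug model; ",
            "the two arms will coincide", call. = FALSE)

  vict <- ddi$victim
  offset_h <- max(0, -min(ddi$perpetrator_events$time_h))
  shift <- function(ev) {
    ev$time_h <- ev$time_h + offset_h
    ev
  }
  samp <- vict$sampling_times_h + offset_h

  run <- function(events) {
    prot <- study_protocol(events, samp, vict$analytes, vict$individual)
    sched <- data.frame(drug = prot$events$drug,
                        time = prot$events$time_h * 60,
                        amount = prot$events$amount,
                        formulation = prot$events$formulation,
                        food_state = prot$events$food_state,
                        stringsAsFactors = FALSE)
    sched <- sched[sched$amount > 0, , drop = FALSE]
    sys <- build_system(vict$individual, drugs,
                        schedule = if (nrow(sched)) sched else NULL,
                        options = options)
    grid <- .output_grid(sched$time, samp * 60, pts = grid_points)
    traj <- integrate_system(sys, grid, rtol = rtol %||% sys$opts$rtol,
                             atol = atol %||% sys$opts$atol)
    .result_from_traj(traj, prot, sys, time_offset_min = offset_h * 60)
  }
  alone <- run(shift(vict$events))
  combo <- run(rbind(shift(vict$events), shift(ddi$perpetrator_events)))
  structure(list(without = alone, with = combo, protocol = ddi),
            class = "ddi_result")
}

#' DDI exposure ratios of a simulated interaction
#'
#' Computes AUClast and Cmax in both arms at the victim sampling times and
#' returns the with/without ratios per analyte.
#'
#' @param ddi_result A `ddi_result` from [simulate_ddi()].
#' @param matrix Observation matrix to evaluate (default plasma).
#' @return Data frame: `analyte`, `auc_without`, `auc_with`, `auc_ratio`,
#'   `cmax_without`, `cmax_with`, `cmax_ratio`.
#' @export
ddi_ratios <- function(ddi_result, matrix = "plasma") {
  stopifnot(inherits(ddi_result, "ddi_result"))
  an <- ddi_result$without$protocol$analytes
  an <- an[an$matrix == matrix, , drop = FALSE]
  out <- lapply(seq_len(nrow(an)), function(k) {
    s0 <- analyte_series(ddi_result$without, an$drug[k], matrix)
    s1 <- analyte_series(ddi_result$with, an$drug[k], matrix)
    a0 <- auc_last(s0$time_h, s0$value)
    a1 <- auc_last(s1$time_h, s1$value)
    c0 <- cmax(s0$value)
    c1 <- cmax(s1$value)
    data.frame(analyte = an$drug[k], auc_without = a0, auc_with = a1,
               auc_ratio = ddi_auc_ratio(a1, a0), cmax_without = c0,
               cmax_with = c1, cmax_ratio = ddi_cmax_ratio(c1, c0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# ---- non-compartmental metrics ---------------------------------------------

#' Area under the curve to the last observation (linear trapezoid)
#'
#' @param time Nondecreasing time vector (>= 2 points).
#' @param conc Concentration vector of equal length.
#' @return AUClast in concentration x time units.
#' @export
auc_last <- function(time, conc) {
  if (length(time) < 2 || length(conc) != length(time))
    stop("validation error: need >= 2 matched samples", call. = FALSE)
  if (any(diff(time) < 0))
    stop("validation error: 'time' must be nondecreasing", call. = FALSE)
  sum(diff(time) * (utils::head(conc, -1) + utils::tail(conc, -1)) / 2)
}

#' Maximum observed concentration
#'
#' @param conc Concentration vector (>= 1 sample).
#' @return Cmax on the sampling grid.
#' @export
cmax <- function(conc) {
  if (!length(conc)) stop("validation error: empty series", call. = FALSE)
  max(conc)
}

#' DDI AUC ratio
#'
#' AUClast of the victim during coadministration divided by AUClast of the
#' victim alone.
#'
#' @param auc_with,auc_without AUClast values (alone must be > 0).
#' @return Dimensionless ratio.
#' @export
ddi_auc_ratio <- function(auc_with, auc_without) {
  if (!is.numeric(auc_without) || auc_without <= 0)
    stop("validation error: 'auc_without' must be > 0", call. = FALSE)
  auc_with / auc_without
}

#' DDI Cmax ratio
#'
#' @param cmax_with,cmax_without Cmax values (alone must be > 0).
#' @return Dimensionless ratio.
#' @export
ddi_cmax_ratio <- function(cmax_with, cmax_without) {
  if (!is.numeric(cmax_without) || cmax_without <= 0)
    stop("validation error: 'cmax_without' must be > 0", call. = FALSE)
  cmax_with / cmax_without
}

#' Cumulative fraction of dose excreted unchanged in urine
#'
#' @param result A `simulation_result`.
#' @param drug Drug name with a tracked urine sink and nonzero dose.
#' @return Data frame `time_h`, `fe` (nondecreasing, <= 1).
#' @export
fraction_excreted_urine <- function(result, drug) {
  stopifnot(inherits(result, "simulation_result"))
  sys <- result$system
  if (!drug %in% names(sys$drugs))
    stop("drug not simulated: ", drug, call. = FALSE)
  has_gfr <- any(vapply(sys$drugs[[drug]]$processes,
                        function(p) p$kind == "gfr", logical(1)))
  if (!has_gfr)
    stop("drug without urine sink: ", drug, call. = FALSE)
  o <- .drug_offset(sys, drug)
  dose <- .molar_dose(sys, drug)
  if (dose <= 0)
    stop("fraction excreted undefined: no dose of ", drug, call. = FALSE)
  data.frame(time_h = result$time_h,
             fe = result$trajectory[, o + .IDX$urine] / dose)
}

#' Saliva concentration from a plasma series
#'
#' Saliva mirrors the unbound plasma concentration: pointwise
#' `fu * plasma`. With the packaged carbamazepine fu of 0.25 this yields
#' the clinical saliva:plasma ratio of 1:4.
#'
#' @param plasma_series Numeric plasma concentration vector.
#' @param fu Fraction unbound in plasma, (0, 1].
#' @return Saliva concentration vector.
#' @export
saliva_profile <- function(plasma_series, fu) {
  if (!is.numeric(fu) || fu <= 0 || fu > 1)
    stop("validation error: 'fu' must be in (0, 1]", call. = FALSE)
  fu * plasma_series
}

#' Mass-balance audit of a simulation
#'
#' Total drug-equivalents (lumen + all organs + urine + metabolized sinks,
#' minus material formed from a parent) per drug and time point, compared
#' with the cumulative administered dose.
#'
#' @param result A `simulation_result`.
#' @return Data frame: `time_h`, one column per drug with the relative
#'   balance error (total - expected) / max(dose, formed).
#' @export
mass_balance <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  sys <- result$system
  traj <- result$trajectory
  times <- attr(traj, "times")
  out <- data.frame(time_h = result$time_h)
  for (drg in names(sys$drugs)) {
    o <- .drug_offset(sys, drg)
    total <- rowSums(traj[, o + c(1:14, .IDX$st_solid, .IDX$st_diss,
                                  .IDX$int_solid, .IDX$int_diss,
                                  .IDX$urine, .IDX$metab), drop = FALSE])
    formed <- traj[, o + .IDX$formed]
    sched <- sys$schedule
    dosed <- vapply(times, function(tt) {
      if (is.null(sched)) return(0)
      rows <- sched$drug == drg & sched$time <= tt + 1e-9
      sum(sched$amount[rows]) / sys$drugs[[drg]]$molecular_weight * 1000
    }, numeric(1))
    expected <- dosed + formed
    scale <- pmax(expected, max(expected) * 1e-6, 1e-12)
    out[[drg]] <- (total - expected) / scale
  }
  out
}

#' Write simulated profiles to CSV
#'
#' Long format with columns `time_h, analyte, matrix,
#' concentration_umol_per_L, concentration_mg_per_L` (urine rows carry the
#' dimensionless fe in both value columns).
#'
#' @param result A `simulation_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(result, path) {
  stopifnot(inherits(result, "simulation_result"))
  utils::write.csv(result$observations, path, row.names = FALSE)
  invisible(path)
}
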