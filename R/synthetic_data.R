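# Synthetic "observed" clinical datasets: the package's stand-in for
# digitized study data. Emulates sparse sampling schedules, plasma /
# saliva / urine-fraction observables, multiplicative lognormal residual
# noise and per-study mean +/- SD reporting.

# run code with a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Residual noise model for synthetic observations
#'
#' Multiplicative lognormal residuals: an observation is the model value
#' times `10^e` with `e ~ N(0, sigma_log10^2)`. Values at or below the
#' limit of quantification are dropped.
#'
#' @param sigma_log10 Spread of the log10 residuals (default 0.15,
#'   a typical between-subject spread of digitized concentration data).
#' @param loq Lower limit of quantification (same units as the values).
#' @param seed RNG seed; the generator is reproducible given the seed.
#' @return A `noise_model`.
#' @export
noise_model <- function(sigma_log10 = 0.15, loq = 0, seed = 1) {
  if (!is.numeric(sigma_log10) || sigma_log10 < 0)
    stop("validation error: 'sigma_log10' must be >= 0", call. = FALSE)
  structure(list(sigma_log10 = sigma_log10, loq = loq, seed = seed),
            class = "noise_model")
}

.simulate_truth_table <- function(protocol, drugs, options, rtol, atol,
                                  grid_points) {
  sim <- simulate_study(protocol, drugs, options = options, rtol = rtol,
                        atol = atol, grid_points = grid_points)
  out <- lapply(seq_len(nrow(protocol$analytes)), function(k) {
    s <- analyte_series(sim, protocol$analytes$drug[k],
                        protocol$analytes$matrix[k], at_sampling = TRUE)
    data.frame(analyte = protocol$analytes$drug[k],
               matrix = protocol$analytes$matrix[k], time_h = s$time_h,
               truth = s$value, stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, out), sim = sim)
}

.add_noise <- function(truth_tab, noise, n_subjects, study_id) {
  ns <- nrow(truth_tab)
  subj <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    e <- if (noise$sigma_log10 > 0)
      stats::rnorm(ns, 0, noise$sigma_log10) else numeric(ns)
    data.frame(subject = s, analyte = truth_tab$analyte,
               matrix = truth_tab$matrix, time_h = truth_tab$time_h,
               value = truth_tab$truth * 10^e, stringsAsFactors = FALSE)
  }))
  agg <- do.call(rbind, lapply(
    split(subj, paste(subj$analyte, subj$matrix, subj$time_h)),
    function(g) data.frame(
      study_id = study_id, analyte = g$analyte[1], matrix = g$matrix[1],
      time_h = g$time_h[1], value = mean(g$value),
      sd = if (n_subjects > 1) stats::sd(g$value) else NA_real_,
      stringsAsFactors = FALSE)))
  agg <- agg[order(agg$analyte, agg$matrix, agg$time_h), , drop = FALSE]
  rownames(agg) <- NULL
  agg <- agg[agg$value > noise$loq, , drop = FALSE]
  list(observed = agg, subjects = subj)
}

#' Generate a synthetic observed study dataset
#'
#' Simulates the protocol with the supplied drug models as ground truth,
#' then draws `n_subjects` noisy replicates at the protocol sampling
#' schedule (multiplicative lognormal residuals) and reports per-time mean
#' and SD like a published study table. Deterministic given the noise
#' model's seed.
#'
#' @param protocol A [study_protocol()].
#' @param drugs Drug models defining the ground truth.
#' @param noise A [noise_model()].
#' @param n_subjects Number of simulated subjects (>= 1).
#' @param options,rtol,atol,grid_points Passed to [simulate_study()].
#' @return A `synthetic_study`: `observed` (study-level mean/SD table with
#'   columns `study_id, analyte, matrix, time_h, value, sd`), `subjects`
#'   (per-subject values), `truth` (noise-free values), `protocol`,
#'   `true_drugs`, `n_subjects`.
#' @export
generate_observed_dataset <- function(protocol, drugs = default_drug_set(),
                                      noise = noise_model(),
                                      n_subjects = 1, options = list(),
                                      rtol = NULL, atol = NULL,
                                      grid_points = 200) {
  stopifnot(inherits(protocol, "study_protocol"),
            inherits(noise, "noise_model"))
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("validation error: 'n_subjects' must be >= 1", call. = FALSE)
  tt <- .simulate_truth_table(protocol, drugs, options, rtol, atol,
                              grid_points)
  drawn <- .with_seed(noise$seed,
                      .add_noise(tt$table, noise, n_subjects, "synthetic"))
  structure(list(observed = drawn$observed, subjects = drawn$subjects,
                 truth = tt$table, protocol = protocol, true_drugs = drugs,
                 n_subjects = n_subjects, noise = noise),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d observations, %d subject(s), sigma_log10 = %g\n",
    nrow(x$observed), x$n_subjects, x$noise$sigma_log10))
  invisible(x)
}

#' Generate a paired synthetic DDI dataset
#'
#' Simulates both arms of a DDI protocol as ground truth and draws shared
#' subjects (`n_subjects` per arm, residual noise drawn per arm from one
#' seeded stream).
#'
#' @param ddi A [ddi_protocol()].
#' @param drugs All involved drug models.
#' @param noise A [noise_model()].
#' @param n_subjects Subjects per arm.
#' @param options,rtol,atol,grid_points Passed to [simulate_ddi()].
#' @return List of two `synthetic_study` objects (`without`, `with`) plus
#'   the simulated `ddi_result`.
#' @export
generate_ddi_dataset <- function(ddi, drugs = default_drug_set(),
                                 noise = noise_model(), n_subjects = 1,
                                 options = list(), rtol = NULL,
                                 atol = NULL, grid_points = 200) {
  stopifnot(inherits(ddi, "ddi_protocol"))
  res <- simulate_ddi(ddi, drugs, options = options, rtol = rtol,
                      atol = atol, grid_points = grid_points)
  tab_for <- function(sim_result, prot) {
    do.call(rbind, lapply(seq_len(nrow(prot$analytes)), function(k) {
      s <- analyte_series(sim_result, prot$analytes$drug[k],
                          prot$analytes$matrix[k], at_sampling = TRUE)
      # restrict to the victim sampling clock
      s <- s[!is.na(s$value), , drop = FALSE]
      data.frame(analyte = prot$analytes$drug[k],
                 matrix = prot$analytes$matrix[k], time_h = s$time_h,
                 truth = s$value, stringsAsFactors = FALSE)
    }))
  }
  drawn <- .with_seed(noise$seed, {
    t0 <- tab_for(res$without, res$without$protocol)
    t1 <- tab_for(res$with, res$with$protocol)
    list(a = .add_noise(t0, noise, n_subjects, "synthetic_ddi_without"),
         b = .add_noise(t1, noise, n_subjects, "synthetic_ddi_with"))
  })
  wrap <- function(d, truth, prot) structure(
    list(observed = d$observed, subjects = d$subjects, truth = truth,
         protocol = prot, true_drugs = drugs, n_subjects = n_subjects,
         noise = noise), class = "synthetic_study")
  list(without = wrap(drawn$a, NULL, res$without$protocol),
       with = wrap(drawn$b, NULL, res$with$protocol),
       simulated = res)
}

#' Write a synthetic study to the observed-data CSV schema
#'
#' Columns: `study_id, analyte, matrix, time_h, value, sd` — the same
#' schema [evaluation_report()] consumes.
#'
#' @param study A `synthetic_study`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observed_csv <- function(study, path) {
  stopifnot(inherits(study, "synthetic_study"))
  utils::write.csv(study$observed, path, row.names = FALSE)
  invisible(path)
}

#' Read an observed-data CSV
#'
#' @param path CSV path with the schema of [write_observed_csv()].
#' @return Data frame.
#' @export
read_observed_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
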