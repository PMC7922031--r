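# Study protocols: dosing events, sampling schedule, observed analytes.

#' Dose events and regimens
#'
#' `dose_event()` builds a single administration; `dosing_regimen()` expands
#' a repeated regimen into an event table. Times are hours from protocol
#' start; amounts are mg.
#'
#' @param drug Drug name (must match a loaded model).
#' @param amount Dose in mg (>= 0).
#' @param time_h Administration time, h from protocol start.
#' @param formulation Formulation name on the drug model.
#' @param food_state `"fasted"`, `"fed"`, or `NA` to take the formulation's
#'   default.
#' @return A data frame of dose events.
#' @export
dose_event <- function(drug, amount, time_h = 0, formulation = "solution",
                       food_state = NA_character_) {
  if (!is.numeric(amount) || amount < 0)
    stop("validation error: 'amount' must be >= 0", call. = FALSE)
  data.frame(drug = drug, time_h = time_h, amount = amount,
             formulation = formulation, food_state = food_state,
             stringsAsFactors = FALSE)
}

#' @rdname dose_event
#' @param n_doses Number of administrations.
#' @param interval_h Dosing interval, h.
#' @param start_h Time of the first dose, h.
#' @export
dosing_regimen <- function(drug, amount, n_doses, interval_h, start_h = 0,
                           formulation = "solution",
                           food_state = NA_character_) {
  do.call(rbind, lapply(seq_len(n_doses) - 1, function(k)
    dose_event(drug, amount, start_h + k * interval_h, formulation,
               food_state)))
}

#' Define a study protocol
#'
#' @param events Data frame of dose events ([dose_event()] /
#'   [dosing_regimen()] rows bound together).
#' @param sampling_times_h Observation times, h; must lie inside the
#'   simulated window (>= 0).
#' @param analytes Data frame with columns `drug` and `matrix` (one of
#'   `"plasma"`, `"saliva"`, `"urine_fe"`); at least one row.
#' @param individual The virtual [create_individual()] the study is run in.
#' @return A `study_protocol` object.
#' @export
study_protocol <- function(events, sampling_times_h,
                           analytes = data.frame(
                             drug = unique(events$drug), matrix = "plasma"),
                           individual = create_individual()) {
  stopifnot(is.data.frame(events), nrow(events) >= 1)
  if (!all(c("drug", "time_h", "amount", "formulation") %in% names(events)))
    stop("validation error: malformed events table", call. = FALSE)
  if (!is.numeric(sampling_times_h) || !length(sampling_times_h) ||
      any(sampling_times_h < 0))
    stop("validation error: sampling times must be >= 0", call. = FALSE)
  if (!is.data.frame(analytes) || nrow(analytes) < 1 ||
      !all(c("drug", "matrix") %in% names(analytes)))
    stop("validation error: at least one analyte (drug, matrix) required",
         call. = FALSE)
  if (!all(analytes$matrix %in% c("plasma", "saliva", "urine_fe")))
    stop("validation error: analyte matrix must be plasma, saliva or ",
         "urine_fe", call. = FALSE)
  structure(list(events = events,
                 sampling_times_h = sort(unique(sampling_times_h)),
                 analytes = analytes, individual = individual),
            class = "study_protocol")
}

#' @export
print.study_protocol <- function(x, ...) {
  cat(sprintf(
    "<study_protocol> %d dose event(s) of %s | %d sampling times to %g h\n",
    nrow(x$events), paste(unique(x$events$drug), collapse = " + "),
    length(x$sampling_times_h), max(x$sampling_times_h)))
  invisible(x)
}

#' Define a DDI protocol
#'
#' Couples a victim study protocol with a perpetrator dosing event list.
#' Both arms ("victim alone" and "victim + perpetrator") use identical
#' victim events and sampling; perpetrator events may carry negative times
#' (pretreatment before the victim reference dose at time 0).
#'
#' @param victim A [study_protocol()] for the victim drug(s).
#' @param perpetrator_events Data frame of perpetrator dose events
#'   (`time_h` on the victim clock, negative allowed for pretreatment).
#' @return A `ddi_protocol` object.
#' @export
ddi_protocol <- function(victim, perpetrator_events) {
  stopifnot(inherits(victim, "study_protocol"))
  stopifnot(is.data.frame(perpetrator_events),
            nrow(perpetrator_events) >= 1)
  structure(list(victim = victim, perpetrator_events = perpetrator_events),
            class = "ddi_protocol")
}

#' Load a study protocol from JSON
#'
#' Schema: `events[]` (objects with `drug`, `time_h`, `amount`,
#' `formulation`, optional `food_state`), `sampling_times_h`, `analytes[]`
#' (objects with `drug`, `matrix`).
#'
#' @param path JSON file path.
#' @param individual Individual to bind (default reference).
#' @return A `study_protocol`.
#' @export
load_protocol_config <- function(path, individual = create_individual()) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  ev <- do.call(rbind, lapply(x$events, function(e)
    dose_event(e$drug, e$amount, e$time_h %||% 0,
               e$formulation %||% "solution",
               e$food_state %||% NA_character_)))
  an <- do.call(rbind, lapply(x$analytes, function(a)
    data.frame(drug = a$drug, matrix = a$matrix, stringsAsFactors = FALSE)))
  study_protocol(ev, unlist(x$sampling_times_h), an, individual)
}
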