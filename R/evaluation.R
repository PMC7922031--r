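# Model-performance statistics: concentration-level MRD, exposure-level
# GMFE, two-fold success fraction, and the interaction-strength-dependent
# prediction-success limits of Guest et al. for DDI ratios.

.check_pairs <- function(predicted, observed) {
  if (!length(predicted) || length(predicted) != length(observed))
    stop("validation error: need >= 1 matched predicted/observed pair",
         call. = FALSE)
  if (any(!is.finite(predicted)) || any(!is.finite(observed)) ||
      any(predicted <= 0) || any(observed <= 0))
    stop("validation error: predicted and observed values must be ",
         "positive", call. = FALSE)
  invisible(TRUE)
}

#' Mean relative deviation of predicted concentrations
#'
#' MRD = 10 ^ sqrt(mean(log10(pred/obs)^2)): the root-mean-square log10
#' deviation, back-transformed to a fold scale (>= 1; 1 is a perfect fit).
#'
#' @param predicted,observed Positive paired vectors.
#' @return MRD (dimensionless, >= 1).
#' @export
mrd <- function(predicted, observed) {
  .check_pairs(predicted, observed)
  10^sqrt(mean(log10(predicted / observed)^2))
}

#' Geometric mean fold error of predicted exposure metrics
#'
#' GMFE = 10 ^ mean(|log10(pred/obs)|) (>= 1; 1 is a perfect fit). Used for
#' AUClast, Cmax and DDI ratios.
#'
#' @param predicted,observed Positive paired vectors.
#' @return GMFE (dimensionless, >= 1).
#' @export
gmfe <- function(predicted, observed) {
  .check_pairs(predicted, observed)
  10^mean(abs(log10(predicted / observed)))
}

#' Fraction of predictions within 2-fold of observations
#'
#' Boundary-touching predictions (ratio exactly 0.5 or 2) count as within.
#'
#' @param predicted,observed Positive paired vectors.
#' @param fold Acceptance fold (default 2).
#' @return Fraction in `[0, 1]`.
#' @export
two_fold_fraction <- function(predicted, observed, fold = 2) {
  .check_pairs(predicted, observed)
  r <- predicted / observed
  mean(r >= 1 / fold & r <= fold)
}

#' Prediction-success limits for DDI ratios (Guest et al.)
#'
#' For an observed DDI ratio R_obs the allowed band on the predicted ratio
#' is `[R_obs / L, R_obs * L]` with fold-margin
#' `L = (delta + 2 (R - 1)) / R`, where `R = R_obs` for ratios >= 1 and
#' `R = 1 / R_obs` otherwise (reciprocal symmetry). At `R_obs = 1` the band
#' is `[1/delta, delta]` = `[0.8, 1.25]` with the default `delta = 1.25`,
#' i.e. 20% deviation is allowed where no interaction was observed; the
#' margin widens to 2-fold for strong interactions.
#'
#' @param observed_ratio Observed DDI AUC or Cmax ratio (> 0).
#' @param delta Margin parameter at unity (default 1.25).
#' @return List with `lower`, `upper`, `fold_margin`.
#' @export
guest_limits <- function(observed_ratio, delta = 1.25) {
  if (!is.numeric(observed_ratio) || !is.finite(observed_ratio) ||
      observed_ratio <= 0)
    stop("validation error: 'observed_ratio' must be > 0", call. = FALSE)
  R <- if (observed_ratio >= 1) observed_ratio else 1 / observed_ratio
  L <- (delta + 2 * (R - 1)) / R
  list(lower = observed_ratio / L, upper = observed_ratio * L,
       fold_margin = L)
}

#' Is a predicted DDI ratio within the Guest limits?
#'
#' Inclusive at the boundary; symmetric under joint reciprocal transform of
#' predicted and observed ratios.
#'
#' @param predicted_ratio,observed_ratio Positive DDI ratios.
#' @param delta Margin parameter at unity.
#' @return Logical.
#' @export
guest_within <- function(predicted_ratio, observed_ratio, delta = 1.25) {
  lim <- guest_limits(observed_ratio, delta)
  predicted_ratio >= lim$lower - 1e-12 &
    predicted_ratio <= lim$upper + 1e-12
}

#' Evaluation report over matched predictions and observations
#'
#' Joins predicted and observed concentration tables on
#' `(study_id, analyte, matrix, time_h)` — and, when given, DDI ratio
#' tables on `(study_id, analyte, metric)` — then computes per-study and
#' pooled MRD, two-fold fractions, GMFE and Guest verdicts. Pooled metrics
#' are computed on the pooled pairs, not averaged across studies.
#'
#' @param predicted,observed Data frames with columns `study_id`,
#'   `analyte`, `matrix`, `time_h`, `value` (concentration series).
#' @param predicted_ratios,observed_ratios Optional data frames with
#'   columns `study_id`, `analyte`, `metric` (`"auc"`/`"cmax"`), `value`.
#' @param delta Guest margin parameter.
#' @param loq Values at or below this limit of quantification are excluded
#'   from concentration metrics (default 0: keep all positive values).
#' @return An `evaluation_report`: list with `concentration` (per-study
#'   table), `pooled`, `ddi` (per-ratio Guest verdicts with GMFE), and the
#'   matched pair tables.
#' @export
evaluation_report <- function(predicted, observed, predicted_ratios = NULL,
                              observed_ratios = NULL, delta = 1.25,
                              loq = 0) {
  key <- function(df) paste(df$study_id, df$analyte, df$matrix,
                            round(df$time_h, 9), sep = "|")
  m <- match(key(observed), key(predicted))
  if (anyNA(m)) {
    miss <- unique(paste(observed$study_id, observed$analyte,
                         observed$time_h)[is.na(m)])
    stop("unmatched observation labels: ",
         paste(utils::head(miss, 5), collapse = "; "),
         if (length(miss) > 5) " ...", call. = FALSE)
  }
  pairs <- data.frame(study_id = observed$study_id,
                      analyte = observed$analyte,
                      matrix = observed$matrix, time_h = observed$time_h,
                      obs = observed$value, pred = predicted$value[m],
                      stringsAsFactors = FALSE)
  pairs <- pairs[pairs$obs > loq & pairs$pred > loq, , drop = FALSE]
  if (!nrow(pairs))
    stop("no matched pairs above the limit of quantification",
         call. = FALSE)

  per_study <- do.call(rbind, lapply(split(pairs, pairs$study_id),
                                     function(g)
    data.frame(study_id = g$study_id[1], n = nrow(g),
               mrd = mrd(g$pred, g$obs),
               two_fold = two_fold_fraction(g$pred, g$obs),
               stringsAsFactors = FALSE)))
  rownames(per_study) <- NULL
  pooled <- data.frame(n = nrow(pairs), mrd = mrd(pairs$pred, pairs$obs),
                       two_fold = two_fold_fraction(pairs$pred, pairs$obs))

  ddi <- NULL
  if (!is.null(predicted_ratios) && !is.null(observed_ratios)) {
    rk <- function(df) paste(df$study_id, df$analyte, df$metric, sep = "|")
    mm <- match(rk(observed_ratios), rk(predicted_ratios))
    if (anyNA(mm))
      stop("unmatched ratio labels: ",
           paste(rk(observed_ratios)[is.na(mm)], collapse = "; "),
           call. = FALSE)
    ddi <- observed_ratios
    names(ddi)[names(ddi) == "value"] <- "observed"
    ddi$predicted <- predicted_ratios$value[mm]
    lims <- lapply(ddi$observed, guest_limits, delta = delta)
    ddi$guest_lower <- vapply(lims, `[[`, numeric(1), "lower")
    ddi$guest_upper <- vapply(lims, `[[`, numeric(1), "upper")
    ddi$within <- mapply(guest_within, ddi$predicted, ddi$observed,
                         MoreArgs = list(delta = delta))
    attr(ddi, "gmfe") <- gmfe(ddi$predicted, ddi$observed)
  }
  structure(list(concentration = per_study, pooled = pooled, ddi = ddi,
                 pairs = pairs, delta = delta),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n  Pooled concentrations: n =", x$pooled$n,
      sprintf("| MRD %.3f | within 2-fold %.0f%%\n", x$pooled$mrd,
              100 * x$pooled$two_fold))
  if (!is.null(x$ddi))
    cat(sprintf("  DDI ratios: %d/%d within Guest limits | GMFE %.3f\n",
                sum(x$ddi$within), nrow(x$ddi), attr(x$ddi, "gmfe")))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  x <- list(pooled = report$pooled, per_study = report$concentration,
            delta = report$delta)
  if (!is.null(report$ddi)) {
    x$ddi <- report$ddi
    x$ddi_gmfe <- attr(report$ddi, "gmfe")
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
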