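# Parameter estimation: log-scale least squares on concentration data with
# Monte-Carlo multistart initial points refined by a Levenberg-Marquardt
# local search (written here; no least-squares package is assumed).

#' Address a free parameter inside a drug model
#'
#' @param drug Drug name the parameter belongs to.
#' @param path Character/integer vector indexing into the
#'   `drug_parameters` list, e.g. `list("processes", 1, "k_cat")`.
#' @param lower,upper Finite bounds (ordered).
#' @param transform `"log"` (default; positivity enforced) or `"linear"`.
#' @param name Label (defaults to the collapsed path).
#' @return A `fit_param` descriptor.
#' @export
fit_param <- function(drug, path, lower, upper, transform = "log",
                      name = NULL) {
  if (!is.numeric(lower) || !is.numeric(upper) || !is.finite(lower) ||
      !is.finite(upper) || lower >= upper)
    stop("validation error: bounds must be finite and ordered",
         call. = FALSE)
  transform <- match.arg(transform, c("log", "linear"))
  if (transform == "log" && lower <= 0)
    stop("validation error: log-transformed parameter needs lower > 0",
         call. = FALSE)
  structure(list(drug = drug, path = as.list(path), lower = lower,
                 upper = upper, transform = transform,
                 name = name %||% paste(unlist(path), collapse = "/")),
            class = "fit_param")
}

.get_path <- function(x, path) {
  for (p in path) x <- x[[p]]
  x
}

.set_path <- function(x, path, value) {
  if (length(path) == 1) {
    x[[path[[1]]]] <- value
    return(x)
  }
  x[[path[[1]]]] <- .set_path(x[[path[[1]]]], path[-1], value)
  x
}

.apply_params <- function(drugs, params, theta_nat) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (!p$drug %in% names(drugs))
      stop("fit parameter references unloaded drug: ", p$drug,
           call. = FALSE)
    if (is.null(.get_path(drugs[[p$drug]], p$path)))
      stop("fit parameter path does not resolve: ", p$name, call. = FALSE)
    drugs[[p$drug]] <- .set_path(drugs[[p$drug]], p$path, theta_nat[i])
  }
  drugs
}

.to_internal <- function(theta, params)
  mapply(function(v, p) if (p$transform == "log") log(v) else v,
         theta, params)
.to_natural <- function(z, params)
  mapply(function(v, p) if (p$transform == "log") exp(v) else v,
         z, params)

#' Specify a fitting problem
#'
#' @param params List of [fit_param()] descriptors. Fitting `E_max` jointly
#'   with the matching `EC_50` of the same induction action is refused
#'   (identifiability guard): fix the EC50 from literature.
#' @param datasets List of datasets, each a list with elements `protocol`
#'   (a [study_protocol()]) and `observed` (data frame `analyte`, `matrix`,
#'   `time_h`, `value`).
#' @param drugs Base drug set that the free parameters modify.
#' @param n_starts Number of Monte-Carlo multistart points (the first start
#'   is always the current value in `drugs`).
#' @param seed RNG seed for the multistart draw.
#' @param loq Observations at or below this value are excluded.
#' @param rtol,atol Solver tolerances used inside the objective.
#' @param grid_points Output grid density for the objective simulations.
#' @param options Engine options forwarded to [simulate_study()].
#' @return A `fit_spec`.
#' @export
fit_spec <- function(params, datasets, drugs = default_drug_set(),
                     n_starts = 20, seed = 1, loq = 0, rtol = 1e-6,
                     atol = 1e-9, grid_points = 25, options = list()) {
  stopifnot(length(params) >= 1,
            all(vapply(params, inherits, logical(1), "fit_param")))
  stopifnot(length(datasets) >= 1)
  emax_paths <- vapply(params, function(p)
    identical(p$path[[length(p$path)]], "E_max"), logical(1))
  ec50_paths <- vapply(params, function(p)
    identical(p$path[[length(p$path)]], "EC_50"), logical(1))
  if (any(emax_paths) && any(ec50_paths))
    stop("identifiability guard: refusing to fit E_max and EC_50 jointly; ",
         "fix EC_50 from literature", call. = FALSE)
  for (ds in datasets) {
    if (!inherits(ds$protocol, "study_protocol") ||
        !is.data.frame(ds$observed) || !nrow(ds$observed))
      stop("validation error: each dataset needs a protocol and a ",
           "non-empty observed table", call. = FALSE)
  }
  if (inherits(drugs, "drug_parameters")) drugs <- list(drugs)
  names(drugs) <- vapply(drugs, `[[`, character(1), "name")
  structure(list(params = params, datasets = datasets, drugs = drugs,
                 n_starts = n_starts, seed = seed, loq = loq, rtol = rtol,
                 atol = atol, grid_points = grid_points, options = options),
            class = "fit_spec")
}

# log10 residual vector over all datasets for natural-scale parameters
.residuals <- function(theta_nat, spec) {
  drugs <- .apply_params(spec$drugs, spec$params, theta_nat)
  res <- numeric(0)
  for (ds in spec$datasets) {
    sim <- simulate_study(ds$protocol, drugs, options = spec$options,
                          rtol = spec$rtol, atol = spec$atol,
                          grid_points = spec$grid_points)
    ob <- ds$observed
    ob <- ob[ob$value > spec$loq, , drop = FALSE]
    for (grp in split(ob, paste(ob$analyte, ob$matrix))) {
      s <- analyte_series(sim, grp$analyte[1], grp$matrix[1])
      pred <- stats::approx(s$time_h, s$value, xout = grp$time_h,
                            rule = 2)$y
      keep <- pred > spec$loq
      res <- c(res, log10(pred[keep] / grp$value[keep]))
    }
  }
  if (!length(res))
    stop("empty dataset: no observations above the limit of ",
         "quantification", call. = FALSE)
  res
}

#' Least-squares objective of a fitting problem
#'
#' Sum of squared log10 residuals between simulated and observed
#' concentrations over every dataset in the spec. Simulation failures
#' return a large penalty (1e6) rather than aborting the search.
#'
#' @param theta Natural-scale parameter vector (order of `spec$params`).
#' @param spec A [fit_spec()].
#' @param penalty Value returned on simulation failure.
#' @return Scalar loss (0 for a perfect fit).
#' @export
fit_objective <- function(theta, spec, penalty = 1e6) {
  stopifnot(inherits(spec, "fit_spec"))
  r <- tryCatch(.residuals(theta, spec), error = function(e) {
    message("objective penalty at theta = ",
            paste(signif(theta, 4), collapse = ", "), ": ",
            conditionMessage(e))
    NULL
  })
  if (is.null(r)) return(penalty)
  sum(r^2)
}

# Levenberg-Marquardt on the transformed parameter scale with box clipping.
.lm_refine <- function(z0, spec, maxit = 30, ftol = 1e-10, xtol = 1e-8) {
  params <- spec$params
  lo <- .to_internal(vapply(params, `[[`, numeric(1), "lower"), params)
  hi <- .to_internal(vapply(params, `[[`, numeric(1), "upper"), params)
  clip <- function(z) pmin(pmax(z, lo), hi)
  z <- clip(z0)
  rfun <- function(z) tryCatch(
    .residuals(.to_natural(z, params), spec), error = function(e) NULL)
  r <- rfun(z)
  if (is.null(r)) return(list(z = z, obj = Inf, iters = 0L,
                              converged = FALSE))
  obj <- sum(r^2)
  lambda <- 1e-3
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(maxit)) {
    iters <- it
    if (obj < ftol) { converged <- TRUE; break }
    n <- length(z)
    J <- matrix(0, length(r), n)
    ok <- TRUE
    for (j in seq_len(n)) {
      dz <- 1e-5 * max(1, abs(z[j]))
      zp <- z; zp[j] <- min(zp[j] + dz, hi[j])
      if (zp[j] == z[j]) { zp[j] <- max(z[j] - dz, lo[j]); dz <- zp[j] - z[j] }
      rp <- rfun(zp)
      if (is.null(rp)) { ok <- FALSE; break }
      J[, j] <- (rp - r) / (zp[j] - z[j])
    }
    if (!ok) break
    g <- crossprod(J, r)
    if (max(abs(g)) < 1e-12) { converged <- TRUE; break }
    A <- crossprod(J)
    improved <- FALSE
    for (try in 1:10) {
      M <- A + lambda * diag(pmax(diag(A), 1e-12), nrow(A))
      step <- tryCatch(-solve(M, g), error = function(e) NULL)
      if (!is.null(step)) {
        znew <- clip(z + drop(step))
        rnew <- rfun(znew)
        if (!is.null(rnew) && sum(rnew^2) < obj) {
          rel <- (obj - sum(rnew^2)) / max(obj, 1e-300)
          moved <- max(abs(znew - z))
          z <- znew; r <- rnew; obj <- sum(rnew^2)
          lambda <- max(lambda / 5, 1e-10)
          improved <- TRUE
          if (rel < ftol || moved < xtol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!improved) { converged <- TRUE; break }
    if (converged) break
  }
  list(z = z, obj = obj, iters = iters, converged = converged)
}

#' Fit free parameters by multistart least squares
#'
#' Draws `n_starts` Monte-Carlo initial points uniformly on the transformed
#' bounded space (the first start is the current model value), refines each
#' by Levenberg-Marquardt on the log10 residual vector, and returns the
#' best refined estimate. Deterministic given `spec$seed`.
#'
#' @param spec A [fit_spec()].
#' @param maxit Maximum LM iterations per start.
#' @return A `fit_result`: `estimates` (named natural-scale vector),
#'   `objective`, `starts` (per-start table), `converged`, `seed`, and the
#'   updated `drugs` list.
#' @export
fit_parameters <- function(spec, maxit = 30) {
  stopifnot(inherits(spec, "fit_spec"))
  params <- spec$params
  lo <- .to_internal(vapply(params, `[[`, numeric(1), "lower"), params)
  hi <- .to_internal(vapply(params, `[[`, numeric(1), "upper"), params)
  theta0 <- vapply(params, function(p) {
    v <- .get_path(spec$drugs[[p$drug]], p$path)
    if (is.null(v)) stop("fit parameter path does not resolve: ", p$name,
                         call. = FALSE)
    v
  }, numeric(1))
  z_starts <- list(.to_internal(pmin(pmax(theta0,
                                          vapply(params, `[[`, numeric(1),
                                                 "lower")),
                                     vapply(params, `[[`, numeric(1),
                                            "upper")), params))
  if (spec$n_starts > 1) {
    draws <- .with_seed(spec$seed, {
      matrix(stats::runif((spec$n_starts - 1) * length(params)),
             ncol = length(params))
    })
    for (k in seq_len(nrow(draws)))
      z_starts[[k + 1]] <- lo + draws[k, ] * (hi - lo)
  }
  runs <- lapply(z_starts, .lm_refine, spec = spec, maxit = maxit)
  objs <- vapply(runs, `[[`, numeric(1), "obj")
  if (all(!is.finite(objs)))
    stop("zero successful starts: all objective evaluations failed",
         call. = FALSE)
  best <- which.min(objs)
  est <- .to_natural(runs[[best]]$z, params)
  names(est) <- vapply(params, `[[`, character(1), "name")
  starts <- data.frame(
    start = seq_along(runs),
    objective = objs,
    iterations = vapply(runs, `[[`, integer(1), "iters"),
    converged = vapply(runs, `[[`, logical(1), "converged"))
  structure(list(estimates = est, objective = objs[best], starts = starts,
                 converged = runs[[best]]$converged, seed = spec$seed,
                 drugs = .apply_params(spec$drugs, params, est)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> objective", format(x$objective, digits = 4),
      if (x$converged) "(converged)" else "(not converged)", "\n")
  for (nm in names(x$estimates))
    cat(sprintf("  %s = %s\n", nm, format(x$estimates[[nm]], digits = 6)))
  invisible(x)
}

#' One-at-a-time relative sensitivity of exposure to model parameters
#'
#' Utility: perturbs each addressed parameter by `perturbation` (relative,
#' e.g. 10 for +1000%), re-simulates, and reports the normalized local
#' sensitivity S = (dAUC/AUC) / (dp/p) of the AUClast of the chosen
#' analyte.
#'
#' @param protocol A [study_protocol()].
#' @param params List of [fit_param()] addresses to perturb.
#' @param drugs Base drug set.
#' @param analyte,matrix Observable whose AUClast is the sensitivity
#'   endpoint.
#' @param perturbation Relative perturbation of each parameter.
#' @param ... Passed to [simulate_study()].
#' @return Data frame `parameter`, `sensitivity`.
#' @export
sensitivity_analysis <- function(protocol, params,
                                 drugs = default_drug_set(),
                                 analyte = "carbamazepine",
                                 matrix = "plasma", perturbation = 10,
                                 ...) {
  if (inherits(drugs, "drug_parameters")) drugs <- list(drugs)
  names(drugs) <- vapply(drugs, `[[`, character(1), "name")
  base <- simulate_study(protocol, drugs, ...)
  s0 <- analyte_series(base, analyte, matrix)
  auc0 <- auc_last(s0$time_h, s0$value)
  out <- lapply(params, function(p) {
    v0 <- .get_path(drugs[[p$drug]], p$path)
    d2 <- .apply_params(drugs, list(p), v0 * (1 + perturbation))
    sim <- simulate_study(protocol, d2, ...)
    s1 <- analyte_series(sim, analyte, matrix)
    auc1 <- auc_last(s1$time_h, s1$value)
    data.frame(parameter = p$name,
               sensitivity = ((auc1 - auc0) / auc0) / perturbation,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
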