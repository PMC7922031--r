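# Stiff ODE integration. The engine couples absorption dynamics (minutes)
# with enzyme turnover (days), so an L-stable linearly implicit method is
# required. This is a Rosenbrock(2,3) scheme (the ode23s formula pair of
# Shampine & Reichelt) with a finite-difference Jacobian that is reused
# across steps until a step is rejected or it grows stale, and cubic Hermite
# dense output at requested times. Dose administrations are handled upstream
# by solver restarts (see integrate_system).

.jac_fd <- function(rhs, t, y, f0) {
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    dy <- max(1e-8, 1e-6 * abs(y[j]))
    yp <- y
    yp[j] <- yp[j] + dy
    J[, j] <- (rhs(t, yp) - f0) / dy
  }
  J
}

#' Integrate an ODE with an adaptive stiff Rosenbrock method
#'
#' Low-level integrator used by the PBPK engine; exposed so that degenerate
#' configurations can be checked against closed-form solutions. Returns the
#' solution at `times` (the first entry is the initial time).
#'
#' @param rhs Function `(t, y) -> dy/dt`.
#' @param y0 Initial state (numeric vector).
#' @param times Strictly increasing output times; integration runs from
#'   `times[1]` to `times[length(times)]`.
#' @param rtol,atol Relative / absolute local error tolerances.
#' @param max_step Maximum step size.
#' @param neg_floor States in `[-neg_floor, 0)` are clamped to 0 after each
#'   accepted step; a state below `-neg_floor` aborts with a diagnostic.
#'   Default `Inf` (no clamping): amount non-negativity is a PBPK engine
#'   policy, applied by [integrate_system()], not a property of the
#'   integrator.
#' @return Matrix with `length(times)` rows (one per output time).
#' @export
ode_solve <- function(rhs, y0, times, rtol = 1e-8, atol = 1e-10,
                      max_step = Inf, neg_floor = Inf) {
  stopifnot(length(times) >= 2, all(diff(times) > 0))
  n <- length(y0)
  d <- 1 / (2 + sqrt(2))
  e32 <- 6 + sqrt(2)
  t_end <- times[length(times)]
  out <- matrix(NA_real_, length(times), n)
  out[1, ] <- y0

  t <- times[1]
  y <- y0
  f0 <- rhs(t, y)
  if (length(f0) != n) stop("rhs returned wrong length", call. = FALSE)
  h <- min(max_step, (t_end - t) / 100,
           0.1 / max(max(abs(f0) / (atol + rtol * abs(y))), 1e-8))
  h <- max(h, 1e-10)
  J <- .jac_fd(rhs, t, y, f0)
  jac_age <- 0L
  next_out <- 2L
  nsteps <- 0L

  while (t < t_end) {
    if (t + h > t_end) h <- t_end - t
    # numeric d f / d t (the lumen release schedule is time dependent)
    dt_eps <- max(1e-8, 1e-6 * abs(t))
    Tt <- (rhs(t + dt_eps, y) - f0) / dt_eps
    accepted <- FALSE
    while (!accepted) {
      W <- diag(n) - (h * d) * J
      k1 <- tryCatch(solve(W, f0 + (h * d) * Tt), error = function(e) NULL)
      if (is.null(k1)) {
        h <- h / 2
        if (h < 1e-12)
          stop(sprintf("solver failure at t = %g (singular iteration matrix)",
                       t), call. = FALSE)
        next
      }
      f1 <- rhs(t + 0.5 * h, y + (0.5 * h) * k1)
      k2 <- solve(W, f1 - k1) + k1
      ynew <- y + h * k2
      f2 <- rhs(t + h, ynew)
      k3 <- solve(W, f2 - e32 * (k2 - f1) - 2 * (k1 - f0) + (h * d) * Tt)
      err <- (h / 6) * (k1 - 2 * k2 + k3)
      sc <- atol + rtol * pmax(abs(y), abs(ynew))
      errnorm <- max(abs(err) / sc)
      if (!is.finite(errnorm)) errnorm <- 2
      if (errnorm <= 1) {
        accepted <- TRUE
        tnew <- t + h
        # dense output: cubic Hermite on (t, y, f0) -- (tnew, ynew, f2)
        while (next_out <= length(times) && times[next_out] <= tnew + 1e-12) {
          s <- (times[next_out] - t) / h
          h00 <- (1 + 2 * s) * (1 - s)^2
          h10 <- s * (1 - s)^2
          h01 <- s^2 * (3 - 2 * s)
          h11 <- s^2 * (s - 1)
          out[next_out, ] <- h00 * y + h10 * h * f0 + h01 * ynew +
            h11 * h * f2
          next_out <- next_out + 1L
        }
        t <- tnew
        y <- ynew
        neg <- y < 0
        if (any(neg) && is.finite(neg_floor)) {
          if (any(y < -neg_floor))
            stop(sprintf(
              "solver failure at t = %g: state %d fell below -%g",
              t, which.min(y), neg_floor), call. = FALSE)
          y[neg] <- 0
        }
        f0 <- rhs(t, y)
        jac_age <- jac_age + 1L
        if (jac_age >= 20L) {
          J <- .jac_fd(rhs, t, y, f0)
          jac_age <- 0L
        }
        h <- min(h * min(5, max(0.2, 0.9 * errnorm^(-1 / 3))), max_step)
      } else {
        h <- h * max(0.1, 0.9 * errnorm^(-1 / 3))
        if (jac_age > 0L) {
          J <- .jac_fd(rhs, t, y, f0)
          jac_age <- 0L
        }
        if (h < 1e-12)
          stop(sprintf("solver failure at t = %g (step size underflow)", t),
               call. = FALSE)
      }
      nsteps <- nsteps + 1L
      if (nsteps > 5e6)
        stop(sprintf("solver failure at t = %g (step budget exhausted)", t),
             call. = FALSE)
    }
  }
  out[length(times), ] <- y
  attr(out, "nsteps") <- nsteps
  out
}
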