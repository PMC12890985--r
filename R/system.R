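#' Simulation system specification
#'
#' Collects mass, thermal energy, integration time step, sampling interval,
#' run length and seed for the stochastic integrators.  Reduced units are
#' the default: `kBT = 1`, times in units of the shortest memory time.
#'
#' @param mass effective mass `m = kBT / <qdot^2>` (> 0).
#' @param kBT thermal energy (> 0, default 1).
#' @param dt integration time step (> 0).
#' @param delta sampling interval of the recorded trajectory; must be a
#'   (near-)integer multiple of `dt`.  Default `dt` (record every step).
#' @param n_steps number of integration steps after burn-in; the recorded
#'   trajectory has `floor(n_steps * dt / delta)` samples.
#' @param seed integer random seed.
#' @param burn_in burn-in time discarded before recording; `NULL` means
#'   10 times the longest memory time (GLE) or `100 * dt` otherwise.
#' @return An object of class `system_spec`.
#' @export
system_spec <- function(mass = 1, kBT = 1, dt, delta = dt, n_steps,
                        seed = 1L, burn_in = NULL) {
  stopifnot(mass > 0, kBT > 0, dt > 0, delta >= dt, n_steps >= 1)
  sub <- delta / dt
  if (abs(sub - round(sub)) > 1e-8)
    stop("delta must be an integer multiple of dt")
  structure(list(mass = mass, kBT = kBT, dt = dt, delta = delta,
                 sub = as.integer(round(sub)), n_steps = as.numeric(n_steps),
                 seed = as.integer(seed), burn_in = burn_in),
            class = "system_spec")
}

#' @export
print.system_spec <- function(x, ...) {
  cat(sprintf(
    "system_spec: m = %g, kBT = %g, dt = %g, delta = %g, n_steps = %g, seed = %d\n",
    x$mass, x$kBT, x$dt, x$delta, x$n_steps, x$seed))
  invisible(x)
}

#' Uniformly sampled reaction-coordinate trajectory
#'
#' @param q numeric vector of RC samples at uniform interval `delta`.
#' @param delta sampling interval.
#' @param dt integration step used to generate the samples (metadata).
#' @param seed generating seed (metadata).
#' @param v optional recorded velocities.
#' @param meta named list of generating parameters.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(q, delta, dt = delta, seed = NA_integer_, v = NULL,
                       meta = list()) {
  q <- as.numeric(q)
  if (any(!is.finite(q))) stop("trajectory contains non-finite values")
  stopifnot(delta > 0)
  structure(list(q = q, delta = delta, dt = dt, seed = seed, v = v,
                 meta = meta),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: %d samples, delta = %g (total time %g), seed = %s\n",
    length(x$q), x$delta, length(x$q) * x$delta,
    ifelse(is.na(x$seed), "NA", as.character(x$seed))))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$q)
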