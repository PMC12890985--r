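#' Markovian embedding of a multiexponential kernel
#'
#' Maps each kernel component to one overdamped auxiliary coordinate
#' \eqn{z_i} spring-coupled to `q` with stiffness \eqn{k_i = \gamma_i/\tau_i}
#' and auxiliary friction \eqn{\gamma_i}, so that integrating out the
#' auxiliaries from their stationary distribution recovers the GLE with
#' \eqn{\Gamma(t) = \sum_i k_i e^{-t/\tau_i}} and random-force correlations
#' \eqn{k_BT\,\Gamma(t)}.  The stationary distribution of `q` stays
#' Boltzmann in `U(q)` for any kernel.
#'
#' @param kernel a [memory_kernel()].
#' @return An object of class `embedded_system` with per-component coupling
#'   stiffness `k` and the original kernel.
#' @export
embed_kernel <- function(kernel) {
  if (!inherits(kernel, "memory_kernel")) stop("kernel must be a memory_kernel")
  structure(list(kernel = kernel, k = kernel$gamma / kernel$tau,
                 n = kernel$n),
            class = "embedded_system")
}

#' @export
print.embedded_system <- function(x, ...) {
  cat(sprintf("embedded_system: %d auxiliary coordinate(s), k = %s\n",
              x$n, paste(signif(x$k, 4), collapse = ", ")))
  invisible(x)
}

#' Coordinate-dependent friction profile
#'
#' @param q grid of RC positions (sorted).
#' @param gamma strictly positive friction values on the grid; a scalar is
#'   recycled (constant profile).
#' @param counts optional per-point event counts (used for weighted
#'   averaging of profiles).
#' @return An object of class `friction_profile` with `fun(q)` (linear
#'   interpolation, constant extrapolation) and `dfun(q)`.
#' @export
friction_profile <- function(q, gamma, counts = NULL) {
  if (length(gamma) == 1L) gamma <- rep(gamma, length(q))
  stopifnot(length(q) == length(gamma), !is.unsorted(q))
  if (any(gamma <= 0)) stop("friction profile must be strictly positive")
  f <- stats::approxfun(q, gamma, rule = 2)
  df <- function(x) {
    eps <- diff(range(q)) / (length(q) * 100 + 100)
    (f(x + eps) - f(x - eps)) / (2 * eps)
  }
  structure(list(q = q, gamma = gamma, fun = f, dfun = df, counts = counts),
            class = "friction_profile")
}

#' @export
print.friction_profile <- function(x, ...) {
  cat(sprintf("friction_profile on [%g, %g], gamma in [%g, %g]\n",
              min(x$q), max(x$q), min(x$gamma), max(x$gamma)))
  invisible(x)
}

# ---- helpers ---------------------------------------------------------------

# Draw q(0) from the Boltzmann distribution of `pot` by inverse-CDF sampling
# on a fine grid over a sensible range.
sample_boltzmann <- function(pot, kBT, n = 1L) {
  rng <- boltzmann_range(pot, kBT)
  qs <- seq(rng[1], rng[2], length.out = 4096)
  w <- exp(-(pot$U(qs) - min(pot$U(qs))) / kBT)
  cdf <- cumsum(w) / sum(w)
  stats::approx(cdf, qs, xout = stats::runif(n), rule = 2, ties = "ordered")$y
}

# A range over which the Boltzmann weight is non-negligible.
boltzmann_range <- function(pot, kBT) {
  if (pot$kind == "flat") return(c(-1, 1))
  if (pot$kind == "harmonic") {
    s <- sqrt(kBT / pot$K)
    return(pot$q_folded + c(-8, 8) * s)
  }
  if (is.finite(pot$range[1])) {
    lo <- pot$range[1]; hi <- pot$range[2]
  } else {
    lo <- min(pot$q_folded, pot$q_unfolded); hi <- max(pot$q_folded, pot$q_unfolded)
    lo <- lo - (hi - lo); hi <- hi + (hi - lo)
  }
  # shrink to where U - Umin <= 30 kBT
  qs <- seq(lo, hi, length.out = 4096)
  u <- pot$U(qs); u <- u - min(u)
  ok <- which(u <= 30 * kBT)
  c(qs[min(ok)], qs[max(ok)])
}

force_args <- function(pot) {
  fs <- pot$force_spec
  if (is.null(fs)) {
    rng <- pot$range
    if (!all(is.finite(rng))) rng <- c(-10, 10)
    fine <- seq(rng[1], rng[2], length.out = 2048)
    fs <- list(type = 1L, q = fine, dU = pot$dU(fine))
  }
  list(type = fs$type,
       coef = if (fs$type == 0L) fs$dU_coef else numeric(0),
       qg = if (fs$type == 1L) fs$q else numeric(0),
       dUg = if (fs$type == 1L) fs$dU else numeric(0))
}

guards <- function(pot, kBT) {
  if (pot$kind == "flat") return(c(-Inf, Inf))  # free diffusion is unbounded
  rng <- boltzmann_range(pot, kBT)
  w <- diff(rng)
  c(rng[1] - 25 * w, rng[2] + 25 * w)
}

burn_steps_for <- function(spec, tau_max = NULL) {
  if (!is.null(spec$burn_in)) return(round(spec$burn_in / spec$dt))
  if (!is.null(tau_max)) return(round(10 * tau_max / spec$dt))
  100L
}

finish_traj <- function(res, spec, meta) {
  trajectory(res$q, delta = spec$delta, dt = spec$dt, seed = spec$seed,
             v = res[["v"]], meta = meta)
}

# ---- simulators ------------------------------------------------------------

#' Simulate the GLE with multiexponential memory
#'
#' Integrates the Markovian embedding of the generalized Langevin equation
#' \deqn{m\ddot q = -\nabla U(q) - \int_0^t \Gamma(t-s)\,\dot q(s)\,ds + F_R(t)}
#' with a splitting scheme (velocity half-kicks and position half-drifts
#' around an exact Ornstein-Uhlenbeck update of the auxiliary coordinates).
#' Initial conditions are drawn from equilibrium: `q(0)` Boltzmann in `U`,
#' `v(0)` Maxwell, auxiliaries from their conditional stationary
#' distribution given `q(0)`; a burn-in (default 10 times the longest
#' memory time) is discarded.
#'
#' @param system an `embedded_system` (from [embed_kernel()]) or a
#'   [memory_kernel()].
#' @param potential a `potential_model`.
#' @param spec a [system_spec()].
#' @param record_v record velocities alongside positions.
#' @return A [trajectory()] sampled at `spec$delta`.
#' @export
simulate_gle <- function(system, potential, spec, record_v = FALSE) {
  if (inherits(system, "memory_kernel")) system <- embed_kernel(system)
  stopifnot(inherits(system, "embedded_system"),
            inherits(potential, "potential_model"),
            inherits(spec, "system_spec"))
  ker <- system$kernel
  set.seed(spec$seed)
  q0 <- sample_boltzmann(potential, spec$kBT)
  v0 <- stats::rnorm(1, 0, sqrt(spec$kBT / spec$mass))
  z0 <- q0 + stats::rnorm(ker$n, 0, sqrt(spec$kBT / system$k))
  fa <- force_args(potential)
  g <- guards(potential, spec$kBT)
  res <- sim_gle_cpp(spec$mass, spec$kBT, ker$gamma, ker$tau, spec$dt,
                     q0, v0, z0, spec$n_steps, spec$sub,
                     burn_steps_for(spec, max(ker$tau)),
                     fa$type, fa$coef, fa$qg, fa$dUg, g[1], g[2], record_v)
  finish_traj(res, spec, list(model = "gle", gamma = ker$gamma, tau = ker$tau,
                              mass = spec$mass, kBT = spec$kBT,
                              potential = potential$kind))
}

#' Simulate Markovian Langevin dynamics with constant friction
#'
#' Underdamped Langevin dynamics with instantaneous friction
#' \eqn{\Gamma(t) = 2\gamma_{tot}\delta(t)}, integrated with BAOAB.  For a
#' flat potential the MSD crosses from ballistic to Brownian diffusion
#' around \eqn{\tau_m = m/\gamma_{tot}}.
#'
#' @param gamma_tot total friction coefficient (> 0).
#' @inheritParams simulate_gle
#' @return A [trajectory()].
#' @export
simulate_markovian <- function(gamma_tot, potential, spec, record_v = FALSE) {
  stopifnot(gamma_tot > 0, inherits(potential, "potential_model"),
            inherits(spec, "system_spec"))
  set.seed(spec$seed)
  q0 <- sample_boltzmann(potential, spec$kBT)
  v0 <- stats::rnorm(1, 0, sqrt(spec$kBT / spec$mass))
  fa <- force_args(potential)
  g <- guards(potential, spec$kBT)
  res <- sim_markovian_cpp(spec$mass, spec$kBT, gamma_tot, spec$dt, q0, v0,
                           spec$n_steps, spec$sub,
                           burn_steps_for(spec, 10 * spec$mass / gamma_tot),
                           fa$type, fa$coef, fa$qg, fa$dUg, g[1], g[2], record_v)
  finish_traj(res, spec, list(model = "markovian", gamma_tot = gamma_tot,
                              mass = spec$mass, kBT = spec$kBT,
                              potential = potential$kind))
}

#' Simulate overdamped Langevin dynamics with coordinate-dependent friction
#'
#' Integrates
#' \deqn{\dot q = -U'(q)/\gamma(q) - k_BT\,\gamma'(q)/\gamma(q)^2
#'       + \sqrt{2k_BT/\gamma(q)}\,\xi(t) \quad (\textrm{Ito})}
#' with the Milstein correction.  The spurious-drift term makes the
#' stationary density exactly Boltzmann in `U(q)` regardless of
#' \eqn{\gamma(q)}.
#'
#' @param profile a [friction_profile()] (or positive scalar for constant
#'   friction).
#' @inheritParams simulate_gle
#' @return A [trajectory()].
#' @export
simulate_overdamped_qdep <- function(profile, potential, spec) {
  if (is.numeric(profile) && length(profile) == 1L)
    profile <- friction_profile(c(-1e6, 1e6), rep(profile, 2))
  stopifnot(inherits(profile, "friction_profile"),
            inherits(potential, "potential_model"),
            inherits(spec, "system_spec"))
  set.seed(spec$seed)
  q0 <- sample_boltzmann(potential, spec$kBT)
  fa <- force_args(potential)
  g <- guards(potential, spec$kBT)
  relax <- max(profile$gamma) / max(1e-12, if (!is.null(potential$K)) potential$K else 1)
  qs <- sim_qdep_over_cpp(spec$kBT, spec$dt, q0, spec$n_steps, spec$sub,
                          burn_steps_for(spec, relax / 10),
                          fa$type, fa$coef, fa$qg, fa$dUg,
                          profile$q, profile$gamma, g[1], g[2])
  trajectory(qs, delta = spec$delta, dt = spec$dt, seed = spec$seed,
             meta = list(model = "overdamped_qdep", kBT = spec$kBT,
                         potential = potential$kind))
}

#' Simulate inertial Langevin dynamics with coordinate-dependent friction
#'
#' As [simulate_overdamped_qdep()] but with the inertial term \eqn{m\ddot q}
#' retained: \eqn{m\dot v = -U'(q) - \gamma(q) v + \sqrt{2k_BT\gamma(q)}\xi}.
#' The stationary density is Boltzmann in `(q, v)`.
#'
#' @inheritParams simulate_overdamped_qdep
#' @inheritParams simulate_gle
#' @return A [trajectory()].
#' @export
simulate_inertial_qdep <- function(profile, potential, spec, record_v = FALSE) {
  if (is.numeric(profile) && length(profile) == 1L)
    profile <- friction_profile(c(-1e6, 1e6), rep(profile, 2))
  stopifnot(inherits(profile, "friction_profile"),
            inherits(potential, "potential_model"),
            inherits(spec, "system_spec"))
  set.seed(spec$seed)
  q0 <- sample_boltzmann(potential, spec$kBT)
  v0 <- stats::rnorm(1, 0, sqrt(spec$kBT / spec$mass))
  fa <- force_args(potential)
  g <- guards(potential, spec$kBT)
  res <- sim_qdep_inertial_cpp(spec$mass, spec$kBT, spec$dt, q0, v0,
                               spec$n_steps, spec$sub,
                               burn_steps_for(spec,
                                              10 * spec$mass / min(profile$gamma)),
                               fa$type, fa$coef, fa$qg, fa$dUg,
                               profile$q, profile$gamma, g[1], g[2], record_v)
  finish_traj(res, spec, list(model = "inertial_qdep", mass = spec$mass,
                              kBT = spec$kBT, potential = potential$kind))
}

#' Generate a seeded reference dataset
#'
#' Convenience front end of the synthetic-data layer: simulates the chosen
#' model and attaches all generating parameters as metadata, so that the
#' downstream extraction / fitting / observable stages can be exercised
#' without any external data.
#'
#' @param spec a [system_spec()] (carries the seed).
#' @param potential a `potential_model`.
#' @param kernel a [memory_kernel()] (GLE model), or `NULL` with
#'   `model = "markovian"` and `gamma_tot` given.
#' @param model one of `"gle"`, `"markovian"`.
#' @param gamma_tot total friction for the Markovian model.
#' @return A [trajectory()] with full generating metadata.
#' @export
generate_dataset <- function(spec, potential, kernel = NULL,
                             model = c("gle", "markovian"), gamma_tot = NULL) {
  model <- match.arg(model)
  tr <- switch(model,
    gle = simulate_gle(kernel, potential, spec),
    markovian = simulate_markovian(
      if (is.null(gamma_tot)) gamma_tot(kernel) else gamma_tot, potential, spec))
  tr$meta$spec <- spec
  tr
}
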