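#' Free-energy profile by Boltzmann inversion
#'
#' Histograms the trajectory and inverts the density,
#' \eqn{U(q) = -k_BT \ln p(q)}, shifting the minimum to zero.  Empty
#' interior bins are masked; minima and the barrier are located on the
#' smoothed (spline) profile and `U0`/`L` reported when two wells are
#' found.
#'
#' @param traj a [trajectory()] or numeric samples.
#' @param bins number of histogram bins (default 50 over the 0.5th-99.5th
#'   percentile range).
#' @param kBT thermal energy.
#' @param min_count minimum occupancy for a bin to be used.
#' @return A `potential_model` of kind `"tabulated"` (with `U0` and `L` set
#'   when a double well is detected); attribute `"grid"` holds the bin
#'   centres and raw `U` values.
#' @export
estimate_free_energy <- function(traj, bins = 50, kBT = 1, min_count = 5) {
  q <- if (inherits(traj, "trajectory")) traj$q else as.numeric(traj)
  rng <- stats::quantile(q, c(0.005, 0.995), names = FALSE)
  br <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- graphics::hist(q[q >= rng[1] & q <= rng[2]], breaks = br, plot = FALSE)
  keep <- h$counts >= min_count
  if (sum(keep) < 2) stop("fewer than 2 occupied bins")
  centre <- h$mids[keep]
  dens <- h$counts[keep] / sum(h$counts) / diff(br)[1]
  U <- -kBT * log(dens)
  U <- U - min(U)
  pot <- make_tabulated(centre, U)
  attr(pot, "grid") <- data.frame(q = centre, U = U, count = h$counts[keep])
  pot
}

#' Mean squared displacement of a trajectory
#'
#' Time-origin-averaged MSD \eqn{C_{MSD}(t) = \langle (q(0)-q(t))^2\rangle}
#' on a log-spaced lag grid, with block standard errors (contiguous blocks
#' of time origins).  For confined equilibrium dynamics the curve
#' saturates at `2 Var(q)`.
#'
#' @param traj a [trajectory()].
#' @param lag_grid lag times; default log-spaced, 15 points per decade from
#'   `delta` to a quarter of the trajectory length.
#' @param n_blocks number of blocks for standard errors.
#' @return An `msd_curve` data.frame: `lag`, `msd`, `se`, `alpha` (local
#'   exponent, filled by [local_exponent()]).
#' @export
compute_msd <- function(traj, lag_grid = NULL, n_blocks = 10) {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$q)
  if (is.null(lag_grid)) {
    t_lo <- traj$delta
    t_hi <- n * traj$delta / 4
    lag_grid <- exp(seq(log(t_lo), log(t_hi),
                        length.out = max(5, ceiling(log10(t_hi / t_lo) * 15))))
  }
  if (length(lag_grid) == 0) stop("empty lag grid")
  ks <- unique(pmax(1L, as.integer(round(lag_grid / traj$delta))))
  ks <- ks[ks < n]
  res <- msd_lags_cpp(traj$q, ks, as.integer(n_blocks))
  out <- data.frame(lag = ks * traj$delta, msd = res$msd, se = res$se,
                    alpha = NA_real_)
  out$alpha <- local_exponent_vals(out$lag, out$msd)
  structure(out, class = c("msd_curve", "data.frame"))
}

local_exponent_vals <- function(lag, msd) {
  ok <- msd > 0
  a <- rep(NA_real_, length(lag))
  if (sum(ok) >= 3)
    a[ok] <- local_slope(log(lag[ok]), log(msd[ok]))
  a
}

#' Local (time-dependent) MSD exponent
#'
#' \eqn{\alpha(t) = d\ln C_{MSD}(t) / d\ln t} by centred finite differences
#' on the log-spaced grid (one-sided at the endpoints).
#'
#' @param msd an `msd_curve` (data.frame with `lag` and `msd`).
#' @return the curve with its `alpha` column (re)computed.
#' @export
local_exponent <- function(msd) {
  if (nrow(msd) < 3) stop("need at least 3 grid points")
  if (any(msd$msd <= 0 & msd$lag > 0))
    stop("non-positive MSD values in range")
  msd$alpha <- local_exponent_vals(msd$lag, msd$msd)
  msd
}

#' Logarithmic time average of the local exponent
#'
#' Unweighted mean of \eqn{\alpha(t)} over exponentially spaced time points
#' in `[t_lo, t_hi]` (the subdiffusive window, typically
#' \eqn{\tau_1 < t < \tau_n}), the estimator behind the measured
#' subdiffusive exponent.
#'
#' @param msd an `msd_curve` with `alpha` filled.
#' @param t_lo,t_hi averaging window.
#' @param points_per_decade spacing of the averaging points.
#' @return list with `alpha_sub` (mean) and `spread` (standard deviation
#'   over the window points).
#' @export
log_time_average <- function(msd, t_lo, t_hi, points_per_decade = 10) {
  ok <- is.finite(msd$alpha)
  lag <- msd$lag[ok]; a <- msd$alpha[ok]
  t_lo <- max(t_lo, min(lag)); t_hi <- min(t_hi, max(lag))
  if (!(t_hi > t_lo)) stop("empty averaging window")
  np <- ceiling(log10(t_hi / t_lo) * points_per_decade)
  if (np < 1) stop("window narrower than the grid spacing")
  tp <- exp(seq(log(t_lo), log(t_hi), length.out = np + 1))
  av <- stats::approx(log(lag), a, xout = log(tp), rule = 2)$y
  list(alpha_sub = mean(av), spread = stats::sd(av))
}

#' Mean first-passage times from first-first-passage events
#'
#' Renewal bookkeeping: the scan locates the first crossing of the start
#' position `q_S`; from that start event the first subsequent arrival at
#' each target `q_F` is recorded; once the farthest target has been
#' reached the scan restarts.  Each start event therefore contributes
#' exactly one passage time per target, giving (nearly) independent events
#' suitable for standard errors.
#'
#' Passage times are measured on the sampled path, which misses
#' within-interval excursions and therefore carries an O(sqrt(Delta)) late
#' bias for nearby targets.  When a local diffusivity `D(q)` is available,
#' the standard continuity correction (barrier shift by
#' `0.5826 sqrt(2 D(q_F) Delta)`) removes the leading-order bias.
#'
#' @param traj a [trajectory()].
#' @param q_S starting position (must be visited).
#' @param q_F_grid target positions, all on one side of `q_S` (the
#'   direction defines folding vs unfolding).
#' @param diffusivity optional function `D(q)` (RC units^2 / time) used for
#'   the discrete-sampling continuity correction; `NULL` (default) applies
#'   no correction.
#' @return An `mfpt_profile` data.frame: `q_F`, `mfpt`, `n_events`
#'   (targets never reached get `NA`, not zero), with attributes `q_S` and
#'   `direction`.
#' @export
compute_mfpt <- function(traj, q_S, q_F_grid, diffusivity = NULL) {
  stopifnot(inherits(traj, "trajectory"), length(q_F_grid) >= 1)
  rel <- q_F_grid - q_S
  if (any(rel > 0) && any(rel < 0))
    stop("all targets must lie on one side of q_S")
  s <- if (any(rel < 0)) -1 else 1
  o <- order(abs(rel))
  u <- abs(rel)[o]
  if (!is.null(diffusivity)) {
    shift <- 0.5826 * sqrt(2 * diffusivity(q_F_grid[o]) * traj$delta)
    u <- pmax(0, u - shift)
  }
  y <- s * (traj$q - q_S)
  if (max(y) < 0 || min(y) > 0 || max(y) < max(u))
    if (max(y) < 0 || min(y) > 0)
      stop("trajectory never visits q_S")
  res <- mfpt_scan_cpp(y, u)
  mfpt <- ifelse(res$count > 0, res$sum / res$count * traj$delta, NA_real_)
  out <- data.frame(q_F = q_F_grid[o], mfpt = mfpt, n_events = res$count)
  out <- out[order(match(out$q_F, q_F_grid)), ]
  rownames(out) <- NULL
  structure(out, class = c("mfpt_profile", "data.frame"),
            q_S = q_S, direction = if (s > 0) "up" else "down",
            delta = traj$delta)
}

#' Analytic MFPT for overdamped Markovian dynamics
#'
#' Exact mean first-passage time for the overdamped Langevin equation with
#' coordinate-dependent friction \eqn{\gamma(q)} on the landscape `U(q)`
#' with a reflecting boundary at `q_ref` on the far side of `q_S`:
#' \deqn{\tau(q_S \to q_F) = \frac{1}{k_BT} \int_{q_S}^{q_F} dq\,
#'   \gamma(q)\, e^{U(q)/k_BT} \int_{q_{ref}}^{q} dq'\, e^{-U(q')/k_BT},}
#' handled for both directions.
#'
#' @param profile a [friction_profile()] or positive scalar.
#' @param potential a `potential_model`.
#' @param q_S,q_F start and target positions (distinct).
#' @param q_ref reflecting boundary, on the opposite side of `q_S` from
#'   `q_F`.
#' @param kBT thermal energy.
#' @param n_grid quadrature resolution.
#' @return numeric MFPT.
#' @export
analytic_mfpt_markovian <- function(profile, potential, q_S, q_F, q_ref,
                                    kBT = 1, n_grid = 4001) {
  if (is.numeric(profile) && length(profile) == 1L)
    profile <- friction_profile(c(-1e6, 1e6), rep(profile, 2))
  if (q_S == q_F) return(0)
  dir_up <- q_F > q_S
  if ((dir_up && q_ref > q_S) || (!dir_up && q_ref < q_S))
    stop("reflecting boundary must lie on the far side of q_S from q_F")
  Ufun <- function(q) potential$U(q)
  gfun <- profile$fun
  if (!dir_up) {
    # mirror q -> -q so the passage is always upward
    Ufun <- function(q) potential$U(-q)
    gfun <- function(q) profile$fun(-q)
    q_S <- -q_S; q_F <- -q_F; q_ref <- -q_ref
  }
  x <- seq(q_ref, q_F, length.out = n_grid)
  Ux <- Ufun(x); gx <- gfun(x)
  if (any(gx <= 0)) stop("non-positive friction on the integration range")
  Umin <- min(Ux)
  inner <- cumtrap(exp(-(Ux - Umin) / kBT), x[2] - x[1])  # int_{q_ref}^{x}
  integrand <- gx * exp((Ux - Umin) / kBT) * inner
  iS <- which.min(abs(x - q_S))
  seg <- iS:n_grid
  sum((integrand[seg][-1] + integrand[seg][-length(seg)]) / 2 *
        diff(x[seg])) / kBT
}

#' Invert an MFPT profile to coordinate-dependent friction
#'
#' For overdamped Markovian dynamics the MFPT profile determines the
#' friction:
#' \deqn{\gamma(q) = k_BT\, \frac{d\tau/dq_F\; e^{-U(q)/k_BT}}
#'       {\int_{q_{ref}}^{q} e^{-U(q')/k_BT}\, dq'}.}
#' The raw profile is smoothed (Savitzky-Golay, local quadratic) and made
#' monotone by isotonic projection before differencing; a warning is
#' emitted when the monotonicity correction exceeds 5%.
#'
#' @param mfpt an `mfpt_profile` from [compute_mfpt()].
#' @param potential a `potential_model`.
#' @param q_ref reflecting boundary used for the Boltzmann integral.
#' @param kBT thermal energy.
#' @param sg_window Savitzky-Golay window (odd; default 7 or shorter).
#' @return A [friction_profile()] on the (interior of the) target grid,
#'   with `counts` carrying the event counts.
#' @export
invert_mfpt_to_friction <- function(mfpt, potential, q_ref, kBT = 1,
                                    sg_window = 7) {
  stopifnot(inherits(mfpt, "mfpt_profile"))
  ok <- is.finite(mfpt$mfpt)
  qf <- mfpt$q_F[ok]; tau <- mfpt$mfpt[ok]; cnt <- mfpt$n_events[ok]
  if (length(qf) < 5) stop("too few finite MFPT values to invert")
  q_S <- attr(mfpt, "q_S")
  s <- if (attr(mfpt, "direction") == "up") 1 else -1
  u <- s * (qf - q_S)            # distance in the travel direction
  o <- order(u); u <- u[o]; tau <- tau[o]; qf <- qf[o]; cnt <- cnt[o]
  # isotonic projection (tau must be non-decreasing in distance)
  iso <- stats::isoreg(u, tau)$yf
  corr <- mean(abs(iso - tau)) / max(mean(tau), .Machine$double.eps)
  if (corr > 0.05)
    warning(sprintf("isotonic correction of the MFPT profile is %.1f%%", 100 * corr))
  tau <- iso
  dtau_du <- local_quad_deriv(u, tau, half_window = max(2L, (sg_window - 1L) %/% 2L))
  # Boltzmann integral from q_ref to each target
  fine <- seq(q_ref, qf[length(qf)], length.out = 4001)
  Uf <- potential$U(fine); Uf <- Uf - min(Uf)
  # magnitude of the integral: 'fine' runs against the axis when the
  # passage direction is downward
  B <- abs(cumtrap(exp(-Uf / kBT), fine[2] - fine[1]))
  Bq <- stats::approx(fine, B, xout = qf, rule = 2)$y
  Uq <- potential$U(qf) - min(Uf)
  gam <- kBT * dtau_du * exp(-Uq / kBT) / Bq
  if (any(Bq <= 0)) stop("vanishing Boltzmann integral")
  keep <- is.finite(gam) & gam > 0
  if (sum(keep) < 2) stop("inversion produced no positive friction values")
  oq <- order(qf[keep])
  friction_profile(qf[keep][oq], gam[keep][oq], counts = cnt[keep][oq])
}

# Savitzky-Golay-style smoothed derivative: local quadratic fit around each
# grid point (window clipped one-sided at the edges), evaluated at the point.
local_quad_deriv <- function(x, y, half_window = 3L) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half_window):min(n, i + half_window)
    xc <- x[j] - x[i]
    fit <- stats::lm.fit(cbind(1, xc, xc^2), y[j])
    out[i] <- fit$coefficients[2]
  }
  out
}

#' Average coordinate-dependent friction profiles
#'
#' Pointwise (count-weighted, when event counts are available) mean of
#' several friction profiles on a common grid — the averaging over
#' starting positions used to build a single consensus profile.
#'
#' @param profiles list of [friction_profile()]s on a common grid.
#' @return A [friction_profile()].
#' @export
average_friction_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  q0 <- profiles[[1]]$q
  for (p in profiles)
    if (length(p$q) != length(q0) || any(abs(p$q - q0) > 1e-8 * max(abs(q0), 1)))
      stop("profiles are not on a common grid")
  G <- vapply(profiles, function(p) p$gamma, numeric(length(q0)))
  W <- vapply(profiles, function(p)
    if (!is.null(p$counts)) as.numeric(p$counts) else rep(1, length(q0)),
    numeric(length(q0)))
  if (length(profiles) == 1L) return(profiles[[1]])
  gbar <- rowSums(G * W) / rowSums(W)
  friction_profile(q0, gbar, counts = rowSums(W))
}
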