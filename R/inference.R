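#' Estimate the effective mass of a reaction coordinate
#'
#' By the equipartition analog `m = kBT / <qdot^2>`, with velocities from
#' central differences `v_k = (q_{k+1} - q_{k-1}) / (2 delta)`.  Finite
#' sampling attenuates velocities, so the estimate is only meaningful when
#' `delta` is small compared to the shortest memory time; a warning is
#' emitted when the trajectory is too short to say anything.
#'
#' @param traj a [trajectory()].
#' @param kBT thermal energy.
#' @return numeric mass estimate.
#' @export
estimate_mass <- function(traj, kBT = 1) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$q) < 3) stop("need at least 3 samples for velocities")
  v <- central_velocity(traj$q, traj$delta)
  v2 <- mean(v^2)
  if (!(v2 > 0)) stop("zero velocity variance: constant trajectory")
  kBT / v2
}

central_velocity <- function(q, delta) {
  n <- length(q)
  (q[3:n] - q[1:(n - 2)]) / (2 * delta)
}

# Raw (uncentred) cross moments c_k = mean(a_j b_{j+k}) for k = 0..L via FFT.
fft_cross <- function(a, b, L) {
  n <- length(a)
  m <- stats::nextn(n + L + 1, 2)
  ap <- c(a, numeric(m - n)); bp <- c(b, numeric(m - n))
  cc <- Re(stats::fft(Conj(stats::fft(ap)) * stats::fft(bp), inverse = TRUE)) / m
  cc[1:(L + 1)] / (n - 0:L)
}

#' Correlation functions for memory-kernel extraction
#'
#' Computes the velocity autocorrelation
#' \eqn{C^{vv}(t) = \langle \dot q(0)\dot q(t)\rangle}, the force-velocity
#' correlation \eqn{C^{\nabla U v}(t) = \langle \nabla U(q(t))\,\dot q(0)\rangle}
#' (the orientation for which the forward Volterra recursion of
#' [extract_G()] is exact) and its running (trapezoidal) integral
#' \eqn{I^{Uv}(t)} from a discrete
#' trajectory, as time averages over all valid origins.  Velocities use
#' central differences; the potential gradient is evaluated with the model's
#' `dU` (which may come from a histogram-estimated profile).
#'
#' @param traj a [trajectory()].
#' @param potential a `potential_model` (its `dU` supplies the force); the
#'   flat potential gives identically zero force correlations.
#' @param max_lag largest lag, in time units (must be below the trajectory
#'   length).
#' @param kBT thermal energy (for the mass estimate).
#' @return A `correlation_set`: `lag`, `cvv`, `cuv`, `iuv`, `mass`, `kBT`,
#'   `delta`.
#' @export
compute_correlations <- function(traj, potential, max_lag, kBT = 1) {
  stopifnot(inherits(traj, "trajectory"),
            inherits(potential, "potential_model"))
  L <- floor(max_lag / traj$delta)
  v <- central_velocity(traj$q, traj$delta)
  if (L >= length(v)) stop("max_lag exceeds the trajectory length")
  n <- length(traj$q)
  du <- potential$dU(traj$q[2:(n - 1)])     # aligned with the velocity support
  cvv <- fft_cross(v, v, L)
  if (all(du == 0)) {
    cuv <- numeric(L + 1)
  } else {
    cuv <- fft_cross(v, du, L)   # <grad U(q(t)) qdot(0)>
  }
  iuv <- cumtrap(cuv, traj$delta)
  m <- kBT / cvv[1]
  structure(list(lag = (0:L) * traj$delta, cvv = cvv, cuv = cuv, iuv = iuv,
                 mass = m, kBT = kBT, delta = traj$delta),
            class = "correlation_set")
}

cumtrap <- function(y, h) {
  n <- length(y)
  if (n == 1) return(0)
  c(0, cumsum((y[-1] + y[-n]) / 2 * h))
}

#' Extract the running friction integral G(t) by Volterra inversion
#'
#' Solves the Volterra equation of the first kind relating the memory
#' kernel to trajectory correlation functions,
#' \deqn{m\,[C^{vv}(0) - C^{vv}(t)] = I^{Uv}(t) + \int_0^t G(t-s)\,C^{vv}(s)\,ds,}
#' for `G` on the lag grid by forward substitution under trapezoidal
#' quadrature, with `G(0) = 0`.  The total friction is estimated as the
#' mean of `G` over the final window (last decade of lags by default).
#'
#' @param corr a `correlation_set` from [compute_correlations()] or
#'   [analytic_correlations()].
#' @param kBT thermal energy (consistency only; the mass in `corr` is used).
#' @param plateau_window fraction of the lag axis (from the end, in log
#'   time) used for the plateau estimate; default the last decade.
#' @return A `friction_integral_curve`: `lag`, `G`, `gamma_tot` (plateau),
#'   plus the differentiated kernel `Gamma` on midpoints.
#' @export
extract_G <- function(corr, kBT = corr$kBT, plateau_window = NULL) {
  stopifnot(inherits(corr, "correlation_set"))
  if (!(corr$cvv[1] > 0)) stop("Cvv(0) must be positive")
  G <- volterra_G_cpp(corr$cvv, corr$iuv, corr$mass, corr$delta)
  lag <- corr$lag
  if (is.null(plateau_window)) {
    t_hi <- max(lag)
    idx <- which(lag >= t_hi / 10)
  } else {
    idx <- which(lag >= (1 - plateau_window) * max(lag))
  }
  gt <- mean(G[idx])
  Gam <- diff(G) / corr$delta
  structure(list(lag = lag, G = G, gamma_tot = gt,
                 lag_mid = (lag[-1] + lag[-length(lag)]) / 2, Gamma = Gam),
            class = "friction_integral_curve")
}

#' @export
print.friction_integral_curve <- function(x, ...) {
  cat(sprintf("friction_integral_curve: %d lags up to %g, plateau gamma_tot = %g\n",
              length(x$lag), max(x$lag), x$gamma_tot))
  invisible(x)
}

#' Fit a multiexponential memory kernel to an extracted G(t)
#'
#' Least-squares fit of
#' \eqn{G_{fit}(t) = \sum_{i=1}^n \gamma_i (1 - e^{-t/\tau_i})}
#' on a log-spaced lag subgrid with relative-error weighting (so every
#' decade counts equally), multi-start initialization with trial \eqn{\tau_i}
#' ladders spread across the resolved range, and optimization in log
#' parameters.  Fitting `G` rather than its derivative suppresses the
#' noise that differentiation would amplify.  If two fitted times collapse
#' (within 10%), the fit is re-run with `n - 1` components and a warning is
#' emitted.
#'
#' @param curve a `friction_integral_curve` from [extract_G()] (or a list
#'   with `lag` and `G`).
#' @param n number of exponential components (>= 1).
#' @param t_min,t_max fitted lag range; defaults to `[delta, max(lag)]`.
#' @param n_starts number of multi-start initializations.
#' @param points_per_decade subgrid resolution.
#' @return A [memory_kernel()] with attributes `residual` (relative RMS)
#'   and `fit_n` (components actually used).
#' @export
fit_multiexponential <- function(curve, n, t_min = NULL, t_max = NULL,
                                 n_starts = 8, points_per_decade = 25) {
  stopifnot(n >= 1)
  lag <- curve$lag; G <- curve$G
  pos <- which(lag > 0 & is.finite(G) & G > 0)
  lag <- lag[pos]; G <- G[pos]
  if (is.null(t_min)) t_min <- min(lag)
  if (is.null(t_max)) t_max <- max(lag)
  sel <- lag >= t_min & lag <= t_max
  lag <- lag[sel]; G <- G[sel]
  if (length(lag) < 2 * n + 1) stop("too few points in the fitted range")
  # log-spaced subgrid (unique indices)
  nsub <- max(2 * n + 2, ceiling(log10(t_max / t_min) * points_per_decade))
  tg <- exp(seq(log(min(lag)), log(max(lag)), length.out = nsub))
  idx <- unique(vapply(tg, function(t) which.min(abs(lag - t)), integer(1)))
  tt <- lag[idx]; gg <- G[idx]
  resfun <- function(p) {
    gam <- exp(p[1:n]); tau <- exp(p[(n + 1):(2 * n)])
    fit <- vapply(tt, function(t) sum(gam * (1 - exp(-t / tau))), numeric(1))
    (fit - gg) / gg
  }
  plateau <- max(gg)
  best <- NULL
  lo <- log(min(tt) / 3); hi <- log(max(tt))
  starts <- list()
  for (s in seq_len(n_starts)) {
    # tau ladders of varying span and shift across the resolved range
    span <- (hi - lo) * (0.4 + 0.6 * ((s - 1) %% 4) / 3)
    off <- lo + (hi - lo - span) * (((s - 1) %/% 4) / max(1, ceiling(n_starts / 4) - 1))
    ltau <- if (n == 1) (lo + hi) / 2 else off + span * (seq_len(n) - 1) / (n - 1)
    # gamma start: increments of G across the tau ladder
    Gt <- stats::approx(log(tt), gg, xout = pmin(pmax(ltau, log(min(tt))),
                                                 log(max(tt))), rule = 2)$y
    g0 <- pmax(diff(c(0, Gt)), plateau * 1e-3)
    starts[[s]] <- c(log(g0), ltau)
  }
  for (p0 in starts) {
    fit <- try(minpack.lm::nls.lm(p0, fn = resfun,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200, ftol = 1e-14)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    val <- sum(fit$fvec^2)
    if (is.null(best) || val < best$val) best <- list(par = fit$par, val = val)
  }
  if (is.null(best)) stop("multiexponential fit failed to converge")
  best$value <- best$val / length(tt)
  gam <- exp(best$par[1:n]); tau <- exp(best$par[(n + 1):(2 * n)])
  o <- order(tau); gam <- gam[o]; tau <- tau[o]
  if (n > 1 && any(tau[-1] / tau[-n] < 1.1)) {
    warning(sprintf("fit collapse: two memory times within 10%%; refitting with n = %d",
                    n - 1))
    return(fit_multiexponential(curve, n - 1, t_min, t_max, n_starts,
                                points_per_decade))
  }
  out <- memory_kernel(gam, tau)
  attr(out, "residual") <- sqrt(best$value)
  attr(out, "fit_n") <- n
  out
}
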