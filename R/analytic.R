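#' Exact MSD and correlation functions for the embedded linear GLE
#'
#' For a multiexponential kernel the GLE in a flat (`K = 0`) or harmonic
#' (`K > 0`) potential is a linear stochastic system over
#' `(q, v, z_1..z_n)`.  Its correlation functions follow from the matrix
#' exponential of the drift matrix acting on the stationary covariance;
#' the MSD is then obtained in closed form through the eigendecomposition,
#' \eqn{C_{MSD}(t) = 2\sum_j a_j (e^{\lambda_j t} - 1 - \lambda_j t)/\lambda_j^2}
#' in the free case.  These curves are exact for exponential kernels and
#' serve as the oracle against which the simulators and extractors are
#' validated.
#'
#' @name analytic_theory
#' @keywords internal
NULL

# Drift matrix and noise covariance of the embedded linear system, in the
# shifted coordinates x = (q, v, zt_1..zt_n) with zt_i = z_i - q (the q row
# is dropped when K = 0, where the dynamics of (v, zt) are autonomous).
# Returns A, D (noise covariance), and the stationary covariance S0, which
# is diagonal by Boltzmann statistics of the quadratic energy.
linear_gle_system <- function(kernel, mass, kBT = 1, K = 0) {
  stopifnot(K >= 0, mass > 0, kBT > 0)
  k <- kernel$gamma / kernel$tau
  n <- kernel$n
  if (K > 0) {
    dim <- n + 2
    A <- matrix(0, dim, dim)
    A[1, 2] <- 1                                  # qdot = v
    A[2, 1] <- -K / mass                          # vdot = -K q / m + sum k zt / m
    A[2, 3:dim] <- k / mass
    for (i in seq_len(n)) {
      A[2 + i, 2] <- -1                           # zt_i' = -zt_i/tau_i - v + noise
      A[2 + i, 2 + i] <- -1 / kernel$tau[i]
    }
    D <- diag(c(0, 0, 2 * kBT / kernel$gamma), dim)
    S0 <- diag(c(kBT / K, kBT / mass, kBT / k), dim)
    idx <- list(q = 1L, v = 2L, z = 2L + seq_len(n))
  } else {
    dim <- n + 1
    A <- matrix(0, dim, dim)
    A[1, 2:dim] <- k / mass
    for (i in seq_len(n)) {
      A[1 + i, 1] <- -1
      A[1 + i, 1 + i] <- -1 / kernel$tau[i]
    }
    D <- diag(c(0, 2 * kBT / kernel$gamma), dim)
    S0 <- diag(c(kBT / mass, kBT / k), dim)
    idx <- list(q = NA_integer_, v = 1L, z = 1L + seq_len(n))
  }
  structure(list(A = A, D = D, S0 = S0, idx = idx, K = K, mass = mass,
                 kBT = kBT, kernel = kernel),
            class = "linear_gle_system")
}

#' Residual of the stationary Lyapunov identity
#'
#' The stationary covariance of the embedded linear system must satisfy
#' `A S0 + S0 A' + D = 0`.  Returns the relative Frobenius residual, which
#' should be at machine precision for any valid system.
#'
#' @param sys a system from `linear_gle_system` (internal) or a
#'   [memory_kernel()] plus `mass`, `kBT`, `K`.
#' @param mass,kBT,K system parameters when `sys` is a kernel.
#' @return numeric scalar relative residual.
#' @export
lyapunov_residual <- function(sys, mass = 1, kBT = 1, K = 0) {
  if (inherits(sys, "memory_kernel"))
    sys <- linear_gle_system(sys, mass, kBT, K)
  R <- sys$A %*% sys$S0 + sys$S0 %*% t(sys$A) + sys$D
  norm(R, "F") / max(norm(sys$D, "F"), norm(sys$S0, "F"))
}

# exp(x) - 1 - x, accurate for small |x| (complex-safe)
cexpm1m <- function(x) {
  out <- exp(x) - 1 - x
  small <- Mod(x) < 1e-3
  if (any(small)) {
    xs <- x[small]
    out[small] <- xs^2 / 2 * (1 + xs / 3 + xs^2 / 12 + xs^3 / 60 + xs^4 / 360)
  }
  out
}

# exp(x) - 1, accurate for small |x| (complex-safe)
cexpm1 <- function(x) {
  out <- exp(x) - 1
  small <- Mod(x) < 1e-4
  if (any(small)) {
    xs <- x[small]
    out[small] <- xs * (1 + xs / 2 + xs^2 / 6 + xs^3 / 24)
  }
  out
}

# Modal decomposition of C_ab(t) = [exp(At) S0]_{ab}: returns lambda_j and
# weights w_j so that C_ab(t) = sum_j w_j exp(lambda_j t).
modal_weights <- function(sys, a, b) {
  e <- eigen(sys$A)
  P <- e$vectors
  w <- P[a, ] * solve(P, sys$S0[, b])
  list(lambda = e$values, w = w)
}

#' Analytic MSD of the GLE with multiexponential memory
#'
#' Exact mean squared displacement
#' \eqn{C_{MSD}(t) = \langle (q(0)-q(t))^2 \rangle} for the GLE with kernel
#' `kernel` in a flat (`K = 0`) or harmonic (`K > 0`) potential, computed
#' from the embedded linear system:
#' the velocity autocorrelation is a sum of modes
#' \eqn{C^{vv}(t) = \sum_j a_j e^{\lambda_j t}} and
#' \eqn{C_{MSD}(t) = 2\sum_j a_j(e^{\lambda_j t}-1-\lambda_j t)/\lambda_j^2}.
#' The local exponent \eqn{\alpha(t) = d\ln C_{MSD}/d\ln t} is evaluated
#' from the closed-form derivative, not by finite differences.
#'
#' @param kernel a [memory_kernel()].
#' @param mass effective mass; `mass = 0` selects the overdamped (massless)
#'   GLE, whose response spectrum is real (no inertial ringing).
#' @param kBT thermal energy.
#' @param K harmonic stiffness (>= 0; 0 = free case).
#' @param t_grid lag times; default log-spaced, 20 points per decade over
#'   `[tau_m/1e3, 1e3 * tau_n]` (`[tau_1/1e3, ...]` when massless).
#' @return An `msd_curve` data.frame with columns `lag`, `msd`, `alpha`,
#'   and `se` (zero: the curve is exact).
#' @examples
#' k <- make_hierarchical_kernel(1, 1, 3, c = 12, d = 2.7)
#' msd <- analytic_msd(k, mass = 1e-3 * gamma_tot(k))
#' @export
analytic_msd <- function(kernel, mass, kBT = 1, K = 0, t_grid = NULL) {
  if (mass == 0) return(analytic_msd_massless(kernel, kBT, K, t_grid))
  sys <- linear_gle_system(kernel, mass, kBT, K)
  if (K > 0) {
    ev <- eigen(sys$A, only.values = TRUE)$values
    if (any(Re(ev) >= 0))
      stop("drift matrix is not Hurwitz: invalid kernel parameters")
  }
  if (is.null(t_grid)) {
    tau_m <- mass / gamma_tot(kernel)
    t_lo <- tau_m / 1e3
    t_hi <- 1e3 * max(kernel$tau)
    t_grid <- exp(seq(log(t_lo), log(t_hi),
                      length.out = ceiling(log10(t_hi / t_lo) * 20)))
  }
  stopifnot(all(t_grid > 0))
  mw <- modal_weights(sys, sys$idx$v, sys$idx$v)
  lam <- mw$lambda; w <- mw$w
  # enforce exact equipartition of the mode sum (removes rounding drift)
  w <- w * (kBT / mass) / sum(w)
  msd <- alpha <- numeric(length(t_grid))
  for (i in seq_along(t_grid)) {
    x <- lam * t_grid[i]
    m_i <- 2 * sum(w * cexpm1m(x) / lam^2)
    d_i <- 2 * sum(w * cexpm1(x) / lam)        # dC/dt
    msd[i] <- Re(m_i)
    alpha[i] <- Re(d_i) * t_grid[i] / Re(m_i)
  }
  structure(data.frame(lag = t_grid, msd = msd, alpha = alpha, se = 0),
            class = c("msd_curve", "data.frame"),
            K = K, mass = mass, kBT = kBT)
}

# Massless (overdamped) free/harmonic GLE MSD by exact partial fractions.
# With Gamma~(s) = sum_i gamma_i/(1 + tau_i s) = N(s)/D(s), the free MSD is
# C~(s) = 2 kBT D(s) / (s^2 N(s)): a linear-in-t part plus a Prony series
# over the (real, negative) roots of N; the harmonic case has
# C~qq(s) = Var(q) N(s) / (s N(s) + K D(s)).
analytic_msd_massless <- function(kernel, kBT = 1, K = 0, t_grid = NULL) {
  gam <- kernel$gamma; tau <- kernel$tau; n <- kernel$n
  if (is.null(t_grid)) {
    t_lo <- min(tau) / 1e3; t_hi <- 1e3 * max(tau)
    t_grid <- exp(seq(log(t_lo), log(t_hi),
                      length.out = ceiling(log10(t_hi / t_lo) * 20)))
  }
  stopifnot(all(t_grid > 0))
  # polynomial coefficients (ascending) of D = prod(1 + tau_i s)
  polymul <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1)
    for (i in seq_along(a)) out[i:(i + length(b) - 1)] <-
        out[i:(i + length(b) - 1)] + a[i] * b
    out
  }
  D <- 1
  for (i in seq_len(n)) D <- polymul(D, c(1, tau[i]))
  N <- numeric(n)  # degree n-1
  for (i in seq_len(n)) {
    Pi <- gam[i]
    for (j in seq_len(n)) if (j != i) Pi <- polymul(Pi, c(1, tau[j]))
    N <- N + c(Pi, numeric(n - length(Pi)))
  }
  polyval <- function(p, x) {
    s <- 0
    for (i in rev(seq_along(p))) s <- s * x + p[i]
    s
  }
  dpoly <- function(p) p[-1] * seq_len(length(p) - 1)
  if (K == 0) {
    # C(t)/2kBT = t/N(0) + B + sum_r c_r e^{s_r t}; residues of D/(s^2 N)
    r <- polyroot(N)
    r <- Re(r)  # interlacing real roots of a Stieltjes function
    cr <- vapply(r, function(s0)
      polyval(D, s0) / (s0^2 * polyval(dpoly(N), s0)), numeric(1))
    A <- 1 / N[1]                                   # slope: 1/Gamma~(0)=1/gamma_tot
    # constant term from the s -> 0 expansion of D/N; note C(0+) = B + sum(cr)
    # = 2kBT/sum(k_i) > 0: the massless curve jumps instantaneously to the
    # elastic response against the memory springs
    B <- (sum(tau) * N[1] - N[2]) / N[1]^2
    msd <- vapply(t_grid, function(t)
      2 * kBT * (A * t + B + sum(cr * exp(r * t))), numeric(1))
    dmsd <- vapply(t_grid, function(t)
      2 * kBT * (A + sum(cr * r * exp(r * t))), numeric(1))
  } else {
    varq <- kBT / K
    den <- c(0, N) + K * D                          # s N(s) + K D(s), degree n
    r <- Re(polyroot(den))
    cr <- vapply(r, function(s0)
      polyval(N, s0) / polyval(dpoly(den), s0), numeric(1))
    msd <- vapply(t_grid, function(t)
      2 * (varq - varq * sum(cr * exp(r * t))), numeric(1))
    dmsd <- vapply(t_grid, function(t)
      -2 * varq * sum(cr * r * exp(r * t)), numeric(1))
  }
  structure(data.frame(lag = t_grid, msd = msd, alpha = dmsd * t_grid / msd,
                       se = 0),
            class = c("msd_curve", "data.frame"),
            K = K, mass = 0, kBT = kBT)
}

#' Analytic correlation functions of the embedded GLE in a harmonic well
#'
#' Exact velocity autocorrelation \eqn{C^{vv}(t)}, force-velocity
#' correlation \eqn{C^{\nabla U v}(t) = K\,C^{qv}(t)} and its running
#' integral \eqn{I^{Uv}(t) = K(C^{qq}(t) - C^{qq}(0))}, evaluated on a
#' uniform lag grid.  These feed the Volterra extraction as a quadrature
#' oracle that isolates discretization error from estimator noise.
#'
#' @inheritParams analytic_msd
#' @param K harmonic stiffness (> 0 required so the force term is defined;
#'   `K = 0` returns zero force correlations).
#' @param delta lag spacing.
#' @param n_lags number of lags (grid `0, delta, ..., (n_lags-1)*delta`).
#' @return A `correlation_set` list: `lag`, `cvv`, `cuv`, `iuv`, `mass`,
#'   `kBT`, `delta`.
#' @export
analytic_correlations <- function(kernel, mass, kBT = 1, K, delta, n_lags) {
  sys <- linear_gle_system(kernel, mass, kBT, K)
  lag <- (seq_len(n_lags) - 1) * delta
  mv <- modal_weights(sys, sys$idx$v, sys$idx$v)
  cvv <- vapply(lag, function(t) Re(sum(mv$w * exp(mv$lambda * t))), numeric(1))
  if (K > 0) {
    # C^{grad U, v}(t) = K <q(t) v(0)> (the orientation for which the forward
    # Volterra recursion holds); its running integral is K [Cqq(0) - Cqq(t)]
    mqv <- modal_weights(sys, sys$idx$q, sys$idx$v)
    mqq <- modal_weights(sys, sys$idx$q, sys$idx$q)
    cuv <- vapply(lag, function(t) K * Re(sum(mqv$w * exp(mqv$lambda * t))),
                  numeric(1))
    iuv <- vapply(lag, function(t) -K * Re(sum(mqq$w * cexpm1(mqq$lambda * t))),
                  numeric(1))
  } else {
    cuv <- iuv <- numeric(n_lags)
  }
  structure(list(lag = lag, cvv = cvv, cuv = cuv, iuv = iuv,
                 mass = mass, kBT = kBT, delta = delta),
            class = "correlation_set")
}

#' Harmonic stiffness matched to a trajectory
#'
#' `K = kBT / Var(q)`: the stiffness of the harmonic potential that
#' reproduces the positional variance of the data, used to build the
#' harmonic analytic MSD that captures confined double-well dynamics.
#'
#' @param traj a [trajectory()] or numeric vector of samples.
#' @param kBT thermal energy.
#' @return numeric stiffness.
#' @export
harmonic_stiffness <- function(traj, kBT = 1) {
  q <- if (inherits(traj, "trajectory")) traj$q else as.numeric(traj)
  v <- stats::var(q)
  if (!(v > 0)) stop("degenerate (zero-variance) trajectory")
  kBT / v
}

#' Limiting MSD exponents at the grid extremes
#'
#' Evaluates the local exponent of an (analytic) MSD curve at its shortest
#' and longest lag.  For the free GLE these limits are the ballistic
#' exponent 2 (t << tau_m) and the Brownian exponent 1 (t >> tau_n); in a
#' confining potential the long-time exponent tends to 0.
#'
#' @param msd an `msd_curve` (with `alpha` column).
#' @param tau_m inertial time; the grid must extend below it.
#' @param tau_n longest memory time; the grid must extend beyond it.
#' @return list with `alpha_short`, `alpha_long`.
#' @export
limiting_exponents <- function(msd, tau_m, tau_n) {
  if (min(msd$lag) > tau_m / 10 || max(msd$lag) < 10 * tau_n)
    stop("t grid must span t << tau_m and t >> tau_n")
  list(alpha_short = msd$alpha[1], alpha_long = msd$alpha[nrow(msd)])
}

#' Oscillation amplitude of an MSD curve
#'
#' Quantifies short-time ringing of the MSD on the log-log scale as the
#' total variation of the local exponent alpha(t) in a window, minus the
#' net monotone change: zero for a monotone alpha(t), positive when the
#' curve oscillates.  Used to show that extrapolating a shorter hierarchy
#' component damps the inertial ringing.
#'
#' @param msd an `msd_curve`.
#' @param t_lo,t_hi window of lags.
#' @return numeric oscillation amplitude (total variation minus net drift
#'   of alpha).
#' @export
msd_oscillation_amplitude <- function(msd, t_lo, t_hi) {
  i <- which(msd$lag >= t_lo & msd$lag <= t_hi)
  if (length(i) < 3) stop("window contains fewer than 3 grid points")
  a <- msd$alpha[i]
  sum(abs(diff(a))) - abs(a[length(a)] - a[1])
}
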