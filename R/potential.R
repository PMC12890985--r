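#' Free-energy landscape objects
#'
#' A `potential_model` bundles the free energy `U(q)` (in kBT units), its
#' gradient, and the landmark positions of a (possibly double-well) profile:
#' the folded and unfolded minima, the barrier top, the barrier height `U0`
#' above the global minimum, and the distance `L` between the unfolded
#' minimum and the barrier.
#'
#' @name potential_model
#' @keywords internal
NULL

new_potential <- function(U, dU, kind, q_folded = NA_real_, q_unfolded = NA_real_,
                          q_barrier = NA_real_, U0 = NA_real_, L = NA_real_,
                          K = NULL, force_spec = NULL, range = c(-Inf, Inf)) {
  structure(list(U = U, dU = dU, kind = kind,
                 q_folded = q_folded, q_unfolded = q_unfolded,
                 q_barrier = q_barrier, U0 = U0, L = L, K = K,
                 force_spec = force_spec, range = range),
            class = "potential_model")
}

#' @export
print.potential_model <- function(x, ...) {
  cat(sprintf("potential_model (%s)", x$kind))
  if (is.finite(x$U0))
    cat(sprintf(": U0 = %.4g kBT, minima at %.4g / %.4g, barrier at %.4g, L = %.4g",
                x$U0, x$q_unfolded, x$q_folded, x$q_barrier, x$L))
  if (!is.null(x$K)) cat(sprintf(", K = %.4g", x$K))
  cat("\n")
  invisible(x)
}

#' Quartic double-well free-energy profile
#'
#' The minimal smooth two-minimum landscape: a quartic polynomial with minima
#' exactly at `q_unfolded` and `q_folded`, barrier height `U0` (kBT) above
#' the global minimum, and well-depth difference `asymmetry`
#' (`U(q_unfolded) - U(q_folded)`, kBT).  The global minimum is shifted to
#' zero.
#'
#' @param U0 barrier height above the global minimum, kBT (> 0).
#' @param q_unfolded,q_folded positions of the two minima (distinct).
#' @param asymmetry well-depth difference `U(q_unfolded) - U(q_folded)` in
#'   kBT; 0 gives a symmetric well.  Must satisfy `|asymmetry| < U0`.
#' @return A `potential_model` with the barrier position, `U0`, and
#'   `L = |q_barrier - q_unfolded|` filled in.
#' @examples
#' pot <- make_double_well(3.2, q_unfolded = 0.3, q_folded = 0.8)
#' pot$U(pot$q_barrier)  # == 3.2
#' @export
make_double_well <- function(U0, q_unfolded = 0.25, q_folded = 0.75,
                             asymmetry = 0) {
  if (!(U0 > 0)) stop("U0 must be positive")
  if (q_unfolded == q_folded) stop("minima must be distinct")
  if (abs(asymmetry) >= U0)
    stop("|asymmetry| must be smaller than the barrier height U0")
  a <- min(q_unfolded, q_folded); b <- max(q_unfolded, q_folded)
  # U'(q) = A (q - a)(q - m0)(q - b): extrema exactly at a, m0, b.
  # Depths above the two minima: D_a = A J1(m0), D_b = A J2(m0) with
  # J1 = int_a^m0 p dq, J2 = -int_m0^b p dq (both > 0 for a < m0 < b, A > 0).
  Jfun <- function(m0) {
    S <- a + m0 + b; P <- a * m0 + a * b + m0 * b; Q <- a * m0 * b
    Uanti <- function(q) q^4 / 4 - S * q^3 / 3 + P * q^2 / 2 - Q * q
    c(J1 = Uanti(m0) - Uanti(a), J2 = Uanti(m0) - Uanti(b))
  }
  # target signed asymmetry in the (a, b) orientation
  s_ab <- if (a == q_unfolded) -asymmetry else asymmetry  # U(b) - U(a)
  g <- function(m0) {
    J <- Jfun(m0)
    (J[["J1"]] - J[["J2"]]) / max(J) - s_ab / U0
  }
  eps <- (b - a) * 1e-9
  m0 <- stats::uniroot(g, lower = a + eps, upper = b - eps, tol = 1e-14)$root
  J <- Jfun(m0)
  A <- U0 / max(J)
  S <- a + m0 + b; P <- a * m0 + a * b + m0 * b; Q <- a * m0 * b
  U_raw <- function(q) A * (q^4 / 4 - S * q^3 / 3 + P * q^2 / 2 - Q * q)
  U_off <- min(U_raw(a), U_raw(b))
  U <- function(q) U_raw(q) - U_off
  dU <- function(q) A * (q - a) * (q - m0) * (q - b)
  # dU polynomial in ascending powers for the compiled integrators
  dU_coef <- A * c(-Q, P, -S, 1)
  new_potential(U, dU, kind = "double_well",
                q_folded = q_folded, q_unfolded = q_unfolded, q_barrier = m0,
                U0 = U0, L = abs(m0 - q_unfolded),
                force_spec = list(type = 0L, dU_coef = dU_coef),
                range = c(a - 5 * (b - a), b + 5 * (b - a)))
}

#' Harmonic free-energy profile
#'
#' `U(q) = K (q - q0)^2 / 2` with stiffness `K` in kBT / length^2.
#'
#' @param K stiffness (> 0), kBT per squared RC unit.
#' @param q0 minimum position.
#' @return A `potential_model` with the `K` field set.
#' @export
make_harmonic <- function(K, q0 = 0) {
  stopifnot(K > 0)
  new_potential(function(q) 0.5 * K * (q - q0)^2,
                function(q) K * (q - q0),
                kind = "harmonic", q_folded = q0, q_unfolded = q0,
                K = K,
                force_spec = list(type = 0L, dU_coef = c(-K * q0, K)))
}

#' Flat (free) potential `U(q) = 0`
#'
#' @return A `potential_model` with zero gradient everywhere.
#' @export
make_flat <- function() {
  new_potential(function(q) rep(0, length(q)), function(q) rep(0, length(q)),
                kind = "flat", force_spec = list(type = 2L))
}

#' Tabulated free-energy profile
#'
#' Accepts an arbitrary sampled profile `U(q)` (kBT) and builds a smooth
#' interpolating model with the gradient from a fitted spline; landmark
#' positions (minima, barrier) are located on the interior of the grid when
#' the profile is double-welled.
#'
#' @param q sorted grid of RC positions.
#' @param U free energy on the grid, kBT.
#' @param locate_landmarks if TRUE, locate the two minima and the
#'   intervening maximum and fill `U0` and `L`.
#' @return A `potential_model` of kind `"tabulated"`.
#' @export
make_tabulated <- function(q, U, locate_landmarks = TRUE) {
  stopifnot(length(q) == length(U), length(q) >= 4, !is.unsorted(q))
  keep <- is.finite(U)
  q <- q[keep]; U <- U[keep]
  sp <- stats::splinefun(q, U, method = "natural")
  Ufun <- function(x) sp(x)
  dUfun <- function(x) sp(x, deriv = 1)
  fine <- seq(min(q), max(q), length.out = max(512L, 4L * length(q)))
  fs <- list(type = 1L, q = fine, dU = dUfun(fine))
  pot <- new_potential(Ufun, dUfun, kind = "tabulated", force_spec = fs,
                       range = range(q))
  if (locate_landmarks) {
    # windowed local minima on the tabulated profile (robust to bin noise)
    n <- length(q)
    w <- max(2L, n %/% 10)
    is_min <- vapply(seq_len(n), function(i) {
      nb <- U[max(1, i - w):min(n, i + w)]
      U[i] <= min(nb) + 1e-12
    }, logical(1))
    mins <- which(is_min)
    # keep one representative per plateau of consecutive indices
    if (length(mins) > 1) mins <- mins[c(TRUE, diff(mins) > 1)]
    if (length(mins) >= 2) {
      o <- mins[order(U[mins])][1:2]
      i1 <- min(o); i2 <- max(o)
      ib <- i1 + which.max(U[i1:i2]) - 1L
      if (ib > i1 && ib < i2) {
        # polish positions on the spline
        m1 <- stats::optimize(Ufun, q[c(max(1, i1 - w), ib)])$minimum
        m2 <- stats::optimize(Ufun, q[c(ib, min(n, i2 + w))])$minimum
        mb <- stats::optimize(function(x) -Ufun(x), c(m1, m2))$minimum
        if (Ufun(m1) <= Ufun(m2)) { qf <- m1; qu <- m2 } else { qf <- m2; qu <- m1 }
        pot$q_folded <- qf; pot$q_unfolded <- qu; pot$q_barrier <- mb
        pot$U0 <- Ufun(mb) - min(Ufun(m1), Ufun(m2))
        pot$L <- abs(mb - qu)
      }
    }
  }
  pot
}
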