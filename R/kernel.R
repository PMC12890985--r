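#' Multiexponential friction memory kernel
#'
#' Represents a friction memory kernel
#' \deqn{\Gamma(t) = \sum_{i=1}^n (\gamma_i/\tau_i)\, e^{-t/\tau_i}}
#' by its friction coefficients `gamma` (units kBT * time / length^2) and
#' memory times `tau` (time), sorted by increasing `tau`.
#'
#' @param gamma numeric vector of positive friction coefficients.
#' @param tau numeric vector of positive memory times, same length as
#'   `gamma`; strictly increasing after sorting.
#' @return An object of class `memory_kernel` with elements `gamma`, `tau`,
#'   and `n`.
#' @examples
#' k <- memory_kernel(gamma = c(1, 2.7, 7.29), tau = c(1, 12, 144))
#' gamma_tot(k)
#' @export
memory_kernel <- function(gamma, tau) {
  if (length(gamma) == 0L) stop("kernel must have at least one component")
  if (length(gamma) != length(tau)) stop("gamma and tau must have equal length")
  if (any(!is.finite(gamma)) || any(!is.finite(tau)))
    stop("kernel parameters must be finite")
  if (any(gamma <= 0)) stop("all gamma_i must be positive")
  if (any(tau <= 0)) stop("all tau_i must be positive")
  o <- order(tau)
  gamma <- as.numeric(gamma[o]); tau <- as.numeric(tau[o])
  if (any(diff(tau) <= 0)) stop("memory times tau_i must be strictly increasing")
  structure(list(gamma = gamma, tau = tau, n = length(gamma)),
            class = "memory_kernel")
}

#' @export
print.memory_kernel <- function(x, ...) {
  cat(sprintf("memory_kernel: %d exponential component(s), gamma_tot = %g\n",
              x$n, gamma_tot(x)))
  print(data.frame(i = seq_len(x$n), gamma = x$gamma, tau = x$tau,
                   k = x$gamma / x$tau))
  invisible(x)
}

#' Build a hierarchical (geometric-ladder) memory kernel
#'
#' Constructs the n-component kernel with memory times
#' \eqn{\tau_i = \tau_1 c^{i-1}} and friction coefficients
#' \eqn{\gamma_i = \gamma_1 d^{i-1}}: the hierarchy that produces an
#' effective finite-range power law \eqn{\Gamma(t) \propto t^{-\alpha}} with
#' \eqn{\alpha = \ln(c/d)/\ln(c)}.
#'
#' @param gamma1 friction coefficient of the fastest component (> 0).
#' @param tau1 shortest memory time (> 0).
#' @param n number of components (>= 1).
#' @param c memory-time ratio (> 1 so that times increase).
#' @param d friction-coefficient ratio (> 0).
#' @return A [memory_kernel()].
#' @examples
#' make_hierarchical_kernel(1, 1, n = 3, c = 12, d = 2.7)
#' @export
make_hierarchical_kernel <- function(gamma1, tau1, n, c, d) {
  stopifnot(gamma1 > 0, tau1 > 0, n >= 1, d > 0)
  if (n > 1 && c <= 1)
    stop("c must exceed 1 so that memory times are strictly increasing")
  i <- seq_len(n) - 1
  memory_kernel(gamma = gamma1 * d^i, tau = tau1 * (if (n == 1) 1 else c)^i)
}

#' Total friction coefficient
#'
#' \eqn{\gamma_{tot} = G(\infty) = \sum_i \gamma_i}, the long-time plateau of
#' the running friction integral.
#'
#' @param kernel a [memory_kernel()].
#' @return numeric scalar.
#' @export
gamma_tot <- function(kernel) sum(kernel$gamma)

#' Evaluate the memory kernel \eqn{\Gamma(t)}
#'
#' @param kernel a [memory_kernel()].
#' @param t numeric vector of times (>= 0).
#' @return \eqn{\Gamma(t)} evaluated at `t`.
#' @export
kernel_gamma <- function(kernel, t) {
  vapply(t, function(ti) sum(kernel$gamma / kernel$tau * exp(-ti / kernel$tau)),
         numeric(1))
}

#' Evaluate the running friction integral \eqn{G(t) = \int_0^t \Gamma(s) ds}
#'
#' For a multiexponential kernel,
#' \eqn{G(t) = \sum_i \gamma_i (1 - e^{-t/\tau_i})}.
#'
#' @inheritParams kernel_gamma
#' @return \eqn{G(t)} evaluated at `t`.
#' @export
kernel_G <- function(kernel, t) {
  vapply(t, function(ti) sum(kernel$gamma * (1 - exp(-ti / kernel$tau))),
         numeric(1))
}

#' Hierarchy ratios of a memory kernel
#'
#' Computes the mean memory-time ratio `c` and mean friction-coefficient
#' ratio `d` as geometric means of the consecutive ratios
#' \eqn{\tau_{i+1}/\tau_i} and \eqn{\gamma_{i+1}/\gamma_i} over the chosen
#' component subset, plus the predicted subdiffusive exponent
#' \eqn{\alpha = \ln(c/d)/\ln(c)}.
#'
#' @param kernel a [memory_kernel()].
#' @param subset integer indices of the components to use (default all).
#' @return An object of class `hierarchy_ratios`: list with `c`, `d`, and
#'   `alpha_sub_pred` (NA when `c <= 1`).
#' @examples
#' k <- make_hierarchical_kernel(1, 1, 3, c = 21, d = 5.3)
#' hierarchy_ratios(k)
#' @export
hierarchy_ratios <- function(kernel, subset = seq_len(kernel$n)) {
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) < 2L)
    stop("at least 2 components are needed to form ratios")
  if (any(subset < 1L) || any(subset > kernel$n))
    stop("subset indices out of range")
  tau <- kernel$tau[subset]; gam <- kernel$gamma[subset]
  c_hat <- exp(mean(log(tau[-1] / tau[-length(tau)])))
  d_hat <- exp(mean(log(gam[-1] / gam[-length(gam)])))
  structure(list(c = c_hat, d = d_hat,
                 alpha_sub_pred = if (c_hat > 1) log(c_hat / d_hat) / log(c_hat) else NA_real_),
            class = "hierarchy_ratios")
}

#' @export
print.hierarchy_ratios <- function(x, ...) {
  cat(sprintf("hierarchy_ratios: c = %.4g, d = %.4g, alpha_sub_pred = %.4g\n",
              x$c, x$d, x$alpha_sub_pred))
  invisible(x)
}

#' Predicted subdiffusive MSD exponent of a hierarchical kernel
#'
#' For memory components spaced by ratios `c` (times) and `d` (friction
#' coefficients) with `c > d` and `d >= 1`, the MSD exhibits intermediate
#' subdiffusive scaling \eqn{C_{MSD}(t) \propto t^{\alpha}} for
#' \eqn{\tau_1 < t < \tau_n} with
#' \deqn{\alpha_{sub} = \ln(c/d) / \ln(c).}
#'
#' @param x a `hierarchy_ratios` object, a [memory_kernel()], or a numeric
#'   ratio `c` (then `d` must be given).
#' @param d friction-coefficient ratio when `x` is the numeric `c`.
#' @param subset component subset used when `x` is a kernel (default all).
#' @return numeric scalar \eqn{\alpha_{sub}}.
#' @examples
#' predict_alpha(14, 5.1)  # protein-G-like ratios -> 0.38
#' @export
predict_alpha <- function(x, d = NULL, subset = NULL) {
  if (inherits(x, "memory_kernel")) {
    if (is.null(subset)) subset <- seq_len(x$n)
    r <- hierarchy_ratios(x, subset)
    cc <- r$c; dd <- r$d
  } else if (inherits(x, "hierarchy_ratios")) {
    cc <- x$c; dd <- x$d
  } else {
    if (is.null(d)) stop("d must be supplied when x is the numeric ratio c")
    cc <- x; dd <- d
  }
  if (cc <= 1) stop("alpha prediction requires c > 1")
  log(cc / dd) / log(cc)
}

#' Extrapolate hierarchical memory components
#'
#' Prepends `n_shorter` components at shorter times
#' (\eqn{\tau_0 = \tau_1/c}, \eqn{\gamma_0 = \gamma_1/d}, recursively) and
#' appends `n_longer` at longer times
#' (\eqn{\tau_{n+1} = \tau_n c}, \eqn{\gamma_{n+1} = \gamma_n d}).  Because
#' `c > 1` and `d > 1` for hierarchical ladders, shorter components carry
#' exponentially smaller friction and leave \eqn{\gamma_{tot}} nearly
#' unchanged, while longer components increase it.
#'
#' @param kernel a [memory_kernel()].
#' @param ratios a `hierarchy_ratios` object (or list with `c` and `d`).
#' @param n_shorter,n_longer numbers of components to add (>= 0).
#' @return A new [memory_kernel()]; attribute `"gamma_tot"` holds the new
#'   total friction.
#' @export
extrapolate_components <- function(kernel, ratios, n_shorter = 0L, n_longer = 0L) {
  stopifnot(n_shorter >= 0, n_longer >= 0)
  cc <- ratios$c; dd <- ratios$d
  gam <- kernel$gamma; tau <- kernel$tau
  if (n_shorter > 0) {
    i <- seq_len(n_shorter)
    gam <- c(rev(gam[1] / dd^i), gam)
    tau <- c(rev(tau[1] / cc^i), tau)
  }
  if (n_longer > 0) {
    i <- seq_len(n_longer)
    gam <- c(gam, gam[length(gam)] * dd^i)
    tau <- c(tau, tau[length(tau)] * cc^i)
  }
  out <- memory_kernel(gam, tau)
  attr(out, "gamma_tot") <- gamma_tot(out)
  out
}

#' Inertial and diffusion timescales
#'
#' \eqn{\tau_m = m/\gamma_{tot}} is the inertial relaxation time and
#' \eqn{\tau_D = \gamma_{tot} L^2 / k_BT} the time to diffuse over the
#' distance `L` (unfolded minimum to barrier top) on a flat landscape.
#' Their ratio quantifies how overdamped the dynamics are; for protein
#' reaction coordinates it is of order 1e-7 or smaller.
#'
#' @param kernel a [memory_kernel()] (or numeric `gamma_tot`).
#' @param mass effective mass `m = kBT / <qdot^2>`.
#' @param L distance between the unfolded minimum and the barrier.
#' @param kBT thermal energy (default 1, reduced units).
#' @return list with `tau_m`, `tau_D`, and `ratio` (= tau_m / tau_D).
#' @export
timescales <- function(kernel, mass, L, kBT = 1) {
  gt <- if (inherits(kernel, "memory_kernel")) gamma_tot(kernel) else as.numeric(kernel)
  stopifnot(gt > 0, mass > 0, L > 0, kBT > 0)
  tau_m <- mass / gt
  tau_D <- gt * L^2 / kBT
  list(tau_m = tau_m, tau_D = tau_D, ratio = tau_m / tau_D)
}

#' Finite power-law range of a multiexponential kernel
#'
#' Measures over how many decades \eqn{\Gamma(t)} follows the hierarchical
#' power law \eqn{t^{-\alpha}} with \eqn{\alpha = \ln(c/d)/\ln(c)}: the
#' longest contiguous time range over which \eqn{\log_{10}\Gamma} stays
#' within `band` decades of the power-law line (offset fitted on
#' \eqn{[\tau_1, \tau_n]} with the slope held at the prediction).  The
#' pointwise log-log slope itself oscillates between the discrete
#' components even for an exact ladder, so adherence to the line, not the
#' local derivative, is the meaningful measure of effective power-law
#' behavior.  For hierarchical ladders the range grows with the number of
#' components.
#'
#' @param kernel a [memory_kernel()].
#' @param band allowed deviation from the power-law line, in decades of
#'   \eqn{\Gamma} (default 0.1).
#' @param points_per_decade resolution of the evaluation grid.
#' @return list with `decades` (length of the longest contiguous in-band
#'   run), `t_lo`, `t_hi` (its endpoints), and `slope_target`.
#' @export
powerlaw_range <- function(kernel, band = 0.1, points_per_decade = 40) {
  if (kernel$n < 2L) stop("power-law range needs >= 2 components")
  target <- -predict_alpha(kernel)
  t_lo <- min(kernel$tau) / 100
  t_hi <- max(kernel$tau) * 100
  nt <- ceiling(log10(t_hi / t_lo) * points_per_decade)
  lt <- seq(log(t_lo), log(t_hi), length.out = nt)
  lg <- log(kernel_gamma(kernel, exp(lt)))
  win <- lt >= log(min(kernel$tau)) & lt <= log(max(kernel$tau))
  a0 <- mean(lg[win] - target * lt[win])          # fitted offset, fixed slope
  ok <- abs(lg - (a0 + target * lt)) <= band * log(10)
  r <- rle(ok)
  if (!any(r$values)) return(list(decades = 0, t_lo = NA, t_hi = NA,
                                  slope_target = target))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- which.max(ifelse(r$values, r$lengths, 0L))
  i0 <- starts[best]; i1 <- ends[best]
  list(decades = (lt[i1] - lt[i0]) / log(10),
       t_lo = exp(lt[i0]), t_hi = exp(lt[i1]), slope_target = target)
}

# centred finite-difference slope on a (possibly non-uniform) grid,
# one-sided at the ends
local_slope <- function(x, y) {
  n <- length(x)
  s <- numeric(n)
  s[1] <- (y[2] - y[1]) / (x[2] - x[1])
  s[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    s[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  s
}
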