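# Shared fixtures and small utilities for the test suite.  Heavier
# simulated fixtures are cached so several tests can reuse one run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# reference lambda-repressor-like ladder
ladder_lambda <- function() make_hierarchical_kernel(1, 1, 3, c = 12, d = 2.7)

# pooled MSD over a list of trajectories (equal lengths)
pooled_msd <- function(trajs, ...) {
  msds <- lapply(trajs, compute_msd, ...)
  out <- msds[[1]]
  out$msd <- rowMeans(vapply(msds, function(m) m$msd, numeric(nrow(out))))
  local_exponent(out)
}

# chi-squared goodness-of-fit of decorrelated samples against the Boltzmann
# density of `pot`; returns the p-value
boltzmann_chisq_p <- function(q, pot, kBT = 1, stride, bins = 20) {
  sub <- q[seq(1, length(q), by = stride)]
  rng <- stats::quantile(q, c(0.005, 0.995), names = FALSE)
  br <- seq(rng[1], rng[2], length.out = bins + 1)
  counts <- graphics::hist(sub[sub >= rng[1] & sub <= rng[2]], breaks = br,
                           plot = FALSE)$counts
  fine <- seq(rng[1], rng[2], length.out = 4001)
  w <- exp(-(pot$U(fine) - min(pot$U(fine))) / kBT)
  cdf <- c(0, cumsum((w[-1] + w[-length(w)]) / 2 * diff(fine)[1]))
  Fb <- stats::approx(fine, cdf / max(cdf), xout = br)$y
  p <- diff(Fb) / (max(Fb) - min(Fb))
  stats::chisq.test(counts, p = p / sum(p))$p.value
}
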