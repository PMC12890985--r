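test_that("mass estimation follows the equipartition analog", {
  tr <- simulate_markovian(1, make_flat(),
                           system_spec(mass = 2, dt = 0.001, delta = 0.001,
                                       n_steps = 2e6, seed = 1))
  m <- estimate_mass(tr)
  expect_lt(abs(m / 2 - 1), 0.05)
  # q -> 2q scales <qdot^2> by 4, so the mass drops fourfold, exactly
  tr2 <- trajectory(2 * tr$q, delta = tr$delta)
  expect_equal(estimate_mass(tr2), m / 4)
  expect_error(estimate_mass(trajectory(rep(1, 100), delta = 1)),
               "constant")
  expect_error(estimate_mass(trajectory(c(1, 2), delta = 1)), "3 samples")
})

test_that("correlation estimators behave on degenerate inputs", {
  set.seed(1)
  wn <- trajectory(rnorm(40000), delta = 1)
  co <- compute_correlations(wn, make_flat(), max_lag = 10)
  # central differences have support of two sampling steps: no correlation
  # survives beyond lag 3
  expect_gt(co$cvv[1], 0)
  expect_lt(max(abs(co$cvv[4:11])), 4 / sqrt(40000))
  expect_equal(co$cuv, rep(0, 11))
  # time reversal leaves the autocorrelation unchanged
  cr <- compute_correlations(trajectory(rev(wn$q), delta = 1), make_flat(),
                             max_lag = 10)
  expect_equal(cr$cvv, co$cvv, tolerance = 1e-12)
  expect_error(compute_correlations(wn, make_flat(), max_lag = 1e6),
               "max_lag")
})

test_that("Volterra inversion recovers G(t) from exact correlations", {
  # analytic correlation input isolates the quadrature error
  k1 <- memory_kernel(2, 1)
  co <- analytic_correlations(k1, mass = 0.5, kBT = 1, K = 3,
                              delta = 0.01, n_lags = 1001)
  G <- extract_G(co)
  expect_equal(G$G[1], 0)
  ref <- 2 * (1 - exp(-G$lag / 1))
  sel <- G$lag > 0 & G$lag <= 10
  expect_lt(max(abs(G$G[sel] - ref[sel])) / max(ref), 0.01)
  # three-component ladder
  k3 <- ladder_lambda()
  co3 <- analytic_correlations(k3, mass = 0.1, kBT = 1, K = 2,
                               delta = 0.02, n_lags = 2000)
  G3 <- extract_G(co3)
  ref3 <- kernel_G(k3, G3$lag)
  expect_lt(max(abs(G3$G[-1] - ref3[-1])) / max(ref3), 0.01)
  expect_error(extract_G(structure(list(cvv = c(-1, 1), iuv = c(0, 0),
                                        lag = c(0, 1), delta = 1, mass = 1,
                                        kBT = 1),
                                   class = "correlation_set")),
               "positive")
})

test_that("Markovian trajectories yield a plateau at gamma_tot", {
  pot <- make_harmonic(5)
  tr <- simulate_markovian(4, pot,
                           system_spec(mass = 0.2, dt = 0.002, delta = 0.002,
                                       n_steps = 4e6, seed = 3))
  G <- extract_G(compute_correlations(tr, pot, max_lag = 2))
  expect_lt(abs(G$gamma_tot / 4 - 1), 0.1)
  # a single-exponential fit collapses onto the plateau with a short time
  fit <- fit_multiexponential(G, 1)
  expect_lt(abs(sum(fit$gamma) / 4 - 1), 0.15)
  expect_lt(fit$tau[1], 10 * tr$delta)
})

test_that("multiexponential fits are exact on noise-free curves", {
  k <- ladder_lambda()
  lag <- 10^seq(-1.5, 3.5, 0.02)
  fit <- fit_multiexponential(list(lag = lag, G = kernel_G(k, lag)), 3)
  expect_equal(fit$gamma, k$gamma, tolerance = 1e-4)
  expect_equal(fit$tau, k$tau, tolerance = 1e-4)
  expect_lt(attr(fit, "residual"), 1e-6)
})

test_that("overfitted components collapse with a warning", {
  k2 <- memory_kernel(c(1, 3), c(1, 30))
  lag <- 10^seq(-1, 3, 0.02)
  expect_warning(fit <- fit_multiexponential(list(lag = lag,
                                                  G = kernel_G(k2, lag)), 3),
                 "collapse")
  expect_lte(fit$n, 2)
  expect_equal(gamma_tot(fit), 4, tolerance = 0.01)
})

test_that("simulate -> extract -> fit round trip recovers a two-component
           ladder", {
  # a faster sibling of the full three-component acceptance round trip
  k <- make_hierarchical_kernel(1, 1, 2, c = 12, d = 2.7)
  m <- 1e-3 * gamma_tot(k)
  Gs <- lapply(1:3, function(s) {
    tr <- simulate_gle(k, make_flat(),
                       system_spec(mass = m, dt = 1 / 50, delta = 1 / 25,
                                   n_steps = round(1500 * 12 * 50), seed = s))
    extract_G(compute_correlations(tr, make_flat(), max_lag = 15 * 12))
  })
  Gm <- Gs[[1]]
  Gm$G <- rowMeans(vapply(Gs, function(g) g$G, numeric(length(Gm$G))))
  fit <- fit_multiexponential(Gm, 2)
  expect_lt(max(abs(fit$gamma / k$gamma - 1)), 0.2)
  expect_lt(max(abs(fit$tau / k$tau - 1)), 0.2)
  # plateau conservation
  expect_lt(abs(sum(fit$gamma) / Gm$gamma_tot - 1), 0.05)
})

test_that("the kernel round trip also holds in a double-well landscape", {
  # soft wells: the Volterra deconvolution in a confining potential is
  # ill-conditioned (the velocity autocorrelation integrates to zero), so
  # longer trajectories and a resolved force channel are needed
  k <- ladder_lambda()
  pot <- make_double_well(1.5, -2, 2)
  Gs <- lapply(1:5, function(s) {
    tr <- simulate_gle(k, pot,
                       system_spec(mass = 0.4, dt = 0.00625, delta = 0.025,
                                   n_steps = round(1400 * 144 / 0.00625),
                                   seed = s))
    extract_G(compute_correlations(tr, pot, max_lag = 3.5 * 144))
  })
  Gm <- Gs[[1]]
  Gm$G <- rowMeans(vapply(Gs, function(g) g$G, numeric(length(Gm$G))))
  fit <- fit_multiexponential(Gm, 3)
  expect_lt(max(abs(fit$gamma / k$gamma - 1)), 0.2)
  expect_lt(max(abs(fit$tau / k$tau - 1)), 0.2)
})
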