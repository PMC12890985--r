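test_that("kernel embedding exposes per-component coupling stiffness", {
  k <- ladder_lambda()
  es <- embed_kernel(k)
  expect_equal(es$k, k$gamma / k$tau)
  expect_equal(es$n, 3L)
  expect_error(embed_kernel(list(gamma = 1)), "memory_kernel")
  expect_error(memory_kernel(numeric(0), numeric(0)))
})

test_that("trajectories are reproducible under a fixed seed", {
  k <- memory_kernel(c(1, 2), c(0.5, 5))
  pot <- make_harmonic(3)
  spec <- system_spec(mass = 0.05, dt = 0.005, delta = 0.01, n_steps = 2e4,
                      seed = 123)
  t1 <- simulate_gle(k, pot, spec)
  t2 <- simulate_gle(k, pot, spec)
  expect_identical(t1$q, t2$q)
  spec2 <- spec; spec2$seed <- 124L
  expect_false(identical(t1$q, simulate_gle(k, pot, spec2)$q))
})

test_that("GLE equilibrium satisfies equipartition in a harmonic well", {
  k <- ladder_lambda()
  tr <- cached("gle_harm", simulate_gle(
    k, make_harmonic(4),
    system_spec(mass = 0.02, dt = 1 / 200, delta = 0.01, n_steps = 6e6,
                seed = 21)))
  # <q^2> = kBT/K within ~3 standard errors of the block estimate
  nb <- 20
  vb <- tapply(tr$q, rep(seq_len(nb), each = ceiling(length(tr$q) / nb))[
    seq_along(tr$q)], var)
  se <- sd(vb) / sqrt(nb)
  expect_lt(abs(var(tr$q) - 0.25), 4 * se + 0.002)
})

test_that("fluctuation-dissipation: simulated Cvv matches the linear-system
           oracle in a harmonic well", {
  k <- ladder_lambda()
  tr <- cached("gle_harm", simulate_gle(
    k, make_harmonic(4),
    system_spec(mass = 0.02, dt = 1 / 200, delta = 0.01, n_steps = 6e6,
                seed = 21)))
  co <- compute_correlations(tr, make_harmonic(4), max_lag = 5)
  ca <- analytic_correlations(k, mass = 0.02, kBT = 1, K = 4,
                              delta = tr$delta, n_lags = length(co$lag))
  sel <- co$lag >= 0.5 & co$lag <= 3    # resolvable window at this delta
  expect_lt(max(abs(co$cvv[sel] - ca$cvv[sel])) / ca$cvv[1], 0.05)
})

test_that("free GLE MSD matches the analytic oracle", {
  k <- make_hierarchical_kernel(1, 1, 3, 14, 5.1)
  m <- 1e-3 * gamma_tot(k)
  tr <- simulate_gle(k, make_flat(),
                     system_spec(mass = m, dt = 1 / 50, delta = 1 / 10,
                                 n_steps = 5e6, seed = 7))
  msd <- compute_msd(tr)
  an <- analytic_msd(k, mass = m, K = 0, t_grid = msd$lag)
  sel <- msd$lag >= m / gamma_tot(k) & msd$lag <= 10 * max(k$tau)
  expect_lt(max(abs(msd$msd[sel] / an$msd[sel] - 1)), 0.05)
})

test_that("Markovian free and harmonic MSDs match closed forms", {
  # free particle: 2 kBT/gamma [t - tau_m (1 - exp(-t/tau_m))]
  spec <- system_spec(mass = 0.5, dt = 0.002, delta = 0.01, n_steps = 5e6,
                      seed = 2)
  tr <- simulate_markovian(2, make_flat(), spec)
  msd <- compute_msd(tr)
  tau_m <- 0.25
  ref <- (msd$lag - tau_m * (1 - exp(-msd$lag / tau_m)))
  sel <- msd$lag <= 30
  expect_true(all(abs(msd$msd[sel] - ref[sel]) <=
                    0.05 * ref[sel] + 4 * msd$se[sel]))
  # exponent reaches 1 well beyond tau_m
  a_late <- log_time_average(msd, 5, 50)$alpha_sub
  expect_equal(a_late, 1, tolerance = 0.05)
  # overdamped harmonic: Ornstein-Uhlenbeck closed form
  tro <- simulate_markovian(5, make_harmonic(2),
                            system_spec(mass = 0.01, dt = 5e-4, delta = 0.01,
                                        n_steps = 6e6, seed = 3))
  msdo <- compute_msd(tro)
  refo <- (1 - exp(-2 * msdo$lag / 5))
  sel <- msdo$lag >= 0.05 & msdo$lag <= 20
  expect_lt(mean(abs(msdo$msd[sel] / refo[sel] - 1)), 0.03)
})

test_that("every simulator leaves the Boltzmann distribution invariant", {
  pot <- make_double_well(1.5, 0.25, 0.75)
  k <- memory_kernel(c(1, 3), c(0.5, 10))
  stride <- 400   # ~20 time units: beyond the well-hopping correlation
  tr1 <- cached("dw_traj", simulate_gle(
    k, pot, system_spec(mass = 0.02, dt = 5e-4, delta = 0.05, n_steps = 4e7,
                        seed = 4)))
  expect_gt(boltzmann_chisq_p(tr1$q, pot, stride = stride), 0.01)
  tr2 <- simulate_markovian(4, pot, system_spec(mass = 0.02, dt = 5e-4,
                                                delta = 0.05, n_steps = 2e7,
                                                seed = 5))
  expect_gt(boltzmann_chisq_p(tr2$q, pot, stride = stride / 2), 0.01)
  prof <- friction_profile(c(0, 1), c(2, 6))
  tr3 <- simulate_inertial_qdep(prof, pot,
                                system_spec(mass = 0.02, dt = 5e-4,
                                            delta = 0.05, n_steps = 2e7,
                                            seed = 6))
  expect_gt(boltzmann_chisq_p(tr3$q, pot, stride = stride / 2), 0.01)
})

test_that("overdamped coordinate-dependent friction: pure diffusion limit", {
  # flat U, constant gamma: MSD = 2 (kBT/gamma) t with alpha = 1 throughout
  tr <- simulate_overdamped_qdep(4, make_flat(),
                                 system_spec(dt = 0.01, delta = 0.05,
                                             n_steps = 4e6, seed = 8))
  msd <- compute_msd(tr)
  sel <- msd$lag <= 100
  expect_lt(max(abs(msd$msd[sel] / (2 * 0.25 * msd$lag[sel]) - 1)), 0.05)
  expect_true(all(abs(msd$alpha[sel][-1] - 1) < 0.1))
})

test_that("inertial coordinate-dependent friction equilibrates velocities", {
  prof <- friction_profile(c(-2, 2), c(3, 3))
  tr <- simulate_inertial_qdep(prof, make_harmonic(2),
                               system_spec(mass = 0.3, dt = 0.002,
                                           delta = 0.01, n_steps = 2e6,
                                           seed = 5),
                               record_v = TRUE)
  expect_equal(mean(tr$v^2), 1 / 0.3, tolerance = 0.05)
  # small-mass limit converges to the overdamped integrator at long lags
  pot <- make_harmonic(2)
  sp <- system_spec(mass = 0.002, dt = 5e-4, delta = 0.05, n_steps = 4e6,
                    seed = 9)
  tri <- simulate_inertial_qdep(prof, pot, sp)
  tro <- simulate_overdamped_qdep(prof, pot,
                                  system_spec(dt = 5e-4, delta = 0.05,
                                              n_steps = 4e6, seed = 10))
  mi <- compute_msd(tri); mo <- compute_msd(tro)
  sel <- mi$lag >= 0.5 & mi$lag <= 10
  expect_lt(max(abs(mi$msd[sel] / mo$msd[sel] - 1)), 0.1)
})

test_that("halving dt does not change equilibrium moments beyond noise", {
  k <- memory_kernel(c(1, 2), c(0.5, 5))
  pot <- make_harmonic(3)
  v <- sapply(c(0.01, 0.005), function(dt) {
    var(simulate_gle(k, pot, system_spec(mass = 0.05, dt = dt, delta = 0.05,
                                         n_steps = round(2e4 / dt),
                                         seed = 31))$q)
  })
  expect_lt(abs(v[1] - v[2]) / (1 / 3), 0.05)
})

test_that("numerical blow-up is reported with the step index", {
  pot <- make_double_well(3, 0, 1)
  spec <- system_spec(mass = 1e-4, dt = 0.05, delta = 0.05, n_steps = 1e5,
                      seed = 1)
  expect_error(simulate_gle(ladder_lambda(), pot, spec), "blow-up.*step")
})
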