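test_that("free-energy estimation inverts known densities", {
  set.seed(11)
  # Gaussian samples: quadratic profile with K = kBT / sigma^2
  x <- rnorm(2e5, sd = 0.1)
  fes <- estimate_free_energy(x)
  g <- attr(fes, "grid")
  Kfit <- lm(g$U ~ I(g$q^2 / 2))$coefficients[2]
  expect_equal(unname(Kfit), 100, tolerance = 0.05)
  # uniform samples: flat profile up to binomial bin noise
  u <- runif(2e5)
  fesu <- estimate_free_energy(u)
  gu <- attr(fesu, "grid")
  expect_lt(max(gu$U) - min(gu$U), 0.15)
  expect_error(estimate_free_energy(rep(1, 1000)), "occupied bins")
})

test_that("double-well free energy is recovered from GLE sampling", {
  pot <- make_double_well(1.5, 0.25, 0.75)
  k <- memory_kernel(c(1, 3), c(0.5, 10))
  tr <- cached("dw_traj", simulate_gle(
    pot = pot, system = k,
    spec = system_spec(mass = 0.02, dt = 5e-4, delta = 0.05, n_steps = 4e7,
                       seed = 4)))
  fes <- estimate_free_energy(tr)
  expect_lt(abs(fes$U0 - 1.5), 0.2)
  expect_equal(fes$q_barrier, pot$q_barrier, tolerance = 0.05)
  expect_equal(sort(c(fes$q_folded, fes$q_unfolded)), c(0.25, 0.75),
               tolerance = 0.05)
})

test_that("MSD of deterministic and equilibrium trajectories", {
  # linear motion: exactly ballistic
  tr <- trajectory(0.3 * (0:5000), delta = 1)
  msd <- compute_msd(tr)
  expect_equal(msd$msd, 0.3^2 * msd$lag^2, tolerance = 1e-12)
  expect_equal(msd$alpha[-c(1, nrow(msd))],
               rep(2, nrow(msd) - 2), tolerance = 1e-9)
  # confined equilibrium: saturation at 2 Var(q)
  trh <- cached("dw_traj", simulate_gle(
    pot = make_double_well(1.5, 0.25, 0.75), system = memory_kernel(c(1, 3), c(0.5, 10)),
    spec = system_spec(mass = 0.02, dt = 5e-4, delta = 0.05, n_steps = 4e7,
                       seed = 4)))
  msdh <- compute_msd(trh)
  tail_val <- mean(msdh$msd[msdh$lag >= max(msdh$lag) / 4])
  expect_lt(abs(tail_val / (2 * var(trh$q)) - 1), 0.1)
  expect_error(compute_msd(trh, lag_grid = numeric(0)), "empty")
})

test_that("local exponent is the log-log derivative", {
  lag <- 10^seq(-1, 3, 0.1)
  msd <- structure(data.frame(lag = lag, msd = 2.7 * lag^0.5, se = 0,
                              alpha = NA_real_),
                   class = c("msd_curve", "data.frame"))
  msd <- local_exponent(msd)
  expect_equal(msd$alpha, rep(0.5, length(lag)), tolerance = 1e-9)
  expect_error(local_exponent(msd[1:2, ]), "3 grid points")
  bad <- msd; bad$msd[5] <- -1
  expect_error(local_exponent(bad), "non-positive")
})

test_that("logarithmic time averaging of the exponent", {
  lag <- 10^seq(-1, 3, 0.05)
  msd <- structure(data.frame(lag = lag, msd = lag^0.41, se = 0,
                              alpha = NA_real_),
                   class = c("msd_curve", "data.frame"))
  msd <- local_exponent(msd)
  lt <- log_time_average(msd, 0.5, 200)
  expect_equal(lt$alpha_sub, 0.41, tolerance = 1e-6)
  expect_lt(lt$spread, 1e-6)
  expect_error(log_time_average(msd, 5000, 10000), "window")
})

test_that("first-first-passage bookkeeping on deterministic input", {
  tr <- trajectory(seq(0, 10, by = 0.01), delta = 0.01)
  mf <- compute_mfpt(tr, q_S = 2, q_F_grid = c(2, 3, 4.5))
  expect_equal(mf$mfpt, c(0, 1, 2.5), tolerance = 1e-9)
  expect_equal(mf$n_events, rep(1L, 3))
  # unreachable target: missing, not zero
  mf2 <- compute_mfpt(tr, 2, c(3, 99))
  expect_true(is.na(mf2$mfpt[mf2$q_F == 99]))
  expect_error(compute_mfpt(tr, 2, c(1, 3)), "one side")
  expect_error(compute_mfpt(tr, -5, 3), "never visits")
})

test_that("analytic Markovian MFPT: flat landscape and additivity", {
  flat <- make_flat()
  # from the reflecting edge over distance L: tau = gamma L^2 / (2 kBT),
  # half the diffusion time gamma L^2 / kBT
  expect_equal(analytic_mfpt_markovian(3, flat, q_S = 0, q_F = 2, q_ref = 0),
               3 * 4 / 2, tolerance = 1e-4)
  # renewal additivity with a fixed reflecting edge
  pot <- make_double_well(2, 0, 1)
  t_ac <- analytic_mfpt_markovian(2, pot, 0.1, 0.9, q_ref = -0.5)
  t_ab <- analytic_mfpt_markovian(2, pot, 0.1, 0.5, q_ref = -0.5)
  t_bc <- analytic_mfpt_markovian(2, pot, 0.5, 0.9, q_ref = -0.5)
  expect_equal(t_ac, t_ab + t_bc, tolerance = 1e-3)
  expect_equal(analytic_mfpt_markovian(2, pot, 0.5, 0.5, q_ref = -0.5), 0)
  expect_error(analytic_mfpt_markovian(2, pot, 0.5, 0.9, q_ref = 2), "far side")
})

test_that("sampled MFPTs agree with the analytic Markovian solution", {
  pot <- make_double_well(2, 0, 1)
  tr <- cached("qdep_const", simulate_overdamped_qdep(
    5, pot, system_spec(dt = 0.001, delta = 0.001, n_steps = 5e7, seed = 1)))
  grid <- seq(0.2, 1, by = 0.1)
  mf <- compute_mfpt(tr, 0, grid, diffusivity = function(q) rep(0.2, length(q)))
  qref <- quantile(tr$q, 1e-5)
  ana <- sapply(grid, function(qf)
    analytic_mfpt_markovian(5, pot, 0, qf, q_ref = qref))
  expect_lt(max(abs(mf$mfpt / ana - 1)), 0.05)
})

test_that("MFPT inversion is exact on analytically generated profiles", {
  pot <- make_double_well(2, 0, 1)
  grid <- seq(0.1, 1.1, by = 0.0125)
  qref <- -0.45
  tau <- sapply(grid, function(qf)
    analytic_mfpt_markovian(3, pot, 0, qf, q_ref = qref))
  mf <- structure(data.frame(q_F = grid, mfpt = tau, n_events = 1000),
                  class = c("mfpt_profile", "data.frame"), q_S = 0,
                  direction = "up", delta = 1e-3)
  inv <- invert_mfpt_to_friction(mf, pot, q_ref = qref, sg_window = 5)
  interior <- inv$q >= 0.15 & inv$q <= 1.0
  expect_lt(max(abs(inv$gamma[interior] / 3 - 1)), 0.02)
})

test_that("friction profiles average pointwise with count weights", {
  p1 <- friction_profile(0:10, rep(1, 11), counts = rep(2, 11))
  p3 <- friction_profile(0:10, rep(3, 11), counts = rep(2, 11))
  expect_equal(average_friction_profiles(list(p1, p1))$gamma, p1$gamma)
  expect_equal(average_friction_profiles(list(p1, p3))$gamma, rep(2, 11))
  # count weighting
  p3w <- friction_profile(0:10, rep(3, 11), counts = rep(6, 11))
  expect_equal(average_friction_profiles(list(p1, p3w))$gamma, rep(2.5, 11))
  expect_error(average_friction_profiles(list(p1, friction_profile(0:5, 1))),
               "common grid")
})

test_that("memory suppresses the mid-window MSD exponent relative to the
           Markovian comparator", {
  k <- ladder_lambda()
  gt <- gamma_tot(k); m <- 1e-3 * gt
  tau_n <- max(k$tau)
  sp <- function(seed) system_spec(mass = m, dt = 1 / 50, delta = 1 / 10,
                                   n_steps = round(500 * tau_n * 50),
                                   seed = seed)
  msd_g <- pooled_msd(lapply(1:2, function(s)
    simulate_gle(k, make_flat(), sp(s))))
  msd_m <- pooled_msd(lapply(1:2, function(s)
    simulate_markovian(gt, make_flat(), sp(10 + s))))
  a_gle <- log_time_average(msd_g, 1, tau_n)$alpha_sub
  a_mar <- log_time_average(msd_m, 1, tau_n)$alpha_sub
  expect_equal(a_mar, 1, tolerance = 0.05)  # memoryless: Brownian in-window
  expect_lt(a_gle, 0.8)                     # hierarchical memory: subdiffusive
})
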