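test_that("drift construction combines advantages and the goal weight", {
  p <- ddm_params(t0 = 0.3, a = 1, md = 1, fd = 1)
  expect_equal(drift_rate(p, trial_covariates(2, -2)), 4)
  expect_equal(drift_rate(p, trial_covariates(2, 2)), 0)
  p2 <- ddm_params(t0 = 0.3, a = 1, md = 1.8, fd = 1.5, gd = 0.31, p = 0.7)
  expect_equal(drift_rate(p2, trial_covariates(1, -2, goal_sign = -1,
                                               condition = "subgoal")),
               0.7 * (1.8 * 1 - 1.5 * (-2)) - 0.31)
  expect_error(trial_covariates(1, 1, goal_sign = 1, condition = "base"),
               "goal_sign")
  expect_error(ddm_params(t0 = 0.3, a = 1, md = 1, fd = 1, z = 0.8, sz = 0.5),
               "inside the bounds")
})

test_that("first-passage densities integrate to the closed-form choice probabilities", {
  # drift-free symmetry: half the mass at each bound
  up <- integrate(function(t) wiener_fpt_density(0, 1, 0, t)[, "upper"],
                  0, Inf, rel.tol = 1e-10)$value
  expect_equal(up, 0.5, tolerance = 1e-7)
  # drifted absorption probability: (1 - e^-1) / (1 - e^-2)
  up2 <- integrate(function(t) wiener_fpt_density(0.5, 1, 0, t)[, "upper"],
                   0, Inf, rel.tol = 1e-10)$value
  expect_equal(up2, (1 - exp(-1)) / (1 - exp(-2)), tolerance = 1e-6)
  expect_equal(up2, prob_upper(0.5, 1, 0), tolerance = 1e-6)
  # conservation across random parameter sets
  set.seed(11)
  for (i in 1:5) {
    d <- runif(1, -2, 2); a <- runif(1, 0.5, 2); z <- runif(1, -0.3, 0.3) * a
    m <- integrate(function(t) rowSums(wiener_fpt_density(d, a, z, t)),
                   0, Inf, rel.tol = 1e-9)$value
    expect_equal(m, 1, tolerance = 1e-6)
    pu <- integrate(function(t) wiener_fpt_density(d, a, z, t)[, "upper"],
                    0, Inf, rel.tol = 1e-9)$value
    expect_equal(pu, prob_upper(d, a, z), tolerance = 1e-6)
  }
  expect_error(wiener_fpt_density(0, 1, 0, c(-1, 1)), "positive")
})

test_that("variability mixing matches brute-force quadrature of the core density", {
  p <- ddm_params(t0 = 0.2, a = 1.1, md = 1, fd = 1, z = 0.1, sz = 0.4,
                  sd = 0.9)
  cov <- trial_covariates(2, -1)
  d <- drift_rate(p, cov)
  ts <- c(0.5, 0.9, 1.6, 3.0)
  got <- defective_density(p, cov, 1, ts)
  # oracle: direct double numerical integration over the start uniform and
  # the drift normal
  oracle <- sapply(ts, function(t) {
    integrate(function(x0) sapply(x0, function(x0i) {
      integrate(function(v) sapply(v, function(vi)
        wiener_fpt_density(vi, p$a, x0i, t - p$t0)[, "upper"]) *
          dnorm(v, d, p$sd), d - 6 * p$sd, d + 6 * p$sd,
        rel.tol = 1e-9)$value
    }) / p$sz, p$z - p$sz / 2, p$z + p$sz / 2, rel.tol = 1e-8)$value
  })
  expect_equal(got, oracle, tolerance = 1e-5)
  # degenerate mixing: sz = sd = 0 reduces to the core density
  p0 <- ddm_params(t0 = 0.2, a = 1.1, md = 1, fd = 1, z = 0.1)
  expect_equal(defective_density(p0, cov, 1, ts),
               as.numeric(wiener_fpt_density(d, p0$a, p0$z, ts - p0$t0)[, "upper"]))
  # symmetric mixing preserves the upper/lower symmetry at zero drift
  ps <- ddm_params(t0 = 0.2, a = 1, md = 1, fd = 1, sd = 0.8)
  cov0 <- trial_covariates(1, 1)
  expect_equal(defective_density(ps, cov0, 1, ts),
               defective_density(ps, cov0, -1, ts))
})

test_that("defective mass is conserved and the floor keeps the likelihood finite", {
  set.seed(21)
  for (i in 1:4) {
    p <- ddm_params(t0 = runif(1, 0, 0.4), a = runif(1, 0.7, 1.8),
                    md = 1, fd = 1, z = runif(1, -0.2, 0.2),
                    sz = runif(1, 0, 0.5), sd = runif(1, 0, 1.2))
    cov <- trial_covariates(sample(1:3, 1), -sample(1:3, 1) + 0)
    grid <- seq(p$t0 + 1e-5, p$t0 + 40, length.out = 20000)
    h <- diff(grid)[1]
    mass <- sum(defective_density(p, cov, 1, grid) +
                  defective_density(p, cov, -1, grid)) * h
    expect_equal(mass, 1, tolerance = 1e-4)
  }
  # rt at or below t0 gets the floor, not zero
  p <- ddm_params(t0 = 0.3, a = 1, md = 1, fd = 1)
  expect_equal(defective_density(p, trial_covariates(1, -1), 1, 0.1), 1e-10)
  dat <- data.frame(mAdv = 1, fAdv = 1, goal_sign = 0, condition = "base",
                    choice = 1L, rt = 0.1)
  expect_true(is.finite(ddm_loglik(p, dat)))
  expect_equal(ddm_loglik(p, dat[0, ]), 0)
})

test_that("monotonicity and sign symmetry of the choice probability", {
  ds <- seq(-2, 2, by = 0.5)
  pu <- sapply(ds, prob_upper, a = 1.2, z = 0)
  expect_true(all(diff(pu) > 0))
  zs <- seq(-0.8, 0.8, by = 0.2)
  pz <- sapply(zs, function(z) prob_upper(0.4, 1.2, z))
  expect_true(all(diff(pz) > 0))
  for (d in c(-1, 0.3, 2))
    for (z in c(-0.3, 0, 0.4))
      expect_equal(prob_upper(d, 1.2, z), 1 - prob_upper(-d, 1.2, -z))
})

test_that("the simulator agrees with the density (choice fractions and RT distribution)", {
  p <- ddm_params(t0 = 0.3, a = 1.2, md = 1, fd = 1, sz = 0.3, sd = 0.6)
  cov <- trial_covariates(2, -1)
  n <- 2e4
  sim <- ddm_simulate(p, cov, n = n, rng_seed = 5)
  expect_true(all(sim$choice[!sim$censored] %in% c(-1, 1)))
  p_up <- integrate(function(t) defective_density(p, cov, 1, t),
                    p$t0, p$t0 + 50, rel.tol = 1e-8)$value
  se <- sqrt(p_up * (1 - p_up) / n)
  expect_lt(abs(mean(sim$choice == 1) - p_up), 3 * se + 0.005)
  expect_lt(ks_distance_sim_density(p, cov, n_paths = n, seed = 9), 0.02)
  # determinism under a fixed seed
  expect_identical(ddm_simulate(p, cov, n = 50, rng_seed = 3),
                   ddm_simulate(p, cov, n = 50, rng_seed = 3))
  # strong drift limit
  pl <- ddm_params(t0 = 0.3, a = 1, md = 5, fd = 1)
  siml <- ddm_simulate(pl, trial_covariates(3, -1), n = 500, rng_seed = 2)
  expect_gt(mean(siml$choice == 1), 0.995)
})

test_that("the log-likelihood peaks near the generating parameters", {
  p <- ddm_params(t0 = 0.3, a = 1.2, md = 1.7, fd = 1.5, sz = 0.3, sd = 0.8)
  covs <- data.frame(mAdv = rep(c(1, 2, 2, 1), 250),
                     fAdv = rep(c(1, 2, 1, 3), 250),
                     goal_sign = 0, condition = "base")
  sim <- ddm_simulate(p, covs, rng_seed = 8)
  dat <- cbind(covs, choice = sim$choice, rt = sim$rt)
  ll_true <- ddm_loglik(p, dat)
  for (perturb in list(c(md = 2.6), c(fd = 0.6), c(a = 1.9), c(t0 = 0.05))) {
    q <- p
    q[[names(perturb)]] <- unname(perturb)
    expect_gt(ll_true, ddm_loglik(q, dat))
  }
})
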