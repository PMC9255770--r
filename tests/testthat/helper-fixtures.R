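# Shared fixtures: all data are generated in code at test time.

# a single designed base layout with the given advantages
base_layout <- function(m, f, experiment = "exp1", orientation = "LR",
                        mirrored = FALSE) {
  mazeddm:::make_base_layout(m, f, experiment, orientation, mirrored)
}

subgoal_layout <- function(m, f, goal_end = "upper", orientation = "LR",
                           mirrored = FALSE) {
  mazeddm:::make_subgoal_layout(m, f, goal_end, orientation, mirrored)
}

# tiny synthetic cohort for pipeline-level tests
tiny_cohort <- function(n = 4L, experiment = "exp1", seed = 7L, ...) {
  cfg <- population_config(experiment, n, rng_seed = seed, ...)
  layouts <- if (experiment == "exp1") enumerate_base_trials("exp1")
             else c(enumerate_base_trials("exp2", "horizontal"),
                    enumerate_subgoal_trials("horizontal"))
  obs <- simulate_experiment(sample_population(cfg), layouts, cfg)
  list(config = cfg, layouts = layouts, obs = obs)
}

# empirical CDF distance between simulated RTs and the density-implied CDF
ks_distance_sim_density <- function(params, cov, n_paths = 2e4, seed = 1) {
  sim <- ddm_simulate(params, cov, n = n_paths, rng_seed = seed)
  sim <- sim[!sim$censored, ]
  grid <- seq(params$t0 + 1e-4, max(sim$rt) + 1, length.out = 4000)
  du <- defective_density(params, cov, 1, grid)
  dl <- defective_density(params, cov, -1, grid)
  h <- diff(grid)[1]
  cdf <- cumsum(du + dl) * h
  emp <- ecdf(sim$rt)(grid)
  max(abs(emp - cdf))
}
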