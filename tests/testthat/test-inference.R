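test_that("the variant lattices have the designed structure", {
  l1 <- make_variant_lattice("exp1")
  expect_length(l1, 8L)
  base <- l1$equal_w
  expect_true(base$equal_weights)
  expect_false(base$free_z)
  expect_equal(base$free_parameter_count, 3L)    # t0, a, shared weight
  winner <- l1$diff_w_var
  expect_setequal(winner$par_names, c("t0", "a", "md", "fd", "sz", "sd"))
  expect_equal(winner$free_parameter_count, 6L)
  l2 <- make_variant_lattice("exp2")
  expect_setequal(names(l2), c("baseline", "gd", "gd_additive",
                               "gd_independent", "gd_proportional",
                               "gd_proportional_t0"))
  expect_true("p" %in% l2$gd_proportional$par_names)
  expect_true(all(c("gd", "p", "t0_sub") %in% l2$gd_proportional_t0$par_names))
  expect_equal(l2$gd_proportional$free_parameter_count, 8L)
})

test_that("folds are reproducible, sized as configured, and shared", {
  ids <- paste0("P", 1:95)
  folds <- make_folds(ids, 10, 35, rng_seed = 2)
  expect_length(folds, 10L)
  for (f in folds) {
    expect_length(f$test, 35L)
    expect_length(f$train, 60L)
    expect_length(intersect(f$train, f$test), 0L)
  }
  expect_identical(folds, make_folds(ids, 10, 35, rng_seed = 2))
  expect_error(make_folds(ids, 5, 95, 1), "smaller than the cohort")
})

test_that("fitting recovers sane estimates and respects optimizer dominance", {
  p <- ddm_params(t0 = 0.3, a = 1.2, md = 1.7, fd = 1.4, sz = 0.3, sd = 0.8)
  covs <- data.frame(mAdv = rep(c(1, 2, 2, 1, 3, 1), 80),
                     fAdv = rep(c(1, 2, 1, 3, 1, 2), 80),
                     goal_sign = 0, condition = "base")
  sim <- ddm_simulate(p, covs, rng_seed = 31)
  dat <- cbind(covs, choice = sim$choice, rt = sim$rt,
               participant_id = "P1")
  variant <- variant_spec("diff_w_var")
  truth <- c(t0 = 0.3, a = 1.2, md = 1.7, fd = 1.4, sz = 0.3, sd = 0.8)
  quad <- ddm_quadrature(15L, 8L)
  fit <- fit_variant(dat, variant, n_starts = 2, rng_seed = 5, init = truth,
                     max_starts = 3, quad = quad,
                     control = list(eval.max = 300, iter.max = 200,
                                    rel.tol = 1e-7))
  # optimizer dominance: the fit is at least as good as the truth
  expect_lte(fit$snll, variant_snll(truth, variant, dat, quad) + 1e-6)
  expect_lt(abs(fit$params[["md"]] - 1.7), 0.5)
  expect_lt(abs(fit$params[["t0"]] - 0.3), 0.1)
  # more starts can only improve the best objective (same seed pool)
  fit1 <- fit_variant(dat, variant, n_starts = 1, rng_seed = 9,
                      max_starts = 1, quad = quad,
                      control = list(eval.max = 150, iter.max = 100,
                                     rel.tol = 1e-6))
  expect_lte(fit$snll, fit1$snll + 0.1)
})

test_that("cross-validation produces one row per fold and variant with shared folds", {
  coh <- tiny_cohort(6, "exp1", seed = 3)
  dat <- make_ddm_data(preprocess_observations(coh$obs, coh$layouts,
                                               "exp1")$data)
  variants <- make_variant_lattice("exp1")[c("equal_w", "diff_w")]
  folds <- make_folds(unique(dat$participant_id), 2, 2, rng_seed = 4)
  tab <- cross_validate(dat, variants, folds, n_starts = 1, rng_seed = 6,
                        max_starts = 1, quad = ddm_quadrature(15L, 8L),
                        control = list(eval.max = 150, iter.max = 100,
                                       rel.tol = 1e-5))
  expect_equal(nrow(tab), 4L)
  expect_setequal(unique(tab$variant), c("equal_w", "diff_w"))
  expect_true(all(is.finite(tab$test_snll)))
  # nested-model sanity: the richer model trains at least as well
  for (f in unique(tab$fold_id)) {
    t_eq <- tab$train_snll[tab$fold_id == f & tab$variant == "equal_w"]
    t_df <- tab$train_snll[tab$fold_id == f & tab$variant == "diff_w"]
    expect_lte(t_df, t_eq + 0.5)   # optimizer tolerance
  }
})

test_that("model comparison picks dominant variants and falls back to parsimony", {
  # dominance: A beats B on every fold by a wide margin
  folds <- 1:20
  tab <- rbind(
    data.frame(fold_id = folds, variant = "A", n_free = 6,
               test_snll = 100 + rnorm(20, 0, 1)),
    data.frame(fold_id = folds, variant = "B", n_free = 5,
               test_snll = 120 + rnorm(20, 0, 1)))
  rep <- compare_models(tab)
  expect_equal(rep$winner, "A")
  expect_equal(rep$rationale, "lower_sNLL")
  expect_true(all(rep$pairwise$p_adj < 0.05))
  # indistinguishable pair: fewer free parameters wins
  set.seed(2)
  noise <- rnorm(20, 0, 1)
  tab2 <- rbind(
    data.frame(fold_id = folds, variant = "rich", n_free = 8,
               test_snll = 100 + noise + rnorm(20, 0, 0.1)),
    data.frame(fold_id = folds, variant = "lean", n_free = 6,
               test_snll = 100 + noise + rnorm(20, 0, 0.1)))
  rep2 <- compare_models(tab2)
  expect_equal(rep2$winner, "lean")
  expect_equal(rep2$rationale, "fewer_params_tie")
})

test_that("fold-blocked paired comparison matches a fold-random-intercept model", {
  skip_if_not_installed("lme4")
  set.seed(14)
  fold_effect <- rnorm(30, 0, 5)
  tab <- rbind(
    data.frame(fold_id = 1:30, variant = "A", n_free = 6,
               test_snll = 200 + fold_effect + rnorm(30, 0, 0.8)),
    data.frame(fold_id = 1:30, variant = "B", n_free = 6,
               test_snll = 200.6 + fold_effect + rnorm(30, 0, 0.8)))
  rep <- compare_models(tab)
  fit <- lme4::lmer(test_snll ~ variant + (1 | fold_id), data = tab,
                    REML = FALSE)
  tstat <- summary(fit)$coefficients["variantB", "t value"]
  p_lmm <- 2 * pt(-abs(tstat), df = 29)
  expect_equal(rep$pairwise$p_raw[1], p_lmm, tolerance = 0.05)
})
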