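test_that("model_spec validates free/fixed bookkeeping", {
  spec <- model_spec()
  expect_length(spec$free, 10)
  expect_error(model_spec(free = "nope"), "unknown")
  expect_error(model_spec(free = setdiff(spec$free, "gamma")), "gamma")
  red <- model_spec(free = setdiff(spec$free, "gamma"),
                    fixed = list(gamma = 0))
  expect_length(red$free, 9)
  expect_error(model_spec(fixed = list(gamma = 0)), "both free and fixed")
})

test_that("predicted tables reproduce the masking pattern", {
  des <- data.frame(
    condition = rep(c("AM", "Flicker"), each = 3),
    orientation_deg = 0, contrast_pct = rep(c(12, 25, 40), 2))
  tab <- predict_pc_table(des, ref$pop, ref$am, ref$epsilon)
  expect_true(all(tab$pc > 0 & tab$pc < 1))
  # suppression at matched orientation: AM strictly below Flicker
  expect_true(all(tab$pc[tab$condition == "AM"] <
                    tab$pc[tab$condition == "Flicker"]))
  # orthogonal target with small AM magnitudes: nearly equal conditions
  am_small <- am_params(alpha = 0.1, beta = 0.1, gamma = 0.3,
                        k_exc_AM = 1.35, k_inh_AM = 1.35)
  des90 <- data.frame(condition = c("AM", "Flicker"),
                      orientation_deg = 90, contrast_pct = 20)
  tab90 <- predict_pc_table(des90, ref$pop, am_small, ref$epsilon)
  expect_equal(tab90$pc[1], tab90$pc[2], tolerance = 0.01)
  # all AM effects zero: AM column identical to Flicker column
  tab0 <- predict_pc_table(des, ref$pop, ref_flicker, ref$epsilon)
  expect_identical(tab0$pc[tab0$condition == "AM"],
                   tab0$pc[tab0$condition == "Flicker"])
})

test_that("the fast likelihood path matches the reference predictions", {
  des <- experiment_design(contrast_levels = c(4, 12, 40),
                           orientation_levels = c(0, 30),
                           trials_per_cell = 40)
  tr <- generate_from_model(des, ref$pop, ref$am, ref$epsilon, seed = 3)
  cells <- pool_observers(tr)
  spec <- model_spec()
  truth <- list(c50 = 9.65, r0 = 4.55, p = 5.52, k_exc = 1.35,
                epsilon = 0.67, alpha = 1.17, beta = 1.51, gamma = 0.644,
                k_exc_AM = 1.35, k_inh_AM = 0.001)
  u <- ampop:::.pop_transformed(c(truth, spec$fixed), spec)
  fast <- ampop:::.pop_negll(u, spec, ampop:::.pop_prep(cells, spec))
  tab <- predict_pc_table(cells, ref$pop, ref$am, ref$epsilon)
  slow <- -sum(cells$n_correct * log(tab$pc) +
                 (cells$n_trials - cells$n_correct) * log(1 - tab$pc))
  expect_equal(fast, slow, tolerance = 1e-10)
})

test_that("likelihood peaks near the generating parameters at large n", {
  # analytic (infinite-n) cells: expected counts at the true model
  cells <- design_cells(experiment_design(trials_per_cell = 5000))
  tab <- predict_pc_table(cells, ref$pop, ref$am, ref$epsilon)
  cells$n_correct <- tab$pc * cells$n_trials # fractional counts are fine
  spec <- model_spec()
  prep <- ampop:::.pop_prep(cells, spec)
  truth <- list(c50 = 9.65, r0 = 4.55, p = 5.52, k_exc = 1.35,
                epsilon = 0.67, alpha = 1.17, beta = 1.51, gamma = 0.644,
                k_exc_AM = 1.35, k_inh_AM = 0.001)
  nll0 <- ampop:::.pop_negll(ampop:::.pop_transformed(c(truth, spec$fixed),
                                                      spec), spec, prep)
  set.seed(57)
  for (i in 1:20) {
    pert <- truth
    for (nm in c("c50", "p", "gamma", "epsilon")) {
      pert[[nm]] <- pert[[nm]] * runif(1, 0.8, 1.2)
    }
    pert <- ampop:::.pop_project(c(pert, spec$fixed), spec)
    nll1 <- ampop:::.pop_negll(
      ampop:::.pop_transformed(pert[c(spec$free, names(spec$fixed))], spec),
      spec, prep)
    expect_gte(nll1, nll0 - 1e-6)
  }
})

test_that("fitting a reduced model on Flicker-only data converges", {
  des <- experiment_design(orientation_levels = c(0, 45),
                           conditions = "Flicker", trials_per_cell = 60)
  tr <- generate_from_model(des, ref$pop, ref_flicker, ref$epsilon,
                            seed = 61)
  cells <- pool_observers(tr)
  spec_fl <- model_spec(
    free = c("c50", "r0", "p", "k_exc", "epsilon"),
    fixed = list(alpha = 0, beta = 0, gamma = 0, k_exc_AM = 1.35,
                 k_inh_AM = 0.001))
  fit <- fit_population_model(cells, spec_fl, n_restarts = 3, seed = 62)
  expect_true(fit$converged)
  expect_equal(fit$n_params, 5)
  expect_equal(fit$aic, 2 * 5 - 2 * fit$loglik)
  # an out-of-bounds starting point is projected inside, not rejected
  fit2 <- fit_population_model(cells, spec_fl, n_restarts = 2, seed = 63,
                               start = list(p = 0.5, epsilon = 1.7,
                                            r0 = 99))
  expect_true(is.finite(fit2$loglik))
})

test_that("popcode_fit methods are coherent", {
  des <- experiment_design(contrast_levels = c(4, 12, 40),
                           orientation_levels = c(0, 90),
                           trials_per_cell = 50)
  tr <- generate_from_model(des, ref$pop, ref$am, ref$epsilon, seed = 71)
  cells <- pool_observers(tr)
  fit <- fit_population_model(cells, model_spec(), n_restarts = 2,
                              seed = 72, n_polish = 1)
  expect_s3_class(fit, "popcode_fit")
  expect_named(coef(fit),
               c("c50", "r0", "p", "k_exc", "epsilon", "alpha", "beta",
                 "gamma", "k_exc_AM", "k_inh_AM"))
  expect_equal(AIC(fit), fit$aic)
  expect_equal(nrow(predict(fit)), nrow(cells))
  expect_length(residuals(fit), nrow(cells))
  sims <- simulate(fit, nsim = 2, seed = 73)
  expect_length(sims, 2)
  expect_true(all(sims[[1]]$n_correct <= sims[[1]]$n_trials))
  # constraints hold in the estimates
  e <- coef(fit)
  expect_gte(e[["p"]], 2)
  expect_lte(e[["r0"]], 5)
  expect_between(e[["epsilon"]], 0, 1)
  expect_lte(e[["k_exc_AM"]], e[["k_exc"]])
  expect_lte(e[["k_inh_AM"]], e[["k_exc"]])
})

test_that("post-fit ablation zeroes exactly the named effects", {
  des <- experiment_design(contrast_levels = c(4, 12, 40),
                           orientation_levels = 0, trials_per_cell = 40)
  tr <- generate_from_model(des, ref$pop, ref$am, ref$epsilon, seed = 81)
  cells <- pool_observers(tr)
  fit <- fit_population_model(cells, model_spec(), n_restarts = 2,
                              seed = 82, n_polish = 1)
  # empty ablation: identical to the fitted predictions
  expect_equal(ablate_post_fit(fit, character())$pc, fit$fitted$pc)
  # ablating everything makes AM equal Flicker
  ab <- ablate_post_fit(fit, c("alpha", "beta", "gamma"))
  expect_equal(ab$pc[ab$condition == "AM"],
               ab$pc[ab$condition == "Flicker"])
  expect_error(ablate_post_fit(fit, "c50"), "subset")
})

test_that("AIC comparison is exact for identical specs and seeded", {
  des <- experiment_design(contrast_levels = c(4, 12, 40),
                           orientation_levels = c(0, 45),
                           trials_per_cell = 50)
  tr <- generate_from_model(des, ref$pop, ref$am, ref$epsilon, seed = 91)
  cells <- pool_observers(tr)
  spec_g0 <- model_spec(free = setdiff(model_spec()$free, "gamma"),
                        fixed = list(gamma = 0))
  fit_g0a <- fit_population_model(cells, spec_g0, n_restarts = 2, seed = 92,
                                  n_polish = 1)
  fit_g0b <- fit_population_model(cells, spec_g0, n_restarts = 2, seed = 92,
                                  n_polish = 1)
  # same spec, same seed: fits coincide, AIC difference 0 = 2 * delta_k
  expect_equal(fit_g0a$aic, fit_g0b$aic)
  cmp <- compare_models_aic(fit_g0a, fit_g0b, n_boot = 5, seed = 93)
  expect_equal(cmp$aic_difference, 0)
  # determinism of the bootstrap given a seed
  cmp2 <- compare_models_aic(fit_g0a, fit_g0b, n_boot = 5, seed = 93)
  expect_identical(cmp$null_diffs, cmp2$null_diffs)
  # non-nested comparison warns but still computes
  spec_nt <- model_spec(free = setdiff(model_spec()$free,
                                       c("k_exc_AM", "k_inh_AM")),
                        fixed = list(k_exc_AM = 0.001, k_inh_AM = 0.001))
  fit_nt <- fit_population_model(cells, spec_nt, n_restarts = 2, seed = 94,
                                 n_polish = 1)
  expect_warning(cmp3 <- compare_models_aic(fit_nt, fit_g0a, n_boot = 2,
                                            seed = 95), "nested")
  expect_true(is.finite(cmp3$aic_difference))
})

test_that("bootstrap model CIs are reproducible and bracket the estimates", {
  des <- experiment_design(contrast_levels = c(4, 12, 40),
                           orientation_levels = 0, trials_per_cell = 60)
  tr <- generate_from_model(des, ref$pop, ref$am, ref$epsilon, seed = 96)
  cells <- pool_observers(tr)
  spec_small <- model_spec(
    free = c("c50", "p", "gamma"),
    fixed = list(r0 = 4.55, k_exc = 1.35, epsilon = 0.67, alpha = 1.17,
                 beta = 1.51, k_exc_AM = 1.35, k_inh_AM = 0.001))
  fit <- fit_population_model(cells, spec_small, n_restarts = 2, seed = 97,
                              n_polish = 1)
  ci <- bootstrap_model_ci(fit, n_boot = 30, seed = 98)
  ci2 <- bootstrap_model_ci(fit, n_boot = 30, seed = 98)
  expect_identical(ci, ci2)
  est <- coef(fit)
  expect_true(all(ci[, 1] <= est + 1e-8 & est <= ci[, 2] + 1e-8))
})
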