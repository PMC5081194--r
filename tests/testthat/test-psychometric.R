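test_that("psi has the logistic landmarks and bounds", {
  # midpoint: halfway between chance and the ceiling
  expect_equal(psi(10, 10, 2, 0.1), 0.5 + (0.5 - 0.1) / 2)
  # arithmetic example
  expect_equal(psi(14, 10, 2, 0.1), 0.5 + 0.4 / (1 + exp(-2)),
               tolerance = 1e-9)
  # asymptote 1 - lam, floor 0.5, monotone
  cc <- seq(0, 100, by = 0.5)
  v <- psi(cc, 12, 3, 0.17)
  expect_true(all(v >= 0.5 & v <= 1 - 0.17 + 1e-12))
  expect_true(all(diff(v) > 0))
  expect_equal(psi(1e3, 12, 3, 0.17), 0.83, tolerance = 1e-9)
  expect_error(psi(10, 10, 0, 0.1), "s")
  expect_error(psi(10, 10, 2, 0.6), "lam")
})

test_that("ML fitting recovers generating parameters at large n", {
  cells <- make_psi_cells(12, 3, 0.17, n = 1e5, seed = 1,
                          contrasts = c(2, 4, 7, 12, 22, 40, 70))
  fit <- fit_psychometric(cells, n_restarts = 10, seed = 2)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["c_m"]], 12, tolerance = 0.02)
  expect_equal(fit$estimates[["s"]], 3, tolerance = 0.02 * 3)
  expect_equal(fit$estimates[["lam"]], 0.17, tolerance = 0.02 * 0.17)
})

test_that("degenerate data set the boundary flag instead of erroring", {
  # all cells at chance: ceiling deficit pegs at 0.5
  cells <- data.frame(condition = "AM", orientation_deg = 0,
                      contrast_pct = c(4, 7, 12, 22, 40), n_trials = 100,
                      n_correct = c(52, 49, 50, 48, 51))
  fit <- fit_psychometric(cells, n_restarts = 6, seed = 3)
  expect_true(fit$boundary)
  expect_lt(max(predict(fit)), 0.55)
  # perfect performance: lam near 0, midpoint below the tested range
  cells$n_correct <- cells$n_trials
  fit <- fit_psychometric(cells, n_restarts = 6, seed = 4)
  expect_true(fit$boundary)
  expect_lt(fit$estimates[["lam"]], 0.01)
  expect_lt(fit$estimates[["c_m"]], 4)
})

test_that("fitting is invariant to cell order and to splitting cells", {
  cells <- make_psi_cells(10, 2.5, 0.12, n = 80, seed = 5)
  f1 <- fit_psychometric(cells, n_restarts = 8, seed = 9)
  f2 <- fit_psychometric(cells[sample(nrow(cells)), ], n_restarts = 8,
                         seed = 9)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-6)
  # split each cell into two half-cells with the counts divided up
  split_cells <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    x <- cells[i, ]
    k <- x$n_correct %/% 2
    rbind(transform(x, n_trials = 40, n_correct = k),
          transform(x, n_trials = 40, n_correct = x$n_correct - k))
  }))
  f3 <- fit_psychometric(split_cells, n_restarts = 8, seed = 9)
  expect_equal(f1$estimates, f3$estimates, tolerance = 1e-6)
})

test_that("input validation catches malformed cell tables", {
  cells <- make_psi_cells(10, 2, 0.1)
  expect_error(fit_psychometric(cells[1:2, ]), "3 distinct contrast")
  bad <- cells; bad$n_correct[1] <- bad$n_trials[1] + 1
  expect_error(fit_psychometric(bad), "n_correct")
  two_cond <- rbind(cells, transform(cells, condition = "Flicker"))
  expect_error(fit_psychometric(two_cond), "one condition")
})

test_that("deviance bootstrap flags a grossly mis-specified fit", {
  # step-function data cannot be captured by the smooth logistic
  cells <- data.frame(condition = "Flicker", orientation_deg = 0,
                      contrast_pct = c(2, 6, 10, 14, 18, 22, 30, 40),
                      n_trials = 400,
                      n_correct = round(400 * c(0.5, 0.52, 0.95, 0.55,
                                                0.95, 0.6, 0.97, 0.97)))
  fit <- fit_psychometric(cells, n_restarts = 8, seed = 11)
  gof <- deviance_gof(fit, n_boot = 200, seed = 12)
  expect_lt(gof$p_value, 0.01)
  expect_error(deviance_gof(fit, n_boot = 0), "n_boot")
})

test_that("deviance p-values are calibrated for well-specified data", {
  # data simulated from the fitted model: rejection at 5% should be rare
  set.seed(21)
  pvals <- vapply(1:40, function(r) {
    cells <- make_psi_cells(12, 3, 0.15, n = 60)
    fit <- fit_psychometric(cells, n_restarts = 4)
    deviance_gof(fit, n_boot = 120)$p_value
  }, 0)
  # 99% binomial envelope for 40 draws at nominal 0.05
  expect_lte(sum(pvals < 0.05), qbinom(0.995, 40, 0.05) + 1)
})

test_that("bootstrap CIs cover the generating parameters", {
  set.seed(31)
  hits <- matrix(NA, 50, 3, dimnames = list(NULL, c("c_m", "s", "lam")))
  truth <- c(c_m = 12, s = 3, lam = 0.15)
  for (r in 1:50) {
    cells <- make_psi_cells(truth[1], truth[2], truth[3], n = 50)
    fit <- fit_psychometric(cells, n_restarts = 4)
    ci <- bootstrap_pf_ci(fit, n_boot = 120, level = 0.95)
    hits[r, ] <- truth >= ci[, 1] & truth <= ci[, 2]
  }
  # >= 90% empirical coverage at nominal 95%
  expect_true(all(colMeans(hits) >= 0.9 - 1e-9))
})

test_that("the ceiling comparison behaves on trivial and strong cases", {
  cells_am <- make_psi_cells(12, 3, 0.25, n = 250, condition = "AM",
                             seed = 41)
  cells_fl <- make_psi_cells(12, 3, 0.02, n = 250, condition = "Flicker",
                             seed = 42)
  fit_am <- fit_psychometric(cells_am, n_restarts = 8, seed = 43)
  fit_fl <- fit_psychometric(cells_fl, n_restarts = 8, seed = 44)
  # a fit against itself: exactly zero difference
  cmp0 <- compare_lambda(fit_am, fit_am, n_boot = 19, seed = 45)
  expect_equal(cmp0$delta_lambda, 0)
  # a strong ceiling difference is detected
  cmp <- compare_lambda(fit_am, fit_fl, n_boot = 199, seed = 46)
  expect_gt(cmp$delta_lambda, 0.1)
  expect_lt(cmp$p_value, 0.05)
  # mismatched orientations refuse to compare
  fit_o <- fit_psychometric(
    make_psi_cells(12, 3, 0.1, orientation = 45, seed = 47),
    n_restarts = 4, seed = 48)
  expect_error(compare_lambda(fit_am, fit_o), "orientation")
})

test_that("the orientation regression recovers slope and rejects noise", {
  # noiseless line: lam = 0.17 - 0.0028 * ori gives slope 0.0028 exactly
  oris <- c(0, 15, 30, 45)
  fits <- lapply(oris, function(o) {
    cells <- make_psi_cells(12, 3, 0.17 - 0.0028 * o, n = 1e4,
                            orientation = o, seed = 50 + o)
    fit_psychometric(cells, n_restarts = 8, seed = 60 + o)
  })
  reg <- lambda_orientation_regression(fits, n_boot = 99, seed = 71)
  expect_equal(reg$slope, 0.0028, tolerance = 0.05)
  expect_lt(reg$p_value, 0.05)
  expect_error(lambda_orientation_regression(fits[1:2]), "3 orientation")
})

test_that("bonferroni multiplies and caps", {
  expect_equal(bonferroni(c(0.01, 0.4), 5), c(0.05, 1))
  expect_equal(bonferroni(c(0.2, 0.03)), c(0.4, 0.06))
})
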