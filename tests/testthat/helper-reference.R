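# Reference parameterization used across the tests (the bundled fitted
# estimates), plus small builders for synthetic cell-count tables.

ref <- reference_estimates()

ref_flicker <- am_params(alpha = 0, beta = 0, gamma = 0,
                         k_exc_AM = ref$am$k_exc_AM,
                         k_inh_AM = ref$am$k_inh_AM,
                         inducer_orientation = 0)

# cell counts drawn from a known psychometric function
make_psi_cells <- function(c_m, s, lam, n = 50,
                           contrasts = c(4, 7, 12, 22, 40),
                           condition = "AM", orientation = 0,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pr <- psi(contrasts, c_m, s, lam)
  data.frame(condition = condition, orientation_deg = orientation,
             contrast_pct = contrasts, n_trials = n,
             n_correct = rbinom(length(contrasts), n, pr))
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
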