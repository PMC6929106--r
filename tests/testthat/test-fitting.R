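noiseless_curve <- function(params, hrf = 1, rsf = 1,
                            doses = c(1, 2, 4, 8), o2 = 20,
                            label = if (rsf == 1) "none" else "drug") {
  adj <- condition_adjusted_params(params, hrf = hrf, rsf = rsf)
  data.frame(cell_line = "X", o2_percent = o2, impairment_label = label,
             drug_conc_nM = 0, dose_Gy = doses,
             surviving_fraction =
               analytic_mean_survival(adj$params, doses, rsf = adj$rsf))
}

test_that("lethality parameters are recovered exactly from noiseless curves", {
  truth <- gl_params(4e-3, 0.15)
  fit <- fit_lethality(noiseless_curve(truth))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["k_idsb"]), 4e-3, tolerance = 1e-4)
  expect_equal(unname(coef(fit)["k_cdsb"]), 0.15, tolerance = 1e-4)
  expect_lt(fit$objective_value, 1e-12)
})

test_that("under-determined designs are rejected", {
  truth <- gl_params(4e-3, 0.15)
  expect_error(fit_lethality(noiseless_curve(truth, doses = 2)),
               "at least 3 distinct")
  expect_error(fit_lethality(noiseless_curve(truth, doses = c(0, 2))),
               "at least 3 distinct")
})

test_that("zero-dose records are excluded from the objective", {
  truth <- gl_params(4e-3, 0.15)
  d <- noiseless_curve(truth, doses = c(0, 1, 2, 4, 8))
  d$surviving_fraction[1] <- 1
  fit <- fit_lethality(d)
  expect_identical(fit$n_points, 4L)
  expect_equal(unname(coef(fit)["k_idsb"]), 4e-3, tolerance = 1e-4)
})

test_that("HRF is recovered from a hypoxic curve with frozen lethalities", {
  truth <- gl_params(4.83e-3, 0.169)
  fit <- fit_hrf(noiseless_curve(truth, hrf = 1.6, o2 = 1), params = truth)
  expect_equal(unname(coef(fit)["hrf"]), 1.6, tolerance = 1e-3)
  # hypoxic data identical to normoxic data: no oxygen effect, hrf at the
  # lower bound
  expect_warning(
    fit0 <- fit_hrf(noiseless_curve(truth, o2 = 1), params = truth),
    "bound")
  expect_equal(unname(coef(fit0)["hrf"]), 1, tolerance = 1e-6)
})

test_that("RSF is recovered, including the large deficiency regime", {
  truth <- gl_params(4.38e-3, 0.233)
  fit <- fit_rsf(noiseless_curve(truth, rsf = 9.6), params = truth)
  expect_equal(unname(coef(fit)["rsf"]), 9.6, tolerance = 1e-2)
  expect_warning(
    fit0 <- fit_rsf(noiseless_curve(truth), params = truth), "bound")
  expect_equal(unname(coef(fit0)["rsf"]), 1, tolerance = 1e-6)
})

test_that("RSF recovery preserves the ordering of a concentration series", {
  truth <- gl_params(3.88e-3, 0.255)
  rec <- vapply(c(1.7, 2.5, 4.2), function(r)
    unname(coef(fit_rsf(noiseless_curve(truth, rsf = r),
                        params = truth))["rsf"]), 0)
  expect_true(all(diff(rec) > 0))
  expect_equal(rec, c(1.7, 2.5, 4.2), tolerance = 1e-3)
})

test_that("the objective is invariant under record reordering", {
  truth <- gl_params(4e-3, 0.15)
  d <- generate_dataset(truth, doses = c(1, 2, 4, 8),
                        noise_sigma_log = 0.1, seed = 3)
  f1 <- fit_lethality(d)
  f2 <- fit_lethality(d[rev(seq_len(nrow(d))), ])
  expect_equal(f1$objective_value, f2$objective_value, tolerance = 1e-10)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-5)
})

test_that("fit order of HRF and RSF does not change combined predictions", {
  truth <- gl_params(4e-3, 0.15)
  d_hyp <- noiseless_curve(truth, hrf = 1.6, o2 = 1)
  d_drug <- noiseless_curve(truth, rsf = 2.5)
  hrf_first <- c(coef(fit_hrf(d_hyp, truth))["hrf"],
                 coef(fit_rsf(d_drug, truth))["rsf"])
  rsf_first <- c(coef(fit_rsf(d_drug, truth))["rsf"],
                 coef(fit_hrf(d_hyp, truth))["hrf"])[c(2, 1)]
  p1 <- predict_combined(truth, hrf = hrf_first[1], rsf = hrf_first[2])
  p2 <- predict_combined(truth, hrf = rsf_first[1], rsf = rsf_first[2])
  expect_identical(p1, p2)
})

test_that("combined prediction reproduces the baseline and generator curves", {
  truth <- gl_params(4e-3, 0.15)
  base <- predict_combined(truth, hrf = 1, rsf = 1, doses = c(1, 2, 4, 8))
  expect_equal(base$surviving_fraction,
               analytic_mean_survival(truth, c(1, 2, 4, 8)))
  comb <- predict_combined(truth, hrf = 1.6, rsf = 2.5,
                           doses = c(1, 2, 4, 8))
  gen <- noiseless_curve(truth, hrf = 1.6, rsf = 2.5, o2 = 1)
  expect_equal(comb$surviving_fraction, gen$surviving_fraction)
  # sensitisation pushes the combined curve below the untreated hypoxic one
  hyp <- predict_combined(truth, hrf = 1.6, rsf = 1, doses = 4)
  expect_lt(comb$surviving_fraction[3], hyp$surviving_fraction)
})

test_that("LQ Taylor coefficients match numerical low-dose derivatives", {
  cases <- ref_lines()
  for (nm in names(cases)) {
    p <- cases[[nm]]$params
    for (r in cases[[nm]]$rsf) {
      lq <- lq_taylor_coefficients(p, rsf = r)
      num <- loopsurv:::.numerical_lq(p, rsf = r)
      expect_equal(unname(lq["alpha"]), unname(num["alpha"]),
                   tolerance = 1e-4)
      expect_equal(unname(lq["beta"]), unname(num["beta"]),
                   tolerance = 1e-4)
    }
  }
  expect_equal(unname(lq_taylor_coefficients(gl_params(0, 0))),
               c(0, 0))
  expect_equal(unname(lq_taylor_coefficients(gl_params(4.83e-3, 0.169))["alpha"]),
               4.83e-3 * 5e-3 * 6000, tolerance = 1e-12)
})

test_that("the LQ quadratic tracks the closed form at low doses", {
  for (ln in ref_lines()[c("lungA", "renal", "hamster")]) {
    p <- ln$params
    lq <- lq_taylor_coefficients(p)
    d <- seq(0.05, 0.5, by = 0.05)
    s_lq <- exp(-lq["alpha"] * d - lq["beta"] * d^2)
    s <- analytic_mean_survival(p, d)
    expect_lt(max(abs(s_lq / s - 1)), 0.01)
  }
})

test_that("weighted fitting uses the reported measurement uncertainties", {
  truth <- gl_params(4e-3, 0.15)
  d <- noiseless_curve(truth)
  d$sf_sem <- 0.05 * d$surviving_fraction
  fw <- fit_lethality(d, weighted = TRUE)
  expect_equal(unname(coef(fw)["k_idsb"]), 4e-3, tolerance = 1e-4)
  d$sf_sem <- NULL
  expect_error(fit_lethality(d, weighted = TRUE), "sf_sem")
})
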