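test_that("zero noise reproduces the closed-form curve exactly", {
  p <- gl_params(4.83e-3, 0.169)
  d <- generate_dataset(p, noise_sigma_log = 0, n_replicates = 1, seed = 1)
  expect_equal(d$surviving_fraction,
               analytic_mean_survival(p, d$dose_Gy))
})

test_that("identical seeds give identical datasets", {
  p <- gl_params(4e-3, 0.15)
  a <- generate_dataset(p, basic_conditions(), seed = 7)
  b <- generate_dataset(p, basic_conditions(), seed = 7)
  expect_identical(a, b)
  c <- generate_dataset(p, basic_conditions(), seed = 8)
  expect_false(identical(a$surviving_fraction, c$surviving_fraction))
})

test_that("generated log residuals have the requested noise level", {
  p <- gl_params(3e-3, 0.2)
  sigma <- 0.1
  d <- generate_dataset(p, doses = c(2, 4, 8), noise_sigma_log = sigma,
                        n_replicates = 400, seed = 5)
  res <- log(d$surviving_fraction) -
    log(analytic_mean_survival(p, d$dose_Gy))
  n <- length(res)
  expect_lt(abs(sd(res) - sigma), 3 * sigma / sqrt(2 * (n - 1)))
})

test_that("collapsed replicates carry the mean and SEM", {
  p <- gl_params(4e-3, 0.15)
  d <- generate_dataset(p, noise_sigma_log = 0.1, n_replicates = 5,
                        seed = 2, collapse_replicates = FALSE)
  dc <- generate_dataset(p, noise_sigma_log = 0.1, n_replicates = 5,
                         seed = 2, collapse_replicates = TRUE)
  expect_identical(nrow(dc), 4L)
  for (i in seq_len(nrow(dc))) {
    g <- d$surviving_fraction[d$dose_Gy == dc$dose_Gy[i]]
    expect_equal(dc$surviving_fraction[i], mean(g))
    expect_equal(dc$sf_sem[i], sd(g) / sqrt(length(g)))
  }
})

test_that("surviving fractions are truncated at 1", {
  p <- gl_params(1e-5, 1e-4)   # nearly flat curve; noise would exceed 1
  d <- generate_dataset(p, doses = c(1, 2, 4), noise_sigma_log = 0.5,
                        n_replicates = 50, seed = 3)
  expect_true(all(d$surviving_fraction <= 1))
  expect_true(all(d$surviving_fraction > 0))
})

test_that("the synthetic campaign satisfies the dataset invariants", {
  camp <- synthetic_campaign(seed = 4)
  expect_s3_class(camp, "survival_dataset")
  expect_true(all(camp$surviving_fraction > 0 &
                    camp$surviving_fraction <= 1))
  truth <- attr(camp, "truth")
  expect_true(all(c("cell_line", "hrf", "rsf", "k_idsb", "k_cdsb") %in%
                    names(truth)))
  expect_true(all(truth$k_idsb >= 1.5e-3 & truth$k_idsb <= 5e-3))
  expect_true(all(truth$k_cdsb >= 0.13 & truth$k_cdsb <= 0.26))
  expect_true(all(truth$hrf >= 1 & truth$hrf <= 2.5))
  expect_true(all(truth$rsf >= 1 & truth$rsf <= 15))
  expect_identical(length(unique(camp$cell_line)), 8L)
  # every line has a normoxic untreated curve so the workflow can run
  for (cl in unique(camp$cell_line)) {
    d <- camp[camp$cell_line == cl, ]
    expect_gte(sum(d$o2_percent >= 20 & d$impairment_label == "none" &
                     d$dose_Gy > 0), 3)
  }
  expect_identical(synthetic_campaign(seed = 4), camp)
})

test_that("a noiseless campaign is recovered exactly by the full workflow", {
  camp <- synthetic_campaign(seed = 6, noise_sigma_log = 0, n_replicates = 1)
  truth <- attr(camp, "truth")
  fit <- suppressWarnings(loopsurv(camp))
  tab <- coef(fit)
  for (cl in unique(truth$cell_line)) {
    tr <- truth[truth$cell_line == cl, ]
    est <- tab[tab$cell_line == cl, ]
    expect_equal(est$estimate[est$parameter == "k_idsb"], tr$k_idsb[1],
                 tolerance = 1e-3)
    expect_equal(est$estimate[est$parameter == "k_cdsb"], tr$k_cdsb[1],
                 tolerance = 1e-3)
    for (o2 in unique(tr$o2_percent[tr$hrf > 1])) {
      expect_equal(
        est$estimate[est$stage == "hrf" &
                       est$condition == paste0(o2, "% O2")],
        tr$hrf[tr$o2_percent == o2][1], tolerance = 1e-3)
    }
  }
})

test_that("generated datasets round-trip through the CSV dialect", {
  p <- gl_params(4e-3, 0.15)
  d <- generate_dataset(p, basic_conditions(), noise_sigma_log = 0.05,
                        seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survival_csv(d, path)
  back <- read_survival_csv(path)
  expect_equal(as.data.frame(back),
               as.data.frame(d), tolerance = 1e-12,
               ignore_attr = TRUE)
})
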