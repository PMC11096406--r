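test_that("lognormal calibration matches the quartile construction", {
  z75 <- qnorm(0.75)
  cal <- calibrate_lognormal(param_dist(1, exp(-z75), exp(z75)))
  expect_equal(unname(cal["meanlog"]), 0)
  expect_equal(unname(cal["sdlog"]), 1)

  cal_mu <- calibrate_lognormal(param_dist(0.32, 0.17, 0.66))
  expect_equal(unname(cal_mu["meanlog"]), log(0.32), tolerance = 1e-10)
  expect_equal(unname(cal_mu["sdlog"]), log(0.66 / 0.17) / (2 * z75),
               tolerance = 1e-10)
  # implied quartiles are log-symmetric about the median and preserve the
  # requested quartile ratio
  q <- qlnorm(c(0.25, 0.75), cal_mu["meanlog"], cal_mu["sdlog"])
  expect_equal(log(q[2]) - log(0.32), log(0.32) - log(q[1]))
  expect_equal(q[2] / q[1], 0.66 / 0.17, tolerance = 1e-10)

  # log-symmetric triplet: quartiles reproduced exactly
  cal2 <- calibrate_lognormal(param_dist(2, 1, 4))
  expect_equal(qlnorm(c(0.25, 0.75), cal2["meanlog"], cal2["sdlog"]),
               c(1, 4), tolerance = 1e-12)

  expect_error(param_dist(1, 2, 3), "q25 < median")
  expect_error(param_dist(-1, -2, 3), "positive")
})

test_that("split-lognormal calibration hits all three quartiles exactly", {
  d <- param_dist(0.07, 0.01, 0.12)
  cal <- calibrate_split_lognormal(d)
  z75 <- qnorm(0.75)
  expect_equal(unname(cal["sdlog_lower"]), log(0.07 / 0.01) / z75)
  expect_equal(unname(cal["sdlog_upper"]), log(0.12 / 0.07) / z75)
  # reduces to the log-symmetric law when the triplet is log-symmetric
  sym <- calibrate_split_lognormal(param_dist(2, 1, 4))
  expect_equal(unname(sym["sdlog_lower"]), unname(sym["sdlog_upper"]))

  withr::with_seed(11, {
    x <- skinrate:::r_param_dist(2e5, d)
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    expect_equal(q, c(0.01, 0.07, 0.12), tolerance = 0.02)
  })
})

test_that("identical configs generate identical cohorts", {
  cfg <- cohort_config(n_per_class = c(4, 4, 4), seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # and the seed matters
  c2 <- generate_cohort(cohort_config(n_per_class = c(4, 4, 4), seed = 10))
  expect_false(identical(a$truth$mu, c2$truth$mu))
})

test_that("generated parameter quartiles converge to the configured triplets", {
  cfg <- cohort_config(n_per_class = c(3400, 3300, 3300), seed = 2)
  truth <- generate_cohort(cfg)$truth
  targets <- list(
    mu = c(0.17, 0.32, 0.66),
    gamma = c(0.01, 0.07, 0.12),
    rupture_strain = c(1.27, 1.69, 2.47)
  )
  for (p in names(targets)) {
    q <- quantile(truth[[p]], c(0.25, 0.5, 0.75), names = FALSE)
    expect_equal(q, targets[[p]], tolerance = 0.05)
  }
})

test_that("per-class medians of true mu stay near 0.32 MPa under the null", {
  cfg <- cohort_config(n_per_class = c(10000, 10000, 10000),
                       n_points = 20, seed = 4)
  truth <- generate_cohort(cfg)$truth
  med <- tapply(truth$mu, truth$rate_class, median)
  expect_equal(as.vector(med), rep(0.32, 3), tolerance = 0.03)
})

test_that("rate_effect shifts the affected classes' medians monotonically", {
  med_for <- function(r) {
    truth <- generate_cohort(
      cohort_config(n_per_class = c(800, 800, 800), rate_effect = r,
                    n_points = 20, seed = 6))$truth
    sapply(split(truth, truth$rate_class),
           function(d) c(mu = median(d$mu), gamma = median(d$gamma),
                         ru = median(d$rupture_strain)))
  }
  m0 <- med_for(0); m1 <- med_for(0.25); m2 <- med_for(0.5)
  # class 1 (zero shift) is untouched; classes 2 and 3 increase strictly
  expect_equal(m0[, 1], m1[, 1])
  expect_true(all(m1[, 2:3] > m0[, 2:3]))
  expect_true(all(m2[, 2:3] > m1[, 2:3]))
  # a length-3 rate_effect targets a single class
  m_one <- generate_cohort(
    cohort_config(n_per_class = c(800, 800, 800),
                  rate_effect = c(0, 0, 1), n_points = 20, seed = 6))$truth
  med_one <- tapply(m_one$mu, m_one$rate_class, median)
  expect_equal(as.vector(med_one[1:2]), as.vector(m0["mu", 1:2]))
  expect_gt(med_one[3], 2 * m0["mu", 3])
})

test_that("zero-noise cohorts have exactly Veronda-Westmann curves", {
  cohort <- generate_cohort(cohort_config(n_per_class = c(2, 2, 2),
                                          noise_cv = 0, seed = 8))
  for (i in seq_along(cohort$records)) {
    rec <- cohort$records[[i]]
    tr <- cohort$truth[i, ]
    sigma <- rec$force / rec$area
    eps <- rec$displacement / rec$gauge_length
    expect_equal(sigma, vw_nominal_stress(eps, tr$mu, tr$gamma),
                 tolerance = 1e-12)
    fit <- vw_fit(to_stress_strain(rec))
    expect_lt(fit$residual_norm, 1e-8)
  }
})

test_that("cohorts round-trip through the delimited-text format", {
  cohort <- generate_cohort(cohort_config(n_per_class = c(2, 2, 2),
                                          seed = 12))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  back <- read_cohort(dir)
  expect_equal(length(back), length(cohort$records))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$force, cohort$records[[i]]$force,
                 tolerance = 1e-9)
    expect_equal(back[[i]]$rate_class, cohort$records[[i]]$rate_class)
  }
  # headerless two-column file with explicit geometry
  f <- file.path(dir, "plain.csv")
  write.table(data.frame(c(0, 1, 2), c(0, 5, 10)), f, sep = ",",
              row.names = FALSE, col.names = FALSE)
  rec <- read_tensile_record(f, gauge_length = 10, area = 5,
                             rate_class = 2)
  expect_equal(to_stress_strain(rec)$stress, c(0, 1, 2))
})

test_that("config validation rejects malformed settings", {
  expect_error(cohort_config(n_per_class = c(5, 5)), "three")
  expect_error(cohort_config(noise_cv = -0.1), "noise_cv")
  expect_error(cohort_config(n_points = 5), "n_points")
  expect_error(cohort_config(rate_effect = c(1, 2)), "rate_effect")
})
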