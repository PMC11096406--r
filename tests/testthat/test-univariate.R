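test_that("IQR fences follow the linear-interpolation quantile convention", {
  # one wild ut_stress value; every other parameter constant-in-range
  ft <- data.frame(
    sample_id = paste0("s", 1:5), rate_class = c(0.3, 0.3, 2, 2, 8),
    ut_stress = c(1, 2, 3, 4, 100), ut_strain = 1, toughness = 1,
    mu = 1, gamma = 1
  )
  scr <- outlier_screen(ft)
  # on [1,2,3,4,100]: Q1 = 2, Q3 = 4 (type 7), upper fence 4 + 3*2 = 10
  row <- scr$fences[scr$fences$parameter == "ut_stress", ]
  expect_equal(row$lower, -4)
  expect_equal(row$upper, 10)
  expect_equal(scr$removed$ut_stress, 100)
  expect_equal(nrow(scr$kept), 4)

  # all-identical parameters: zero IQR, boundary-inclusive, nothing removed
  ft2 <- ft
  ft2$ut_stress <- 1
  expect_equal(nrow(outlier_screen(ft2)$removed), 0)
})

test_that("heavy-tailed cohorts are screened only above the upper fence", {
  cohort <- generate_cohort(cohort_config(n_per_class = c(100, 100, 100),
                                          n_points = 20, seed = 7))
  ft <- cbind(build_feature_table(cohort$records, fit = FALSE),
              mu = cohort$truth$mu, gamma = cohort$truth$gamma)
  scr <- outlier_screen(ft)
  expect_gt(nrow(scr$removed), 0)
  for (p in c("ut_stress", "ut_strain", "toughness", "mu", "gamma")) {
    fr <- scr$fences[scr$fences$parameter == p, ]
    expect_true(all(scr$removed[[p]] > fr$lower))
  }
})

test_that("the decision tree takes the documented branches on stubbed p-values", {
  stub <- function(p) function(...) list(statistic = NA_real_, p.value = p)
  x <- rnorm(10); y <- rnorm(10)

  tr <- decide_pair(x, y, alpha = 0.01, tests = list(
    shapiro = stub(0.5), f = stub(0.5), t_pooled = stub(0.2)))
  expect_equal(tr$steps$test,
               c("shapiro_x", "shapiro_y", "f_variance", "t_pooled"))
  expect_equal(tr$terminal_test, "t_pooled")
  expect_equal(tr$conclusion, "equal")

  tr2 <- decide_pair(x, y, alpha = 0.01, tests = list(
    shapiro = local({
      calls <- 0
      function(...) {
        calls <<- calls + 1
        list(statistic = NA_real_,
             p.value = if (calls == 1) 0.001 else 0.5)
      }
    }),
    ks = stub(0.3), wilcoxon = stub(0.004)))
  expect_equal(tr2$terminal_test, "wilcoxon")
  expect_equal(tr2$conclusion, "not equal")

  tr3 <- decide_pair(x, y, alpha = 0.01, tests = list(
    shapiro = stub(0.5), f = stub(0.001), t_welch = stub(0.5)))
  expect_equal(tr3$terminal_test, "t_welch")
  expect_equal(tr3$conclusion, "equal")

  tr4 <- decide_pair(x, y, alpha = 0.01, tests = list(
    shapiro = stub(0.001), ks = stub(0.001), t_welch = stub(0.002)))
  expect_equal(tr4$terminal_test, "t_welch")
  expect_equal(tr4$conclusion, "not equal")

  expect_error(decide_pair(1:2, y), "at least 3")
})

test_that("every input reaches exactly one terminal test", {
  withr::with_seed(21, {
    for (i in 1:25) {
      x <- rlnorm(8 + i %% 5); y <- rnorm(8 + (i * 3) %% 7, sd = 1 + i %% 3)
      tr <- decide_pair(x, y, alpha = 0.01)
      expect_true(tr$terminal_test %in% c("t_pooled", "t_welch", "wilcoxon"))
      expect_equal(tr$steps$test[1:2], c("shapiro_x", "shapiro_y"))
      expect_true(all(tr$steps$p_value >= 0 & tr$steps$p_value <= 1))
      expect_equal(nrow(tr$steps), 4L)  # 2 normality + 1 gate + 1 terminal
    }
  })
})

test_that("Wilcoxon matches brute-force enumeration for small samples", {
  expect_equal(wilcoxon_enum_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  withr::with_seed(5, {
    for (i in 1:30) {
      nx <- sample(3:6, 1); ny <- sample(3:6, 1)
      repeat {
        x <- round(rnorm(nx), 4); y <- round(rnorm(ny, 0.4), 4)
        if (!anyDuplicated(c(x, y))) break
      }
      p_pkg <- skinrate:::default_tests()$wilcoxon(x, y)$p.value
      expect_equal(p_pkg, wilcoxon_enum_p(x, y), tolerance = 1e-12,
                   info = sprintf("nx=%d ny=%d", nx, ny))
    }
  })
})

test_that("Cohen's d uses the pooled standard deviation", {
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), 1)
  x <- c(0.2, 1.1, 2.4, -0.5)
  expect_equal(cohens_d(x, x), 0)
  expect_error(cohens_d(rep(1, 3), rep(1, 4)), "undefined")
  # symmetric in arguments
  y <- c(3.2, 1.4, 0.9)
  expect_equal(cohens_d(x, y), cohens_d(y, x))
})

test_that("minimum sample size search is exact and monotone", {
  expect_equal(min_sample_size(d = 0.4, alpha = 0.05, power = 0.85,
                               ratio = 1, tails = "one"), 91L)
  expect_equal(min_sample_size(d = 1, alpha = 0.05, power = 0.80,
                               tails = "two"), 17L)
  expect_lt(power_t_test2(16, 1, 0.05, tails = "two"), 0.80)
  expect_gte(power_t_test2(17, 1, 0.05, tails = "two"), 0.80)

  # minimality on a grid of queries
  grid <- expand.grid(d = c(0.3, 0.6, 1.2), power = c(0.8, 0.9),
                      tails = c("one", "two"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    n <- min_sample_size(grid$d[i], 0.05, grid$power[i],
                         tails = grid$tails[i])
    expect_gte(power_t_test2(n, grid$d[i], 0.05, tails = grid$tails[i]),
               grid$power[i])
    if (n > 2) {
      expect_lt(power_t_test2(n - 1, grid$d[i], 0.05,
                              tails = grid$tails[i]), grid$power[i])
    }
  }
  # monotone: nonincreasing in d, nondecreasing in power
  expect_gte(min_sample_size(0.3, power = 0.85),
             min_sample_size(0.5, power = 0.85))
  expect_lte(min_sample_size(0.4, power = 0.8),
             min_sample_size(0.4, power = 0.95))
})

test_that("run_univariate covers 5 parameters x 3 pairs and flags shifts", {
  ft <- make_feature_table(c(30, 30, 30), delta = 0, seed = 13)
  res <- run_univariate(ft, alpha = 0.01)
  expect_equal(nrow(res), 15)
  expect_equal(sort(unique(res$parameter)),
               sort(c("ut_stress", "ut_strain", "toughness", "mu", "gamma")))
  expect_length(attr(res, "traces"), 15)

  # identical groups: no rejections, terminal p near 1
  ft_dup <- ft
  ft_dup[ft_dup$rate_class == 2,
         c("ut_stress", "ut_strain", "toughness", "mu", "gamma")] <-
    ft_dup[ft_dup$rate_class == 0.3,
           c("ut_stress", "ut_strain", "toughness", "mu", "gamma")]
  res_dup <- run_univariate(ft_dup)
  sub <- res_dup[res_dup$rate_a == 0.3 & res_dup$rate_b == 2, ]
  expect_true(all(sub$conclusion == "equal"))
  expect_true(all(sub$p_value > 0.9))

  # a strong shift on one class is detected for the shifted parameters
  cohort <- generate_cohort(
    cohort_config(n_per_class = c(150, 150, 150),
                  rate_effect = c(0, 0, 0.75), n_points = 20, seed = 14))
  ftc <- cbind(build_feature_table(cohort$records, fit = FALSE),
               mu = cohort$truth$mu, gamma = cohort$truth$gamma)
  resc <- run_univariate(ftc)
  shifted_pairs <- resc[resc$rate_b == 8 | resc$rate_a == 8, ]
  expect_gte(sum(shifted_pairs$conclusion == "not equal"), 4)
  null_pair <- resc[resc$rate_a == 0.3 & resc$rate_b == 2, ]
  expect_true(all(null_pair$p_value > 0.01))

  expect_error(run_univariate(ft[ft$rate_class != 2, ]), "three rate")
})

test_that("the effect-size matrix reports both aggregators", {
  ft <- make_feature_table(c(25, 25, 25), delta = 0.3, seed = 17)
  dm <- cohens_d_matrix(ft)
  expect_equal(dim(dm$d), c(5, 3))
  expect_true(all(dm$d >= 0))
  expect_equal(dm$mean, mean(dm$d))
  expect_equal(dm$max, max(dm$d))
})
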