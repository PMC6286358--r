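test_that("spearman matches hand-computed rank correlations", {
  expect_equal(spearman(1:10, (1:10)^3)$statistic, 1)
  expect_equal(spearman(1:10, rev(1:10))$statistic, -1)
  # n = 4, d = (0,1,-1,0): rho = 1 - 6*2/(4*15) = 0.8
  expect_equal(spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))$statistic, 0.8)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:2, 1:2), "at least 3")

  s <- spearman(1:20, 1:20 + rnorm(20), alpha = 0.05, m = 8)
  expect_equal(s$alpha_corrected, 0.00625)

  # permutation p agrees with the t approximation in the bulk
  set.seed(1)
  x <- rnorm(25); y <- x + rnorm(25, 0, 2)
  a <- spearman(x, y)
  b <- spearman(x, y, exact_perm = TRUE, n_perm = 4000)
  expect_equal(a$p_value, b$p_value, tolerance = 0.05)
})

test_that("partial spearman behaves like a first-order partial on ranks", {
  set.seed(2)
  # z constant -> reduces to plain Spearman
  x <- rnorm(30); y <- x + rnorm(30)
  pc <- partial_spearman(x, y, rep(1, 30))
  expect_equal(pc$statistic, spearman(x, y)$statistic)

  # x = y -> partial correlation 1 whenever defined
  z <- rnorm(30)
  expect_equal(partial_spearman(x, x + 0, z)$statistic, 1, tolerance = 1e-12)

  # y (noisily) monotone in z, x independent -> partial ~ 0
  n <- 400
  z2 <- rnorm(n); y2 <- exp(z2) + rnorm(n, 0, 0.1); x2 <- rnorm(n)
  expect_lt(abs(partial_spearman(x2, y2, z2)$statistic), 0.12)

  # exactly monotone in z -> rank correlation 1, partial undefined
  expect_error(partial_spearman(x2, exp(z2), z2), "monotone function")

  # z independent of both -> partial ~ plain
  x3 <- rnorm(n); y3 <- x3 + rnorm(n); z3 <- rnorm(n)
  expect_equal(partial_spearman(x3, y3, z3)$statistic,
               spearman(x3, y3)$statistic, tolerance = 0.05)

  expect_error(partial_spearman(1:10, rnorm(10), 1:10), "monotone function")
})

test_that("multiple regression recovers exact linear structure", {
  age <- c(10, 20, 30, 40, 25, 33)
  edu <- c(2, 8, 12, 16, 9, 11.5)
  r <- suppressWarnings(multiple_regression(2 * edu, age, edu))  # exact fit
  expect_equal(r$coef_edu, 2, tolerance = 1e-8)
  expect_equal(r$coef_age, 0, tolerance = 1e-8)
  expect_equal(r$r_squared, 1, tolerance = 1e-8)

  r2 <- suppressWarnings(multiple_regression(age + edu, age, edu))
  expect_equal(r2$coef_diff, 0, tolerance = 1e-8)
  expect_equal(r2$coef_diff, r2$coef_edu - r2$coef_age)

  expect_error(multiple_regression(rnorm(5), 1:5, 2 * (1:5)), "singular")

  set.seed(3)
  r3 <- multiple_regression(rnorm(300), rnorm(300), rnorm(300))
  expect_lt(r3$r_squared, 0.05)
})

test_that("group tests combine Kruskal-Wallis with pairwise Wilcoxon", {
  set.seed(4)
  g <- list(a = rnorm(10), b = rnorm(10) + 10, c = rnorm(10))
  out <- group_tests(g, m_corrections = 4)
  expect_equal(out$kruskal_wallis$test_name, "Kruskal-Wallis")
  expect_equal(out[["a vs b"]]$alpha_corrected, 0.0125)
  # disjoint supports, n = 10 each: extreme rank sum
  expect_lt(out[["a vs b"]]$p_value, 0.001)
  expect_true(out[["a vs b"]]$significant)
  expect_false(out[["a vs c"]]$significant)
  expect_length(out, 4)  # KW + 3 pairs

  expect_error(group_tests(list(a = 1, b = rnorm(5))), "at least 2")

  # two-group KW and Wilcoxon agree asymptotically (H = z^2)
  set.seed(5)
  g2 <- list(x = rnorm(300), y = rnorm(300, 0.1))
  out2 <- group_tests(g2)
  expect_equal(out2$kruskal_wallis$p_value, out2[["x vs y"]]$p_value,
               tolerance = 0.02)
})

test_that("distribution checks flag skew and test variance homogeneity", {
  set.seed(6)
  g <- list(skewed = rexp(60)^2, normal = rnorm(60))
  out <- distribution_checks(g)
  expect_lt(out$ks_skewed$p_value, 0.01)
  expect_match(out$ks_skewed$note, "approximate")
  expect_s3_class(out$levene, "stat_result")

  # unequal variances are detected
  gv <- list(a = rnorm(50, sd = 1), b = rnorm(50, sd = 4))
  expect_lt(distribution_checks(gv)$levene$p_value, 0.01)

  # Brown-Forsythe option
  expect_s3_class(distribution_checks(gv, center = "median")$levene,
                  "stat_result")

  expect_error(distribution_checks(list(a = rep(1, 5), b = rep(1, 5))),
               "degenerate")
})

test_that("proportion test matches the hand-computed 2x2 chi-square", {
  eq <- proportion_test(5, 10, 10, 20)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  sep <- proportion_test(10, 10, 0, 10)
  expect_equal(sep$statistic, 20)           # uncorrected chi-square
  expect_equal(proportion_test(0, 10, 10, 10)$statistic, sep$statistic)

  # Yates correction is available and shrinks the statistic
  expect_lt(proportion_test(10, 10, 0, 10, correct = TRUE)$statistic, 20)
  expect_error(proportion_test(11, 10, 1, 10))
})

test_that("bonferroni thresholds match the standard corrections", {
  expect_equal(bonferroni(0.05, 8), 0.00625)
  expect_equal(round(bonferroni(0.05, 8), 4), 0.0063)
  expect_equal(bonferroni(0.05, 4), 0.0125)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(0.05, 6), 0.05 / 6)  # prints as 0.0083
  expect_error(bonferroni(1.2, 4))
})

test_that("confound battery runs on whatever covariates are present", {
  set.seed(7)
  n <- 40
  df <- data.frame(mean_N = rnorm(n, 20), mean_RE = rnorm(n, 5),
                   mean_LSC = rnorm(n, 8), mean_ASP = rnorm(n, 4),
                   education_years = runif(n, 0, 20),
                   sex = sample(c("male", "female"), n, TRUE),
                   income = rlnorm(n), cpz_dose = rlnorm(n, 5))
  out <- confound_battery(df)
  expect_named(out, c("sex", "income", "education_adjusted_income",
                      "dose", "education_adjusted_dose"))
  expect_equal(out$income$mean_N$alpha_corrected, 0.0125)
  expect_identical(out$education_adjusted_dose$mean_N$covariates, "cpz_dose")
  # without covariate columns only available blocks are produced
  out2 <- confound_battery(df[, c("mean_N", "education_years", "sex")],
                           attributes = "mean_N")
  expect_named(out2, "sex")
})
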