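test_that("the maturation curve satisfies its defining properties", {
  expect_equal(maturation_curve(0, f0 = 3, f_inf = 20, T = 5), 3)
  expect_equal(maturation_curve(1e6, f0 = 3, f_inf = 20, T = 5), 20)
  expect_equal(maturation_curve(6, f0 = 0, f_inf = 1, T = 6), 1 - exp(-1))
  expect_error(maturation_curve(1, 0, 1, T = 0), "must be > 0")
  expect_error(maturation_curve(1, 0, 1, T = -2), "must be > 0")

  # exact solution of df/dt = (f_inf - f)/T, f(0) = f0:
  # central-difference derivative matches the ODE right-hand side
  f0 <- 4; fi <- 18; Tc <- 6; h <- 1e-5
  for (t in c(0.5, 2, 7, 20)) {
    dfdt <- (maturation_curve(t + h, f0, fi, Tc) -
               maturation_curve(t - h, f0, fi, Tc)) / (2 * h)
    expect_equal(dfdt, (fi - maturation_curve(t, f0, fi, Tc)) / Tc,
                 tolerance = 1e-6)
  }

  # monotone: increasing iff f_inf > f0
  t <- 0:30
  expect_true(all(diff(maturation_curve(t, 2, 20, 4)) > 0))
  expect_true(all(diff(maturation_curve(t, 20, 2, 4)) < 0))
})

test_that("bin_series floors years and computes mean/SEM/count per bin", {
  b <- bin_series(c(10, 12, 20), c(6.2, 6.9, 10.0))
  expect_identical(b$bin, c(6L, 10L))
  expect_identical(b$n, c(2L, 1L))
  expect_equal(b$mean, c(11, 20))
  expect_true(is.na(b$sem[2]))          # singleton bin: SEM undefined

  b2 <- bin_series(c(4, 6), c(3.1, 3.9))
  expect_equal(b2$mean, 5)
  expect_equal(b2$sem, 1)               # sd = sqrt(2), sem = sqrt(2)/sqrt(2)
  expect_equal(sum(b$n), 3)
})

test_that("noiseless curve data are recovered essentially exactly", {
  b <- generate_binned_series(f0 = 4, f_inf = 18, T = 6, bins = 26,
                              per_bin = 10, noise_sd = 0, seed = 3)
  fit <- fit_maturation(b, attribute = "N")
  truth <- c(f0 = 4, f_inf = 18, T = 6)
  expect_true(all(abs(coef(fit) - truth) / truth <= 1e-4))
  expect_gte(fit$r_squared, 0.999)
  expect_true(fit$converged)
  expect_equal(fit$delta, abs(coef(fit)[["f_inf"]] - coef(fit)[["f0"]]))
})

test_that("flat and decreasing series are handled as the model admits", {
  flat <- structure(data.frame(bin = 0:9, mean = rep(7, 10),
                               sem = rep(0.1, 10), n = rep(5L, 10)),
                    variable = "education_years",
                    class = c("binned_series", "data.frame"))
  f <- fit_maturation(flat, attribute = "N")
  expect_lt(f$delta, 0.05)
  expect_equal(f$r_squared, 0)

  dec <- generate_binned_series(f0 = 20, f_inf = 3, T = 2, bins = 15,
                                per_bin = 8, noise_sd = 0.1, seed = 4)
  fd <- fit_maturation(dec, attribute = "RE")
  expect_gt(coef(fd)[["f0"]], coef(fd)[["f_inf"]])  # RE-like decrease allowed
  expect_lte(coef(fd)[["f0"]], 29)                   # edge-counted bound
})

test_that("fits respect bounds, bin minimum and the interfaces", {
  b <- generate_binned_series(4, 18, 6, bins = 20, per_bin = 10,
                              noise_sd = 0.2, seed = 8)
  expect_error(fit_maturation(b[1:3, ], attribute = "N"), "at least 4 bins")

  fit <- fit_maturation(b, attribute = "N")
  cf <- coef(fit)
  expect_true(all(cf >= c(0, 0, 0) - 1e-9))
  expect_true(all(cf <= c(30, 30, 30) + 1e-9))

  # vector and formula interfaces agree
  set.seed(21)
  edu <- runif(120, 0, 20)
  val <- maturation_curve(edu, 5, 16, 4) + rnorm(120, 0, 0.5)
  f1 <- fit_maturation(val, times = edu, attribute = "N")
  df <- data.frame(mean_N = val, education_years = edu)
  f2 <- fit_maturation(mean_N ~ education_years, data = df)
  expect_equal(coef(f1), coef(f2))
  expect_identical(f2$attribute, "N")
  expect_identical(f2$time_variable, "education_years")

  # methods behave
  expect_equal(predict(f1, 0), coef(f1)[["f0"]], tolerance = 1e-6)
  expect_length(residuals(f1), nrow(f1$binned))
  expect_equal(fitted(f1) + residuals(f1), f1$binned$mean)
  s <- summary(f1)
  expect_s3_class(s, "summary.maturation_fit")
  sim <- simulate(f1, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(nrow(f1$binned), 4L))
})

test_that("single-subject bins get the weakest finite weight, not dropped", {
  vals <- c(maturation_curve(0:10, 4, 16, 5) + rnorm(11, 0, 0.1),
            maturation_curve(0:10, 4, 16, 5) + rnorm(11, 0, 0.1),
            maturation_curve(25, 4, 16, 5))          # lone old bin
  times <- c(0:10, 0:10, 25)
  set.seed(31)
  fit <- fit_maturation(vals, times = times, attribute = "N")
  expect_true(25L %in% fit$binned$bin)
  expect_equal(nrow(fit$binned), 12)
})

test_that("temporal-order permutation is seeded and discriminates trend", {
  set.seed(41)
  edu <- runif(80, 0, 20)
  trended <- maturation_curve(edu, 4, 18, 6) + rnorm(80, 0, 1)
  flat <- rnorm(80, 10, 1)

  p1 <- permute_time(trended, edu, n_perm = 199, seed = 5, attribute = "N")
  expect_gt(p1$observed_rho, quantile(abs(p1$null_rho), 0.975))
  expect_gt(p1$observed_r2, quantile(p1$null_r2, 0.975, na.rm = TRUE))
  expect_lt(p1$p_rho, 0.05)
  expect_gt(mean(p1$null_r2, na.rm = TRUE) + 1e-9, 0 - 1)  # defined
  expect_lt(mean(p1$null_r2, na.rm = TRUE), p1$observed_r2)

  p0 <- permute_time(flat, edu, n_perm = 199, seed = 5, attribute = "N")
  expect_gt(p0$p_rho, 0.05)

  # single surrogate with a fixed seed is reproducible
  a <- permute_time(trended, edu, n_perm = 1, seed = 9, attribute = "N")
  b <- permute_time(trended, edu, n_perm = 1, seed = 9, attribute = "N")
  expect_identical(a$null_rho, b$null_rho)
  expect_identical(a$null_r2, b$null_r2)
})
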