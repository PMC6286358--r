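test_that("generator parameters are validated", {
  expect_error(generator_params(0.6, 0.3, 0.3), "<= 1")
  expect_error(generator_params(-0.1, 0, 0), "\\[0, 1\\]")
  expect_error(generator_params(0.5, 0.2, 0.1, length = 0), "length")
})

test_that("generator limits match the mixture semantics", {
  # forced novelty: every token distinct
  toks <- generate_transcript(generator_params(1, 0, 0, length = 30),
                              seed = 1)
  expect_equal(graph_attributes(toks)[c("N", "RE", "LSC")],
               c(N = 30, RE = 0, LSC = 1))

  # forced perseveration locks into a short loop: RE near its maximum
  tp <- generate_transcript(generator_params(0, 1, 0, length = 30), seed = 2)
  expect_gte(attr_RE(tp), 27)
  expect_lte(attr_N(tp), 2)

  # determinism under the seed
  p <- generator_params(0.5, 0.2, 0.15, length = 120)
  expect_identical(generate_transcript(p, seed = 7),
                   generate_transcript(p, seed = 7))
  expect_false(identical(generate_transcript(p, seed = 7),
                         generate_transcript(p, seed = 8)))
})

test_that("each generator dial drives its attribute monotonically", {
  mean_attr <- function(theta, reps = 40) {
    vals <- vapply(seq_len(reps), function(r) {
      p <- do.call(generator_params, c(theta, list(length = 300)))
      windowed_profile(generate_transcript(p, seed = 1000 + r))$mean_attributes
    }, numeric(4))
    rowMeans(vals)
  }
  lo_new <- mean_attr(list(theta_new = 0.3, theta_persev = 0.2,
                           theta_return = 0.1))
  hi_new <- mean_attr(list(theta_new = 0.7, theta_persev = 0.2,
                           theta_return = 0.1))
  expect_gt(hi_new[["N"]], lo_new[["N"]])

  lo_per <- mean_attr(list(theta_new = 0.4, theta_persev = 0.05,
                           theta_return = 0.1))
  hi_per <- mean_attr(list(theta_new = 0.4, theta_persev = 0.45,
                           theta_return = 0.1))
  expect_gt(hi_per[["RE"]], lo_per[["RE"]])

  lo_ret <- mean_attr(list(theta_new = 0.45, theta_persev = 0.2,
                           theta_return = 0.02))
  hi_ret <- mean_attr(list(theta_new = 0.45, theta_persev = 0.2,
                           theta_return = 0.33))
  expect_gt(hi_ret[["LSC"]], lo_ret[["LSC"]])
})

test_that("cohort metadata has the specified coupling and dropout rates", {
  spec <- cohort_spec(n_control = 300, n_psychosis = 300,
                      transcript_length = 40)
  coh <- generate_cohort(spec, seed = 5)
  md <- attr(coh, "metadata")
  expect_equal(nrow(md), 600)
  # education never exceeds the schooling potential
  expect_true(all(md$education_years <= pmax(md$age_years - 6, 0) + 1e-9))
  # dropout rates within binomial error of 0.28 / 0.62 at n = 300
  p_ctl <- mean(md$dropout[md$group == "control"])
  p_psy <- mean(md$dropout[md$group == "psychosis"])
  expect_lt(abs(p_ctl - 0.28), 3 * sqrt(0.28 * 0.72 / 300))
  expect_lt(abs(p_psy - 0.62), 3 * sqrt(0.62 * 0.38 / 300))

  # degenerate age interval
  one_age <- generate_cohort(cohort_spec(n_control = 5, n_psychosis = 5,
                                         age_range = c(30, 30),
                                         transcript_length = 40), seed = 6)
  expect_true(all(attr(one_age, "metadata")$age_years == 30))

  expect_error(cohort_spec(n_control = 0), "n_control")
})

test_that("a generated cohort round-trips through the corpus reader", {
  spec <- cohort_spec(n_control = 4, n_psychosis = 3,
                      transcript_length = 60)
  coh <- generate_cohort(spec, seed = 9)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir, file.path(dir, "metadata.csv"))
  expect_length(back, 7)
  for (id in names(coh)) {
    expect_identical(back[[id]]$tokens, coh[[id]]$tokens)
    expect_identical(back[[id]]$group, coh[[id]]$group)
    expect_equal(back[[id]]$education_years, coh[[id]]$education_years)
  }
})

test_that("generated binned series follow the curve as specified", {
  b0 <- generate_binned_series(4, 18, 6, bins = 12, per_bin = 5,
                               noise_sd = 0, seed = 1)
  expect_equal(b0$mean, maturation_curve(0:11, 4, 18, 6))
  expect_equal(b0$sem, rep(0, 12))

  bf <- generate_binned_series(7, 7, 3, bins = 10, per_bin = 5,
                               noise_sd = 0, seed = 1)
  expect_true(all(bf$mean == 7))  # f0 = f_inf: flat regardless of T

  bn <- generate_binned_series(4, 18, 6, bins = 20, per_bin = 10,
                               noise_sd = 0.2, seed = 2)
  expect_equal(bn$sem, rep(0.2 / sqrt(10), 20))
  fit <- fit_maturation(bn, attribute = "N")
  truth <- c(f0 = 4, f_inf = 18, T = 6)
  expect_true(all(abs(coef(fit) - truth) / truth < 0.10))
})

test_that("control maturation and psychosis flatness propagate end-to-end", {
  # small, fast cohort: the full-size directional checks are the
  # acceptance suite's job
  spec <- cohort_spec(n_control = 30, n_psychosis = 30,
                      transcript_length = 150, noise_sd = 0.02)
  tab <- analyze_cohort(generate_cohort(spec, seed = 17), n_shuffles = 0)
  ctl <- tab[tab$group == "control", ]
  psy <- tab[tab$group == "psychosis", ]
  rho_ctl <- cor(ctl$mean_N, ctl$education_years, method = "spearman")
  rho_psy <- cor(psy$mean_N, psy$education_years, method = "spearman")
  expect_gt(rho_ctl, 0.5)
  expect_lt(abs(rho_psy), 0.4)
})
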