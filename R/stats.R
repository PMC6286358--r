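#' Statistical test results
#'
#' Lightweight container for the cohort statistics battery. Every test
#' returns a `"stat_result"` with the test name, statistic, p-value, sample
#' size, and — when a Bonferroni-corrected threshold applies — the corrected
#' alpha and the resulting significance flag.
#'
#' @param test_name character label.
#' @param statistic numeric test statistic.
#' @param p_value p-value in \[0, 1\].
#' @param n sample size.
#' @param alpha_corrected optional corrected significance threshold.
#' @param covariates optional character vector of adjustment variables.
#' @param note optional free-text qualifier.
#' @return an object of class `"stat_result"`.
#' @export
stat_result <- function(test_name, statistic, p_value, n,
                        alpha_corrected = NULL, covariates = NULL,
                        note = NULL) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(
    test_name = test_name, statistic = unname(statistic),
    p_value = unname(p_value), n = as.integer(n),
    alpha_corrected = alpha_corrected,
    significant = if (is.null(alpha_corrected)) NULL
                  else isTRUE(p_value < alpha_corrected),
    covariates = covariates, note = note),
    class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$test_name, ": statistic = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 4), ", n = ", x$n, sep = "")
  if (!is.null(x$alpha_corrected))
    cat(", alpha = ", round(x$alpha_corrected, 4),
        if (x$significant) " *" else " (n.s.)", sep = "")
  if (!is.null(x$covariates))
    cat(" [adjusted for ", paste(x$covariates, collapse = ", "), "]", sep = "")
  if (!is.null(x$note)) cat("  —", x$note)
  cat("\n")
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' Returns `alpha / m` exactly; displays round to 4 decimals (0.05 over 8
#' comparisons prints as 0.0063 but is retained as 0.00625 internally).
#'
#' @param alpha family-wise level, in (0, 1).
#' @param m number of comparisons, >= 1.
#' @return the exact corrected threshold.
#' @export
bonferroni <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Spearman rank correlation
#'
#' Tie-corrected (midrank) Spearman correlation with a two-sided p-value
#' from the t approximation (`exact_perm = TRUE` instead draws an empirical
#' permutation p, useful at very small n).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param alpha,m optional family-wise level and comparison count; when
#'   given, the result carries `alpha_corrected = alpha/m`.
#' @param exact_perm use a permutation p-value instead of the t approximation.
#' @param n_perm permutations when `exact_perm = TRUE`.
#' @return a [stat_result()] whose `statistic` is rho.
#' @export
spearman <- function(x, y, alpha = NULL, m = 1, exact_perm = FALSE,
                     n_perm = 10000) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector")
  rho <- cor(x, y, method = "spearman")
  p <- if (exact_perm) {
    null <- replicate(n_perm, cor(x, sample(y), method = "spearman"))
    (1 + sum(abs(null) >= abs(rho))) / (n_perm + 1)
  } else {
    suppressWarnings(cor.test(x, y, method = "spearman",
                              exact = FALSE)$p.value)
  }
  stat_result("Spearman", rho, p, length(x),
              alpha_corrected = if (is.null(alpha)) NULL else
                bonferroni(alpha, m))
}

#' First-order partial Spearman correlation
#'
#' Correlation between `x` and `y` with `z` partialled out, on midranks:
#' all three vectors are rank-transformed, the Pearson partial correlation
#' \deqn{r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) /
#'   \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}
#' is formed on the ranks, and the p-value uses a t statistic with `n - 3`
#' degrees of freedom. If `z` is constant the plain Spearman correlation is
#' returned (nothing to partial out).
#'
#' @param x,y,z numeric vectors of equal length >= 4.
#' @inheritParams spearman
#' @param z_name label of the adjustment variable.
#' @return a [stat_result()] whose `statistic` is the partial rho.
#' @export
partial_spearman <- function(x, y, z, alpha = NULL, m = 1, z_name = "z") {
  stopifnot(length(x) == length(y), length(y) == length(z))
  keep <- !is.na(x) & !is.na(y) & !is.na(z)
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete triples")
  ac <- if (is.null(alpha)) NULL else bonferroni(alpha, m)
  if (sd(z) == 0) {
    out <- spearman(x, y, alpha = alpha, m = m)
    out$test_name <- "partial Spearman (constant z)"
    out$covariates <- z_name
    return(out)
  }
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  rxy <- cor(rx, ry); rxz <- cor(rx, rz); ryz <- cor(ry, rz)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("partial correlation undefined: a variable is a monotone function of z")
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- clamp(r, -1, 1)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 3) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 3)
  }
  stat_result("partial Spearman", r, p, n, alpha_corrected = ac,
              covariates = z_name)
}

#' Multiple linear regression of an attribute on age and education
#'
#' Ordinary least squares `attribute ~ age + education`, reporting the model
#' R^2, the overall F-test p-value, both slopes and their difference
#' (`coef_diff = coef_edu - coef_age`), the contrast used to judge whether
#' education dominates age.
#'
#' @param attribute,age,education numeric vectors of equal length >= 4.
#' @return object of class `"regression_result"`.
#' @export
multiple_regression <- function(attribute, age, education) {
  stopifnot(length(attribute) == length(age),
            length(age) == length(education))
  df <- data.frame(y = attribute, age = age, education = education)
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 4) stop("need at least 4 complete cases")
  qrX <- qr(cbind(1, df$age, df$education))
  if (qrX$rank < 3) stop("singular design: age and education are collinear")
  fit <- lm(y ~ age + education, data = df)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p_overall <- unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  cf <- coef(fit)
  structure(list(r_squared = sm$r.squared, p_overall = p_overall,
                 coef_age = unname(cf[["age"]]),
                 coef_edu = unname(cf[["education"]]),
                 coef_diff = unname(cf[["education"]] - cf[["age"]]),
                 n = nrow(df), lm = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "OLS attribute ~ age + education (n = %d)\n  R^2 = %.4f, overall p = %.4g\n  coef age = %.4f, coef edu = %.4f, edu - age = %.4f\n",
    x$n, x$r_squared, x$p_overall, x$coef_age, x$coef_edu, x$coef_diff))
  invisible(x)
}

#' Kruskal–Wallis plus pairwise Wilcoxon group tests
#'
#' Omnibus tie-corrected Kruskal–Wallis test across all groups, followed by
#' two-tailed Wilcoxon rank-sum tests for each requested pair, each reported
#' against the Bonferroni-corrected threshold `alpha / m_corrections`. The
#' Wilcoxon tests use the exact distribution when both groups have at most
#' 10 observations and no ties, and the tie- and continuity-corrected normal
#' approximation otherwise.
#'
#' @param values_by_group named list of numeric vectors (>= 2 groups, each
#'   with >= 2 observations).
#' @param comparisons list of length-2 character vectors of group names;
#'   defaults to all pairs.
#' @param m_corrections number of comparisons for the Bonferroni correction;
#'   defaults to `length(comparisons)`.
#' @param alpha family-wise level.
#' @return list of [stat_result()]: the Kruskal–Wallis test first, then one
#'   Wilcoxon result per pair (named `"A vs B"`).
#' @export
group_tests <- function(values_by_group, comparisons = NULL,
                        m_corrections = NULL, alpha = 0.05) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2,
            !is.null(names(values_by_group)))
  sizes <- lengths(values_by_group)
  if (any(sizes < 2))
    stop("every group needs at least 2 observations (",
         paste(names(values_by_group)[sizes < 2], collapse = ", "), ")")
  if (is.null(comparisons))
    comparisons <- utils::combn(names(values_by_group), 2, simplify = FALSE)
  if (is.null(m_corrections)) m_corrections <- length(comparisons)
  ac <- bonferroni(alpha, m_corrections)

  kw <- kruskal.test(values_by_group)
  out <- list(kruskal_wallis = stat_result(
    "Kruskal-Wallis", unname(kw$statistic), kw$p.value,
    sum(sizes), alpha_corrected = alpha))
  for (cmp in comparisons) {
    a <- values_by_group[[cmp[1]]]; b <- values_by_group[[cmp[2]]]
    use_exact <- length(a) <= 10 && length(b) <= 10
    wt <- suppressWarnings(wilcox.test(a, b, exact = use_exact,
                                       correct = TRUE))
    out[[paste(cmp[1], "vs", cmp[2])]] <- stat_result(
      paste("Wilcoxon rank-sum:", cmp[1], "vs", cmp[2]),
      unname(wt$statistic), wt$p.value, length(a) + length(b),
      alpha_corrected = ac)
  }
  out
}

#' Distributional assumption checks
#'
#' Per group, a one-sample Kolmogorov–Smirnov test against a normal
#' distribution with the group's estimated mean and SD (flagged approximate:
#' estimating the moments from the same data makes the test conservative),
#' plus Levene's test of variance homogeneity across groups (classic
#' mean-centered by default; `center = "median"` gives Brown–Forsythe).
#' Together these motivate (or not) the nonparametric battery.
#'
#' @inheritParams group_tests
#' @param center centering for Levene's test.
#' @return named list of [stat_result()]: one `ks_<group>` per group and one
#'   `levene` entry.
#' @export
distribution_checks <- function(values_by_group,
                                center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(is.list(values_by_group), !is.null(names(values_by_group)))
  sizes <- lengths(values_by_group)
  if (any(sizes < 4)) stop("every group needs at least 4 observations")
  if (all(vapply(values_by_group, function(v) sd(v) == 0, logical(1))))
    stop("degenerate input: all groups are constant")
  out <- list()
  for (g in names(values_by_group)) {
    v <- values_by_group[[g]]
    if (sd(v) == 0) stop("degenerate input: group '", g, "' is constant")
    ks <- suppressWarnings(ks.test(v, "pnorm", mean(v), sd(v)))
    out[[paste0("ks_", g)]] <- stat_result(
      paste("Kolmogorov-Smirnov normality:", g), unname(ks$statistic),
      ks$p.value, length(v),
      note = "approximate: normal parameters estimated from the sample")
  }
  y <- unlist(values_by_group, use.names = FALSE)
  grp <- factor(rep(names(values_by_group), sizes))
  lv <- car::leveneTest(y, grp, center = if (center == "mean") mean else median)
  out$levene <- stat_result(
    paste0("Levene (center = ", center, ")"),
    lv[1, "F value"], lv[1, "Pr(>F)"], length(y))
  out
}

#' Two-sample Kolmogorov–Smirnov test
#'
#' @param x,y numeric vectors.
#' @return a [stat_result()].
#' @export
ks_two_sample <- function(x, y) {
  ks <- suppressWarnings(ks.test(x, y))
  stat_result("Kolmogorov-Smirnov two-sample", unname(ks$statistic),
              ks$p.value, length(x) + length(y))
}

#' Chi-square test for two proportions
#'
#' Compares `k1/n1` with `k2/n2` (e.g. school-dropout frequency in two
#' groups) with a 2x2 chi-square test, by default without Yates continuity
#' correction.
#'
#' @param k1,n1,k2,n2 successes and totals in each group.
#' @param correct apply the Yates continuity correction.
#' @return a [stat_result()] whose `statistic` is the chi-square value.
#' @export
proportion_test <- function(k1, n1, k2, n2, correct = FALSE) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (k1 / n1 == k2 / n2)
    return(stat_result("chi-square proportions", 0, 1, n1 + n2))
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  stat_result("chi-square proportions", unname(ct$statistic), ct$p.value,
              n1 + n2)
}

#' Confound battery for a covariate table
#'
#' Runs the generic confound pattern on a per-subject table: sex difference
#' per attribute (Wilcoxon), income correlation (Spearman), partial
#' correlations with education adjusted by a covariate, and medication-dose
#' correlation when a dose column is present. Only covariate columns present
#' in `data` are analysed.
#'
#' @param data data.frame with columns `education_years` and attribute
#'   columns, plus optional `sex`, `income`, `cpz_dose`.
#' @param attributes attribute column names to analyse.
#' @param alpha family-wise level; corrected for `length(attributes)`
#'   comparisons per block.
#' @return nested list of [stat_result()] per block and attribute.
#' @export
confound_battery <- function(data, attributes = c("mean_N", "mean_RE",
                                                  "mean_LSC", "mean_ASP"),
                             alpha = 0.05) {
  attributes <- intersect(attributes, names(data))
  if (!length(attributes)) stop("no attribute columns found in data")
  m <- length(attributes)
  out <- list()
  if (!is.null(data$sex) && length(unique(na.omit(data$sex))) >= 2) {
    out$sex <- lapply(setNames(attributes, attributes), function(a) {
      byg <- split(data[[a]], data$sex)
      byg <- byg[names(byg) %in% c("male", "female")]
      wt <- suppressWarnings(wilcox.test(byg[[1]], byg[[2]]))
      stat_result(paste("Wilcoxon sex difference:", a),
                  unname(wt$statistic), wt$p.value,
                  sum(lengths(byg)), alpha_corrected = bonferroni(alpha, m))
    })
  }
  if (!is.null(data$income) && sum(!is.na(data$income)) >= 4) {
    out$income <- lapply(setNames(attributes, attributes), function(a)
      spearman(data[[a]], data$income, alpha = alpha, m = m))
    out$education_adjusted_income <- lapply(
      setNames(attributes, attributes), function(a)
        partial_spearman(data[[a]], data$education_years, data$income,
                         alpha = alpha, m = m, z_name = "income"))
  }
  if (!is.null(data$cpz_dose) && sum(!is.na(data$cpz_dose)) >= 4) {
    out$dose <- lapply(setNames(attributes, attributes), function(a)
      spearman(data[[a]], data$cpz_dose, alpha = alpha, m = m))
    out$education_adjusted_dose <- lapply(
      setNames(attributes, attributes), function(a)
        partial_spearman(data[[a]], data$education_years, data$cpz_dose,
                         alpha = alpha, m = m, z_name = "cpz_dose"))
  }
  out
}
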