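#' Saturating-exponential maturation curve
#'
#' The developmental trajectory assumed for every graph attribute:
#' \deqn{f(t) = f_0 + (f_\infty - f_0)(1 - e^{-t/T})}
#' the unique solution of \eqn{df/dt = (f_\infty - f)/T} with
#' \eqn{f(0) = f_0}. `t` is years of age or of education, `f0` the initial
#' value, `f_inf` the asymptote, and `T` the characteristic time (years) at
#' which \eqn{1 - e^{-1} \approx 63\%} of the total change is reached. The
#' curve is monotone: increasing when `f_inf > f0`, decreasing otherwise.
#'
#' @param t time in years (vectorized).
#' @param f0 initial value.
#' @param f_inf asymptotic value.
#' @param T characteristic time, strictly positive.
#' @return numeric vector of curve values.
#' @examples
#' maturation_curve(6, f0 = 0, f_inf = 1, T = 6) # 1 - exp(-1)
#' @export
maturation_curve <- function(t, f0, f_inf, T) {
  if (any(T <= 0)) stop("characteristic time T must be > 0")
  f0 + (f_inf - f0) * (1 - exp(-t / T))
}

#' Bin per-subject values by integer years
#'
#' Averages an attribute over all subjects sharing the same (floored) year of
#' age or education, the aggregation on which the maturation model is fit.
#' SEM is the sample standard deviation divided by the square root of the bin
#' count; it is `NA` for single-subject bins (handled by [fit_maturation()]).
#'
#' @param values per-subject attribute values.
#' @param times per-subject years (age or education), same length.
#' @param variable label: `"education_years"` or `"age_years"`.
#' @return data.frame of class `"binned_series"` with columns `bin`
#'   (integer years, ascending), `mean`, `sem`, `n`, and attribute
#'   `"variable"`.
#' @export
bin_series <- function(values, times,
                       variable = c("education_years", "age_years")) {
  variable <- match.arg(variable)
  stopifnot(length(values) == length(times), length(values) > 0)
  keep <- !is.na(values) & !is.na(times)
  values <- values[keep]; times <- times[keep]
  b <- floor(times)
  bins <- sort(unique(b))
  out <- data.frame(
    bin = as.integer(bins),
    mean = vapply(bins, function(k) mean(values[b == k]), numeric(1)),
    sem = vapply(bins, function(k) {
      v <- values[b == k]
      if (length(v) < 2) NA_real_ else sd(v) / sqrt(length(v))
    }, numeric(1)),
    n = vapply(bins, function(k) sum(b == k), integer(1)))
  structure(out, variable = variable, class = c("binned_series", "data.frame"))
}

as_binned <- function(x) {
  if (inherits(x, "binned_series")) return(x)
  stopifnot(is.data.frame(x), all(c("bin", "mean", "sem", "n") %in% names(x)))
  structure(x, class = c("binned_series", "data.frame"))
}

attribute_bounds <- function(attribute, window_length = 30) {
  # node-counted attributes are bounded by the window's node capacity,
  # edge-counted ones by its edge capacity
  vmax <- if (attribute %in% c("N", "LSC")) window_length else window_length - 1
  c(lower = 0, upper = vmax)
}

#' Fit the maturation model to binned attribute data
#'
#' Bounded, SEM-weighted nonlinear least squares of the saturating
#' exponential [maturation_curve()] on bin means. The fit follows the
#' conventions of the windowed word-graph analysis: values are binned at
#' integer years ([bin_series()]); weights are `1/SEM^2` (inverse variance;
#' `weights = "inv_sem"` uses `1/SEM`); box bounds reflect what a 30-word
#' window can hold — `f0, f_inf` in `[0, 30]` for node-counted attributes (N,
#' LSC) and `[0, 29]` for edge-counted ones (RE, ASP) — and the
#' characteristic time is bounded in `[0, 30]` years; start points are
#' `f_inf` = maximum bin mean, `f0` = minimum bin mean, `T` = 12 years.
#'
#' Single-subject bins have no SEM; they are kept in the fit with the largest
#' SEM observed among multi-subject bins (the weakest finite weight). Zero
#' SEMs (noiseless data) are replaced by the smallest positive SEM; if no
#' positive SEM exists the fit is unweighted.
#'
#' The optimizer is Levenberg–Marquardt with box constraints
#' ([minpack.lm::nlsLM()]); on failure the start point is jittered uniformly
#' within bounds up to `restarts` times and the best (lowest weighted SSE)
#' iterate is kept, with `converged = FALSE` if no attempt converged.
#' Goodness of fit is reported on the unweighted bin means: `r_squared`
#' = 1 − SSE/SST (0 for a flat series), `sse`, and
#' `rmse = sqrt(SSE / (n_bins − 3))`.
#'
#' @param x a formula like `mean_N ~ education_years` evaluated in `data`, a
#'   `binned_series`, or a numeric vector of per-subject values (then supply
#'   `times`).
#' @param data data.frame for the formula interface.
#' @param times per-subject years when `x` is a numeric vector.
#' @param attribute one of `"N"`, `"RE"`, `"LSC"`, `"ASP"`; sets the value
#'   bounds. Guessed from the formula/variable name when possible.
#' @param time_variable `"education_years"` or `"age_years"` (label only).
#' @param weights `"inv_sem_sq"` (default) or `"inv_sem"`.
#' @param window_length window size defining the attribute bounds.
#' @param t_start start point for the characteristic time (years).
#' @param restarts jittered restarts on non-convergence.
#' @param ... passed between methods.
#' @return object of class `"maturation_fit"`; see
#'   [print.maturation_fit()] and friends.
#' @examples
#' set.seed(1)
#' b <- generate_binned_series(f0 = 4, f_inf = 18, T = 6, bins = 20,
#'                             per_bin = 10, noise_sd = 0.2)
#' fit <- fit_maturation(b, attribute = "N")
#' coef(fit)
#' @export
fit_maturation <- function(x, ...) UseMethod("fit_maturation")

#' @rdname fit_maturation
#' @export
fit_maturation.formula <- function(x, data, attribute = NULL, ...) {
  mf <- model.frame(x, data)
  values <- mf[[1]]
  times <- mf[[2]]
  tv_name <- names(mf)[2]
  time_variable <- if (grepl("age", tv_name, ignore.case = TRUE) &&
                       !grepl("edu", tv_name, ignore.case = TRUE))
    "age_years" else "education_years"
  if (is.null(attribute)) attribute <- guess_attribute(names(mf)[1])
  out <- fit_maturation.numeric(values, times = times, attribute = attribute,
                                time_variable = time_variable, ...)
  out$call <- match.call()
  out
}

guess_attribute <- function(nm) {
  for (a in c("LSC", "ASP", "RE", "N"))
    if (grepl(paste0("(^|_)", a, "$"), nm, ignore.case = TRUE)) return(a)
  stop("cannot guess the attribute from '", nm,
       "'; pass attribute = \"N\", \"RE\", \"LSC\" or \"ASP\"")
}

#' @rdname fit_maturation
#' @export
fit_maturation.numeric <- function(x, times,
                                   attribute = c("N", "RE", "LSC", "ASP"),
                                   time_variable = c("education_years",
                                                     "age_years"), ...) {
  attribute <- match.arg(attribute)
  time_variable <- match.arg(time_variable)
  b <- bin_series(x, times, variable = time_variable)
  out <- fit_maturation.binned_series(b, attribute = attribute, ...)
  out$n_subjects <- sum(!is.na(x) & !is.na(times))
  out$call <- match.call()
  out
}

#' @rdname fit_maturation
#' @export
fit_maturation.binned_series <- function(x,
                                         attribute = c("N", "RE", "LSC", "ASP"),
                                         weights = c("inv_sem_sq", "inv_sem"),
                                         window_length = 30, t_start = 12,
                                         restarts = 10, ...) {
  attribute <- match.arg(attribute)
  weights <- match.arg(weights)
  b <- as_binned(x)
  if (nrow(b) < 4)
    stop("need at least 4 bins to fit the 3-parameter model (got ",
         nrow(b), ")")
  b <- b[order(b$bin), , drop = FALSE]

  sem <- b$sem
  multi <- !is.na(sem)
  if (any(!multi)) {
    if (any(multi)) sem[!multi] <- max(sem[multi])
    else sem[] <- 1   # all singleton bins: unweighted
  }
  if (any(sem == 0)) {
    pos <- sem[sem > 0]
    sem[sem == 0] <- if (length(pos)) min(pos) else 1
  }
  w <- if (weights == "inv_sem_sq") 1 / sem^2 else 1 / sem

  bnd <- attribute_bounds(attribute, window_length)
  lower <- c(f0 = bnd[["lower"]], f_inf = bnd[["lower"]], T = 1e-6)
  upper <- c(f0 = bnd[["upper"]], f_inf = bnd[["upper"]], T = 30)
  start0 <- c(f0 = clamp(min(b$mean), lower[["f0"]], upper[["f0"]]),
              f_inf = clamp(max(b$mean), lower[["f_inf"]], upper[["f_inf"]]),
              T = clamp(t_start, 0.5, upper[["T"]]))

  df <- data.frame(t = b$bin, y = b$mean)
  one_fit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(y ~ f0 + (f_inf - f0) * (1 - exp(-t / T)),
                        data = df, start = as.list(start), weights = w,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  best <- NULL; best_wsse <- Inf; converged <- FALSE
  starts <- list(start0)
  for (k in seq_len(restarts))
    starts[[k + 1]] <- c(f0 = runif(1, lower[["f0"]], upper[["f0"]]),
                         f_inf = runif(1, lower[["f_inf"]], upper[["f_inf"]]),
                         T = runif(1, 0.5, upper[["T"]]))
  for (k in seq_along(starts)) {
    m <- one_fit(starts[[k]])
    if (is.null(m)) next
    wsse <- sum(w * resid(m)^2)
    conv <- isTRUE(m$convInfo$isConv)
    if (wsse < best_wsse - 1e-12 || (conv && !converged)) {
      best <- m; best_wsse <- wsse; converged <- conv
    }
    if (k == 1 && conv) break  # default start converged; no restarts needed
  }
  cf <- if (!is.null(best)) coef(best) else {
    # degenerate data (e.g. a flat series makes T unidentifiable) can defeat
    # the gradient-based optimizer; fall back to bounded direct minimization
    obj <- function(p) sum(w * (b$mean - maturation_curve(b$bin, p[1], p[2],
                                                          max(p[3], 1e-6)))^2)
    op <- optim(start0, obj, method = "L-BFGS-B", lower = lower,
                upper = upper)
    converged <- op$convergence == 0
    best_wsse <- op$value
    setNames(op$par, c("f0", "f_inf", "T"))
  }
  fit_vals <- maturation_curve(b$bin, cf[["f0"]], cf[["f_inf"]], cf[["T"]])
  sse <- sum((b$mean - fit_vals)^2)
  sst <- sum((b$mean - mean(b$mean))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 0
  structure(list(
    coefficients = c(f0 = unname(cf[["f0"]]), f_inf = unname(cf[["f_inf"]]),
                     T = unname(cf[["T"]])),
    delta = abs(cf[["f_inf"]] - cf[["f0"]]),
    r_squared = r2, sse = sse,
    rmse = sqrt(sse / max(nrow(b) - 3, 1)),
    wsse = best_wsse,
    converged = converged,
    binned = b, fitted_bins = fit_vals, weights_scheme = weights,
    attribute = attribute, time_variable = attr(b, "variable"),
    bounds = list(lower = lower, upper = upper), nls = best,
    n_subjects = sum(b$n), call = match.call()),
    class = "maturation_fit")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Methods for maturation fits
#'
#' Standard accessors for `"maturation_fit"` objects: `coef()` returns
#' `(f0, f_inf, T)`; `predict()` evaluates the fitted curve at new times
#' (`newdata` may be a numeric vector of years or a data.frame with a `t`
#' column; defaults to the fitted bin centers); `residuals()` and `fitted()`
#' operate on the bin means; `plot()` draws bin means with SEM bars and the
#' fitted curve; `simulate()` draws new bin-mean series from the fitted
#' curve plus Gaussian noise with the residual standard deviation.
#'
#' @param x,object a `"maturation_fit"`.
#' @param newdata numeric vector of years or data.frame with column `t`.
#' @param nsim number of simulated series.
#' @param seed optional seed.
#' @param ... further arguments (graphics parameters for `plot`).
#' @name maturation_fit-methods
NULL

#' @rdname maturation_fit-methods
#' @export
print.maturation_fit <- function(x, ...) {
  cat("Saturating-exponential maturation fit:", x$attribute, "~",
      x$time_variable, "\n")
  cat(sprintf("  f0 = %.3f, f_inf = %.3f, T = %.2f y, |f_inf - f0| = %.3f\n",
              x$coefficients[["f0"]], x$coefficients[["f_inf"]],
              x$coefficients[["T"]], x$delta))
  cat(sprintf("  R^2 = %.4f, SSE = %.4f, RMSE = %.4f on %d bins (%d subjects)%s\n",
              x$r_squared, x$sse, x$rmse, nrow(x$binned), x$n_subjects,
              if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

#' @rdname maturation_fit-methods
#' @export
summary.maturation_fit <- function(object, ...) {
  se <- tryCatch(sqrt(diag(vcov(object$nls))), error = function(e)
    rep(NA_real_, 3))
  out <- list(coefficients = cbind(Estimate = object$coefficients,
                                   `Std. Error` = se),
              delta = object$delta, r_squared = object$r_squared,
              sse = object$sse, rmse = object$rmse,
              converged = object$converged,
              attribute = object$attribute,
              time_variable = object$time_variable,
              n_bins = nrow(object$binned), n_subjects = object$n_subjects)
  class(out) <- "summary.maturation_fit"
  out
}

#' @export
print.summary.maturation_fit <- function(x, ...) {
  cat("Maturation fit:", x$attribute, "~", x$time_variable, "\n\n")
  print(round(x$coefficients, 4))
  cat(sprintf("\n|f_inf - f0| = %.4f\nR^2 = %.4f  SSE = %.4f  RMSE = %.4f  (%d bins, %d subjects)\n",
              x$delta, x$r_squared, x$sse, x$rmse, x$n_bins, x$n_subjects))
  if (!x$converged) cat("Warning: optimizer did not converge\n")
  invisible(x)
}

#' @rdname maturation_fit-methods
#' @export
coef.maturation_fit <- function(object, ...) object$coefficients

#' @rdname maturation_fit-methods
#' @export
predict.maturation_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$binned$bin
  else if (is.data.frame(newdata)) newdata$t
  else as.numeric(newdata)
  cf <- object$coefficients
  maturation_curve(t, cf[["f0"]], cf[["f_inf"]], cf[["T"]])
}

#' @rdname maturation_fit-methods
#' @export
fitted.maturation_fit <- function(object, ...) object$fitted_bins

#' @rdname maturation_fit-methods
#' @export
residuals.maturation_fit <- function(object, ...)
  object$binned$mean - object$fitted_bins

#' @rdname maturation_fit-methods
#' @export
plot.maturation_fit <- function(x, ...) {
  b <- x$binned
  xlab <- if (x$time_variable == "age_years") "years of age" else
    "years of education"
  plot(b$bin, b$mean, pch = 19, xlab = xlab, ylab = x$attribute,
       ylim = range(c(b$mean - b$sem, b$mean + b$sem, x$fitted_bins),
                    na.rm = TRUE), ...)
  ok <- !is.na(b$sem) & b$sem > 0
  if (any(ok))
    arrows(b$bin[ok], b$mean[ok] - b$sem[ok], b$bin[ok], b$mean[ok] + b$sem[ok],
           angle = 90, code = 3, length = 0.03)
  tt <- seq(min(b$bin), max(b$bin), length.out = 200)
  lines(tt, predict(x, tt), lwd = 2)
  invisible(x)
}

#' @rdname maturation_fit-methods
#' @export
simulate.maturation_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  sdres <- sd(residuals(object))
  if (is.na(sdres)) sdres <- 0
  mu <- object$fitted_bins
  out <- as.data.frame(replicate(nsim, mu + rnorm(length(mu), 0, sdres)))
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(bin = object$binned$bin, out)
}
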