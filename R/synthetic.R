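#' Parameters for the synthetic transcript generator
#'
#' The generator emits tokens by a three-way mixture that gives an
#' independent, interpretable dial for each recurrence axis the graph
#' attributes measure:
#' * with probability `theta_new` a previously unseen word is drawn from a
#'   Zipf-weighted pool (drives lexical diversity N up);
#' * with probability `theta_persev` the successor of the current word's
#'   previous occurrence is re-emitted, reproducing an earlier bigram
#'   (drives repeated edges RE up);
#' * with probability `theta_return` the process jumps to a uniformly chosen
#'   earlier word, closing long-range cycles (drives LSC and ASP up);
#' * with the residual probability a recently used word is repeated.
#'
#' @param theta_new,theta_persev,theta_return mixture probabilities in
#'   \[0, 1\] with sum <= 1.
#' @param length number of tokens to emit (>= 1).
#' @param zipf_exponent exponent of the rank-frequency law shaping the
#'   novel-word pool.
#' @param pool_size size of the word pool novel words are drawn from.
#' @param recent_k how far back the residual "recent word" choice looks.
#' @return an object of class `"generator_params"`.
#' @export
generator_params <- function(theta_new, theta_persev, theta_return,
                             length = 300, zipf_exponent = 1.1,
                             pool_size = 5000, recent_k = 5) {
  th <- c(theta_new, theta_persev, theta_return)
  if (any(th < 0) || any(th > 1))
    stop("all theta probabilities must lie in [0, 1]")
  if (sum(th) > 1 + 1e-12)
    stop("theta_new + theta_persev + theta_return must be <= 1 (got ",
         round(sum(th), 4), ")")
  if (length < 1) stop("length must be >= 1")
  structure(list(theta_new = theta_new, theta_persev = theta_persev,
                 theta_return = theta_return, length = as.integer(length),
                 zipf_exponent = zipf_exponent,
                 pool_size = as.integer(pool_size),
                 recent_k = as.integer(recent_k)),
            class = "generator_params")
}

#' Generate one synthetic transcript
#'
#' Emits `params$length` tokens by the mixture process described in
#' [generator_params()]. Deterministic given `seed`.
#'
#' @param params a [generator_params()] object.
#' @param seed optional integer seed.
#' @return character vector of tokens.
#' @examples
#' toks <- generate_transcript(generator_params(1, 0, 0, length = 30), seed = 1)
#' attr_N(toks) # all distinct
#' @export
generate_transcript <- function(params, seed = NULL) {
  stopifnot(inherits(params, "generator_params"))
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  V <- params$pool_size
  zipf_w <- (1:V)^(-params$zipf_exponent)
  words <- sprintf("w%05d", 1:V)
  seen <- logical(V)
  L <- params$length
  ids <- integer(L)
  # positions of the most recent and next-most-recent occurrence per word
  last_pos <- integer(V)
  penult_pos <- integer(V)

  draw_novel <- function() {
    unseen <- which(!seen)
    if (!length(unseen)) return(sample.int(V, 1, prob = zipf_w))
    if (length(unseen) == 1) unseen else
      sample(unseen, 1, prob = zipf_w[unseen])
  }
  emit <- function(t, w) {
    ids[t] <<- w
    penult_pos[w] <<- last_pos[w]
    last_pos[w] <<- t
    seen[w] <<- TRUE
  }
  emit(1L, draw_novel())
  thr <- cumsum(c(params$theta_new, params$theta_persev, params$theta_return))
  for (t in seq_len(L)[-1]) {
    u <- runif(1)
    cur <- ids[t - 1L]
    w <- if (u < thr[1]) {
      draw_novel()
    } else if (u < thr[2]) {
      # reproduce the bigram that followed the current word last time around
      prev <- penult_pos[cur]
      if (prev > 0 && prev + 1L < t) ids[prev + 1L] else recent_word(ids, t, params$recent_k)
    } else if (u < thr[3]) {
      distinct <- unique(ids[seq_len(t - 1L)])
      if (length(distinct) == 1) distinct else sample(distinct, 1)
    } else {
      recent_word(ids, t, params$recent_k)
    }
    emit(t, w)
  }
  words[ids]
}

recent_word <- function(ids, t, k) {
  lo <- max(1L, t - k)
  cand <- ids[lo:(t - 1L)]
  if (length(cand) == 1) cand else sample(cand, 1)
}

#' Specification of a synthetic cohort
#'
#' Describes a two-group cohort (controls and psychosis) whose speech-graph
#' structure matures with education in the control group only. For controls,
#' each generator dial follows the saturating-exponential
#' [maturation_curve()] in years of education with the given
#' `(f0, f_inf, T)`; psychosis-like subjects keep the flat, child-like level
#' `f0` regardless of age or education. Ages are drawn uniformly in
#' `age_range`; education is coupled to age (schooling from age 6, capped at
#' 22 years) with group-specific school-dropout truncation.
#'
#' @param n_control,n_psychosis group sizes.
#' @param age_range ages in years, drawn uniformly.
#' @param trajectories named list with elements `theta_new`, `theta_persev`,
#'   `theta_return`, each `c(f0 = , f_inf = , T = )` on the probability
#'   scale.
#' @param dropout_prob_control,dropout_prob_psychosis school-dropout
#'   probabilities (defaults 0.28 and 0.62).
#' @param noise_sd SD of the Gaussian jitter added to each subject's theta.
#' @param transcript_length tokens per transcript.
#' @param zipf_exponent passed to [generator_params()].
#' @return an object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_control = 135, n_psychosis = 65,
                        age_range = c(2, 58),
                        trajectories = list(
                          theta_new = c(f0 = 0.35, f_inf = 0.62, T = 2),
                          theta_persev = c(f0 = 0.40, f_inf = 0.03, T = 1.5),
                          theta_return = c(f0 = 0.04, f_inf = 0.30, T = 10)),
                        dropout_prob_control = 0.28,
                        dropout_prob_psychosis = 0.62,
                        noise_sd = 0.03, transcript_length = 300,
                        zipf_exponent = 1.1) {
  stopifnot(n_control >= 1, n_psychosis >= 1,
            length(age_range) == 2, age_range[1] <= age_range[2],
            dropout_prob_control >= 0, dropout_prob_control <= 1,
            dropout_prob_psychosis >= 0, dropout_prob_psychosis <= 1,
            noise_sd >= 0,
            all(c("theta_new", "theta_persev", "theta_return") %in%
                  names(trajectories)))
  for (tr in trajectories)
    stopifnot(all(c("f0", "f_inf", "T") %in% names(tr)), tr[["T"]] > 0)
  f0s <- vapply(trajectories, function(tr) tr[["f0"]], numeric(1))
  fis <- vapply(trajectories, function(tr) tr[["f_inf"]], numeric(1))
  if (sum(f0s) > 1 || sum(fis) > 1)
    stop("trajectory f0 (and f_inf) values must sum to <= 1 across the three thetas")
  structure(list(n_control = n_control, n_psychosis = n_psychosis,
                 age_range = age_range, trajectories = trajectories,
                 dropout_prob_control = dropout_prob_control,
                 dropout_prob_psychosis = dropout_prob_psychosis,
                 noise_sd = noise_sd,
                 transcript_length = as.integer(transcript_length),
                 zipf_exponent = zipf_exponent),
            class = "cohort_spec")
}

# deterministic 31-bit string hash, for per-subject RNG streams
string_seed <- function(id, master) {
  h <- as.numeric(master) %% 2147483647
  for (c in utf8ToInt(as.character(id)))
    h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

theta_at <- function(trajectories, education, flat = FALSE) {
  vapply(trajectories, function(tr) {
    if (flat) tr[["f0"]]
    else maturation_curve(education, tr[["f0"]], tr[["f_inf"]], tr[["T"]])
  }, numeric(1))
}

#' Generate a synthetic cohort
#'
#' Draws metadata (ages, education with dropout truncation, sex) and one
#' transcript per subject according to a [cohort_spec()]. Control subjects'
#' generator dials follow the maturation trajectories in education years;
#' psychosis-like subjects keep the flat child-like level. Per-subject RNG
#' streams are derived deterministically from the master seed and the
#' subject id, so results do not depend on generation order.
#'
#' @param spec a [cohort_spec()].
#' @param seed master integer seed.
#' @return an object of class `"cohort"` (see [read_cohort()]) with the
#'   metadata table attached as attribute `"metadata"`.
#' @export
generate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed %% .Machine$integer.max))
  n <- spec$n_control + spec$n_psychosis
  group <- rep(c("control", "psychosis"),
               c(spec$n_control, spec$n_psychosis))
  id <- sprintf("%s%03d", ifelse(group == "control", "C", "P"), seq_len(n))
  age <- runif(n, spec$age_range[1], spec$age_range[2])
  sex <- sample(c("male", "female"), n, replace = TRUE)
  p_drop <- ifelse(group == "control", spec$dropout_prob_control,
                   spec$dropout_prob_psychosis)
  dropout <- rbinom(n, 1, p_drop) == 1
  potential <- pmin(pmax(age - 6, 0), 22)
  # completed schooling lags slightly behind the maximum possible;
  # dropouts stop at a uniform fraction of it
  edu <- pmax(potential - rpois(n, 0.5), 0)
  edu[dropout] <- floor(runif(sum(dropout), 0, 0.6) * potential[dropout])
  edu <- floor(edu)

  records <- vector("list", n)
  for (i in seq_len(n)) {
    sseed <- string_seed(id[i], seed)
    set.seed(sseed)
    th <- theta_at(spec$trajectories, edu[i],
                   flat = group[i] == "psychosis")
    th <- clamp(th + rnorm(3, 0, spec$noise_sd), 0, 0.95)
    if (sum(th) > 0.98) th <- th * 0.98 / sum(th)
    toks <- generate_transcript(
      generator_params(th[["theta_new"]], th[["theta_persev"]],
                       th[["theta_return"]], length = spec$transcript_length,
                       zipf_exponent = spec$zipf_exponent),
      seed = sseed)
    records[[i]] <- transcript(id[i], toks, group[i], age_years = age[i],
                               education_years = edu[i], sex = sex[i],
                               dropout = dropout[i])
  }
  names(records) <- id
  md <- data.frame(subject_id = id, group = group, age_years = age,
                   education_years = edu, sex = sex, income = NA_real_,
                   panss_negative = NA_real_, cpz_dose = NA_real_,
                   dropout = dropout, stringsAsFactors = FALSE)
  structure(records, class = "cohort", metadata = md)
}

#' Write a synthetic cohort to disk
#'
#' Writes one `<subject_id>.txt` per transcript plus `metadata.csv`, in
#' exactly the dialect [read_cohort()] consumes.
#'
#' @param cohort a `"cohort"` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tr in cohort)
    writeLines(paste(tr$tokens, collapse = " "),
               file.path(dir, paste0(tr$subject_id, ".txt")))
  write_metadata(attr(cohort, "metadata"), file.path(dir, "metadata.csv"))
  invisible(dir)
}

#' Simulate a binned attribute series from the maturation curve
#'
#' Direct simulation used for parameter-recovery checks: bin means are
#' [maturation_curve()] evaluations at integer years `0 .. bins - 1` plus
#' Gaussian noise of SD `noise_sd / sqrt(per_bin)`, and each bin's SEM is
#' `noise_sd / sqrt(per_bin)`.
#'
#' @param f0,f_inf,T curve parameters (`T > 0`).
#' @param bins number of integer-year bins.
#' @param per_bin subjects per bin (>= 1).
#' @param noise_sd subject-level noise SD.
#' @param seed optional integer seed.
#' @param variable label for the binning variable.
#' @return a `"binned_series"` data.frame (see [bin_series()]).
#' @export
generate_binned_series <- function(f0, f_inf, T, bins = 20, per_bin = 10,
                                   noise_sd = 0.2, seed = NULL,
                                   variable = c("education_years",
                                                "age_years")) {
  stopifnot(T > 0, per_bin >= 1, bins >= 1)
  variable <- match.arg(variable)
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  t <- 0:(bins - 1)
  sem <- noise_sd / sqrt(per_bin)
  mu <- maturation_curve(t, f0, f_inf, T) + rnorm(bins, 0, sem)
  structure(data.frame(bin = as.integer(t), mean = mu, sem = sem,
                       n = as.integer(per_bin)),
            variable = variable, class = c("binned_series", "data.frame"))
}
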