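#' Per-subject windowed and shuffle-normalized attributes for a cohort
#'
#' Runs the full non-semantic pipeline over a cohort: per subject, the
#' windowed attribute means ([windowed_profile()]) and — unless
#' `n_shuffles = 0` — the shuffle-normalized attributes
#' ([shuffle_normalize()]). Each subject gets an RNG stream derived
#' deterministically from the master seed and the subject id, so results are
#' reproducible and independent of subject order.
#'
#' @param cohort a `"cohort"` (from [read_cohort()] or [generate_cohort()]).
#' @inheritParams shuffle_normalize
#' @param n_shuffles shuffles per window for normalization; 0 skips
#'   normalization.
#' @param seed master seed for the shuffle null.
#' @return data.frame with one row per subject: metadata columns, `n_windows`,
#'   `short_transcript`, mean attributes (`mean_N` .. `mean_ASP`) and, when
#'   normalized, `norm_N` .. `norm_ASP`.
#' @export
analyze_cohort <- function(cohort, window_length = 30, step = 15,
                           n_shuffles = 100, seed = 1,
                           re_mode = c("sum", "excess"),
                           asp_mode = c("directed", "undirected"),
                           normalize_by = c("window", "subject")) {
  stopifnot(inherits(cohort, "cohort"))
  re_mode <- match.arg(re_mode)
  asp_mode <- match.arg(asp_mode)
  normalize_by <- match.arg(normalize_by)
  md <- attr(cohort, "metadata")
  rows <- lapply(cohort, function(tr) {
    wp <- windowed_profile(tr, window_length, step,
                           re_mode = re_mode, asp_mode = asp_mode)
    row <- data.frame(subject_id = tr$subject_id, group = tr$group,
                      age_years = tr$age_years,
                      education_years = tr$education_years, sex = tr$sex,
                      n_tokens = length(tr$tokens),
                      n_windows = wp$n_windows, short_transcript = wp$short,
                      stringsAsFactors = FALSE)
    row[paste0("mean_", names(wp$mean_attributes))] <-
      as.list(wp$mean_attributes)
    if (n_shuffles > 0) {
      nr <- shuffle_normalize(tr, n_shuffles = n_shuffles,
                              seed = string_seed(tr$subject_id, seed),
                              window_length = window_length, step = step,
                              re_mode = re_mode, asp_mode = asp_mode,
                              normalize_by = normalize_by)
      row[names(nr$values)] <- as.list(nr$values)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(md$dropout))
    out$dropout <- md$dropout[match(out$subject_id, md$subject_id)]
  out
}
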