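#' Slice a token sequence into moving windows
#'
#' Fixed-length windows control for verbosity differences between subjects:
#' the default is 30-word windows advancing 15 words (50% overlap). Only
#' full-length windows are emitted; a transcript shorter than one window
#' yields a single short window flagged via the `"short"` attribute.
#'
#' @param tokens character token vector.
#' @param window_length window size in words (>= 2).
#' @param step offset between consecutive windows, `1 <= step <= window_length`.
#' @return list of token windows, with attributes `offsets` (0-based start
#'   offsets) and `short` (logical).
#' @export
make_windows <- function(tokens, window_length = 30, step = 15) {
  stopifnot(window_length >= 2, step >= 1, step <= window_length)
  n <- length(tokens)
  if (n < window_length) {
    if (n == 0) stop("cannot window an empty token sequence")
    return(structure(list(tokens), offsets = 0L, short = TRUE))
  }
  starts <- as.integer(seq.int(1L, n - window_length + 1L, by = step))
  wins <- lapply(starts, function(s) tokens[s:(s + window_length - 1L)])
  structure(wins, offsets = starts - 1L, short = FALSE)
}

#' Windowed graph-attribute profile of a transcript
#'
#' Builds one word graph per moving window, computes the four attributes for
#' each, and averages them across windows. The per-subject means (not the
#' whole-transcript graph) are the quantities used in all downstream group
#' and maturation analyses.
#'
#' @param x a [transcript()] or a character token vector.
#' @param window_length,step see [make_windows()].
#' @inheritParams graph_attributes
#' @return an object of class `"windowed_profile"`: list with `subject_id`,
#'   `window_length`, `step`, `per_window` (data.frame of N, RE, LSC, ASP per
#'   window), `mean_attributes` (named numeric), `n_windows`, `short`.
#' @export
windowed_profile <- function(x, window_length = 30, step = 15,
                             re_mode = c("sum", "excess"),
                             asp_mode = c("directed", "undirected")) {
  re_mode <- match.arg(re_mode)
  asp_mode <- match.arg(asp_mode)
  tokens <- if (inherits(x, "transcript")) x$tokens else as.character(x)
  sid <- if (inherits(x, "transcript")) x$subject_id else NA_character_
  wins <- make_windows(tokens, window_length, step)
  per <- t(vapply(wins, function(w)
    graph_attrs_cpp(match(w, unique(w)),
                    asp_directed = asp_mode == "directed",
                    re_excess = re_mode == "excess")[1:4],
    numeric(4)))
  per <- as.data.frame(per)
  names(per) <- c("N", "RE", "LSC", "ASP")
  structure(list(subject_id = sid, window_length = window_length,
                 step = step, per_window = per,
                 mean_attributes = colMeans(per),
                 n_windows = nrow(per), short = attr(wins, "short")),
            class = "windowed_profile")
}

#' @export
print.windowed_profile <- function(x, ...) {
  cat("Windowed profile", if (!is.na(x$subject_id)) paste0("'", x$subject_id, "'"),
      ":", x$n_windows, "window(s) of", x$window_length, "words, step",
      x$step, if (x$short) "(short transcript)", "\n")
  print(round(x$mean_attributes, 3))
  invisible(x)
}

#' Shuffle-normalized graph attributes
#'
#' Measures how far a transcript's structure departs from random word order.
#' Each window is shuffled `n_shuffles` times — preserving the word multiset,
#' which is equivalent to a random permutation of edges — the attributes of
#' the shuffled graphs are averaged to form a per-window denominator, and the
#' observed window attribute is divided by it. By default the per-window
#' ratios are then averaged across windows (`normalize_by = "window"`);
#' `normalize_by = "subject"` instead divides the subject's mean observed
#' attribute by the mean shuffled denominator.
#'
#' Because a permutation preserves the node set, the normalized node count is
#' exactly 1 for every window. Windows whose shuffled denominator is zero for
#' some attribute (e.g. RE on an all-distinct window) are skipped for that
#' attribute and counted in `skipped`; if every window is skipped the value
#' is `NA` and flagged.
#'
#' @param x a [transcript()] or character token vector.
#' @param n_shuffles number of random permutations per window (default 100).
#' @param seed optional integer seed for reproducibility.
#' @inheritParams windowed_profile
#' @param normalize_by `"window"` (ratio per window, then averaged) or
#'   `"subject"` (means first, then one ratio).
#' @return object of class `"normalized_attributes"`: list with
#'   `subject_id`, `n_shuffles`, `values` (named `norm_N`, `norm_RE`,
#'   `norm_LSC`, `norm_ASP`), `skipped` (windows skipped per attribute),
#'   `n_windows`, `seed`.
#' @export
shuffle_normalize <- function(x, n_shuffles = 100, seed = NULL,
                              window_length = 30, step = 15,
                              re_mode = c("sum", "excess"),
                              asp_mode = c("directed", "undirected"),
                              normalize_by = c("window", "subject")) {
  stopifnot(n_shuffles >= 1)
  re_mode <- match.arg(re_mode)
  asp_mode <- match.arg(asp_mode)
  normalize_by <- match.arg(normalize_by)
  tokens <- if (inherits(x, "transcript")) x$tokens else as.character(x)
  sid <- if (inherits(x, "transcript")) x$subject_id else NA_character_
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  wins <- make_windows(tokens, window_length, step)
  obs <- matrix(NA_real_, length(wins), 4)
  den <- matrix(NA_real_, length(wins), 4)
  for (i in seq_along(wins)) {
    ids <- match(wins[[i]], unique(wins[[i]]))
    obs[i, ] <- graph_attrs_cpp(ids, asp_directed = asp_mode == "directed",
                                re_excess = re_mode == "excess")[1:4]
    sh <- shuffle_attrs_cpp(ids, n_shuffles,
                            asp_directed = asp_mode == "directed",
                            re_excess = re_mode == "excess")
    den[i, ] <- colMeans(sh)
  }
  nm <- c("norm_N", "norm_RE", "norm_LSC", "norm_ASP")
  ok <- den > 0
  skipped <- colSums(!ok)
  values <- if (normalize_by == "window") {
    ratio <- obs / den
    ratio[!ok] <- NA_real_
    colMeans(ratio, na.rm = TRUE)
  } else {
    num <- colMeans(obs)
    d <- vapply(1:4, function(j) mean(den[ok[, j], j]), numeric(1))
    num / d
  }
  values[is.nan(values)] <- NA_real_
  names(values) <- names(skipped) <- nm
  if (anyNA(values))
    warning("normalized attribute undefined (all windows skipped) for: ",
            paste(nm[is.na(values)], collapse = ", "))
  structure(list(subject_id = sid, n_shuffles = n_shuffles, values = values,
                 skipped = skipped, n_windows = length(wins),
                 seed = seed),
            class = "normalized_attributes")
}

#' @export
print.normalized_attributes <- function(x, ...) {
  cat("Shuffle-normalized attributes",
      if (!is.na(x$subject_id)) paste0("'", x$subject_id, "'"),
      "(", x$n_shuffles, "shuffles,", x$n_windows, "windows )\n")
  print(round(x$values, 4))
  if (any(x$skipped > 0))
    cat("windows skipped (zero denominator):",
        paste(names(x$skipped)[x$skipped > 0],
              x$skipped[x$skipped > 0], collapse = ", "), "\n")
  invisible(x)
}
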