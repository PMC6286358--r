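#' Construct a transcript record
#'
#' Bundles a subject's token sequence with the cohort metadata used by the
#' downstream analyses (group membership, age and education in years, and
#' optional clinical covariates).
#'
#' @param subject_id character scalar identifier.
#' @param tokens character vector of word tokens (see [tokenize()]).
#' @param group `"control"` or `"psychosis"` (case-insensitive).
#' @param age_years,education_years non-negative numbers. Education exceeding
#'   age is allowed (real cohorts contain such records) but triggers a
#'   warning.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param income,panss_negative,cpz_dose optional non-negative covariates.
#' @param dropout optional logical school-dropout flag.
#' @return an object of class `"transcript"`.
#' @export
transcript <- function(subject_id, tokens, group, age_years, education_years,
                       sex = "unknown", income = NA_real_,
                       panss_negative = NA_real_, cpz_dose = NA_real_,
                       dropout = NA) {
  subject_id <- as.character(subject_id)
  if (length(tokens) == 0 || any(!nzchar(tokens)))
    stop("empty transcript for subject '", subject_id, "'")
  group <- match.arg(tolower(as.character(group)), c("control", "psychosis"))
  sex <- match.arg(tolower(as.character(sex)), c("male", "female", "unknown"))
  age_years <- as.numeric(age_years)
  education_years <- as.numeric(education_years)
  if (is.na(age_years) || age_years < 0) stop("age_years must be non-negative")
  if (is.na(education_years) || education_years < 0)
    stop("education_years must be non-negative")
  if (education_years > age_years)
    warning("subject '", subject_id, "': education_years (", education_years,
            ") exceeds age_years (", age_years, ")")
  structure(
    list(subject_id = subject_id, tokens = as.character(tokens),
         group = group, age_years = age_years,
         education_years = education_years, sex = sex,
         income = as.numeric(income),
         panss_negative = as.numeric(panss_negative),
         cpz_dose = as.numeric(cpz_dose),
         dropout = if (is.na(dropout)) NA else as.logical(dropout)),
    class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat("Transcript '", x$subject_id, "' (", x$group, "): ",
      length(x$tokens), " tokens, age ", x$age_years, " y, education ",
      x$education_years, " y\n", sep = "")
  invisible(x)
}

# the metadata columns, in canonical order
.meta_cols <- c("subject_id", "group", "age_years", "education_years", "sex",
                "income", "panss_negative", "cpz_dose", "dropout")

#' Read cohort metadata
#'
#' Reads a delimiter-separated metadata table with a header. The delimiter
#' (comma or tab) is auto-detected from the header line. Required columns:
#' `subject_id`, `group`, `age_years`, `education_years`; the optional
#' columns `sex`, `income`, `panss_negative`, `cpz_dose`, `dropout` are
#' filled with `NA`/`"unknown"` when absent.
#'
#' @param path path to a CSV or TSV file.
#' @return a data.frame with the canonical metadata columns.
#' @export
read_metadata <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  md <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   quote = "\"", comment.char = "")
  req <- c("subject_id", "group", "age_years", "education_years")
  miss <- setdiff(req, names(md))
  if (length(miss))
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "))
  md$subject_id <- as.character(md$subject_id)
  if (anyDuplicated(md$subject_id))
    stop("duplicate subject_id in metadata: ",
         paste(unique(md$subject_id[duplicated(md$subject_id)]), collapse = ", "))
  grp <- tolower(as.character(md$group))
  bad <- !grp %in% c("control", "psychosis")
  if (any(bad))
    stop("unknown group label(s): ", paste(unique(md$group[bad]), collapse = ", "))
  md$group <- grp
  if (is.null(md$sex)) md$sex <- "unknown"
  md$sex <- tolower(as.character(md$sex))
  md$sex[!md$sex %in% c("male", "female")] <- "unknown"
  for (col in c("income", "panss_negative", "cpz_dose"))
    md[[col]] <- if (is.null(md[[col]])) NA_real_ else as.numeric(md[[col]])
  md$dropout <- if (is.null(md$dropout)) NA else as.logical(md$dropout)
  md$age_years <- as.numeric(md$age_years)
  md$education_years <- as.numeric(md$education_years)
  md[, .meta_cols]
}

#' Write cohort metadata
#'
#' Writes the metadata table as CSV, serializing numbers at full double
#' precision so a read/write round trip is exact.
#'
#' @param metadata data.frame as returned by [read_metadata()].
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  out <- metadata
  for (col in names(out))
    if (is.numeric(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), "",
                           sprintf("%.17g", out[[col]]))
  write.table(out, path, sep = ",", row.names = FALSE, quote = TRUE,
              na = "")
  invisible(path)
}

#' Read a cohort of transcripts plus metadata
#'
#' Pairs a collection of transcript texts with a metadata table and returns
#' tokenized [transcript()] records. Texts may be given as (i) a directory
#' containing `<subject_id>.txt` files, or per-subject report triples
#' `<subject_id>_dream.txt`, `<subject_id>_day.txt`, `<subject_id>_image.txt`
#' concatenated in that fixed order, or (ii) a named character vector of raw
#' texts keyed by subject id.
#'
#' Metadata rows whose subject has no text are skipped with a warning; texts
#' with no metadata row are ignored.
#'
#' @param transcript_source directory path or named character vector.
#' @param metadata_table path to a CSV/TSV file or a metadata data.frame.
#' @param split_joiners passed to [tokenize()].
#' @return an object of class `"cohort"`: a list of `transcript` records,
#'   with the metadata data.frame attached as attribute `"metadata"`.
#' @export
read_cohort <- function(transcript_source, metadata_table,
                        split_joiners = FALSE) {
  md <- if (is.character(metadata_table) && length(metadata_table) == 1L)
    read_metadata(metadata_table) else validate_metadata(metadata_table)
  get_text <- make_text_lookup(transcript_source)
  records <- list()
  skipped <- character()
  for (i in seq_len(nrow(md))) {
    id <- md$subject_id[i]
    txt <- get_text(id)
    if (is.null(txt)) {
      skipped <- c(skipped, id)
      next
    }
    records[[id]] <- transcript(
      subject_id = id,
      tokens = tokenize(txt, split_joiners = split_joiners, subject_id = id),
      group = md$group[i], age_years = md$age_years[i],
      education_years = md$education_years[i], sex = md$sex[i],
      income = md$income[i], panss_negative = md$panss_negative[i],
      cpz_dose = md$cpz_dose[i], dropout = md$dropout[i])
  }
  if (length(skipped))
    warning(length(skipped), " metadata row(s) without transcript skipped: ",
            paste(skipped, collapse = ", "))
  structure(records, class = "cohort",
            metadata = md[md$subject_id %in% names(records), , drop = FALSE])
}

validate_metadata <- function(md) {
  stopifnot(is.data.frame(md))
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_metadata(fill_meta_cols(md), tmp)
  read_metadata(tmp)
}

fill_meta_cols <- function(md) {
  for (col in .meta_cols)
    if (is.null(md[[col]]))
      md[[col]] <- if (col == "sex") "unknown" else NA
  md[, .meta_cols]
}

make_text_lookup <- function(src) {
  if (is.character(src) && length(src) == 1L && dir.exists(src)) {
    function(id) {
      single <- file.path(src, paste0(id, ".txt"))
      if (file.exists(single))
        return(paste(readLines(single, warn = FALSE, encoding = "UTF-8"),
                     collapse = "\n"))
      parts <- file.path(src, paste0(id, "_", c("dream", "day", "image"),
                                     ".txt"))
      present <- file.exists(parts)
      if (!any(present)) return(NULL)
      paste(unlist(lapply(parts[present], function(p)
        paste(readLines(p, warn = FALSE, encoding = "UTF-8"),
              collapse = "\n"))), collapse = "\n")
    }
  } else if (is.character(src) && !is.null(names(src))) {
    function(id) if (id %in% names(src)) src[[id]] else NULL
  } else {
    stop("transcript_source must be a directory path or a named character vector")
  }
}

#' @export
print.cohort <- function(x, ...) {
  md <- attr(x, "metadata")
  cat("Cohort of", length(x), "transcripts (",
      sum(md$group == "control"), "control,",
      sum(md$group == "psychosis"), "psychosis )\n")
  invisible(x)
}

#' Write per-subject results to CSV / JSON
#'
#' `write_attributes_csv()` writes a per-subject attribute table (as produced
#' by [analyze_cohort()]); `write_results_json()` serializes fit or test
#' results (lists, `maturation_fit` summaries, `stat_result`s) as JSON.
#'
#' @param x data.frame (CSV) or list-like result (JSON).
#' @param path output path.
#' @export
write_attributes_csv <- function(x, path) {
  write.table(x, path, sep = ",", row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_attributes_csv
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(unclass_deep(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x[] <- lapply(x, unclass_deep)
  }
  x
}
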