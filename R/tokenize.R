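#' Tokenize raw transcript text
#'
#' Splits free text into the word tokens that become graph nodes. Tokens are
#' maximal runs of Unicode letters and digits, optionally joined by internal
#' apostrophes or ASCII hyphens (`"don't"`, `"well-being"` stay single
#' tokens); everything is case-folded to lower case and punctuation and
#' whitespace are discarded. No lemmatization, stemming or stop-word removal
#' is performed: surface word forms are the units of analysis.
#'
#' Em dashes and other non-ASCII dashes always separate tokens. With
#' `split_joiners = TRUE` apostrophes and hyphens split tokens instead of
#' joining them (some transcription conventions treat clitics as separate
#' words; the original convention is not standardized, so both are offered).
#'
#' @param raw_text character scalar (or vector, concatenated in order) of
#'   UTF-8 text.
#' @param split_joiners logical; if `TRUE`, apostrophes and hyphens act as
#'   separators rather than internal joiners.
#' @param subject_id optional id used in error messages.
#' @return character vector of lower-case tokens, in original order.
#' @examples
#' tokenize("The dog, the DOG!")
#' @export
tokenize <- function(raw_text, split_joiners = FALSE, subject_id = NULL) {
  if (!is.character(raw_text)) stop("raw_text must be character")
  txt <- tolower(paste(raw_text, collapse = " "))
  pat <- if (split_joiners) {
    "[\\p{L}\\p{N}]+"
  } else {
    "[\\p{L}\\p{N}]+(?:['’-][\\p{L}\\p{N}]+)*"
  }
  toks <- regmatches(txt, gregexpr(pat, txt, perl = TRUE))[[1]]
  if (length(toks) == 0) {
    who <- if (is.null(subject_id)) "" else paste0(" for subject '", subject_id, "'")
    stop("empty transcript", who, ": no word tokens found")
  }
  toks
}
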