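#' Segment a clinical report into labelled sentences
#'
#' Rule-based sentence splitting on terminal punctuation (`.`, `?`, `!`,
#' `;`) and newlines, with section detection: a sentence takes the label of
#' the last matched section cue (e.g. "Impression", "Findings"); sentences
#' before any cue are labelled `"body"`. Lines matching any boilerplate
#' pattern are removed before splitting.
#'
#' @param report_text Non-empty report string.
#' @param section_cues Character vector of section header cues (matched
#'   case-insensitively at the start of a line or followed by a colon).
#' @param boilerplate Character vector of regular expressions; whole lines
#'   matching any of them are dropped.
#' @return Object of class `sentence_bundle`: data frame with `text`,
#'   `section`, `negated` (initialized `NA`), `timestamp` (sentence order).
#' @examples
#' b <- segment_report("Impression: Lesion present. No recurrence.")
#' b$section
#' @export
segment_report <- function(report_text,
                           section_cues = c("Impression", "Findings",
                                            "History", "Technique"),
                           boilerplate = c("^\\s*Electronically signed",
                                           "^\\s*Page \\d+")) {
  if (!is.character(report_text) || length(report_text) != 1L ||
      !nzchar(trimws(report_text)))
    stop_moesurv("'report_text' must be a non-empty string")
  lines <- unlist(strsplit(report_text, "\n", fixed = TRUE))
  for (pat in boilerplate) lines <- lines[!grepl(pat, lines, ignore.case = TRUE)]
  text <- paste(lines, collapse = "\n")

  # walk through sentence pieces, tracking the current section label
  pieces <- unlist(strsplit(text, "(?<=[.?!;])\\s+|\\n+", perl = TRUE))
  pieces <- trimws(pieces)
  pieces <- pieces[nzchar(pieces)]
  cue_re <- paste0("^(", paste(section_cues, collapse = "|"), ")\\s*:")
  section <- "body"
  out_text <- character(0); out_section <- character(0)
  for (p in pieces) {
    m <- regexpr(cue_re, p, ignore.case = TRUE)
    if (m > 0) {
      hit <- regmatches(p, m)
      section <- sub("\\s*:$", "", hit)
      p <- trimws(sub(cue_re, "", p, ignore.case = TRUE))
      if (!nzchar(p)) next
    }
    out_text <- c(out_text, p)
    out_section <- c(out_section, section)
  }
  structure(data.frame(text = out_text, section = out_section,
                       negated = NA, timestamp = seq_along(out_text),
                       stringsAsFactors = FALSE),
            class = c("sentence_bundle", "data.frame"))
}

#' Tag sentence-level negation
#'
#' A sentence is flagged negated when a negation cue appears as a whole word
#' before at least one following content token. Cues inside larger words
#' ("nostril") never match.
#'
#' @param bundle A `sentence_bundle` from [segment_report()].
#' @param cue_lexicon Character vector of negation cues (may be multi-word,
#'   e.g. `"negative for"`).
#' @return The bundle with the `negated` column filled in.
#' @examples
#' b <- segment_report("No evidence of splenomegaly. Spleen is enlarged.")
#' tag_negation(b)$negated
#' @export
tag_negation <- function(bundle,
                         cue_lexicon = c("no", "not", "without", "absent",
                                         "negative for", "free of", "denies")) {
  if (!inherits(bundle, "sentence_bundle"))
    stop_moesurv("'bundle' must come from segment_report()")
  res <- vapply(bundle$text, function(s) {
    low <- tolower(s)
    for (cue in cue_lexicon) {
      # word-bounded cue followed by at least one further word token
      pat <- paste0("\\b", gsub(" ", "\\\\s+", cue), "\\b\\s+\\w")
      if (grepl(pat, low, perl = TRUE)) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
  bundle$negated <- res
  bundle
}

#' Write / read sentence bundles as JSONL
#'
#' One JSON object per line with fields `text`, `section`, `negated`,
#' `timestamp`.
#'
#' @param bundle A `sentence_bundle`.
#' @param path Output file.
#' @return `path` (write) or a `sentence_bundle` (read).
#' @export
write_sentences_jsonl <- function(bundle, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(bundle))) {
    writeLines(jsonlite::toJSON(as.list(bundle[i, , drop = FALSE][1, ]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_sentences_jsonl
#' @export
read_sentences_jsonl <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) as.data.frame(jsonlite::fromJSON(l)))
  out <- do.call(rbind, rows)
  structure(out, class = c("sentence_bundle", "data.frame"))
}
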