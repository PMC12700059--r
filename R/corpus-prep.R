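# Transcript cleaning and structuring: annotation scrubbing, topic
# filtering, document views (sequential vs topic-grouped), sentence
# extraction and lexical covariates.

#' Interview transcript
#'
#' Ordered, topic-tagged segments of one participant's interview plus the
#' declared topic inventory (which fixes the canonical topic order shared
#' across participants).
#'
#' @param participant_id identifier string.
#' @param segments data.frame with columns `topic_id`, `order`, `text`.
#' @param topics declared topic inventory, in canonical order; defaults to
#'   the topics present, in first-appearance order.
#' @return Object of class `transcript`.
#' @export
transcript <- function(participant_id, segments, topics = NULL) {
  stopifnot(is.data.frame(segments),
            all(c("topic_id", "order", "text") %in% names(segments)))
  if (nrow(segments) > 1 && any(diff(segments$order) <= 0))
    stopf("transcript %s: segment order must be strictly increasing",
          participant_id)
  topics <- topics %||% unique(segments$topic_id)
  unknown <- setdiff(segments$topic_id, topics)
  if (length(unknown))
    stopf("transcript %s: topic(s) outside the declared inventory: %s",
          participant_id, paste(unknown, collapse = ", "))
  structure(list(participant_id = participant_id, segments = segments,
                 topics = topics),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("transcript %s: %d segments over %d topics\n",
              x$participant_id, nrow(x$segments),
              length(unique(x$segments$topic_id))))
  invisible(x)
}

default_annotation_patterns <- function() {
  c(
    # parenthesized transcription annotations, optionally timestamped
    "\\((?:inaudible|unintelligible|crosstalk|laugh(?:s|ter)?|pause|silence|overlapping)[^)]*\\)",
    # URLs
    "(?:https?://|www\\.)[^\\s]+",
    # forum/user tags: r/..., u/..., /r/..., @user
    "(?<![[:alnum:]/])/?[ru]/[A-Za-z0-9_-]+",
    "(?<![[:alnum:]])@[A-Za-z0-9_]+"
  )
}

#' Clean raw transcript or post text
#'
#' Replaces transcription annotations (e.g. `"(inaudible 00:12)"`), URLs
#' and user/forum tags with the literal `"[UNK]"` token; strips HTML tags,
#' markdown styling marks and emoji; collapses whitespace runs to a single
#' space. Capitalization is preserved. Cleaning is total (never errors)
#' and idempotent.
#'
#' @param raw character vector of raw text.
#' @param annotation_patterns Perl regular expressions replaced by
#'   `"[UNK]"`; transcription conventions vary, so the default list is
#'   configurable.
#' @return Cleaned character vector.
#' @export
clean_text <- function(raw, annotation_patterns = default_annotation_patterns()) {
  x <- enc2utf8(as.character(raw))
  for (p in annotation_patterns)
    x <- gsub(p, "[UNK]", x, perl = TRUE, ignore.case = TRUE)
  x <- gsub("<[^>]+>", " ", x, perl = TRUE)          # HTML tags
  x <- gsub("[*`~_#]+", "", x, perl = TRUE)          # markdown styling marks
  # emoji and related symbol blocks (So category + variation selectors)
  x <- gsub("[\U0001F000-\U0001FAFF\U00002600-\U000027BF\U0001F1E6-\U0001F1FF\UFE0F\U200D\U2B00-\U2BFF]",
            "", x, perl = TRUE)
  x <- gsub("\\s+", " ", x, perl = TRUE)
  trimws(x)
}

#' Default word tokenizer
#'
#' Unicode-aware segmentation on whitespace with punctuation split off as
#' separate tokens; the literal `"[UNK]"` marker is kept as one token.
#' Pluggable wherever a backend supplies its own tokenization.
#'
#' @param text character scalar.
#' @return Character vector of tokens.
#' @export
tokenize_words <- function(text) {
  if (length(text) != 1) stopf("'text' must be a single string")
  m <- gregexpr("\\[UNK\\]|[[:alnum:]']+|[^[:space:][:alnum:]']",
                text, perl = TRUE)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(text, list(m))[[1]]
}

is_word_token <- function(tokens) grepl("[[:alnum:]]", tokens)

#' Drop topics from a transcript
#'
#' @param transcript a [transcript()].
#' @param exclude topic ids to drop; must belong to the declared
#'   inventory.
#' @return The filtered transcript (inventory shrunk accordingly). An
#'   empty result is flagged with a warning.
#' @export
filter_topics <- function(transcript, exclude) {
  stopifnot(inherits(transcript, "transcript"))
  unknown <- setdiff(exclude, transcript$topics)
  if (length(unknown))
    stopf("unknown topic id(s) in 'exclude': %s",
          paste(unknown, collapse = ", "))
  keep <- !(transcript$segments$topic_id %in% exclude)
  segs <- transcript$segments[keep, , drop = FALSE]
  rownames(segs) <- NULL
  if (nrow(segs) == 0)
    warnf("transcript %s: all segments removed by topic filter",
          transcript$participant_id)
  out <- transcript
  out$segments <- segs
  out$topics <- setdiff(transcript$topics, exclude)
  out
}

#' Development-cohort topic exclusion preset
#'
#' The development preset drops the final two topics of the inventory
#' (study-specific content with limited generalizability) plus the
#' study-medication topic when one is declared.
#'
#' @param topics topic inventory in canonical order.
#' @param medication_topic id of the study-medication topic, if any.
#' @return Character vector of topic ids to exclude.
#' @export
development_topic_exclusions <- function(topics,
                                         medication_topic = "medication") {
  stopifnot(length(topics) >= 2)
  unique(c(utils::tail(topics, 2), intersect(medication_topic, topics)))
}

#' Structure a transcript into token documents
#'
#' Two views: `"sequential"` keeps the conversational order and yields a
#' single document; `"topic_grouped"` concatenates all segments of the
#' same topic and orders documents by the declared topic inventory, so
#' the topic order is shared across participants. Neither view changes
#' the token content (the token multiset is conserved).
#'
#' @param transcript a [transcript()] (text is cleaned with
#'   [clean_text()] first).
#' @param mode `"sequential"` or `"topic_grouped"`.
#' @param tokenizer tokenizing function, by default [tokenize_words()].
#' @return Object of class `document_view`: `participant_id`, `mode`, and
#'   `documents`, a named list of token vectors.
#' @export
structure_documents <- function(transcript,
                                mode = c("sequential", "topic_grouped"),
                                tokenizer = tokenize_words) {
  mode <- match.arg(mode)
  stopifnot(inherits(transcript, "transcript"))
  segs <- transcript$segments
  if (nrow(segs) == 0) {
    warnf("transcript %s is empty; returning an empty view",
          transcript$participant_id)
    return(structure(list(participant_id = transcript$participant_id,
                          mode = mode, documents = list()),
                     class = "document_view"))
  }
  cleaned <- clean_text(segs$text)
  toks <- lapply(cleaned, tokenizer)
  documents <- if (mode == "sequential") {
    list(doc = unlist(toks, use.names = FALSE))
  } else {
    present <- intersect(transcript$topics, segs$topic_id)
    out <- lapply(present, function(tp) {
      unlist(toks[segs$topic_id == tp], use.names = FALSE)
    })
    names(out) <- present
    out
  }
  structure(list(participant_id = transcript$participant_id, mode = mode,
                 documents = documents),
            class = "document_view")
}

#' @export
print.document_view <- function(x, ...) {
  cat(sprintf("document_view %s (%s): %d document(s), %d tokens\n",
              x$participant_id, x$mode, length(x$documents),
              sum(lengths(x$documents))))
  invisible(x)
}

#' Extract sentences from a document view
#'
#' Token streams are split after `"."`, `"!"` or `"?"`; sentences with
#' fewer than `min_words` word tokens (tokens containing an alphanumeric
#' character) are discarded, dropping fragments before clustering. The
#' split rule is deliberately literal, so abbreviations like `"Dr."`
#' split too (documented limitation).
#'
#' @param view a [document_view()].
#' @param min_words minimum word-token count to keep a sentence
#'   (default 3).
#' @return data.frame with columns `sentence_id`, `participant_id`,
#'   `doc_id`, `n_words`, `text`, plus a `tokens` list-column.
#' @export
extract_sentences <- function(view, min_words = 3L) {
  stopifnot(inherits(view, "document_view"))
  rows <- list()
  for (doc_id in names(view$documents)) {
    toks <- view$documents[[doc_id]]
    if (length(toks) == 0) next
    ends <- which(toks %in% c(".", "!", "?"))
    bounds <- unique(c(ends, length(toks)))
    start <- 1
    k <- 0
    for (e in sort(bounds)) {
      sent <- toks[start:e]
      start <- e + 1
      if (sum(is_word_token(sent)) < min_words) next
      k <- k + 1
      rows[[length(rows) + 1]] <- list(
        sentence_id = sprintf("%s:%s:s%03d", view$participant_id, doc_id, k),
        participant_id = view$participant_id, doc_id = doc_id,
        n_words = sum(is_word_token(sent)),
        text = paste(sent, collapse = " "), tokens = sent)
    }
  }
  out <- data.frame(
    sentence_id = vapply(rows, `[[`, "", "sentence_id"),
    participant_id = vapply(rows, `[[`, "", "participant_id"),
    doc_id = vapply(rows, `[[`, "", "doc_id"),
    n_words = vapply(rows, `[[`, 1L, "n_words"),
    text = vapply(rows, `[[`, "", "text"),
    stringsAsFactors = FALSE)
  out$tokens <- lapply(rows, `[[`, "tokens")
  out
}

#' Verbosity and vocabulary of a document view
#'
#' Verbosity is the number of word tokens over all documents; vocabulary
#' is the number of unique word tokens after case folding.
#'
#' @param view a [document_view()].
#' @return Named numeric vector `c(verbosity = , vocabulary = )`.
#' @export
lexical_covariates <- function(view) {
  stopifnot(inherits(view, "document_view"))
  toks <- unlist(view$documents, use.names = FALSE)
  words <- toks[is_word_token(toks)]
  c(verbosity = length(words), vocabulary = length(unique(tolower(words))))
}
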