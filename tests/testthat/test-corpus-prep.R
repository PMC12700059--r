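test_that("clean_text applies the replacement rules and is idempotent", {
  cases <- list(
    c("(inaudible 00:12) I hurt", "[UNK] I hurt"),
    c("pain   is <b>bad</b>", "pain is bad"),
    c("see https://x.y and r/backpain", "see [UNK] and [UNK]"),
    c("ask u/someone or @dr_pain", "ask [UNK] or [UNK]"),
    c("**really** _bad_ `pain`", "really bad pain"),
    c("(crosstalk) (laughs) ok", "[UNK] [UNK] ok"),
    c("Keep My Case", "Keep My Case"))
  for (cs in cases) {
    expect_identical(clean_text(cs[1]), cs[2])
    expect_identical(clean_text(clean_text(cs[1])), cs[2])  # idempotent
  }
  expect_identical(clean_text("no pain \U0001F600 today"), "no pain today")
})

test_that("tokenizer splits punctuation but keeps the [UNK] marker", {
  expect_identical(tokenize_words("I hurt, badly."),
                   c("I", "hurt", ",", "badly", "."))
  expect_identical(tokenize_words("[UNK] here"), c("[UNK]", "here"))
  expect_identical(tokenize_words(""), character(0))
})

test_that("topic filtering drops topics, keeps order, validates ids", {
  tr <- transcript("p", data.frame(
    topic_id = c("a", "b", "a", "c"), order = 1:4,
    text = sprintf("t%d", 1:4)), topics = c("a", "b", "c"))
  same <- filter_topics(tr, character(0))
  expect_identical(same$segments, tr$segments)
  fb <- filter_topics(tr, "b")
  expect_identical(fb$segments$text, c("t1", "t3", "t4"))
  expect_identical(fb$topics, c("a", "c"))
  expect_error(filter_topics(tr, "zz"), "unknown topic")
  expect_warning(filter_topics(tr, c("a", "b", "c")), "all segments")
})

test_that("development preset drops the last two topics plus medication", {
  topics <- c(sprintf("t%02d", 1:13), "medication", "opinion", "misc")
  excl <- development_topic_exclusions(topics)
  expect_setequal(excl, c("opinion", "misc", "medication"))
  tr16 <- transcript("p", data.frame(topic_id = topics, order = 1:16,
                                     text = "x x x"), topics = topics)
  expect_identical(length(filter_topics(tr16, excl)$topics), 13L)
})

test_that("structuring conserves tokens and groups topics canonically", {
  tr <- transcript("p", data.frame(
    topic_id = c("A", "B", "A"), order = 1:3,
    text = c("one two", "three four", "five six")),
    topics = c("A", "B"))
  tg <- structure_documents(tr, "topic_grouped")
  expect_identical(names(tg$documents), c("A", "B"))
  expect_identical(tg$documents$A, c("one", "two", "five", "six"))
  expect_identical(tg$documents$B, c("three", "four"))
  sq <- structure_documents(tr, "sequential")
  expect_identical(length(sq$documents), 1L)
  # token multiset conservation across both modes
  expect_identical(sort(unlist(tg$documents, use.names = FALSE)),
                   sort(sq$documents[[1]]))
  # single-topic transcript: both views coincide up to doc id
  tr1 <- transcript("q", data.frame(topic_id = "A", order = 1L,
                                    text = "a b c"), topics = "A")
  expect_identical(unname(structure_documents(tr1, "sequential")$documents),
                   unname(structure_documents(tr1, "topic_grouped")$documents))
})

test_that("filtering and structuring commute on topic-grouped views", {
  tr <- generate_transcript(small_config(seed = 9), "P001", "responder")
  excl <- tr$topics[c(2, 5)]
  a <- structure_documents(filter_topics(tr, excl), "topic_grouped")
  b <- structure_documents(tr, "topic_grouped")
  b$documents <- b$documents[setdiff(names(b$documents), excl)]
  expect_identical(a$documents, b$documents)
})

test_that("sentence extraction applies the literal split-and-length rule", {
  view <- structure(list(participant_id = "p", mode = "sequential",
                         documents = list(doc = tokenize_words(
                           "I hurt. It burns badly. Dr. Smith helped me."))),
                    class = "document_view")
  s <- extract_sentences(view)
  # "I hurt." (2 words) dropped; "Dr." split naively -> "Smith helped me."
  expect_identical(s$text, c("It burns badly .", "Smith helped me ."))
  expect_identical(s$n_words, c(3L, 3L))
  # no terminator: one sentence
  v2 <- structure(list(participant_id = "p", mode = "sequential",
                       documents = list(doc = c("a", "b", "c"))),
                  class = "document_view")
  expect_identical(nrow(extract_sentences(v2)), 1L)
})

test_that("lexical covariates count words and case-folded vocabulary", {
  v <- structure(list(participant_id = "p", mode = "sequential",
                      documents = list(doc = c("a", "a", "b"))),
                 class = "document_view")
  expect_identical(lexical_covariates(v), c(verbosity = 3L, vocabulary = 2L))
  v0 <- structure(list(participant_id = "p", mode = "sequential",
                       documents = list()), class = "document_view")
  expect_identical(lexical_covariates(v0),
                   c(verbosity = 0L, vocabulary = 0L))
  vc <- structure(list(participant_id = "p", mode = "sequential",
                       documents = list(doc = c("Pain", "pain", "."))),
                  class = "document_view")
  expect_identical(lexical_covariates(vc), c(verbosity = 2L, vocabulary = 1L))
})

test_that("transcripts JSONL round-trips with inventory and errors carry line numbers", {
  co <- generate_cohort(small_config(n = 3, seed = 12))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_transcripts(co$transcripts, path)
  back <- read_transcripts(path)
  for (i in 1:3) {
    expect_identical(back[[i]]$segments, co$transcripts[[i]]$segments)
    expect_identical(back[[i]]$topics, co$transcripts[[i]]$topics)
  }
  bad <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"participant_id":"p","topic_id":"a","order":1,"text":"x"}',
               '{"participant_id":"p","order":2,"text":"y"}'), bad)
  expect_error(read_transcripts(bad), "line 2.*topic_id")
})
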