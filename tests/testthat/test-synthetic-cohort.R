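test_that("cohort generation is deterministic and order-independent", {
  cfg <- small_config(seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # disjoint subsets generated separately equal the matching slice
  sub <- generate_cohort(cfg, participants = c("P002", "P009"))
  expect_identical(sub$diaries[[1]], a$diaries[[2]])
  expect_identical(sub$transcripts[[2]], a$transcripts[[9]])
})

test_that("responder allocation is exact and the ground truth is complete", {
  co <- generate_cohort(small_config(n = 10))
  expect_identical(sum(co$truth$true_class == "responder"), 5L)
  expect_identical(nrow(co$truth), 10L)
  # half-up allocation: floor(7 * 0.5 + 0.5) = 4 responders
  co7 <- generate_cohort(small_config(n = 7, responder_fraction = 0.5))
  expect_identical(sum(co7$truth$true_class == "responder"), 4L)
  co4 <- generate_cohort(small_config(n = 10, responder_fraction = 0.25))
  expect_identical(sum(co4$truth$true_class == "responder"), 3L)
  expect_setequal(co$truth$participant_id,
                  vapply(co$diaries, `[[`, "", "participant_id"))
})

test_that("diaries have the configured design and moments", {
  cfg <- small_config(seed = 3, baseline_mean = 6, baseline_sd = 0.5,
                      responder_drop = 3)
  d <- generate_diary(cfg, "P900", "responder")
  tab <- table(d$ratings$phase)
  expect_identical(as.integer(tab[c("baseline", "treatment1",
                                    "treatment2", "washout")]),
                   c(28L, 28L, 28L, 14L))
  expect_true(all(d$ratings$rating >= 0 & d$ratings$rating <= 10))
  expect_true(all(d$ratings$rating == round(d$ratings$rating)))
  # treatment-phase mean near baseline_mean - drop = 3 (Monte-Carlo over
  # a moderate pool of independent diaries to beat rounding noise)
  tmeans <- vapply(1:40, function(i) {
    di <- generate_diary(cfg, sprintf("M%03d", i), "responder")
    mean(di$ratings$rating[di$ratings$phase == "treatment1"])
  }, numeric(1))
  expect_lt(abs(mean(tmeans) - 3), 0.2)
  # null configuration: no drop anywhere
  cfg0 <- small_config(seed = 5, responder_drop = 0)
  deltas <- vapply(1:40, function(i) {
    di <- generate_diary(cfg0, sprintf("N%03d", i), "responder")
    mean(di$ratings$rating[di$ratings$phase == "treatment1"]) -
      mean(di$ratings$rating[di$ratings$phase == "baseline"])
  }, numeric(1))
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se + 1e-9)
  expect_error(generate_diary(cfg, "P1", "placebo"), "true_class")
})

test_that("baseline moments match the configuration within 3 SE", {
  cfg <- small_config(seed = 11, baseline_mean = 5, baseline_sd = 1.2)
  ratings <- unlist(lapply(1:36, function(i) {
    d <- generate_diary(cfg, sprintf("B%03d", i), "nonresponder")
    d$ratings$rating[d$ratings$phase == "baseline"]
  }))
  n <- length(ratings)
  expect_gte(n, 1000)
  # integer rounding adds 1/12 to the variance
  sd_theory <- sqrt(1.2^2 + 1 / 12)
  expect_lt(abs(mean(ratings) - 5), 3 * sd_theory / sqrt(n))
  expect_lt(abs(sd(ratings) - sd_theory), 3 * sd_theory / sqrt(2 * n))
})

test_that("transcripts carry class-specific cue tokens at the set rates", {
  cfg <- small_config(seed = 2, n = 20, template_rate = 0)
  co <- generate_cohort(cfg)
  cue_frac <- function(tr, cls) {
    toks <- unlist(lapply(tr$segments$text, tokenize_words))
    toks <- toks[toks != "."]
    cues <- concept_tokens(cfg)
    mean(toks %in% cues$token[cues$class == cls])
  }
  resp <- co$truth$true_class == "responder"
  own_rate <- vapply(co$transcripts[resp], cue_frac, numeric(1),
                     cls = "responder")
  other_rate <- vapply(co$transcripts[resp], cue_frac, numeric(1),
                       cls = "nonresponder")
  se <- sd(own_rate) / sqrt(length(own_rate))
  expect_lt(abs(mean(own_rate) - cfg$concept_rate), 2 * se + 0.005)
  expect_lt(mean(other_rate), cfg$concept_rate)
  # structure: one segment per topic, randomized order, lengths in range
  tr <- co$transcripts[[1]]
  expect_setequal(tr$segments$topic_id, tr$topics)
  expect_identical(tr$segments$order, seq_len(nrow(tr$segments)))
})

test_that("reserved cue tokens must fit in the vocabulary", {
  expect_error(synthetic_config(vocab_size = 3, n_signal_dims = 2),
               "reserved")
  expect_error(synthetic_config(responder_fraction = 1.5), "fraction")
})

test_that("a default cohort generates quickly", {
  t0 <- proc.time()[["elapsed"]]
  invisible(generate_cohort(synthetic_config(seed = 99)))
  expect_lt(proc.time()[["elapsed"]] - t0, 5)
})
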