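# Synthetic trial generator: seeded pain-rating diaries and topic-tagged
# interview transcripts with a planted, class-dependent semantic signal.
# The generator defines the study conditions the rest of the package is
# tested under; its defaults are documented in the methods vignette.

#' Configuration of a synthetic placebo-trial cohort
#'
#' Bundles every constant of the simulated trial: diary design (rating
#' counts per phase, baseline level and spread, planted treatment-phase
#' drop for responders), interview design (topics, segment lengths,
#' vocabulary), and the planted semantic signal (class-specific cue-token
#' rates, cue loading strength, number of signal dimensions). A cohort is
#' a pure function of its configuration: identical configurations produce
#' byte-identical cohorts.
#'
#' Diary design follows the two-week twice-daily scheme of the emulated
#' trials: 28 baseline ratings, 28 per treatment phase (two phases), and a
#' one-week (14-rating) washout. Interviews cover 16 topics.
#'
#' @param seed integer master seed; per-participant substreams are derived
#'   from it with [hash31()] so generation is order-independent.
#' @param n_participants cohort size.
#' @param responder_fraction proportion of true responders in `[0,1]`;
#'   allocation is exact (`floor(n * fraction + 0.5)` responders).
#' @param baseline_mean,baseline_sd rating units (0-10 scale) of the
#'   baseline-phase Gaussian before clipping/rounding.
#' @param responder_drop mean treatment-phase decrease (rating units) for
#'   true responders.
#' @param nonresponder_drop same for non-responders (default 0).
#' @param n_baseline,n_per_treatment_phase,n_phases,n_washout rating counts
#'   per phase and number of treatment phases.
#' @param vocab_size number of neutral vocabulary tokens.
#' @param n_topics number of interview topics.
#' @param tokens_per_topic length-2 integer range of tokens per segment.
#' @param concept_rate probability that a transcript token is a cue token
#'   of the speaker's own class.
#' @param concept_rate_other probability of an other-class cue token.
#' @param concept_strength loading (embedding units) that a cue token adds
#'   on its signal dimension, with sign given by its class.
#' @param n_signal_dims number of embedding dimensions carrying the
#'   planted signal.
#' @param sentence_tokens length-2 range of tokens per generated sentence
#'   (a period is appended after each run, so transcripts can be split
#'   into sentences downstream).
#' @param template_rate probability that a generated sentence is drawn
#'   verbatim from the speaker's class-specific template pool rather than
#'   sampled token by token. Templates emulate the recurrent phrasings of
#'   real interviews and give density-based sentence clustering genuine
#'   structure to find; they are drawn once per configuration from the
#'   same token mixture, so expected cue rates are unchanged.
#' @param n_templates number of template sentences per class.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_participants = 60L,
                             responder_fraction = 0.5,
                             baseline_mean = 6,
                             baseline_sd = 1.5,
                             responder_drop = 1.5,
                             nonresponder_drop = 0,
                             n_baseline = 28L,
                             n_per_treatment_phase = 28L,
                             n_phases = 2L,
                             n_washout = 14L,
                             vocab_size = 500L,
                             n_topics = 16L,
                             tokens_per_topic = c(30L, 80L),
                             concept_rate = 0.10,
                             concept_rate_other = 0.02,
                             concept_strength = 3,
                             n_signal_dims = 2L,
                             sentence_tokens = c(5L, 12L),
                             template_rate = 0.3,
                             n_templates = 20L) {
  cfg <- list(seed = as.integer(seed),
              n_participants = as.integer(n_participants),
              responder_fraction = responder_fraction,
              baseline_mean = baseline_mean,
              baseline_sd = baseline_sd,
              responder_drop = responder_drop,
              nonresponder_drop = nonresponder_drop,
              n_baseline = as.integer(n_baseline),
              n_per_treatment_phase = as.integer(n_per_treatment_phase),
              n_phases = as.integer(n_phases),
              n_washout = as.integer(n_washout),
              vocab_size = as.integer(vocab_size),
              n_topics = as.integer(n_topics),
              tokens_per_topic = as.integer(tokens_per_topic),
              concept_rate = concept_rate,
              concept_rate_other = concept_rate_other,
              concept_strength = concept_strength,
              n_signal_dims = as.integer(n_signal_dims),
              sentence_tokens = as.integer(sentence_tokens),
              template_rate = template_rate,
              n_templates = as.integer(n_templates))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  for (f in c("n_participants", "n_baseline", "n_per_treatment_phase",
              "n_phases", "vocab_size", "n_topics", "n_signal_dims")) {
    if (!is_count(cfg[[f]])) stopf("'%s' must be an integer >= 1", f)
  }
  if (!is_count(cfg$n_washout, min = 0)) stopf("'n_washout' must be >= 0")
  if (!is_prob(cfg$responder_fraction))
    stopf("'responder_fraction' must be in [0,1]")
  if (!is_prob(cfg$concept_rate) || !is_prob(cfg$concept_rate_other))
    stopf("concept rates must be in [0,1]")
  if (cfg$concept_rate + cfg$concept_rate_other > 1)
    stopf("concept rates must sum to at most 1")
  if (cfg$baseline_sd < 0) stopf("'baseline_sd' must be >= 0")
  if (length(cfg$tokens_per_topic) != 2 ||
      any(cfg$tokens_per_topic < 1) ||
      cfg$tokens_per_topic[1] > cfg$tokens_per_topic[2])
    stopf("'tokens_per_topic' must be an increasing range of counts >= 1")
  if (length(cfg$sentence_tokens) != 2 || any(cfg$sentence_tokens < 1) ||
      cfg$sentence_tokens[1] > cfg$sentence_tokens[2])
    stopf("'sentence_tokens' must be an increasing range of counts >= 1")
  if (!is_prob(cfg$template_rate)) stopf("'template_rate' must be in [0,1]")
  if (!is_count(cfg$n_templates, min = 0))
    stopf("'n_templates' must be >= 0")
  if (cfg$template_rate > 0 && cfg$n_templates < 1)
    stopf("template_rate > 0 requires n_templates >= 1")
  n_reserved <- 2L * cfg$n_signal_dims
  if (cfg$vocab_size < n_reserved)
    stopf("vocab_size (%d) smaller than the %d reserved concept tokens",
          cfg$vocab_size, n_reserved)
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "synthetic_config: %d participants (%.0f%% responders), seed %d\n",
    x$n_participants, 100 * x$responder_fraction, x$seed))
  cat(sprintf("  diary: baseline %g +/- %g, drop %g (responders), %d+%dx%d+%d ratings\n",
              x$baseline_mean, x$baseline_sd, x$responder_drop,
              x$n_baseline, x$n_per_treatment_phase, x$n_phases, x$n_washout))
  cat(sprintf("  language: %d topics, vocab %d, cue rates %g/%g, strength %g on %d dims\n",
              x$n_topics, x$vocab_size, x$concept_rate, x$concept_rate_other,
              x$concept_strength, x$n_signal_dims))
  invisible(x)
}

topic_inventory <- function(cfg) sprintf("topic%02d", seq_len(cfg$n_topics))

#' Cue tokens planted by a configuration
#'
#' One responder-associated and one non-responder-associated cue token per
#' signal dimension. Responder cues load `+concept_strength` and
#' non-responder cues `-concept_strength` on their dimension. The two
#' cues of a dimension are antonym-like: they share the same pseudo-random
#' base vector (column `base`) and differ only in the sign of their
#' loading, so the class contrast they induce lies exactly on the signal
#' dimensions rather than leaking through unrelated dimensions of the cue
#' tokens' base vectors.
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns `token`, `class`, `dim`, `loading`,
#'   `base`.
#' @export
concept_tokens <- function(config) {
  dims <- seq_len(config$n_signal_dims)
  data.frame(
    token = c(sprintf("respcue%d", dims), sprintf("nonrespcue%d", dims)),
    class = rep(c("responder", "nonresponder"), each = length(dims)),
    dim = c(dims, dims),
    loading = rep(c(config$concept_strength, -config$concept_strength),
                  each = length(dims)),
    base = rep(sprintf("cue%d", dims), 2),
    stringsAsFactors = FALSE)
}

check_class_label <- function(true_class) {
  if (!is.character(true_class) || length(true_class) != 1 ||
      !true_class %in% c("responder", "nonresponder"))
    stopf("'true_class' must be \"responder\" or \"nonresponder\", got %s",
          deparse(true_class))
  true_class
}

#' Generate one participant's pain-rating diary
#'
#' Twice-daily 0-10 ratings over the full trial: a baseline phase, two
#' treatment phases during which true responders' ratings drop by
#' `responder_drop` on average, and a washout phase back at baseline level.
#' Ratings are Gaussian, clipped to `[0,10]` and rounded to integers
#' (app-style numeric rating scale).
#'
#' @param config a [synthetic_config()].
#' @param participant_id participant identifier string.
#' @param true_class `"responder"` or `"nonresponder"`.
#' @return A [pain_diary()] object.
#' @export
generate_diary <- function(config, participant_id, true_class) {
  validate_synthetic_config(config)
  check_class_label(true_class)
  drop <- if (true_class == "responder") config$responder_drop else
    config$nonresponder_drop
  phases <- c("baseline",
              sprintf("treatment%d", seq_len(config$n_phases)),
              if (config$n_washout > 0) "washout")
  counts <- c(config$n_baseline,
              rep(config$n_per_treatment_phase, config$n_phases),
              if (config$n_washout > 0) config$n_washout)
  means <- c(config$baseline_mean,
             rep(config$baseline_mean - drop, config$n_phases),
             if (config$n_washout > 0) config$baseline_mean)
  ratings <- with_seed(hash31(config$seed, participant_id, "diary"), {
    unlist(lapply(seq_along(phases), function(i) {
      round(pmin(10, pmax(0, stats::rnorm(counts[i], means[i],
                                          config$baseline_sd))))
    }))
  })
  pain_diary(participant_id,
             data.frame(phase = rep(phases, counts),
                        index = unlist(lapply(counts, seq_len)),
                        rating = ratings,
                        stringsAsFactors = FALSE))
}

#' Generate one participant's interview transcript
#'
#' Topic-tagged segments in randomized conversational order. Token content
#' mixes a neutral vocabulary with class-specific cue tokens: own-class
#' cues appear at rate `concept_rate`, other-class cues at
#' `concept_rate_other`. Which of the per-dimension own-class cues a
#' participant favours is itself random (per-participant Dirichlet weights
#' over the signal dimensions), emulating speakers who express the same
#' latent disposition through different surface concepts; the class signal
#' is therefore carried reliably by the cue dimensions jointly, not by any
#' single one. Periods are inserted every few tokens so the transcript can
#' be split into sentences downstream.
#'
#' @inheritParams generate_diary
#' @return A [transcript()] object carrying the topic inventory.
#' @export
generate_transcript <- function(config, participant_id, true_class) {
  validate_synthetic_config(config)
  check_class_label(true_class)
  templates <- class_templates(config, true_class)
  cues <- concept_tokens(config)
  own <- cues$token[cues$class == true_class]      # ordered by dimension
  other <- cues$token[cues$class != true_class]
  topics <- topic_inventory(config)
  with_seed(hash31(config$seed, participant_id, "transcript"), {
    topic_order <- sample(topics)
    # sparse Dirichlet(1/2) preference over cue dimensions: most speakers
    # lean strongly on one surface concept, so no single embedding
    # dimension is reliable across the cohort while the joint signal is
    g <- stats::rgamma(length(own), shape = 0.5)
    cue_weights <- g / sum(g)
    segs <- lapply(seq_along(topic_order), function(i) {
      n_tok <- sample(seq(config$tokens_per_topic[1],
                          config$tokens_per_topic[2]), 1)
      toks <- character(0)
      while (length(toks) < n_tok) {
        sent <- if (length(templates) &&
                    stats::runif(1) < config$template_rate)
          templates[[sample.int(length(templates), 1)]]
        else
          fresh_sentence_tokens(config, own, other, cue_weights)
        toks <- c(toks, sent, ".")
      }
      # trim to the drawn segment length, keeping the closing period
      if (length(toks) > n_tok + 1) toks <- c(toks[seq_len(n_tok)], ".")
      list(topic_id = topic_order[i], order = i,
           text = paste(toks, collapse = " "))
    })
    transcript(participant_id,
               data.frame(topic_id = vapply(segs, `[[`, "", "topic_id"),
                          order = vapply(segs, `[[`, 1L, "order"),
                          text = vapply(segs, `[[`, "", "text"),
                          stringsAsFactors = FALSE),
               topics = topics)
  })
}

# One freshly sampled sentence: a mixture of neutral vocabulary and cue
# tokens at the configured class-specific rates. Assumes an active RNG
# stream (called inside with_seed).
fresh_sentence_tokens <- function(config, own, other, cue_weights) {
  len <- sample(seq(config$sentence_tokens[1], config$sentence_tokens[2]), 1)
  kind <- sample(c("own", "other", "neutral"), len, replace = TRUE,
                 prob = c(config$concept_rate, config$concept_rate_other,
                          1 - config$concept_rate -
                            config$concept_rate_other))
  toks <- character(len)
  toks[kind == "own"] <- own[sample.int(length(own), sum(kind == "own"),
                                        replace = TRUE, prob = cue_weights)]
  toks[kind == "other"] <- sample(other, sum(kind == "other"),
                                  replace = TRUE)
  toks[kind == "neutral"] <- sprintf(
    "w%04d", sample.int(config$vocab_size, sum(kind == "neutral"),
                        replace = TRUE))
  toks
}

#' Class-specific template sentences of a configuration
#'
#' The pool of recurrent sentences speakers of a class reuse verbatim (at
#' rate `template_rate`). All templates share class-neutral skeletons:
#' the neutral tokens and the cue positions are drawn once per
#' configuration and are identical for both classes; only the cue slots
#' are filled with the class's own cue tokens. The between-class contrast
#' carried by templates therefore lies exactly on the planted signal
#' dimensions, while the recurrent verbatim sentences give density-based
#' sentence clustering genuine structure.
#'
#' @param config a [synthetic_config()].
#' @param true_class `"responder"` or `"nonresponder"`.
#' @return List of token vectors (possibly empty).
#' @export
class_templates <- function(config, true_class) {
  check_class_label(true_class)
  if (config$n_templates == 0 || config$template_rate == 0) return(list())
  cues <- concept_tokens(config)
  own <- cues$token[cues$class == true_class]
  skeletons <- with_seed(hash31(config$seed, "templates"), {
    lapply(seq_len(config$n_templates), function(i) {
      len <- sample(seq(config$sentence_tokens[1],
                        config$sentence_tokens[2]), 1)
      toks <- sprintf("w%04d", sample.int(config$vocab_size, len,
                                          replace = TRUE))
      # alternate class-neutral and cue-bearing templates; a cued
      # template voices one cue dimension (round-robin theme)
      cued <- i %% 2L == 0L
      slots <- if (cued) which(stats::runif(len) < config$concept_rate)
               else integer(0)
      list(tokens = toks, slots = slots,
           theme = 1L + (i %/% 2L) %% length(own))
    })
  })
  out <- lapply(skeletons, function(sk) {
    toks <- sk$tokens
    toks[sk$slots] <- own[sk$theme]
    toks
  })
  attr(out, "theme") <- vapply(skeletons, `[[`, 1L, "theme")
  out
}

#' Generate a full synthetic cohort
#'
#' One diary and one transcript per participant, plus the ground truth.
#' Responder status is allocated exactly (`floor(n * fraction + 0.5)`
#' responders, assigned to the first participants) and every artifact is
#' drawn from a per-participant substream keyed by `(seed, participant_id)`,
#' so disjoint subsets generated separately coincide with the matching
#' slice of the full cohort.
#'
#' @param config a [synthetic_config()].
#' @param participants optional subset of participant ids to generate.
#' @return A list with elements `diaries`, `transcripts`, `truth`
#'   (data.frame `participant_id`, `true_class`, `planted_effect`) and
#'   `config`, of class `synthetic_cohort`.
#' @export
generate_cohort <- function(config, participants = NULL) {
  validate_synthetic_config(config)
  ids <- sprintf("P%03d", seq_len(config$n_participants))
  n_resp <- floor(config$n_participants * config$responder_fraction + 0.5)
  classes <- ifelse(seq_along(ids) <= n_resp, "responder", "nonresponder")
  truth <- data.frame(participant_id = ids, true_class = classes,
                      planted_effect = ifelse(classes == "responder",
                                              config$responder_drop,
                                              config$nonresponder_drop),
                      stringsAsFactors = FALSE)
  if (!is.null(participants)) {
    missing <- setdiff(participants, ids)
    if (length(missing))
      stopf("unknown participant ids: %s", paste(missing, collapse = ", "))
    truth <- truth[match(participants, truth$participant_id), , drop = FALSE]
    rownames(truth) <- NULL
  }
  diaries <- Map(function(id, cl) generate_diary(config, id, cl),
                 truth$participant_id, truth$true_class)
  transcripts <- Map(function(id, cl) generate_transcript(config, id, cl),
                     truth$participant_id, truth$true_class)
  structure(list(diaries = diaries, transcripts = transcripts,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d participants (%d responders), seed %d\n",
              nrow(x$truth), sum(x$truth$true_class == "responder"),
              x$config$seed))
  invisible(x)
}
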