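# Responder labelling from pain-rating diaries: one-sided permutation test
# of treatment vs baseline ratings, and analgesia magnitude.

#' Pain-rating diary
#'
#' One participant's phase-tagged 0-10 ratings. Phases are `baseline`,
#' `treatment1`, `treatment2`, ... and `washout`; indices must be unique
#' within a phase.
#'
#' @param participant_id identifier string.
#' @param ratings data.frame with columns `phase`, `index`, `rating`.
#' @return An object of class `pain_diary`.
#' @export
pain_diary <- function(participant_id, ratings) {
  stopifnot(is.data.frame(ratings),
            all(c("phase", "index", "rating") %in% names(ratings)))
  if (any(!is.finite(ratings$rating)) ||
      any(ratings$rating < 0 | ratings$rating > 10))
    stopf("diary %s: ratings must be finite values in [0,10]", participant_id)
  ok_phase <- grepl("^(baseline|treatment[0-9]+|washout)$", ratings$phase)
  if (!all(ok_phase))
    stopf("diary %s: unknown phase label(s): %s", participant_id,
          paste(unique(ratings$phase[!ok_phase]), collapse = ", "))
  dup <- stats::aggregate(list(n = ratings$index),
                          by = list(phase = ratings$phase,
                                    index = ratings$index), FUN = length)
  if (any(dup$n > 1))
    stopf("diary %s: duplicated rating indices within a phase",
          participant_id)
  structure(list(participant_id = participant_id,
                 ratings = ratings[order(match(ratings$phase,
                                               unique(ratings$phase)),
                                         ratings$index), , drop = FALSE]),
            class = "pain_diary")
}

#' @export
print.pain_diary <- function(x, ...) {
  tab <- table(x$ratings$phase)
  cat(sprintf("pain_diary %s: %s\n", x$participant_id,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

phase_ratings <- function(diary, phase) {
  diary$ratings$rating[diary$ratings$phase == phase]
}

treatment_phases <- function(diary) {
  ph <- unique(diary$ratings$phase)
  sort(ph[grepl("^treatment[0-9]+$", ph)])
}

# One-sided Welch (or plain mean-difference) statistics for a set of
# group-1 index columns over the pooled vector z. Larger values favour
# H1: group 1 mean > group 2 mean. Zero-variance splits get +/-Inf with
# the sign of the mean difference (0 when the means tie).
split_stats <- function(z, idx1, statistic) {
  n <- length(z)
  n1 <- nrow(idx1)
  n2 <- n - n1
  g1 <- matrix(z[idx1], nrow = n1)
  s1 <- colSums(g1)
  m1 <- s1 / n1
  m2 <- (sum(z) - s1) / n2
  if (statistic == "mean_diff") return(m1 - m2)
  q1 <- colSums(g1^2)
  v1 <- pmax(0, (q1 - n1 * m1^2) / (n1 - 1))
  v2 <- pmax(0, ((sum(z^2) - q1) - n2 * m2^2) / (n2 - 1))
  se <- sqrt(v1 / n1 + v2 / n2)
  d <- m1 - m2
  out <- ifelse(se > 0, d / se, ifelse(d > 0, Inf, ifelse(d < 0, -Inf, 0)))
  as.numeric(out)
}

#' One-sided permutation test for lowered treatment ratings
#'
#' Tests H1: treatment ratings are lower than baseline ratings, using the
#' Welch t statistic on (baseline - treatment) by default. All
#' `choose(n1+n2, n1)` group assignments are enumerated exactly when their
#' number does not exceed `n_perm`; otherwise a Monte-Carlo sample of
#' `n_perm` permutations is drawn and the observed arrangement is counted
#' in both numerator and denominator (add-one convention). The exact
#' branch returns `#(stat_perm >= stat_obs) / #splits`.
#'
#' If both groups are constant and equal the test is degenerate and
#' returns `p = 1` by convention.
#'
#' @param baseline,treatment numeric rating vectors (each length >= 2).
#' @param n_perm permutation budget (default 10000).
#' @param seed RNG seed for the Monte-Carlo branch.
#' @param statistic `"welch"` (default) or `"mean_diff"`.
#' @return One-sided p-value in (0, 1].
#' @export
permutation_mean_test <- function(baseline, treatment, n_perm = 10000L,
                                  seed = 1L,
                                  statistic = c("welch", "mean_diff")) {
  statistic <- match.arg(statistic)
  if (length(baseline) < 2 || length(treatment) < 2)
    stopf("each group needs at least 2 ratings (got %d and %d)",
          length(baseline), length(treatment))
  if (!is_count(n_perm)) stopf("'n_perm' must be a positive count")
  z <- c(baseline, treatment)
  if (all(z == z[1])) return(1)
  n1 <- length(baseline)
  n <- length(z)
  obs <- split_stats(z, matrix(seq_len(n1), ncol = 1), statistic)
  tol <- 1e-12 * max(1, abs(obs[is.finite(obs)]), na.rm = TRUE)
  n_splits <- choose(n, n1)
  if (n_splits <= n_perm) {
    idx <- utils::combn(n, n1)
    stats_all <- split_stats(z, idx, statistic)
    sum(stats_all >= obs - tol) / n_splits
  } else {
    idx <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) sample.int(n, n1),
             integer(n1))
    })
    stats_mc <- split_stats(z, idx, statistic)
    (1 + sum(stats_mc >= obs - tol)) / (1 + n_perm)
  }
}

#' Label a participant responder or non-responder
#'
#' Each treatment phase is tested marginally against the same baseline
#' with [permutation_mean_test()]; the participant is a responder if the
#' p-value of *either* treatment phase falls below `alpha`. No
#' multiplicity correction is applied (this mirrors the labelling rule of
#' the emulated trials).
#'
#' @param diary a [pain_diary()].
#' @param alpha significance level (default 0.05).
#' @param n_perm,seed,statistic passed to [permutation_mean_test()].
#' @return A list of class `outcome_label` with the per-phase p-values,
#'   the responder flag and the analgesia magnitude.
#' @export
label_responder <- function(diary, alpha = 0.05, n_perm = 10000L, seed = 1L,
                            statistic = c("welch", "mean_diff")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(diary, "pain_diary"))
  phases <- treatment_phases(diary)
  if (length(phases) == 0)
    stopf("diary %s has no treatment phase; phases found: %s",
          diary$participant_id,
          paste(unique(diary$ratings$phase), collapse = ", "))
  base <- phase_ratings(diary, "baseline")
  p_values <- vapply(phases, function(ph) {
    permutation_mean_test(base, phase_ratings(diary, ph), n_perm = n_perm,
                          seed = hash31(seed, diary$participant_id, ph),
                          statistic = statistic)
  }, numeric(1))
  structure(list(participant_id = diary$participant_id,
                 p_values = p_values,
                 responder = any(p_values < alpha),
                 analgesia_pct = analgesia_magnitude(diary),
                 alpha = alpha),
            class = "outcome_label")
}

#' @export
print.outcome_label <- function(x, ...) {
  cat(sprintf("%s: %s (p = %s; analgesia %.1f%%)\n", x$participant_id,
              if (x$responder) "responder" else "non-responder",
              paste(signif(x$p_values, 3), collapse = ", "),
              x$analgesia_pct))
  invisible(x)
}

#' Percent pain relief in the treatment-outcome window
#'
#' `100 * (mean(baseline) - mean(window)) / mean(baseline)`, where the
#' window defaults to the final 14 ratings (the last treatment week,
#' twice-daily) of the final treatment phase.
#'
#' @param diary a [pain_diary()].
#' @param window_size number of trailing ratings of the last treatment
#'   phase to average (capped at the phase length).
#' @return Percent pain relief (positive = improvement).
#' @export
analgesia_magnitude <- function(diary, window_size = 14L) {
  stopifnot(inherits(diary, "pain_diary"))
  base <- phase_ratings(diary, "baseline")
  if (length(base) == 0 || mean(base) <= 0)
    stopf("diary %s: baseline mean must be > 0 for percent change",
          diary$participant_id)
  phases <- treatment_phases(diary)
  if (length(phases) == 0)
    stopf("diary %s has no treatment phase", diary$participant_id)
  last <- phase_ratings(diary, phases[length(phases)])
  w <- utils::tail(last, window_size)
  100 * (mean(base) - mean(w)) / mean(base)
}

#' Label a whole cohort of diaries
#'
#' @param diaries list of [pain_diary()] objects.
#' @inheritParams label_responder
#' @return data.frame with one row per participant: per-phase p-values,
#'   responder flag and analgesia percent.
#' @export
label_cohort <- function(diaries, alpha = 0.05, n_perm = 10000L, seed = 1L) {
  labs <- lapply(diaries, label_responder, alpha = alpha, n_perm = n_perm,
                 seed = seed)
  phases <- names(labs[[1]]$p_values)
  out <- data.frame(participant_id = vapply(labs, `[[`, "", "participant_id"),
                    stringsAsFactors = FALSE)
  for (ph in phases) out[[paste0("p_", ph)]] <-
    vapply(labs, function(l) l$p_values[[ph]], numeric(1))
  out$responder <- vapply(labs, `[[`, TRUE, "responder")
  out$analgesia_pct <- vapply(labs, `[[`, 1, "analgesia_pct")
  rownames(out) <- NULL
  out
}
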