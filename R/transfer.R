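# Validation of a fitted model on an independent cohort: as-is
# application, restricted-topic refit, cross-model feature correlation,
# predicted-group analgesia contrasts, no-treatment specificity.

#' Apply a fitted model as-is to an external cohort
#'
#' Predictions are fixed by the pipeline (no refitting: test labels
#' cannot influence them). Significance of the validation accuracy is
#' assessed by permuting the test labels against the fixed predictions,
#' `p = (1 + #{perm accuracy >= observed}) / (1 + n_perm)`.
#'
#' @param pipeline a [final_fit()] pipeline.
#' @param embeddings numeric matrix (participants x D) from the same
#'   backend/pooling as training; if both the matrix and the pipeline
#'   carry an encoder fingerprint they must agree (error, not warning).
#' @param labels true class labels of the external cohort.
#' @param n_perm label permutations for the significance test.
#' @param seed RNG seed.
#' @param analgesia optional per-participant analgesia percents, used for
#'   a predicted-group contrast.
#' @return List of class `validation_report`: `mode`, `accuracy`,
#'   `permutation_p`, `confusion`, `predictions`, and (when analgesia is
#'   supplied) `group_means`, `t`, `p`, `cohens_d`.
#' @export
apply_model <- function(pipeline, embeddings, labels, n_perm = 1000L,
                        seed = 1L, analgesia = NULL) {
  stopifnot(inherits(pipeline, "fitted_pipeline"))
  fp <- attr(embeddings, "fingerprint")
  if (!is.null(fp) && !is.null(pipeline$backend_fingerprint) &&
      fp != pipeline$backend_fingerprint)
    stopf(paste("embedding fingerprint (%s) does not match the pipeline's",
                "training backend (%s)"), fp, pipeline$backend_fingerprint)
  s <- as_signed_labels(labels)
  pred <- predict(pipeline, embeddings, type = "class")
  acc <- mean(pred == signed_to_class(s))
  perm_acc <- with_seed(hash31(seed, "applyperm"), {
    vapply(seq_len(n_perm),
           function(b) mean(pred == signed_to_class(sample(s))), numeric(1))
  })
  confusion <- table(predicted = factor(pred, c(NEGATIVE_CLASS,
                                                POSITIVE_CLASS)),
                     true = factor(signed_to_class(s),
                                   c(NEGATIVE_CLASS, POSITIVE_CLASS)))
  out <- list(mode = "full_model", accuracy = acc,
              permutation_p = (1 + sum(perm_acc >= acc - 1e-12)) /
                (1 + n_perm),
              confusion = confusion,
              predictions = data.frame(
                participant_id = rownames(embeddings) %||%
                  sprintf("s%03d", seq_along(pred)),
                predicted = pred, true = signed_to_class(s),
                decision = predict(pipeline, embeddings, type = "decision"),
                stringsAsFactors = FALSE),
              n_perm = n_perm, seed = seed)
  if (!is.null(analgesia)) {
    out <- c(out, predicted_group_analgesia(analgesia, pred))
  }
  structure(out, class = "validation_report")
}

predicted_group_analgesia <- function(analgesia, pred) {
  groups <- factor(pred, c(NEGATIVE_CLASS, POSITIVE_CLASS))
  means <- tapply(analgesia, groups, mean)
  if (all(table(groups) >= 2)) {
    gc <- group_contrast(analgesia, groups)
    list(group_means = means, t = gc$t, p = gc$p, cohens_d = gc$cohens_d)
  } else {
    list(group_means = means, t = NA_real_, p = NA_real_,
         cohens_d = NA_real_)
  }
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation (%s): accuracy %.3f, permutation p = %.4f\n",
              x$mode, x$accuracy, x$permutation_p))
  print(x$confusion)
  invisible(x)
}

#' Refit the pipeline on a restricted topic set
#'
#' Restricts every training transcript to `overlap_topics`, re-embeds,
#' and reruns the full final fit with hyperparameter re-tuning. Used when
#' the validation cohort's interview covers only a subset of the training
#' topics. Participants left with no text in the overlap topics are
#' excluded with a warning.
#'
#' @param transcripts list of training [transcript()] objects.
#' @param labels training class labels (same order as `transcripts`).
#' @param overlap_topics topic ids retained.
#' @param backend encoder backend.
#' @param mode,pooling structuring and pooling modes.
#' @param grid,inner_folds,seed passed to [final_fit()].
#' @return A [final_fit()] pipeline (attribute `"participants"` lists the
#'   ids actually used).
#' @export
restricted_refit <- function(transcripts, labels, overlap_topics, backend,
                             mode = "sequential", pooling = "mean",
                             grid = default_grid(), inner_folds = 10L,
                             seed = 1L) {
  topics <- transcripts[[1]]$topics
  missing <- setdiff(overlap_topics, topics)
  if (length(missing))
    stopf("overlap topic(s) absent from the training inventory: %s",
          paste(missing, collapse = ", "))
  restricted <- lapply(transcripts, function(tr)
    suppressWarnings(filter_topics(tr, setdiff(tr$topics, overlap_topics))))
  has_text <- vapply(restricted, function(tr) nrow(tr$segments) > 0,
                     logical(1))
  if (any(!has_text)) {
    warnf("excluding %d participant(s) with no text in the overlap topics: %s",
          sum(!has_text),
          paste(vapply(restricted[!has_text], `[[`, "", "participant_id"),
                collapse = ", "))
  }
  X <- embed_transcripts(backend, restricted[has_text], mode = mode,
                         pooling = pooling)
  fit <- final_fit(X, labels[has_text], grid = grid,
                   inner_folds = inner_folds, seed = seed)
  attr(fit, "participants") <- rownames(X)
  fit
}

#' Correlation between the selected features of two models
#'
#' Pearson correlations between every selected-feature column of pipeline
#' A and of pipeline B (after each pipeline's own scaling), over the
#' participants shared by both embedding matrices.
#'
#' @param pipeline_a,pipeline_b [final_fit()] pipelines.
#' @param embeddings_a,embeddings_b full-dimension embedding matrices with
#'   participant rownames, in each pipeline's own feature space.
#' @return Numeric matrix (`k_A` x `k_B`) of correlations.
#' @export
cross_feature_correlation <- function(pipeline_a, pipeline_b,
                                      embeddings_a, embeddings_b) {
  shared <- intersect(rownames(embeddings_a), rownames(embeddings_b))
  if (length(shared) < 3)
    stopf("pipelines share %d participant(s); need at least 3",
          length(shared))
  fa <- selected_features(pipeline_a, embeddings_a[shared, , drop = FALSE])
  fb <- selected_features(pipeline_b, embeddings_b[shared, , drop = FALSE])
  stats::cor(fa, fb)
}

#' Selected, scaled feature columns of a pipeline
#'
#' @param pipeline a [final_fit()] pipeline.
#' @param embeddings full-dimension embedding matrix.
#' @return Matrix (participants x k) named `feature1..featurek`.
#' @export
selected_features <- function(pipeline, embeddings) {
  Xs <- robust_scale_apply(as.matrix(embeddings),
                           list(medians = pipeline$medians,
                                iqrs = pipeline$iqrs))
  out <- Xs[, pipeline$selected, drop = FALSE]
  colnames(out) <- sprintf("feature%d", seq_along(pipeline$selected))
  out
}

#' Two-group contrast: pooled t-test and Cohen's d
#'
#' Two-sided independent-samples t-test with pooled variance;
#' `Cohen's d = (mean(group 2) - mean(group 1)) / pooled SD` (so the sign
#' flips if the groups are swapped). A Welch variant is available.
#'
#' @param values numeric vector of per-participant scalars.
#' @param groups two-level factor (or coercible) aligned with `values`;
#'   both groups need >= 2 members.
#' @param welch use Welch's t instead of the pooled-variance t.
#' @return List: `t`, `p`, `cohens_d`, `group_means`, `df`.
#' @export
group_contrast <- function(values, groups, welch = FALSE) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2)
    stopf("'groups' must have exactly 2 levels, got %d", nlevels(groups))
  counts <- table(groups)
  if (any(counts < 2))
    stopf("both groups need at least 2 members (got %s)",
          paste(counts, collapse = ", "))
  g1 <- values[groups == levels(groups)[1]]
  g2 <- values[groups == levels(groups)[2]]
  tt <- stats::t.test(g2, g1, var.equal = !welch)
  sp <- sqrt(((length(g1) - 1) * stats::var(g1) +
                (length(g2) - 1) * stats::var(g2)) /
               (length(g1) + length(g2) - 2))
  d <- if (sp > 0) (mean(g2) - mean(g1)) / sp else
    ifelse(mean(g2) == mean(g1), 0, NA_real_)
  list(t = unname(tt$statistic), p = tt$p.value, cohens_d = d,
       group_means = c(mean(g1), mean(g2)), df = unname(tt$parameter))
}

#' Specificity check on a no-treatment arm
#'
#' Correlates the signed boundary distance with analgesia magnitude in a
#' cohort that received no treatment, and contrasts analgesia between
#' predicted groups. In a no-treatment arm (no placebo-analgesia
#' coupling) both quantities should be null-consistent; a positive
#' coupling is expected only in the placebo arm. Reported without
#' thresholding.
#'
#' @param pipeline a [final_fit()] pipeline.
#' @param embeddings no-treatment cohort embeddings (>= 4 participants).
#' @param analgesia analgesia percents aligned with the rows.
#' @return List of class `specificity_report`: `r`, `r_p`, `n`,
#'   `group_means`, `t`, `p`, `cohens_d`, `predicted`.
#' @export
specificity_check <- function(pipeline, embeddings, analgesia) {
  if (nrow(embeddings) < 4)
    stopf("no-treatment cohort needs at least 4 participants")
  stopifnot(length(analgesia) == nrow(embeddings))
  dist <- signed_distance(pipeline, embeddings)
  ct <- stats::cor.test(dist, analgesia, method = "pearson")
  pred <- predict(pipeline, embeddings, type = "class")
  contrast <- predicted_group_analgesia(analgesia, pred)
  structure(c(list(r = unname(ct$estimate), r_p = ct$p.value,
                   n = nrow(embeddings), predicted = pred,
                   signed_distances = dist),
              contrast),
            class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat(sprintf("specificity check (n = %d): r = %.3f (p = %.3f), Cohen's d = %.2f (p = %.3f)\n",
              x$n, x$r, x$r_p, x$cohens_d, x$p))
  invisible(x)
}
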