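# A second synthetic cohort sharing the training encoder stands in for
# the independent validation study.
validation_fixture <- function() {
  if (is.null(fixture_env$validation)) {
    fx <- default_cohort_fixture()
    cfg2 <- synthetic_config(seed = 505, n_participants = 20)
    co2 <- generate_cohort(cfg2)
    X2 <- embed_transcripts(fx$encoder, co2$transcripts,
                            mode = "sequential", pooling = "mean")
    fixture_env$validation <- list(train = fx, cohort2 = co2, X2 = X2,
                                   y2 = co2$truth$true_class)
  }
  fixture_env$validation
}

test_that("as-is application scores fixed predictions with a permutation p", {
  v <- validation_fixture()
  pipe <- final_fit(v$train$X, v$train$y, seed = 2)
  rep_ <- apply_model(pipe, v$X2, v$y2, n_perm = 200, seed = 3)
  expect_identical(sum(rep_$confusion), 20L)
  expect_gt(rep_$accuracy, 0.7)               # planted signal transfers
  expect_lt(rep_$permutation_p, 0.05)
  # perfect self-prediction: p is the add-one minimum when no ties
  self <- apply_model(pipe, v$X2,
                      predict(pipe, v$X2, type = "class") == "responder",
                      n_perm = 50, seed = 4)
  expect_equal(self$accuracy, 1)
  # add-one minimum 1/(1+n_perm): a permutation ties only if it exactly
  # reproduces the label vector, which these seeds do not
  expect_equal(self$permutation_p, 1 / 51)
  # mutation check: changing test labels cannot change predictions
  y_flip <- !(v$y2 == "responder")
  rep_flip <- apply_model(pipe, v$X2, y_flip, n_perm = 10, seed = 3)
  expect_identical(rep_flip$predictions$predicted,
                   rep_$predictions$predicted)
  expect_equal(rep_flip$accuracy, 1 - rep_$accuracy)
})

test_that("fingerprint mismatches are an error, not a warning", {
  v <- validation_fixture()
  pipe <- final_fit(v$train$X, v$train$y, seed = 2)
  Xbad <- v$X2
  attr(Xbad, "fingerprint") <- hash31("some-other-backend")
  expect_error(apply_model(pipe, Xbad, v$y2), "fingerprint")
})

test_that("restricted refit with all topics reproduces the full model", {
  v <- validation_fixture()
  fx <- v$train
  full <- final_fit(fx$X, fx$y, seed = 11)
  same <- restricted_refit(fx$cohort$transcripts, fx$y,
                           overlap_topics = fx$cohort$transcripts[[1]]$topics,
                           backend = fx$encoder, seed = 11)
  expect_identical(same$selected, full$selected)
  expect_equal(same$w, full$w)
  expect_equal(same$b, full$b)
  expect_equal(same$medians, full$medians)
  expect_error(restricted_refit(fx$cohort$transcripts, fx$y,
                                overlap_topics = "no-such-topic",
                                backend = fx$encoder), "absent")
})

test_that("a four-topic restricted model still validates on a second cohort", {
  v <- validation_fixture()
  fx <- v$train
  overlap <- fx$cohort$transcripts[[1]]$topics[1:4]
  pipe4 <- restricted_refit(fx$cohort$transcripts, fx$y, overlap,
                            backend = fx$encoder, seed = 12)
  restricted2 <- lapply(v$cohort2$transcripts, function(tr)
    filter_topics(tr, setdiff(tr$topics, overlap)))
  X2r <- embed_transcripts(fx$encoder, restricted2, "sequential", "mean")
  rep_ <- apply_model(pipe4, X2r, v$y2, n_perm = 200, seed = 5)
  expect_gte(rep_$accuracy, 0.8)              # cues are spread over topics
})

test_that("cross-model feature correlations recover shared signal", {
  v <- validation_fixture()
  fx <- v$train
  pipeA <- final_fit(fx$X, fx$y, seed = 2)
  pipeB <- restricted_refit(fx$cohort$transcripts, fx$y,
                            fx$cohort$transcripts[[1]]$topics[1:8],
                            backend = fx$encoder, seed = 3)
  M <- cross_feature_correlation(pipeA, pipeB, fx$X, fx$X)
  expect_identical(dim(M), c(length(pipeA$selected),
                             length(pipeB$selected)))
  # each full-model feature has a strongly correlated counterpart
  expect_true(all(apply(abs(M), 1, max) > 0.7))
  self <- cross_feature_correlation(pipeA, pipeA, fx$X, fx$X)
  expect_equal(unname(diag(self)), rep(1, length(pipeA$selected)))
  Xanon <- fx$X
  rownames(Xanon) <- paste0("other-", seq_len(nrow(Xanon)))
  expect_error(cross_feature_correlation(pipeA, pipeB, fx$X, Xanon),
               "share")
})

test_that("group contrast matches hand arithmetic and is antisymmetric", {
  gc <- group_contrast(c(1, 2, 3, 3, 4, 5), rep(c("a", "b"), each = 3))
  expect_equal(gc$cohens_d, 2)
  expect_equal(gc$group_means, c(2, 4))
  # pooled t equals stats::t.test with var.equal
  tt <- t.test(c(3, 4, 5), c(1, 2, 3), var.equal = TRUE)
  expect_equal(gc$t, unname(tt$statistic))
  expect_equal(gc$p, tt$p.value)
  swap <- group_contrast(c(1, 2, 3, 3, 4, 5), rep(c("b", "a"), each = 3))
  expect_equal(swap$cohens_d, -2)
  same <- group_contrast(rep(c(2, 4), 4), rep(c("a", "b"), each = 4))
  expect_equal(same$cohens_d, 0)
  expect_equal(same$p, 1)
  expect_error(group_contrast(1:3, c("a", "a", "b")), "at least 2")
})

test_that("specificity check reports a complete record on small cohorts", {
  v <- validation_fixture()
  pipe <- final_fit(v$train$X, v$train$y, seed = 2)
  with_seed(3, analg <- rnorm(4, 10, 5))
  rep_ <- specificity_check(pipe, v$X2[1:4, ], analg)
  expect_true(all(c("r", "r_p", "n", "group_means", "t", "p",
                    "cohens_d", "predicted") %in% names(rep_)))
  expect_identical(rep_$n, 4L)
  expect_true(is.finite(rep_$r))
  expect_error(specificity_check(pipe, v$X2[1:3, ], analg[1:3]),
               "at least 4")
})
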