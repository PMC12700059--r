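# A small fitted pipeline with identity scaling for geometry checks.
toy_pipeline <- function(w = c(3, 4), b = 0, D = 4, selected = c(1, 2)) {
  structure(list(medians = rep(0, D), iqrs = rep(1, D),
                 selected = selected, w = w, b = b,
                 k = length(selected), C = 1,
                 positive_class = "responder",
                 training_accuracy = NA_real_,
                 inner_cv_accuracy = NA_real_,
                 grid = NULL, seed = 1, backend_fingerprint = NULL),
            class = "fitted_pipeline")
}

test_that("signed distance is the normalized affine functional", {
  p <- toy_pipeline(w = c(3, 4), b = 0)
  expect_equal(signed_distance(p, c(1, 1, 9, 9)), 7 / 5)
  expect_equal(signed_distance(p, c(0, 0, 1, -1)), 0)
  # affine in its argument (after scaling/selection): exact
  x <- c(2, -1, 0, 0); y <- c(-3, 4, 0, 0); a <- 0.3
  expect_equal(signed_distance(p, a * x + (1 - a) * y),
               a * signed_distance(p, x) + (1 - a) * signed_distance(p, y))
  expect_error(signed_distance(p, c(1, 2)), "dimensions")
})

test_that("distance sign matches the predicted class on a real fit", {
  fx <- default_cohort_fixture()
  pipe <- final_fit(fx$X, fx$y, seed = 6)
  d <- signed_distance(pipe, fx$X)
  expect_identical(unname(ifelse(d > 0, "responder", "nonresponder")),
                   unname(predict(pipe, fx$X, type = "class")))
})

test_that("concept probes rank planted cues on the correct sides", {
  fx <- default_cohort_fixture()
  pipe <- final_fit(fx$X, fx$y, seed = 6)
  cues <- concept_tokens(fx$config)
  probes <- probe_concepts(pipe, fx$encoder, cues$token)
  got <- probes$side[match(cues$token, probes$label)]
  expect_identical(got, cues$class)
  # ranking invariant to input order; duplicates identical
  probes2 <- probe_concepts(pipe, fx$encoder, rev(cues$token))
  expect_equal(probes2$signed_distance[match(probes$label, probes2$label)],
               probes$signed_distance)
  dup <- probe_concepts(pipe, fx$encoder, c("respcue1", "respcue1"))
  expect_equal(dup$signed_distance[1], dup$signed_distance[2])
  expect_warning(
    probe_concepts(pipe, fx$encoder, c("respcue1", "   ")), "zero tokens")
})

test_that("cluster centroids inherit the mean of member distances", {
  p <- toy_pipeline()
  with_seed(5, V <- matrix(rnorm(80), 20, 4))
  labels <- rep(c(1L, 2L, -1L), c(8, 8, 4))
  rownames(V) <- sprintf("s%02d", 1:20)
  cl <- cluster_summary(V, labels, p, describe = NULL)
  expect_identical(nrow(cl), 2L)
  for (i in 1:2) {
    members <- cl$members[[i]]
    expect_equal(cl$signed_distance[i],
                 mean(signed_distance(p, V[members, ])))
    expect_identical(cl$size[i], length(members))
  }
  # centroid of a hand-built cluster
  expect_equal(cl$centroid[[which(cl$cluster_id == 1)]],
               colMeans(V[1:8, ]))
  # noise points belong to no cluster
  expect_false(any(sprintf("s%02d", 17:20) %in% unlist(cl$members)))
})

test_that("template-driven sentence clusters separate by class direction", {
  fx <- default_cohort_fixture()
  pipe <- final_fit(fx$X, fx$y, seed = 6)
  # recurrent sentences: both class variants of every cue-bearing
  # template, repeated as they would recur across participants
  tR <- class_templates(fx$config, "responder")
  tN <- class_templates(fx$config, "nonresponder")
  cued <- which(vapply(tR, function(x) any(grepl("respcue", x)), TRUE))
  toks <- c(lapply(tR[cued], identity), lapply(tN[cued], identity))
  toks <- rep(toks, each = 8)
  sentences <- data.frame(
    sentence_id = sprintf("t%03d", seq_along(toks)),
    participant_id = "pool", doc_id = "doc",
    n_words = lengths(toks),
    text = vapply(toks, paste, "", collapse = " "),
    stringsAsFactors = FALSE)
  sentences$tokens <- toks
  variant <- rep(rep(c("responder", "nonresponder"), each = length(cued)),
                 each = 8)
  skeleton <- rep(rep(seq_along(cued), 2), each = 8)
  SV <- embed_sentences(fx$encoder, sentences, pooling = "mean")
  labels <- cluster_sentences(SV, min_cluster_size = 5)
  expect_gt(max(labels), 1)
  cl <- cluster_summary(SV, labels, pipe, sentences = sentences)
  expect_true(all(cl$size >= 5))
  # within each skeleton, the responder variant's cluster sits on the
  # more responder-like side of the boundary than its paired
  # non-responder variant
  cluster_of <- function(sk, cls) {
    rows <- which(skeleton == sk & variant == cls)
    lab <- unique(labels[rows])
    lab[lab != -1L][1]
  }
  diffs <- vapply(seq_along(cued), function(sk) {
    a <- cluster_of(sk, "responder"); b <- cluster_of(sk, "nonresponder")
    if (is.na(a) || is.na(b) || a == b) return(NA_real_)
    cl$signed_distance[cl$cluster_id == a] -
      cl$signed_distance[cl$cluster_id == b]
  }, numeric(1))
  diffs <- diffs[!is.na(diffs)]
  expect_gt(length(diffs), 3)
  expect_true(all(diffs > 0))
  # default description hook produces non-empty text
  expect_true(all(nzchar(cl$description)))
})

test_that("feature-covariate correlations report r, p and stars", {
  with_seed(9, {
    f <- matrix(rnorm(60), 30, 2, dimnames = list(sprintf("p%02d", 1:30),
                                                  c("f1", "f2")))
    cov <- data.frame(same = f[, 1], noise = rnorm(30),
                      const = rep(1, 30))
  })
  rep_ <- correlate_features(f, cov)
  r_same <- rep_$r[rep_$feature == "f1" & rep_$covariate == "same"]
  expect_equal(r_same, 1)
  expect_identical(rep_$stars[rep_$feature == "f1" &
                                rep_$covariate == "same"], "***")
  expect_true(is.na(rep_$r[rep_$feature == "f1" &
                             rep_$covariate == "const"]))
  # symmetric in the two arguments
  r_ab <- rep_$r[rep_$feature == "f2" & rep_$covariate == "noise"]
  expect_equal(r_ab, cor(cov$noise, f[, 2]))
  # agrees with cor.test p-value
  ct <- cor.test(f[, 2], cov$noise)
  expect_equal(rep_$p[rep_$feature == "f2" & rep_$covariate == "noise"],
               ct$p.value)
})

test_that("ICC(2,k) matches the mean-squares oracle", {
  expect_equal(icc_2k(cbind(1:6, 1:6, 1:6)), 1)
  expect_true(is.na(icc_2k(matrix(3, 4, 3))))
  # oracle via aov mean squares on a hand-built 6 x 3 matrix
  M <- rbind(c(9, 2, 5), c(6, 1, 3), c(8, 4, 6), c(7, 1, 2),
             c(10, 5, 6), c(6, 2, 4))
  df <- data.frame(y = as.vector(M),
                   item = factor(rep(1:6, 3)),
                   rater = factor(rep(1:3, each = 6)))
  ms <- summary(aov(y ~ item + rater, data = df))[[1]]$`Mean Sq`
  oracle <- (ms[1] - ms[3]) / (ms[1] + (ms[2] - ms[3]) / 6)
  expect_equal(icc_2k(M), oracle)
  expect_error(icc_2k(cbind(c(1, NA), c(2, 3))), "missing")
  expect_error(icc_2k(matrix(1, 1, 3)), "at least 2")
})
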