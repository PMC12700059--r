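test_that("robust scaling uses median and interpolated IQR", {
  X <- cbind(a = c(1, 2, 3, 4, 5), b = rep(7, 5))
  sc <- robust_scale_fit(X)
  expect_equal(sc$medians, c(3, 7))
  expect_equal(sc$iqrs, c(2, 1))              # zero IQR -> unit divisor
  Xs <- robust_scale_apply(X, sc)
  expect_equal(unname(Xs[5, 1]), 1)
  expect_equal(Xs[, 2], rep(0, 5))
  expect_equal(median(Xs[, 1]), 0)
  # matches stats::quantile type 7 on a ragged feature
  z <- c(0.3, 2.2, -1, 5, 0.7, 0.1)
  sc2 <- robust_scale_fit(cbind(z))
  expect_equal(sc2$medians, unname(quantile(z, 0.5, type = 7)))
  expect_equal(sc2$iqrs, unname(diff(quantile(z, c(0.25, 0.75), type = 7))))
  expect_error(robust_scale_fit(matrix(0, 1, 2)), "2 samples")
})

test_that("k-best selection ranks by ANOVA F with index tie-breaks", {
  y <- rep(c(TRUE, FALSE), each = 5)
  X <- cbind(const = rep(1, 10),              # F = 0, never ahead
             sep = c(rep(1, 5), rep(0, 5)) + seq(0, 0.09, 0.01),
             noise = c(0.3, -0.2, 0.1, 0, 0.2, 0.1, -0.1, 0.2, -0.3, 0))
  expect_identical(select_k_best(X, y, 1), 2L)
  expect_identical(select_k_best(X, y, 3), c(2L, 3L, 1L))
  expect_error(select_k_best(X, y, 4), "k must be")
  # equal-F duplicate columns: lower index wins
  X2 <- cbind(X[, 2], X[, 2])
  expect_identical(select_k_best(X2, y, 1), 1L)
  # agreement with stats::aov on a single feature
  f_pkg <- placebotalk:::anova_f_scores(X[, 3, drop = FALSE],
                                        ifelse(y, 1, -1))
  f_aov <- summary(aov(X[, 3] ~ factor(y)))[[1]]$`F value`[1]
  expect_equal(unname(f_pkg), f_aov)
})

test_that("the L1 squared-hinge SVC matches an independent convex solver", {
  with_seed(10, {
    X <- matrix(rnorm(12), 6, 2)
    y <- c(1, 1, 1, -1, -1, -1)
    X[y == 1, 1] <- X[y == 1, 1] + 2
  })
  for (C in c(0.05, 0.5, 2, 10)) {
    fit <- svc_fit(X, y > 0, C)
    orc <- oracle_svc(X, y, C)
    expect_equal(fit$objective, orc$objective, tolerance = 1e-6)
    expect_equal(fit$w, orc$w, tolerance = 1e-3)
    d_fit <- drop(X %*% fit$w) + fit$b
    d_orc <- drop(X %*% orc$w) + orc$b
    nz <- abs(d_orc) > 1e-6      # away from the degenerate all-zero fit
    expect_identical(sign(d_fit[nz]), sign(d_orc[nz]))
  }
  # separable data is classified perfectly at large C
  fit <- svc_fit(X, y > 0, 50)
  expect_true(all(sign(drop(X %*% fit$w) + fit$b) == y))
  # C -> 0 drives the weights to zero
  expect_equal(svc_fit(X, y > 0, 1e-6)$w, c(0, 0))
  expect_error(svc_fit(X, rep(TRUE, 6), 1), "both classes")
})

test_that("nested LOOCV equals a fold-by-fold refit oracle exactly", {
  with_seed(8, {
    X <- matrix(rnorm(24), 12, 2)
    y <- rep(c(TRUE, FALSE), 6)
    X[y, 1] <- X[y, 1] + 1.5
  })
  rownames(X) <- sprintf("id%02d", 1:12)
  grid <- data.frame(k = 1L, C = 1)
  cv <- suppressWarnings(   # documented inner-fold reduction at n = 11
    nested_cv(X, y, grid = grid, seed = 2))
  # oracle: compose the exported primitives fold by fold
  oracle_dec <- vapply(1:12, function(i) {
    tr <- setdiff(1:12, i)
    sc <- robust_scale_fit(X[tr, ])
    Xs <- robust_scale_apply(X[tr, ], sc)
    sel <- select_k_best(Xs, y[tr], 1)
    fit <- svc_fit(Xs[, sel, drop = FALSE], y[tr], 1)
    drop(robust_scale_apply(X[i, , drop = FALSE], sc)[, sel] %*% fit$w) +
      fit$b
  }, numeric(1))
  expect_equal(cv$predictions$decision, oracle_dec)
  expect_identical(cv$predictions$predicted,
                   ifelse(oracle_dec > 0, "responder", "nonresponder"))
  expect_equal(cv$outer_accuracy,
               mean((oracle_dec > 0) == y))
})

test_that("the held-out sample never influences its own fold's fit", {
  with_seed(14, {
    X <- matrix(rnorm(28), 14, 2)
    y <- rep(c(TRUE, FALSE), 7)
  })
  rownames(X) <- sprintf("id%02d", 1:14)
  grid <- data.frame(k = 2L, C = 1)
  Xm <- X
  Xm[3, ] <- Xm[3, ] + 100                     # corrupt one held-out row
  mut <- suppressWarnings(nested_cv(Xm, y, grid = grid, seed = 5))
  # fold 3's parameters are a function of the other rows only: refit them
  # from the uncorrupted rows and reproduce the corrupted row's decision
  sc <- robust_scale_fit(X[-3, ])
  Xs <- robust_scale_apply(X[-3, ], sc)
  sel <- select_k_best(Xs, y[-3], 2)
  fit <- svc_fit(Xs[, sel, drop = FALSE], y[-3], 1)
  d3 <- drop(robust_scale_apply(Xm[3, , drop = FALSE], sc)[, sel] %*%
               fit$w) + fit$b
  expect_equal(mut$predictions$decision[3], d3)
})

test_that("shuffled labels give chance-level accuracy", {
  fx <- default_cohort_fixture()
  with_seed(33, y_perm <- sample(fx$y))
  cv <- nested_cv(fx$X[, 1:50], y_perm, grid = data.frame(k = 2L, C = 1),
                  seed = 9)
  band <- qbinom(c(0.005, 0.995), length(y_perm), 0.5) / length(y_perm)
  expect_gte(cv$outer_accuracy, band[1])
  expect_lte(cv$outer_accuracy, band[2])
})

test_that("permutation significance uses the add-one convention", {
  with_seed(2, {
    X <- matrix(rnorm(28), 14, 2)
    y <- rep(c(TRUE, FALSE), 7)
    X[y, ] <- X[y, ] + 3                       # strong signal
  })
  pt <- suppressWarnings(permutation_significance(
    X, y, grid = data.frame(k = 1L, C = 1), n_perm = 19, seed = 3))
  expect_gt(pt$p, 0)
  expect_gt(pt$observed_accuracy, 0.85)        # strong planted signal
  expect_equal(pt$p,
               (1 + sum(pt$perm_accuracies >= pt$observed_accuracy - 1e-12)) /
                 20)
  expect_lte(pt$p, 0.25)
  expect_error(permutation_significance(X, y, n_perm = 0), "n_perm")
})

test_that("bootstrap CI brackets the fold accuracy and ignores order", {
  expect_equal(bootstrap_accuracy_ci(rep(TRUE, 10), seed = 1), c(1, 1))
  correct <- rep(c(TRUE, FALSE), 21)
  ci <- bootstrap_accuracy_ci(correct, n_boot = 4000, seed = 7)
  expect_lt(ci[1], 0.5)
  expect_gt(ci[2], 0.5)
  expect_identical(ci, bootstrap_accuracy_ci(rev(correct), n_boot = 4000,
                                             seed = 7))
  # matches an independent re-implementation within resampling error
  ind <- with_seed(99, quantile(replicate(4000,
    mean(sample(correct, replace = TRUE))), c(0.025, 0.975), names = FALSE))
  expect_lt(max(abs(ci - ind)), 0.08)
})

test_that("final_fit reproduces itself and reports both accuracies", {
  fx <- default_cohort_fixture()
  a <- final_fit(fx$X, fx$y, seed = 4)
  b <- final_fit(fx$X, fx$y, seed = 4)
  expect_identical(a[names(a) != "backend_fingerprint"],
                   b[names(b) != "backend_fingerprint"])
  expect_setequal(a$selected, 1:2)
  expect_gte(a$k, 2)
  expect_true(is.finite(a$inner_cv_accuracy))
  expect_gte(a$training_accuracy, a$inner_cv_accuracy - 0.1)
  expect_identical(a$backend_fingerprint, fx$encoder$fingerprint)
  # predictions agree between class and decision types
  d <- predict(a, fx$X, type = "decision")
  expect_identical(predict(a, fx$X, type = "class"),
                   ifelse(d > 0, "responder", "nonresponder"))
})
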