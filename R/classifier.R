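# Responder classification from document embeddings: robust scaling,
# k-best ANOVA-F selection, L1-regularized linear SVC, nested
# cross-validation (stratified 10-fold inner grid search, leave-one-out
# outer loop), label-permutation significance, bootstrap CI.

POSITIVE_CLASS <- "responder"
NEGATIVE_CLASS <- "nonresponder"

# y can be logical (TRUE = responder), a factor, or a character vector
# using the responder/nonresponder labels; internally +/-1 with
# +1 = responder (decision value > 0 predicts responder).
as_signed_labels <- function(y) {
  if (is.logical(y)) return(ifelse(y, 1, -1))
  y <- as.character(y)
  bad <- setdiff(unique(y), c(POSITIVE_CLASS, NEGATIVE_CLASS))
  if (length(bad))
    stopf("labels must be %s/%s (or logical); got: %s", POSITIVE_CLASS,
          NEGATIVE_CLASS, paste(bad, collapse = ", "))
  ifelse(y == POSITIVE_CLASS, 1, -1)
}

signed_to_class <- function(s) ifelse(s > 0, POSITIVE_CLASS, NEGATIVE_CLASS)

#' Fit robust (median/IQR) feature scaling
#'
#' Per-feature centering by the median and scaling by the interquartile
#' range (Q3 - Q1, linear-interpolation quantiles). Features with zero
#' IQR are given unit scale so constant features map to zero.
#'
#' @param X numeric matrix (samples x features), at least 2 rows.
#' @return List with `medians` and `iqrs`.
#' @export
robust_scale_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stopf("robust scaling needs at least 2 samples")
  n <- nrow(X)
  # column-wise sort in one radix pass; interpolation indices are shared
  S <- matrix(X[order(col(X), X, method = "radix")], n, ncol(X))
  q_at <- function(p) {             # type-7 quantile on pre-sorted columns
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    S[lo, ] + (h - lo) * (S[hi, ] - S[lo, ])
  }
  med <- q_at(0.5)
  iqr <- q_at(0.75) - q_at(0.25)
  list(medians = as.numeric(med),
       iqrs = ifelse(iqr > 0, as.numeric(iqr), 1))
}

#' Apply fitted robust scaling
#'
#' @param X numeric matrix.
#' @param params list from [robust_scale_fit()].
#' @export
robust_scale_apply <- function(X, params) {
  X <- as.matrix(X)
  if (ncol(X) != length(params$medians))
    stopf("X has %d features but the scaler was fit on %d", ncol(X),
          length(params$medians))
  sweep(sweep(X, 2, params$medians, "-"), 2, params$iqrs, "/")
}

# Per-feature one-way ANOVA F between the two classes, vectorized.
anova_f_scores <- function(X, s) {
  n <- nrow(X)
  g1 <- s > 0
  n1 <- sum(g1); n2 <- n - n1
  if (n1 == 0 || n2 == 0) stopf("both classes must be present")
  m1 <- colMeans(X[g1, , drop = FALSE])
  m2 <- colMeans(X[!g1, , drop = FALSE])
  m <- (n1 * m1 + n2 * m2) / n
  ss_b <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  ss_w <- colSums(sweep(X[g1, , drop = FALSE], 2, m1, "-")^2) +
    colSums(sweep(X[!g1, , drop = FALSE], 2, m2, "-")^2)
  ms_w <- ss_w / (n - 2)
  ifelse(ms_w > 0, ss_b / ms_w, ifelse(ss_b > 0, Inf, 0))
}

#' Select the k best features by between-class ANOVA F
#'
#' @param X numeric matrix (scaled features).
#' @param y class labels (see package conventions).
#' @param k number of features to keep, `1 <= k <= ncol(X)`.
#' @return Integer vector of selected column indices, in decreasing score
#'   order; ties broken toward the lower index.
#' @export
select_k_best <- function(X, y, k) {
  X <- as.matrix(X)
  if (!is_count(k) || k > ncol(X))
    stopf("k must be a count in [1, %d], got %s", ncol(X), format(k))
  f <- anova_f_scores(X, as_signed_labels(y))
  order(-f, seq_along(f))[seq_len(k)]
}

#' Fit an L1-regularized linear support-vector classifier
#'
#' Minimizes `||w||_1 + C * sum_i max(0, 1 - y_i (w . x_i + b))^2`
#' (squared-hinge loss, unpenalized intercept) with an accelerated
#' proximal-gradient solver. `C` is the inverse regularization strength:
#' the weight vector becomes sparser as `C` decreases and `w -> 0` as
#' `C -> 0`.
#'
#' @param X numeric matrix (samples x features).
#' @param y class labels; both classes must be present.
#' @param C inverse regularization strength (> 0).
#' @param max_iter,tol solver controls.
#' @return List with `w`, `b`, `objective`.
#' @export
svc_fit <- function(X, y, C = 1, max_iter = 2000L, tol = 1e-10) {
  X <- as.matrix(X)
  s <- as_signed_labels(y)
  if (length(unique(s)) < 2)
    stopf("svc_fit needs both classes in y")
  if (!is.numeric(C) || length(C) != 1 || C <= 0) stopf("C must be > 0")
  .svc_l1_sqhinge(X, as.numeric(s), C, as.integer(max_iter), tol)
}

#' Default hyperparameter grid
#'
#' `k` in {1, 2, 5, 10, 20, 50} crossed with `C` in {0.01, 0.1, 1, 10},
#' ordered by `k` then `C` so accuracy ties resolve toward parsimony.
#'
#' @param k,C candidate values.
#' @export
default_grid <- function(k = c(1L, 2L, 5L, 10L, 20L, 50L),
                         C = c(0.01, 0.1, 1, 10)) {
  g <- expand.grid(C = C, k = as.integer(k))[, c("k", "C")]
  g <- g[order(g$k, g$C), ]
  rownames(g) <- NULL
  g
}

# Stratified fold assignment: members of each class are shuffled
# (seeded) and dealt round-robin into nf folds.
stratified_folds <- function(s, nf, seed) {
  fold <- integer(length(s))
  with_seed(seed, {
    for (cls in unique(s)) {
      members <- which(s == cls)
      fold[members[sample.int(length(members))]] <-
        rep_len(seq_len(nf), length(members))
    }
  })
  fold
}

effective_inner_folds <- function(s, inner_folds, warn = TRUE) {
  min_class <- min(table(s))
  if (min_class < 2)
    stopf("inner cross-validation needs at least 2 members per class")
  if (min_class < inner_folds) {
    if (warn)
      warnf("smallest class has %d members; inner folds reduced to %d",
            min_class, min_class)
    min_class
  } else inner_folds
}

# Fit scaler + selector + SVC on (X, s) for one (k, C) and return the
# fitted triple. Shared by the CV loops and final_fit.
fit_pipeline_once <- function(X, s, k, C) {
  sc <- robust_scale_fit(X)
  Xs <- robust_scale_apply(X, sc)
  f <- anova_f_scores(Xs, s)
  sel <- order(-f, seq_along(f))[seq_len(k)]
  fit <- .svc_l1_sqhinge(Xs[, sel, drop = FALSE], as.numeric(s), C,
                         2000L, 1e-10)
  list(scaler = sc, selected = sel, w = fit$w, b = fit$b)
}

pipeline_decision <- function(p, Xnew) {
  Xs <- robust_scale_apply(Xnew, p$scaler)
  drop(Xs[, p$selected, drop = FALSE] %*% p$w) + p$b
}

# Inner grid search: returns per-combo accuracy over nf stratified folds.
# Scaling and selection are refit inside every fold (no leakage). The
# ANOVA-F score is invariant to per-feature affine maps, so the selection
# ordering is computed on the raw training block and only the top-max(k)
# columns are robust-scaled; the fold's fits then share that ordering
# across k values.
inner_grid_accuracy <- function(X, s, grid, nf, seed) {
  fold <- stratified_folds(s, nf, seed)
  correct <- numeric(nrow(grid))
  max_k <- max(grid$k)
  for (f in seq_len(nf)) {
    tr <- fold != f
    if (length(unique(s[tr])) < 2) next
    fs <- anova_f_scores(X[tr, , drop = FALSE], s[tr])
    top <- order(-fs, seq_along(fs))[seq_len(max_k)]
    sc <- robust_scale_fit(X[tr, top, drop = FALSE])
    Xs_tr <- robust_scale_apply(X[tr, top, drop = FALSE], sc)
    Xs_va <- robust_scale_apply(X[!tr, top, drop = FALSE], sc)
    for (g in seq_len(nrow(grid))) {
      sel <- seq_len(grid$k[g])
      fit <- .svc_l1_sqhinge(Xs_tr[, sel, drop = FALSE],
                             as.numeric(s[tr]), grid$C[g], 300L, 1e-7)
      d <- drop(Xs_va[, sel, drop = FALSE] %*% fit$w) + fit$b
      correct[g] <- correct[g] + sum((d > 0) == (s[!tr] > 0))
    }
  }
  correct / length(s)
}

#' Nested cross-validation of the responder classifier
#'
#' Outer loop: leave-one-out over samples. For each left-out sample the
#' hyperparameters `(k, C)` are chosen by a stratified `inner_folds`-fold
#' grid search on the remaining samples (accuracy criterion; ties resolve
#' to the smaller `k`, then the smaller `C`), the pipeline
#' (scaler + selector + SVC) is refit on those samples, and the held-out
#' sample is predicted. Scaling and selection are always fit inside folds,
#' never on held-out data.
#'
#' @param X numeric matrix (samples x features) with sample ids as
#'   rownames.
#' @param y class labels.
#' @param grid data.frame of `k`, `C` candidates (default
#'   [default_grid()]); `k` values above `ncol(X)` are dropped.
#' @param inner_folds inner fold count (default 10); reduced with a
#'   warning when the smallest class is smaller.
#' @param seed seed for fold assignment.
#' @param n_boot bootstrap replicates for the accuracy CI.
#' @return Object of class `cv_report`: `outer_accuracy`,
#'   `inner_accuracy` (mean over outer folds of the selected combo's
#'   inner accuracy), `predictions` (per-fold predicted class, decision
#'   value and chosen hyperparameters), `bootstrap_ci`, `grid`, `seed`.
#' @export
nested_cv <- function(X, y, grid = default_grid(), inner_folds = 10L,
                      seed = 1L, n_boot = 2000L) {
  X <- as.matrix(X)
  s <- as_signed_labels(y)
  n <- nrow(X)
  if (n < 2) stopf("nested_cv needs at least 2 samples")
  if (length(unique(s)) < 2) stopf("both classes must be present")
  grid <- grid[grid$k <= ncol(X), , drop = FALSE]
  if (nrow(grid) == 0) stopf("empty hyperparameter grid after k <= ncol(X)")
  ids <- rownames(X) %||% sprintf("s%03d", seq_len(n))
  decision <- numeric(n)
  chosen_k <- integer(n); chosen_C <- numeric(n); inner_acc <- numeric(n)
  nf_warned <- FALSE
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    s_tr <- s[tr]
    nf <- effective_inner_folds(s_tr, inner_folds, warn = !nf_warned)
    if (nf < inner_folds) nf_warned <- TRUE
    if (nrow(grid) > 1) {
      acc <- inner_grid_accuracy(X[tr, , drop = FALSE], s_tr, grid, nf,
                                 hash31(seed, "inner", i))
      best <- which.max(acc)      # grid is k-then-C ordered: first max wins
      inner_acc[i] <- acc[best]
    } else {
      best <- 1L
      inner_acc[i] <- NA_real_
    }
    chosen_k[i] <- grid$k[best]; chosen_C[i] <- grid$C[best]
    p <- fit_pipeline_once(X[tr, , drop = FALSE], s_tr,
                           grid$k[best], grid$C[best])
    decision[i] <- pipeline_decision(p, X[i, , drop = FALSE])
  }
  correct <- (decision > 0) == (s > 0)
  structure(list(
    outer_accuracy = mean(correct),
    inner_accuracy = mean(inner_acc),
    predictions = data.frame(participant_id = ids,
                             true = signed_to_class(s),
                             predicted = signed_to_class(decision),
                             decision = decision,
                             k = chosen_k, C = chosen_C,
                             inner_accuracy = inner_acc,
                             stringsAsFactors = FALSE),
    bootstrap_ci = bootstrap_accuracy_ci(correct, seed = hash31(seed, "boot"),
                                         n_boot = n_boot),
    grid = grid, seed = seed), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("nested CV over %d samples: outer accuracy %.3f (95%% CI %.2f-%.2f)\n",
              nrow(x$predictions), x$outer_accuracy,
              x$bootstrap_ci[1], x$bootstrap_ci[2]))
  if (!is.na(x$inner_accuracy))
    cat(sprintf("  mean inner-CV accuracy of selected models: %.3f\n",
                x$inner_accuracy))
  if (!is.null(x$permutation_p))
    cat(sprintf("  label-permutation p = %.4f\n", x$permutation_p))
  invisible(x)
}

#' Label-permutation significance of the cross-validated accuracy
#'
#' Repeats the full nested cross-validation on `n_perm` label
#' permutations and reports `p = (1 + #{perm accuracy >= observed}) /
#' (1 + n_perm)` (add-one convention, so p is never 0).
#'
#' @inheritParams nested_cv
#' @param n_perm number of label permutations.
#' @param observed optionally, a precomputed `cv_report` for the
#'   unpermuted labels (to avoid refitting).
#' @return List of class `perm_test`: `p`, `observed_accuracy`,
#'   `perm_accuracies`, `n_perm`, `seed`.
#' @export
permutation_significance <- function(X, y, grid = default_grid(),
                                     n_perm = 100L, seed = 1L,
                                     inner_folds = 10L, observed = NULL) {
  if (!is_count(n_perm)) stopf("'n_perm' must be >= 1")
  s <- as_signed_labels(y)
  if (is.null(observed))
    observed <- nested_cv(X, y, grid = grid, inner_folds = inner_folds,
                          seed = seed, n_boot = 2L)
  obs_acc <- observed$outer_accuracy
  perm_acc <- vapply(seq_len(n_perm), function(b) {
    s_perm <- with_seed(hash31(seed, "perm", b), sample(s))
    suppressWarnings(
      nested_cv(X, s_perm > 0, grid = grid, inner_folds = inner_folds,
                seed = hash31(seed, "permcv", b),
                n_boot = 2L)$outer_accuracy)
  }, numeric(1))
  structure(list(p = (1 + sum(perm_acc >= obs_acc - 1e-12)) / (1 + n_perm),
                 observed_accuracy = obs_acc, perm_accuracies = perm_acc,
                 n_perm = n_perm, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test: accuracy %.3f, p = %.4f (%d permutations)\n",
              x$observed_accuracy, x$p, x$n_perm))
  invisible(x)
}

#' Percentile bootstrap CI for a cross-validated accuracy
#'
#' Resamples the per-fold correctness indicators with replacement and
#' returns the percentile interval of the resampled mean. Invariant to
#' fold order.
#'
#' @param correct logical (or 0/1) vector of per-fold outcomes.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return Numeric `c(lo, hi)`.
#' @export
bootstrap_accuracy_ci <- function(correct, n_boot = 2000L, seed = 1L,
                                  level = 0.95) {
  correct <- as.numeric(correct)
  if (length(correct) == 0) stopf("need at least one fold outcome")
  n <- length(correct)
  means <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(b) mean(correct[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  as.numeric(stats::quantile(sort(means), c((1 - level) / 2,
                                            1 - (1 - level) / 2),
                             type = 7, names = FALSE))
}

#' Fit the final pipeline on all samples
#'
#' A single stratified grid search on all data chooses `(k, C)` (same
#' tie-breaks as [nested_cv()]); the scaler, selector and SVC are then
#' refit on all samples. The grid-search accuracy and the all-sample
#' training accuracy are reported separately.
#'
#' @inheritParams nested_cv
#' @param backend_fingerprint optional fingerprint of the encoder that
#'   produced `X` (taken from `attr(X, "fingerprint")` when present);
#'   stored so downstream application can refuse mismatched feature
#'   spaces.
#' @return Object of class `fitted_pipeline`: scaling parameters
#'   (`medians`, `iqrs`), `selected` feature indices, hyperplane `w`,
#'   `b`, hyperparameters `k`, `C`, accuracies, grid, seed, and the
#'   positive-class convention (decision value > 0 predicts responder).
#' @export
final_fit <- function(X, y, grid = default_grid(), inner_folds = 10L,
                      seed = 1L, backend_fingerprint = NULL) {
  X <- as.matrix(X)
  s <- as_signed_labels(y)
  if (length(unique(s)) < 2) stopf("both classes must be present")
  grid <- grid[grid$k <= ncol(X), , drop = FALSE]
  nf <- effective_inner_folds(s, inner_folds)
  if (nrow(grid) > 1) {
    acc <- inner_grid_accuracy(X, s, grid, nf, hash31(seed, "final"))
    best <- which.max(acc)
    inner_cv_accuracy <- acc[best]
  } else {
    best <- 1L
    inner_cv_accuracy <- NA_real_
  }
  p <- fit_pipeline_once(X, s, grid$k[best], grid$C[best])
  d <- pipeline_decision(p, X)
  structure(list(medians = p$scaler$medians, iqrs = p$scaler$iqrs,
                 selected = p$selected, w = p$w, b = p$b,
                 k = grid$k[best], C = grid$C[best],
                 positive_class = POSITIVE_CLASS,
                 training_accuracy = mean((d > 0) == (s > 0)),
                 inner_cv_accuracy = inner_cv_accuracy,
                 grid = grid, seed = seed,
                 backend_fingerprint = backend_fingerprint %||%
                   attr(X, "fingerprint")),
            class = "fitted_pipeline")
}

#' @export
print.fitted_pipeline <- function(x, ...) {
  cat(sprintf("fitted_pipeline: k = %d, C = %g; training accuracy %.3f",
              x$k, x$C, x$training_accuracy))
  if (!is.na(x$inner_cv_accuracy))
    cat(sprintf(", grid-search accuracy %.3f", x$inner_cv_accuracy))
  cat(sprintf("\n  selected features: %s\n",
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Predict with a fitted pipeline
#'
#' @param object a [final_fit()] pipeline.
#' @param newdata numeric matrix in the original (full-dimension) feature
#'   space.
#' @param type `"class"` (responder/nonresponder) or `"decision"` (the
#'   raw decision value `w . x' + b`).
#' @param ... unused.
#' @export
predict.fitted_pipeline <- function(object, newdata,
                                    type = c("class", "decision"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$medians))
    stopf("newdata has %d features but the pipeline was fit on %d",
          ncol(newdata), length(object$medians))
  Xs <- robust_scale_apply(newdata, list(medians = object$medians,
                                         iqrs = object$iqrs))
  d <- drop(Xs[, object$selected, drop = FALSE] %*% object$w) + object$b
  if (type == "decision") d else signed_to_class(d)
}
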