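# Interpretation of the fitted model: signed distances of embedded
# concepts to the decision hyperplane, sentence clustering, cluster
# summaries, feature-covariate anchoring, and rater-agreement ICC.

#' Signed Euclidean distance to the decision boundary
#'
#' Applies the pipeline's stored scaling, restricts to the selected
#' features, and returns `(w . x' + b) / ||w||_2`. Positive distances lie
#' on the responder side, negative on the non-responder side; zero is on
#' the boundary. The distance is an affine functional of the input, so a
#' convex combination of vectors maps to the same combination of their
#' distances.
#'
#' @param pipeline a [final_fit()] pipeline.
#' @param vectors numeric vector (length D) or matrix (rows = vectors) in
#'   the full embedding space.
#' @return Numeric vector of signed distances.
#' @export
signed_distance <- function(pipeline, vectors) {
  stopifnot(inherits(pipeline, "fitted_pipeline"))
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1)
  if (ncol(vectors) != length(pipeline$medians))
    stopf("vectors have %d dimensions but the pipeline was fit on %d",
          ncol(vectors), length(pipeline$medians))
  wn <- sqrt(sum(pipeline$w^2))
  if (wn == 0) stopf("degenerate pipeline: all-zero weight vector")
  predict(pipeline, vectors, type = "decision") / wn
}

#' Project concept strings onto the decision boundary
#'
#' Each concept string is tokenized and encoded by the backend, pooled
#' with the same mode as the fitted model's features, and projected to
#' its signed boundary distance. Concepts are returned ranked from the
#' most responder-like (largest positive distance) to the most
#' non-responder-like.
#'
#' @param pipeline a [final_fit()] pipeline.
#' @param backend encoder backend (must match the training embedding
#'   space; the fingerprint is checked when both sides carry one).
#' @param concepts character vector of words/phrases (e.g. read from a
#'   one-concept-per-line file).
#' @param pooling pooling mode; keep the mode used for the training
#'   features.
#' @return data.frame of class `concept_probes`: `label`,
#'   `signed_distance`, `side`, sorted by decreasing distance. Concepts
#'   that tokenize to zero tokens are skipped with a warning.
#' @export
probe_concepts <- function(pipeline, backend, concepts,
                           pooling = c("mean", "max")) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(pipeline, "fitted_pipeline"))
  if (length(concepts) == 0) stopf("'concepts' must be non-empty")
  if (!is.null(pipeline$backend_fingerprint) &&
      !is.null(backend$fingerprint) &&
      pipeline$backend_fingerprint != backend$fingerprint)
    stopf("encoder fingerprint does not match the pipeline's training backend")
  toks <- lapply(concepts, backend$tokenize %||% tokenize_words)
  empty <- lengths(toks) == 0
  if (any(empty)) {
    warnf("skipping %d concept(s) that tokenize to zero tokens: %s",
          sum(empty), paste(concepts[empty], collapse = ", "))
    concepts <- concepts[!empty]
    toks <- toks[!empty]
  }
  if (length(concepts) == 0) stopf("no embeddable concepts left")
  V <- t(vapply(toks, function(tk)
    embed_document(backend, tk, pooling)$vector,
    numeric(backend$dimension)))
  d <- signed_distance(pipeline, V)
  out <- data.frame(label = concepts, signed_distance = d,
                    side = ifelse(d > 0, "responder", "nonresponder"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$signed_distance), ]
  rownames(out) <- NULL
  class(out) <- c("concept_probes", "data.frame")
  out
}

#' Cluster sentence embeddings by density
#'
#' Clusters sentence vectors in the full embedding space (Euclidean
#' metric) with the hierarchical density-based algorithm of
#' [hdbscan_fit()]. Sentences that cannot be assigned to any stable
#' cluster are labelled `-1` (noise) and are discarded from downstream
#' summaries, restricting the interpreted semantics to recurrent
#' concepts.
#'
#' @param sentence_vectors numeric matrix (sentences x D).
#' @param min_cluster_size smallest allowed cluster (default 5).
#' @return Integer cluster labels (`1..K`, `-1` = noise).
#' @export
cluster_sentences <- function(sentence_vectors, min_cluster_size = 5L) {
  hdbscan_fit(sentence_vectors, min_cluster_size = min_cluster_size)$labels
}

#' Summarize sentence clusters against the decision boundary
#'
#' Each cluster is represented by its centroid (arithmetic mean of the
#' member sentence vectors) and the centroid's signed distance to the
#' boundary. Because the distance is affine, the centroid distance equals
#' the mean of the member distances. Cluster descriptions are left empty
#' unless a labelling hook is supplied; the default hook concatenates the
#' three sentences closest to the centroid.
#'
#' @param sentence_vectors numeric matrix (sentences x D) with sentence
#'   ids as rownames.
#' @param labels integer labels from [cluster_sentences()].
#' @param pipeline a [final_fit()] pipeline.
#' @param sentences optional data.frame from [extract_sentences()] (used
#'   by the description hook).
#' @param describe optional hook `function(texts) -> character(1)`; use
#'   `NULL` for no descriptions.
#' @return data.frame of class `sentence_clusters`: `cluster_id`, `size`,
#'   `signed_distance`, `description`, plus a `members` list-column of
#'   sentence ids; sorted by decreasing distance.
#' @export
cluster_summary <- function(sentence_vectors, labels, pipeline,
                            sentences = NULL,
                            describe = default_cluster_description) {
  stopifnot(nrow(sentence_vectors) == length(labels))
  ids <- rownames(sentence_vectors) %||%
    sprintf("s%04d", seq_len(nrow(sentence_vectors)))
  keep <- labels != -1L
  cl_ids <- sort(unique(labels[keep]))
  rows <- lapply(cl_ids, function(cl) {
    members <- which(labels == cl)
    centroid <- colMeans(sentence_vectors[members, , drop = FALSE])
    desc <- ""
    if (!is.null(describe) && !is.null(sentences)) {
      texts <- sentences$text[match(ids[members], sentences$sentence_id)]
      V <- sentence_vectors[members, , drop = FALSE]
      d2 <- colSums((t(V) - centroid)^2)
      desc <- describe(texts[order(d2)])
    }
    list(cluster_id = cl, size = length(members),
         signed_distance = as.numeric(signed_distance(pipeline, centroid)),
         description = desc, members = ids[members],
         centroid = centroid)
  })
  out <- data.frame(
    cluster_id = vapply(rows, `[[`, 1L, "cluster_id"),
    size = vapply(rows, `[[`, 1L, "size"),
    signed_distance = vapply(rows, `[[`, 1, "signed_distance"),
    description = vapply(rows, `[[`, "", "description"),
    stringsAsFactors = FALSE)
  out$members <- lapply(rows, `[[`, "members")
  out$centroid <- lapply(rows, `[[`, "centroid")
  out <- out[order(-out$signed_distance), ]
  rownames(out) <- NULL
  class(out) <- c("sentence_clusters", "data.frame")
  out
}

#' Default cluster description hook
#'
#' Concatenates the three most central sentences. A generative-model
#' labeller can be plugged in through the same interface
#' (`function(texts) -> character(1)`, texts ordered by centrality).
#'
#' @param texts member sentences, most central first.
#' @export
default_cluster_description <- function(texts) {
  paste(utils::head(texts[!is.na(texts)], 3), collapse = " | ")
}

#' Correlate selected model features with covariates
#'
#' Pearson correlation (two-sided test) between each selected-feature
#' column and each covariate, over pairwise-complete observations.
#' Significance stars are reported at 0.05 / 0.01 / 0.001 with no
#' multiple-testing correction; these correlations are exploratory
#' anchors, never used for selection.
#'
#' @param features numeric matrix (participants x selected features) with
#'   participant ids as rownames.
#' @param covariates data.frame of named scalar covariates, one row per
#'   participant (matched by rownames or a `participant_id` column).
#' @param min_pairs minimum complete pairs required (default 3).
#' @return data.frame: `feature`, `covariate`, `n`, `r`, `p`, `stars`.
#'   Constant columns give `NA` correlations.
#' @export
correlate_features <- function(features, covariates, min_pairs = 3L) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("feature%d", seq_len(ncol(features)))
  if ("participant_id" %in% names(covariates)) {
    ord <- match(rownames(features), covariates$participant_id)
    covariates <- covariates[ord, setdiff(names(covariates),
                                          "participant_id"), drop = FALSE]
  }
  stopifnot(nrow(covariates) == nrow(features))
  res <- expand.grid(feature = colnames(features),
                     covariate = names(covariates),
                     stringsAsFactors = FALSE)
  stats_ <- lapply(seq_len(nrow(res)), function(i) {
    x <- features[, res$feature[i]]
    yv <- covariates[[res$covariate[i]]]
    ok <- is.finite(x) & is.finite(yv)
    if (sum(ok) < min_pairs || stats::sd(x[ok]) == 0 ||
        stats::sd(yv[ok]) == 0)
      return(c(n = sum(ok), r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(x[ok], yv[ok], method = "pearson")
    c(n = sum(ok), r = unname(ct$estimate), p = ct$p.value)
  })
  res$n <- vapply(stats_, `[[`, 1, "n")
  res$r <- vapply(stats_, `[[`, 1, "r")
  res$p <- vapply(stats_, `[[`, 1, "p")
  res$stars <- ifelse(is.na(res$p), "",
                      ifelse(res$p < 0.001, "***",
                             ifelse(res$p < 0.01, "**",
                                    ifelse(res$p < 0.05, "*", ""))))
  res
}

#' Intraclass correlation ICC(2,k)
#'
#' Two-way random-effects, absolute-agreement, average-measures
#' intraclass correlation from the standard mean squares:
#' `(MS_items - MS_error) / (MS_items + (MS_raters - MS_error) / n)`.
#' Used for inter-rater agreement of cluster-description fit scores.
#'
#' @param ratings numeric matrix, items (rows) x raters (columns), no
#'   missing cells.
#' @return The ICC(2,k) scalar; `NA` for a degenerate (all-constant)
#'   matrix.
#' @export
icc_2k <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stopf("need at least 2 items and 2 raters")
  if (anyNA(ratings)) stopf("missing cells are not supported")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((ratings - outer(row_m, rep(1, k)) -
                   outer(rep(1, n), col_m) + grand)^2)
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  denom <- ms_rows + (ms_cols - ms_err) / n
  if (ms_rows == 0 && ms_err == 0 && ms_cols == 0) return(NA_real_)
  if (denom == 0) return(NA_real_)
  (ms_rows - ms_err) / denom
}
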