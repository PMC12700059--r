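# Format readers/writers and end-to-end orchestration.

#' Write pain diaries to a ratings CSV
#'
#' Columns: `participant_id`, `phase`, `index`, `rating`.
#'
#' @param diaries list of [pain_diary()] objects.
#' @param path output file.
#' @export
write_ratings <- function(diaries, path) {
  rows <- do.call(rbind, lapply(diaries, function(d)
    cbind(participant_id = d$participant_id, d$ratings)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read pain diaries from a ratings CSV
#'
#' Validates phase labels and the 0-10 rating range; errors name the
#' offending line of the file.
#'
#' @param path CSV with header `participant_id,phase,index,rating`.
#' @return List of [pain_diary()] objects (one per participant, in file
#'   order).
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stopf("ratings file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "phase", "index", "rating")
  if (!all(need %in% names(df)))
    stopf("ratings CSV must have columns %s", paste(need, collapse = ","))
  if (nrow(df) == 0) return(list())
  line <- seq_len(nrow(df)) + 1L   # header is line 1
  bad_phase <- !grepl("^(baseline|treatment[0-9]+|washout)$", df$phase)
  if (any(bad_phase))
    stopf("line %d: unknown phase label '%s'", line[bad_phase][1],
          df$phase[bad_phase][1])
  bad_rating <- !is.finite(df$rating) | df$rating < 0 | df$rating > 10
  if (any(bad_rating))
    stopf("line %d: rating %s outside [0,10]", line[bad_rating][1],
          format(df$rating[bad_rating][1]))
  df$rating <- as.numeric(df$rating)
  ids <- unique(df$participant_id)
  out <- lapply(ids, function(id) {
    d <- df[df$participant_id == id, c("phase", "index", "rating")]
    rownames(d) <- NULL
    pain_diary(id, d)
  })
  names(out) <- ids
  out
}

#' Write transcripts as JSONL
#'
#' One segment per line: `participant_id`, `topic_id`, `order`, `text`.
#' The topic inventory is written as a first header line of type
#' `"inventory"`.
#'
#' @param transcripts list of [transcript()] objects.
#' @param path output file.
#' @export
write_transcripts <- function(transcripts, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(type = "inventory",
                                   topics = transcripts[[1]]$topics),
                              auto_unbox = TRUE), con)
  for (tr in transcripts) {
    for (i in seq_len(nrow(tr$segments))) {
      writeLines(jsonlite::toJSON(
        list(participant_id = tr$participant_id,
             topic_id = tr$segments$topic_id[i],
             order = tr$segments$order[i],
             text = tr$segments$text[i]), auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Read transcripts from JSONL
#'
#' @param path JSONL file as written by [write_transcripts()] (a leading
#'   inventory line is optional). Malformed lines or missing fields are
#'   reported with their line number.
#' @return List of [transcript()] objects.
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) stopf("transcripts file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  topics <- NULL
  recs <- list()
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stopf("line %d: malformed JSON (%s)",
                                              i, conditionMessage(e)))
    if (identical(obj$type, "inventory")) {
      topics <- obj$topics
      next
    }
    for (f in c("participant_id", "topic_id", "order", "text"))
      if (is.null(obj[[f]]))
        stopf("line %d: segment missing field '%s'", i, f)
    recs[[length(recs) + 1]] <- obj
  }
  if (length(recs) == 0) return(list())
  df <- data.frame(
    participant_id = vapply(recs, `[[`, "", "participant_id"),
    topic_id = vapply(recs, `[[`, "", "topic_id"),
    order = vapply(recs, function(r) as.integer(r$order), 1L),
    text = vapply(recs, `[[`, "", "text"),
    stringsAsFactors = FALSE)
  lapply(unique(df$participant_id), function(id) {
    segs <- df[df$participant_id == id, c("topic_id", "order", "text")]
    segs <- segs[order(segs$order), ]
    rownames(segs) <- NULL
    transcript(id, segs, topics = topics)
  })
}

#' Write an analysis report as JSON
#'
#' Numeric values are serialized at full precision so reports round-trip
#' losslessly; a schema version is embedded.
#'
#' @param report a list (e.g. a `cv_report` stripped to plain values).
#' @param path output file.
#' @export
write_report <- function(report, path) {
  payload <- c(list(schema = "placebotalk-report/1"), unclass(report))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       force = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run configuration for the end-to-end pipeline
#'
#' Validates the stage parameters up front; unknown keys are rejected so
#' misspelled options fail loudly rather than silently using defaults.
#'
#' @param config a named list or the path of a YAML file.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    seed = 1L, out_dir = NULL,
    ratings_csv = NULL, transcripts_jsonl = NULL, concepts_txt = NULL,
    simulate = TRUE, synthetic = list(),
    alpha = 0.05, n_perm_outcome = 2000L,
    encoder_dim = 768L, lambda = 0,
    structuring = "sequential", pooling = "mean",
    grid = NULL, inner_folds = 10L,
    n_perm_classifier = 0L, min_cluster_size = 5L,
    max_cluster_sentences = 2000L,
    validate_cohort = FALSE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$out_dir)) stopf("'out_dir' is required")
  if (!cfg$structuring %in% c("sequential", "topic_grouped"))
    stopf("'structuring' must be sequential or topic_grouped")
  if (!cfg$pooling %in% c("mean", "max"))
    stopf("'pooling' must be mean or max")
  if (!cfg$simulate) {
    for (f in c("ratings_csv", "transcripts_jsonl")) {
      if (is.null(cfg[[f]])) stopf("'%s' is required when simulate = FALSE", f)
      if (!file.exists(cfg[[f]])) stopf("input path not found: %s", cfg[[f]])
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (optional) -> label outcomes -> prep -> embed -> fit
#' -> interpret -> validate (optional). Every artifact is written under
#' `out_dir` and stamped with the configuration hash; the run log records
#' the per-stage seeds and wall times. Any stage error aborts with a
#' stage-named message; artifacts of completed stages are retained.
#'
#' @param config a [run_config()] (or a list/YAML path coerced to one).
#' @return Invisibly, a list with the main results and artifact paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash the scientific configuration, not the filesystem locations
  hash_fields <- setdiff(names(cfg), c("out_dir", "ratings_csv",
                                       "transcripts_jsonl", "concepts_txt"))
  cfg_hash <- hash31(paste(deparse(unclass(cfg)[hash_fields]),
                           collapse = ""))
  log_path <- file.path(cfg$out_dir, "run.log")
  cat(sprintf("placebotalk run %s; config hash %d\n",
              format(Sys.time(), "%Y-%m-%d %H:%M:%S"), cfg_hash),
      file = log_path)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    cat(sprintf("stage %-14s %.2fs\n", name,
                proc.time()[["elapsed"]] - t0),
        file = log_path, append = TRUE)
    res
  }

  sim <- stage("simulate", {
    if (cfg$simulate) {
      scfg <- do.call(synthetic_config,
                      c(list(seed = cfg$seed), cfg$synthetic))
      cohort <- generate_cohort(scfg)
      write_ratings(cohort$diaries,
                    file.path(cfg$out_dir, "ratings.csv"))
      write_transcripts(cohort$transcripts,
                        file.path(cfg$out_dir, "transcripts.jsonl"))
      utils::write.csv(cohort$truth,
                       file.path(cfg$out_dir, "ground_truth.csv"),
                       row.names = FALSE)
      cohort
    } else {
      list(diaries = read_ratings(cfg$ratings_csv),
           transcripts = read_transcripts(cfg$transcripts_jsonl),
           config = NULL)
    }
  })

  outcomes <- stage("label-outcomes", {
    out <- label_cohort(sim$diaries, alpha = cfg$alpha,
                        n_perm = cfg$n_perm_outcome,
                        seed = hash31(cfg$seed, "outcomes"))
    utils::write.csv(out, file.path(cfg$out_dir, "outcomes.csv"),
                     row.names = FALSE)
    out
  })

  backend <- stage("prep", {
    if (!is.null(sim$config)) toy_encoder_for(sim$config,
                                              dim = cfg$encoder_dim,
                                              lambda = cfg$lambda)
    else toy_encoder(dim = cfg$encoder_dim, lambda = cfg$lambda,
                     seed = hash31(cfg$seed, "encoder"))
  })

  X <- stage("embed", {
    X <- embed_transcripts(backend, sim$transcripts,
                           mode = cfg$structuring, pooling = cfg$pooling)
    utils::write.csv(data.frame(participant_id = rownames(X), X,
                                check.names = FALSE),
                     file.path(cfg$out_dir, "embeddings.csv"),
                     row.names = FALSE)
    X
  })

  y <- outcomes$responder[match(rownames(X), outcomes$participant_id)]
  fit <- stage("fit", {
    grid <- cfg$grid %||% default_grid()
    cv <- nested_cv(X, y, grid = grid, inner_folds = cfg$inner_folds,
                    seed = hash31(cfg$seed, "cv"))
    if (cfg$n_perm_classifier > 0)
      cv$permutation_p <- permutation_significance(
        X, y, grid = grid, n_perm = cfg$n_perm_classifier,
        seed = hash31(cfg$seed, "permsig"), inner_folds = cfg$inner_folds,
        observed = cv)$p
    pipe <- final_fit(X, y, grid = grid, inner_folds = cfg$inner_folds,
                      seed = hash31(cfg$seed, "final"))
    write_report(list(config_hash = cfg_hash, seed = cfg$seed,
                      outer_accuracy = cv$outer_accuracy,
                      inner_accuracy = cv$inner_accuracy,
                      permutation_p = cv$permutation_p,
                      bootstrap_ci = cv$bootstrap_ci,
                      k = pipe$k, C = pipe$C,
                      selected = pipe$selected,
                      training_accuracy = pipe$training_accuracy),
                 file.path(cfg$out_dir, "fit_report.json"))
    list(cv = cv, pipeline = pipe)
  })

  interpret <- stage("interpret", {
    concepts <- if (!is.null(cfg$concepts_txt))
      readLines(cfg$concepts_txt, warn = FALSE)
    else if (!is.null(sim$config)) concept_tokens(sim$config)$token
    probes <- if (length(concepts))
      probe_concepts(fit$pipeline, backend, concepts,
                     pooling = cfg$pooling) else NULL
    sentences <- do.call(rbind.data.frame, lapply(sim$transcripts,
      function(tr) extract_sentences(
        structure_documents(tr, mode = "sequential",
                            tokenizer = backend$tokenize))))
    clusters <- NULL
    if (nrow(sentences) > cfg$max_cluster_sentences) {
      keep <- with_seed(hash31(cfg$seed, "sentencesub"),
                        sort(sample.int(nrow(sentences),
                                        cfg$max_cluster_sentences)))
      sentences <- sentences[keep, , drop = FALSE]
    }
    if (nrow(sentences) >= cfg$min_cluster_size) {
      SV <- embed_sentences(backend, sentences, pooling = cfg$pooling)
      labels <- cluster_sentences(SV,
                                  min_cluster_size = cfg$min_cluster_size)
      clusters <- cluster_summary(SV, labels, fit$pipeline,
                                  sentences = sentences)
      write_report(list(config_hash = cfg_hash,
                        n_clusters = nrow(clusters),
                        clusters = clusters[, c("cluster_id", "size",
                                                "signed_distance",
                                                "description")]),
                   file.path(cfg$out_dir, "clusters.json"))
    }
    if (!is.null(probes))
      utils::write.csv(probes[, c("label", "signed_distance", "side")],
                       file.path(cfg$out_dir, "concept_probes.csv"),
                       row.names = FALSE)
    list(probes = probes, clusters = clusters)
  })

  validation <- if (isTRUE(cfg$validate_cohort)) stage("validate", {
    scfg2 <- do.call(synthetic_config,
                     c(list(seed = hash31(cfg$seed, "study2")),
                       utils::modifyList(cfg$synthetic %||% list(),
                                         list(n_participants = 20L))))
    cohort2 <- generate_cohort(scfg2)
    # the validation cohort must be embedded with the training backend
    X2 <- embed_transcripts(backend, cohort2$transcripts,
                            mode = cfg$structuring, pooling = cfg$pooling)
    attr(X2, "fingerprint") <- backend$fingerprint
    out2 <- label_cohort(cohort2$diaries, alpha = cfg$alpha,
                         n_perm = cfg$n_perm_outcome,
                         seed = hash31(cfg$seed, "outcomes2"))
    rep <- apply_model(fit$pipeline, X2,
                       out2$responder[match(rownames(X2),
                                            out2$participant_id)],
                       seed = hash31(cfg$seed, "validate"),
                       analgesia = out2$analgesia_pct[
                         match(rownames(X2), out2$participant_id)])
    write_report(list(config_hash = cfg_hash, accuracy = rep$accuracy,
                      permutation_p = rep$permutation_p,
                      confusion = as.data.frame(rep$confusion)),
                 file.path(cfg$out_dir, "validation.json"))
    rep
  }) else NULL

  invisible(list(config = cfg, config_hash = cfg_hash,
                 outcomes = outcomes, embeddings = X,
                 cv = fit$cv, pipeline = fit$pipeline,
                 probes = interpret$probes, clusters = interpret$clusters,
                 validation = validation,
                 out_dir = cfg$out_dir))
}
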