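# Masked-language-model fine-tuning control loop: schedule contract,
# three-way validation losses with fixed masks, and checkpoint selection.
# The trainable backend shipped here is a deliberately small lookup-table
# model (tied token-embedding matrix + output bias, softmax over the
# vocabulary given the mean context vector); real transformer backends can
# plug into the same contract.

#' Fine-tuning schedule
#'
#' @param eval_interval evaluate validation losses every this many steps
#'   (default 50).
#' @param mask_rate proportion of tokens masked per evaluation (default
#'   0.15, the usual masked-language-modelling convention).
#' @param frozen_layers number of parameter groups the backend must keep
#'   fixed during training.
#' @param max_steps total training steps.
#' @param seed seed for mask draws and batch order.
#' @return Object of class `finetune_schedule`.
#' @export
finetune_schedule <- function(eval_interval = 50L, mask_rate = 0.15,
                              frozen_layers = 0L, max_steps = 200L,
                              seed = 1L) {
  stopifnot(is_count(eval_interval), is_prob(mask_rate), mask_rate > 0,
            is_count(max_steps, min = 0), is_count(frozen_layers, min = 0))
  structure(list(eval_interval = as.integer(eval_interval),
                 mask_rate = mask_rate,
                 frozen_layers = as.integer(frozen_layers),
                 max_steps = as.integer(max_steps),
                 seed = as.integer(seed), loss_log = NULL),
            class = "finetune_schedule")
}

#' Toy trainable masked-language-model backend
#'
#' Predicts a masked token from the mean embedding of its context window
#' (+/- `context` tokens) through a softmax over the vocabulary, with tied
#' input/output embeddings plus an output bias. Two parameter groups
#' ("layers"): the embedding matrix and the bias; `frozen_layers = 1`
#' freezes the embedding matrix.
#'
#' @param vocab character vector of vocabulary tokens.
#' @param dim embedding dimension of the toy model.
#' @param seed parameter-initialization seed.
#' @param lr learning-rate of the plain gradient-descent training step.
#' @param context one-sided context width in tokens.
#' @return A list with `params`, `n_layers`, `loss(corpus, masks)`,
#'   `train_step(corpus, frozen_layers)`, `get_checkpoint()`,
#'   `set_checkpoint(ckpt)`.
#' @export
toy_mlm_backend <- function(vocab, dim = 16L, seed = 1L, lr = 0.5,
                            context = 2L) {
  stopifnot(length(vocab) >= 2, is_count(dim))
  vocab <- unique(vocab)
  V <- length(vocab)
  state <- new.env(parent = emptyenv())
  state$E <- with_seed(hash31(seed, "mlm-init"),
                       matrix(stats::rnorm(V * dim, sd = 0.5), V, dim))
  state$bias <- numeric(V)
  state$step <- 0L
  tok_id <- function(toks) {
    id <- match(toks, vocab)
    if (anyNA(id)) stopf("token(s) outside the backend vocabulary: %s",
                         paste(unique(toks[is.na(id)]), collapse = ", "))
    id
  }
  context_vec <- function(ids, pos) {
    span <- setdiff(seq(max(1, pos - context), min(length(ids), pos + context)),
                    pos)
    if (length(span) == 0) return(numeric(ncol(state$E)))
    colMeans(state$E[ids[span], , drop = FALSE])
  }
  forward <- function(ids, pos) {
    ctx <- context_vec(ids, pos)
    logits <- drop(state$E %*% ctx) + state$bias
    logits <- logits - max(logits)
    p <- exp(logits)
    p / sum(p)
  }
  loss_one <- function(ids, pos) -log(forward(ids, pos)[ids[pos]])
  list(
    vocab = vocab,
    n_layers = 2L,
    loss = function(corpus, masks) {
      # corpus: list of token vectors; masks: list of masked positions
      tot <- 0; m <- 0
      for (i in seq_along(corpus)) {
        ids <- tok_id(corpus[[i]])
        for (pos in masks[[i]]) { tot <- tot + loss_one(ids, pos); m <- m + 1 }
      }
      if (m == 0) stopf("empty mask set")
      tot / m
    },
    train_step = function(corpus, frozen_layers = 0L, rng_seed = NULL) {
      state$step <- state$step + 1L
      seq_i <- 1 + (state$step - 1L) %% length(corpus)
      ids <- tok_id(corpus[[seq_i]])
      pos <- if (is.null(rng_seed)) 1 + (state$step %% length(ids)) else
        with_seed(rng_seed, sample.int(length(ids), 1))
      p <- forward(ids, pos)
      err <- p
      err[ids[pos]] <- err[ids[pos]] - 1   # dL/dlogits for cross-entropy
      if (frozen_layers < 2) state$bias <- state$bias - lr * err
      if (frozen_layers < 1) {
        ctx <- context_vec(ids, pos)
        state$E <- state$E - lr * (err %o% ctx)
      }
      invisible(state$step)
    },
    get_checkpoint = function() list(E = state$E, bias = state$bias,
                                     step = state$step),
    set_checkpoint = function(ckpt) {
      state$E <- ckpt$E; state$bias <- ckpt$bias; state$step <- ckpt$step
      invisible(NULL)
    })
}

draw_masks <- function(corpus, mask_rate, seed) {
  with_seed(seed, lapply(corpus, function(toks) {
    n <- length(toks)
    k <- max(1L, round(mask_rate * n))
    sort(sample.int(n, min(k, n)))
  }))
}

#' Controlled masked-language-model fine-tuning
#'
#' Runs `max_steps` training steps on `train_corpus` and, every
#' `eval_interval` steps (and at step 0), records the mean masked-token
#' prediction loss on three named validation corpora (by convention:
#' in-domain posts, clinical-interview proxy, and general text), each with
#' a fixed seeded mask set. Returns the checkpoint minimizing the mean of
#' the three losses after normalizing each by its step-0 value (a
#' scale-free total order; ties go to the earliest step), together with
#' the schedule carrying the full loss log.
#'
#' @param backend a trainable backend (see [toy_mlm_backend()]).
#' @param train_corpus list of token vectors.
#' @param schedule a [finetune_schedule()].
#' @param val_sets named list of three validation corpora (lists of token
#'   vectors); all must be non-empty.
#' @return List with `checkpoint`, `best_step`, and `schedule` (its
#'   `loss_log` holds one row per evaluation point).
#' @export
mlm_finetune <- function(backend, train_corpus, schedule, val_sets) {
  stopifnot(inherits(schedule, "finetune_schedule"),
            is.list(val_sets), length(val_sets) == 3)
  if (is.null(names(val_sets)) || any(!nzchar(names(val_sets))))
    names(val_sets) <- c("domain", "clinical", "general")
  for (nm in names(val_sets))
    if (length(val_sets[[nm]]) == 0)
      stopf("validation set '%s' is empty", nm)
  masks <- lapply(seq_along(val_sets), function(i)
    draw_masks(val_sets[[i]], schedule$mask_rate,
               hash31(schedule$seed, "mask", names(val_sets)[i])))
  eval_losses <- function() vapply(seq_along(val_sets), function(i)
    backend$loss(val_sets[[i]], masks[[i]]), numeric(1))
  log_steps <- seq(0L, schedule$max_steps, by = schedule$eval_interval)
  loss_log <- matrix(NA_real_, nrow = length(log_steps),
                     ncol = length(val_sets),
                     dimnames = list(NULL, names(val_sets)))
  checkpoints <- vector("list", length(log_steps))
  loss_log[1, ] <- eval_losses()
  checkpoints[[1]] <- backend$get_checkpoint()
  row <- 1L
  if (schedule$max_steps > 0) {
    for (step in seq_len(schedule$max_steps)) {
      backend$train_step(train_corpus, schedule$frozen_layers,
                         rng_seed = hash31(schedule$seed, "step", step))
      if (step %% schedule$eval_interval == 0) {
        row <- row + 1L
        loss_log[row, ] <- eval_losses()
        checkpoints[[row]] <- backend$get_checkpoint()
      }
    }
  }
  norm <- sweep(loss_log, 2, loss_log[1, ], "/")
  score <- rowMeans(norm)
  best <- which.min(score)           # which.min takes the earliest tie
  schedule$loss_log <- data.frame(step = log_steps, loss_log,
                                  check.names = FALSE)
  list(checkpoint = checkpoints[[best]], best_step = log_steps[best],
       schedule = schedule)
}
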