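# Document embeddings: encoder-backend contract, mean/max token pooling,
# the two-overlapping-window scheme for over-long documents, and a
# deterministic toy encoder with a planted class signal.

#' Pool per-token vectors into one vector
#'
#' Elementwise mean or elementwise maximum across tokens. Both modes are
#' invariant to token order; mean pooling reflects the average semantic
#' content, max pooling the most salient value per dimension.
#'
#' @param token_vectors numeric matrix, one row per token.
#' @param mode `"mean"` or `"max"`.
#' @return Numeric vector of length `ncol(token_vectors)`.
#' @export
pool_vectors <- function(token_vectors, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  if (is.null(dim(token_vectors)))
    token_vectors <- matrix(token_vectors, nrow = 1)
  if (nrow(token_vectors) == 0) stopf("cannot pool zero token vectors")
  if (mode == "mean") colMeans(token_vectors)
  else do.call(pmax, lapply(seq_len(nrow(token_vectors)),
                            function(i) token_vectors[i, ]))
}

#' Split an over-long token sequence into encoder windows
#'
#' Documents within the window limit `W` pass through unchanged. Documents
#' up to twice the limit are split into two overlapping windows: the first
#' `W` tokens and the last `W` tokens (overlap `2W - len >= 0`), which
#' together cover the full document. Longer documents (beyond the regime
#' of the two-window scheme) fall back to consecutive windows with 50%
#' overlap and are flagged with a message.
#'
#' @param tokens token vector.
#' @param W window size in tokens.
#' @return List of token windows.
#' @export
window_split <- function(tokens, W) {
  if (!is_count(W)) stopf("window size W must be a count >= 1")
  len <- length(tokens)
  if (len <= W) return(list(tokens))
  if (len <= 2 * W)
    return(list(tokens[seq_len(W)], tokens[seq(len - W + 1, len)]))
  message(sprintf(
    "document of %d tokens exceeds twice the window (%d); using %d%%-overlap windows",
    len, W, 50))
  step <- max(1L, floor(W / 2))
  starts <- unique(c(seq(1L, len - W, by = step), len - W + 1L))
  lapply(starts, function(s) tokens[seq(s, s + W - 1)])
}

#' Embed one document with an encoder backend
#'
#' Tokens are encoded to per-token vectors and pooled to a document
#' vector. Over-long documents are windowed with [window_split()]; window
#' vectors are then pooled with the same mode, matching the token pooling
#' strategy. For max pooling the windowed path is exactly the pooled full
#' token list; for mean pooling, tokens shared by two windows are
#' up-weighted (two-stage mean).
#'
#' @param backend an encoder backend (see [toy_encoder()]): a list with
#'   `dimension`, `max_window`, `tokenize(text)` and `encode(tokens)`.
#' @param doc token vector, or a single string (tokenized by the backend).
#' @param pooling `"mean"` or `"max"`.
#' @param doc_id optional identifier stored on the result.
#' @return Object of class `document_embedding`: `doc_id`, `vector`,
#'   `pooling`, `windowed`, `n_tokens`.
#' @export
embed_document <- function(backend, doc, pooling = c("mean", "max"),
                           doc_id = NULL) {
  pooling <- match.arg(pooling)
  stopifnot(is.list(backend), is.function(backend$encode))
  if (is.character(doc) && length(doc) == 1 && !is.null(backend$tokenize))
    doc <- backend$tokenize(doc)
  if (length(doc) == 0) stopf("cannot embed an empty document")
  W <- backend$max_window
  windows <- window_split(doc, W)
  wvecs <- t(vapply(windows,
                    function(w) pool_vectors(backend$encode(w), pooling),
                    numeric(backend$dimension)))
  structure(list(doc_id = doc_id, vector = pool_vectors(wvecs, pooling),
                 pooling = pooling, windowed = length(doc) > W,
                 n_tokens = length(doc)),
            class = "document_embedding")
}

#' Deterministic toy encoder with a planted class signal
#'
#' A desk-scale encoder conforming to the backend contract: every token
#' maps to a reproducible pseudo-random D-vector (seeded per token, so the
#' mapping is total over any vocabulary), and designated concept tokens
#' additionally load `loading` units on their signal dimension. With
#' `lambda > 0` each output vector is mixed with the mean of its +/- 2
#' neighbours, giving a context-sensitive variant; with `lambda = 0` the
#' encoder is purely lexical (frequency-sensitive under mean pooling).
#'
#' @param dim embedding dimension (default 768).
#' @param max_window maximum tokens per encoded sequence (default 4096).
#' @param seed encoder seed (part of the fingerprint).
#' @param concepts data.frame with columns `token`, `dim`, `loading` and
#'   optionally `base` (for instance from [concept_tokens()]); may be
#'   `NULL`. When `base` is given, the token's pseudo-random base vector
#'   is seeded from that name instead of the token itself, letting
#'   antonym-like cue pairs share a base and differ only in loading.
#' @param lambda context-mixing weight in `[0, 1)`.
#' @return An encoder backend: list with `dimension`, `max_window`,
#'   `tokenize`, `encode`, `fingerprint`.
#' @export
toy_encoder <- function(dim = 768L, max_window = 4096L, seed = 1L,
                        concepts = NULL, lambda = 0) {
  stopifnot(is_count(dim), is_count(max_window), is_prob(lambda), lambda < 1)
  if (!is.null(concepts))
    stopifnot(all(c("token", "dim", "loading") %in% names(concepts)),
              all(concepts$dim >= 1), all(concepts$dim <= dim))
  cache <- new.env(parent = emptyenv())
  loading_of <- if (is.null(concepts)) function(tok) NULL else {
    idx <- split(seq_len(nrow(concepts)), concepts$token)
    function(tok) idx[[tok]]
  }
  token_vector <- function(tok) {
    v <- cache[[tok]]
    if (!is.null(v)) return(v)
    rows <- loading_of(tok)
    base_name <- if (length(rows) && !is.null(concepts$base))
      concepts$base[rows[1]] else tok
    v <- with_seed(hash31(seed, "token", base_name), stats::rnorm(dim))
    if (length(rows))
      v[concepts$dim[rows]] <- v[concepts$dim[rows]] + concepts$loading[rows]
    cache[[tok]] <- v
    v
  }
  encode <- function(tokens) {
    if (length(tokens) == 0) stopf("cannot encode an empty token sequence")
    if (length(tokens) > max_window)
      stopf("sequence of %d tokens exceeds the encoder window (%d)",
            length(tokens), max_window)
    uniq <- unique(tokens)
    for (tok in uniq) token_vector(tok)
    V <- matrix(unlist(mget(tokens, envir = cache), use.names = FALSE),
                nrow = length(tokens), byrow = TRUE)
    if (lambda > 0 && length(tokens) > 1) {
      n <- nrow(V)
      ctx <- matrix(0, n, ncol(V))
      cnt <- numeric(n)
      for (off in c(-2L, -1L, 1L, 2L)) {
        src <- seq_len(n) + off
        ok <- src >= 1 & src <= n
        ctx[ok, ] <- ctx[ok, ] + V[src[ok], , drop = FALSE]
        cnt[ok] <- cnt[ok] + 1
      }
      V <- (1 - lambda) * V + lambda * (ctx / pmax(cnt, 1))
    }
    V
  }
  fp_concepts <- if (is.null(concepts)) "none" else
    paste(concepts$token, concepts$dim, signif(concepts$loading, 10),
          concepts$base %||% concepts$token, sep = ":", collapse = ";")
  list(dimension = as.integer(dim), max_window = as.integer(max_window),
       tokenize = tokenize_words, encode = encode,
       fingerprint = hash31("toy_encoder", dim, max_window, seed,
                            fp_concepts, signif(lambda, 10)))
}

#' Toy encoder matched to a synthetic configuration
#'
#' Convenience wrapper: builds a [toy_encoder()] whose concept loadings
#' are the cue tokens planted by `config` (responder cues positive,
#' non-responder cues negative, on the first `n_signal_dims` dimensions).
#'
#' @param config a [synthetic_config()].
#' @param dim,lambda,seed passed to [toy_encoder()].
#' @export
toy_encoder_for <- function(config, dim = 768L, lambda = 0, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  toy_encoder(dim = dim, seed = seed %||% hash31(config$seed, "encoder"),
              concepts = concept_tokens(config), lambda = lambda)
}

#' Embed a set of transcripts into a feature matrix
#'
#' Structures each transcript ([structure_documents()]), embeds each
#' document and pools multi-document (topic-grouped) views by the same
#' pooling mode, yielding one D-vector per participant.
#'
#' @param backend encoder backend.
#' @param transcripts list of [transcript()] objects.
#' @param mode structuring mode, `"sequential"` or `"topic_grouped"`.
#' @param pooling `"mean"` or `"max"`.
#' @return Numeric matrix (participants x D) with participant ids as
#'   rownames and the backend fingerprint as attribute `"fingerprint"`.
#' @export
embed_transcripts <- function(backend, transcripts,
                              mode = c("sequential", "topic_grouped"),
                              pooling = c("mean", "max")) {
  mode <- match.arg(mode)
  pooling <- match.arg(pooling)
  vecs <- lapply(transcripts, function(tr) {
    view <- structure_documents(tr, mode = mode,
                                tokenizer = backend$tokenize %||% tokenize_words)
    docs <- Filter(length, view$documents)
    if (length(docs) == 0)
      stopf("participant %s has no tokens to embed", tr$participant_id)
    dvecs <- t(vapply(docs, function(d)
      embed_document(backend, d, pooling)$vector,
      numeric(backend$dimension)))
    pool_vectors(dvecs, pooling)
  })
  X <- do.call(rbind, vecs)
  rownames(X) <- vapply(transcripts, `[[`, "", "participant_id")
  attr(X, "fingerprint") <- backend$fingerprint
  X
}

#' Embed extracted sentences
#'
#' @param backend encoder backend.
#' @param sentences data.frame from [extract_sentences()].
#' @param pooling `"mean"` or `"max"`.
#' @return Matrix (sentences x D) with `sentence_id` rownames and the
#'   backend fingerprint attached.
#' @export
embed_sentences <- function(backend, sentences, pooling = c("mean", "max")) {
  pooling <- match.arg(pooling)
  X <- t(vapply(sentences$tokens, function(toks)
    embed_document(backend, toks, pooling)$vector,
    numeric(backend$dimension)))
  rownames(X) <- sentences$sentence_id
  attr(X, "fingerprint") <- backend$fingerprint
  X
}
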