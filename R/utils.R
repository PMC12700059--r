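# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic 31-bit string hash
#'
#' Polynomial rolling hash of the concatenated arguments, reduced modulo
#' 2^31 - 1. Used to derive independent, reproducible RNG substreams
#' (e.g. one per participant and artifact) and to fingerprint encoder
#' configurations. Stable across platforms and R sessions.
#'
#' @param ... values pasted together (with a separator) before hashing.
#' @return A single integer in [0, 2^31 - 2].
#' @export
hash31 <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                    character(1)), collapse = "\r")
  bytes <- utf8ToInt(s)
  h <- 0
  m <- 2147483647
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. Mersenne-Twister + inversion are pinned so output is stable.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min &&
    x == as.integer(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1
}
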