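# Shared fixtures: small cohorts and encoders are built once per test run.

small_config <- function(seed = 1, n = 12, ...) {
  synthetic_config(seed = seed, n_participants = n, vocab_size = 120,
                   n_topics = 6, tokens_per_topic = c(10L, 25L), ...)
}

# cached default-size cohort + embeddings used by several test files
fixture_env <- new.env(parent = emptyenv())

default_cohort_fixture <- function() {
  if (is.null(fixture_env$cohort)) {
    cfg <- synthetic_config(seed = 404)
    cohort <- generate_cohort(cfg)
    enc <- toy_encoder_for(cfg)
    X <- embed_transcripts(enc, cohort$transcripts, mode = "sequential",
                           pooling = "mean")
    fixture_env$cohort <- list(config = cfg, cohort = cohort, encoder = enc,
                               X = X, y = cohort$truth$true_class)
  }
  fixture_env$cohort
}

# two tight Gaussian blobs plus sparse uniform outliers
blob_fixture <- function(seed = 7, n_blob = 30, n_noise = 10) {
  with_seed(seed, {
    blob <- function(n, cx, cy) cbind(rnorm(n, cx, 0.1), rnorm(n, cy, 0.1))
    X <- rbind(blob(n_blob, 0, 0), blob(n_blob, 5, 5),
               cbind(runif(n_noise, -50, 50), runif(n_noise, -50, 50)))
    list(X = X,
         truth = c(rep(1L, n_blob), rep(2L, n_blob), rep(-1L, n_noise)))
  })
}

# brute-force one-sided permutation p over all exact splits, independent
# of the package's vectorized implementation
brute_force_perm_p <- function(baseline, treatment) {
  z <- c(baseline, treatment)
  n1 <- length(baseline)
  welch <- function(a, b) {
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    d <- mean(a) - mean(b)
    if (se == 0) return(sign(d) * Inf)
    d / se
  }
  obs <- welch(z[seq_len(n1)], z[-seq_len(n1)])
  splits <- utils::combn(length(z), n1)
  hits <- 0
  for (j in seq_len(ncol(splits))) {
    g1 <- splits[, j]
    if (welch(z[g1], z[-g1]) >= obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(splits)
}

# L-BFGS-B oracle for the L1 squared-hinge SVC via the split w = w+ - w-
# reformulation (box-constrained smooth problem)
oracle_svc <- function(X, y, C) {
  p <- ncol(X)
  obj <- function(th) {
    w <- th[1:p] - th[(p + 1):(2 * p)]
    m <- pmax(0, 1 - y * (drop(X %*% w) + th[2 * p + 1]))
    sum(th[1:(2 * p)]) + C * sum(m^2)
  }
  gr <- function(th) {
    w <- th[1:p] - th[(p + 1):(2 * p)]
    m <- pmax(0, 1 - y * (drop(X %*% w) + th[2 * p + 1]))
    g <- -2 * C * drop(t(X) %*% (y * m))
    c(1 + g, 1 - g, -2 * C * sum(y * m))
  }
  o <- stats::optim(rep(0, 2 * p + 1), obj, gr, method = "L-BFGS-B",
                    lower = c(rep(0, 2 * p), -Inf),
                    control = list(maxit = 5000, factr = 1e3))
  list(w = o$par[1:p] - o$par[(p + 1):(2 * p)], b = o$par[2 * p + 1],
       objective = o$value)
}
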