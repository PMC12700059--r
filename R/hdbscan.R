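# Hierarchical density-based clustering (HDBSCAN): mutual-reachability
# distances, single-linkage hierarchy, condensed tree with
# minimum-cluster-size pruning, and stability-based (excess-of-mass)
# cluster extraction. Points that never join a stable cluster are noise.
# Implemented here because no installed package provides the algorithm;
# behaviour follows the published algorithm with the usual conventions
# (core distance to the min_samples-th neighbour counting the point
# itself; the hierarchy root is never selected as a cluster).

#' Hierarchical density-based clustering with noise
#'
#' @param X numeric matrix (points x dimensions), Euclidean metric.
#' @param min_cluster_size smallest allowed cluster (>= 2); also the
#'   default for `min_samples`.
#' @param min_samples neighbourhood size used for core distances.
#' @return List of class `hdbscan_fit`: `labels` (integers `1..K`, noise
#'   `-1`), `n_clusters`, `stabilities`, `min_cluster_size`.
#' @export
hdbscan_fit <- function(X, min_cluster_size = 5L,
                        min_samples = min_cluster_size) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (!is_count(min_cluster_size, min = 2))
    stopf("min_cluster_size must be an integer >= 2")
  if (n < min_cluster_size)
    stopf("need at least min_cluster_size (%d) points, got %d",
          min_cluster_size, n)
  D <- as.matrix(stats::dist(X))
  if (max(D) == 0) {   # zero-diameter input: one cluster by convention
    return(structure(list(labels = rep(1L, n), n_clusters = 1L,
                          stabilities = Inf,
                          min_cluster_size = as.integer(min_cluster_size)),
                     class = "hdbscan_fit"))
  }
  ms <- min(min_samples, n)
  core <- apply(D, 1, function(row) sort(row)[ms])  # row includes self (0)
  M <- pmax(D, outer(core, core, pmax))
  diag(M) <- 0
  hc <- stats::hclust(stats::as.dist(M), method = "single")
  ext <- condense_tree(hc$merge, hc$height, n, min_cluster_size)
  labels <- extract_clusters(ext, n)
  structure(list(labels = labels$labels,
                 n_clusters = labels$n_clusters,
                 stabilities = labels$stabilities,
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "hdbscan_fit")
}

#' @export
print.hdbscan_fit <- function(x, ...) {
  cat(sprintf("hdbscan_fit: %d cluster(s), %d noise point(s) of %d\n",
              x$n_clusters, sum(x$labels == -1L), length(x$labels)))
  invisible(x)
}

# Walk the single-linkage merge tree from the root downward, pruning
# splits whose smaller side is below min_cluster_size. Returns per-point
# fall-out clusters and lambdas plus the condensed-cluster bookkeeping
# needed for stability extraction.
condense_tree <- function(merge, height, n, mcs) {
  n_merge <- nrow(merge)
  node_points <- vector("list", n_merge)
  node_size <- integer(n_merge)
  for (m in seq_len(n_merge)) {
    pts <- unlist(lapply(merge[m, ], function(ch)
      if (ch < 0) -ch else node_points[[ch]]))
    node_points[[m]] <- pts
    node_size[m] <- length(pts)
  }
  lam <- 1 / pmax(height, 1e-12)

  parent <- integer(0); birth <- numeric(0); stab <- numeric(0)
  children <- list()
  fall_cluster <- integer(n); fall_lambda <- numeric(n)
  new_cluster <- function(par, lb) {
    parent[length(parent) + 1L] <<- par
    birth[length(birth) + 1L] <<- lb
    stab[length(stab) + 1L] <<- 0
    children[[length(birth)]] <<- integer(0)
    if (par > 0) children[[par]] <<- c(children[[par]], length(birth))
    length(birth)
  }
  root <- new_cluster(0L, 0)
  stack <- list(list(node = n_merge, cluster = root))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node; cl <- top$cluster
    l <- lam[node]
    ch <- merge[node, ]
    sizes <- ifelse(ch < 0, 1L, node_size[pmax(ch, 1L)])
    if (all(sizes >= mcs)) {
      # true split: two new condensed clusters are born at lambda l;
      # every point leaves `cl` here
      stab[cl] <- stab[cl] + sum(sizes) * (l - birth[cl])
      for (j in 1:2) {
        sub <- new_cluster(cl, l)
        stack[[length(stack) + 1L]] <- list(node = ch[j], cluster = sub)
      }
    } else {
      for (j in 1:2) {
        if (sizes[j] < mcs) {
          pts <- if (ch[j] < 0) -ch[j] else node_points[[ch[j]]]
          fall_cluster[pts] <- cl
          fall_lambda[pts] <- l
          stab[cl] <- stab[cl] + sizes[j] * (l - birth[cl])
        } else {
          stack[[length(stack) + 1L]] <- list(node = ch[j], cluster = cl)
        }
      }
    }
  }
  list(parent = parent, birth = birth, stab = stab, children = children,
       fall_cluster = fall_cluster, fall_lambda = fall_lambda, root = root)
}

# Excess-of-mass selection over the condensed tree, then point labels.
extract_clusters <- function(ext, n) {
  k <- length(ext$birth)
  selected <- logical(k)
  total <- ext$stab
  for (c in rev(seq_len(k))) {
    kids <- ext$children[[c]]
    if (length(kids) == 0) {
      selected[c] <- c != ext$root
      total[c] <- ext$stab[c]
    } else {
      child_sum <- sum(total[kids])
      if (child_sum > ext$stab[c] || c == ext$root) {
        total[c] <- child_sum
      } else {
        selected[c] <- TRUE
        total[c] <- ext$stab[c]
        # deselect every descendant
        desc <- kids
        while (length(desc)) {
          selected[desc] <- FALSE
          desc <- unlist(ext$children[desc])
        }
      }
    }
  }
  sel_ids <- which(selected)
  labels <- rep(-1L, n)
  if (length(sel_ids)) {
    relabel <- integer(k)
    relabel[sel_ids] <- seq_along(sel_ids)
    for (p in seq_len(n)) {
      c <- ext$fall_cluster[p]
      while (c > 0 && !selected[c]) c <- ext$parent[c]
      if (c > 0) labels[p] <- relabel[c]
    }
  }
  list(labels = labels, n_clusters = length(sel_ids),
       stabilities = ext$stab[sel_ids])
}
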