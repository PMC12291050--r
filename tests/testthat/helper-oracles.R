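# independent exhaustive-search oracles used to validate the greedy
# clustering; these enumerate every set partition (Bell numbers, n <= 8)
# and are deliberately implemented without reference to the greedy code

# all set partitions of 1..n as lists of integer vectors
all_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  smaller <- all_partitions(n - 1L)
  out <- list()
  for (p in smaller) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# feasibility: every member pair within tau of each other (min-denominator
# convention, so the block range relative to its smallest member suffices);
# optionally no two members of a block from the same run
block_feasible <- function(x, idx, tau, run_ids = NULL) {
  ok <- (max(x[idx]) - min(x[idx])) / min(x[idx]) <= tau
  if (ok && !is.null(run_ids)) ok <- !anyDuplicated(run_ids[idx])
  ok
}

# oracle: minimize block count, then total squared deviation from block
# means; returns canonical partition (blocks sorted by smallest member ccs,
# members sorted)
oracle_cluster <- function(x, tau, run_ids = NULL) {
  parts <- all_partitions(length(x))
  best <- NULL; best_k <- Inf; best_spread <- Inf
  for (p in parts) {
    if (!all(vapply(p, function(idx)
      block_feasible(x, idx, tau, run_ids), logical(1)))) next
    k <- length(p)
    spread <- sum(vapply(p, function(idx)
      sum((x[idx] - mean(x[idx]))^2), numeric(1)))
    if (k < best_k || (k == best_k && spread < best_spread - 1e-12)) {
      best <- p; best_k <- k; best_spread <- spread
    }
  }
  if (is.null(best)) return(NULL)
  best <- lapply(best, sort)
  best[order(vapply(best, function(idx) min(x[idx]), numeric(1)))]
}

# canonical partition from greedy integer labels over sorted x
labels_to_partition <- function(labels) {
  blocks <- split(seq_along(labels), labels)
  blocks <- lapply(blocks, sort)
  unname(blocks[order(vapply(blocks, min, integer(1)))])
}

# random small clustering instance: 1..3 planted clusters separated by
# >= 3% with 0.3% relative jitter, echoing curated CCS data
random_cluster_instance <- function(n_obs, n_runs = 1L) {
  # with the one-observation-per-(cluster, run) constraint the instance
  # needs at least ceil(n_obs / n_runs) clusters to be realizable
  k_min <- if (n_runs > 1L) ceiling(n_obs / n_runs) else 1L
  ks <- max(1L, k_min):3L
  n_clusters <- ks[sample.int(length(ks), 1L)]
  base <- runif(1, 350, 700)
  centers <- base * cumprod(c(1, 1 + runif(max(n_clusters - 1L, 0),
                                           0.03, 0.08)))[seq_len(n_clusters)]
  cl <- sort(sample(seq_len(n_clusters), n_obs, replace = TRUE))
  if (n_runs > 1L) {
    # a run holds at most one observation per cluster
    while (max(tabulate(cl)) > n_runs)
      cl <- sort(sample(seq_len(n_clusters), n_obs, replace = TRUE))
  }
  x <- centers[cl] * (1 + rnorm(n_obs, 0, 0.003))
  run_ids <- if (n_runs > 1L) {
    # at most one observation of a cluster per run
    r <- integer(n_obs)
    for (k in unique(cl)) {
      members <- which(cl == k)
      r[members] <- sample(seq_len(n_runs), length(members))
    }
    paste0("R", r)
  } else NULL
  list(x = x, run_ids = run_ids, n_clusters = n_clusters)
}
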