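# Shared fixtures built in code at test time.

# brute-force Ward oracle: greedy agglomeration minimising the increase in
# total within-cluster SSE, heights reported as sqrt(2 * delta SSE) (the
# convention in which a singleton pair merges at its Euclidean distance).
# Ties broken by lowest pair index. Independent of the package's clustering
# path (plain loops over all candidate pairs).
brute_force_ward <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  clusters <- lapply(seq_len(n), function(i) i)       # member rows
  ids <- -seq_len(n)                                   # hclust-style ids
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  sse <- function(rows) {
    if (length(rows) == 1L) return(0)
    ctr <- colMeans(x[rows, , drop = FALSE])
    sum(sweep(x[rows, , drop = FALSE], 2L, ctr)^2)
  }
  for (m in seq_len(n - 1L)) {
    best <- NULL; best_cost <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        cost <- sse(c(clusters[[i]], clusters[[j]])) -
          sse(clusters[[i]]) - sse(clusters[[j]])
        if (cost < best_cost - 1e-12) {
          best_cost <- cost; best <- c(i, j)
        }
      }
    }
    merge[m, ] <- c(ids[best[1L]], ids[best[2L]])
    height[m] <- sqrt(2 * best_cost)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    ids[best[1L]] <- m
    clusters <- clusters[-best[2L]]
    ids <- ids[-best[2L]]
  }
  list(merge = merge, height = height)
}

# partition of leaves implied by a merge matrix cut at k clusters
merge_partition <- function(merge, n, k) {
  lab <- -seq_len(n)
  groups <- as.list(seq_len(n))
  names(groups) <- as.character(-seq_len(n))
  for (m in seq_len(n - k)) {
    a <- as.character(merge[m, 1L]); b <- as.character(merge[m, 2L])
    groups[[as.character(m)]] <- c(groups[[a]], groups[[b]])
    groups[[a]] <- NULL; groups[[b]] <- NULL
  }
  part <- integer(n)
  for (g in seq_along(groups)) part[groups[[g]]] <- g
  part
}

# canonical form of a partition (label-invariant)
canon_partition <- function(p) as.integer(factor(p, levels = unique(p)))

make_step_sweep <- function(v, dt = 0.1, step_pA = 100, pre_ms = 100,
                            step_ms = 1000, post_ms = 100) {
  ep <- protocol_epochs(start_ms = c(0, pre_ms, pre_ms + step_ms),
                        duration_ms = c(pre_ms, step_ms, post_ms),
                        command_level = c(0, step_pA, 0),
                        kind = c("holding", "step", "holding"))
  sweep_trace(v, dt = dt, units = "mV", epochs = ep,
              meta = list(step_pA = step_pA))
}
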