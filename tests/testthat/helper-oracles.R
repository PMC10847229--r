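# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: metrics by exhaustive enumeration, OLS by the
# normal equations, KS by direct ECDF scanning.

# Random symmetric signed weighted adjacency (zero diagonal).
random_signed_graph <- function(n_nodes, p_edge = 0.5) {
  adj <- matrix(0, n_nodes, n_nodes)
  for (i in seq_len(n_nodes - 1L)) {
    for (j in seq((i + 1L), n_nodes)) {
      if (runif(1) < p_edge) {
        adj[i, j] <- adj[j, i] <- runif(1, -1, 1)
      }
    }
  }
  dimnames(adj) <- list(paste0("r", seq_len(n_nodes)),
                        paste0("r", seq_len(n_nodes)))
  adj
}

as_tnet <- function(adj, alpha = 0.05, n = 10L) {
  n_nodes <- nrow(adj)
  structure(
    list(adjacency = adj, alpha = alpha,
         density = sum(adj[upper.tri(adj)] != 0) /
           (n_nodes * (n_nodes - 1) / 2),
         n = n, regions = rownames(adj), group = NULL),
    class = "thresholded_network")
}

# Brute-force nodal metrics: loops over node pairs and triples.
brute_metrics <- function(adj) {
  n <- nrow(adj)
  out <- data.frame(region = rownames(adj), degree = 0L, s_pos = 0,
                    s_neg = 0, clustering = 0)
  for (i in seq_len(n)) {
    nbrs <- which(adj[i, ] != 0)
    out$degree[i] <- length(nbrs)
    out$s_pos[i] <- sum(adj[i, nbrs][adj[i, nbrs] > 0])
    out$s_neg[i] <- sum(abs(adj[i, nbrs][adj[i, nbrs] < 0]))
    if (length(nbrs) >= 2L) {
      pairs <- combn(nbrs, 2L)
      closed <- sum(apply(pairs, 2L, function(pr) adj[pr[1L], pr[2L]] != 0))
      out$clustering[i] <- closed / ncol(pairs)
    }
  }
  out
}

# Two-sample KS statistic by direct ECDF scan.
ks_stat_oracle <- function(x, y) {
  pooled <- sort(unique(c(x, y)))
  max(abs(vapply(pooled, function(q) mean(x <= q) - mean(y <= q), numeric(1))))
}

# Exact two-sample KS p by full enumeration of label assignments.
ks_p_enumeration <- function(x, y) {
  z <- c(x, y)
  n1 <- length(x)
  combs <- combn(length(z), n1)
  d_obs <- ks_stat_oracle(x, y)
  d_perm <- apply(combs, 2L, function(idx) ks_stat_oracle(z[idx], z[-idx]))
  mean(d_perm >= d_obs - 1e-12)
}

# OLS coefficients by the normal equations.
ols_oracle <- function(x_mat, y) {
  solve(t(x_mat) %*% x_mat, t(x_mat) %*% y)[, 1L]
}

# Small single-group cohort generator for network-level tests.
one_group_cohort <- function(n, within_r = 0.8, between_r = 0, seed = 1,
                             n_per_block = 9L, noise_sd = 0.1) {
  regions <- default_regions()[seq_len(3L * n_per_block)]
  part <- setNames(rep(1:3, each = n_per_block), regions)
  spec <- cohort_spec(
    n_per_group = n, regions = regions, planted_partition = part,
    within_block_r = within_r, between_block_r = between_r,
    noise_sd = noise_sd,
    group_design = data.frame(sex = "male", genotype = "WT",
                              treatment = "vehicle"),
    seed = seed)
  list(spec = spec, table = compute_suvr(generate_suvr_cohort(spec)))
}
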