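# Co-classification indicator matrix of a membership vector.
.coclass <- function(membership) {
  outer(membership, membership, "==") * 1
}

# One Louvain partition of a weighted graph at resolution gamma.
.louvain_membership <- function(graph, gamma) {
  cl <- igraph::cluster_louvain(graph, resolution = gamma)
  as.integer(igraph::membership(cl))
}

# Exact probability that a fixed node pair lands in the same community when
# a partition's labels are uniformly permuted over nodes: depends only on
# community sizes.
.perm_together_prob <- function(membership) {
  n <- length(membership)
  sizes <- table(membership)
  sum(sizes * (sizes - 1)) / (n * (n - 1))
}

#' Multi-resolution consensus clustering of a thresholded network
#'
#' Community structure of the positive-weight subgraph, robust to the
#' modularity resolution limit: Louvain modularity partitions are computed
#' at `n_samples` resolutions spread over `gamma_range`; the ensemble is
#' summarized by the co-classification matrix `A` (fraction of partitions
#' placing each region pair together); entries not exceeding a permutation
#' null (the 95th percentile of co-classification under `n_null` random
#' relabelings of the ensemble partitions) are zeroed; and the thresholded
#' `A` is itself re-clustered, iterating until the consensus ensemble is
#' unanimous. Negative edges are excluded here (community detection focuses
#' on positive covariance) but are retained by [nodal_metrics()].
#'
#' The run is deterministic given `seed`. A network with no positive edges
#' yields a single all-in-one community with a warning.
#'
#' @param tnet A [threshold_network()] result.
#' @param gamma_range Resolution interval (default 0.5 to 3).
#' @param n_samples Number of resolutions in the ensemble (evenly spaced).
#' @param n_null Number of permutation replicates for the consensus null.
#' @param seed Integer seed (required; logged on the result).
#' @param null_quantile Quantile of the null co-classification distribution
#'   used as threshold.
#' @param n_consensus Partitions per consensus iteration.
#' @param max_iter Consensus iteration cap; exceeding it is an error.
#' @return An object of class `mrcc_result`: `partition` (tibble `region`,
#'   `community`), `k`, `coclassification` (the ensemble matrix `A`),
#'   `null_threshold`, `gammas`, `n_iter`, `seed`.
#' @export
mrcc <- function(tnet, gamma_range = c(0.5, 3), n_samples = 200L,
                 n_null = 10000L, seed, null_quantile = 0.95,
                 n_consensus = 64L, max_iter = 25L) {
  stopifnot(inherits(tnet, "thresholded_network"))
  if (missing(seed)) abort("`seed` is required for a reproducible consensus.")
  .check_scalar_num(null_quantile, "null_quantile", 0, 1)
  w <- tnet$adjacency
  w[w < 0] <- 0
  regions <- tnet$regions
  n <- length(regions)
  if (all(w == 0)) {
    warn("No positive edges: returning a single all-in-one community.")
    return(structure(
      list(partition = tibble::tibble(region = regions, community = 1L),
           k = 1L, coclassification = matrix(1, n, n,
                                             dimnames = list(regions, regions)),
           null_threshold = NA_real_, gammas = numeric(), n_iter = 0L,
           seed = as.integer(seed)),
      class = "mrcc_result"))
  }
  set.seed(.derive_seed(seed, "mrcc"))
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  gammas <- seq(gamma_range[1L], gamma_range[2L], length.out = n_samples)
  ensemble <- lapply(gammas, function(gam) .louvain_membership(g, gam))
  a <- Reduce(`+`, lapply(ensemble, .coclass)) / length(ensemble)
  dimnames(a) <- list(regions, regions)

  # Permutation null for one pair under random relabeling of each ensemble
  # partition: Bernoulli with the partition's exact same-community
  # probability, averaged over the ensemble.
  probs <- vapply(ensemble, .perm_together_prob, numeric(1))
  null_draws <- matrix(rbinom(n_null * length(probs), 1L,
                              rep(probs, each = n_null)),
                       nrow = n_null)
  null_vals <- rowMeans(null_draws)
  thr <- unname(quantile(null_vals, null_quantile, type = 1))

  consensus_of <- function(a_mat) {
    a_thr <- a_mat
    a_thr[a_thr <= thr] <- 0
    diag(a_thr) <- 0
    for (iter in seq_len(max_iter)) {
      if (all(a_thr == 0)) {
        return(list(membership = seq_len(n), n_iter = iter))
      }
      gc <- igraph::graph_from_adjacency_matrix(
        a_thr, mode = "undirected", weighted = TRUE, diag = FALSE)
      parts <- lapply(seq_len(n_consensus), function(i) {
        .louvain_membership(gc, 1)
      })
      canon <- lapply(parts, function(p) match(p, unique(p)))
      if (all(vapply(canon, identical, logical(1), canon[[1L]]))) {
        return(list(membership = canon[[1L]], n_iter = iter))
      }
      a_thr <- Reduce(`+`, lapply(parts, .coclass)) / length(parts)
      a_thr[a_thr <= thr] <- 0
      diag(a_thr) <- 0
    }
    abort(sprintf(
      "Consensus did not converge in %d iterations (null threshold %.3f).",
      max_iter, thr))
  }
  cons <- consensus_of(a)
  membership <- match(cons$membership, unique(cons$membership))
  structure(
    list(partition = tibble::tibble(region = regions,
                                    community = as.integer(membership)),
         k = length(unique(membership)), coclassification = a,
         null_threshold = thr, gammas = gammas, n_iter = cons$n_iter,
         seed = as.integer(seed)),
    class = "mrcc_result")
}

#' @export
print.mrcc_result <- function(x, ...) {
  cat(sprintf(
    "MRCC consensus: %d communities over %d regions (%d resolutions, null threshold %.3f)\n",
    x$k, nrow(x$partition), length(x$gammas), x$null_threshold))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy mrcc_result
#' @export
tidy.mrcc_result <- function(x, ...) x$partition

#' @rdname tidiers
#' @method glance mrcc_result
#' @export
glance.mrcc_result <- function(x, ...) {
  tibble::tibble(k = x$k, n_regions = nrow(x$partition),
                 n_resolutions = length(x$gammas),
                 null_threshold = x$null_threshold, n_iter = x$n_iter,
                 seed = x$seed)
}

#' Number of communities in a partition
#'
#' @param partition A tibble with a `community` column (e.g. from
#'   [mrcc()]'s `$partition`), or a bare label vector.
#' @return Integer count of distinct community labels.
#' @export
count_communities <- function(partition) {
  labels <- if (is.data.frame(partition)) partition$community else partition
  length(unique(labels))
}

#' Impose a reference partition on a comparison group's SUVr table
#'
#' Evaluates a comparison group's regional data under a reference group's
#' community assignment (e.g. wild-type male partitions imposed on treated
#' or female groups), so like subnetworks are compared across groups: per
#' animal and community, the arithmetic mean SUVr over member regions.
#'
#' @param reference Partition tibble (`region`, `community`) covering every
#'   region column of `data` except `exclude`.
#' @param data Cohort SUVr table for the comparison group.
#' @param exclude Region columns to ignore (the reference region).
#' @return A long tibble: metadata columns, `community`, `mean_suvr`.
#' @export
impose_partition <- function(reference, data, exclude = "Cerebellum") {
  if (!all(c("region", "community") %in% names(reference))) {
    abort("`reference` must have columns `region` and `community`.")
  }
  regs <- setdiff(.assert_cohort(data), exclude)
  missing <- setdiff(regs, reference$region)
  if (length(missing) > 0L) {
    abort(paste("Regions absent from the reference partition:",
                toString(missing)))
  }
  meta <- intersect(.meta_cols, names(data))
  data |>
    tidyr::pivot_longer(dplyr::all_of(regs), names_to = "region",
                        values_to = "suvr") |>
    dplyr::inner_join(reference[c("region", "community")], by = "region") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(meta, "community")))) |>
    dplyr::summarise(mean_suvr = mean(.data$suvr), .groups = "drop")
}

#' Community-wise ANOVA between two groups under a shared partition
#'
#' One-way ANOVA of per-animal community-mean SUVr between two groups, one
#' test per community (two groups, so `F` on 1 and `n_a + n_b - 2` df and
#' `F = t^2` of the pooled two-sample t test), Bonferroni-corrected across
#' the `K` communities: `p_bonferroni = min(1, p * K)`.
#'
#' @param a,b Community-mean tables from [impose_partition()] for the two
#'   groups (same partition).
#' @param labels Length-2 group labels for the report.
#' @return A tibble: `community`, `n_a`, `n_b`, `f_statistic`, `p_value`,
#'   `p_bonferroni`, `mean_a`, `mean_b`. Communities where F is undefined
#'   (no within-group variance and equal means) carry `NA` with a note
#'   column.
#' @export
community_anova <- function(a, b, labels = c("a", "b")) {
  for (d in list(a, b)) {
    if (!all(c("community", "mean_suvr") %in% names(d))) {
      abort("Inputs must come from `impose_partition()`.")
    }
  }
  communities <- sort(unique(a$community))
  if (!setequal(communities, unique(b$community))) {
    abort("The two groups must share the same partition (same communities).")
  }
  k <- length(communities)
  purrr::map(communities, function(cm) {
    xa <- a$mean_suvr[a$community == cm]
    xb <- b$mean_suvr[b$community == cm]
    if (length(xa) < 2L || length(xb) < 2L) {
      abort(sprintf("Community %s needs >= 2 animals per group.", cm))
    }
    grp <- factor(rep(labels, c(length(xa), length(xb))))
    vals <- c(xa, xb)
    ssb <- sum(tapply(vals, grp, function(v) length(v) * (mean(v) - mean(vals))^2))
    ssw <- sum(tapply(vals, grp, function(v) sum((v - mean(v))^2)))
    df2 <- length(vals) - 2L
    if (ssw == 0 && ssb == 0) {
      return(tibble::tibble(community = cm, n_a = length(xa), n_b = length(xb),
                            f_statistic = NA_real_, p_value = NA_real_,
                            p_bonferroni = NA_real_, mean_a = mean(xa),
                            mean_b = mean(xb), note = "F undefined: no variance"))
    }
    f <- (ssb / 1) / (ssw / df2)
    p <- pf(f, 1, df2, lower.tail = FALSE)
    tibble::tibble(community = cm, n_a = length(xa), n_b = length(xb),
                   f_statistic = f, p_value = p,
                   p_bonferroni = pmin(1, p * k), mean_a = mean(xa),
                   mean_b = mean(xb), note = NA_character_)
  }) |> dplyr::bind_rows()
}
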