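#' Metabolic covariance network of one cohort
#'
#' Across-animal Pearson correlation between every pair of regions in a
#' group's SUVr table — the group's metabolic covariance network. Two-sided
#' p-values come from the t transform `t = r sqrt((n-2)/(1-r^2))` with
#' `n - 2` degrees of freedom. The reference region is excluded. Because
#' Pearson correlation is invariant to per-column affine rescaling,
#' z-scoring the inputs first (as imaging pipelines do) leaves `r`
#' unchanged; this invariance is part of the tested contract.
#'
#' Zero-variance regions (a degenerate cohort) degrade to isolated nodes:
#' their correlations are set to 0 with p = 1, with a warning naming the
#' region.
#'
#' @param data Cohort SUVr table for one group (>= 4 animals).
#' @param reference Reference region to exclude.
#' @param group Optional label (e.g. "male WT vehicle") carried on the
#'   object.
#' @return An object of class `covariance_network`: `r` and `p` matrices
#'   (diagonal of `r` set to 0 by convention), `n`, `regions`, `group`.
#' @export
covariance_matrix <- function(data, reference = "Cerebellum", group = NULL) {
  regs <- setdiff(.assert_cohort(data), reference)
  n <- nrow(data)
  if (n < 4L) abort("Need at least 4 animals to build a covariance network.")
  x <- as.matrix(data[regs])
  sds <- apply(x, 2L, sd)
  degenerate <- regs[sds == 0]
  if (length(degenerate) > 0L) {
    warn(paste("Zero-variance regions set to isolated nodes:",
               toString(degenerate)))
  }
  r <- suppressWarnings(cor(x))
  r[!is.finite(r)] <- 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  if (length(degenerate) > 0L) {
    r[degenerate, ] <- 0; r[, degenerate] <- 0
    p[degenerate, ] <- 1; p[, degenerate] <- 1
  }
  diag(r) <- 0
  diag(p) <- 1
  structure(list(r = r, p = p, n = n, regions = regs, group = group),
            class = "covariance_network")
}

#' @export
print.covariance_network <- function(x, ...) {
  cat(sprintf("Metabolic covariance network: %d regions, n = %d animals%s\n",
              length(x$regions), x$n,
              if (is.null(x$group)) "" else paste0(" (", x$group, ")")))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy covariance_network
#' @export
tidy.covariance_network <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(region_a = x$regions[idx[, 1L]],
                 region_b = x$regions[idx[, 2L]],
                 r = x$r[idx], p = x$p[idx])
}

#' Threshold a covariance network at an edge significance level
#'
#' Keeps the signed correlation as edge weight wherever the edge p-value is
#' below `alpha`; all other edges are zeroed. Density is surviving edges
#' over all `N (N-1) / 2` region pairs. Raising `alpha` never removes an
#' edge (edge sets are nested in `alpha`).
#'
#' @param net A [covariance_matrix()] result.
#' @param alpha Edge significance threshold (default 0.05, below which
#'   graphs were judged too sparse to analyze).
#' @return An object of class `thresholded_network`: signed weighted
#'   `adjacency`, `alpha`, `density`, `n`, `regions`, `group`.
#' @export
threshold_network <- function(net, alpha = 0.05) {
  stopifnot(inherits(net, "covariance_network"))
  .check_scalar_num(alpha, "alpha", 0, 1)
  adj <- ifelse(net$p < alpha, net$r, 0)
  diag(adj) <- 0
  n_regions <- length(net$regions)
  possible <- n_regions * (n_regions - 1) / 2
  structure(
    list(adjacency = adj, alpha = alpha,
         density = sum(adj[upper.tri(adj)] != 0) / possible,
         n = net$n, regions = net$regions, group = net$group),
    class = "thresholded_network")
}

#' @export
print.thresholded_network <- function(x, ...) {
  cat(sprintf("Thresholded network (alpha = %g): %d regions, density %.3f\n",
              x$alpha, length(x$regions), x$density))
  invisible(x)
}

#' Signed nodal graph metrics
#'
#' For every region of a thresholded network: `degree` (count of surviving
#' edges), `s_pos` (sum of positive edge weights), `s_neg` (summed
#' magnitude of negative edge weights, reported as a positive number), and
#' the clustering coefficient. The default clustering coefficient is the
#' binary, sign-blind Watts-Strogatz form on the surviving-edge graph —
#' closed triads over `k (k-1) / 2`, 0 when `k < 2`. Weighted (Onnela
#' geometric-mean, on |w|) and signed (Zhang-Horvath) variants are
#' available behind `clustering`.
#'
#' @param tnet A [threshold_network()] result.
#' @param clustering `"binary"` (default), `"onnela"`, or `"signed"`.
#' @return A tibble: `region`, `degree`, `s_pos`, `s_neg`, `clustering`,
#'   plus the group label if present.
#' @export
nodal_metrics <- function(tnet, clustering = c("binary", "onnela", "signed")) {
  stopifnot(inherits(tnet, "thresholded_network"))
  clustering <- match.arg(clustering)
  w <- tnet$adjacency
  a <- (w != 0) * 1
  k <- rowSums(a)
  cc <- switch(clustering,
    binary = {
      tri <- diag(a %*% a %*% a) / 2
      ifelse(k < 2, 0, tri / (k * (k - 1) / 2))
    },
    onnela = {
      wh <- (abs(w) / max(abs(w), 1e-300))^(1 / 3)
      tri <- diag(wh %*% wh %*% wh) / 2
      ifelse(k < 2, 0, tri / (k * (k - 1) / 2))
    },
    signed = {
      num <- diag(w %*% w %*% w) / 2
      den <- (rowSums(abs(w))^2 - rowSums(w^2)) / 2
      ifelse(den <= 0, 0, num / den)
    })
  out <- tibble::tibble(region = tnet$regions,
                        degree = as.integer(unname(k)),
                        s_pos = unname(rowSums(w * (w > 0))),
                        s_neg = unname(rowSums(abs(w) * (w < 0))),
                        clustering = unname(cc))
  if (!is.null(tnet$group)) out$group <- tnet$group
  out
}

# Two-sample KS statistic: max absolute ECDF difference over the pooled
# support.
.ks_statistic <- function(x, y) {
  pooled <- sort(unique(c(x, y)))
  fx <- vapply(pooled, function(q) mean(x <= q), numeric(1))
  fy <- vapply(pooled, function(q) mean(y <= q), numeric(1))
  max(abs(fx - fy))
}

# Asymptotic two-sided two-sample KS p-value: limiting Kolmogorov
# distribution evaluated at sqrt(mn/(m+n)) * D.
.ks_p_asymptotic <- function(d, n1, n2) {
  lambda <- sqrt(n1 * n2 / (n1 + n2)) * d
  if (lambda == 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov comparison of nodal-metric distributions
#'
#' Compares the global distribution of a nodal metric (e.g. the 27 regional
#' degrees) between two groups. `D` is the maximum absolute difference of
#' the empirical CDFs; `D = 0` exactly when the two empirical distributions
#' coincide on the pooled support. The p-value is exact (permutation
#' distribution of `D`, ties respected, via [stats::psmirnov()]) when both
#' samples have at most `exact_max` observations, asymptotic otherwise.
#'
#' @param a,b Numeric vectors of nodal-metric values.
#' @param metric Optional metric name carried through.
#' @param labels Length-2 character vector naming the groups.
#' @param exact_max Largest per-sample size for which the exact p is used.
#' @return A one-row tibble: `metric`, `group_a`, `group_b`, `statistic`,
#'   `p_value`, `exact`, `n_a`, `n_b`.
#' @export
compare_metric_distributions <- function(a, b, metric = NA_character_,
                                         labels = c("a", "b"),
                                         exact_max = 30L) {
  if (length(a) == 0L || length(b) == 0L) abort("Both samples must be nonempty.")
  d <- .ks_statistic(a, b)
  exact <- length(a) <= exact_max && length(b) <= exact_max
  p <- if (exact) {
    stats::psmirnov(d, sizes = c(length(a), length(b)), z = c(a, b),
                    two.sided = TRUE, exact = TRUE, lower.tail = FALSE)
  } else {
    .ks_p_asymptotic(d, length(a), length(b))
  }
  tibble::tibble(metric = metric, group_a = labels[1L], group_b = labels[2L],
                 statistic = d, p_value = min(max(p, 0), 1), exact = exact,
                 n_a = length(a), n_b = length(b))
}

#' Build, threshold and summarize networks for every group of a cohort table
#'
#' Convenience wrapper over [covariance_matrix()], [threshold_network()] and
#' [nodal_metrics()], splitting the cohort by sex x genotype x treatment.
#' Groups with fewer than `min_n` animals are skipped with a warning.
#'
#' @param data Cohort SUVr table with metadata columns.
#' @param alpha Edge threshold.
#' @param reference Reference region to exclude.
#' @param min_n Minimum group size.
#' @param clustering Clustering-coefficient variant, see [nodal_metrics()].
#' @return A list: `networks` (named list of `thresholded_network`),
#'   `metrics` (one tidy tibble of nodal metrics across groups, with `sex`,
#'   `genotype`, `treatment` columns), `density` (per-group tibble).
#' @export
group_networks <- function(data, alpha = 0.05, reference = "Cerebellum",
                           min_n = 4L, clustering = "binary") {
  .assert_cohort(data)
  keys <- dplyr::distinct(data[intersect(c("sex", "genotype", "treatment"),
                                         names(data))])
  networks <- list()
  metrics <- list()
  dens <- list()
  for (i in seq_len(nrow(keys))) {
    key <- keys[i, , drop = FALSE]
    sub <- dplyr::semi_join(data, key, by = names(key))
    label <- paste(unlist(key), collapse = "_")
    if (nrow(sub) < min_n) {
      warn(sprintf("Group `%s` has %d < %d animals; skipped.", label,
                   nrow(sub), min_n))
      next
    }
    net <- covariance_matrix(sub, reference = reference, group = label)
    tnet <- threshold_network(net, alpha = alpha)
    networks[[label]] <- tnet
    metrics[[label]] <- dplyr::bind_cols(
      nodal_metrics(tnet, clustering = clustering)[
        c("region", "degree", "s_pos", "s_neg", "clustering")],
      key)
    dens[[label]] <- dplyr::bind_cols(
      tibble::tibble(group = label, density = tnet$density, n = tnet$n), key)
  }
  list(networks = networks,
       metrics = dplyr::bind_rows(metrics),
       density = dplyr::bind_rows(dens))
}
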