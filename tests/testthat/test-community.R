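test_that("two disconnected positive cliques are recovered as two communities", {
  adj <- matrix(0, 8, 8,
                dimnames = list(letters[1:8], letters[1:8]))
  adj[1:4, 1:4] <- 0.9
  adj[5:8, 5:8] <- 0.9
  diag(adj) <- 0
  for (s in c(1, 2, 3)) {
    m <- mrcc(as_tnet(adj), seed = s, n_samples = 100, n_null = 2000)
    expect_equal(m$k, 2L)
    expect_equal(adjusted_rand_index(m$partition$community,
                                     rep(1:2, each = 4)), 1)
  }
})

test_that("MRCC recovers a planted three-block partition", {
  cohort <- one_group_cohort(200, within_r = 0.8, between_r = 0, seed = 41)
  tn <- threshold_network(covariance_matrix(cohort$table))
  m <- mrcc(tn, seed = 42)
  truth <- cohort$spec$planted_partition[m$partition$region]
  expect_gte(adjusted_rand_index(m$partition$community, truth), 0.9)
  # unanimous consensus: co-classification restricted to the consensus is
  # block-structured above the null threshold
  same <- outer(m$partition$community, m$partition$community, "==")
  expect_true(all(m$coclassification[same] > m$null_threshold))
})

test_that("consensus is stable across seeds on a clean network", {
  cohort <- one_group_cohort(200, within_r = 0.8, between_r = 0, seed = 43)
  tn <- threshold_network(covariance_matrix(cohort$table))
  m1 <- mrcc(tn, seed = 1, n_samples = 200, n_null = 5000)
  m2 <- mrcc(tn, seed = 2, n_samples = 200, n_null = 5000)
  expect_equal(adjusted_rand_index(m1$partition$community,
                                   m2$partition$community), 1)
  # and identical seed reproduces the object exactly
  m3 <- mrcc(tn, seed = 1, n_samples = 200, n_null = 5000)
  expect_identical(m1$partition, m3$partition)
  expect_identical(m1$null_threshold, m3$null_threshold)
})

test_that("MRCC is invariant to region ordering", {
  cohort <- one_group_cohort(150, within_r = 0.7, between_r = 0, seed = 45,
                             n_per_block = 5)
  tn <- threshold_network(covariance_matrix(cohort$table))
  m1 <- mrcc(tn, seed = 9, n_samples = 100, n_null = 2000)
  set.seed(5)
  perm <- sample(length(tn$regions))
  tn2 <- tn
  tn2$adjacency <- tn$adjacency[perm, perm]
  tn2$regions <- tn$regions[perm]
  m2 <- mrcc(tn2, seed = 9, n_samples = 100, n_null = 2000)
  joined <- merge(m1$partition, m2$partition, by = "region")
  expect_equal(adjusted_rand_index(joined$community.x, joined$community.y), 1)
})

test_that("a network with no positive edges collapses to one community", {
  adj <- matrix(-0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(adj) <- 0
  expect_warning(m <- mrcc(as_tnet(adj), seed = 1), "positive")
  expect_equal(m$k, 1L)
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(46)
  for (i in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 1)), 1)
})

test_that("count_communities counts distinct labels", {
  expect_equal(count_communities(rep(1L, 27)), 1L)
  expect_equal(count_communities(1:27), 27L)
  set.seed(47)
  for (i in 1:10) {
    labels <- sample(1:6, 27, replace = TRUE)
    expect_equal(count_communities(labels), length(unique(labels)))
    expect_equal(count_communities(tibble::tibble(community = labels)),
                 length(unique(labels)))
  }
})

test_that("partition imposition averages member regions per animal", {
  cohort <- one_group_cohort(8, seed = 48, n_per_block = 3)$table
  regs <- setdiff(region_cols(cohort), "Cerebellum")
  part <- tibble::tibble(region = regs,
                         community = rep(1:3, each = 3))
  means <- impose_partition(part, cohort)
  # oracle: group-by mean recomputed directly
  for (i in seq_len(nrow(cohort))) {
    for (cm in 1:3) {
      members <- part$region[part$community == cm]
      expect_equal(
        means$mean_suvr[means$animal_id == cohort$animal_id[i] &
                          means$community == cm],
        mean(as.numeric(cohort[i, members])))
    }
  }
  # all regions in one community -> row mean; singleton -> the region itself
  one <- impose_partition(tibble::tibble(region = regs, community = 1L),
                          cohort)
  expect_equal(one$mean_suvr, rowMeans(cohort[regs]))
  single <- impose_partition(
    tibble::tibble(region = regs, community = seq_along(regs)), cohort)
  expect_equal(single$mean_suvr[single$community == 1], cohort[[regs[1]]])
})

test_that("imposition rejects tables with unpartitioned regions", {
  cohort <- one_group_cohort(6, seed = 49, n_per_block = 3)$table
  regs <- setdiff(region_cols(cohort), "Cerebellum")
  part <- tibble::tibble(region = regs[-1], community = 1L)
  expect_error(impose_partition(part, cohort), regs[1])
})

test_that("equal-size communities average back to the global mean", {
  cohort <- one_group_cohort(7, seed = 50, n_per_block = 3)$table
  regs <- setdiff(region_cols(cohort), "Cerebellum")
  part <- tibble::tibble(region = regs, community = rep(1:3, each = 3))
  means <- impose_partition(part, cohort)
  per_animal <- tapply(means$mean_suvr, means$animal_id, mean)
  expect_equal(as.numeric(per_animal[cohort$animal_id]),
               as.numeric(rowMeans(cohort[regs])), tolerance = 1e-12)
})

test_that("two-group community ANOVA equals the squared pooled t test", {
  set.seed(51)
  mk <- function(n, shift = 0) {
    tibble::tibble(animal_id = paste0("x", 1:n, "_", shift),
                   community = rep(1:2, each = n)[1:n],
                   mean_suvr = rnorm(n, 1 + shift, 0.1))
  }
  a <- dplyr::bind_rows(mk(6), dplyr::mutate(mk(6), community = 2))
  b <- dplyr::bind_rows(mk(6, 0.3), dplyr::mutate(mk(6, 0.3), community = 2))
  res <- community_anova(a, b)
  for (cm in 1:2) {
    xa <- a$mean_suvr[a$community == cm]
    xb <- b$mean_suvr[b$community == cm]
    tt <- stats::t.test(xa, xb, var.equal = TRUE)
    expect_equal(res$f_statistic[res$community == cm],
                 unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p_value[res$community == cm], tt$p.value,
                 tolerance = 1e-10)
    expect_equal(res$p_bonferroni[res$community == cm],
                 min(1, tt$p.value * 2), tolerance = 1e-12)
  }
})

test_that("identical groups give F = 0 and degenerate inputs are reported", {
  a <- tibble::tibble(animal_id = paste0("a", 1:4), community = 1L,
                      mean_suvr = c(1, 1.1, 0.9, 1.05))
  res <- community_anova(a, dplyr::mutate(a, animal_id = paste0("b", 1:4)))
  expect_equal(res$f_statistic, 0)
  expect_equal(res$p_value, 1)
  const <- tibble::tibble(animal_id = paste0("c", 1:3), community = 1L,
                          mean_suvr = 1)
  res2 <- community_anova(const,
                          dplyr::mutate(const, animal_id = paste0("d", 1:3)))
  expect_true(is.na(res2$f_statistic))
  expect_match(res2$note, "undefined")
})

test_that("only communities with a planted shift survive Bonferroni", {
  set.seed(52)
  hits <- replicate(60, {
    n <- 12
    a <- tibble::tibble(animal_id = rep(paste0("a", 1:n), 3),
                        community = rep(1:3, each = n),
                        mean_suvr = rnorm(3 * n, 1, 0.05))
    b <- tibble::tibble(animal_id = rep(paste0("b", 1:n), 3),
                        community = rep(1:3, each = n),
                        mean_suvr = rnorm(3 * n, 1, 0.05) +
                          rep(c(0.1, 0, 0), each = n))
    res <- community_anova(a, b)
    c(shifted = res$p_bonferroni[1] < 0.05,
      false_pos = any(res$p_bonferroni[2:3] < 0.05))
  })
  expect_gte(mean(hits["shifted", ]), 0.9)
  expect_lte(mean(hits["false_pos", ]), 0.1)
})
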