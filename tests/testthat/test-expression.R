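make_design <- function(n = 77, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    animal_id = sprintf("a%03d", 1:n),
    sex = sample(c("male", "female"), n, replace = TRUE),
    genotype = sample(c("WT", "5XFAD"), n, replace = TRUE),
    treatment = sample(c("vehicle", "low", "medium", "high"), n,
                       replace = TRUE),
    auc = ifelse(sample(c(TRUE, FALSE), n, replace = TRUE),
                 runif(n, 20, 250), 0))
}

expr_from_design <- function(design, genes, noise_sd = 0.1, seed = 2,
                             beta_auc = 0, beta_sex = 0) {
  spec <- expression_sim_spec(genes = genes, beta_auc = beta_auc,
                              beta_sex = beta_sex, noise_sd = noise_sd,
                              seed = seed)
  generate_expression(spec, design$auc, design$sex, design$animal_id) |>
    dplyr::left_join(design[c("animal_id", "genotype", "treatment")],
                     by = "animal_id")
}

test_that("factor-model coefficients match an independent normal-equations solve", {
  design <- make_design(seed = 61)
  expr <- expr_from_design(design, paste0("g", 1:3), seed = 62)
  fits <- de_linear_model(expr)
  d1 <- expr[expr$gene == "g1", ]
  x <- stats::model.matrix(~ genotype + sex + treatment, data = d1)
  beta <- ols_oracle(x, d1$log2_intensity)
  fit_lm <- lm(log2_intensity ~ genotype + sex + treatment, data = d1)
  expect_equal(unname(coef(fit_lm)), unname(beta), tolerance = 1e-10)
  # marginal F per factor from nested RSS computed by hand
  rss <- function(xm) {
    b <- ols_oracle(xm, d1$log2_intensity)
    sum((d1$log2_intensity - xm %*% b)^2)
  }
  rss_full <- rss(x)
  df_res <- nrow(d1) - ncol(x)
  got <- fits[fits$gene == "g1", ]
  for (fac in c("genotype", "sex", "treatment")) {
    keep <- !startsWith(colnames(x), fac)
    rss_red <- rss(x[, keep, drop = FALSE])
    df_fac <- sum(!keep)
    f_oracle <- ((rss_red - rss_full) / df_fac) / (rss_full / df_res)
    expect_equal(got$f_statistic[got$factor == fac], f_oracle,
                 tolerance = 1e-10)
    expect_equal(got$p_value[got$factor == fac],
                 pf(f_oracle, df_fac, df_res, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("a pure noiseless sex effect is attributed to sex alone", {
  design <- make_design(seed = 63)
  spec <- expression_sim_spec(genes = "g", beta_auc = 0, beta_sex = 0.5,
                              noise_sd = 1e-8, seed = 64)
  expr <- generate_expression(spec, design$auc * 0, design$sex,
                              design$animal_id) |>
    dplyr::left_join(design[c("animal_id", "genotype", "treatment")],
                     by = "animal_id")
  fit <- de_linear_model(expr)
  expect_lt(fit$p_value[fit$factor == "sex"], 1e-10)
  expect_gt(min(fit$p_value[fit$factor != "sex"]), 0.05)
})

test_that("null genes are flagged at the familywise rate implied by three factor tests", {
  design <- make_design(seed = 65)
  rates <- sapply(1:10, function(i) {
    expr <- expr_from_design(design, paste0("g", 1:50), noise_sd = 0.2,
                             seed = 600 + i)
    fits <- de_linear_model(expr)
    per_factor <- mean(fits$p_value < 0.05)
    gene_flag <- mean(tapply(fits$significant, fits$gene, any))
    c(per_factor, gene_flag)
  })
  n_tests <- 10 * 50 * 3
  per_factor_rate <- mean(rates[1, ])
  ci <- 0.05 + c(-1, 1) * 3 * sqrt(0.05 * 0.95 / n_tests)
  expect_gt(per_factor_rate, ci[1])
  expect_lt(per_factor_rate, ci[2])
  # familywise flag rate near 1 - (1 - alpha)^3 for three near-independent tests
  expect_gt(mean(rates[2, ]), 0.09)
  expect_lt(mean(rates[2, ]), 0.20)
})

test_that("delta-from-vehicle is the group-by mean difference", {
  design <- make_design(seed = 66)
  expr <- expr_from_design(design, c("g1", "g2"), seed = 67)
  deltas <- delta_from_vehicle(expr)
  for (g in c("g1", "g2")) {
    for (sx in c("male", "female")) {
      veh <- mean(expr$log2_intensity[expr$gene == g & expr$sex == sx &
                                        expr$treatment == "vehicle"])
      for (trt in c("low", "medium", "high")) {
        got <- deltas$delta[deltas$gene == g & deltas$sex == sx &
                              deltas$treatment == trt]
        oracle <- mean(expr$log2_intensity[expr$gene == g & expr$sex == sx &
                                             expr$treatment == trt]) - veh
        expect_equal(got, oracle, tolerance = 1e-12)
      }
    }
  }
  # vehicle against itself is identically zero
  veh_rows <- deltas[deltas$treatment == "vehicle", ]
  expect_true(all(abs(veh_rows$delta) < 1e-12))
})

test_that("delta-from-vehicle is translation equivariant and supports a WT baseline", {
  design <- make_design(seed = 68)
  expr <- expr_from_design(design, "g1", seed = 69)
  shifted <- dplyr::mutate(expr, log2_intensity = log2_intensity +
                             ifelse(treatment == "high", 0.7, 0))
  d0 <- delta_from_vehicle(expr)
  d1 <- delta_from_vehicle(shifted)
  joined <- dplyr::inner_join(d0, d1, by = c("gene", "sex", "treatment"))
  expect_equal(joined$delta.y - joined$delta.x,
               ifelse(joined$treatment == "high", 0.7, 0), tolerance = 1e-12)
  wt <- delta_from_vehicle(expr, baseline = "wt_vehicle")
  g <- "g1"; sx <- "male"
  base <- mean(expr$log2_intensity[expr$gene == g & expr$sex == sx &
                                     expr$genotype == "WT" &
                                     expr$treatment == "vehicle"])
  oracle <- mean(expr$log2_intensity[expr$gene == g & expr$sex == sx &
                                       expr$genotype != "WT" &
                                       expr$treatment == "high"]) - base
  expect_equal(wt$delta[wt$gene == g & wt$sex == sx &
                          wt$treatment == "high"], oracle, tolerance = 1e-12)
})

test_that("exposure model output matches lm and the R^2 decomposition", {
  design <- make_design(seed = 70)
  expr <- expr_from_design(design, "g1", noise_sd = 0.15, seed = 71,
                           beta_auc = 0.0008, beta_sex = -0.07)
  fit <- gene_exposure_model(expr)
  d <- expr[expr$gene == "g1", ]
  x <- cbind(1, d$auc, as.numeric(d$sex == "female"))
  beta <- ols_oracle(x, d$log2_intensity)
  expect_equal(fit$beta_auc, unname(beta[2]), tolerance = 1e-10)
  expect_equal(fit$beta_sex, unname(beta[3]), tolerance = 1e-10)
  resid <- d$log2_intensity - x %*% beta
  r2 <- 1 - sum(resid^2) /
    sum((d$log2_intensity - mean(d$log2_intensity))^2)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)
  # sex coding flips the sign of beta_sex
  flipped <- gene_exposure_model(expr, sex_reference = "female")
  expect_equal(flipped$beta_sex, -fit$beta_sex, tolerance = 1e-12)
})

test_that("exposure-model estimates cover the truth at the nominal rate", {
  beta_auc_true <- 0.00075
  beta_sex_true <- -0.069
  cover <- sapply(1:200, function(i) {
    spec <- expression_sim_spec(genes = "g", beta_auc = beta_auc_true,
                                beta_sex = beta_sex_true, noise_sd = 0.12,
                                seed = 8000 + i)
    set.seed(8000 + i)
    auc <- c(runif(60, 20, 250), rep(0, 17))
    sexes <- sample(rep(c("male", "female"), length.out = 77))
    fit <- gene_exposure_model(generate_expression(spec, auc, sexes))
    c(abs(fit$beta_auc - beta_auc_true) <= 2 * fit$se_auc,
      abs(fit$beta_sex - beta_sex_true) <= 2 * fit$se_sex)
  })
  expect_gte(mean(cover[1, ]), 0.9)
  expect_gte(mean(cover[2, ]), 0.9)
})

test_that("model fits are invariant to row ordering and constant AUC is flagged", {
  design <- make_design(seed = 72)
  expr <- expr_from_design(design, c("g1", "g2"), seed = 73)
  set.seed(74)
  shuffled <- expr[sample(nrow(expr)), ]
  expect_equal(gene_exposure_model(expr)[c("beta_auc", "beta_sex")],
               gene_exposure_model(shuffled)[c("beta_auc", "beta_sex")],
               tolerance = 1e-12)
  const <- dplyr::mutate(expr, auc = 5)
  fit <- gene_exposure_model(const)
  expect_false(any(fit$estimable))
})

test_that("network-summary exposure model reports exact and null relationships", {
  set.seed(75)
  d <- tibble::tibble(metric = "mean_degree",
                      auc = rep(c(0, 30, 90, 170), 2),
                      sex = rep(c("male", "female"), each = 4))
  exact <- dplyr::mutate(d, value = 2 + 0.01 * auc)
  fit <- network_metric_exposure_model(exact)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$beta_auc, 0.01, tolerance = 1e-10)
  # independence: rejection rate near alpha across replicates
  rejections <- replicate(300, {
    nulls <- dplyr::mutate(d, value = rnorm(8))
    network_metric_exposure_model(nulls)$p_auc < 0.05
  })
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 300) + 0.01)
})
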