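.assert_expression <- function(expr, need = c("animal_id", "gene", "log2_intensity"),
                               call = rlang::caller_env()) {
  if (!all(need %in% names(expr))) {
    abort(paste("Expression table must have columns:", toString(need)),
          call = call)
  }
  if (anyNA(expr$log2_intensity) || any(!is.finite(expr$log2_intensity))) {
    abort("Expression values must be finite.", call = call)
  }
  invisible(expr)
}

#' Per-gene linear models of genotype, sex and treatment
#'
#' Ordinary least squares of log2 intensity on the three design factors as
#' categorical predictors, gene by gene. Each factor is judged by its
#' marginal (drop-one) partial F test, so the verdict does not depend on
#' factor order. A gene is flagged significant when
#' any factor's partial F test has p < `alpha`; raw p-values are reported
#' (no multiple-testing correction, matching the screening use), with an
#' optional Benjamini-Hochberg column for users who want one.
#'
#' @param expr Long expression table with columns `animal_id`, `gene`,
#'   `log2_intensity`, `genotype`, `sex`, `treatment`.
#' @param alpha Per-factor significance level for flagging.
#' @param fdr Also append BH-adjusted p per factor across genes.
#' @return A tibble, one row per gene x factor: `gene`, `factor`, `df`,
#'   `f_statistic`, `p_value`, (`p_bh`), `significant` (gene-level flag),
#'   `estimable`.
#' @export
de_linear_model <- function(expr, alpha = 0.05, fdr = FALSE) {
  .assert_expression(expr, c("animal_id", "gene", "log2_intensity",
                             "genotype", "sex", "treatment"))
  factors <- c("genotype", "sex", "treatment")
  used <- factors[vapply(factors, function(f) {
    length(unique(expr[[f]])) >= 2L
  }, logical(1))]
  if (length(used) == 0L) abort("No factor has 2+ levels.")
  fml <- stats::reformulate(used, response = "log2_intensity")
  out <- expr |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(function(d, key) {
      fit <- lm(fml, data = d)
      if (any(is.na(coef(fit)))) {
        return(tibble::tibble(factor = used, df = NA_integer_,
                              f_statistic = NA_real_, p_value = NA_real_,
                              estimable = FALSE))
      }
      an <- suppressWarnings(stats::drop1(fit, test = "F"))
      tibble::tibble(factor = used,
                     df = an[used, "Df"],
                     f_statistic = an[used, "F value"],
                     p_value = an[used, "Pr(>F)"],
                     estimable = TRUE)
    }) |>
    dplyr::ungroup()
  if (fdr) {
    out <- out |>
      dplyr::group_by(.data$factor) |>
      dplyr::mutate(p_bh = stats::p.adjust(.data$p_value, "BH")) |>
      dplyr::ungroup()
  }
  out |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(significant = any(.data$p_value < alpha, na.rm = TRUE)) |>
    dplyr::ungroup()
}

#' Per-gene mean expression change from the vehicle group
#'
#' For each gene, sex and treatment: mean log2 intensity in the treated
#' group minus mean log2 intensity in the matching vehicle group (the
#' heat-map summary of treatment response). The baseline is either each
#' sex's vehicle group of the same genotype (`"matched"`, default on
#' genotype-pure tables) or the sex-matched wild-type vehicle group
#' (`"wt_vehicle"`).
#'
#' @param expr Long expression table with `sex`, `treatment` (and `genotype`
#'   when `baseline = "wt_vehicle"`).
#' @param baseline `"matched"` or `"wt_vehicle"`.
#' @return A tibble: `gene`, `sex`, `treatment`, `delta` (log2 units), with
#'   `NA` delta and a warning when a sex lacks a vehicle baseline.
#' @export
delta_from_vehicle <- function(expr, baseline = c("matched", "wt_vehicle")) {
  baseline <- match.arg(baseline)
  need <- c("animal_id", "gene", "log2_intensity", "sex", "treatment")
  if (baseline == "wt_vehicle") need <- c(need, "genotype")
  .assert_expression(expr, need)
  base_tbl <- if (baseline == "wt_vehicle") {
    dplyr::filter(expr, .data$genotype == "WT", .data$treatment == "vehicle")
  } else {
    dplyr::filter(expr, .data$treatment == "vehicle")
  }
  base_means <- base_tbl |>
    dplyr::group_by(.data$gene, .data$sex) |>
    dplyr::summarise(base_mean = mean(.data$log2_intensity), .groups = "drop")
  trt <- expr
  if (baseline == "wt_vehicle") trt <- dplyr::filter(trt, .data$genotype != "WT")
  out <- trt |>
    dplyr::group_by(.data$gene, .data$sex, .data$treatment) |>
    dplyr::summarise(trt_mean = mean(.data$log2_intensity), .groups = "drop") |>
    dplyr::left_join(base_means, by = c("gene", "sex")) |>
    dplyr::mutate(delta = .data$trt_mean - .data$base_mean) |>
    dplyr::select("gene", "sex", "treatment", "delta")
  if (anyNA(out$delta)) {
    warn("Some sexes lack a vehicle baseline; their deltas are NA.")
  }
  out
}

#' Per-gene exposure-by-sex linear models
#'
#' The PK/PD stage: for each gene, `lm(log2_intensity ~ auc + sex)` with
#' AUC continuous (mg.h/L) and sex an indicator (male is the reference
#' level, so `beta_sex` is the additive female effect; the sign flips under
#' the opposite coding).
#'
#' @param expr Long expression table with per-animal `auc` and `sex`.
#' @param sex_reference Reference sex level (default `"male"`).
#' @return A `gene_exposure_fit` tibble: `gene`, `beta_auc`, `se_auc`,
#'   `p_auc`, `beta_sex`, `se_sex`, `p_sex`, `r_squared`, `n`, `estimable`.
#' @export
gene_exposure_model <- function(expr, sex_reference = "male") {
  .assert_expression(expr, c("animal_id", "gene", "log2_intensity", "auc",
                             "sex"))
  if (length(unique(expr$sex)) < 2L) {
    abort("Both sexes must be present to estimate the sex effect.")
  }
  out <- expr |>
    dplyr::mutate(sex = stats::relevel(factor(.data$sex), ref = sex_reference)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(function(d, key) {
      if (var(d$auc) == 0) {
        return(tibble::tibble(beta_auc = NA_real_, se_auc = NA_real_,
                              p_auc = NA_real_, beta_sex = NA_real_,
                              se_sex = NA_real_, p_sex = NA_real_,
                              r_squared = NA_real_, n = nrow(d),
                              estimable = FALSE))
      }
      fit <- lm(log2_intensity ~ auc + sex, data = d)
      sm <- suppressWarnings(summary(fit))
      co <- sm$coefficients
      tibble::tibble(beta_auc = co["auc", 1L], se_auc = co["auc", 2L],
                     p_auc = co["auc", 4L],
                     beta_sex = co[3L, 1L], se_sex = co[3L, 2L],
                     p_sex = co[3L, 4L],
                     r_squared = sm$r.squared, n = nrow(d), estimable = TRUE)
    }) |>
    dplyr::ungroup()
  class(out) <- c("gene_exposure_fit", class(out))
  out
}

#' Exposure-by-sex regression of network summaries
#'
#' Multi-linear regression of each global network summary (mean degree,
#' density, mean positive/negative strength, mean clustering) on group
#' exposure and sex. The scientific expectation for chronic-dosing PET data
#' is a null result; the function reports the full fit either way and never
#' asserts.
#'
#' @param metrics Data frame with one row per group x metric: columns
#'   `metric`, `value`, `auc`, `sex`.
#' @param sex_reference Reference sex level.
#' @return A tibble per metric: `metric`, `beta_auc`, `se_auc`, `p_auc`,
#'   `beta_sex`, `se_sex`, `p_sex`, `r_squared`, `n`, `estimable`.
#' @export
network_metric_exposure_model <- function(metrics, sex_reference = "male") {
  need <- c("metric", "value", "auc", "sex")
  if (!all(need %in% names(metrics))) {
    abort(paste("`metrics` must have columns:", toString(need)))
  }
  metrics |>
    dplyr::mutate(sex = stats::relevel(factor(.data$sex), ref = sex_reference)) |>
    dplyr::group_by(.data$metric) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 4L || var(d$auc) == 0 || length(unique(d$sex)) < 2L) {
        return(tibble::tibble(beta_auc = NA_real_, se_auc = NA_real_,
                              p_auc = NA_real_, beta_sex = NA_real_,
                              se_sex = NA_real_, p_sex = NA_real_,
                              r_squared = NA_real_, n = nrow(d),
                              estimable = FALSE))
      }
      fit <- lm(value ~ auc + sex, data = d)
      sm <- suppressWarnings(summary(fit))
      co <- sm$coefficients
      tibble::tibble(beta_auc = co["auc", 1L], se_auc = co["auc", 2L],
                     p_auc = co["auc", 4L],
                     beta_sex = co[3L, 1L], se_sex = co[3L, 2L],
                     p_sex = co[3L, 4L],
                     r_squared = sm$r.squared, n = nrow(d), estimable = TRUE)
    }) |>
    dplyr::ungroup()
}

#' Correlate expression deltas with a module signature
#'
#' Generic utility: Pearson correlation between per-gene expression deltas
#' and a user-supplied module signature vector (e.g. a human co-expression
#' module's effect sizes), matched by gene name.
#'
#' @param deltas Tibble from [delta_from_vehicle()] (or any tibble with
#'   `gene` and a numeric column named by `value_col`).
#' @param signature Named numeric vector: gene -> signature value.
#' @param value_col Column of `deltas` to correlate.
#' @return A one-row tibble: `r`, `p_value`, `n_genes`.
#' @export
module_signature_correlation <- function(deltas, signature, value_col = "delta") {
  common <- intersect(deltas$gene, names(signature))
  if (length(common) < 3L) abort("Need at least 3 shared genes.")
  d <- deltas[match(common, deltas$gene), ]
  ct <- stats::cor.test(d[[value_col]], signature[common])
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n_genes = length(common))
}
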