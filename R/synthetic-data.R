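#' Specification for a synthetic SUVr cohort
#'
#' Describes a multi-group imaging cohort whose regional SUVr values are drawn
#' from a multivariate normal with a block-constant ("planted community")
#' correlation structure: pairs of regions within the same planted block share
#' correlation `within_block_r`, pairs in different blocks share
#' `between_block_r`. Group (sex x genotype x treatment) effects enter the
#' per-region means only, so the covariance structure every network stage
#' assumes is known exactly and recoverable.
#'
#' @param n_per_group Animals per sex x genotype x treatment arm.
#' @param regions Ordered character vector of bilateral region names. The
#'   default is the packaged 27-region mouse atlas (see [region_pairing()]);
#'   the reference region is handled separately via `reference`.
#' @param planted_partition Integer vector (named by region, or in region
#'   order) assigning each region to a planted block. Default: three
#'   contiguous equal blocks.
#' @param within_block_r,between_block_r Target Pearson correlations inside /
#'   across planted blocks, each in \[-1, 1\]. The implied correlation matrix
#'   must be positive semi-definite; this is validated before any sampling.
#' @param group_design Data frame with columns `sex`, `genotype`, `treatment`
#'   (one row per arm). Default: WT vehicle plus 5XFAD vehicle/low/medium/high
#'   in both sexes, mirroring a chronic dosing study design.
#' @param group_mean_shifts Optional data frame (`sex`, `treatment`, then one
#'   column per shifted region) of additive per-region mean SUVr offsets.
#' @param base_mean Baseline regional SUVr mean (unitless; cerebellum-scaled
#'   uptake sits near 1).
#' @param noise_sd Residual (per-region marginal) standard deviation of SUVr.
#' @param reference Name of the reference region column appended to the table
#'   (independent, mean 1); `NULL` to omit.
#' @param reference_sd Marginal SD of the reference region.
#' @param seed Integer seed; the generator is a pure function of (spec, seed).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 10,
                        regions = default_regions(),
                        planted_partition = NULL,
                        within_block_r = 0.6,
                        between_block_r = 0.1,
                        group_design = default_group_design(),
                        group_mean_shifts = NULL,
                        base_mean = 1,
                        noise_sd = 0.1,
                        reference = "Cerebellum",
                        reference_sd = 0.05,
                        seed = 1L) {
  .check_scalar_num(n_per_group, "n_per_group", lower = 1)
  .check_scalar_num(within_block_r, "within_block_r", -1, 1)
  .check_scalar_num(between_block_r, "between_block_r", -1, 1)
  .check_scalar_num(noise_sd, "noise_sd", lower = 0)
  stopifnot(is.character(regions), length(regions) >= 2L,
            !anyDuplicated(regions))
  if (!is.null(reference) && reference %in% regions) {
    abort("`reference` must not also appear in `regions`.")
  }
  if (is.null(planted_partition)) {
    planted_partition <- setNames(
      sort(rep_len(1:3, length(regions))), regions)
  }
  if (is.null(names(planted_partition))) {
    names(planted_partition) <- regions
  }
  if (!setequal(names(planted_partition), regions)) {
    abort("`planted_partition` must assign every region exactly once.")
  }
  planted_partition <- planted_partition[regions]
  corr <- .block_correlation(planted_partition, within_block_r, between_block_r)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort(sprintf(
      "Implied region correlation matrix is not positive semi-definite (smallest eigenvalue %.3g).",
      min(ev)))
  }
  structure(
    list(n_per_group = n_per_group, regions = regions,
         planted_partition = planted_partition,
         within_block_r = within_block_r, between_block_r = between_block_r,
         group_design = group_design, group_mean_shifts = group_mean_shifts,
         base_mean = base_mean, noise_sd = noise_sd,
         reference = reference, reference_sd = reference_sd,
         correlation = corr, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic SUVr cohort spec\n")
  cat(sprintf("  %d regions in %d planted blocks; r_within = %g, r_between = %g\n",
              length(x$regions), length(unique(x$planted_partition)),
              x$within_block_r, x$between_block_r))
  cat(sprintf("  %d arms x %d animals; noise_sd = %g; seed = %d\n",
              nrow(x$group_design), x$n_per_group, x$noise_sd, x$seed))
  invisible(x)
}

#' Packaged bilateral atlas region names (reference region excluded)
#' @param include_reference Also append `"Cerebellum"`.
#' @return Character vector of 27 (or 28) region names.
#' @export
default_regions <- function(include_reference = FALSE) {
  pr <- region_pairing()
  regs <- unique(pr$bilateral)
  if (!include_reference) regs <- setdiff(regs, "Cerebellum")
  regs
}

#' Default chronic-dosing study design
#'
#' Wild-type vehicle controls plus transgenic arms at vehicle and three
#' chronic dose levels, in both sexes.
#' @return A tibble with columns `sex`, `genotype`, `treatment`.
#' @export
default_group_design <- function() {
  tidyr::expand_grid(
    sex = c("male", "female"),
    genotype = "5XFAD",
    treatment = c("vehicle", "low", "medium", "high")) |>
    dplyr::bind_rows(tidyr::expand_grid(
      sex = c("male", "female"), genotype = "WT", treatment = "vehicle"))
}

.block_correlation <- function(partition, within_r, between_r) {
  same <- outer(partition, partition, "==")
  corr <- ifelse(same, within_r, between_r)
  diag(corr) <- 1
  dimnames(corr) <- list(names(partition), names(partition))
  corr
}

# Draw n samples from N(0, C) given a correlation matrix C (possibly rank
# deficient, e.g. within_block_r = 1), via symmetric eigen square root.
.rmvnorm_corr <- function(n, corr) {
  e <- eigen(corr, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  rt <- e$vectors %*% (sqrt(vals) * t(e$vectors))
  z <- matrix(rnorm(n * ncol(corr)), n, ncol(corr))
  z %*% rt
}

#' Generate a synthetic SUVr cohort table
#'
#' Samples one row per animal from the multivariate normal implied by the
#' spec's planted block-correlation structure, applies per-group mean shifts,
#' and attaches metadata columns. Identical spec and seed give a
#' byte-identical table.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble: `animal_id`, `sex`, `genotype`, `treatment`, then one
#'   column per region (plus the reference region, if specified).
#' @export
generate_suvr_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(.derive_seed(spec$seed, "suvr"))
  design <- spec$group_design
  p <- length(spec$regions)
  rows <- purrr::pmap(design, function(sex, genotype, treatment) {
    n <- spec$n_per_group
    x <- .rmvnorm_corr(n, spec$correlation) * spec$noise_sd
    mu <- rep(spec$base_mean, p)
    if (!is.null(spec$group_mean_shifts)) {
      hit <- spec$group_mean_shifts$sex == sex &
        spec$group_mean_shifts$treatment == treatment
      if (any(hit)) {
        sh <- spec$group_mean_shifts[which(hit)[1L], , drop = FALSE]
        for (r in intersect(names(sh), spec$regions)) {
          mu[match(r, spec$regions)] <- mu[match(r, spec$regions)] + sh[[r]]
        }
      }
    }
    x <- sweep(x, 2L, mu, "+")
    colnames(x) <- spec$regions
    out <- tibble::as_tibble(x)
    if (!is.null(spec$reference)) {
      out[[spec$reference]] <- 1 + rnorm(n, 0, spec$reference_sd)
    }
    dplyr::bind_cols(
      tibble::tibble(sex = sex, genotype = genotype, treatment = treatment),
      out)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out,
    animal_id = sprintf("m%03d", dplyr::row_number()), .before = 1L)
  out
}

#' Specification for simulated plasma concentration profiles
#'
#' One-compartment first-order-absorption kinetics with lognormal
#' between-subject variability on CL/F and V/F, allometric weight scaling,
#' an optional dose covariate, and proportional residual error. Defaults
#' mirror a single-dose mouse PK study: 3 animals per sex at 10, 30 and
#' 100 mg/kg, sampled 0.25-24 h post-dose.
#'
#' @param params A [pk_params()] set of structural parameters.
#' @param doses_mg_per_kg Dose levels (mg/kg).
#' @param n_per_dose_per_sex Animals per dose per sex.
#' @param weights_kg Either a single mean body weight (kg) around which
#'   animal weights are drawn lognormally with `weight_cv`, or a vector of
#'   one weight per animal.
#' @param weight_cv Coefficient of variation for drawn body weights.
#' @param bsv_sd Lognormal between-subject SD applied to CL/F and V/F.
#' @param prop_error_sd Proportional residual error SD.
#' @param sample_times_h Sampling times (h), strictly increasing, all > 0.
#' @param seed Integer seed.
#' @return An object of class `pk_sim_spec`.
#' @export
pk_sim_spec <- function(params = pk_params(),
                        doses_mg_per_kg = c(10, 30, 100),
                        n_per_dose_per_sex = 3,
                        weights_kg = 0.025,
                        weight_cv = 0.1,
                        bsv_sd = 0.2,
                        prop_error_sd = 0.15,
                        sample_times_h = c(0.25, 0.5, 1, 2, 4, 6, 24),
                        seed = 1L) {
  stopifnot(inherits(params, "pk_params"))
  if (any(doses_mg_per_kg <= 0)) abort("All doses must be > 0.")
  if (any(sample_times_h < 0) || is.unsorted(sample_times_h, strictly = TRUE)) {
    abort("`sample_times_h` must be non-negative and strictly increasing.")
  }
  .check_scalar_num(bsv_sd, "bsv_sd", lower = 0)
  .check_scalar_num(prop_error_sd, "prop_error_sd", lower = 0)
  structure(
    list(params = params, doses_mg_per_kg = doses_mg_per_kg,
         n_per_dose_per_sex = n_per_dose_per_sex, weights_kg = weights_kg,
         weight_cv = weight_cv, bsv_sd = bsv_sd,
         prop_error_sd = prop_error_sd, sample_times_h = sample_times_h,
         seed = as.integer(seed)),
    class = "pk_sim_spec")
}

#' Simulate per-animal concentration-time profiles
#'
#' Individual parameters are the structural typical values scaled
#' allometrically to each animal's weight, adjusted by the dose covariate,
#' and multiplied by lognormal between-subject deviations; observations are
#' the closed-form model prediction times `(1 + proportional error)`.
#' Negative post-error concentrations are truncated at zero (a count is
#' attached as attribute `n_truncated`).
#'
#' @param spec A [pk_sim_spec()].
#' @return A tibble with columns `animal_id`, `sex`, `dose_mg_per_kg`,
#'   `weight_kg`, `eta_cl`, `eta_v`, `time_h`, `conc_ng_per_ml`.
#' @export
generate_pk_profiles <- function(spec) {
  stopifnot(inherits(spec, "pk_sim_spec"))
  set.seed(.derive_seed(spec$seed, "pk"))
  design <- tidyr::expand_grid(sex = c("male", "female"),
                               dose_mg_per_kg = spec$doses_mg_per_kg) |>
    tidyr::uncount(spec$n_per_dose_per_sex)
  n <- nrow(design)
  if (length(spec$weights_kg) == 1L) {
    w <- spec$weights_kg * exp(rnorm(n, 0, spec$weight_cv))
  } else {
    if (length(spec$weights_kg) != n) {
      abort(sprintf("`weights_kg` must have length 1 or %d (one per animal).", n))
    }
    w <- spec$weights_kg
  }
  eta_cl <- rnorm(n, 0, spec$bsv_sd)
  eta_v <- rnorm(n, 0, spec$bsv_sd)
  design <- dplyr::mutate(design,
    animal_id = sprintf("pk%03d", dplyr::row_number()),
    weight_kg = w, eta_cl = eta_cl, eta_v = eta_v, .before = 1L)
  n_trunc <- 0L
  out <- purrr::pmap(design, function(animal_id, sex, dose_mg_per_kg,
                                      weight_kg, eta_cl, eta_v) {
    pred <- simulate_concentration(
      spec$params, dose_mg_per_kg = dose_mg_per_kg, weight_kg = weight_kg,
      times_h = spec$sample_times_h, eta_cl = eta_cl, eta_v = eta_v)
    obs <- pred$conc_ng_per_ml *
      (1 + rnorm(length(spec$sample_times_h), 0, spec$prop_error_sd))
    n_trunc <<- n_trunc + sum(obs < 0)
    tibble::tibble(animal_id = animal_id, sex = sex,
                   dose_mg_per_kg = dose_mg_per_kg, weight_kg = weight_kg,
                   eta_cl = eta_cl, eta_v = eta_v,
                   time_h = spec$sample_times_h,
                   conc_ng_per_ml = pmax(obs, 0))
  }) |> dplyr::bind_rows()
  if (n_trunc > 0L) {
    rlang::inform(sprintf("%d simulated concentrations truncated at 0.", n_trunc))
  }
  attr(out, "n_truncated") <- n_trunc
  out
}

#' Specification for simulated log2 expression
#'
#' Per-gene linear model: `log2 intensity = intercept + beta_auc * AUC +
#' beta_sex * 1[female] + N(0, noise_sd)`. Default genes and effect scales
#' mirror an exposure-response panel where AUC is measured in mg.h/L.
#'
#' @param genes Character vector of gene names.
#' @param intercept,beta_auc,beta_sex,noise_sd Numeric vectors recycled to
#'   `length(genes)`: baseline log2 intensity, slope on AUC (log2 units per
#'   mg.h/L), additive female effect (log2 units), residual SD.
#' @param seed Integer seed.
#' @return An object of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(genes = c("Amer3", "Lamp2", "Lrtm2", "Psma5", "Stat3"),
                                intercept = 8,
                                beta_auc = c(-0.0006, 0.00075, 0.00098, -0.0036, 0.001),
                                beta_sex = c(0.014, -0.069, -0.085, -0.0016, -0.11),
                                noise_sd = 0.1,
                                seed = 1L) {
  stopifnot(is.character(genes), length(genes) >= 1L)
  rec <- function(x, nm) {
    if (!length(x) %in% c(1L, length(genes))) {
      abort(sprintf("`%s` must have length 1 or length(genes) = %d.", nm,
                    length(genes)))
    }
    rep_len(x, length(genes))
  }
  structure(
    list(genes = genes, intercept = rec(intercept, "intercept"),
         beta_auc = rec(beta_auc, "beta_auc"),
         beta_sex = rec(beta_sex, "beta_sex"),
         noise_sd = rec(noise_sd, "noise_sd"), seed = as.integer(seed)),
    class = "expression_sim_spec")
}

#' Generate a synthetic log2 expression table
#'
#' @param spec An [expression_sim_spec()].
#' @param exposures Per-animal AUC (mg.h/L), aligned with `sexes`.
#' @param sexes Per-animal sex labels (`"male"`/`"female"`).
#' @param animal_ids Optional per-animal ids (default `a001`, ...).
#' @return A long tibble: `animal_id`, `sex`, `auc`, `gene`, `log2_intensity`.
#' @export
generate_expression <- function(spec, exposures, sexes, animal_ids = NULL) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  if (length(exposures) != length(sexes)) {
    abort("`exposures` and `sexes` must describe the same animals (equal length).")
  }
  if (!all(sexes %in% c("male", "female"))) {
    abort('`sexes` must be "male" or "female".')
  }
  if (is.null(animal_ids)) animal_ids <- sprintf("a%03d", seq_along(exposures))
  if (length(animal_ids) != length(exposures)) {
    abort("`animal_ids` must align with `exposures`.")
  }
  set.seed(.derive_seed(spec$seed, "expression"))
  female <- as.numeric(sexes == "female")
  purrr::imap(spec$genes, function(g, i) {
    mu <- spec$intercept[i] + spec$beta_auc[i] * exposures +
      spec$beta_sex[i] * female
    tibble::tibble(animal_id = animal_ids, sex = sexes, auc = exposures,
                   gene = g,
                   log2_intensity = mu + rnorm(length(mu), 0, spec$noise_sd[i]))
  }) |> dplyr::bind_rows()
}
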