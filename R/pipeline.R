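#' Configuration for a full pipeline run
#'
#' Bundles every stage's parameters and a master seed so that one object
#' determines the entire analysis. Group definitions are explicit in the
#' cohort spec's design, never inferred. The config round-trips losslessly
#' through [jsonlite::toJSON()] of its scalar fields (specs are rebuilt
#' from their stored arguments).
#'
#' @param cohort A [cohort_spec()] or `NULL` to use defaults with `seed`.
#' @param pk_sim A [pk_sim_spec()] or `NULL` likewise.
#' @param expression A [expression_sim_spec()] or `NULL` likewise.
#' @param alpha Edge significance threshold.
#' @param variance_fraction PCA consensus-region target.
#' @param gamma_range,n_samples,n_null MRCC settings.
#' @param reference_group Named list (`sex`, `genotype`, `treatment`)
#'   defining the reference partition group (default wild-type male
#'   vehicle).
#' @param reference_region Reference region name.
#' @param seed Master integer seed; every stochastic stage derives its own
#'   stream from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = NULL, pk_sim = NULL, expression = NULL,
                       alpha = 0.05, variance_fraction = 0.8,
                       gamma_range = c(0.5, 3), n_samples = 200L,
                       n_null = 10000L,
                       reference_group = list(sex = "male", genotype = "WT",
                                              treatment = "vehicle"),
                       reference_region = "Cerebellum", seed = 1L) {
  seed <- as.integer(seed)
  structure(
    list(cohort = cohort %||% cohort_spec(seed = seed),
         pk_sim = pk_sim %||% pk_sim_spec(seed = seed),
         expression = expression %||% expression_sim_spec(seed = seed),
         alpha = alpha, variance_fraction = variance_fraction,
         gamma_range = gamma_range, n_samples = as.integer(n_samples),
         n_null = as.integer(n_null), reference_group = reference_group,
         reference_region = reference_region, seed = seed),
    class = "run_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the end-to-end chain on data generated from the config's specs:
#' PK simulation, population fit and per-animal exposure; SUVr processing
#' and consensus-region selection; per-group covariance networks,
#' thresholding, nodal metrics and KS comparisons between groups; MRCC on
#' the reference group with imposition and community ANOVA on every other
#' group; exposure-by-sex models of gene expression and of global network
#' summaries. When `out_dir` is given, every tabular artifact is written as
#' CSV (full precision) together with a JSON manifest recording parameters,
#' seeds and artifact names; two runs with the same config are
#' byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return A named list of all stage results (invisibly also written to
#'   `out_dir`): `suvr`, `consensus_regions`, `networks`, `nodal_metrics`,
#'   `density`, `ks_comparisons`, `reference_partition`, `community_anova`,
#'   `pk_profiles`, `pk_fit`, `exposures`,
#'   `exposure_concentration`, `expression`, `gene_exposure`,
#'   `network_exposure`, `manifest`.
#' @export
run_full_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))

  # --- pharmacokinetics ------------------------------------------------
  profiles <- generate_pk_profiles(config$pk_sim)
  pk_fit <- fit_population_pk(profiles, covariates = c("dose_cl", "dose_v"),
                              start = config$pk_sim$params)
  animals_pk <- dplyr::distinct(
    profiles[c("animal_id", "sex", "dose_mg_per_kg", "weight_kg", "eta_cl")])
  exposures <- predict_individual_auc(pk_fit$params, animals_pk)
  c_half <- profiles |>
    dplyr::filter(.data$time_h == 0.5) |>
    dplyr::select("animal_id", c_half = "conc_ng_per_ml")
  exp_conc <- exposure_concentration_regression(
    dplyr::inner_join(exposures, c_half, by = "animal_id"))

  # --- SUVr processing -------------------------------------------------
  cohort <- generate_suvr_cohort(config$cohort)
  suvr <- compute_suvr(cohort, reference = config$reference_region)
  split_keys <- dplyr::distinct(suvr[c("sex", "genotype", "treatment")])
  cohort_tables <- purrr::pmap(split_keys, function(sex, genotype, treatment) {
    dplyr::filter(suvr, .data$sex == !!sex, .data$genotype == !!genotype,
                  .data$treatment == !!treatment)
  })
  names(cohort_tables) <- apply(split_keys, 1L, paste, collapse = "_")
  consensus <- select_consensus_regions(
    cohort_tables, variance_fraction = config$variance_fraction,
    reference = config$reference_region)

  # --- covariance networks --------------------------------------------
  nets <- group_networks(suvr, alpha = config$alpha,
                         reference = config$reference_region)
  ks <- .pairwise_ks(nets$metrics)

  # --- community structure --------------------------------------------
  ref_label <- paste(config$reference_group$sex, config$reference_group$genotype,
                     config$reference_group$treatment, sep = "_")
  if (!ref_label %in% names(nets$networks)) {
    abort(sprintf("Reference group `%s` not present in the cohort design.",
                  ref_label))
  }
  ref_mrcc <- mrcc(nets$networks[[ref_label]], gamma_range = config$gamma_range,
                   n_samples = config$n_samples, n_null = config$n_null,
                   seed = config$seed)
  ref_means <- impose_partition(ref_mrcc$partition,
                                cohort_tables[[ref_label]],
                                exclude = config$reference_region)
  anovas <- purrr::imap(
    cohort_tables[setdiff(names(cohort_tables), ref_label)],
    function(tab, nm) {
      cmp <- community_anova(
        ref_means,
        impose_partition(ref_mrcc$partition, tab,
                         exclude = config$reference_region),
        labels = c(ref_label, nm))
      dplyr::mutate(cmp, group = nm, .before = 1L)
    }) |> dplyr::bind_rows()

  # --- exposure-response ----------------------------------------------
  # chronic arms: map treatment levels onto per-animal exposures via the
  # fitted model (vehicle -> AUC 0)
  dose_map <- c(vehicle = 0, low = 10, medium = 30, high = 56)
  fad <- dplyr::filter(suvr, .data$genotype != "WT")
  animals_expr <- dplyr::distinct(fad[c("animal_id", "sex", "treatment")]) |>
    dplyr::mutate(dose_mg_per_kg = unname(dose_map[.data$treatment]),
                  weight_kg = config$pk_sim$weights_kg[1L])
  dosed <- dplyr::filter(animals_expr, .data$dose_mg_per_kg > 0)
  dosed <- predict_individual_auc(pk_fit$params, dosed)
  animals_expr <- dplyr::left_join(
    animals_expr, dosed[c("animal_id", "auc")], by = "animal_id") |>
    dplyr::mutate(auc = dplyr::coalesce(.data$auc, 0))
  expr <- generate_expression(config$expression, animals_expr$auc,
                              animals_expr$sex, animals_expr$animal_id) |>
    dplyr::left_join(animals_expr[c("animal_id", "treatment")],
                     by = "animal_id")
  gene_fits <- gene_exposure_model(expr)
  global_metrics <- nets$metrics |>
    dplyr::filter(.data$genotype != "WT") |>
    dplyr::group_by(.data$sex, .data$treatment) |>
    dplyr::summarise(mean_degree = mean(.data$degree),
                     mean_s_pos = mean(.data$s_pos),
                     mean_s_neg = mean(.data$s_neg),
                     mean_clustering = mean(.data$clustering),
                     .groups = "drop") |>
    dplyr::left_join(
      nets$density |>
        dplyr::filter(.data$genotype != "WT") |>
        dplyr::select("sex", "treatment", "density"),
      by = c("sex", "treatment")) |>
    tidyr::pivot_longer(cols = c("mean_degree", "mean_s_pos", "mean_s_neg",
                                 "mean_clustering", "density"),
                        names_to = "metric", values_to = "value") |>
    dplyr::left_join(
      animals_expr |>
        dplyr::group_by(.data$sex, .data$treatment) |>
        dplyr::summarise(auc = mean(.data$auc), .groups = "drop"),
      by = c("sex", "treatment"))
  net_fits <- network_metric_exposure_model(global_metrics)

  results <- list(
    suvr = suvr, consensus_regions = consensus, networks = nets$networks,
    nodal_metrics = nets$metrics, density = nets$density, ks_comparisons = ks,
    reference_partition = ref_mrcc, community_anova = anovas,
    pk_profiles = profiles, pk_fit = pk_fit, exposures = exposures,
    exposure_concentration = exp_conc, expression = expr,
    gene_exposure = gene_fits, network_exposure = net_fits)
  results$manifest <- .build_manifest(config, results)
  if (!is.null(out_dir)) .write_artifacts(results, out_dir)
  results
}

# KS comparisons of each nodal metric between every pair of groups that
# share a sex (treatment contrasts) plus male-vs-female at equal treatment.
.pairwise_ks <- function(metrics) {
  groups <- dplyr::distinct(metrics[c("sex", "genotype", "treatment")])
  labs <- apply(groups, 1L, paste, collapse = "_")
  out <- list()
  for (m in c("degree", "s_pos", "s_neg", "clustering")) {
    for (i in seq_len(nrow(groups) - 1L)) {
      for (j in seq((i + 1L), nrow(groups))) {
        same_sex <- groups$sex[i] == groups$sex[j]
        same_trt <- groups$treatment[i] == groups$treatment[j] &
          groups$genotype[i] == groups$genotype[j]
        if (!same_sex && !same_trt) next
        gi <- dplyr::semi_join(metrics, groups[i, ],
                               by = c("sex", "genotype", "treatment"))
        gj <- dplyr::semi_join(metrics, groups[j, ],
                               by = c("sex", "genotype", "treatment"))
        out[[length(out) + 1L]] <- compare_metric_distributions(
          gi[[m]], gj[[m]], metric = m, labels = c(labs[i], labs[j]))
      }
    }
  }
  dplyr::bind_rows(out)
}

.build_manifest <- function(config, results) {
  list(
    package = "suvrnet",
    version = as.character(utils::packageVersion("suvrnet")),
    seed = config$seed,
    parameters = list(
      alpha = config$alpha, variance_fraction = config$variance_fraction,
      gamma_range = config$gamma_range, n_samples = config$n_samples,
      n_null = config$n_null, reference_group = config$reference_group,
      reference_region = config$reference_region,
      n_per_group = config$cohort$n_per_group,
      within_block_r = config$cohort$within_block_r,
      between_block_r = config$cohort$between_block_r,
      noise_sd = config$cohort$noise_sd),
    artifacts = c("suvr.csv", "consensus_regions.csv", "nodal_metrics.csv",
                  "density.csv", "ks_comparisons.csv", "partition.csv",
                  "community_anova.csv", "pk_profiles.csv", "pk_fit.csv",
                  "exposures.csv", "exposure_concentration.csv",
                  "expression.csv", "gene_exposure.csv",
                  "network_exposure.csv"),
    k_reference = results$reference_partition$k,
    n_consensus_regions = length(results$consensus_regions$consensus))
}

.write_artifacts <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(results$suvr, "suvr.csv")
  wr(results$consensus_regions$report, "consensus_regions.csv")
  wr(results$nodal_metrics, "nodal_metrics.csv")
  wr(results$density, "density.csv")
  wr(results$ks_comparisons, "ks_comparisons.csv")
  wr(results$reference_partition$partition, "partition.csv")
  wr(results$community_anova, "community_anova.csv")
  wr(results$pk_profiles, "pk_profiles.csv")
  wr(tidy(results$pk_fit), "pk_fit.csv")
  wr(results$exposures, "exposures.csv")
  wr(results$exposure_concentration, "exposure_concentration.csv")
  wr(results$expression, "expression.csv")
  wr(results$gene_exposure, "gene_exposure.csv")
  wr(results$network_exposure, "network_exposure.csv")
  jsonlite::write_json(results$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
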