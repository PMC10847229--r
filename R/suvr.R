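#' Packaged unilateral-to-bilateral region pairing
#'
#' The shipped mouse brain atlas mapping: 56 unilateral (left/right) region
#' labels onto 28 bilateral regions (27 analysis regions plus the cerebellum
#' reference). Users can supply their own mapping file with the same two
#' columns to [average_bilateral()].
#'
#' @param file Optional path to a CSV with columns `unilateral`, `bilateral`
#'   overriding the packaged table.
#' @return A tibble with columns `unilateral` and `bilateral`.
#' @export
region_pairing <- function(file = NULL) {
  path <- file %||% system.file("extdata", "region_pairing.csv",
                                package = "suvrnet", mustWork = TRUE)
  pr <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("unilateral", "bilateral") %in% names(pr))) {
    abort("Pairing file must have columns `unilateral` and `bilateral`.")
  }
  if (anyDuplicated(pr$unilateral)) {
    abort("Each unilateral label must map to exactly one bilateral label.")
  }
  counts <- table(pr$bilateral)
  if (any(counts != 2L)) {
    abort(paste("Every bilateral region needs exactly two unilateral members;",
                "offending:", toString(names(counts)[counts != 2L])))
  }
  pr
}

#' Average left/right unilateral regions into bilateral regions
#'
#' Each bilateral value is the arithmetic mean of its two unilateral
#' members. Metadata columns pass through unchanged; bilateral columns
#' appear in first-member order of the pairing.
#'
#' @param data Cohort table whose region columns are unilateral labels.
#' @param pairing A pairing table from [region_pairing()].
#' @return A cohort tibble with one column per bilateral region.
#' @export
average_bilateral <- function(data, pairing = region_pairing()) {
  regs <- .assert_cohort(data)
  unmatched <- setdiff(regs, pairing$unilateral)
  if (length(unmatched) > 0L) {
    abort(paste("Unilateral regions missing from pairing:", toString(unmatched)))
  }
  pr <- dplyr::filter(pairing, .data$unilateral %in% regs)
  incomplete <- names(which(table(pr$bilateral) != 2L))
  if (length(incomplete) > 0L) {
    abort(paste("Bilateral regions missing a hemisphere in the data:",
                toString(incomplete)))
  }
  meta <- data[intersect(.meta_cols, names(data))]
  bilats <- unique(pr$bilateral)
  vals <- purrr::map(bilats, function(b) {
    members <- pr$unilateral[pr$bilateral == b]
    (data[[members[1L]]] + data[[members[2L]]]) / 2
  })
  dplyr::bind_cols(meta, tibble::as_tibble(setNames(vals, bilats)))
}

#' Normalize regional uptake to a reference region (SUVr)
#'
#' Divides every region column, animal by animal, by that animal's value in
#' the reference region, making uptake comparable across animals. The
#' reference column is retained and is identically 1 afterwards; the
#' operation is idempotent.
#'
#' @param data Cohort table (bilateral regions).
#' @param reference Reference region column name.
#' @return The cohort tibble with all region columns ratioed to the
#'   reference.
#' @export
compute_suvr <- function(data, reference = "Cerebellum") {
  regs <- .assert_cohort(data)
  if (!reference %in% regs) {
    abort(sprintf("Reference region `%s` not found among region columns.", reference))
  }
  ref <- data[[reference]]
  if (any(ref <= 0)) {
    ids <- if ("animal_id" %in% names(data)) {
      toString(data$animal_id[ref <= 0])
    } else {
      toString(which(ref <= 0))
    }
    abort(paste("Non-positive reference values for animals:", ids))
  }
  out <- data
  for (r in regs) out[[r]] <- out[[r]] / ref
  out
}

#' PCA-based consensus region selection across cohorts
#'
#' Per cohort: principal component analysis of the animal x region SUVr
#' matrix (columns z-standardized so high-mean regions do not dominate);
#' the leading components are taken until cumulative explained variance
#' reaches `variance_fraction`; each region is scored by the
#' variance-weighted sum of its squared loadings over those components
#' (scores sum to the explained fraction and are renormalized to 1); the
#' smallest top-scoring region set whose cumulative score reaches
#' `variance_fraction` is that cohort's selection. The consensus set is by
#' default the strict intersection of the per-cohort selections;
#' alternatively regions selected in at least `min_frequency` of cohorts.
#'
#' This ranking rule is one committed interpretation of "regions explaining
#' a fraction of the variance" and is isolated here so alternatives can be
#' swapped in.
#'
#' @param tables List of cohort SUVr tables (or a single table).
#' @param variance_fraction Target explained-variance fraction (default 0.8).
#' @param reference Reference region to exclude from candidacy.
#' @param method `"intersection"` (default) or `"frequency"`.
#' @param min_frequency Minimum fraction of cohorts (used when
#'   `method = "frequency"`).
#' @return A list: `consensus` (character vector, possibly empty),
#'   `per_cohort` (list of per-cohort selections), and `report` (tidy tibble
#'   of per-cohort region scores and selection flags).
#' @export
select_consensus_regions <- function(tables, variance_fraction = 0.8,
                                     reference = "Cerebellum",
                                     method = c("intersection", "frequency"),
                                     min_frequency = 0.5) {
  method <- match.arg(method)
  .check_scalar_num(variance_fraction, "variance_fraction", 0, 1)
  if (is.data.frame(tables)) tables <- list(tables)
  if (is.null(names(tables))) {
    names(tables) <- paste0("cohort", seq_along(tables))
  }
  per_cohort <- list()
  report <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    regs <- setdiff(.assert_cohort(tab), reference)
    if (nrow(tab) < 3L) {
      warn(sprintf("Cohort `%s` has fewer than 3 animals; skipped.", nm))
      next
    }
    x <- as.matrix(tab[regs])
    sds <- apply(x, 2L, sd)
    if (any(sds == 0)) {
      # constant regions carry no variance: zero score, excluded from PCA
      const <- regs[sds == 0]
      x <- x[, sds > 0, drop = FALSE]
      regs_pca <- setdiff(regs, const)
    } else {
      regs_pca <- regs
    }
    pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
    ev <- pc$sdev^2 / sum(pc$sdev^2)
    n_comp <- which(cumsum(ev) >= variance_fraction)[1L]
    load2 <- pc$rotation[, seq_len(n_comp), drop = FALSE]^2
    score <- setNames(as.numeric(load2 %*% ev[seq_len(n_comp)]), regs_pca)
    score <- score / sum(score)
    full_score <- setNames(rep(0, length(regs)), regs)
    full_score[names(score)] <- score
    ord <- order(full_score, decreasing = TRUE)
    csum <- cumsum(full_score[ord])
    k <- which(csum >= variance_fraction)[1L]
    sel <- regs[ord][seq_len(k)]
    per_cohort[[nm]] <- sel
    report[[nm]] <- tibble::tibble(
      cohort = nm, region = regs, score = unname(full_score),
      rank = match(regs, regs[ord]), selected = regs %in% sel,
      n_components = n_comp)
  }
  if (length(per_cohort) == 0L) {
    return(list(consensus = character(), per_cohort = per_cohort,
                report = tibble::tibble()))
  }
  consensus <- switch(method,
    intersection = Reduce(intersect, per_cohort),
    frequency = {
      freq <- table(unlist(per_cohort)) / length(per_cohort)
      names(freq)[freq >= min_frequency]
    })
  list(consensus = consensus, per_cohort = per_cohort,
       report = dplyr::bind_rows(report))
}
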