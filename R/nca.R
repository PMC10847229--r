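#' Noncompartmental analysis of one concentration-time profile
#'
#' Model-free exposure summary: Cmax/Tmax by argmax; AUC(0-last) by the
#' linear-up/log-down trapezoid (log interpolation on strictly declining
#' positive segments, linear otherwise); terminal slope `lambda_z` by
#' log-linear regression over the tail, choosing among the last 3..6
#' observations (Tmax excluded) the window with the best adjusted R^2;
#' `AUC(0-inf) = AUC(0-last) + C_last / lambda_z`; observed apparent
#' clearance `CL/F = dose / AUC(0-inf)`.
#'
#' When fewer than 3 positive post-Tmax points exist, or the selected tail
#' slope is non-negative, `lambda_z` and all quantities derived from it are
#' `NA` and the result is flagged non-estimable.
#'
#' @param times_h Sampling times (h), strictly increasing.
#' @param conc Concentrations (any unit; outputs follow it).
#' @param dose_mg Administered dose. AUC units follow `conc` x h; if `conc`
#'   is in mg/L, `cl_f_obs` is in L/h.
#' @return A one-row tibble: `cmax`, `tmax`, `lambda_z`, `lambda_z_n`
#'   (points used), `auc_0_last`, `auc_0_inf`, `cl_f_obs`, `estimable`.
#' @export
run_nca <- function(times_h, conc, dose_mg = NA_real_) {
  if (length(times_h) != length(conc)) abort("`times_h` and `conc` must align.")
  if (is.unsorted(times_h, strictly = TRUE)) {
    abort("`times_h` must be strictly increasing.")
  }
  if (any(conc < 0)) abort("Concentrations must be >= 0.")
  i_max <- which.max(conc)
  cmax <- conc[i_max]
  tmax <- times_h[i_max]
  auc_last <- .auc_lin_up_log_down(times_h, conc)

  lz <- .lambda_z(times_h, conc, i_max)
  if (is.na(lz$lambda_z)) {
    return(tibble::tibble(cmax = cmax, tmax = tmax, lambda_z = NA_real_,
                          lambda_z_n = NA_integer_, auc_0_last = auc_last,
                          auc_0_inf = NA_real_, cl_f_obs = NA_real_,
                          estimable = FALSE))
  }
  c_last <- conc[length(conc)]
  auc_inf <- auc_last + c_last / lz$lambda_z
  tibble::tibble(cmax = cmax, tmax = tmax, lambda_z = lz$lambda_z,
                 lambda_z_n = lz$n, auc_0_last = auc_last,
                 auc_0_inf = auc_inf, cl_f_obs = dose_mg / auc_inf,
                 estimable = TRUE)
}

# Linear trapezoid while concentrations rise or touch zero; log trapezoid
# on strictly declining positive segments.
.auc_lin_up_log_down <- function(t, c) {
  if (length(t) < 2L) return(0)
  dt <- diff(t)
  c1 <- c[-length(c)]
  c2 <- c[-1L]
  seg <- ifelse(c1 > 0 & c2 > 0 & c2 < c1,
                dt * (c1 - c2) / log(c1 / c2),
                dt * (c1 + c2) / 2)
  sum(seg)
}

# Terminal slope: log-linear OLS over candidate tails of 3..6 points drawn
# from positive observations strictly after Tmax; best adjusted R^2 wins.
.lambda_z <- function(t, c, i_max) {
  idx <- which(seq_along(c) > i_max & c > 0)
  if (length(idx) < 3L) return(list(lambda_z = NA_real_, n = NA_integer_))
  best <- list(lambda_z = NA_real_, n = NA_integer_, adj_r2 = -Inf)
  for (k in 3:min(6L, length(idx))) {
    use <- utils::tail(idx, k)
    fit <- lm(log(c[use]) ~ t[use])
    slope <- coef(fit)[2L]
    adj <- suppressWarnings(summary(fit)$adj.r.squared)
    if (slope < 0 && adj > best$adj_r2) {
      best <- list(lambda_z = -unname(slope), n = k, adj_r2 = adj)
    }
  }
  best
}

#' NCA over every animal in a concentration table
#'
#' @param profiles Tibble as produced by [generate_pk_profiles()] (columns
#'   `animal_id`, `dose_mg_per_kg`, `weight_kg`, `time_h`, `conc_ng_per_ml`,
#'   plus any metadata).
#' @return One row per animal: metadata plus the [run_nca()] columns, with
#'   `auc_0_inf` in ng.h/mL and `cl_f_obs` in L/h.
#' @export
run_nca_table <- function(profiles) {
  need <- c("animal_id", "dose_mg_per_kg", "weight_kg", "time_h", "conc_ng_per_ml")
  if (!all(need %in% names(profiles))) {
    abort(paste("`profiles` must have columns:", toString(need)))
  }
  profiles |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("animal_id", "sex", "dose_mg_per_kg", "weight_kg")))) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      res <- run_nca(d$time_h, d$conc_ng_per_ml / 1000,
                     dose_mg = key$dose_mg_per_kg * key$weight_kg)
      # back to ng/mL-based units for concentration quantities
      dplyr::mutate(res,
                    cmax = .data$cmax * 1000,
                    auc_0_last = .data$auc_0_last * 1000,
                    auc_0_inf = .data$auc_0_inf * 1000)
    }) |>
    dplyr::ungroup()
}
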