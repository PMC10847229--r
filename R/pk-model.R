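#' Structural population PK parameter set
#'
#' One-compartment, first-order absorption, oral dosing. Typical apparent
#' clearance and volume refer to an animal at `ref_weight_kg`; individual
#' values are scaled allometrically with fixed exponents 0.75 (CL/F) and 1.0
#' (V/F) and optionally adjusted by a dose covariate. Defaults are an
#' allometric projection of clinical levetiracetam kinetics to mouse scale
#' (elimination half-life about 1 h, tmax about 0.7 h).
#'
#' @param ka Absorption rate constant (1/h).
#' @param cl_f_typ Typical apparent clearance CL/F (L/h) at `ref_weight_kg`.
#' @param v_f_typ Typical apparent volume V/F (L) at `ref_weight_kg`.
#' @param ref_weight_kg Reference body weight (kg).
#' @param exp_cl,exp_v Allometric exponents on CL/F and V/F (fixed by
#'   convention at 0.75 and 1.0).
#' @param dose_effect_cl,dose_effect_v Dose-covariate coefficients on CL/F
#'   and V/F; 0 disables the covariate.
#' @param dose_covariate_form `"power"`:
#'   `g(dose) = (dose / dose_ref)^coef`; `"proportional"`:
#'   `g(dose) = 1 + coef * (dose - dose_ref) / dose_ref`.
#' @param dose_ref_mg_per_kg Reference dose level for the covariate (mg/kg).
#' @param bsv_sd_cl,bsv_sd_v Lognormal between-subject SDs (used by
#'   simulation specs; informational here).
#' @return An object of class `pk_params`.
#' @export
pk_params <- function(ka = 2,
                      cl_f_typ = 0.010,
                      v_f_typ = 0.015,
                      ref_weight_kg = 0.025,
                      exp_cl = 0.75,
                      exp_v = 1.0,
                      dose_effect_cl = 0,
                      dose_effect_v = 0,
                      dose_covariate_form = c("power", "proportional"),
                      dose_ref_mg_per_kg = 30,
                      bsv_sd_cl = 0,
                      bsv_sd_v = 0) {
  .check_scalar_num(ka, "ka", lower = 1e-12)
  .check_scalar_num(cl_f_typ, "cl_f_typ", lower = 1e-12)
  .check_scalar_num(v_f_typ, "v_f_typ", lower = 1e-12)
  .check_scalar_num(ref_weight_kg, "ref_weight_kg", lower = 1e-12)
  structure(
    list(ka = ka, cl_f_typ = cl_f_typ, v_f_typ = v_f_typ,
         ref_weight_kg = ref_weight_kg, exp_cl = exp_cl, exp_v = exp_v,
         dose_effect_cl = dose_effect_cl, dose_effect_v = dose_effect_v,
         dose_covariate_form = match.arg(dose_covariate_form),
         dose_ref_mg_per_kg = dose_ref_mg_per_kg,
         bsv_sd_cl = bsv_sd_cl, bsv_sd_v = bsv_sd_v),
    class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("One-compartment oral PK parameters\n")
  cat(sprintf("  ka = %g /h; CL/F = %g L/h, V/F = %g L at %g kg\n",
              x$ka, x$cl_f_typ, x$v_f_typ, x$ref_weight_kg))
  cat(sprintf("  allometric exponents %g (CL), %g (V); dose covariate (%s): CL %g, V %g\n",
              x$exp_cl, x$exp_v, x$dose_covariate_form,
              x$dose_effect_cl, x$dose_effect_v))
  invisible(x)
}

.dose_cov <- function(coef, dose, form, dose_ref) {
  if (coef == 0 || is.null(dose)) return(1)
  switch(form,
         power = (dose / dose_ref)^coef,
         proportional = 1 + coef * (dose - dose_ref) / dose_ref)
}

#' Allometric and dose-covariate scaling of CL/F and V/F
#'
#' `cl_f = cl_f_typ * (W / W_ref)^0.75 * g_cl(dose)` and
#' `v_f = v_f_typ * (W / W_ref)^1.0 * g_v(dose)`, where `g` is the configured
#' dose-covariate form (identity when the coefficient is zero or no dose
#' level is supplied).
#'
#' @param params A [pk_params()].
#' @param weight_kg Body weight (kg), > 0 (vectorized).
#' @param dose_mg_per_kg Dose level (mg/kg) for the covariate, or `NULL`.
#' @return A list with components `cl_f` (L/h) and `v_f` (L).
#' @export
apply_allometry <- function(params, weight_kg, dose_mg_per_kg = NULL) {
  stopifnot(inherits(params, "pk_params"))
  if (any(weight_kg <= 0)) abort("`weight_kg` must be > 0.")
  wr <- weight_kg / params$ref_weight_kg
  list(
    cl_f = params$cl_f_typ * wr^params$exp_cl *
      .dose_cov(params$dose_effect_cl, dose_mg_per_kg,
                params$dose_covariate_form, params$dose_ref_mg_per_kg),
    v_f = params$v_f_typ * wr^params$exp_v *
      .dose_cov(params$dose_effect_v, dose_mg_per_kg,
                params$dose_covariate_form, params$dose_ref_mg_per_kg))
}

# Closed-form oral one-compartment concentration (mg/L) at times t (h).
# Falls back to the analytic equal-rate limit when ka ~= ke.
.conc_1cmt_oral <- function(dose_mg, ka, cl_f, v_f, times_h) {
  ke <- cl_f / v_f
  if (abs(ka - ke) / ke < 1e-9) {
    dose_mg * ka * times_h / v_f * exp(-ka * times_h)
  } else {
    dose_mg * ka / (v_f * (ka - ke)) *
      (exp(-ke * times_h) - exp(-ka * times_h))
  }
}

#' Simulate a noiseless concentration-time profile
#'
#' Evaluates the closed-form one-compartment oral-absorption curve
#' `C(t) = D ka / (V (ka - ke)) (exp(-ke t) - exp(-ka t))`, `ke = CL/V`,
#' with CL and V from [apply_allometry()] and optional individual lognormal
#' deviations `exp(eta)`. Concentrations are reported in ng/mL.
#'
#' @param params A [pk_params()].
#' @param dose_mg_per_kg Dose level (mg/kg); the administered amount is
#'   `dose_mg_per_kg * weight_kg`.
#' @param weight_kg Body weight (kg).
#' @param times_h Sampling times (h), all >= 0.
#' @param eta_cl,eta_v Individual random effects on log CL/F and log V/F.
#' @param sex Optional label carried through.
#' @param animal_id Optional id carried through.
#' @return A tibble: `animal_id`, `sex`, `dose_mg_per_kg`, `weight_kg`,
#'   `time_h`, `conc_ng_per_ml`.
#' @export
simulate_concentration <- function(params, dose_mg_per_kg, weight_kg, times_h,
                                   eta_cl = 0, eta_v = 0, sex = NA_character_,
                                   animal_id = NA_character_) {
  stopifnot(inherits(params, "pk_params"))
  if (any(times_h < 0)) abort("`times_h` must be >= 0.")
  sc <- apply_allometry(params, weight_kg, dose_mg_per_kg)
  cl_f <- sc$cl_f * exp(eta_cl)
  v_f <- sc$v_f * exp(eta_v)
  dose_mg <- dose_mg_per_kg * weight_kg
  conc_mg_l <- .conc_1cmt_oral(dose_mg, params$ka, cl_f, v_f, times_h)
  tibble::tibble(animal_id = animal_id, sex = sex,
                 dose_mg_per_kg = dose_mg_per_kg, weight_kg = weight_kg,
                 time_h = times_h,
                 conc_ng_per_ml = conc_mg_l * 1000)
}

#' Predict per-animal exposure (AUC) from clearance
#'
#' Under linear kinetics the total exposure is dose-normalized clearance:
#' `AUC(0-inf) = dose / (CL/F)`. Individual clearance comes from
#' [apply_allometry()] times `exp(eta_cl)`. With twice-daily chronic dosing
#' and linear kinetics the daily steady-state AUC is `2 * dose / (CL/F)`,
#' reported alongside.
#'
#' @param params A [pk_params()].
#' @param animals Data frame with columns `weight_kg`, `dose_mg_per_kg`, and
#'   optionally `animal_id`, `sex`, `eta_cl`.
#' @return The input tibble plus `cl_f_ind` (L/h), `auc` (single-dose
#'   AUC(0-inf), mg.h/L), and `auc_daily_bid` (mg.h/L per day at steady
#'   state under twice-daily dosing).
#' @export
predict_individual_auc <- function(params, animals) {
  stopifnot(inherits(params, "pk_params"))
  need <- c("weight_kg", "dose_mg_per_kg")
  if (!all(need %in% names(animals))) {
    abort("`animals` must have columns `weight_kg` and `dose_mg_per_kg`.")
  }
  eta <- animals[["eta_cl"]] %||% rep(0, nrow(animals))
  sc <- apply_allometry(params, animals$weight_kg, animals$dose_mg_per_kg)
  cl_ind <- sc$cl_f * exp(eta)
  dose_mg <- animals$dose_mg_per_kg * animals$weight_kg
  dplyr::mutate(tibble::as_tibble(animals),
                cl_f_ind = cl_ind,
                auc = dose_mg / cl_ind,
                auc_daily_bid = 2 * dose_mg / cl_ind)
}
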