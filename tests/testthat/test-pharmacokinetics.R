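test_that("closed-form concentration matches numerical ODE integration", {
  skip_if_not_installed("deSolve")
  p <- pk_params(ka = 1.7, cl_f_typ = 0.012, v_f_typ = 0.018)
  w <- 0.028
  dose <- 30 * w
  sc <- apply_allometry(p, w)
  times <- c(0.25, 0.5, 1, 2, 4, 6, 24)
  rhs <- function(t, y, parms) {
    with(as.list(parms), list(c(-ka * y[1], ka * y[1] - ke * y[2])))
  }
  ode <- deSolve::lsoda(c(depot = dose, central = 0), c(0, times), rhs,
                        c(ka = p$ka, ke = sc$cl_f / sc$v_f),
                        rtol = 1e-10, atol = 1e-12)
  expected <- ode[-1, "central"] / sc$v_f * 1000
  got <- simulate_concentration(p, 30, w, times)$conc_ng_per_ml
  expect_equal(got, unname(expected), tolerance = 1e-6)
})

test_that("concentration starts at zero and obeys the fast-absorption limit", {
  p <- pk_params()
  expect_equal(simulate_concentration(p, 30, 0.025, 0)$conc_ng_per_ml, 0)
  ke <- p$cl_f_typ / p$v_f_typ
  fast <- pk_params(ka = 100 * ke, cl_f_typ = p$cl_f_typ,
                    v_f_typ = p$v_f_typ)
  t_late <- 3 / ke
  got <- simulate_concentration(fast, 30, 0.025, t_late)$conc_ng_per_ml
  bolus <- 30 * 0.025 / p$v_f_typ * exp(-ke * t_late) * 1000
  expect_equal(got, bolus, tolerance = 0.0102)
})

test_that("equal-rate limit is continuous in ka", {
  p_eq <- pk_params(ka = 0.010 / 0.015, cl_f_typ = 0.010, v_f_typ = 0.015)
  p_near <- pk_params(ka = 0.010 / 0.015 * (1 + 1e-7), cl_f_typ = 0.010,
                      v_f_typ = 0.015)
  t <- c(0.5, 1, 2, 4)
  expect_equal(simulate_concentration(p_eq, 30, 0.025, t)$conc_ng_per_ml,
               simulate_concentration(p_near, 30, 0.025, t)$conc_ng_per_ml,
               tolerance = 1e-5)
})

test_that("allometric scaling follows the fixed exponents", {
  p <- pk_params()
  at_ref <- apply_allometry(p, p$ref_weight_kg)
  expect_equal(at_ref$cl_f, p$cl_f_typ)
  expect_equal(at_ref$v_f, p$v_f_typ)
  doubled <- apply_allometry(p, 2 * p$ref_weight_kg)
  expect_equal(doubled$cl_f, p$cl_f_typ * 2^0.75)
  expect_equal(doubled$v_f, p$v_f_typ * 2)
  # log-log regression over a weight sweep recovers the exponent
  w <- seq(0.015, 0.045, length.out = 20)
  cl <- apply_allometry(p, w)$cl_f
  slope <- unname(coef(lm(log(cl) ~ log(w)))[2])
  expect_equal(slope, 0.75, tolerance = 1e-10)
})

test_that("dose covariate forms behave as declared", {
  p_pow <- pk_params(dose_effect_cl = 0.3, dose_covariate_form = "power")
  expect_equal(apply_allometry(p_pow, 0.025, 30)$cl_f, p_pow$cl_f_typ)
  expect_equal(apply_allometry(p_pow, 0.025, 60)$cl_f,
               p_pow$cl_f_typ * 2^0.3)
  p_prop <- pk_params(dose_effect_cl = 0.2,
                      dose_covariate_form = "proportional")
  expect_equal(apply_allometry(p_prop, 0.025, 60)$cl_f,
               p_prop$cl_f_typ * 1.2)
})

test_that("NCA on a dense noiseless profile recovers CL/F within 0.5%", {
  p <- pk_params()
  ke <- p$cl_f_typ / p$v_f_typ
  times <- seq(0.01, 10 * log(2) / ke, by = 0.01)
  prof <- simulate_concentration(p, 30, p$ref_weight_kg, times)
  res <- run_nca(prof$time_h, prof$conc_ng_per_ml / 1000,
                 dose_mg = 30 * p$ref_weight_kg)
  expect_true(res$estimable)
  expect_lt(abs(res$cl_f_obs - p$cl_f_typ) / p$cl_f_typ, 0.005)
})

test_that("lambda_z is exact on log-linear data and tmax is the argmax", {
  k <- 0.31
  t <- c(0, 1, 2, 4, 6)
  conc <- c(0, 80, 50 * exp(-k * 2), 50 * exp(-k * 4), 50 * exp(-k * 6))
  res <- run_nca(t, conc)
  expect_equal(res$lambda_z, k, tolerance = 1e-12)
  expect_equal(res$tmax, 1)
  expect_equal(res$cmax, 80)
})

test_that("NCA flags non-estimable terminal phases", {
  res <- run_nca(c(0.5, 1, 2), c(10, 8, 6))
  expect_false(res$estimable)
  expect_true(is.na(res$auc_0_inf))
  rising <- run_nca(c(0.25, 0.5, 1, 2, 4), c(1, 2, 3, 4, 5))
  expect_false(rising$estimable)
})

test_that("NCA is scale equivariant and AUC refines to dose/CL", {
  p <- pk_params()
  times <- seq(0.05, 30, by = 0.05)
  prof <- simulate_concentration(p, 30, p$ref_weight_kg, times)
  base <- run_nca(prof$time_h, prof$conc_ng_per_ml, dose_mg = 1)
  scaled <- run_nca(prof$time_h, 3 * prof$conc_ng_per_ml, dose_mg = 1)
  expect_equal(scaled$cmax, 3 * base$cmax)
  expect_equal(scaled$auc_0_inf, 3 * base$auc_0_inf, tolerance = 1e-12)
  expect_equal(scaled$cl_f_obs, base$cl_f_obs / 3, tolerance = 1e-12)
  # monotone refinement toward D/CL
  errs <- sapply(c(0.5, 0.1, 0.02), function(dt) {
    tt <- seq(dt, 40, by = dt)
    pr <- simulate_concentration(p, 30, p$ref_weight_kg, tt)
    res <- run_nca(pr$time_h, pr$conc_ng_per_ml / 1000,
                   dose_mg = 30 * p$ref_weight_kg)
    abs(res$auc_0_inf - 30 * p$ref_weight_kg / p$cl_f_typ)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("noise-free population fit recovers the generating parameters", {
  spec <- pk_sim_spec(bsv_sd = 0, prop_error_sd = 0, weight_cv = 0.1,
                      seed = 8)
  prof <- generate_pk_profiles(spec)
  fit <- fit_population_pk(prof, covariates = character(),
                           start = pk_params(ka = 4, cl_f_typ = 0.03,
                                             v_f_typ = 0.05))
  truth <- spec$params
  expect_lt(abs(fit$params$ka - truth$ka) / truth$ka, 1e-6)
  expect_lt(abs(fit$params$cl_f_typ - truth$cl_f_typ) / truth$cl_f_typ, 1e-6)
  expect_lt(abs(fit$params$v_f_typ - truth$v_f_typ) / truth$v_f_typ, 1e-6)
})

test_that("dose covariate on CL/F is detected when present and not invented", {
  with_effect <- sapply(1:10, function(i) {
    truth <- pk_params(dose_effect_cl = 0.4)
    spec <- pk_sim_spec(params = truth, bsv_sd = 0.1, prop_error_sd = 0.1,
                        seed = 300 + i)
    fit <- fit_population_pk(generate_pk_profiles(spec),
                             covariates = "dose_cl")
    "dose_cl" %in% fit$retained
  })
  without_effect <- sapply(1:10, function(i) {
    spec <- pk_sim_spec(bsv_sd = 0.1, prop_error_sd = 0.1, seed = 400 + i)
    fit <- fit_population_pk(generate_pk_profiles(spec),
                             covariates = "dose_cl")
    "dose_cl" %in% fit$retained
  })
  expect_gte(mean(with_effect), 0.9)
  expect_lte(mean(without_effect), 0.1)
})

test_that("predicted AUC is dose-normalized clearance", {
  p <- pk_params()
  animals <- tibble::tibble(animal_id = "x", weight_kg = p$ref_weight_kg,
                            dose_mg_per_kg = 0.25 / p$ref_weight_kg)
  # dose 0.25 mg with CL/F fixed at 0.05 L/h -> AUC 5 mg.h/L
  p2 <- pk_params(cl_f_typ = 0.05)
  est <- predict_individual_auc(p2, animals)
  expect_equal(est$auc, 0.25 / 0.05)
  # linearity: doubling dose doubles AUC when the dose covariate is off
  est2 <- predict_individual_auc(
    p2, dplyr::mutate(animals, dose_mg_per_kg = 2 * dose_mg_per_kg))
  expect_equal(est2$auc, 2 * est$auc)
  # cross-check against dense-profile NCA on the same animal
  times <- seq(0.01, 60, by = 0.01)
  prof <- simulate_concentration(p, 30, p$ref_weight_kg, times)
  nca <- run_nca(prof$time_h, prof$conc_ng_per_ml / 1000,
                 dose_mg = 30 * p$ref_weight_kg)
  model_auc <- predict_individual_auc(
    p, tibble::tibble(weight_kg = p$ref_weight_kg, dose_mg_per_kg = 30))$auc
  expect_lt(abs(nca$auc_0_inf - model_auc) / model_auc, 0.005)
  # twice-daily steady state doubles the daily exposure
  est3 <- predict_individual_auc(p2, animals)
  expect_equal(est3$auc_daily_bid, 2 * est3$auc)
})

test_that("exposure-concentration regression matches the normal equations", {
  set.seed(12)
  spec <- pk_sim_spec(seed = 12)
  prof <- generate_pk_profiles(spec)
  animals <- dplyr::distinct(prof[c("animal_id", "sex", "dose_mg_per_kg",
                                    "weight_kg", "eta_cl")])
  exposures <- predict_individual_auc(spec$params, animals)
  c_half <- prof[prof$time_h == 0.5, c("animal_id", "conc_ng_per_ml")]
  names(c_half)[2] <- "c_half"
  d <- dplyr::inner_join(exposures, c_half, by = "animal_id")
  res <- exposure_concentration_regression(d)
  x <- d$c_half; y <- d$auc
  beta <- ols_oracle(cbind(1, x), y)
  r2 <- 1 - sum((y - cbind(1, x) %*% beta)^2) / sum((y - mean(y))^2)
  expect_equal(res$slope, unname(beta[2]), tolerance = 1e-12)
  expect_equal(res$r_squared, r2, tolerance = 1e-12)
  # exact collinearity gives R^2 = 1
  perfect <- exposure_concentration_regression(
    data.frame(auc = 1:5 * 2 + 1, c_half = 1:5))
  expect_equal(perfect$r_squared, 1)
  expect_error(exposure_concentration_regression(
    data.frame(auc = 1:4, c_half = rep(1, 4))), "variance")
})

test_that("slope p-values are well calibrated under permutation of the predictor", {
  set.seed(33)
  n <- 24
  x <- runif(n)
  y <- runif(n)
  pvals <- replicate(400, {
    exposure_concentration_regression(
      data.frame(auc = y, c_half = sample(x)))$p_value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
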