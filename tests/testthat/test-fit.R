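test_that("the ML discrepancy matches hand arithmetic and is a true divergence", {
  S <- random_pd(3)
  expect_equal(ml_discrepancy(S, S), 0, tolerance = 1e-12)
  # 1x1 case: ln(1) + 2 - ln(2) - 1
  expect_equal(ml_discrepancy(matrix(2), matrix(1)), 1 - log(2))
  expect_error(ml_discrepancy(S, -S), "positive definite")
  expect_error(ml_discrepancy(S, random_pd(2)), "equal dimension")
})

test_that("the discrepancy is nonnegative over random PD pairs", {
  set.seed(2024)
  for (i in 1:1000) {
    p <- sample(2:4, 1)
    expect_gte(ml_discrepancy(random_pd(p), random_pd(p)), 0)
  }
})

test_that("saturated dyadic models reproduce the sample covariance", {
  m <- study_moments()
  d <- study_design()
  S <- moments_to_covariance(m)$sigma
  for (model in list(build_apim(d), build_mim(d))) {
    fit <- fit_ml(model, m)
    expect_true(fit$converged)
    expect_lt(fit$chisq, 1e-6)
    expect_lt(max(abs(fit$Sigma - S[model$observed, model$observed])), 1e-6)
    expect_equal(fit$fit$srmr, 0, tolerance = 1e-6)
  }
})

test_that("saturated ML estimates match the closed-form moment oracle", {
  m <- study_moments()
  d <- study_design()
  S <- moments_to_covariance(m)$sigma
  v <- design_variables(d)

  apim <- fit_ml(build_apim(d), m)
  oracle <- saturated_path_oracle(S, stats::setNames(
    list(c(v[1], v[2]), c(v[2], v[1])), v[3:4]))
  expect_equal(apim$estimates[["actor_man"]], oracle[[v[3]]][[v[1]]],
               tolerance = 1e-6)
  expect_equal(apim$estimates[["partner_woman_man"]], oracle[[v[3]]][[v[2]]],
               tolerance = 1e-6)
  expect_equal(apim$estimates[["actor_woman"]], oracle[[v[4]]][[v[2]]],
               tolerance = 1e-6)
  expect_equal(apim$estimates[["partner_man_woman"]], oracle[[v[4]]][[v[1]]],
               tolerance = 1e-6)

  mim <- fit_ml(build_mim(d), m)
  oracle_iv <- saturated_path_oracle(S, stats::setNames(
    list(c(v[1], v[4]), c(v[2], v[3])), v[3:4]))
  expect_equal(mim$estimates[["actor_man"]], oracle_iv[[v[3]]][[v[1]]],
               tolerance = 1e-6)
  expect_equal(mim$estimates[["feedback_woman_man"]], oracle_iv[[v[3]]][[v[4]]],
               tolerance = 1e-6)
  expect_equal(mim$estimates[["feedback_man_woman"]], oracle_iv[[v[4]]][[v[3]]],
               tolerance = 1e-6)
})

test_that("the moment oracle itself reproduces the normal-equation arithmetic", {
  m <- study_moments()
  S <- moments_to_covariance(m)$sigma
  # standardized actor = (r_xy - r_xz r_zy)/(1 - r_xz^2), rescaled by SDs
  r <- m$correlations
  std <- (r["anxiety_man", "satisfaction_man"] -
          r["anxiety_man", "anxiety_woman"] *
          r["anxiety_woman", "satisfaction_man"]) /
    (1 - r["anxiety_man", "anxiety_woman"]^2)
  expected <- std * m$sds[["satisfaction_man"]] / m$sds[["anxiety_man"]]
  got <- saturated_path_oracle(
    S, list(satisfaction_man = c("anxiety_man", "anxiety_woman")))
  expect_equal(got$satisfaction_man[["anxiety_man"]], unname(expected),
               tolerance = 1e-12)
  # uncorrelated predictor and outcome give a zero coefficient
  S0 <- diag(c(2, 3)); dimnames(S0) <- list(c("x", "y"), c("x", "y"))
  expect_equal(saturated_path_oracle(S0, list(y = "x"))$y[["x"]], 0)
  # a system with more instruments than predictors is refused
  S3 <- random_pd(4)
  dimnames(S3) <- list(letters[1:4], letters[1:4])
  expect_error(saturated_path_oracle(S3, list(c = "a", d = "c")),
               "just-identified")
})

test_that("a two-predictor regression submodel equals the lm() solution", {
  set.seed(5)
  n <- 200
  X <- matrix(rnorm(2 * n), n)
  y <- 1.5 * X[, 1] - 0.7 * X[, 2] + rnorm(n)
  dat <- cbind(x1 = X[, 1], x2 = X[, 2], y = y)
  S <- cov(dat)
  model <- path_model(
    observed = c("x1", "x2", "y"),
    paths = data.frame(from = c("x1", "x2"), to = "y",
                       label = c("b1", "b2"), value = 0),
    covs = data.frame(v1 = c("x1", "x2", "x1", "y"),
                      v2 = c("x1", "x2", "x2", "y"),
                      label = c("v1", "v2", "c12", "res"),
                      value = c(1, 1, 0, 1)))
  fit <- fit_ml(model, S, n = n)
  ref <- coef(lm(y ~ x1 + x2, data = as.data.frame(dat)))
  expect_equal(fit$estimates[["b1"]], unname(ref["x1"]), tolerance = 1e-6)
  expect_equal(fit$estimates[["b2"]], unname(ref["x2"]), tolerance = 1e-6)
  expect_lt(fit$chisq, 1e-6)
})

test_that("fit indices follow their defining formulas", {
  idx <- fit_indices(5, 1, 100, 50, 1)
  expect_equal(idx$cfi, 1 - 4 / 49)
  expect_equal(idx$rmsea, sqrt(4 / 100))
  expect_equal(idx$tli_raw, (50 - 5) / (50 - 1))
  # over-fitting model: chi-square below df pins CFI at 1 and RMSEA at 0
  idx2 <- fit_indices(0.4, 1, 141, 60, 6)
  expect_equal(idx2$cfi, 1)
  expect_equal(idx2$rmsea, 0)
  expect_error(fit_indices(3, 0, 100, 50, 1), "zero degrees of freedom")
})

test_that("ideal fit yields ideal indices on a fitted model", {
  m <- study_moments()
  fit <- fit_ml(build_apim(study_design()), m)
  expect_equal(fit$fit$cfi, 1)
  expect_equal(fit$fit$rmsea, 0)
  expect_equal(fit$fit$srmr, 0, tolerance = 1e-7)
  expect_true(fit$fit$saturated)
})

test_that("the chi-square difference test guards nesting and clips noise", {
  m <- study_moments()
  d <- study_design()
  full <- fit_ml(build_apim(d), m)
  restricted <- fit_ml(build_apim(d, "actor_equal"), m)
  cmp <- chisq_diff_test(restricted, full)
  expect_gte(cmp$dchisq, 0)
  expect_equal(cmp$ddf, 1)
  # the difference equals independently recomputed discrepancies x N
  expect_equal(cmp$dchisq,
               max(m$n * (restricted$discrepancy - full$discrepancy), 0),
               tolerance = 1e-6)
  expect_error(chisq_diff_test(full, full), "more degrees of freedom")
})

test_that("estimates are invariant to variable order and equivariant to scale", {
  m <- study_moments()
  d <- study_design()
  S <- moments_to_covariance(m)$sigma
  fit <- fit_ml(build_apim(d), S, n = m$n)
  perm <- rev(rownames(S))
  fit_perm <- fit_ml(build_apim(d), S[perm, perm], n = m$n)
  expect_equal(fit$estimates, fit_perm$estimates, tolerance = 1e-6)

  # doubling the units of the men's predictor halves its paths
  scl <- c(anxiety_man = 2, anxiety_woman = 1,
           satisfaction_man = 1, satisfaction_woman = 1)[rownames(S)]
  S_scaled <- S * outer(scl, scl)
  fit_scaled <- fit_ml(build_apim(d), S_scaled, n = m$n)
  expect_equal(fit_scaled$estimates[["actor_man"]],
               fit$estimates[["actor_man"]] / 2, tolerance = 1e-6)
  expect_equal(fit_scaled$estimates[["partner_man_woman"]],
               fit$estimates[["partner_man_woman"]] / 2, tolerance = 1e-6)
  expect_equal(fit_scaled$estimates[["actor_woman"]],
               fit$estimates[["actor_woman"]], tolerance = 1e-6)
})

test_that("under-identified models are refused before optimization", {
  S <- random_pd(2)
  dimnames(S) <- list(c("x", "y"), c("x", "y"))
  model <- suppressWarnings(path_model(
    observed = c("x", "y"),
    paths = data.frame(from = c("x", "y"), to = c("y", "x"),
                       label = c("b1", "b2"), value = 0),
    covs = data.frame(v1 = c("x", "y"), v2 = c("x", "y"),
                      label = c("vx", "vy"), value = 1)))
  expect_error(fit_ml(model, S, n = 50), "under-identified")
})

test_that("negative variance estimates raise a Heywood warning", {
  # two unit-loading indicators whose covariance exceeds one indicator's
  # variance force that indicator's residual below zero
  S <- matrix(c(1, 1.3, 1.3, 2), 2, 2)
  dimnames(S) <- list(c("y1", "y2"), c("y1", "y2"))
  model <- path_model(
    observed = c("y1", "y2"), latent = "L",
    paths = data.frame(from = "L", to = c("y1", "y2"),
                       label = NA_character_, value = 1),
    covs = data.frame(v1 = c("L", "y1", "y2"), v2 = c("L", "y1", "y2"),
                      label = c("phi", "e1", "e2"), value = 1))
  expect_warning(fit <- fit_ml(model, S, n = 50), "Heywood")
  expect_lt(fit$estimates[["e1"]], 0)
})
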