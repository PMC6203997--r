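test_that("the basic APIM carries the canonical free-parameter layout", {
  model <- build_apim(study_design())
  labs <- free_params(model)
  # 4 paths + 2 exogenous variances + 1 exogenous covariance
  # + 2 residual variances + 1 residual covariance
  expect_length(labs, 10)
  expect_setequal(
    labs,
    c("actor_man", "actor_woman", "partner_woman_man", "partner_man_woman",
      "var_anxiety_man", "var_anxiety_woman", "cov_anxiety",
      "res_satisfaction_man", "res_satisfaction_woman",
      "rescov_satisfaction"))
})

test_that("swapping the roles permutes estimates and preserves fit", {
  m <- study_moments()
  d1 <- study_design()
  d2 <- dyad_design(roles = c("woman", "man"))
  for (build in list(build_apim, build_mim)) {
    f1 <- fit_ml(build(d1), m)
    f2 <- fit_ml(build(d2), m)
    expect_equal(f1$chisq, f2$chisq, tolerance = 1e-8)
    expect_equal(f1$df, f2$df)
    expect_equal(f1$estimates[["actor_man"]], f2$estimates[["actor_man"]],
                 tolerance = 1e-6)
    expect_equal(f1$estimates[["actor_woman"]], f2$estimates[["actor_woman"]],
                 tolerance = 1e-6)
  }
  c1 <- fit_ml(build_cfm(d1), m)
  c2 <- fit_ml(build_cfm(d2), m)
  expect_equal(c1$chisq, c2$chisq, tolerance = 1e-6)
  expect_equal(c1$estimates[["dyadic_effect"]],
               c2$estimates[["dyadic_effect"]], tolerance = 1e-5)
})

test_that("MIM indirect effects are the product of their factors", {
  m <- study_moments()
  fit <- fit_ml(build_mim(study_design()), m)
  ind <- mim_indirect_effects(fit)
  expect_equal(nrow(ind), 2)
  # direction role i: actor(i) x feedback(outcome i -> outcome j)
  man <- ind[ind$from_role == "man", ]
  expect_equal(man$estimate,
               fit$estimates[["actor_man"]] *
                 fit$estimates[["feedback_man_woman"]], tolerance = 1e-10)
  woman <- ind[ind$from_role == "woman", ]
  expect_equal(woman$estimate,
               fit$estimates[["actor_woman"]] *
                 fit$estimates[["feedback_woman_man"]], tolerance = 1e-10)
  expect_true(all(ind$se > 0))
  # delta-method SE reduces to |a| se_f when the actor is error-free:
  # sanity only - here just check z = est/se
  expect_equal(ind$z, ind$estimate / ind$se)
  expect_error(mim_indirect_effects(fit_ml(build_apim(study_design()), m)),
               "Mutual Influence")
})

test_that("a zero actor effect zeroes the indirect effect", {
  d <- study_design()
  spec <- generator_spec("mim", n = 4000, seed = 21,
                         theta = c(actor_man = 0))
  mom <- summarize_dyads(simulate_dyads(spec))
  fit <- fit_ml(build_mim(d), mom)
  ind <- mim_indirect_effects(fit)
  man <- ind[ind$from_role == "man", ]
  # estimate is the product of a near-zero actor and a bounded feedback
  expect_lt(abs(man$estimate), 0.1)
  expect_gt(man$p, 0.01)
})

test_that("CFM variance decomposition behaves at its extremes", {
  m <- study_moments()
  d <- study_design()
  fit <- fit_ml(build_cfm(d), m)
  r2 <- cfm_latent_r2(fit)
  b <- fit$estimates[["dyadic_effect"]]
  phi <- fit$estimates[["var_anxiety_dyad"]]
  psi <- fit$estimates[["res_satisfaction_dyad"]]
  expect_equal(r2, 100 * b^2 * phi / (b^2 * phi + psi), tolerance = 1e-10)

  # b = 0 gives 0%; psi = 0 gives 100%
  fit0 <- fit
  fit0$estimates[["dyadic_effect"]] <- 0
  expect_equal(cfm_latent_r2(fit0), 0)
  fit1 <- fit
  fit1$estimates[["res_satisfaction_dyad"]] <- 0
  expect_equal(cfm_latent_r2(fit1), 100)
})

test_that("both CFM scalings agree on the scale-free quantities", {
  m <- study_moments()
  d <- study_design()
  f_load <- fit_ml(build_cfm(d), m)
  f_var <- fit_ml(build_cfm(d, scale_by_latent_variance = TRUE), m)
  expect_equal(f_load$chisq, f_var$chisq, tolerance = 1e-5)
  expect_equal(f_load$df, f_var$df)
  expect_equal(cfm_latent_r2(f_load), cfm_latent_r2(f_var),
               tolerance = 1e-3)
})

test_that("fixing the CFM effect to zero gives a nested null", {
  m <- study_moments()
  d <- study_design()
  full <- fit_ml(build_cfm(d), m)
  null_model <- build_cfm(d)
  i <- which(null_model$paths$label %in% "dyadic_effect")
  null_model$paths$label[i] <- NA_character_
  null_model$paths$value[i] <- 0
  null_fit <- fit_ml(null_model, m)
  expect_equal(null_fit$df, 2)
  cmp <- chisq_diff_test(null_fit, full)
  expect_gte(cmp$dchisq, 0)
  expect_lt(cmp$p.value, 0.05)  # the dyad-level effect is real here
})

test_that("CFM estimates ignore which member is listed first", {
  m <- study_moments()
  f1 <- fit_ml(build_cfm(study_design()), m)
  f2 <- fit_ml(build_cfm(dyad_design(roles = c("woman", "man"))), m)
  expect_equal(f1$estimates[["var_anxiety_dyad"]],
               f2$estimates[["var_anxiety_dyad"]], tolerance = 1e-4)
})

test_that("the hypothesis suite mirrors the study conclusions", {
  m <- study_moments()
  rep <- run_hypothesis_suite(m, study_design())
  expect_equal(nrow(rep), 7)
  expect_true(all(rep$supported[c(1, 2, 5, 7)]))
  expect_false(any(rep$supported[c(3, 4, 6)]))
  det <- attr(rep, "details")
  # per-direction partner effects: significant toward men, not toward women
  expect_lt(det$partner_direction_p[["partner_woman_man"]], 0.05)
  expect_gt(det$partner_direction_p[["partner_man_woman"]], 0.05)
})

test_that("null cross-construct structure supports no effect hypotheses", {
  # population with every predictor-outcome and feedback path zero
  spec <- generator_spec("apim", n = 20000, seed = 77,
                         theta = c(actor_man = 0, actor_woman = 0,
                                   partner_woman_man = 0,
                                   partner_man_woman = 0))
  mom <- summarize_dyads(simulate_dyads(spec))
  rep <- suppressWarnings(run_hypothesis_suite(mom, study_design()))
  expect_false(any(rep$supported[c(1, 2, 5, 7)]))
})
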