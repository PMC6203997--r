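test_that("generator populations match the fitting engine's RAM identity", {
  d <- study_design()
  spec <- generator_spec("apim", n = 100, seed = 1)
  ram <- implied_covariance(build_apim(d), spec$theta)
  expect_equal(spec$sigma, ram[colnames(spec$sigma), colnames(spec$sigma)],
               tolerance = 1e-12)

  spec_c <- generator_spec("cfm", n = 100, seed = 1)
  ram_c <- implied_covariance(build_cfm(d), spec_c$theta)
  expect_equal(spec_c$sigma,
               ram_c[colnames(spec_c$sigma), colnames(spec_c$sigma)],
               tolerance = 1e-12)
})

test_that("the MIM reduced form agrees with the RAM route", {
  d <- study_design()
  spec <- generator_spec("mim", n = 100, seed = 1,
                         theta = c(feedback_woman_man = 0.6,
                                   feedback_man_woman = 0.25))
  ram <- implied_covariance(build_mim(d), spec$theta)
  expect_equal(spec$sigma, ram[colnames(spec$sigma), colnames(spec$sigma)],
               tolerance = 1e-12)
})

test_that("zero paths give a block-diagonal population covariance", {
  spec <- generator_spec("apim", n = 10, seed = 1,
                         theta = c(actor_man = 0, actor_woman = 0,
                                   partner_woman_man = 0,
                                   partner_man_woman = 0))
  s <- spec$sigma
  x <- paste0("anxiety_", c("man", "woman"))
  y <- paste0("satisfaction_", c("man", "woman"))
  expect_equal(max(abs(s[x, y])), 0)
})

test_that("a CFM with b = 0 links constructs only within person", {
  spec <- generator_spec("cfm", n = 10, seed = 1,
                         theta = c(dyadic_effect = 0))
  s <- spec$sigma
  # cross-person, cross-construct covariances vanish by path tracing
  expect_equal(s["anxiety_man", "satisfaction_woman"], 0)
  expect_equal(s["anxiety_woman", "satisfaction_man"], 0)
  # within-person link survives through the residual covariance
  expect_equal(s["anxiety_man", "satisfaction_man"], -4)
})

test_that("an explosive feedback loop is rejected at specification", {
  expect_error(generator_spec("mim", theta = c(feedback_woman_man = 1.2,
                                               feedback_man_woman = 0.9)),
               "stable reduced form")
})

test_that("a non-PD population is rejected with an eigenvalue diagnostic", {
  expect_error(generator_spec("apim", theta = c(cov_anxiety = 30)),
               "positive definite.*eigenvalue")
})

test_that("the simulator is seeded, deterministic and shape-correct", {
  spec <- generator_spec("apim", n = 25, seed = 99)
  t1 <- simulate_dyads(spec)
  t2 <- simulate_dyads(spec)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 25)

  one <- simulate_dyads(generator_spec("cfm", n = 1, seed = 3))
  expect_equal(nrow(one), 1)
  expect_true(all(is.finite(unlist(one[, -1]))))

  # a different seed moves the draws
  t3 <- simulate_dyads(generator_spec("apim", n = 25, seed = 100))
  expect_false(identical(t1$anxiety_man, t3$anxiety_man))
})

test_that("simulated samples converge to the implied population moments", {
  spec <- generator_spec("mim", n = 50000, seed = 8)
  tab <- simulate_dyads(spec)
  got <- moments_to_covariance(summarize_dyads(tab))$sigma
  truth <- spec$sigma
  v <- colnames(truth)
  got <- got[v, v]
  for (i in seq_along(v)) for (j in seq_len(i)) {
    se <- sqrt((truth[i, i] * truth[j, j] + truth[i, j]^2) / spec$n)
    expect_lt(abs(got[i, j] - truth[i, j]), 3 * se)
  }
})

test_that("fitting the matching model to a big sample recovers the truth", {
  d <- study_design()
  for (fw in c("apim", "mim", "cfm")) {
    spec <- generator_spec(fw, n = 10000, seed = 31)
    mom <- summarize_dyads(simulate_dyads(spec))
    fit <- fit_ml(matching_model_for_test(fw, d), mom)
    labs <- names(spec$theta)
    # path-type parameters within 2 MC SEs (the reported SE estimates it)
    path_labs <- grep("^actor|^partner|^feedback|^dyadic", labs, value = TRUE)
    for (l in path_labs)
      expect_lt(abs(fit$estimates[[l]] - spec$theta[[l]]),
                2 * fit$se[[l]] + 1e-8)
  }
})

test_that("a small recovery experiment is unbiased and well covered", {
  spec <- generator_spec("apim", n = 141, seed = 17)
  out <- recovery_experiment(spec, replicates = 60, n_grid = 500)
  expect_true(attr(out, "valid"))
  paths <- out[grepl("^actor|^partner", out$parameter), ]
  # 3 MC standard errors of the mean estimate
  expect_true(all(abs(paths$bias) < 3 * paths$empirical_sd / sqrt(60)))
  expect_true(all(paths$coverage > 0.8))
  expect_equal(sort(unique(out$n)), 500)
})
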