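# Shared fixtures and small constructors used across the test files.

# Data matrix whose *sample* mean vector and (n-1) covariance equal the
# targets exactly: draw, center, whiten by the sample factor, recolor.
exact_moment_data <- function(n, mu, sigma, seed = 1) {
  k <- length(mu)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * k), n, k)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  W <- chol(stats::cov(Z))
  X <- Z %*% solve(W) %*% chol(sigma)
  sweep(X, 2, mu, "+")
}

# a random well-conditioned PD matrix
random_pd <- function(p) {
  A <- matrix(stats::rnorm(p * p), p)
  crossprod(A) + diag(p)
}

study_moments <- function() infertile_couples_moments()

study_design <- function() dyad_design(roles = c("man", "woman"),
                                       predictor = "anxiety",
                                       outcome = "satisfaction")

matching_model_for_test <- function(framework, design) {
  switch(framework,
         apim = build_apim(design),
         mim = build_mim(design),
         cfm = build_cfm(design))
}

# small complete dyad table used by I/O and CLI tests
toy_dyad_table <- function(n = 20, seed = 42) {
  spec <- generator_spec("apim", n = n, seed = seed)
  simulate_dyads(spec)
}
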