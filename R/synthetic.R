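#' Specification for a synthetic dyad generator
#'
#' Describes a population with known APIM, MIM or CFM structure from which
#' multivariate-normal dyad scores are drawn.  Population parameters are
#' named by the labels of the corresponding model builder
#' ([build_apim()], [build_mim()], [build_cfm()]); `theta` overrides any
#' subset of the defaults, which echo the magnitudes of the packaged
#' infertile-couples moments (predictor SDs near 4.4, outcome SDs near
#' 6.6, actor effects near -0.45).
#'
#' @param framework `"apim"`, `"mim"` or `"cfm"`.
#' @param n Number of dyads to draw (default 141, the size of the packaged
#'   study).
#' @param design A [dyad_design()].
#' @param theta Named numeric vector of population parameter overrides.
#' @param means Named means for the observed variables (default all 0).
#' @param seed Integer seed; draws are bit-reproducible given the seed.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(framework = c("apim", "mim", "cfm"), n = 141,
                           design = dyad_design(), theta = NULL,
                           means = NULL, seed = NULL) {
  framework <- match.arg(framework)
  v <- design_variables(design)
  x <- v[1:2]; y <- v[3:4]
  r <- design$roles
  defaults <- switch(framework,
    apim = stats::setNames(
      c(-0.45, -0.45, -0.2, -0.2, 18.5, 19.9, 4.0, 35, 36, 14),
      c(paste0("actor_", r),
        paste0("partner_", r[2], "_", r[1]), paste0("partner_", r[1], "_", r[2]),
        paste0("var_", x), paste0("cov_", design$predictor),
        paste0("res_", y), paste0("rescov_", design$outcome))),
    mim = stats::setNames(
      c(-0.37, -0.36, 0.45, 0.45, 18.5, 19.9, 4.0, 32, 33, -14),
      c(paste0("actor_", r),
        paste0("feedback_", r[2], "_", r[1]), paste0("feedback_", r[1], "_", r[2]),
        paste0("var_", x), paste0("cov_", design$predictor),
        paste0("res_", y), paste0("rescov_", design$outcome))),
    cfm = stats::setNames(
      c(-1.4, 4.0, 10, 14.5, 15.9, 20, 21, -4, -3.4),
      c("dyadic_effect", paste0("var_", design$predictor, "_dyad"),
        paste0("res_", design$outcome, "_dyad"),
        paste0("res_", c(x, y)), paste0("rescov_", r))))
  if (!is.null(theta)) {
    unknown <- setdiff(names(theta), names(defaults))
    if (length(unknown))
      stop("unknown population parameters: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    defaults[names(theta)] <- theta
  }
  mu <- stats::setNames(rep(0, 4), v)
  if (!is.null(means)) mu[names(means)] <- means

  spec <- structure(list(framework = framework, n = as.integer(n),
                         design = design, theta = defaults, means = mu,
                         seed = seed),
                    class = "generator_spec")
  if (framework == "mim") {
    fb <- defaults[grep("^feedback", names(defaults))]
    prod_fb <- prod(fb)
    if (abs(prod_fb) >= 1)
      stop("feedback product ", format(prod_fb), " must satisfy |b12*b21| < 1 ",
           "for a stable reduced form", call. = FALSE)
  }
  sigma <- implied_population_covariance(spec)   # validates PD
  spec$sigma <- sigma
  spec
}

#' Population covariance implied by a generator specification
#'
#' APIM and CFM populations are assembled through the same RAM identity
#' used by the fitting engine; the MIM population is assembled through the
#' reduced form of the nonrecursive system,
#' \eqn{Y = (I-B)^{-1}(\Gamma X + e)}, as an independent route that the
#' test suite checks against the RAM identity.
#'
#' @param spec A [generator_spec()].
#' @return Positive-definite covariance matrix over the four observed
#'   variables.
#' @export
implied_population_covariance <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  v <- design_variables(spec$design)
  if (spec$framework == "mim") {
    x <- v[1:2]; y <- v[3:4]
    r <- spec$design$roles
    th <- spec$theta
    G <- diag(th[paste0("actor_", r)])                 # X -> own Y
    B <- matrix(0, 2, 2)
    B[1, 2] <- th[[paste0("feedback_", r[2], "_", r[1])]]  # y2 -> y1
    B[2, 1] <- th[[paste0("feedback_", r[1], "_", r[2])]]  # y1 -> y2
    Sx <- matrix(th[[paste0("cov_", spec$design$predictor)]], 2, 2)
    diag(Sx) <- th[paste0("var_", x)]
    Pe <- matrix(th[[paste0("rescov_", spec$design$outcome)]], 2, 2)
    diag(Pe) <- th[paste0("res_", y)]
    IBi <- solve(diag(2) - B)
    Syy <- IBi %*% (G %*% Sx %*% t(G) + Pe) %*% t(IBi)
    Sxy <- Sx %*% t(G) %*% t(IBi)
    sigma <- rbind(cbind(Sx, Sxy), cbind(t(Sxy), Syy))
    dimnames(sigma) <- list(v, v)
  } else {
    model <- switch(spec$framework,
                    apim = build_apim(spec$design),
                    cfm = build_cfm(spec$design))
    sigma <- implied_covariance(model, spec$theta)
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(ev))
    stop("population covariance is not positive definite (smallest ",
         "eigenvalue ", format(min(ev)), ")", call. = FALSE)
  sigma
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Draw a synthetic dyad sample
#'
#' `n` independent multivariate-normal dyads with the spec's implied
#' population covariance and means, via a Cholesky factor applied to a
#' standard-normal matrix.  Bit-for-bit reproducible for a fixed seed.
#'
#' @param spec A [generator_spec()].
#' @return A [dyad_table()] with columns `dyad_id` and the four design
#'   variables.
#' @export
simulate_dyads <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  sigma <- spec$sigma
  v <- colnames(sigma)
  ch <- chol(sigma)
  Z <- with_seed(spec$seed,
                 matrix(stats::rnorm(spec$n * ncol(sigma)), nrow = spec$n))
  dat <- Z %*% ch
  dat <- sweep(dat, 2, spec$means[v], "+")
  colnames(dat) <- v
  out <- data.frame(dyad_id = seq_len(spec$n))
  for (cn in v) out[[cn]] <- dat[, cn]
  dyad_table(out, roles = spec$design$roles,
             variables = c(spec$design$predictor, spec$design$outcome))
}

matching_model <- function(spec, variant = NULL) {
  switch(spec$framework,
         apim = build_apim(spec$design,
                           if (is.null(variant)) "basic" else variant),
         mim = build_mim(spec$design,
                         if (is.null(variant)) "basic" else variant),
         cfm = build_cfm(spec$design))
}

#' Monte-Carlo parameter-recovery experiment
#'
#' Repeatedly simulates from a [generator_spec()] and refits the matching
#' model, summarizing per-parameter mean estimate, bias, RMSE, the
#' empirical SD of the estimates, the mean reported SE, and 95% Wald
#' coverage for each sample size in `n_grid`.  When the population
#' satisfies an equality constraint (`type1_variant` given, e.g.
#' `"actor_equal"` with equal population actor effects), the rejection
#' rate of the corresponding chi-square difference test at `alpha` is also
#' recorded.  Replicate r at grid position g uses seed
#' `seed + (g - 1) * replicates + r` so replicates are independent and
#' reproducible.
#'
#' @param spec A [generator_spec()] (its `n` is ignored in favor of
#'   `n_grid`).
#' @param replicates Replicates per grid point (>= 50).
#' @param n_grid Sample sizes to simulate at.
#' @param type1_variant Optional equality-constrained variant for the
#'   type-I-error check.
#' @param alpha Test level for coverage/rejection bookkeeping.
#' @return A data frame (one row per n x parameter) with attributes
#'   `type1` (rejection rate per n, or `NULL`) and `nonconvergence`; the
#'   experiment is flagged invalid (attribute `valid`) if more than 5% of
#'   fits fail to converge.
#' @export
recovery_experiment <- function(spec, replicates = 100, n_grid = spec$n,
                                type1_variant = NULL, alpha = 0.05) {
  stopifnot(inherits(spec, "generator_spec"))
  if (replicates < 50)
    stop("use at least 50 replicates for a stable summary", call. = FALSE)
  base_seed <- if (is.null(spec$seed)) 1L else spec$seed
  model <- matching_model(spec)
  labs <- free_params(model)
  truth <- spec$theta[labs]
  rows <- list()
  type1 <- NULL
  n_fail <- 0; n_total <- 0
  for (g in seq_along(n_grid)) {
    n <- n_grid[g]
    est <- matrix(NA_real_, replicates, length(labs),
                  dimnames = list(NULL, labs))
    ses <- est
    rej <- rep(NA, replicates)
    for (rep_i in seq_len(replicates)) {
      s <- spec
      s$n <- as.integer(n)
      s$seed <- base_seed + (g - 1L) * replicates + rep_i
      tab <- simulate_dyads(s)
      mom <- summarize_dyads(tab)
      fit <- tryCatch(
        suppressWarnings(fit_ml(model, mom)), error = function(e) NULL)
      n_total <- n_total + 1
      if (is.null(fit) || !fit$converged) { n_fail <- n_fail + 1; next }
      est[rep_i, ] <- fit$estimates[labs]
      ses[rep_i, ] <- fit$se[labs]
      if (!is.null(type1_variant)) {
        rfit <- tryCatch(
          suppressWarnings(fit_ml(matching_model(s, type1_variant), mom)),
          error = function(e) NULL)
        if (!is.null(rfit))
          rej[rep_i] <- chisq_diff_test(rfit, fit)$p.value < alpha
      }
    }
    zc <- stats::qnorm(1 - alpha / 2)
    cover <- colMeans(abs(est - rep(truth, each = replicates)) <= zc * ses,
                      na.rm = TRUE)
    rows[[g]] <- data.frame(
      n = n, parameter = labs, truth = unname(truth),
      mean = unname(colMeans(est, na.rm = TRUE)),
      bias = unname(colMeans(est, na.rm = TRUE) - truth),
      rmse = unname(sqrt(colMeans(
        (est - rep(truth, each = replicates))^2, na.rm = TRUE))),
      empirical_sd = unname(apply(est, 2, stats::sd, na.rm = TRUE)),
      mean_se = unname(colMeans(ses, na.rm = TRUE)),
      coverage = unname(cover),
      stringsAsFactors = FALSE)
    if (!is.null(type1_variant))
      type1 <- rbind(type1, data.frame(n = n,
                                       rejection_rate = mean(rej, na.rm = TRUE)))
  }
  out <- do.call(rbind, rows)
  fail_rate <- n_fail / n_total
  if (fail_rate > 0.05)
    warning("nonconvergence rate ", format(fail_rate),
            " exceeds 5%; experiment flagged invalid", call. = FALSE)
  structure(out, type1 = type1, nonconvergence = fail_rate,
            valid = fail_rate <= 0.05, class = c("recovery_table",
                                                 "data.frame"))
}
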