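#' Design of a four-variable dyadic analysis
#'
#' Names the two member roles and the per-member predictor and outcome
#' variables.  Observed variables enter the moment matrix in the order
#' predictor(role1), predictor(role2), outcome(role1), outcome(role2).
#'
#' @param roles Two distinct role names (default `"man"`, `"woman"`).
#' @param predictor,outcome Variable base names; the observed columns are
#'   `<variable>_<role>`.
#' @return An object of class `dyad_design`.
#' @export
dyad_design <- function(roles = c("man", "woman"), predictor = "anxiety",
                        outcome = "satisfaction") {
  if (length(roles) != 2 || anyDuplicated(roles))
    stop("need exactly two distinguishable roles", call. = FALSE)
  if (predictor == outcome)
    stop("predictor and outcome must differ", call. = FALSE)
  structure(list(roles = roles, predictor = predictor, outcome = outcome),
            class = "dyad_design")
}

#' Observed-variable names of a dyadic design
#'
#' @param design A [dyad_design()].
#' @return Character vector `c(x1, x2, y1, y2)` in model order.
#' @export
design_variables <- function(design) {
  stopifnot(inherits(design, "dyad_design"))
  c(paste(design$predictor, design$roles, sep = "_"),
    paste(design$outcome, design$roles, sep = "_"))
}

# shared variance/covariance block for APIM and MIM: free exogenous
# variances and covariance (compositional effect), free residual variances
# and covariance (residual nonindependence)
dyad_cov_block <- function(x, y, design) {
  data.frame(
    v1 = c(x[1], x[2], x[1], y[1], y[2], y[1]),
    v2 = c(x[1], x[2], x[2], y[1], y[2], y[2]),
    label = c(paste0("var_", x[1]), paste0("var_", x[2]),
              paste0("cov_", design$predictor),
              paste0("res_", y[1]), paste0("res_", y[2]),
              paste0("rescov_", design$outcome)),
    value = c(1, 1, 0, 1, 1, 0),
    stringsAsFactors = FALSE)
}

#' Build an Actor-Partner Interdependence Model
#'
#' Each member's predictor affects both members' outcomes: actor paths
#' `x_i -> y_i` and partner paths `x_j -> y_i`.  The exogenous covariance
#' (compositional effect) and the residual outcome covariance (residual
#' nonindependence) are free.  The basic model is saturated (df = 0);
#' variants tie the actor and/or partner paths across roles via shared
#' labels, giving df 1, 1 and 2.
#'
#' @param design A [dyad_design()].
#' @param variant One of `"basic"`, `"actor_equal"`, `"partner_equal"`,
#'   `"both_equal"`.
#' @return A [path_model()].
#' @export
build_apim <- function(design,
                       variant = c("basic", "actor_equal", "partner_equal",
                                   "both_equal")) {
  variant <- match.arg(variant)
  v <- design_variables(design)
  x <- v[1:2]; y <- v[3:4]
  r <- design$roles
  tie_a <- variant %in% c("actor_equal", "both_equal")
  tie_p <- variant %in% c("partner_equal", "both_equal")
  actor_lab <- if (tie_a) c("actor", "actor") else paste0("actor_", r)
  partner_lab <- if (tie_p) c("partner", "partner") else
    c(paste0("partner_", r[2], "_", r[1]), paste0("partner_", r[1], "_", r[2]))
  paths <- data.frame(
    from = c(x[1], x[2], x[2], x[1]),
    to = c(y[1], y[2], y[1], y[2]),
    label = c(actor_lab, partner_lab),
    value = 0, stringsAsFactors = FALSE)
  path_model(observed = v, paths = paths, covs = dyad_cov_block(x, y, design),
             meta = list(framework = "apim", variant = variant,
                         design = design,
                         actor = stats::setNames(actor_lab, r),
                         partner = stats::setNames(partner_lab, r)))
}

#' Build a Mutual Influence Model
#'
#' Actor paths `x_i -> y_i` plus reciprocal feedback paths between the two
#' outcomes (`y1 -> y2` and `y2 -> y1`), making the model nonrecursive;
#' there are no partner paths from the predictors.  The basic model is
#' just-identified (df = 0); variants tie the actor and/or feedback paths.
#'
#' @param design A [dyad_design()].
#' @param variant One of `"basic"`, `"actor_equal"`, `"feedback_equal"`,
#'   `"both_equal"`.
#' @return A [path_model()].
#' @export
build_mim <- function(design,
                      variant = c("basic", "actor_equal", "feedback_equal",
                                  "both_equal")) {
  variant <- match.arg(variant)
  v <- design_variables(design)
  x <- v[1:2]; y <- v[3:4]
  r <- design$roles
  tie_a <- variant %in% c("actor_equal", "both_equal")
  tie_f <- variant %in% c("feedback_equal", "both_equal")
  actor_lab <- if (tie_a) c("actor", "actor") else paste0("actor_", r)
  # feedback_<from role>_<to role>: path from that member's outcome
  feed_lab <- if (tie_f) c("feedback", "feedback") else
    c(paste0("feedback_", r[2], "_", r[1]), paste0("feedback_", r[1], "_", r[2]))
  paths <- data.frame(
    from = c(x[1], x[2], y[2], y[1]),
    to = c(y[1], y[2], y[1], y[2]),
    label = c(actor_lab, feed_lab),
    value = 0, stringsAsFactors = FALSE)
  path_model(observed = v, paths = paths, covs = dyad_cov_block(x, y, design),
             meta = list(framework = "mim", variant = variant,
                         design = design,
                         actor = stats::setNames(actor_lab, r),
                         # keyed by the role whose outcome the path leaves
                         feedback = stats::setNames(feed_lab, c(r[2], r[1]))))
}

#' Build a Common Fate Model
#'
#' The four observed scores load on two dyad-level latent variables (one
#' per construct); the causal path runs between the latents.  By default
#' every loading is fixed to 1 (so the latents are in the observed metric)
#' and the latent predictor variance is free; `scale_by_latent_variance`
#' instead fixes the latent predictor variance to 1 and frees the
#' loadings, tied within each latent.  Residuals are correlated within
#' person.  Either way the model has 9 free parameters and df = 1.
#'
#' @param design A [dyad_design()].
#' @param scale_by_latent_variance Use unit latent variance instead of unit
#'   loadings for identification.
#' @return A [path_model()] with latents `<predictor>_dyad` and
#'   `<outcome>_dyad`.
#' @export
build_cfm <- function(design, scale_by_latent_variance = FALSE) {
  v <- design_variables(design)
  x <- v[1:2]; y <- v[3:4]
  r <- design$roles
  lx <- paste0(design$predictor, "_dyad")
  ly <- paste0(design$outcome, "_dyad")
  if (!scale_by_latent_variance) {
    load_lab <- rep(NA_character_, 4)
    phi <- data.frame(v1 = lx, v2 = lx, label = paste0("var_", lx), value = 1)
    psi <- data.frame(v1 = ly, v2 = ly, label = paste0("res_", ly), value = 1)
  } else {
    # scale both latents by fixing their (residual) variances to 1 and
    # freeing the loadings, tied within construct
    load_lab <- c(rep(paste0("loading_", design$predictor), 2),
                  rep(paste0("loading_", design$outcome), 2))
    phi <- data.frame(v1 = lx, v2 = lx, label = NA_character_, value = 1)
    psi <- data.frame(v1 = ly, v2 = ly, label = NA_character_, value = 1)
  }
  load_val <- rep(1, 4)
  paths <- data.frame(
    from = c(lx, lx, ly, ly, lx),
    to = c(x[1], x[2], y[1], y[2], ly),
    label = c(load_lab, "dyadic_effect"),
    value = c(load_val, 0), stringsAsFactors = FALSE)
  covs <- rbind(
    phi, psi,
    data.frame(v1 = c(x, y), v2 = c(x, y),
               label = paste0("res_", c(x, y)), value = 1),
    data.frame(v1 = x, v2 = y, label = paste0("rescov_", r), value = 0))
  path_model(observed = v, latent = c(lx, ly), paths = paths, covs = covs,
             meta = list(framework = "cfm", design = design,
                         latent_x = lx, latent_y = ly,
                         effect = "dyadic_effect",
                         phi = paste0("var_", lx),
                         psi = paste0("res_", ly)))
}

#' Indirect effects in a fitted Mutual Influence Model
#'
#' In the MIM each member's predictor reaches the partner's outcome only
#' through the member's own outcome, so the indirect effect per direction
#' is the product actor(role) x feedback(role -> partner).  Standard
#' errors use the first-order delta method on the estimated parameter
#' covariance, z is tested against the standard normal.
#'
#' @param fit A [fit_ml()] result for a model built by [build_mim()].
#' @return Data frame with one row per direction: `from_role`, `to_role`,
#'   `estimate`, `se`, `z`, `p`.
#' @export
mim_indirect_effects <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  meta <- fit$model$meta
  if (is.null(meta$framework) || meta$framework != "mim")
    stop("fit is not from a Mutual Influence Model", call. = FALSE)
  if (is.null(fit$vcov))
    stop("fit lacks a parameter covariance; refit with standard errors",
         call. = FALSE)
  roles <- meta$design$roles
  out <- data.frame(from_role = roles, to_role = rev(roles),
                    estimate = NA_real_, se = NA_real_, z = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (i in 1:2) {
    a_lab <- meta$actor[[roles[i]]]
    f_lab <- meta$feedback[[roles[i]]]   # path from role i's outcome
    a <- fit$estimates[[a_lab]]
    f <- fit$estimates[[f_lab]]
    est <- a * f
    if (a_lab == f_lab) stop("degenerate label sharing", call. = FALSE)
    g <- c(f, a)
    vc <- fit$vcov[c(a_lab, f_lab), c(a_lab, f_lab)]
    se <- sqrt(max(drop(t(g) %*% vc %*% g), 0))
    out$estimate[i] <- est
    out$se[i] <- se
    out$z[i] <- if (se > 0) est / se else NA_real_
    out$p[i] <- 2 * stats::pnorm(-abs(out$z[i]))
  }
  out
}

#' Latent variance explained in a fitted Common Fate Model
#'
#' \deqn{R^2 = \frac{b^2 \phi}{b^2 \phi + \psi}} where `b` is the latent
#' regression, `phi` the latent predictor variance and `psi` the latent
#' residual variance.  A negative fitted `psi` (Heywood case) is clipped
#' to zero with a warning.
#'
#' @param fit A [fit_ml()] result for a model built by [build_cfm()].
#' @return The explained variance as a percentage.
#' @export
cfm_latent_r2 <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  meta <- fit$model$meta
  if (is.null(meta$framework) || meta$framework != "cfm")
    stop("fit is not from a Common Fate Model", call. = FALSE)
  b <- fit$estimates[[meta$effect]]
  phi <- if (meta$phi %in% names(fit$estimates)) fit$estimates[[meta$phi]]
         else 1   # latent variance fixed for identification
  psi <- if (meta$psi %in% names(fit$estimates)) fit$estimates[[meta$psi]]
         else 1
  if (psi < 0) {
    warning("negative latent residual variance clipped to 0 for R^2",
            call. = FALSE)
    psi <- 0
  }
  denom <- b^2 * phi + psi
  if (denom <= 0) return(NA_real_)
  100 * b^2 * phi / denom
}

#' Test the seven standard dyadic hypotheses
#'
#' Runs the full model battery on four-variable summary moments and
#' reports, per hypothesis: (1) actor effects exist (both saturated-APIM
#' actor z tests significant); (2) partner effects exist (judged on the
#' pooled partner effect of the partner-equal APIM, with the per-direction
#' saturated tests also recorded); (3) actor effects differ by role
#' (actor-equality chi-square difference test); (4) partner effects differ
#' by role; (5) dyadic feedback exists (either MIM feedback z test
#' significant); (6) feedback differs by role; (7) a dyad-level effect
#' links the latent constructs (CFM latent regression z test).
#'
#' @param moments A [summary_moments()] covering the design's four
#'   variables.
#' @param design A [dyad_design()].
#' @param alpha Two-sided significance level (default 0.05).
#' @param n_mult Chi-square multiplier convention passed to [fit_ml()].
#' @return An object of class `hypothesis_report`: a data frame with
#'   columns `id`, `hypothesis`, `test`, `statistic`, `p`, `supported`,
#'   with the underlying fits in `attr(, "fits")` and per-direction detail
#'   in `attr(, "details")`.
#' @export
run_hypothesis_suite <- function(moments, design = dyad_design(),
                                 alpha = 0.05, n_mult = "n") {
  v <- design_variables(design)
  if (!all(v %in% moments$variables))
    stop("moments lack design variables: ",
         paste(setdiff(v, moments$variables), collapse = ", "), call. = FALSE)
  r <- design$roles
  fits <- list(
    apim = fit_ml(build_apim(design), moments, n_mult = n_mult),
    apim_actor = fit_ml(build_apim(design, "actor_equal"), moments,
                        n_mult = n_mult),
    apim_partner = fit_ml(build_apim(design, "partner_equal"), moments,
                          n_mult = n_mult),
    mim = fit_ml(build_mim(design), moments, n_mult = n_mult),
    mim_feedback = fit_ml(build_mim(design, "feedback_equal"), moments,
                          n_mult = n_mult),
    cfm = fit_ml(build_cfm(design), moments, n_mult = n_mult))

  ap <- fits$apim
  actor_p <- ap$pvalues[paste0("actor_", r)]
  actor_z <- ap$z[paste0("actor_", r)]
  partner_labs <- c(paste0("partner_", r[2], "_", r[1]),
                    paste0("partner_", r[1], "_", r[2]))
  partner_p <- ap$pvalues[partner_labs]
  pooled_partner_z <- fits$apim_partner$z[["partner"]]
  pooled_partner_p <- fits$apim_partner$pvalues[["partner"]]
  cmp_actor <- chisq_diff_test(fits$apim_actor, ap)
  cmp_partner <- chisq_diff_test(fits$apim_partner, ap)
  feed_labs <- c(paste0("feedback_", r[2], "_", r[1]),
                 paste0("feedback_", r[1], "_", r[2]))
  feed_p <- fits$mim$pvalues[feed_labs]
  feed_z <- fits$mim$z[feed_labs]
  cmp_feed <- chisq_diff_test(fits$mim_feedback, fits$mim)
  cfm_z <- fits$cfm$z[["dyadic_effect"]]
  cfm_p <- fits$cfm$pvalues[["dyadic_effect"]]

  # weakest-direction summary for "both significant", strongest for "any"
  i_weak_actor <- which.max(actor_p)
  i_strong_feed <- which.min(feed_p)
  report <- data.frame(
    id = 1:7,
    hypothesis = c(
      "Actor effects of the predictor on one's own outcome",
      "Partner effects of the predictor on the partner's outcome",
      "Actor effects differ between roles",
      "Partner effects differ between roles",
      "Dyadic feedback between the two outcomes",
      "Feedback effects differ between roles",
      "Dyad-level latent effect of the predictor on the outcome"),
    test = c("z (both saturated APIM actor paths)",
             "z (pooled partner effect, partner-equal APIM)",
             "chi-square difference (actor-equal vs saturated APIM)",
             "chi-square difference (partner-equal vs saturated APIM)",
             "z (MIM feedback paths, either direction)",
             "chi-square difference (feedback-equal vs basic MIM)",
             "z (CFM latent regression)"),
    statistic = c(actor_z[i_weak_actor], pooled_partner_z,
                  cmp_actor$dchisq, cmp_partner$dchisq,
                  feed_z[i_strong_feed], cmp_feed$dchisq, cfm_z),
    p = c(max(actor_p), pooled_partner_p, cmp_actor$p.value,
          cmp_partner$p.value, min(feed_p), cmp_feed$p.value, cfm_p),
    stringsAsFactors = FALSE)
  report$supported <- report$p < alpha
  structure(report, alpha = alpha,
            details = list(actor_p = actor_p,
                           partner_direction_p = partner_p,
                           pooled_partner_p = pooled_partner_p,
                           feedback_p = feed_p),
            fits = fits,
            class = c("hypothesis_report", "data.frame"))
}

#' @export
print.hypothesis_report <- function(x, ...) {
  cat("Dyadic hypothesis suite (alpha =", attr(x, "alpha"), ")\n\n")
  df <- as.data.frame(x)
  df$statistic <- round(df$statistic, 3)
  df$p <- signif(df$p, 3)
  df$decision <- ifelse(df$supported, "supported", "not supported")
  print(df[, c("id", "hypothesis", "statistic", "p", "decision")],
        row.names = FALSE, right = FALSE)
  det <- attr(x, "details")
  cat("\nPer-direction partner-effect p-values (saturated APIM): ",
      paste(names(det$partner_direction_p),
            signif(det$partner_direction_p, 3), collapse = ", "), "\n")
  invisible(x)
}
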