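#' Maximum-likelihood discrepancy between covariance matrices
#'
#' \deqn{F_{ML} = \ln|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \ln|S| - p,}
#' nonnegative, zero iff \eqn{\Sigma = S}.  Scaled by the sample size it
#' becomes the model chi-square.
#'
#' @param S Sample covariance matrix (positive definite).
#' @param Sigma Model-implied covariance matrix (positive definite, same
#'   dimension).
#' @return The scalar discrepancy.
#' @export
ml_discrepancy <- function(S, Sigma) {
  S <- as.matrix(S); Sigma <- as.matrix(Sigma)
  p <- nrow(S)
  if (nrow(Sigma) != p || ncol(S) != p || ncol(Sigma) != p)
    stop("S and Sigma must be square matrices of equal dimension",
         call. = FALSE)
  chS <- tryCatch(chol(S), error = function(e) NULL)
  chSig <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(chS) || is.null(chSig))
    stop("both matrices must be positive definite", call. = FALSE)
  ld_S <- 2 * sum(log(diag(chS)))
  ld_Sig <- 2 * sum(log(diag(chSig)))
  ld_Sig + sum(S * chol2inv(chSig)) - ld_S - p
}

# Precompiled discrepancy and analytic-gradient closures: fixed RAM
# entries and the free-entry index maps are resolved once, so each
# evaluation is a handful of small matrix operations.  With
# E = (I-A)^{-1} and G = Sigma^{-1}(Sigma - S)Sigma^{-1}, dF/dA_{ij} =
# 2[E S_m E' P E]_{ji} and dF/dS_{kl} is [E' P E] (doubled off-diagonal),
# where P carries G into the full-variable space.  The objective returns
# a large penalty outside the PD region so quasi-Newton steps retreat;
# the gradient is zero there (the line search relies on the objective).
make_ml_closures <- function(model, S) {
  vars <- c(model$observed, model$latent)
  m <- length(vars)
  p <- length(model$observed)
  labs <- free_params(model)
  pa <- model$paths
  cv <- model$covs
  A0 <- matrix(0, m, m)
  S0 <- matrix(0, m, m)
  ti <- match(pa$to, vars); fi <- match(pa$from, vars)
  fixA <- is.na(pa$label)
  A0[cbind(ti, fi)[fixA, , drop = FALSE]] <- pa$value[fixA]
  i1 <- match(cv$v1, vars); i2 <- match(cv$v2, vars)
  fixC <- is.na(cv$label)
  S0[cbind(i1, i2)[fixC, , drop = FALSE]] <- cv$value[fixC]
  S0[cbind(i2, i1)[fixC, , drop = FALSE]] <- cv$value[fixC]
  freeA_idx <- (fi[!fixA] - 1L) * m + ti[!fixA]
  freeA_par <- match(pa$label[!fixA], labs)
  freeS_lo <- (i2[!fixC] - 1L) * m + i1[!fixC]
  freeS_hi <- (i1[!fixC] - 1L) * m + i2[!fixC]
  freeS_par <- match(cv$label[!fixC], labs)
  Sobs <- S[model$observed, model$observed]
  ld_S <- as.numeric(determinant(Sobs, logarithm = TRUE)$modulus)
  Im <- diag(m)
  obs <- seq_len(p)
  nfree <- length(labs)
  ti_free <- ti[!fixA]; fi_free <- fi[!fixA]
  s1_free <- i1[!fixC]; s2_free <- i2[!fixC]
  core <- function(theta) {
    A <- A0; A[freeA_idx] <- theta[freeA_par]
    Sm <- S0; Sm[freeS_lo] <- theta[freeS_par]; Sm[freeS_hi] <- theta[freeS_par]
    E <- tryCatch(solve(Im - A), error = function(e) NULL)
    if (is.null(E) || anyNA(E)) return(NULL)
    full <- E %*% Sm %*% t(E)
    sig <- (full[obs, obs, drop = FALSE] +
            t(full[obs, obs, drop = FALSE])) / 2
    ch <- tryCatch(chol(sig), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    list(E = E, Sm = Sm, sig = sig, siginv = chol2inv(ch),
         value = 2 * sum(log(diag(ch))) + sum(Sobs * chol2inv(ch)) -
           ld_S - p)
  }
  fn <- function(theta) {
    cr <- core(theta)
    if (is.null(cr) || !is.finite(cr$value)) return(1e10)
    cr$value
  }
  gr <- function(theta) {
    cr <- core(theta)
    if (is.null(cr) || !is.finite(cr$value)) return(numeric(nfree))
    G <- cr$siginv %*% (cr$sig - Sobs) %*% cr$siginv
    P <- matrix(0, m, m)
    P[obs, obs] <- G
    PE <- P %*% cr$E
    M <- crossprod(cr$E, PE)                    # E' P E
    Q <- (cr$E %*% cr$Sm %*% t(cr$E)) %*% PE    # E Sm E' P E
    g <- numeric(nfree)
    for (r in seq_along(freeA_par))
      g[freeA_par[r]] <- g[freeA_par[r]] + 2 * Q[fi_free[r], ti_free[r]]
    for (r in seq_along(freeS_par)) {
      add <- if (s1_free[r] == s2_free[r]) M[s1_free[r], s1_free[r]]
             else 2 * M[s1_free[r], s2_free[r]]
      g[freeS_par[r]] <- g[freeS_par[r]] + add
    }
    g
  }
  list(fn = fn, gr = gr)
}

num_gradient <- function(fn, theta) {
  h <- 1e-6 * pmax(abs(theta), 1)
  vapply(seq_along(theta), function(i) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h[i]; tm[i] <- tm[i] - h[i]
    (fn(tp) - fn(tm)) / (2 * h[i])
  }, numeric(1))
}

# Data-driven start values.  For observed-variable models the saturated
# system has a closed-form solution (normal/instrumental moment equations
# for the paths, then S-parameters from (I-A) S (I-A)'), which serves as
# the start even for equality-constrained variants.  Latent models use
# moment proxies for unit-loading constructs and sample variances.
start_values <- function(model, S) {
  theta <- model_starts(model)
  labs <- names(theta)
  vars <- c(model$observed, model$latent)
  pa <- model$paths
  cv <- model$covs
  obs <- model$observed

  if (length(model$latent) == 0) {
    p <- length(obs)
    outcomes <- unique(pa$to)
    exo <- setdiff(obs, outcomes)
    A <- matrix(0, p, p, dimnames = list(obs, obs))
    written <- stats::setNames(rep(FALSE, length(labs)), labs)
    for (y in outcomes) {
      rows <- which(pa$to == y)
      preds <- pa$from[rows]
      free <- !is.na(pa$label[rows])
      endo <- intersect(preds, outcomes)
      b <- NULL
      if (length(endo) && length(exo) == length(preds))
        b <- tryCatch(solve(S[exo, preds, drop = FALSE], S[exo, y]),
                      error = function(e) NULL)
      if (is.null(b))
        b <- tryCatch(solve(S[preds, preds, drop = FALSE], S[preds, y]),
                      error = function(e) rep(0, length(preds)))
      A[y, preds] <- b
      A[y, preds[!free]] <- pa$value[rows][!free]
      for (k in seq_along(rows)) {
        lab <- pa$label[rows[k]]
        if (free[k] && !written[lab]) { theta[lab] <- b[k]; written[lab] <- TRUE }
      }
    }
    IA <- diag(p) - A
    Sm <- IA %*% S[obs, obs] %*% t(IA)
    dimnames(Sm) <- list(obs, obs)
    for (i in seq_len(nrow(cv))) {
      lab <- cv$label[i]
      if (is.na(lab) || written[lab]) next
      theta[lab] <- Sm[cv$v1[i], cv$v2[i]]
      written[lab] <- TRUE
    }
    # guard degenerate variance starts
    for (i in seq_len(nrow(cv))) {
      lab <- cv$label[i]
      if (!is.na(lab) && cv$v1[i] == cv$v2[i] && theta[lab] <= 0)
        theta[lab] <- 0.5 * S[cv$v1[i], cv$v1[i]]
    }
    theta[!is.finite(theta)] <- 0
    return(theta)
  }

  outcomes <- unique(pa$to[!is.na(pa$label) | pa$value != 0])

  # variance entries keyed by variable
  for (i in seq_len(nrow(cv))) {
    if (is.na(cv$label[i])) next
    v1 <- cv$v1[i]; v2 <- cv$v2[i]
    if (v1 == v2 && v1 %in% model$observed) {
      base <- S[v1, v1]
      theta[cv$label[i]] <- if (v1 %in% outcomes) 0.6 * base else base
    } else if (v1 == v2) {
      # latent variance: mean covariance among its unit-loading indicators
      ind <- pa$from == v1 & is.na(pa$label) & pa$value == 1 &
        pa$to %in% model$observed
      ind_vars <- pa$to[ind]
      if (length(ind_vars) >= 2) {
        cc <- S[ind_vars, ind_vars]
        theta[cv$label[i]] <- max(mean(cc[upper.tri(cc)]),
                                  0.05 * mean(diag(S)))
      } else {
        theta[cv$label[i]] <- 0.5 * mean(diag(S))
      }
    }
  }

  # per-outcome OLS starts for paths among observed variables
  for (y in intersect(outcomes, model$observed)) {
    rows <- which(pa$to == y & !is.na(pa$label) & pa$from %in% model$observed)
    if (!length(rows)) next
    preds <- pa$from[rows]
    b <- tryCatch(solve(S[preds, preds, drop = FALSE], S[preds, y]),
                  error = function(e) rep(0, length(preds)))
    for (k in seq_along(rows)) {
      lab <- pa$label[rows[k]]
      if (theta[lab] == 0 || is.na(theta[lab])) theta[lab] <- b[k]
    }
    # shrink residual-variance start by the regression fit
    res <- S[y, y] - sum(b * S[preds, y])
    vrow <- which(cv$v1 == y & cv$v2 == y & !is.na(cv$label))
    if (length(vrow)) theta[cv$label[vrow[1]]] <- max(res, 0.1 * S[y, y])
  }

  theta[!is.finite(theta)] <- 0
  theta
}

polish_newton <- function(fn, gr, theta, max_iter = 30, tol = 1e-10) {
  for (it in seq_len(max_iter)) {
    g <- gr(theta)
    if (sqrt(sum(g^2)) < tol) break
    H <- stats::optimHess(theta, fn, gr)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    f0 <- fn(theta)
    alpha <- 1
    improved <- FALSE
    while (alpha >= 1e-4) {
      cand <- theta - alpha * step
      if (fn(cand) <= f0 + 1e-12) { theta <- cand; improved <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!improved) break
  }
  theta
}

#' Fit a path model by maximum likelihood to a covariance matrix
#'
#' Minimizes the ML discrepancy [ml_discrepancy()] over the free
#' parameters by quasi-Newton (BFGS) iteration with up to five
#' deterministically jittered restarts.  The model chi-square is
#' `N * F_ML` where `N` is `n` (the default, following the convention of
#' mainstream SEM software) or `n - 1`.  Standard errors come from the
#' inverse of the numerically differentiated Hessian of `N * F_ML / 2` at
#' the minimum; z statistics are tested against the standard normal.
#' Only the covariance structure is modeled; means are treated as
#' saturated.
#'
#' @param model A [path_model()] with `df >= 0`.
#' @param S Sample covariance matrix with dimnames covering the model's
#'   observed variables, or a [summary_moments()] object.
#' @param n Number of dyads behind `S` (taken from `S` when it is a
#'   `summary_moments` object).
#' @param n_mult Chi-square multiplier convention, `"n"` (default) or
#'   `"n-1"`.
#' @param start Optional named start vector overriding the data-driven
#'   defaults.
#' @param restarts Maximum number of jittered restarts when the gradient
#'   criterion (norm < 1e-6) is not met.
#' @return An object of class `sem_fit`: parameter table (estimate, SE, z,
#'   two-sided p), `chisq`, `df`, `pvalue`, `discrepancy`, fit indices,
#'   parameter covariance `vcov`, implied covariance `Sigma`, convergence
#'   status.
#' @export
fit_ml <- function(model, S, n = NULL, n_mult = c("n", "n-1"),
                   start = NULL, restarts = 5) {
  stopifnot(inherits(model, "path_model"))
  n_mult <- match.arg(n_mult)
  if (inherits(S, "summary_moments")) {
    mc <- moments_to_covariance(S)
    if (is.null(n)) n <- mc$n
    S <- mc$sigma
  }
  if (is.null(n)) stop("'n' is required when S is a plain matrix",
                       call. = FALSE)
  S <- as.matrix(S)
  obs <- model$observed
  if (is.null(dimnames(S)) && nrow(S) == length(obs)) {
    dimnames(S) <- list(obs, obs)
  }
  if (!all(obs %in% rownames(S)))
    stop("S lacks variables: ",
         paste(setdiff(obs, rownames(S)), collapse = ", "), call. = FALSE)
  S <- S[obs, obs]
  df <- model_df(model)
  if (df < 0)
    stop("model is under-identified: ", -df,
         " more free parameters than observed moments", call. = FALSE)
  N_mult <- if (n_mult == "n") n else n - 1

  labs <- free_params(model)
  cl <- make_ml_closures(model, S)
  fn <- cl$fn; gr <- cl$gr
  theta <- start_values(model, S)
  if (!is.null(start)) theta[names(start)] <- start
  if (fn(theta) >= 1e10) theta[] <- 0.1

  best <- NULL
  scale0 <- pmax(abs(theta), 0.5)
  for (attempt in 0:restarts) {
    init <- if (attempt == 0) theta else
      # deterministic jitter, growing with the attempt index
      theta + 0.15 * attempt * scale0 * cos(seq_along(theta) * (attempt + 1))
    if (fn(init) >= 1e10) init <- theta
    opt <- stats::optim(init, fn, gr, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-12))
    # damped Newton polish sharpens the gradient criterion
    opt$par <- polish_newton(fn, gr, opt$par)
    opt$value <- fn(opt$par)
    grad <- gr(opt$par)
    gnorm <- sqrt(sum(grad^2))
    if (is.null(best) || opt$value < best$value) {
      best <- opt; best$gnorm <- gnorm
    }
    if (gnorm < 1e-6) break
  }
  est <- stats::setNames(best$par, labs)
  converged <- best$gnorm < 1e-6
  if (!converged)
    warning("optimizer did not meet the gradient criterion (|g| = ",
            format(best$gnorm), ") after ", restarts, " restarts",
            call. = FALSE)
  discrepancy <- fn(est)
  chisq <- max(N_mult * discrepancy, 0)
  # a saturated model reproduces S exactly; a residual discrepancy at
  # machine scale is optimization noise, not misfit
  if (df == 0 && discrepancy < 1e-8) chisq <- 0

  # observed information of N_mult * F/2 (the Hessian is linear in the
  # multiplier, so differentiate F once and rescale)
  H <- (N_mult / 2) * stats::optimHess(est, fn, gr)
  vc <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(vc)) || any(diag(vc) < 0)) {
    warning("information matrix is ill-conditioned; standard errors use a ",
            "pseudo-inverse", call. = FALSE)
    vc <- MASS::ginv(H)
  } else {
    rc <- rcond(H)
    if (rc < 1e-12)
      warning("information matrix nearly singular (rcond = ", format(rc),
              ")", call. = FALSE)
  }
  dimnames(vc) <- list(labs, labs)
  se <- sqrt(pmax(diag(vc), 0))
  z <- est / ifelse(se > 0, se, NA_real_)
  pz <- 2 * stats::pnorm(-abs(z))

  # Heywood check: negative fitted variances
  cvv <- model$covs
  var_labs <- unique(cvv$label[!is.na(cvv$label) & cvv$v1 == cvv$v2])
  hey <- var_labs[est[var_labs] < 0]
  if (length(hey))
    warning("Heywood case: negative variance estimate for ",
            paste(hey, collapse = ", "), call. = FALSE)

  sigma_hat <- implied_covariance(model, est)
  base <- baseline_chisq(S, N_mult)
  indices <- fit_indices(chisq, df, n, base$chisq, base$df, S, sigma_hat)

  structure(
    list(model = model,
         estimates = est, se = stats::setNames(se, labs),
         z = stats::setNames(z, labs), pvalues = stats::setNames(pz, labs),
         vcov = vc,
         chisq = chisq, df = df,
         pvalue = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE)
                  else NA_real_,
         discrepancy = discrepancy,
         fit = indices,
         Sigma = sigma_hat, S = S, n = n, n_mult = n_mult,
         converged = converged, gradient_norm = best$gnorm,
         heywood = hey),
    class = "sem_fit")
}

# independence baseline: covariances fixed to 0, variances free, whose ML
# solution is diag(S); chi-square has the closed form -N log|R|
baseline_chisq <- function(S, N_mult) {
  p <- nrow(S)
  ld_S <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  list(chisq = max(N_mult * (sum(log(diag(S))) - ld_S), 0),
       df = p * (p - 1) / 2)
}

#' Goodness-of-fit indices for a covariance-structure model
#'
#' Computes chi-square/df, CFI, TLI (capped at 1 with the raw value
#' retained), RMSEA and SRMR against an independence baseline fitted to
#' the same sample covariance.  With `df = 0` (saturated models) RMSEA is
#' 0 by convention and chi-square/df and TLI are undefined; the returned
#' `saturated` flag records this.
#'
#' @param chisq,df Model chi-square and degrees of freedom.
#' @param n Sample size (used in the RMSEA denominator).
#' @param baseline_chisq,baseline_df Chi-square and df of the independence
#'   (zero-covariance) baseline.
#' @param S,Sigma Optional sample and implied covariance matrices; needed
#'   for SRMR.
#' @return List with `chisq_df`, `cfi`, `tli`, `tli_raw`, `rmsea`, `srmr`,
#'   `baseline_chisq`, `baseline_df`, `saturated`.
#' @export
fit_indices <- function(chisq, df, n, baseline_chisq, baseline_df,
                        S = NULL, Sigma = NULL) {
  if (df == 0 && chisq > 1e-6)
    stop("inconsistent input: zero degrees of freedom with nonzero chi-square",
         call. = FALSE)
  num <- max(chisq - df, 0)
  den <- max(baseline_chisq - baseline_df, chisq - df, 0)
  cfi <- if (den > 0) 1 - num / den else 1
  if (df > 0 && baseline_df > 0) {
    rb <- baseline_chisq / baseline_df
    tli_raw <- (rb - chisq / df) / (rb - 1)
    tli <- min(tli_raw, 1)
  } else {
    tli_raw <- NA_real_; tli <- NA_real_
  }
  rmsea <- if (df > 0) sqrt(max(chisq - df, 0) / (df * n)) else 0
  srmr <- NA_real_
  if (!is.null(S) && !is.null(Sigma)) {
    d <- outer(sqrt(diag(S)), sqrt(diag(S)))
    std_res <- (S - Sigma) / d
    srmr <- sqrt(mean(std_res[lower.tri(std_res, diag = TRUE)]^2))
  }
  list(chisq_df = if (df > 0) chisq / df else NA_real_,
       cfi = cfi, tli = tli, tli_raw = tli_raw, rmsea = rmsea, srmr = srmr,
       baseline_chisq = baseline_chisq, baseline_df = baseline_df,
       saturated = df == 0)
}

#' Chi-square difference test for nested models
#'
#' Likelihood-ratio comparison of a restricted model against the fuller
#' model it is nested in (typically an equality-constrained variant against
#' the saturated dyadic model).  A tiny negative difference (|value| <
#' 1e-6) from numerical optimization is clipped to zero.
#'
#' @param restricted,full [sem_fit()] results on the same data, with
#'   `restricted` having more degrees of freedom.
#' @return An object of class `model_comparison` with `dchisq`, `ddf`,
#'   `p.value`.
#' @export
chisq_diff_test <- function(restricted, full) {
  stopifnot(inherits(restricted, "sem_fit"), inherits(full, "sem_fit"))
  if (!setequal(restricted$model$observed, full$model$observed))
    stop("models are fitted to different variables", call. = FALSE)
  if (restricted$n != full$n)
    stop("models are fitted to different sample sizes", call. = FALSE)
  ddf <- restricted$df - full$df
  if (ddf <= 0)
    stop("'restricted' must have more degrees of freedom than 'full' ",
         "(got Δdf = ", ddf, ")", call. = FALSE)
  d <- restricted$chisq - full$chisq
  if (d < -1e-6)
    warning("chi-square difference is negative (", format(d),
            "); the models may not be nested", call. = FALSE)
  d <- max(d, 0)
  structure(list(dchisq = d, ddf = ddf,
                 p.value = stats::pchisq(d, ddf, lower.tail = FALSE)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Chi-square difference test: Δχ²(%d) = %.3f, p = %.3f\n",
              x$ddf, x$dchisq, x$p.value))
  invisible(x)
}

#' Closed-form coefficients for just-identified path systems
#'
#' Solves the moment equations of a saturated simultaneous-equation system
#' directly: ordinary normal equations when an outcome has only exogenous
#' predictors, instrumental-moment equations (all exogenous variables as
#' instruments) when it has endogenous ones.  Used as the independent
#' cross-check for [fit_ml()] on saturated models.
#'
#' @param S Sample covariance matrix with dimnames.
#' @param equations Named list: outcome name -> character vector of its
#'   predictors.
#' @return Named list of coefficient vectors, one per outcome.
#' @export
saturated_path_oracle <- function(S, equations) {
  S <- as.matrix(S)
  outcomes <- names(equations)
  exo <- setdiff(rownames(S), outcomes)
  out <- stats::setNames(vector("list", length(outcomes)), outcomes)
  for (y in outcomes) {
    preds <- equations[[y]]
    endo <- intersect(preds, outcomes)
    if (!length(endo)) {
      Z <- preds
    } else {
      Z <- exo
    }
    if (length(Z) != length(preds))
      stop("equation for '", y, "' is not just-identified: ", length(Z),
           " instruments for ", length(preds), " predictors", call. = FALSE)
    out[[y]] <- stats::setNames(
      solve(S[Z, preds, drop = FALSE], S[Z, y]), preds)
  }
  out
}

#' @export
print.sem_fit <- function(x, digits = 3, ...) {
  cat("Covariance-structure ML fit (n =", x$n, ")\n")
  if (!is.null(x$model$meta$framework))
    cat("Framework:", toupper(x$model$meta$framework),
        if (!is.null(x$model$meta$variant)) paste0("(", x$model$meta$variant, ")"),
        "\n")
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  tab <- parameter_table(x)
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$z <- round(tab$z, 2)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  if (x$df > 0) {
    cat(sprintf("\nχ²(%d) = %.3f, p = %.3f, χ²/df = %.3f\n",
                x$df, x$chisq, x$pvalue, x$fit$chisq_df))
    cat(sprintf("CFI = %.3f, TLI = %.3f, RMSEA = %.3f, SRMR = %.3f\n",
                x$fit$cfi, x$fit$tli, x$fit$rmsea, x$fit$srmr))
  } else {
    cat("\nModel is saturated (df = 0); fit is exact.\n")
  }
  invisible(x)
}

#' Parameter table of a fitted model
#'
#' @param fit A `sem_fit` object.
#' @return Data frame with columns `label`, `estimate`, `se`, `z`, `p`.
#' @export
parameter_table <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  data.frame(label = names(fit$estimates),
             estimate = unname(fit$estimates),
             se = unname(fit$se), z = unname(fit$z), p = unname(fit$pvalues),
             stringsAsFactors = FALSE)
}
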