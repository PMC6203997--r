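#' Summary moments for a set of dyadic variables
#'
#' Bundles the sufficient statistics of a multivariate-normal description of
#' dyad-level data: the number of dyads, per-variable means and standard
#' deviations, and the correlation matrix.  Covariance-structure models can
#' be fitted directly to an object of this class, which is how published
#' analyses are reproduced when only a descriptive table is available.
#'
#' @param n Number of dyads the moments were computed from.
#' @param means Numeric vector of variable means.
#' @param sds Numeric vector of standard deviations (must be positive).
#'   Conventional descriptive (n-1 denominator) values are expected.
#' @param correlations Symmetric correlation matrix with unit diagonal.
#' @param variables Character vector of variable names; defaults to the
#'   names of `means` or the dimnames of `correlations`.
#' @param p_values Optional symmetric matrix of two-sided p-values for the
#'   correlations (filled in by [summarize_dyads()]).
#'
#' @return An object of class `summary_moments`.
#' @seealso [moments_to_covariance()], [summarize_dyads()],
#'   [infertile_couples_moments()]
#' @export
summary_moments <- function(n, means, sds, correlations, variables = NULL,
                            p_values = NULL) {
  correlations <- as.matrix(correlations)
  k <- length(means)
  if (is.null(variables)) {
    variables <- names(means)
    if (is.null(variables)) variables <- rownames(correlations)
    if (is.null(variables)) variables <- paste0("v", seq_len(k))
  }
  if (length(sds) != k || nrow(correlations) != k || ncol(correlations) != k)
    stop("means, sds and correlations must describe the same variables",
         call. = FALSE)
  if (length(variables) != k)
    stop("'variables' must name every column", call. = FALSE)
  if (anyDuplicated(variables))
    stop("variable names must be unique", call. = FALSE)
  if (any(!is.finite(sds)) || any(sds <= 0))
    stop("all standard deviations must be positive", call. = FALSE)
  if (max(abs(correlations - t(correlations))) > 1e-12)
    stop("correlation matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(correlations) - 1)) > 1e-12)
    stop("correlation matrix must have a unit diagonal", call. = FALSE)
  off <- correlations[upper.tri(correlations)]
  if (any(off < -1 | off > 1))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  if (n < 1 || n != round(n))
    stop("'n' must be a positive integer", call. = FALSE)

  dimnames(correlations) <- list(variables, variables)
  means <- stats::setNames(as.numeric(means), variables)
  sds <- stats::setNames(as.numeric(sds), variables)

  # eigenvalues slightly below zero are expected when correlations were
  # rounded for print; warn rather than refuse
  ev <- eigen(correlations, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) {
    if (min(ev) > -1e-8) {
      warning("correlation matrix is marginally non-PSD (smallest eigenvalue ",
              format(min(ev)), "), consistent with rounding", call. = FALSE)
    } else {
      warning("correlation matrix is not positive semi-definite (smallest ",
              "eigenvalue ", format(min(ev)), ")", call. = FALSE)
    }
  }
  structure(
    list(n = as.integer(n), variables = variables, means = means, sds = sds,
         correlations = correlations, p_values = p_values),
    class = "summary_moments")
}

#' @export
print.summary_moments <- function(x, digits = 3, ...) {
  cat("Summary moments for", length(x$variables), "variables over",
      x$n, "dyads\n\n")
  desc <- data.frame(mean = round(x$means, digits), sd = round(x$sds, digits))
  print(desc)
  cat("\nCorrelations:\n")
  print(round(x$correlations, digits))
  invisible(x)
}

#' Convert summary moments to a covariance matrix and mean vector
#'
#' The covariance is assembled elementwise as
#' \eqn{\sigma_{ij} = r_{ij} s_i s_j}.  Because printed correlations are
#' rounded, the result can be very slightly indefinite; eigenvalues above
#' `-1e-8` are tolerated silently, anything worse is an error unless
#' `repair = TRUE`, which clips negative eigenvalues to zero (nearest-PSD
#' in the eigenvalue sense).
#'
#' @param moments A [summary_moments()] object.
#' @param repair Clip negative eigenvalues instead of failing.
#' @return A list with elements `sigma` (covariance matrix), `mu`
#'   (mean vector) and `n`.
#' @export
moments_to_covariance <- function(moments, repair = FALSE) {
  stopifnot(inherits(moments, "summary_moments"))
  sigma <- moments$correlations * outer(moments$sds, moments$sds)
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE)
  tol <- 1e-8 * max(abs(ev$values))
  if (min(ev$values) < -tol) {
    if (!repair)
      stop("derived covariance matrix is not positive semi-definite ",
           "(smallest eigenvalue ", format(min(ev$values)),
           "); rerun with repair = TRUE to clip to the nearest PSD matrix",
           call. = FALSE)
    vals <- pmax(ev$values, 0)
    sigma <- ev$vectors %*% (vals * t(ev$vectors))
    sigma <- (sigma + t(sigma)) / 2
    dimnames(sigma) <- dimnames(moments$correlations)
  }
  list(sigma = sigma, mu = moments$means, n = moments$n)
}

#' Published moments for the infertile-couples anxiety study
#'
#' Summary statistics (n = 141 couples) of husbands' and wives' anxiety
#' (HADS-A, range 0-21) and marital satisfaction (10-item ENRICH, range
#' 10-50) from a cross-sectional study of couples attending an infertility
#' clinic.  The four variables carry the roles `man`/`woman`; these moments
#' are sufficient to fit every dyadic model in this package and serve as
#' the canonical worked example.
#'
#' @return A [summary_moments()] object with variables
#'   `satisfaction_man`, `anxiety_man`, `satisfaction_woman`,
#'   `anxiety_woman`.
#' @export
infertile_couples_moments <- function() {
  path <- system.file("extdata", "infertile_couples_moments.json",
                      package = "dyadfit", mustWork = TRUE)
  read_moments(path)
}

#' Read summary moments from a JSON document
#'
#' The document must contain keys `n`, `variables`, `means`, `sds` and
#' `correlations` (a full square matrix).
#'
#' @param path File path.
#' @return A [summary_moments()] object.
#' @export
read_moments <- function(path) {
  doc <- jsonlite::fromJSON(path)
  summary_moments(n = doc$n, means = doc$means, sds = doc$sds,
                  correlations = doc$correlations, variables = doc$variables)
}

#' Write summary moments to a JSON document
#'
#' @param moments A [summary_moments()] object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_moments <- function(moments, path) {
  stopifnot(inherits(moments, "summary_moments"))
  doc <- list(n = moments$n, variables = moments$variables,
              means = unname(moments$means), sds = unname(moments$sds),
              correlations = unname(moments$correlations))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
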