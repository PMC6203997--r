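#' Wide-format dyad table
#'
#' One row per dyad, with every analysis variable measured once per member.
#' Members are distinguishable by a role label (e.g. `"man"`/`"woman"`,
#' `"patient"`/`"caregiver"`); the data column for variable `v` of role `r`
#' is named `v_r`.
#'
#' @param data A data frame holding the id column and one column per
#'   (variable, role) pair.
#' @param roles Character vector of exactly two distinct role names.
#' @param variables Character vector of variable names; for each, both
#'   `<variable>_<role1>` and `<variable>_<role2>` must be present.
#' @param dyad_id Name of the dyad identifier column (unique per row).
#'
#' @return An object of class `dyad_table` (a data frame subclass).  Rows
#'   with a missing value in any analysis column are retained but flagged;
#'   see [complete_dyads()].
#' @export
dyad_table <- function(data, roles, variables, dyad_id = "dyad_id") {
  data <- as.data.frame(data)
  if (length(roles) != 2 || anyDuplicated(roles))
    stop("dyads need exactly two distinguishable roles", call. = FALSE)
  if (!dyad_id %in% names(data))
    stop("dyad id column '", dyad_id, "' not found", call. = FALSE)
  if (anyDuplicated(data[[dyad_id]]))
    stop("duplicate dyad ids: ",
         paste(unique(data[[dyad_id]][duplicated(data[[dyad_id]])]),
               collapse = ", "), call. = FALSE)
  for (v in variables) {
    for (r in roles) {
      col <- paste(v, r, sep = "_")
      if (!col %in% names(data))
        stop("missing column for variable '", v, "' of role '", r,
             "' (expected '", col, "')", call. = FALSE)
      if (!is.numeric(data[[col]]))
        stop("column '", col, "' must be numeric", call. = FALSE)
    }
  }
  structure(data,
            roles = roles, variables = variables, dyad_id = dyad_id,
            class = c("dyad_table", "data.frame"))
}

#' @export
print.dyad_table <- function(x, ...) {
  cat("Dyad table:", nrow(x), "dyads, roles",
      paste(sQuote(attr(x, "roles")), collapse = " / "),
      "\nVariables:", paste(attr(x, "variables"), collapse = ", "), "\n")
  n_inc <- sum(!complete_dyads(x))
  if (n_inc > 0) cat(n_inc, "dyads flagged incomplete\n")
  NextMethod()
}

dyad_columns <- function(table, variables = NULL) {
  if (is.null(variables)) variables <- attr(table, "variables")
  as.vector(t(outer(variables, attr(table, "roles"), paste, sep = "_")))
}

#' Which dyads have complete analysis data?
#'
#' @param table A [dyad_table()].
#' @param variables Variables to require; defaults to all.
#' @return Logical vector, `TRUE` for rows with no missing analysis value.
#' @export
complete_dyads <- function(table, variables = NULL) {
  stats::complete.cases(as.data.frame(table)[, dyad_columns(table, variables),
                                             drop = FALSE])
}

#' Read a wide-format dyad table from delimited text
#'
#' @param path Path to a delimited text file with a header row.  Comma is
#'   the default separator; tab is detected automatically (or force it by
#'   passing `sep`).
#' @param config Column mapping: either a named list or the path to a YAML
#'   file with keys `role1`, `role2`, `dyad_id` and `variables`, where
#'   `variables` maps each analysis variable to its two data columns in
#'   `(role1, role2)` order, e.g.
#'   `variables: {anxiety: [anx_m, anx_w]}`.
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab.
#' @return A [dyad_table()].
#' @export
read_dyad_table <- function(path, config, sep = NULL) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  for (key in c("role1", "role2", "variables"))
    if (is.null(config[[key]]))
      stop("column mapping is missing the '", key, "' key", call. = FALSE)
  id_col <- if (is.null(config$dyad_id)) "dyad_id" else config$dyad_id
  roles <- c(config$role1, config$role2)

  if (is.null(sep)) {
    header <- readLines(path, n = 1)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!id_col %in% names(raw))
    stop("mapped dyad id column '", id_col, "' not found in ", path,
         call. = FALSE)

  out <- data.frame(dyad_id = raw[[id_col]])
  vars <- names(config$variables)
  for (v in vars) {
    cols <- unlist(config$variables[[v]])
    if (length(cols) != 2)
      stop("variable '", v, "' must map to two columns (one per role)",
           call. = FALSE)
    for (i in 1:2) {
      if (!cols[i] %in% names(raw))
        stop("mapped column '", cols[i], "' for variable '", v,
             "' of role '", roles[i], "' not found", call. = FALSE)
      out[[paste(v, roles[i], sep = "_")]] <- as.numeric(raw[[cols[i]]])
    }
  }
  dyad_table(out, roles = roles, variables = vars, dyad_id = "dyad_id")
}

#' Write a dyad table as delimited text
#'
#' Columns are written under their internal `<variable>_<role>` names, so a
#' file produced here round-trips through [read_dyad_table()] with the
#' identity mapping.
#'
#' @param table A [dyad_table()].
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_dyad_table <- function(table, path, sep = ",") {
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Identity column mapping for a dyad table's own file format
#'
#' @param table A [dyad_table()].
#' @return A config list accepted by [read_dyad_table()].
#' @export
dyad_table_config <- function(table) {
  roles <- attr(table, "roles")
  vars <- attr(table, "variables")
  list(role1 = roles[1], role2 = roles[2], dyad_id = attr(table, "dyad_id"),
       variables = stats::setNames(
         lapply(vars, function(v) paste(v, roles, sep = "_")), vars))
}

#' Descriptive summary of a dyad table
#'
#' Computes, after listwise deletion on the requested variables, the number
#' of complete dyads, per-column means and standard deviations (n-1
#' denominator) and the full correlation matrix with two-sided p-values
#' from the t transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}}.
#'
#' @param table A [dyad_table()].
#' @param variables Analysis variables; defaults to all.
#' @return A [summary_moments()] object whose `p_values` element holds the
#'   correlation p-value matrix.
#' @export
summarize_dyads <- function(table, variables = NULL) {
  cols <- dyad_columns(table, variables)
  keep <- complete_dyads(table, variables)
  dat <- as.matrix(as.data.frame(table)[keep, cols, drop = FALSE])
  n <- nrow(dat)
  if (n < 3)
    stop("fewer than 3 complete dyads: descriptive summary is not defined",
         call. = FALSE)
  r <- stats::cor(dat)
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pmat <- 2 * stats::pt(-abs(tval), df = n - 2)
  diag(pmat) <- NA_real_
  summary_moments(n = n, means = colMeans(dat), sds = apply(dat, 2, stats::sd),
                  correlations = r, variables = cols, p_values = pmat)
}

#' Paired t test from summary moments
#'
#' Tests the mean difference of two paired measurements when only means,
#' SDs, their correlation and the sample size are available:
#' \deqn{t = \frac{\bar x_1 - \bar x_2}
#'   {\sqrt{(s_1^2 + s_2^2 - 2 r s_1 s_2)/n}}, \quad df = n - 1.}
#'
#' @param mean1,mean2 Group means.
#' @param sd1,sd2 Standard deviations (positive).
#' @param r12 Correlation between the paired measurements.
#' @param n Number of pairs.
#' @return An object of class `htest`.
#' @export
paired_t_from_summary <- function(mean1, mean2, sd1, sd2, r12, n) {
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive",
                                 call. = FALSE)
  if (r12 < -1 || r12 > 1) stop("r12 must lie in [-1, 1]", call. = FALSE)
  vd <- sd1^2 + sd2^2 - 2 * r12 * sd1 * sd2
  if (vd <= 0)
    stop("variance of the paired difference is zero: comparison degenerate",
         call. = FALSE)
  tstat <- (mean1 - mean2) / sqrt(vd / n)
  df <- n - 1
  structure(
    list(statistic = c(t = tstat), parameter = c(df = df),
         p.value = 2 * stats::pt(-abs(tstat), df),
         estimate = c(`mean difference` = mean1 - mean2),
         method = "Paired t test from summary moments",
         data.name = "summary moments"),
    class = "htest")
}
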