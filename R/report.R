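# Text and JSON rendering of descriptive summaries, fitted models and
# model-comparison tables.

sig_stars <- function(p) {
  ifelse(is.na(p), "",
  ifelse(p < 0.001, "***",
  ifelse(p < 0.01, "**",
  ifelse(p < 0.05, "*",
  ifelse(p < 0.1, "†", "")))))
}

fmt_num <- function(x, digits = 3, paper_style = FALSE) {
  out <- formatC(x, format = "f", digits = digits)
  if (paper_style) {
    # ".457" style: drop the leading zero of |x| < 1
    out <- sub("^(-?)0\\.", "\\1.", out)
  }
  out[is.na(x)] <- "-"
  out
}

#' Render fitted dyadic models as an aligned comparison table
#'
#' One column pair (estimate, SE with significance stars) per fitted
#' variant, followed by a model-fit block and chi-square difference tests
#' against the first (reference, usually saturated) fit.
#'
#' @param fits Named list of [fit_ml()] results on the same data.
#' @param digits Decimals in the human-readable table.
#' @param paper_style Suppress leading zeros (".457" style).
#' @return Character vector of report lines.
#' @export
render_fit_table <- function(fits, digits = 3, paper_style = FALSE) {
  stopifnot(length(fits) >= 1)
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- paste("Model", seq_along(fits))
  labs <- unique(unlist(lapply(fits, function(f) names(f$estimates))))
  header <- c("parameter", names(fits))
  rows <- lapply(labs, function(l) {
    vals <- vapply(fits, function(f) {
      if (!l %in% names(f$estimates)) return("-")
      paste0(fmt_num(f$estimates[[l]], digits, paper_style),
             sig_stars(f$pvalues[[l]]), " (",
             fmt_num(f$se[[l]], digits, paper_style), ")")
    }, character(1))
    c(l, vals)
  })
  fit_rows <- list(
    c("chisq", vapply(fits, function(f)
      fmt_num(f$chisq, digits, paper_style), character(1))),
    c("df", vapply(fits, function(f) as.character(f$df), character(1))),
    c("p", vapply(fits, function(f)
      fmt_num(f$pvalue, digits, paper_style), character(1))),
    c("chisq/df", vapply(fits, function(f)
      fmt_num(f$fit$chisq_df, digits, paper_style), character(1))),
    c("CFI", vapply(fits, function(f)
      fmt_num(f$fit$cfi, digits, paper_style), character(1))),
    c("TLI", vapply(fits, function(f)
      fmt_num(f$fit$tli, digits, paper_style), character(1))),
    c("RMSEA", vapply(fits, function(f)
      fmt_num(f$fit$rmsea, digits, paper_style), character(1))),
    c("SRMR", vapply(fits, function(f)
      fmt_num(f$fit$srmr, digits, paper_style), character(1))))
  cmp_rows <- list()
  if (length(fits) > 1) {
    ref <- fits[[1]]
    cmp_rows <- lapply(names(fits)[-1], function(nm) {
      f <- fits[[nm]]
      if (f$df <= ref$df) return(c(paste0("dchisq ", nm), rep("-", length(fits))))
      cmp <- chisq_diff_test(f, ref)
      vals <- rep("-", length(fits))
      vals[match(nm, names(fits))] <-
        sprintf("%s (df %d, p %s)", fmt_num(cmp$dchisq, digits, paper_style),
                cmp$ddf, fmt_num(cmp$p.value, digits, paper_style))
      c(paste0("dchisq vs ", names(fits)[1]), vals)
    })
  }
  all_rows <- c(list(header), rows, list(c("--- model fit ---",
                                           rep("", length(fits)))),
                fit_rows, cmp_rows)
  widths <- apply(do.call(rbind, all_rows), 2, function(cl) max(nchar(cl)))
  vapply(all_rows, function(rw)
    paste(mapply(formatC, rw, width = widths, flag = "-"), collapse = "  "),
    character(1))
}

#' Machine-readable representation of a fitted model
#'
#' Full-precision counterpart of the rendered tables: every number shown
#' in the text report appears here.
#'
#' @param fit A [fit_ml()] result.
#' @return A nested list ready for [jsonlite::write_json()].
#' @export
fit_to_list <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  list(framework = fit$model$meta$framework,
       variant = fit$model$meta$variant,
       n = fit$n, n_mult = fit$n_mult,
       converged = fit$converged,
       parameters = parameter_table(fit),
       chisq = fit$chisq, df = fit$df, p = fit$pvalue,
       discrepancy = fit$discrepancy,
       fit_indices = fit$fit[c("chisq_df", "cfi", "tli", "tli_raw",
                               "rmsea", "srmr")])
}

#' Render a descriptive summary as report lines
#'
#' @param moments A [summary_moments()] (with correlation p-values when
#'   available).
#' @param digits Decimals.
#' @return Character vector of report lines.
#' @export
render_summary <- function(moments, digits = 3) {
  k <- length(moments$variables)
  lines <- c(sprintf("Descriptive summary (n = %d dyads)", moments$n), "",
             sprintf("%-28s %10s %10s", "variable", "mean", "sd"))
  for (i in seq_len(k))
    lines <- c(lines, sprintf("%-28s %10s %10s", moments$variables[i],
                              fmt_num(moments$means[i], digits),
                              fmt_num(moments$sds[i], digits)))
  lines <- c(lines, "", "Correlations (lower triangle, with significance):")
  for (i in seq_len(k)) {
    cells <- vapply(seq_len(i), function(j) {
      if (i == j) return("1")
      star <- if (!is.null(moments$p_values))
        sig_stars(moments$p_values[i, j]) else ""
      paste0(fmt_num(moments$correlations[i, j], digits), star)
    }, character(1))
    lines <- c(lines, sprintf("%-28s %s", moments$variables[i],
                              paste(formatC(cells, width = 10),
                                    collapse = " ")))
  }
  lines
}

moments_to_list <- function(moments) {
  list(n = moments$n, variables = moments$variables,
       means = unname(moments$means), sds = unname(moments$sds),
       correlations = unname(moments$correlations),
       covariance = unname(moments_to_covariance(moments)$sigma))
}
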