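#' Definition of a sum-scored questionnaire scale
#'
#' @param name Scale name.
#' @param n_items Number of items.
#' @param min,max Integer response range shared by every item (e.g. 1-5 for
#'   a five-point agreement scale, 0-3 for symptom severity).
#' @param reverse Indices of reverse-keyed items (recoded before summing).
#' @return An object of class `scale_definition` whose `range` element is
#'   the attainable total-score range `[k*min, k*max]`.
#' @export
scale_definition <- function(name, n_items, min, max, reverse = integer(0)) {
  stopifnot(n_items >= 1, min < max,
            min == round(min), max == round(max))
  reverse <- as.integer(reverse)
  if (length(reverse) && (any(reverse < 1) || any(reverse > n_items)))
    stop("reverse-item indices must lie in 1..", n_items, call. = FALSE)
  structure(list(name = name, n_items = as.integer(n_items),
                 min = as.integer(min), max = as.integer(max),
                 reverse = reverse,
                 range = c(n_items * min, n_items * max)),
            class = "scale_definition")
}

#' Score a sum scale from item responses
#'
#' Reverse-keyed items are recoded as `min + max - x`, then items are
#' summed.  Respondents with any missing item get an `NA` total.
#'
#' @param items Matrix or data frame, one row per respondent, one column
#'   per item in scale order.
#' @param scale A [scale_definition()].
#' @return Numeric vector of total scores, each within the scale's declared
#'   range.
#' @export
score_scale <- function(items, scale) {
  stopifnot(inherits(scale, "scale_definition"))
  items <- as.matrix(items)
  if (ncol(items) != scale$n_items)
    stop("expected ", scale$n_items, " item columns, got ", ncol(items),
         call. = FALSE)
  bad <- which(!is.na(items) & (items < scale$min | items > scale$max),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("item response out of range [", scale$min, ", ", scale$max,
         "] at item ", bad[1, "col"], ", respondent ", bad[1, "row"],
         call. = FALSE)
  if (length(scale$reverse))
    items[, scale$reverse] <- scale$min + scale$max - items[, scale$reverse]
  rowSums(items)
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' \deqn{\alpha = \frac{k}{k-1}
#'   \left(1 - \frac{\sum_i s_i^2}{s_{\mathrm{total}}^2}\right)}
#' with sample (n-1) variances, where \eqn{s_i^2} are the item variances
#' and \eqn{s_{\mathrm{total}}^2} the variance of the item sum.
#'
#' @param items Item-response matrix (respondents x items), at least two
#'   items and three respondents with complete data.
#' @return The alpha coefficient (always \eqn{\le 1}; can be negative for
#'   badly keyed items).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  items <- items[stats::complete.cases(items), , drop = FALSE]
  k <- ncol(items)
  if (k < 2)
    stop("reliability is undefined for fewer than 2 items", call. = FALSE)
  if (nrow(items) < 3)
    stop("need at least 3 complete respondents", call. = FALSE)
  total_var <- stats::var(rowSums(items))
  if (total_var <= 0)
    stop("total-score variance is zero: reliability undefined", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
}
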