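#' RAM-style path model specification
#'
#' A covariance-structure model in reticular-action-model (RAM) form: a
#' directed-path matrix \eqn{A}, a symmetric variance/covariance matrix
#' \eqn{S}, and a filter \eqn{F} selecting the observed variables.  The
#' model-implied covariance of the observed variables is
#' \deqn{\Sigma(\theta) = F (I - A)^{-1} S (I - A)^{-\top} F^\top.}
#'
#' Entries of \eqn{A} and \eqn{S} are either fixed constants or free
#' parameters identified by a label; two entries sharing a label are
#' constrained equal and count as one parameter.  Degrees of freedom are
#' `p(p+1)/2 - (number of distinct labels)` for `p` observed variables.
#'
#' @param observed Character vector of observed-variable names (their order
#'   fixes the covariance-matrix order).
#' @param latent Character vector of latent-variable names (may be empty).
#' @param paths Data frame with columns `from`, `to`, `label`
#'   (`NA` for a fixed path) and `value` (the fixed value, or the start
#'   value of a free path).
#' @param covs Data frame with columns `v1`, `v2`, `label`, `value`
#'   describing the nonzero entries of `S` (variances when `v1 == v2`).
#'   Each unordered pair may appear once.
#' @param meta Optional list of builder metadata (framework, design,
#'   label roles) carried along for post-processors.
#' @return An object of class `path_model`.
#' @seealso [build_apim()], [build_mim()], [build_cfm()], [fit_ml()]
#' @export
path_model <- function(observed, latent = character(0), paths, covs,
                       meta = list()) {
  vars <- c(observed, latent)
  if (anyDuplicated(vars))
    stop("variable names must be unique across observed and latent",
         call. = FALSE)
  paths <- as.data.frame(paths, stringsAsFactors = FALSE)
  covs <- as.data.frame(covs, stringsAsFactors = FALSE)
  for (col in c("from", "to", "label", "value"))
    if (!col %in% names(paths)) stop("paths lack column '", col, "'",
                                     call. = FALSE)
  for (col in c("v1", "v2", "label", "value"))
    if (!col %in% names(covs)) stop("covs lack column '", col, "'",
                                    call. = FALSE)
  bad <- setdiff(c(paths$from, paths$to, covs$v1, covs$v2), vars)
  if (length(bad))
    stop("unknown variables in specification: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(paste(paths$to, paths$from)))
    stop("duplicate path entries", call. = FALSE)
  key <- apply(cbind(covs$v1, covs$v2), 1,
               function(z) paste(sort(z), collapse = "~~"))
  if (anyDuplicated(key))
    stop("duplicate variance/covariance entries", call. = FALSE)
  model <- structure(list(observed = observed, latent = latent,
                          paths = paths, covs = covs, meta = meta),
                     class = "path_model")
  if (model_df(model) < 0)
    warning("more free parameters than observed moments (df < 0); ",
            "the model cannot be fitted", call. = FALSE)
  model
}

#' Free parameters of a path model
#'
#' @param model A [path_model()].
#' @return Character vector of distinct free-parameter labels, in order of
#'   first appearance (paths before variances/covariances).
#' @export
free_params <- function(model) {
  stopifnot(inherits(model, "path_model"))
  labs <- c(model$paths$label, model$covs$label)
  unique(labs[!is.na(labs)])
}

#' Start values recorded in a path model
#'
#' @param model A [path_model()].
#' @return Named numeric vector, one start per free label (the first entry
#'   carrying that label).
#' @export
model_starts <- function(model) {
  labs <- free_params(model)
  all_lab <- c(model$paths$label, model$covs$label)
  all_val <- c(model$paths$value, model$covs$value)
  stats::setNames(all_val[match(labs, all_lab)], labs)
}

#' Model degrees of freedom
#'
#' @param model A [path_model()].
#' @return `p(p+1)/2` observed moments minus the number of distinct free
#'   labels.
#' @export
model_df <- function(model) {
  p <- length(model$observed)
  p * (p + 1) / 2 - length(free_params(model))
}

# Fill the numeric RAM matrices for a parameter vector named by label.
ram_matrices <- function(model, theta) {
  vars <- c(model$observed, model$latent)
  m <- length(vars)
  A <- matrix(0, m, m, dimnames = list(vars, vars))
  S <- matrix(0, m, m, dimnames = list(vars, vars))
  pa <- model$paths
  val <- ifelse(is.na(pa$label), pa$value, theta[pa$label])
  A[cbind(match(pa$to, vars), match(pa$from, vars))] <- val
  cv <- model$covs
  val <- ifelse(is.na(cv$label), cv$value, theta[cv$label])
  i <- match(cv$v1, vars); j <- match(cv$v2, vars)
  S[cbind(i, j)] <- val
  S[cbind(j, i)] <- val
  list(A = A, S = S)
}

#' Model-implied covariance matrix
#'
#' Evaluates \eqn{F (I - A)^{-1} S (I - A)^{-\top} F^\top} at a parameter
#' vector.  For nonrecursive models, \eqn{I - A} is singular exactly when a
#' feedback loop has product 1, in which case the offending loop is named.
#'
#' @param model A [path_model()].
#' @param theta Named numeric vector covering every free label.
#' @return Covariance matrix over the observed variables, in model order.
#' @export
implied_covariance <- function(model, theta = model_starts(model)) {
  stopifnot(inherits(model, "path_model"))
  missing_lab <- setdiff(free_params(model), names(theta))
  if (length(missing_lab))
    stop("theta lacks values for: ", paste(missing_lab, collapse = ", "),
         call. = FALSE)
  ram <- ram_matrices(model, theta)
  m <- nrow(ram$A)
  IA <- diag(m) - ram$A
  inv <- tryCatch(solve(IA), error = function(e) NULL)
  if (is.null(inv) || !all(is.finite(inv))) {
    loops <- which(ram$A != 0 & t(ram$A) != 0, arr.ind = TRUE)
    loops <- loops[loops[, 1] < loops[, 2], , drop = FALSE]
    vars <- rownames(ram$A)
    desc <- if (nrow(loops)) {
      paste(apply(loops, 1, function(z)
        paste(vars[z[1]], "<->", vars[z[2]])), collapse = "; ")
    } else "unknown"
    stop("nonrecursive feedback loop is unstable (I - A singular): ", desc,
         call. = FALSE)
  }
  full <- inv %*% ram$S %*% t(inv)
  p <- length(model$observed)
  sigma <- full[seq_len(p), seq_len(p), drop = FALSE]
  (sigma + t(sigma)) / 2
}

#' @export
print.path_model <- function(x, ...) {
  cat("RAM path model:", length(x$observed), "observed",
      if (length(x$latent)) paste0("+ ", length(x$latent), " latent") else "",
      "variables\n")
  if (!is.null(x$meta$framework))
    cat("Framework:", toupper(x$meta$framework), "\n")
  cat("Free parameters:", length(free_params(x)), " df:", model_df(x), "\n\n")
  show_ent <- function(df, arrow) {
    lab <- ifelse(is.na(df$label), paste0("= ", signif(df$value, 4)),
                  paste0("[", df$label, "]"))
    paste(" ", df[[1]], arrow, df[[2]], lab)
  }
  if (nrow(x$paths)) {
    cat("Paths:\n")
    cat(show_ent(x$paths[, c("from", "to", "label", "value")], "->"),
        sep = "\n")
  }
  cat("Variances/covariances:\n")
  cat(show_ent(x$covs[, c("v1", "v2", "label", "value")], "~~"), sep = "\n")
  invisible(x)
}

#' Serialize a path model to a plain-text (YAML) document
#'
#' @param model A [path_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_path_model <- function(model, path) {
  doc <- list(observed = model$observed, latent = model$latent,
              paths = lapply(seq_len(nrow(model$paths)), function(i)
                as.list(model$paths[i, ])),
              covs = lapply(seq_len(nrow(model$covs)), function(i)
                as.list(model$covs[i, ])),
              meta = model$meta["framework"])
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a path model from its YAML serialization
#'
#' @param path File path written by [write_path_model()].
#' @return A [path_model()].
#' @export
read_path_model <- function(path) {
  doc <- yaml::read_yaml(path)
  bind_rows <- function(lst, cols) {
    if (!length(lst)) {
      out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                           cols))
      out$value <- numeric(0)
      return(out)
    }
    do.call(rbind, lapply(lst, function(e) {
      e$label <- if (is.null(e$label)) NA_character_ else e$label
      as.data.frame(e[cols], stringsAsFactors = FALSE)
    }))
  }
  lat <- unlist(doc$latent)
  path_model(observed = unlist(doc$observed),
             latent = if (is.null(lat)) character(0) else lat,
             paths = bind_rows(doc$paths, c("from", "to", "label", "value")),
             covs = bind_rows(doc$covs, c("v1", "v2", "label", "value")),
             meta = if (is.null(doc$meta)) list() else doc$meta)
}
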