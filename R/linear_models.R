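# Multiple linear regression on one-hot factorial designs, with and without
# all pairwise interaction terms; nested-model F-tests; and classification of
# inhibitor pairs as additive, synergistic or antagonistic.

build_model_matrix <- function(X, extra = NULL) {
  M <- X$predictors
  if (!is.null(extra)) M <- cbind(M, extra)
  if (X$intercept) M <- cbind(`(Intercept)` = 1, M)
  M
}

check_full_rank <- function(M) {
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    dep <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
    stop("singular design: linearly dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  qrM
}

ols_fit <- function(M, y, intercept) {
  n <- nrow(M)
  p <- ncol(M)
  if (n <= p) stop("need more rows than fitted parameters (n > p)", call. = FALSE)
  qrM <- check_full_rank(M)
  beta <- qr.coef(qrM, y)
  fitted <- drop(M %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- if (intercept) sum((y - mean(y))^2) else sum(y^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  sigma <- sqrt(rss / (n - p))
  XtX_inv <- chol2inv(qr.R(qrM))[order(qrM$pivot), order(qrM$pivot), drop = FALSE]
  se <- sigma * sqrt(diag(XtX_inv))
  names(se) <- colnames(M)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  p_eff <- p - as.integer(intercept)
  structure(
    list(
      coefficients = beta,
      standard_errors = se,
      p_values = pval,
      fitted = fitted,
      residuals = resid,
      response = y,
      rss = rss,
      n = n,
      p = p,
      r2 = r2,
      adjusted_r2 = adjusted_r2(r2, n, p_eff),
      sigma = sigma,
      terms = colnames(M),
      intercept = intercept
    ),
    class = "linear_fit"
  )
}

#' Ordinary least-squares fit of a one-hot design
#'
#' Fits the main-effects multiple linear regression: response on the
#' inhibitor indicators (plus day indicators when present). Coefficient
#' standard errors come from `sigma^2 (X'X)^-1`; the fit records RSS, R^2,
#' adjusted R^2 and the residual standard error `sigma = sqrt(RSS / (n - p))`.
#' Rank-deficient designs are an error naming the dependent columns.
#'
#' @param X A `design_matrix` (see [encode_one_hot()]) with a response.
#' @return A `linear_fit` object.
#' @export
fit_mlr <- function(X) {
  stopifnot(inherits(X, "design_matrix"), !is.null(X$response))
  M <- build_model_matrix(X)
  fit <- ols_fit(M, X$response, X$intercept)
  fit$factors <- X$factors
  fit
}

interaction_columns <- function(X) {
  inh <- intersect(X$factors, colnames(X$predictors))
  if (length(inh) < 2) stop("need at least two inhibitor columns", call. = FALSE)
  pairs <- utils::combn(inh, 2, simplify = FALSE)
  cols <- vapply(pairs, function(pr) {
    X$predictors[, pr[1]] * X$predictors[, pr[2]]
  }, numeric(nrow(X$predictors)))
  cols <- matrix(cols, nrow = nrow(X$predictors))
  colnames(cols) <- vapply(pairs, paste, character(1), collapse = ":")
  cols
}

#' Fit the two-way interaction model
#'
#' Appends all pairwise products of inhibitor indicators (10 terms for five
#' inhibitors) to the main-effects design and fits the joint model. Per-term
#' p-values come from t statistics. Interaction columns that are constant in
#' the data — which happens when viability masking removes every condition
#' carrying a pair, e.g. the L:R column in day-6-only responses — cannot be
#' estimated; they are dropped and listed in `$non_estimable` instead of
#' producing a singular fit.
#'
#' @inheritParams fit_mlr
#' @return An `interaction_fit` (subclass of `linear_fit`) with
#'   `interaction_terms` (data.frame pair/coefficient/se/p_value) and
#'   `non_estimable` (character vector of dropped pair terms).
#' @export
fit_mlr_interactions <- function(X) {
  stopifnot(inherits(X, "design_matrix"), !is.null(X$response))
  ints <- interaction_columns(X)
  constant <- apply(ints, 2, function(col) stats::var(col) == 0)
  dropped <- colnames(ints)[constant]
  ints <- ints[, !constant, drop = FALSE]
  M <- build_model_matrix(X, extra = ints)
  fit <- ols_fit(M, X$response, X$intercept)
  terms <- colnames(ints)
  fit$interaction_terms <- data.frame(
    pair = terms,
    coefficient = unname(fit$coefficients[terms]),
    se = unname(fit$standard_errors[terms]),
    p_value = unname(fit$p_values[terms]),
    stringsAsFactors = FALSE
  )
  fit$non_estimable <- dropped
  fit$factors <- X$factors
  class(fit) <- c("interaction_fit", "linear_fit")
  fit
}

#' Adjusted R-squared with (possibly fractional) effective parameter count
#'
#' `1 - (1 - R^2) (n - 1) / (n - 1 - p_effective)`. `p_effective` counts
#' fitted parameters excluding the intercept and need not be an integer: the
#' Bayesian-regularised network uses its effective number of well-determined
#' weights (gamma) here, which makes fit quality comparable across modelling
#' styles.
#'
#' @param r2 Coefficient of determination.
#' @param n Number of observations.
#' @param p_effective Effective number of (non-intercept) parameters.
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, p_effective) {
  if (n - 1 - p_effective <= 0) {
    stop("degenerate degrees of freedom: n - 1 - p_effective <= 0", call. = FALSE)
  }
  1 - (1 - r2) * (n - 1) / (n - 1 - p_effective)
}

#' F-test comparing nested linear models
#'
#' Tests whether the full model's extra parameters significantly reduce the
#' residual sum of squares:
#' `F = ((RSS_r - RSS_f) / (p_f - p_r)) / (RSS_f / (n - p_f))`, referred to
#' the F(p_f - p_r, n - p_f) distribution. Both fits must be on the same
#' response and the reduced model's terms must be a subset of the full
#' model's.
#'
#' @param reduced,full `linear_fit` objects.
#' @return List with `f_statistic`, `df1`, `df2`, `p_value`.
#' @export
nested_f_test <- function(reduced, full) {
  stopifnot(inherits(reduced, "linear_fit"), inherits(full, "linear_fit"))
  if (reduced$n != full$n || !isTRUE(all.equal(reduced$response, full$response))) {
    stop("models are not fits of the same response", call. = FALSE)
  }
  if (!all(reduced$terms %in% full$terms) || full$p <= reduced$p) {
    stop("models are not nested (reduced terms must be a strict subset)",
         call. = FALSE)
  }
  df1 <- full$p - reduced$p
  df2 <- full$n - full$p
  f <- ((reduced$rss - full$rss) / df1) / (full$rss / df2)
  f <- max(f, 0)
  list(
    f_statistic = f,
    df1 = df1,
    df2 = df2,
    p_value = stats::pf(f, df1, df2, lower.tail = FALSE)
  )
}

canonical_pair <- function(pair, factors = inhibitor_panel()$code) {
  if (length(pair) == 1L && grepl(":", pair, fixed = TRUE)) {
    pair <- strsplit(pair, ":", fixed = TRUE)[[1]]
  }
  stopifnot(length(pair) == 2L)
  bad <- setdiff(pair, factors)
  if (length(bad) > 0) stop("unknown inhibitor code(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  ord <- factors[factors %in% pair]
  paste(ord, collapse = ":")
}

#' Classify an inhibitor pair as additive, synergistic or antagonistic
#'
#' The call is made from the pair's interaction term in a two-way interaction
#' fit: if the term is not significant at `alpha_level` the inhibitors act
#' additively (the joint response is the sum of the individual
#' contributions). A significant interaction whose coefficient shares the
#' sign of the two summed main effects amplifies the joint response beyond
#' additivity (synergistic); an opposite-signed coefficient attenuates it
#' (antagonistic). The evidence behind each call (coefficient, p-value,
#' summed main effects) is returned so calls are auditable.
#'
#' @param fit An `interaction_fit`.
#' @param pair Length-2 character vector of inhibitor codes, or a `"A:B"`
#'   term string.
#' @param alpha_level Significance level for the non-additivity call.
#' @return List with `pair`, `call` (one of `"additive"`, `"synergistic"`,
#'   `"antagonistic"`), `coefficient`, `p_value`, `mains_sum`.
#' @export
classify_interaction <- function(fit, pair, alpha_level = 0.05) {
  stopifnot(inherits(fit, "interaction_fit"), alpha_level > 0, alpha_level < 1)
  term <- canonical_pair(pair, fit$factors %||% inhibitor_panel()$code)
  idx <- match(term, fit$interaction_terms$pair)
  if (is.na(idx)) {
    if (term %in% fit$non_estimable) {
      stop("interaction ", term, " is not estimable in this fit ",
           "(its column is constant after viability masking)", call. = FALSE)
    }
    stop("pair ", term, " not present in fit", call. = FALSE)
  }
  row <- fit$interaction_terms[idx, ]
  members <- strsplit(term, ":", fixed = TRUE)[[1]]
  mains_sum <- sum(fit$coefficients[members])
  call <- if (row$p_value >= alpha_level) {
    "additive"
  } else if (row$coefficient * mains_sum > 0) {
    "synergistic"
  } else if (row$coefficient * mains_sum < 0) {
    "antagonistic"
  } else {
    # degenerate zero summed mains: classify by the interaction's own sign
    if (row$coefficient > 0) "synergistic" else "antagonistic"
  }
  list(pair = term, call = call, coefficient = row$coefficient,
       p_value = row$p_value, mains_sum = mains_sum)
}

#' Classify every estimable inhibitor pair in a fit
#'
#' @inheritParams classify_interaction
#' @return Data.frame with one row per estimable pair: pair, call,
#'   coefficient, p_value, mains_sum.
#' @export
classify_all_interactions <- function(fit, alpha_level = 0.05) {
  stopifnot(inherits(fit, "interaction_fit"))
  rows <- lapply(fit$interaction_terms$pair, function(pr) {
    as.data.frame(classify_interaction(fit, pr, alpha_level),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear fit: n = %d, p = %d, R2 = %.3f, adj R2 = %.3f, sigma = %.4f\n",
              x$n, x$p, x$r2, x$adjusted_r2, x$sigma))
  tab <- data.frame(
    estimate = x$coefficients,
    se = x$standard_errors,
    p = x$p_values
  )
  print(round(tab, 4))
  invisible(x)
}
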