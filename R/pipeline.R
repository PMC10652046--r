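# Orchestration: preprocess -> transform -> model trio (linear, two-way
# interactions, Bayesian-regularised network) -> nested tests and
# interaction calls -> exploratory structure, with split-stability as a
# separate diagnostic. All stages are seeded and the report is reproducible
# from (inputs, config, seed).

#' Analysis configuration
#'
#' @param alpha_level Significance level for interaction calls and F-tests.
#' @param intercept_policy Day-indicator policy (see [encode_one_hot()]).
#' @param transforms Named list of [transform_spec()]s per property.
#' @param brann A [brann_config()]; its seed is re-derived per response from
#'   the global seed so the full run is reproducible.
#' @param k_range Candidate cluster numbers for the silhouette scan.
#' @param n_starts k-means random starts.
#' @param seed Global seed.
#' @return An `analysis_config` object.
#' @export
analysis_config <- function(alpha_level = 0.05,
                            intercept_policy = "with_intercept_drop_one_day",
                            transforms = default_transforms(),
                            brann = brann_config(),
                            k_range = 2:6,
                            n_starts = 25,
                            seed = 1L) {
  stopifnot(alpha_level > 0, alpha_level < 1, inherits(brann, "brann_config"))
  structure(
    list(alpha_level = alpha_level, intercept_policy = intercept_policy,
         transforms = transforms, brann = brann, k_range = k_range,
         n_starts = n_starts, seed = as.integer(seed)),
    class = "analysis_config"
  )
}

fit_response_trio <- function(X, config, response_id) {
  out <- list(response = response_id)
  out$mlr <- tryCatch(fit_mlr(X), error = function(e) e)
  out$mlr_interactions <- tryCatch(fit_mlr_interactions(X), error = function(e) e)
  bc <- config$brann
  bc$seed <- derive_seed(config$seed, 500L, response_id)
  out$brann <- tryCatch(train_branngp(X, bc), error = function(e) e)
  if (!inherits(out$mlr, "error") && !inherits(out$mlr_interactions, "error")) {
    out$f_test <- nested_f_test(out$mlr, out$mlr_interactions)
    out$interaction_calls <- classify_all_interactions(out$mlr_interactions,
                                                       config$alpha_level)
  }
  out
}

resid_normality_p <- function(fit) {
  tryCatch(shapiro_wilk(fit$residuals)$p_value, error = function(e) NA_real_)
}

comparison_rows <- function(trio, response_name, response_id) {
  rows <- list()
  add_row <- function(model_class, adjusted_r2, sigma, r2, resid_p, f_p, failed) {
    rows[[length(rows) + 1L]] <<- data.frame(
      response = response_name, model_class = model_class,
      adjusted_r2 = adjusted_r2, sigma = sigma, r2 = r2,
      resid_normality_p = resid_p, f_vs_reduced_p = f_p,
      failed = failed, stringsAsFactors = FALSE
    )
  }
  if (inherits(trio$mlr, "error")) {
    add_row("mlr", NA, NA, NA, NA, NA, TRUE)
  } else {
    add_row("mlr", trio$mlr$adjusted_r2, trio$mlr$sigma, trio$mlr$r2,
            resid_normality_p(trio$mlr), NA, FALSE)
  }
  if (inherits(trio$mlr_interactions, "error")) {
    add_row("mlr_interactions", NA, NA, NA, NA, NA, TRUE)
  } else {
    add_row("mlr_interactions", trio$mlr_interactions$adjusted_r2,
            trio$mlr_interactions$sigma, trio$mlr_interactions$r2,
            resid_normality_p(trio$mlr_interactions),
            if (!is.null(trio$f_test)) trio$f_test$p_value else NA, FALSE)
  }
  if (inherits(trio$brann, "error")) {
    add_row("branngp", NA, NA, NA, NA, NA, TRUE)
  } else {
    m <- trio$brann$model
    add_row("branngp", m$adjusted_r2_eff, m$sigma_eff, m$r2_train, NA, NA, FALSE)
  }
  do.call(rbind, rows)
}

#' Run the full screen analysis
#'
#' Averages replicates, applies the viability mask and the per-property
#' variance-stabilising transforms (Shapiro-Wilk recorded before and after),
#' fits the model trio — main-effects linear model, two-way interaction
#' model, Bayesian-regularised network — for every emergent property (days
#' pooled with day indicators; morphology day 6 only) and every gene (day 6,
#' no day columns), runs nested F-tests and interaction classification, and
#' derives the exploratory structure (correlation matrix, z-scored PCA,
#' silhouette-guided k-means) from the paired day-6 condition matrix. A
#' stage that fails is recorded in the report and independent stages
#' continue.
#'
#' @param measurements Measurement data.frame, or a `synthetic_dataset`.
#' @param expression Optional expression data.frame (ignored when
#'   `measurements` is a `synthetic_dataset`, which carries its own).
#' @param config An [analysis_config()].
#' @param design A `factorial_design` (defaults to the five-inhibitor 2^5
#'   design with the L,R lethality rule).
#' @return A report list: `model_comparison` (data.frame),
#'   `interaction_calls`, `f_tests`, `normality`, `fits`, `explore`, `log`.
#' @export
run_full_analysis <- function(measurements, expression = NULL,
                              config = analysis_config(),
                              design = enumerate_design()) {
  if (inherits(measurements, "synthetic_dataset")) {
    expression <- measurements$expression
    design <- measurements$design
    measurements <- measurements$measurements
  }
  log <- list(seed = config$seed, n_raw_rows = nrow(measurements))

  meas <- apply_viability_mask(design, measurements)
  log$n_rows_after_mask <- nrow(meas)
  late <- !is.na(design$lethal_from_day) &
    measurements$day > design$lethal_from_day
  late_kept <- meas$day > design$lethal_from_day
  log$masked_conditions <- setdiff(unique(measurements$condition[late]),
                                   unique(meas$condition[late_kept]))
  avg <- average_replicates(meas)

  trios <- list()
  normality <- list()
  comparison <- list()
  calls <- list()
  resp_id <- 0L

  for (prop in intersect(MEASUREMENT_PROPERTIES, unique(avg$property))) {
    resp_id <- resp_id + 1L
    sub <- avg[avg$property == prop, , drop = FALSE]
    spec <- config$transforms[[prop]] %||% transform_spec("identity")
    raw_vals <- sub$value
    transformed <- tryCatch(apply_transform(raw_vals, spec),
                            error = function(e) e)
    if (inherits(transformed, "error")) {
      comparison[[prop]] <- data.frame(
        response = prop, model_class = c("mlr", "mlr_interactions", "branngp"),
        adjusted_r2 = NA_real_, sigma = NA_real_, r2 = NA_real_,
        resid_normality_p = NA_real_, f_vs_reduced_p = NA_real_,
        failed = TRUE, stringsAsFactors = FALSE
      )
      log$stage_failures <- c(log$stage_failures,
                              stats::setNames(conditionMessage(transformed), prop))
      next
    }
    sub$value <- transformed
    normality[[prop]] <- list(
      transform = spec$name,
      log_offset = spec$log_offset,
      before_p = tryCatch(shapiro_wilk(raw_vals)$p_value,
                          error = function(e) NA_real_),
      after_p = tryCatch(shapiro_wilk(sub$value)$p_value,
                         error = function(e) NA_real_)
    )
    X <- encode_one_hot(sub, response = "value",
                        factors = design$factors,
                        intercept_policy = config$intercept_policy)
    trio <- fit_response_trio(X, config, resp_id)
    trios[[prop]] <- trio
    comparison[[prop]] <- comparison_rows(trio, prop, resp_id)
    if (!is.null(trio$interaction_calls)) {
      cc <- trio$interaction_calls
      cc$response <- prop
      calls[[prop]] <- cc
    }
  }

  if (!is.null(expression) && nrow(expression) > 0) {
    expr <- apply_viability_mask(design, expression)
    for (g in sort(unique(expr$gene))) {
      resp_id <- resp_id + 1L
      sub <- expr[expr$gene == g & expr$day == 6L, , drop = FALSE]
      if (nrow(sub) == 0) next
      agg <- stats::aggregate(log2fc ~ condition + day, data = sub, FUN = mean)
      X <- encode_one_hot(agg, response = "log2fc",
                          factors = design$factors,
                          intercept_policy = config$intercept_policy,
                          include_days = FALSE)
      trio <- fit_response_trio(X, config, resp_id)
      trios[[g]] <- trio
      comparison[[g]] <- comparison_rows(trio, g, resp_id)
      if (!is.null(trio$interaction_calls)) {
        cc <- trio$interaction_calls
        cc$response <- g
        calls[[g]] <- cc
      }
    }
  }

  explore <- tryCatch(
    explore_condition_matrix(avg, expression, design, config),
    error = function(e) e
  )

  list(
    model_comparison = do.call(rbind, unname(comparison)),
    interaction_calls = do.call(rbind, unname(calls)),
    f_tests = lapply(trios, `[[`, "f_test"),
    normality = normality,
    fits = trios,
    explore = explore,
    log = log,
    config = config
  )
}

# Paired day-6 condition-level matrix: emergent properties + gene log2fc.
explore_condition_matrix <- function(avg, expression, design, config) {
  day6 <- avg[avg$day == 6L, , drop = FALSE]
  M <- stats::reshape(day6[c("condition", "property", "value")],
                      idvar = "condition", timevar = "property",
                      direction = "wide")
  names(M) <- sub("^value\\.", "", names(M))
  if (!is.null(expression) && nrow(expression) > 0) {
    expr6 <- expression[expression$day == 6L, , drop = FALSE]
    E <- stats::aggregate(log2fc ~ condition + gene, data = expr6, FUN = mean)
    Ew <- stats::reshape(E, idvar = "condition", timevar = "gene",
                         direction = "wide")
    names(Ew) <- sub("^log2fc\\.", "", names(Ew))
    M <- merge(M, Ew, by = "condition", all = TRUE)
  }
  rownames(M) <- M$condition
  M$condition <- NULL
  M <- as.matrix(M)
  corr <- correlation_matrix(M, p_method = "spearman")
  complete <- M[stats::complete.cases(M), , drop = FALSE]
  pca <- pca_zscore(complete)
  Z <- scale(complete)
  clust <- cluster_with_silhouette(
    Z, k_range = config$k_range, n_starts = config$n_starts,
    seed = derive_seed(config$seed, 900L)
  )
  clust$conditions <- rownames(complete)
  list(matrix = M, correlations = corr, pca = pca, clusters = clust,
       n_dropped_rows = nrow(M) - nrow(complete))
}

#' Split-stability diagnostic
#'
#' The screen trains on all data (the design is exhaustive, so prediction on
#' unseen conditions is not the goal); as a stability diagnostic this fits
#' the main-effects linear model on random train/test splits and profiles
#' held-out R^2 across splits. Degenerate splits (constant training or test
#' response, or rank-deficient training design) are skipped and logged.
#'
#' @param X A `design_matrix` with response.
#' @param n_splits Number of random splits (the screen's convention: 50).
#' @param train_fraction Fraction of rows used for training, in (0, 1).
#' @param seed Integer seed.
#' @return List with `r2_test` (per-split held-out R^2), `n_skipped`,
#'   `summary` (mean, sd, min, max).
#' @export
split_evaluate <- function(X, n_splits = 50L, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(X, "design_matrix"), !is.null(X$response))
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  M <- build_model_matrix(X)
  y <- X$response
  n <- nrow(M)
  n_train <- floor(n * train_fraction)
  if (n_train < ncol(M) + 1 || n_train >= n) {
    stop("not enough rows to split at this train_fraction", call. = FALSE)
  }
  r2s <- numeric(0)
  skipped <- 0L
  for (s in seq_len(n_splits)) {
    set.seed(derive_seed(seed, 300L, s))
    idx <- sample.int(n, n_train)
    res <- tryCatch({
      qrM <- qr(M[idx, , drop = FALSE])
      if (qrM$rank < ncol(M)) stop("rank-deficient training design")
      beta <- qr.coef(qrM, y[idx])
      y_te <- y[-idx]
      if (stats::sd(y_te) == 0 || stats::sd(y[idx]) == 0) {
        stop("constant response in split")
      }
      pred <- drop(M[-idx, , drop = FALSE] %*% beta)
      1 - sum((y_te - pred)^2) / sum((y_te - mean(y_te))^2)
    }, error = function(e) NA_real_)
    if (is.na(res)) skipped <- skipped + 1L else r2s <- c(r2s, res)
  }
  list(
    r2_test = r2s,
    n_skipped = skipped,
    summary = c(mean = mean(r2s), sd = stats::sd(r2s),
                min = min(r2s), max = max(r2s))
  )
}

#' Write a structured analysis report
#'
#' Emits `report.json` (model comparison, interaction calls, F-tests,
#' normality record, clustering assignments, log) and a human-readable
#' `model_comparison.tsv` into `dir`.
#'
#' @param report Output of [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    model_comparison = report$model_comparison,
    interaction_calls = report$interaction_calls,
    f_tests = lapply(report$f_tests, function(f) {
      if (is.null(f)) NULL else f[c("f_statistic", "df1", "df2", "p_value")]
    }),
    normality = report$normality,
    log = report$log
  )
  if (!inherits(report$explore, "error") && !is.null(report$explore)) {
    payload$clusters <- list(
      chosen_k = report$explore$clusters$chosen_k,
      silhouette_by_k = as.list(report$explore$clusters$silhouette_by_k),
      assignments = stats::setNames(
        as.list(report$explore$clusters$assignments),
        report$explore$clusters$conditions
      )
    )
  }
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  utils::write.table(report$model_comparison,
                     file.path(dir, "model_comparison.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
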