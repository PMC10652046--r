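# Raw-measurement normalisation: colony morphology scoring, qPCR
# delta-delta-Ct, immunoblot band ratios, replicate averaging, normality
# checks and the variance-stabilising transforms used before modelling.

#' Colony morphology score for one condition
#'
#' Colonies are scored on a fixed 0/1/2 scale: 0 for round, domed (naive ESC)
#' colonies; 1 for flat, irregular, partially transitioned colonies; 2 for
#' fully transitioned (EPL-like) colonies. Per image the scores are summed
#' and divided by the number of colonies scored; the final condition score is
#' the mean of the per-image values, bounded in \[0, 2\].
#'
#' @param per_image List of integer vectors, one per image, each score in
#'   \{0, 1, 2\}; every image must contain at least one colony.
#' @return Numeric scalar in \[0, 2\].
#' @export
#' @examples
#' score_morphology(list(c(0, 1, 2, 2)))  # 1.25
score_morphology <- function(per_image) {
  if (!is.list(per_image) || length(per_image) == 0) {
    stop("per_image must be a non-empty list of score vectors", call. = FALSE)
  }
  means <- vapply(per_image, function(scores) {
    if (length(scores) == 0) stop("image with no colonies", call. = FALSE)
    if (!all(scores %in% c(0, 1, 2))) {
      stop("colony scores must be 0, 1 or 2", call. = FALSE)
    }
    sum(scores) / length(scores)
  }, numeric(1))
  mean(means)
}

#' Relative expression by efficiency-corrected delta-delta-Ct
#'
#' Converts qPCR threshold cycles to a log2 fold change of the target gene in
#' a sample relative to a calibrator (untreated reference culture), each
#' normalised to the reference gene (Actb):
#' `log2fc = log2( E ^ -((Ct_target - Ct_ref)_sample - (Ct_target - Ct_ref)_calibrator) )`.
#' With perfect amplification efficiency `E = 2` this is the classic
#' `-ddCt`. Efficiency correction (E in (1, 2]) covers assays with measured
#' per-primer efficiencies.
#'
#' @param sample,calibrator Lists (or 1-row data.frames) with numeric fields
#'   `ct_target` and `ct_ref`.
#' @param efficiency Amplification efficiency E, in (1, 2].
#' @return log2 fold change (numeric scalar).
#' @export
#' @examples
#' s <- list(ct_target = 24, ct_ref = 20)
#' c0 <- list(ct_target = 25, ct_ref = 20)
#' relative_expression(s, c0)  # +1: one cycle earlier than calibrator
relative_expression <- function(sample, calibrator, efficiency = 2) {
  cts <- c(sample$ct_target, sample$ct_ref, calibrator$ct_target, calibrator$ct_ref)
  if (length(cts) != 4 || !all(is.finite(cts))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  if (!(efficiency > 1 && efficiency <= 2)) {
    stop("efficiency must lie in (1, 2]", call. = FALSE)
  }
  ddct <- (sample$ct_target - sample$ct_ref) -
    (calibrator$ct_target - calibrator$ct_ref)
  -ddct * log2(efficiency)
}

#' Normalise an immunoblot band to loading control and baseline
#'
#' Background signal (a size-matched adjacent region) is subtracted from the
#' band's integrated intensity; the corrected intensity is divided by the
#' background-corrected loading-control band (beta-tubulin) and the resulting
#' ratio expressed as a log2 fold change over the same ratio in the baseline
#' (0 h / untreated) sample. Bands darker than their background are clamped
#' to a small positive floor (1e-6 x loading) rather than going negative;
#' the clamp is reported via the `clamped` attribute.
#'
#' @param band Band integrated intensity (a.u., >= 0).
#' @param background Intensity of the size-matched adjacent region.
#' @param loading Background-corrected loading-control intensity (> 0).
#' @param baseline_ratio `(band - background) / loading` for the baseline
#'   sample (> 0).
#' @return log2 fold change vs baseline, with attribute `clamped`.
#' @export
normalize_blot <- function(band, background, loading, baseline_ratio) {
  stopifnot(is.finite(band), is.finite(background), is.finite(loading),
            is.finite(baseline_ratio))
  if (loading <= 0) stop("loading intensity must be positive", call. = FALSE)
  if (baseline_ratio <= 0) stop("baseline ratio must be positive", call. = FALSE)
  corrected <- band - background
  clamped <- corrected <= 0
  if (clamped) corrected <- 1e-6 * loading
  out <- log2((corrected / loading) / baseline_ratio)
  attr(out, "clamped") <- clamped
  out
}

#' Average replicates before modelling
#'
#' Collapses a long measurement table to one row per (condition, day,
#' property) with `value` the arithmetic mean across replicates, mirroring
#' the screen's convention of averaging >= 3 biological replicates before any
#' model fit. The replicate field is set to the sentinel `"mean"`.
#'
#' @param data Measurement data.frame (condition, day, replicate, property,
#'   value).
#' @return Averaged data.frame, one row per (condition, day, property).
#' @export
average_replicates <- function(data) {
  stopifnot(all(c("condition", "day", "property", "value") %in% names(data)))
  agg <- stats::aggregate(
    value ~ condition + day + property, data = data, FUN = mean
  )
  agg$replicate <- "mean"
  agg[order(agg$property, agg$day, agg$condition),
      c("condition", "day", "replicate", "property", "value")]
}

#' Shapiro-Wilk normality test
#'
#' Thin, validated interface to the Shapiro-Wilk test (Royston's
#' approximation, valid for 3 <= n <= 5000) used before and after the
#' variance-stabilising transforms and on model residuals.
#'
#' @param values Numeric vector, 3 <= length <= 5000, not all identical.
#' @return List with `statistic_W`, `p_value`, `n`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("degenerate input: all values identical", call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  list(statistic_W = unname(sw$statistic), p_value = sw$p.value, n = n)
}

#' Specify a variance-stabilising transform
#'
#' The screen's modelling transforms: `log` (natural log, with an additive
#' offset for responses that can be exactly zero, e.g. morphology scores),
#' `power6` (`x^6`, used for proliferation fractions), `octile`
#' (equal-frequency rank binning into 1..8) and `identity`.
#'
#' @param name One of `"identity"`, `"log"`, `"power6"`, `"octile"`.
#' @param log_offset Non-negative offset added before taking the log; only
#'   meaningful with `name = "log"`.
#' @return A `transform_spec` object.
#' @export
transform_spec <- function(name = c("identity", "log", "power6", "octile"),
                           log_offset = 0) {
  name <- match.arg(name)
  stopifnot(is.numeric(log_offset), log_offset >= 0)
  if (name != "log" && log_offset != 0) {
    stop("log_offset is only used with the log transform", call. = FALSE)
  }
  structure(list(name = name, log_offset = log_offset), class = "transform_spec")
}

#' Apply a variance-stabilising transform
#'
#' Elementwise application of a [transform_spec()]; all transforms are
#' monotone on their valid domain (for `power6`, on non-negative inputs).
#'
#' @param values Numeric vector.
#' @param spec A `transform_spec`.
#' @return Transformed numeric vector (integer bins for `octile`).
#' @export
apply_transform <- function(values, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  switch(spec$name,
    identity = values,
    log = {
      shifted <- values + spec$log_offset
      if (any(shifted <= 0)) {
        stop("log transform: non-positive value after offset ", spec$log_offset,
             call. = FALSE)
      }
      log(shifted)
    },
    power6 = {
      if (any(!is.finite(values))) stop("power6: non-finite input", call. = FALSE)
      values^6
    },
    octile = octile_bin(values)
  )
}

#' Equal-frequency octile binning
#'
#' Rank-based assignment of values to 8 equal-frequency bins (1 = lowest
#' octile), used as an alternative normalisation for strongly non-normal
#' responses. Ties take the average rank and are floored into bins, so the
#' map is deterministic and monotone; with no ties, bin sizes differ by at
#' most one.
#'
#' @param values Numeric vector, length >= 8.
#' @return Integer vector of bins in 1..8.
#' @export
octile_bin <- function(values) {
  n <- length(values)
  if (n < 8) stop("octile binning needs at least 8 values", call. = FALSE)
  r <- rank(values, ties.method = "average")
  bins <- pmin(8L, as.integer(floor((r - 0.5) * 8 / n)) + 1L)
  bins
}

#' Slope of gene upregulation across assay days
#'
#' Least-squares slope of log2 fold change against day, summarising how fast
#' a gene (e.g. the primitive-streak marker T/brachyury in embryoid-body
#' differentiation assays over days 2-4) is upregulated.
#'
#' @param day Integer vector of assay days (>= 2 distinct values).
#' @param log2fc Numeric vector of matching log2 fold changes.
#' @return Slope in log2-fold-change units per day.
#' @export
#' @examples
#' t_slope(c(2, 3, 4), c(0, 1, 2))  # 1
t_slope <- function(day, log2fc) {
  stopifnot(length(day) == length(log2fc), length(day) >= 2)
  if (length(unique(day)) < 2) {
    stop("need at least two distinct days to estimate a slope", call. = FALSE)
  }
  sum((day - mean(day)) * (log2fc - mean(log2fc))) / sum((day - mean(day))^2)
}

#' Default per-property modelling transforms
#'
#' Morphology and apoptosis are log transformed (morphology with a 0.1 offset
#' because a fully naive condition scores exactly 0), proliferation is raised
#' to the sixth power, and cell number is modelled untransformed.
#'
#' @return Named list of `transform_spec`s, one per measurement property.
#' @export
default_transforms <- function() {
  list(
    cell_number = transform_spec("identity"),
    proliferation = transform_spec("power6"),
    apoptosis = transform_spec("log"),
    morphology = transform_spec("log", log_offset = 0.1)
  )
}
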