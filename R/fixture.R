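# Canned ground truths: a screen-like fixture with the qualitative structure
# of the inhibitor screen (signs and interaction types, not magnitudes), an
# additive null truth for type-I-error studies, and a nonlinear-response
# generator for linear-vs-network comparisons.

#' Screen-like synthetic fixture
#'
#' A canned ground truth mimicking the screen's qualitative structure: all
#' five inhibitors reduce cell number and proliferation (rapamycin, R, the
#' largest); a strong synergistic L:R interaction on proliferation and
#' apoptosis (the combination that kills the cultures); antagonistic U:P and
#' R:P interactions on cell number; the \{L, R\} lethal pair masked after
#' day 2; a morphology response raised by the culture condition and
#' suppressed by U and S with no planted S:U interaction (additive); and a
#' seven-gene panel (Rex1, Oct4, Dnmt3b, Fgf5, Lefty2, Otx2, Mixl1) with
#' Rex1-Oct4 and Dnmt3b-Fgf5 positively coupled noise. Marginals are chosen
#' so the standard transforms are the normalising ones: lognormal for
#' apoptosis and morphology (log / log(x+0.1) recover the Gaussian scale)
#' and a bounded fraction for proliferation (x^6 recovers it).
#'
#' Planted interaction magnitudes are calibrated to ~3.6 standard errors of
#' the corresponding term in the replicate-averaged, viability-masked design
#' (per-term power ~0.95 at 3 replicates), so planted calls are recovered
#' reliably while null pairs stay additive at the nominal rate.
#'
#' @param seed Integer seed.
#' @param replicates Replicates per (condition, day) unit.
#' @return A `synthetic_dataset` (see [simulate_factorial()]).
#' @export
make_screen_fixture <- function(seed = 1L, replicates = 3L) {
  simulate_factorial(screen_truth(), replicates = replicates, seed = seed)
}

#' @rdname make_screen_fixture
#' @export
screen_truth <- function() {
  inh <- inhibitor_panel()$code
  zero <- stats::setNames(rep(0, 5), inh)
  mains <- function(...) {
    v <- zero
    args <- c(...)
    v[names(args)] <- args
    v
  }
  property_effects <- list(
    cell_number = list(
      baseline = 1.0,
      main = mains(c(U = -0.15, S = -0.12, L = -0.20, R = -0.30, P = -0.10)),
      day = c(`2` = -0.30, `4` = -0.10, `6` = 0),
      days = c(2L, 4L, 6L)
    ),
    proliferation = list(                    # x^6 (modelling) scale, in (0,1)
      baseline = 0.55,
      main = mains(c(U = -0.030, S = -0.035, L = -0.045, R = -0.060, P = -0.025)),
      day = c(`2` = 0.03, `4` = 0.01, `6` = 0),
      days = c(2L, 4L, 6L)
    ),
    apoptosis = list(                        # log(% annexin+) scale
      baseline = log(5),
      main = mains(c(U = 0.05, S = -0.25, L = 0.30, R = 0.30, P = -0.05)),
      day = c(`2` = 0.20, `4` = 0.10, `6` = 0),
      days = c(2L, 4L, 6L)
    ),
    morphology = list(                       # log(score + 0.1) scale, day 6 only
      baseline = log(1.7),
      main = mains(c(U = -0.45, S = -0.35, L = 0.10, R = -0.15, P = -0.05)),
      day = c(`6` = 0),
      days = 6L
    )
  )
  interactions <- data.frame(
    property = c("cell_number", "cell_number", "proliferation", "apoptosis"),
    pair = c("U:P", "R:P", "L:R", "L:R"),
    coefficient = c(0.075, 0.080, -0.034, 0.17),
    type = c("antagonistic", "antagonistic", "synergistic", "synergistic"),
    stringsAsFactors = FALSE
  )
  genes <- c("Rex1", "Oct4", "Dnmt3b", "Fgf5", "Lefty2", "Otx2", "Mixl1")
  effects <- matrix(0, length(genes), 5, dimnames = list(genes, inh))
  effects["Rex1", c("U", "L")] <- c(0.40, -0.30)
  effects["Oct4", c("U", "L")] <- c(0.30, -0.25)
  effects["Dnmt3b", c("S", "L", "R")] <- c(-0.80, 0.60, -0.70)
  effects["Fgf5", c("S", "R")] <- c(-0.90, -0.60)
  effects["Lefty2", c("S", "L", "P")] <- c(0.50, -0.60, -0.50)
  effects["Otx2", c("S", "R")] <- c(0.60, -0.50)
  effects["Mixl1", "R"] <- 0.30
  sigma <- diag(length(genes))
  dimnames(sigma) <- list(genes, genes)
  sigma["Rex1", "Oct4"] <- sigma["Oct4", "Rex1"] <- 0.8
  sigma["Dnmt3b", "Fgf5"] <- sigma["Fgf5", "Dnmt3b"] <- 0.5
  ground_truth(
    property_effects = property_effects,
    interactions = interactions,
    noise_sd = c(cell_number = 0.08, proliferation = 0.03,
                 apoptosis = 0.15, morphology = 0.15),
    marginal = c(cell_number = "normal", proliferation = "bounded_fraction",
                 apoptosis = "lognormal", morphology = "lognormal"),
    marginal_offset = c(cell_number = 0, proliferation = 0,
                        apoptosis = 0, morphology = 0.1),
    lethal_pairs = list(c("L", "R")),
    lethal_from_day = 2L,
    gene_panel = list(
      genes = genes,
      baseline = stats::setNames(c(-0.3, -0.2, 1.5, 2.0, 1.0, 1.0, 0.2), genes),
      effects = effects,
      sigma = sigma,
      noise_sd = 0.4
    )
  )
}

#' Purely additive ground truth (no interactions)
#'
#' The screen-like cell-number response with every interaction removed and a
#' normal marginal: the null generative model for type-I-error studies of
#' the interaction calls and the nested F-test.
#'
#' @return A `ground_truth` with a single `cell_number` property.
#' @export
make_additive_truth <- function() {
  tr <- screen_truth()
  ground_truth(
    property_effects = tr$property_effects["cell_number"],
    interactions = NULL,
    noise_sd = tr$noise_sd["cell_number"],
    marginal = c(cell_number = "normal"),
    lethal_pairs = tr$lethal_pairs,
    lethal_from_day = tr$lethal_from_day
  )
}

#' Single-day response with a strong multiplicative interaction
#'
#' Generates a replicate-averaged, single-day (day 2, all 32 conditions)
#' response carrying additive main effects plus a large L-by-R product term
#' — a response a main-effects-only linear model cannot represent. Used to
#' compare the Bayesian-regularised network's effective-parameter adjusted
#' R^2 against the plain linear model's.
#'
#' @param seed Integer seed.
#' @param replicates Replicates averaged per condition.
#' @param interaction_coef Product-term coefficient.
#' @param noise_sd Noise SD on the response scale.
#' @return A `design_matrix` (32 rows, inhibitor columns only) with response.
#' @export
simulate_nonlinear_response <- function(seed = 1L, replicates = 3L,
                                        interaction_coef = 1.2,
                                        noise_sd = 0.1) {
  truth <- ground_truth(
    property_effects = list(cell_number = list(
      baseline = 1.0,
      main = stats::setNames(c(-0.5, -0.4, -0.5, -0.6, -0.4),
                             inhibitor_panel()$code),
      day = c(`2` = 0),
      days = 2L
    )),
    interactions = data.frame(property = "cell_number", pair = "L:R",
                              coefficient = -abs(interaction_coef),
                              type = "synergistic",
                              stringsAsFactors = FALSE),
    noise_sd = c(cell_number = noise_sd),
    marginal = c(cell_number = "normal"),
    lethal_pairs = list(c("L", "R")),
    lethal_from_day = 2L
  )
  ds <- simulate_factorial(truth, replicates = replicates, seed = seed)
  avg <- average_replicates(ds$measurements)
  encode_one_hot(avg, response = "value")
}
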