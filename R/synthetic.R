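# Synthetic factorial screens with known ground truth: additive main
# effects, typed pairwise interactions, day effects, non-normal marginals
# (so the variance-stabilising transforms are meaningfully exercised), the
# lethality rule, and a correlated gene panel. Every pipeline stage is
# testable against the planted truth without wet-lab data.

#' Ground truth for a synthetic factorial screen
#'
#' Describes the generative model: per-property baseline, main effects, day
#' effects and noise SD (all on the modelling scale, i.e. after the
#' property's variance-stabilising transform), typed pairwise interactions,
#' the marginal law linking the modelling scale to the observed scale, the
#' lethality rule, and an optional gene panel with a target correlation
#' structure.
#'
#' Marginal laws map a latent modelling-scale draw `z ~ N(mean, sd)` to the
#' observed value: `normal` keeps `z`; `lognormal` observes
#' `max(exp(z) - offset, 0)` (so a log(x + offset) transform recovers the
#' Gaussian scale); `bounded_fraction` observes `clamp(z, eps, 1)^(1/6)` (so
#' the x^6 transform recovers it).
#'
#' @param property_effects Named list (per property) of lists with
#'   `baseline`, `main` (named numeric over inhibitors), `day` (named
#'   numeric over measured days; the baseline day carries 0), `days`
#'   (integer vector of measured days).
#' @param interactions Data.frame with columns `property`, `pair` (e.g.
#'   `"L:R"`), `coefficient`, `type` (`"synergistic"` or `"antagonistic"`).
#'   Types must agree with the classification sign convention (coefficient
#'   sign vs summed mains) or construction fails.
#' @param noise_sd Named numeric, per-property SD on the modelling scale.
#' @param marginal Named character, per-property marginal law.
#' @param marginal_offset Named numeric, offset for `lognormal` marginals.
#' @param lethal_pairs,lethal_from_day Lethality rule (see
#'   [enumerate_design()]).
#' @param gene_panel Optional list: `genes`, `baseline` (named), `effects`
#'   (genes x inhibitors matrix of log2FC main effects), `sigma` (gene
#'   correlation matrix, symmetric PSD with unit diagonal), `noise_sd`
#'   (scalar or per-gene).
#' @param factors Factor alphabet.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(property_effects,
                         interactions = NULL,
                         noise_sd,
                         marginal,
                         marginal_offset = NULL,
                         lethal_pairs = list(c("L", "R")),
                         lethal_from_day = 2L,
                         gene_panel = NULL,
                         factors = inhibitor_panel()$code) {
  props <- names(property_effects)
  stopifnot(length(props) > 0, all(props %in% MEASUREMENT_PROPERTIES))
  if (!all(props %in% names(noise_sd)) || any(noise_sd < 0)) {
    stop("noise_sd must be non-negative and name every property", call. = FALSE)
  }
  stopifnot(all(props %in% names(marginal)),
            all(marginal %in% c("normal", "lognormal", "bounded_fraction")))
  if (is.null(marginal_offset)) {
    marginal_offset <- stats::setNames(rep(0, length(props)), props)
  }
  if (is.null(interactions)) {
    interactions <- data.frame(property = character(0), pair = character(0),
                               coefficient = numeric(0), type = character(0),
                               stringsAsFactors = FALSE)
  }
  if (nrow(interactions) > 0) {
    stopifnot(all(interactions$type %in% c("synergistic", "antagonistic")))
    for (i in seq_len(nrow(interactions))) {
      pr <- strsplit(canonical_pair(interactions$pair[i], factors), ":")[[1]]
      mains_sum <- sum(property_effects[[interactions$property[i]]]$main[pr])
      prod <- interactions$coefficient[i] * mains_sum
      implied <- if (prod > 0) "synergistic" else "antagonistic"
      if (prod != 0 && implied != interactions$type[i]) {
        stop(sprintf("interaction %s on %s: declared %s but sign convention implies %s",
                     interactions$pair[i], interactions$property[i],
                     interactions$type[i], implied), call. = FALSE)
      }
    }
    interactions$pair <- vapply(interactions$pair, canonical_pair,
                                character(1), factors = factors)
  }
  if (!is.null(gene_panel)) {
    S <- gene_panel$sigma
    stopifnot(is.matrix(S), nrow(S) == length(gene_panel$genes),
              isTRUE(all.equal(S, t(S))), all(abs(diag(S) - 1) < 1e-12))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("gene correlation matrix is not positive semi-definite", call. = FALSE)
    }
    if (length(gene_panel$noise_sd) == 1) {
      gene_panel$noise_sd <- stats::setNames(
        rep(gene_panel$noise_sd, length(gene_panel$genes)), gene_panel$genes)
    }
    stopifnot(all(gene_panel$noise_sd >= 0))
  }
  structure(
    list(property_effects = property_effects, interactions = interactions,
         noise_sd = noise_sd, marginal = marginal,
         marginal_offset = marginal_offset,
         lethal_pairs = lethal_pairs,
         lethal_from_day = as.integer(lethal_from_day),
         gene_panel = gene_panel, factors = factors),
    class = "ground_truth"
  )
}

latent_mean <- function(truth, property, inh_set, day) {
  pe <- truth$property_effects[[property]]
  m <- pe$baseline + sum(pe$main[inh_set])
  if (!is.null(pe$day) && as.character(day) %in% names(pe$day)) {
    m <- m + pe$day[[as.character(day)]]
  }
  ints <- truth$interactions
  ints <- ints[ints$property == property, , drop = FALSE]
  if (nrow(ints) > 0) {
    for (i in seq_len(nrow(ints))) {
      pr <- strsplit(ints$pair[i], ":")[[1]]
      if (all(pr %in% inh_set)) m <- m + ints$coefficient[i]
    }
  }
  m
}

observe_marginal <- function(z, marginal, offset) {
  switch(marginal,
    normal = z,
    lognormal = pmax(exp(z) - offset, 0),
    bounded_fraction = pmin(pmax(z, 1e-6), 1)^(1 / 6)
  )
}

#' Simulate a factorial screen from a ground truth
#'
#' For every viable (condition, day) unit of every property the latent
#' modelling-scale mean is baseline + main effects + planted interactions +
#' day effect; each replicate observes a marginal-law draw around it with the
#' property's noise SD. Conditions carrying a lethal pair produce no rows
#' after `lethal_from_day`, so generated data pass [apply_viability_mask()]
#' unchanged. One RNG sub-stream per (property, condition, day) is derived
#' deterministically from the seed, so increasing `replicates` extends
#' existing rows without perturbing them.
#'
#' @param truth A [ground_truth()].
#' @param replicates Replicates per unit (>= 1).
#' @param seed Integer seed.
#' @return A `synthetic_dataset`: list with `measurements`, `expression`
#'   (NULL unless the truth has a gene panel), `truth`, `seed`, `design`.
#' @export
simulate_factorial <- function(truth, replicates = 3L, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), replicates >= 1)
  design <- enumerate_design(truth$factors, truth$lethal_pairs,
                             truth$lethal_from_day)
  conds <- design$conditions
  inh_sets <- lapply(conds, condition_inhibitors, factors = truth$factors)
  lethal <- vapply(conds, function(cc) {
    any(vapply(truth$lethal_pairs, function(pr) {
      condition_has_pair(cc, pr, truth$factors)
    }, logical(1)))
  }, logical(1))

  rows <- list()
  props <- names(truth$property_effects)
  for (pi in seq_along(props)) {
    prop <- props[pi]
    days <- truth$property_effects[[prop]]$days %||% VALID_DAYS
    sd_p <- truth$noise_sd[[prop]]
    for (ci in seq_along(conds)) {
      for (day in days) {
        if (lethal[ci] && day > truth$lethal_from_day) next
        mu <- latent_mean(truth, prop, inh_sets[[ci]], day)
        set.seed(derive_seed(seed, pi, ci, day))
        z <- stats::rnorm(replicates, mu, sd_p)
        v <- observe_marginal(z, truth$marginal[[prop]],
                              truth$marginal_offset[[prop]])
        rows[[length(rows) + 1L]] <- data.frame(
          condition = conds[ci], day = as.integer(day),
          replicate = paste0("r", seq_len(replicates)),
          property = prop, value = v, stringsAsFactors = FALSE
        )
      }
    }
  }
  measurements <- do.call(rbind, rows)
  rownames(measurements) <- NULL
  expression <- if (!is.null(truth$gene_panel)) {
    simulate_expression(truth, replicates, seed)
  } else NULL
  structure(
    list(measurements = measurements, expression = expression,
         truth = truth, seed = as.integer(seed), design = design),
    class = "synthetic_dataset"
  )
}

#' Simulate a correlated gene-expression panel
#'
#' Day-6 log2 fold changes per viable condition: gene-wise condition effects
#' (baseline + inhibitor main effects) plus correlated Gaussian noise whose
#' correlation matrix is the panel's target `sigma` (imposed via its
#' Cholesky/eigen factorisation) and whose per-gene SD is the panel's
#' `noise_sd`. Sub-streams are derived per condition so adding replicates
#' extends rather than perturbs.
#'
#' @inheritParams simulate_factorial
#' @return Data.frame: condition, day, replicate, gene, log2fc.
#' @export
simulate_expression <- function(truth, replicates = 3L, seed = 1L) {
  gp <- truth$gene_panel
  if (is.null(gp)) stop("ground truth has no gene panel", call. = FALSE)
  design <- enumerate_design(truth$factors, truth$lethal_pairs,
                             truth$lethal_from_day)
  day <- 6L
  conds <- design$conditions
  keep <- vapply(conds, function(cc) {
    viable <- !any(vapply(truth$lethal_pairs, function(pr) {
      condition_has_pair(cc, pr, truth$factors)
    }, logical(1)))
    viable || day <= truth$lethal_from_day
  }, logical(1))
  conds <- conds[keep]
  G <- length(gp$genes)
  ev <- eigen(gp$sigma, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), G) %*% t(ev$vectors)
  rows <- list()
  for (ci in seq_along(conds)) {
    inh <- condition_inhibitors(conds[ci], truth$factors)
    mu <- gp$baseline[gp$genes] +
      if (length(inh) > 0) rowSums(gp$effects[gp$genes, inh, drop = FALSE]) else 0
    set.seed(derive_seed(seed, 99L, ci))
    Z <- matrix(stats::rnorm(replicates * G), replicates, G) %*% L
    Z <- sweep(Z, 2, gp$noise_sd[gp$genes], "*")
    vals <- sweep(Z, 2, mu, "+")
    rows[[length(rows) + 1L]] <- data.frame(
      condition = conds[ci], day = day,
      replicate = rep(paste0("r", seq_len(replicates)), times = G),
      gene = rep(gp$genes, each = replicates),
      log2fc = as.vector(vals), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
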