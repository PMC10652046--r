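test_that("zero-noise simulation reproduces the latent means exactly", {
  truth <- make_additive_truth()
  truth$noise_sd["cell_number"] <- 0
  ds <- simulate_factorial(truth, replicates = 2, seed = 3)
  pe <- truth$property_effects$cell_number
  one <- ds$measurements[ds$measurements$condition == "UR" &
                           ds$measurements$day == 4, ]
  expect_equal(unique(one$value),
               pe$baseline + pe$main[["U"]] + pe$main[["R"]] + pe$day[["4"]])
  none <- ds$measurements[ds$measurements$condition == "none" &
                            ds$measurements$day == 6, ]
  expect_equal(unique(none$value), pe$baseline)
})

test_that("simulation is reproducible and replicate-extension-stable", {
  truth <- screen_truth()
  a <- simulate_factorial(truth, replicates = 3, seed = 99)
  b <- simulate_factorial(truth, replicates = 3, seed = 99)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$expression, b$expression)
  # adding replicates extends sub-streams without perturbing existing rows
  big <- simulate_factorial(truth, replicates = 5, seed = 99)
  key <- function(df) paste(df$condition, df$day, df$replicate, df$property)
  common <- match(key(a$measurements), key(big$measurements))
  expect_equal(big$measurements$value[common], a$measurements$value)
})

test_that("lethal conditions produce no late-day rows (mask invariance)", {
  ds <- make_screen_fixture(seed = 7)
  masked <- apply_viability_mask(ds$design, ds$measurements)
  expect_identical(masked, ds$measurements)
  lr_rows <- ds$measurements[grepl("L", ds$measurements$condition) &
                               grepl("R", ds$measurements$condition), ]
  expect_true(all(lr_rows$day <= 2))
  # morphology is only recorded at day 6
  morph <- ds$measurements[ds$measurements$property == "morphology", ]
  expect_true(all(morph$day == 6))
  # observed-scale sanity: proliferation fractions and apoptosis positivity
  prol <- ds$measurements$value[ds$measurements$property == "proliferation"]
  expect_true(all(prol > 0 & prol < 1))
  expect_true(all(ds$measurements$value[ds$measurements$property == "apoptosis"] > 0))
})

test_that("declared interaction types must match the sign convention", {
  truth <- screen_truth()
  bad <- data.frame(property = "cell_number", pair = "U:P",
                    coefficient = 0.075, type = "synergistic",
                    stringsAsFactors = FALSE)
  expect_error(
    ground_truth(
      property_effects = truth$property_effects["cell_number"],
      interactions = bad,
      noise_sd = truth$noise_sd["cell_number"],
      marginal = c(cell_number = "normal")
    ),
    "sign convention implies antagonistic"
  )
})

test_that("expression noise reproduces the planted correlation structure", {
  truth <- screen_truth()
  # null out the mean structure so empirical correlations isolate sigma
  truth$gene_panel$effects[] <- 0
  truth$gene_panel$baseline[] <- 0
  expr <- simulate_expression(truth, replicates = 9, seed = 13)
  W <- reshape(expr, idvar = c("condition", "replicate"), timevar = "gene",
               direction = "wide", drop = "day")
  M <- as.matrix(W[, -(1:2)])
  colnames(M) <- sub("^log2fc\\.", "", colnames(M))
  r <- cor(M)
  expect_equal(r["Rex1", "Oct4"], 0.8, tolerance = 0.1)
  expect_equal(r["Dnmt3b", "Fgf5"], 0.5, tolerance = 0.12)
  # nominally independent pair close to zero
  expect_lt(abs(r["Lefty2", "Mixl1"]), 0.15)
  expect_equal(unname(colMeans(M)), rep(0, 7), tolerance = 0.1)
  # non-PSD correlation matrix is rejected at construction
  truth_bad <- screen_truth()
  s <- truth_bad$gene_panel$sigma
  s["Rex1", "Oct4"] <- s["Oct4", "Rex1"] <- 1.5
  expect_error(
    ground_truth(
      property_effects = truth_bad$property_effects,
      interactions = truth_bad$interactions,
      noise_sd = truth_bad$noise_sd,
      marginal = truth_bad$marginal,
      marginal_offset = truth_bad$marginal_offset,
      gene_panel = modifyList(truth_bad$gene_panel, list(sigma = s))
    ),
    "positive semi-definite"
  )
})

test_that("main effects are recovered without bias across simulations", {
  truth <- make_additive_truth()
  pe <- truth$property_effects$cell_number
  est <- matrix(NA_real_, 60, 5, dimnames = list(NULL, c("U", "S", "L", "R", "P")))
  ses <- est
  for (s in 1:60) {
    ds <- simulate_factorial(truth, replicates = 3, seed = 4000 + s)
    X <- encode_one_hot(average_replicates(ds$measurements), response = "value")
    fit <- fit_mlr(X)
    est[s, ] <- fit$coefficients[colnames(est)]
    ses[s, ] <- fit$standard_errors[colnames(est)]
  }
  bias <- colMeans(est) - pe$main[colnames(est)]
  expect_true(all(abs(bias) < 0.05 * abs(pe$main[colnames(est)]) + 0.01))
  # reported SEs match the empirical spread (generous band at 60 sims)
  ratio <- apply(est, 2, sd) / colMeans(ses)
  expect_true(all(ratio > 0.7 & ratio < 1.4))
})

test_that("the fixture's planted calls come out of the full pipeline", {
  ds <- make_screen_fixture(seed = 1)
  avg <- average_replicates(ds$measurements)
  tf <- default_transforms()
  call_for <- function(property, pair) {
    sub <- avg[avg$property == property, ]
    sub$value <- apply_transform(sub$value, tf[[property]])
    X <- encode_one_hot(sub, response = "value")
    classify_interaction(fit_mlr_interactions(X), pair)$call
  }
  expect_equal(call_for("proliferation", c("L", "R")), "synergistic")
  expect_equal(call_for("cell_number", c("U", "P")), "antagonistic")
  expect_equal(call_for("cell_number", c("R", "P")), "antagonistic")
  expect_equal(call_for("morphology", c("S", "U")), "additive")
})
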