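test_that("fit_mlr matches the normal-equations oracle and OLS geometry", {
  X <- fixture_design_matrix("cell_number", seed = 21)
  fit <- fit_mlr(X)
  M <- cbind(1, X$predictors)
  beta_oracle <- ols_normal_equations(M, X$response)
  expect_equal(unname(fit$coefficients), unname(beta_oracle), tolerance = 1e-10)
  # residuals orthogonal to every predictor column
  ips <- abs(t(M) %*% fit$residuals)
  expect_true(all(ips < 1e-8 * sqrt(colSums(M^2)) * sqrt(sum(fit$residuals^2) + 1)))
  # sigma and adjusted R2 identities
  expect_equal(fit$sigma, sqrt(fit$rss / (fit$n - fit$p)))
  expect_equal(fit$adjusted_r2,
               1 - (1 - fit$r2) * (fit$n - 1) / (fit$n - fit$p))
  expect_lte(fit$adjusted_r2, fit$r2)
})

test_that("zero-noise additive data are recovered exactly", {
  truth <- make_additive_truth()
  truth$noise_sd["cell_number"] <- 0
  ds <- simulate_factorial(truth, replicates = 1, seed = 5)
  X <- encode_one_hot(average_replicates(ds$measurements), response = "value")
  fit <- fit_mlr(X)
  pe <- truth$property_effects$cell_number
  expect_equal(unname(fit$coefficients[c("U", "S", "L", "R", "P")]),
               unname(pe$main), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["day2"]), unname(pe$day[["2"]]),
               tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_lt(fit$rss, 1e-18)
})

test_that("balanced single-day designs give the closed-form contrasts", {
  d <- enumerate_design(lethal_pairs = list())
  grid <- data.frame(condition = d$conditions, day = 6L)
  set.seed(31)
  grid$value <- rnorm(32)
  X <- encode_one_hot(grid, response = "value")
  fit <- fit_mlr(X)
  for (f in c("U", "S", "L", "R", "P")) {
    has <- X$predictors[, f] == 1
    expect_equal(unname(fit$coefficients[f]),
                 mean(grid$value[has]) - mean(grid$value[!has]))
  }
  # on a noise-free additive response, the interaction model reproduces the
  # main effects exactly and estimates every pairwise term as zero
  # (under 0/1 indicator coding the product columns are not orthogonal to
  # the mains, so coefficient invariance only holds when the truth is
  # additive)
  X0 <- X
  X0$response <- drop(X$predictors %*% c(-1, 2, 0.5, -3, 1)) + 4
  fit0 <- fit_mlr(X0)
  fiti <- fit_mlr_interactions(X0)
  expect_equal(fit0$coefficients[c("U", "S", "L", "R", "P")],
               fiti$coefficients[c("U", "S", "L", "R", "P")],
               tolerance = 1e-10)
  expect_lt(max(abs(fiti$interaction_terms$coefficient)), 1e-10)
  expect_equal(nrow(fiti$interaction_terms), choose(5, 2))
})

test_that("perfect fits and rank deficiencies are reported as such", {
  d <- enumerate_design(lethal_pairs = list())
  grid <- data.frame(condition = d$conditions, day = 6L)
  X <- encode_one_hot(grid, response = NULL)
  # response an exact linear function of the predictors
  X$response <- drop(X$predictors %*% c(1, -2, 0.5, 3, -1)) + 2
  fit <- fit_mlr(X)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-12)
  expect_lt(fit$rss, 1e-16)
  # duplicated predictor column -> singular-design error naming the column
  X2 <- X
  X2$predictors <- cbind(X2$predictors, Udup = X2$predictors[, "U"])
  expect_error(fit_mlr(X2), "singular design.*Udup")
})

test_that("adjusted R2 accepts fractional parameter counts and is monotone", {
  expect_equal(adjusted_r2(1, 20, 5), 1)
  expect_equal(adjusted_r2(0.5, 10, 2), 1 - 0.5 * 9 / 7)
  expect_equal(adjusted_r2(0.3, 15, 0), 0.3)
  gammas <- seq(0, 10, by = 0.5)
  vals <- vapply(gammas, function(g) adjusted_r2(0.8, 30, g), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(adjusted_r2(0.5, 6, 5), "degrees of freedom")
})

test_that("the nested F-test follows the hand formula", {
  # synthetic fit stubs with known RSS: F = (5/10)/(5/20) = 2
  mk <- function(rss, p, terms) {
    structure(list(rss = rss, n = 35, p = p, terms = terms,
                   response = 1:35), class = "linear_fit")
  }
  reduced <- mk(10, 5, letters[1:5])
  full <- mk(5, 15, letters[1:15])
  ft <- nested_f_test(reduced, full)
  expect_equal(ft$f_statistic, 2)
  expect_equal(ft$df1, 10)
  expect_equal(ft$df2, 20)
  expect_equal(ft$p_value, pf(2, 10, 20, lower.tail = FALSE))
  # identical RSS -> F = 0, p = 1
  ft0 <- nested_f_test(mk(5, 5, letters[1:5]), mk(5, 15, letters[1:15]))
  expect_equal(ft0$f_statistic, 0)
  expect_equal(ft0$p_value, 1)
  expect_error(nested_f_test(full, reduced), "nested")
  # real nested pair agrees with anova() on the same data
  X <- fixture_design_matrix("cell_number", seed = 33)
  f0 <- fit_mlr(X)
  f1 <- fit_mlr_interactions(X)
  ft2 <- nested_f_test(f0, f1)
  df <- data.frame(y = X$response, X$predictors, check.names = FALSE)
  ints <- df[, c("U", "S", "L", "R", "P")]
  lm0 <- lm(y ~ ., data = df)
  lm1 <- lm(y ~ . + U:S + U:L + U:R + U:P + S:L + S:R + S:P + L:R + L:P + R:P,
            data = df)
  an <- anova(lm0, lm1)
  expect_equal(ft2$f_statistic, an$F[2], tolerance = 1e-10)
  expect_equal(ft2$p_value, an$`Pr(>F)`[2], tolerance = 1e-10)
})

test_that("interaction classification implements the sign rule", {
  X <- fixture_design_matrix("cell_number", seed = 2)
  fiti <- fit_mlr_interactions(X)
  # planted antagonism: positive interaction against negative mains
  up <- classify_interaction(fiti, c("U", "P"))
  expect_equal(up$call, "antagonistic")
  expect_gt(up$coefficient, 0)
  expect_lt(up$mains_sum, 0)
  # pair order does not matter; "A:B" strings accepted
  expect_equal(classify_interaction(fiti, c("P", "U"))$call, up$call)
  expect_equal(classify_interaction(fiti, "U:P")$call, up$call)
  # synergistic planted pair on the proliferation response
  Xp <- fixture_design_matrix("proliferation", seed = 2)
  lr <- classify_interaction(fit_mlr_interactions(Xp), c("L", "R"))
  expect_equal(lr$call, "synergistic")
  expect_lt(lr$coefficient, 0)
  expect_lt(lr$mains_sum, 0)
  # non-significant interaction is additive regardless of sign
  us <- classify_interaction(fiti, c("U", "S"), alpha_level = 1e-6)
  expect_equal(us$call, "additive")
  expect_error(classify_interaction(fiti, c("U", "X")), "unknown")
})

test_that("day-6-only fits drop the masked L:R interaction as non-estimable", {
  X <- fixture_design_matrix("morphology", seed = 3)
  fiti <- fit_mlr_interactions(X)
  expect_true("L:R" %in% fiti$non_estimable)
  expect_equal(nrow(fiti$interaction_terms), 9)
  expect_error(classify_interaction(fiti, c("L", "R")), "not estimable")
  calls <- classify_all_interactions(fiti)
  expect_equal(nrow(calls), 9)
})
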