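test_that("the 2^5 enumeration covers all combinations deterministically", {
  d <- enumerate_design()
  expect_length(d$conditions, 32)
  expect_false(anyDuplicated(d$conditions) > 0)
  expect_true("none" %in% d$conditions)
  expect_true("USLRP" %in% d$conditions)
  # graded order: subset size first, then lexicographic code
  sizes <- lengths(lapply(d$conditions, condition_inhibitors))
  expect_true(all(diff(sizes) >= 0))
  expect_equal(d$conditions[1], "none")
  # exactly eight conditions carry both L and R
  with_lr <- vapply(d$conditions, function(cc) {
    all(c("L", "R") %in% condition_inhibitors(cc))
  }, logical(1))
  expect_equal(sum(with_lr), 8)
  # single factor degenerates to {none, X}
  d1 <- enumerate_design(factors = "U", lethal_pairs = list())
  expect_equal(d1$conditions, c("none", "U"))
  # 2^k law for intermediate k
  for (k in 2:4) {
    expect_length(enumerate_design(inhibitor_panel()$code[1:k],
                                   lethal_pairs = list())$conditions, 2^k)
  }
  expect_error(enumerate_design(c("U", "U")), "duplicate")
})

test_that("condition codes are a bijection of the inhibitor set", {
  expect_equal(condition_code(c("R", "L")), "LR")
  expect_equal(condition_code(character(0)), "none")
  expect_equal(condition_inhibitors("ULR"), c("U", "L", "R"))
  expect_equal(condition_inhibitors("none"), character(0))
  expect_error(condition_code("X"), "unknown inhibitor")
  expect_error(condition_inhibitors("UU"), "malformed")
  d <- enumerate_design()
  roundtrip <- vapply(d$conditions, function(cc) {
    condition_code(condition_inhibitors(cc))
  }, character(1))
  expect_equal(unname(roundtrip), d$conditions)
})

test_that("one-hot encoding follows the fixed column order and policies", {
  X <- encode_one_hot(data.frame(condition = "ULR", day = 4),
                      include_days = TRUE)
  expect_equal(unname(X$predictors[1, ]), c(1, 0, 1, 1, 0, 0, 1))
  expect_equal(colnames(X$predictors), c("U", "S", "L", "R", "P", "day2", "day4"))
  # inhibitor-free control: all-zero inhibitor block
  X0 <- encode_one_hot(data.frame(condition = "none", day = 6))
  expect_equal(unname(X0$predictors[1, c("U", "S", "L", "R", "P")]), rep(0, 5))
  # no-intercept policy keeps the full day set
  Xf <- encode_one_hot(data.frame(condition = c("U", "S"), day = c(2, 6)),
                       intercept_policy = "no_intercept_full_day_set")
  expect_true(all(c("day2", "day4", "day6") %in% colnames(Xf$predictors)))
  expect_false(Xf$intercept)
  expect_error(encode_one_hot(data.frame(condition = "UX", day = 2)),
               "malformed|unknown")
  expect_error(encode_one_hot(data.frame(condition = "U", day = 3)), "days")
})

test_that("the full single-day design has balanced orthogonal columns", {
  d <- enumerate_design()
  X <- encode_one_hot(data.frame(condition = d$conditions, day = 6))
  inh <- X$predictors[, c("U", "S", "L", "R", "P")]
  expect_equal(unname(colSums(inh)), rep(16, 5))
  gram <- t(inh) %*% inh
  expect_true(all(gram[upper.tri(gram)] == 8))
})

test_that("viability masking removes only lethal late-day rows and is idempotent", {
  d <- enumerate_design()
  grid <- expand.grid(condition = d$conditions, day = c(2L, 4L, 6L),
                      stringsAsFactors = FALSE)
  masked <- apply_viability_mask(d, grid)
  expect_equal(length(unique(masked$condition[masked$day == 2])), 32)
  expect_equal(length(unique(masked$condition[masked$day == 4])), 24)
  expect_equal(length(unique(masked$condition[masked$day == 6])), 24)
  # idempotent, order preserved
  expect_identical(apply_viability_mask(d, masked), masked)
  # disabled rule is the identity
  d0 <- enumerate_design(lethal_pairs = list())
  expect_identical(apply_viability_mask(d0, grid), grid)
})

test_that("measurement tables round-trip and malformed rows are located", {
  ds <- make_screen_fixture(seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(ds$measurements, path)
  back <- read_measurements(path)
  key <- function(df) sort(do.call(paste, c(df[c("condition", "day", "replicate",
                                                 "property")],
                                            list(signif(df$value, 10)))))
  expect_equal(key(back), key(ds$measurements))

  bad <- data.frame(condition = c("U", "S"), day = c(2, 4),
                    replicate = "r1", property = "apoptosis",
                    value = c("1.5", "NA"))
  write.csv(bad, path, row.names = FALSE, quote = FALSE)
  expect_error(read_measurements(path), "line 3.*value.*NA")

  bad$value <- c("1.5", "2.0")
  bad$property <- c("apoptosis", "growth")
  write.csv(bad, path, row.names = FALSE, quote = FALSE)
  expect_error(read_measurements(path), "line 3.*unknown property")

  write.csv(bad[, -5], path, row.names = FALSE)
  expect_error(read_measurements(path), "missing column")
})

test_that("expression tables round-trip with strict parsing", {
  ds <- make_screen_fixture(seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_expression(ds$expression, path)
  back <- read_expression(path)
  expect_equal(nrow(back), nrow(ds$expression))
  expect_equal(sort(unique(back$gene)), sort(unique(ds$expression$gene)))
  expect_equal(mean(back$log2fc), mean(ds$expression$log2fc), tolerance = 1e-8)
})
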