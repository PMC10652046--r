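# Factorial design, condition coding, one-hot encoding, viability masking,
# and the flat-file readers/writers shared by all analysis stages.

#' The five-inhibitor panel
#'
#' The screen perturbs five signalling pathways with one small-molecule
#' inhibitor each: U (U0126, Mek1), S (SU5402, Fgfr), L (LY294002, Pi3k),
#' R (rapamycin, mTor) and P (PF-4708671, S6k). Single upper-case letters are
#' the canonical condition-code alphabet, in this fixed order.
#'
#' @return A data.frame with columns `code` and `label`, one row per inhibitor.
#' @export
#' @examples
#' inhibitor_panel()
inhibitor_panel <- function() {
  data.frame(
    code = c("U", "S", "L", "R", "P"),
    label = c(
      "Mek1 inhibitor U0126",
      "Fgfr inhibitor SU5402",
      "Pi3k inhibitor LY294002",
      "mTor inhibitor rapamycin",
      "S6k inhibitor PF-4708671"
    ),
    stringsAsFactors = FALSE
  )
}

#' Measurement property names recognised throughout the package
#' @keywords internal
MEASUREMENT_PROPERTIES <- c("cell_number", "proliferation", "apoptosis", "morphology")

VALID_DAYS <- c(2L, 4L, 6L)

#' Canonical condition code for a set of inhibitors
#'
#' Conditions are named by concatenating the present inhibitor letters in the
#' panel's fixed order (U, S, L, R, P); the inhibitor-free control is coded
#' `"none"` so that CSV round-trips are unambiguous. The code is a bijection
#' of the inhibitor set.
#'
#' @param inhibitors Character vector of one-letter codes (possibly empty).
#' @param factors Alphabet of valid codes, in canonical order.
#' @return A single string.
#' @export
#' @examples
#' condition_code(c("R", "L"))   # "LR"
#' condition_code(character(0))  # "none"
condition_code <- function(inhibitors, factors = inhibitor_panel()$code) {
  inhibitors <- unique(as.character(inhibitors))
  bad <- setdiff(inhibitors, factors)
  if (length(bad) > 0) {
    stop("unknown inhibitor code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  present <- factors[factors %in% inhibitors]
  if (length(present) == 0) "none" else paste(present, collapse = "")
}

#' Inhibitor set encoded by a condition code
#'
#' Inverse of [condition_code()]. `"none"` maps to the empty set.
#'
#' @param code Condition code string.
#' @inheritParams condition_code
#' @return Character vector of inhibitor letters (canonical order).
#' @export
condition_inhibitors <- function(code, factors = inhibitor_panel()$code) {
  stopifnot(length(code) == 1L, is.character(code))
  if (identical(code, "none") || !nzchar(code)) return(character(0))
  letters_in <- strsplit(code, "", fixed = TRUE)[[1]]
  bad <- setdiff(letters_in, factors)
  if (length(bad) > 0 || anyDuplicated(letters_in)) {
    stop("malformed condition code: ", code, call. = FALSE)
  }
  factors[factors %in% letters_in]
}

#' Enumerate the full two-level factorial design
#'
#' Builds all `2^k` presence/absence combinations of the given factors
#' (for the default five-inhibitor panel, 32 conditions). Conditions are
#' ordered by subset size and then lexicographically by canonical code, so the
#' enumeration is deterministic. A lethality rule can be attached: conditions
#' containing any `lethal_pairs` pair are excluded from modelling for days
#' after `lethal_from_day` (see [apply_viability_mask()]); in the screen this
#' is the LY294002+rapamycin combination, non-viable from day 2.
#'
#' @param factors Character vector of distinct one-letter factor codes.
#' @param lethal_pairs List of length-2 character vectors (unordered pairs).
#' @param lethal_from_day Integer day; rows with `day > lethal_from_day` for
#'   lethal conditions are masked. `NA` disables masking.
#' @return An object of class `factorial_design`: list with `factors`,
#'   `conditions` (character vector of codes), `lethal_pairs`,
#'   `lethal_from_day`.
#' @export
#' @examples
#' d <- enumerate_design()
#' length(d$conditions)  # 32
enumerate_design <- function(factors = inhibitor_panel()$code,
                             lethal_pairs = list(c("L", "R")),
                             lethal_from_day = 2L) {
  factors <- as.character(factors)
  if (length(factors) == 0) stop("need at least one factor", call. = FALSE)
  if (anyDuplicated(factors)) {
    stop("invalid design: duplicate factor codes", call. = FALSE)
  }
  k <- length(factors)
  subsets <- lapply(0:(2^k - 1), function(m) factors[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
  codes <- vapply(subsets, condition_code, character(1), factors = factors)
  sizes <- lengths(subsets)
  ord <- order(sizes, codes, method = "radix")
  for (pr in lethal_pairs) {
    if (length(pr) != 2L || any(!pr %in% factors)) {
      stop("lethal_pairs must be pairs of valid factor codes", call. = FALSE)
    }
  }
  structure(
    list(
      factors = factors,
      conditions = codes[ord],
      lethal_pairs = lethal_pairs,
      lethal_from_day = if (is.null(lethal_from_day)) NA_integer_ else as.integer(lethal_from_day)
    ),
    class = "factorial_design"
  )
}

#' @export
print.factorial_design <- function(x, ...) {
  cat(sprintf(
    "2^%d factorial design: %d conditions over factors {%s}\n",
    length(x$factors), length(x$conditions), paste(x$factors, collapse = ",")
  ))
  if (length(x$lethal_pairs) > 0 && !is.na(x$lethal_from_day)) {
    cat(sprintf(
      "lethal pairs (%s) masked for days > %d\n",
      paste(vapply(x$lethal_pairs, paste, character(1), collapse = "&"), collapse = "; "),
      x$lethal_from_day
    ))
  }
  invisible(x)
}

condition_has_pair <- function(code, pair, factors) {
  inh <- condition_inhibitors(code, factors)
  all(pair %in% inh)
}

#' Drop measurements from non-viable conditions
#'
#' Removes rows whose condition contains any of the design's lethal inhibitor
#' pairs and whose day exceeds `lethal_from_day`. In the screen the eight
#' conditions containing both LY294002 (L) and rapamycin (R) lost viability
#' from day 2, so their day-4 and day-6 rows are excluded from modelling while
#' day-2 rows are retained. Row order is preserved and the operation is
#' idempotent.
#'
#' @param design A `factorial_design` with `lethal_pairs`/`lethal_from_day` set.
#' @param data Data.frame with at least `condition` and `day` columns.
#' @return `data` with masked rows removed.
#' @export
apply_viability_mask <- function(design, data) {
  stopifnot(inherits(design, "factorial_design"))
  if (length(design$lethal_pairs) == 0 || is.na(design$lethal_from_day) || nrow(data) == 0) {
    return(data)
  }
  codes <- unique(data$condition)
  lethal_code <- vapply(codes, function(cc) {
    any(vapply(design$lethal_pairs, function(pr) {
      condition_has_pair(cc, pr, design$factors)
    }, logical(1)))
  }, logical(1))
  is_lethal <- lethal_code[match(data$condition, codes)]
  keep <- !(is_lethal & data$day > design$lethal_from_day)
  data[keep, , drop = FALSE]
}

#' One-hot design matrix for condition/day units
#'
#' Encodes each (condition, day) unit as binary indicators: one column per
#' inhibitor (1 when present, 0 when absent) in the fixed order U, S, L, R, P,
#' followed by day indicator columns when the data span several days. Under
#' the default `with_intercept_drop_one_day` policy an intercept is implied
#' and the day-6 indicator is dropped (day 6 is the baseline), which keeps the
#' day block linearly independent of the intercept; the alternative
#' `no_intercept_full_day_set` keeps all day indicators and no intercept.
#'
#' @param data Data.frame with columns `condition`, `day`, and optionally a
#'   response column.
#' @param response Name of the response column in `data`, or `NULL`.
#' @param factors Factor alphabet (canonical order).
#' @param intercept_policy `"with_intercept_drop_one_day"` or
#'   `"no_intercept_full_day_set"`.
#' @param include_days `NULL` to include day indicators iff more than one
#'   distinct day is present, otherwise `TRUE`/`FALSE`.
#' @return A `design_matrix` object: list with `rows` (condition/day
#'   data.frame), `predictors` (0/1 matrix), `response` (numeric or NULL),
#'   `intercept` (logical), `intercept_policy`, `factors`.
#' @export
#' @examples
#' encode_one_hot(data.frame(condition = "ULR", day = 4))$predictors
encode_one_hot <- function(data,
                           response = if ("value" %in% names(data)) "value" else NULL,
                           factors = inhibitor_panel()$code,
                           intercept_policy = c("with_intercept_drop_one_day",
                                                "no_intercept_full_day_set"),
                           include_days = NULL) {
  intercept_policy <- match.arg(intercept_policy)
  stopifnot(all(c("condition", "day") %in% names(data)))
  if (!all(data$day %in% VALID_DAYS)) {
    stop("days must be drawn from {", paste(VALID_DAYS, collapse = ","), "}", call. = FALSE)
  }
  n <- nrow(data)
  inh_sets <- lapply(as.character(data$condition), condition_inhibitors, factors = factors)
  X <- vapply(factors, function(f) {
    as.numeric(vapply(inh_sets, function(s) f %in% s, logical(1)))
  }, numeric(n))
  X <- matrix(X, nrow = n, dimnames = list(NULL, factors))

  days_present <- sort(unique(as.integer(data$day)))
  if (is.null(include_days)) include_days <- length(days_present) > 1L
  if (include_days) {
    # day 6 is the baseline under the intercept policy
    day_cols <- if (intercept_policy == "with_intercept_drop_one_day") {
      setdiff(VALID_DAYS, 6L)
    } else {
      VALID_DAYS
    }
    D <- vapply(day_cols, function(d) as.numeric(data$day == d), numeric(n))
    D <- matrix(D, nrow = n, dimnames = list(NULL, paste0("day", day_cols)))
    X <- cbind(X, D)
  }
  y <- if (!is.null(response)) {
    stopifnot(response %in% names(data))
    as.numeric(data[[response]])
  } else NULL
  structure(
    list(
      rows = data.frame(condition = as.character(data$condition),
                        day = as.integer(data$day),
                        stringsAsFactors = FALSE),
      predictors = X,
      response = y,
      intercept = intercept_policy == "with_intercept_drop_one_day",
      intercept_policy = intercept_policy,
      factors = factors
    ),
    class = "design_matrix"
  )
}

# ---- flat-file plumbing ----------------------------------------------------

read_strict_csv <- function(path, columns, numeric_cols, validate_row = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  missing <- setdiff(columns, names(raw))
  if (length(missing) > 0) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[columns]
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("parse error in %s, line %d: field '%s' has non-numeric value '%s'",
                   basename(path), bad[1] + 1L, col, raw[[col]][bad[1]]),
           call. = FALSE)
    }
    raw[[col]] <- v
  }
  if (!is.null(validate_row)) {
    msg <- validate_row(raw)
    bad <- which(!is.na(msg))
    if (length(bad) > 0) {
      stop(sprintf("parse error in %s, line %d: %s",
                   basename(path), bad[1] + 1L, msg[bad[1]]), call. = FALSE)
    }
  }
  raw
}

#' Read / write measurement tables
#'
#' `measurements.csv` is the long-format table of emergent-property
#' observations with header `condition,day,replicate,property,value`.
#' Reading is strict: a missing column, a non-numeric `value`, an unknown
#' property, or a day outside \{2, 4, 6\} is a parse error naming the
#' offending line. Writing then reading returns the same multiset of rows.
#'
#' @param path File path.
#' @return `read_measurements`: data.frame with columns condition, day,
#'   replicate, property, value.
#' @export
read_measurements <- function(path) {
  out <- read_strict_csv(
    path,
    columns = c("condition", "day", "replicate", "property", "value"),
    numeric_cols = c("day", "value"),
    validate_row = function(df) {
      msg <- rep(NA_character_, nrow(df))
      bad_prop <- !df$property %in% MEASUREMENT_PROPERTIES
      msg[bad_prop] <- sprintf("unknown property '%s'", df$property[bad_prop])
      bad_day <- is.na(msg) & !df$day %in% VALID_DAYS
      msg[bad_day] <- sprintf("day '%s' not in {2,4,6}", df$day[bad_day])
      msg
    }
  )
  out$day <- as.integer(out$day)
  out
}

#' @rdname read_measurements
#' @param data Data.frame as returned by `read_measurements`.
#' @export
write_measurements <- function(data, path) {
  stopifnot(all(c("condition", "day", "replicate", "property", "value") %in% names(data)))
  utils::write.csv(data[c("condition", "day", "replicate", "property", "value")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write gene-expression tables
#'
#' `expression.csv` holds per-condition log2 fold changes with header
#' `condition,day,replicate,gene,log2fc` (fold changes relative to the
#' untreated reference culture, already Actb-normalised).
#'
#' @param path File path.
#' @return Data.frame with columns condition, day, replicate, gene, log2fc.
#' @export
read_expression <- function(path) {
  out <- read_strict_csv(
    path,
    columns = c("condition", "day", "replicate", "gene", "log2fc"),
    numeric_cols = c("day", "log2fc"),
    validate_row = function(df) {
      msg <- rep(NA_character_, nrow(df))
      msg[!nzchar(df$gene)] <- "empty gene symbol"
      msg
    }
  )
  out$day <- as.integer(out$day)
  out
}

#' @rdname read_expression
#' @param data Data.frame as returned by `read_expression`.
#' @export
write_expression <- function(data, path) {
  stopifnot(all(c("condition", "day", "replicate", "gene", "log2fc") %in% names(data)))
  utils::write.csv(data[c("condition", "day", "replicate", "gene", "log2fc")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
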