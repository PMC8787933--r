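#' Validate a patient registry against a schema
#'
#' Checks every record for missing features and unknown levels, and the
#' `ca_performed` / `outcome_class` columns for non-binary values.  The
#' result is a report, not an error: downstream code can decide whether
#' warnings are tolerable.  The CA column is only required when the
#' registry is validated for the survival (outcome) model, whose input
#' set includes the CA decision.
#'
#' @param registry data frame, one row per patient: one column per
#'   decision-input feature, plus the schema's hospital and outcome
#'   columns and (for survival-model use) `ca_performed`.
#' @param schema a [feature_schema()].
#' @param model_role which model the registry must serve: the survival
#'   role additionally requires a valid binary `ca_performed` column.
#' @return list with character vectors `errors` and `warnings`; a valid
#'   registry has `length(errors) == 0`.
#' @export
validate_registry <- function(registry, schema,
                              model_role = c("survival", "decision")) {
  model_role <- match.arg(model_role)
  errors <- character(0)
  warnings <- character(0)
  need <- schema$decision_inputs
  for (f in need) {
    if (!f %in% names(registry)) {
      errors <- c(errors, sprintf("missing feature column '%s'", f))
      next
    }
    v <- as.character(registry[[f]])
    bad <- which(is.na(v) | !(v %in% schema$features[[f]]))
    if (length(bad))
      errors <- c(errors, sprintf(
        "feature '%s': unknown level in record(s) %s", f,
        paste(utils::head(bad, 5), collapse = ", ")))
  }
  for (col in c(schema$hospital_field,
                if (model_role == "survival") "ca_performed",
                schema$outcome_field)) {
    if (!col %in% names(registry)) {
      errors <- c(errors, sprintf("missing column '%s'", col))
    } else if (col != schema$hospital_field) {
      v <- registry[[col]]
      bad <- which(is.na(v) | !(v %in% c(0L, 1L, "0", "1")))
      if (length(bad))
        errors <- c(errors, sprintf(
          "column '%s': non-binary value in record(s) %s", col,
          paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  if ("ca_performed" %in% names(registry) && model_role == "decision" &&
      anyNA(registry$ca_performed))
    warnings <- c(warnings, "ca_performed has missing values (unused by decision model)")
  list(errors = errors, warnings = warnings)
}

#' Read and write registries as plain CSV
#'
#' One row per patient; level strings stored verbatim, binary fields as
#' "0"/"1"; UTF-8 with a header row.  `read_registry` validates against
#' the schema and errors on unknown levels or missing columns so silent
#' vocabulary drift cannot enter an analysis.
#'
#' @param registry data frame as produced by [generate_registry()] or
#'   read from file.
#' @param path CSV file path.
#' @param schema a [feature_schema()].
#' @param validate set `FALSE` to skip schema validation on read.
#' @return `read_registry` returns the registry data frame with character
#'   feature columns and integer binary columns; `write_registry` returns
#'   `path` invisibly.
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(registry, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path, schema, validate = TRUE) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  need <- c(schema$decision_inputs, schema$hospital_field,
            "ca_performed", schema$outcome_field)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("registry file missing column(s): ", paste(missing, collapse = ", "))
  df$ca_performed <- as.integer(df$ca_performed)
  df[[schema$outcome_field]] <- as.integer(df[[schema$outcome_field]])
  if (validate) {
    rep <- validate_registry(df, schema, model_role = "survival")
    if (length(rep$errors))
      stop("registry fails validation:\n  ",
           paste(rep$errors, collapse = "\n  "))
  }
  df
}

#' Partition a registry into modeling subsets
#'
#' Simple (unstratified) random assignment of records to the four
#' modeling subsets — training, validation, testing and cohort analysis —
#' with subset sizes fixed by largest-remainder rounding of the requested
#' proportions, so realized sizes are each within one record of
#' `proportion * N`.
#'
#' @param n number of records, or a data frame whose rows are counted.
#' @param proportions numeric vector summing to 1; default 40/10/25/25.
#' @param seed integer seed; the assignment is deterministic given it.
#' @param names subset names, one per proportion.
#' @return object of class `data_split`: list with `assignment` (factor of
#'   length `n`), `sizes`, `proportions`, and `seed`.
#' @export
split_data <- function(n, proportions = c(train = 0.40, validation = 0.10,
                                          test = 0.25, cohort_analysis = 0.25),
                       seed = 1L, names = NULL) {
  if (is.data.frame(n)) n <- nrow(n)
  if (n < 1) stop("cannot split an empty record list")
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1")
  if (is.null(names)) {
    names <- names(proportions)
    if (is.null(names)) names <- paste0("split", seq_along(proportions))
  }
  sizes <- largest_remainder(proportions, n)
  perm <- withr_seed(seed, sample.int(n))
  # permuting the label multiset gives a uniform assignment at fixed sizes
  assignment <- factor(rep(names, times = sizes)[perm], levels = names)
  structure(list(assignment = assignment,
                 sizes = stats::setNames(sizes, names),
                 proportions = proportions, seed = seed),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat("<data_split> n =", length(x$assignment), "seed =", x$seed, "\n")
  print(x$sizes)
  invisible(x)
}

#' Row indices of one subset of a split
#' @param split a `data_split`.
#' @param which subset name.
#' @return integer vector of record indices.
#' @export
split_indices <- function(split, which) {
  stopifnot(inherits(split, "data_split"), which %in% levels(split$assignment))
  which(split$assignment == which)
}

# Largest-remainder apportionment: floor each quota, then hand the
# remaining units to the largest fractional remainders (ties -> earlier
# entry).
largest_remainder <- function(proportions, n) {
  quota <- proportions * n
  sizes <- floor(quota)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- quota - sizes
    take <- order(-frac, seq_along(frac))[seq_len(rem)]
    sizes[take] <- sizes[take] + 1
  }
  as.integer(sizes)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
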