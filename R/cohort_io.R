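#' Cohort CSV schema
#'
#' The strict column set used for cohort input and output. Booleans are
#' encoded 0/1, mobilization as the literal strings `early|late|bedridden`,
#' and missing optional cells (e.g. `days_to_death` for survivors, Katz
#' components for patients who died before assessment) are empty, never 0.
#'
#' @return character vector of the required column names, in order.
#' @export
cohort_columns <- function() {
  c("patient_id", "age_years", BKA_CONDITIONS, "mobilization",
    "hypoxia", "metabolic_disorder", "died_within_1yr", "days_to_death",
    KATZ_COLUMNS, "postop_comorbidity", "prosthetic_usage",
    "wound_complication")
}

BOOL_COLUMNS <- function() {
  c(BKA_CONDITIONS, "hypoxia", "metabolic_disorder", "died_within_1yr",
    "postop_comorbidity", "prosthetic_usage", "wound_complication")
}

# Validate one parsed row; returns character vector of "field: message"
# entries (empty when the row is valid).
validate_row <- function(row) {
  errs <- character(0)
  add <- function(field, msg) errs[[length(errs) + 1L]] <<- paste0(field, ": ", msg)

  if (is.na(row$patient_id) || !nzchar(row$patient_id)) {
    add("patient_id", "must be non-empty")
  }
  age <- row$age_years
  if (is.na(age) || age != as.integer(age)) {
    add("age_years", "must be a whole number")
  } else if (age < 18) {
    add("age_years", "below 18 violates the adult inclusion criterion")
  }
  for (col in BOOL_COLUMNS()) {
    v <- row[[col]]
    if (is.na(v) || !(v %in% c(0, 1))) add(col, "must be 0 or 1")
  }
  if (is.na(row$mobilization) || !(row$mobilization %in% MOBILIZATION_LEVELS)) {
    add("mobilization", "unrecognized category (allowed: early|late|bedridden)")
  }
  died <- row$died_within_1yr
  if (!is.na(died) && died %in% c(0, 1)) {
    if (died == 1) {
      d <- row$days_to_death
      if (is.na(d)) {
        add("days_to_death", "required for deceased patients")
      } else if (d != as.integer(d) || d < 0) {
        add("days_to_death", "must be a non-negative whole number")
      }
    } else if (!is.na(row$days_to_death)) {
      add("days_to_death", "must be empty for survivors")
    }
  }
  katz <- unlist(row[KATZ_COLUMNS])
  n_present <- sum(!is.na(katz))
  if (n_present > 0L && n_present < 6L) {
    add("katz_components", "partially filled Katz tuple (all six or none)")
  } else if (n_present == 6L && !all(katz %in% c(0, 1))) {
    add("katz_components", "Katz components must be 0 or 1")
  }
  errs
}

#' Read and validate a cohort CSV
#'
#' Reads a patient cohort from the strict CSV schema (see
#' [cohort_columns()]), validating every row against the record
#' invariants: adult age, closed mobilization and comorbidity vocabulary,
#' 0/1 booleans, `days_to_death` present exactly for deceased patients,
#' and Katz components either all six present or all absent.
#'
#' @param path path to a CSV file with a header row.
#' @param strict if `TRUE` (default) any invalid row is an error; if
#'   `FALSE` invalid rows are dropped and reported.
#' @return a list with `cohort` (validated `data.frame`, logical booleans)
#'   and `report` (class `validation_report`: `row_errors` data.frame with
#'   columns `row`, `field`, `message`; `n_accepted`; `n_rejected`).
#' @examples
#' cohort <- simulate_cohort(paper_like_config(seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_cohort(cohort, f)
#' read_cohort(f)$report
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = "", check.names = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[, cohort_columns(), drop = FALSE]
  validate_cohort(raw, strict = strict,
                  source = paste0("file:", path))
}

#' Validate a raw cohort table
#'
#' Row-by-row validation of a cohort `data.frame` (as parsed from CSV or
#' built in code). Validation is deterministic and independent per row.
#'
#' @param raw `data.frame` holding all columns of [cohort_columns()]
#'   (character or native types).
#' @param strict error on any invalid row instead of dropping it.
#' @param source provenance string stored on the result.
#' @return as [read_cohort()].
#' @export
validate_cohort <- function(raw, strict = TRUE, source = "in-memory") {
  num_cols <- setdiff(cohort_columns(), c("patient_id", "mobilization"))
  parsed <- raw
  parsed$patient_id <- as.character(raw$patient_id)
  parsed$mobilization <- as.character(raw$mobilization)
  for (col in num_cols) {
    v <- raw[[col]]
    if (is.logical(v)) v <- as.numeric(v)
    parsed[[col]] <- suppressWarnings(as.numeric(as.character(v)))
    bad_cell <- !is.na(as.character(v)) & nzchar(trimws(as.character(v))) &
      is.na(parsed[[col]])
    # unparseable cells become NA and are caught per-field below, except
    # that we keep the message specific
    attr(parsed[[col]], "unparseable") <- which(bad_cell)
  }

  n <- nrow(parsed)
  err_rows <- integer(0); err_fields <- character(0); err_msgs <- character(0)
  valid <- rep(TRUE, n)
  for (i in seq_len(n)) {
    row <- as.list(parsed[i, , drop = FALSE])
    errs <- validate_row(row)
    for (col in num_cols) {
      if (i %in% attr(parsed[[col]], "unparseable")) {
        errs <- c(errs, paste0(col, ": unparseable cell '", raw[[col]][i], "'"))
      }
    }
    if (length(errs) > 0L) {
      valid[i] <- FALSE
      for (e in errs) {
        sp <- strsplit(e, ": ", fixed = TRUE)[[1]]
        err_rows <- c(err_rows, i)
        err_fields <- c(err_fields, sp[1])
        err_msgs <- c(err_msgs, paste(sp[-1], collapse = ": "))
      }
    }
  }

  dup <- duplicated(parsed$patient_id) & valid
  if (any(dup)) {
    for (i in which(dup)) {
      valid[i] <- FALSE
      err_rows <- c(err_rows, i)
      err_fields <- c(err_fields, "patient_id")
      err_msgs <- c(err_msgs, paste0("duplicate id '", parsed$patient_id[i], "'"))
    }
  }

  report <- structure(
    list(row_errors = data.frame(row = err_rows, field = err_fields,
                                 message = err_msgs,
                                 stringsAsFactors = FALSE),
         n_accepted = sum(valid), n_rejected = sum(!valid)),
    class = "validation_report"
  )
  if (strict && report$n_rejected > 0L) {
    stop("invalid cohort (", report$n_rejected, " bad row(s)); first: row ",
         err_rows[1], ", ", err_fields[1], ": ", err_msgs[1], call. = FALSE)
  }

  cohort <- parsed[valid, , drop = FALSE]
  rownames(cohort) <- NULL
  for (col in c(BOOL_COLUMNS(), KATZ_COLUMNS)) cohort[[col]] <- cohort[[col]] == 1
  cohort$age_years <- as.integer(cohort$age_years)
  cohort$days_to_death <- as.integer(cohort$days_to_death)
  for (col in num_cols) attr(cohort[[col]], "unparseable") <- NULL
  attr(cohort, "source") <- source
  list(cohort = cohort, report = report)
}

#' Write a cohort CSV
#'
#' Serializes a validated cohort back to the strict schema. Booleans are
#' written 0/1 and missing optional fields as empty cells, so that
#' [read_cohort()] of the written file reproduces the cohort
#' field-for-field.
#'
#' @param cohort validated cohort `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort[, cohort_columns(), drop = FALSE]
  for (col in c(BOOL_COLUMNS(), KATZ_COLUMNS)) {
    out[[col]] <- as.integer(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Cohort validation:", x$n_accepted, "accepted,",
      x$n_rejected, "rejected\n")
  if (nrow(x$row_errors) > 0L) {
    for (i in seq_len(nrow(x$row_errors))) {
      cat(sprintf("  row %d [%s] %s\n", x$row_errors$row[i],
                  x$row_errors$field[i], x$row_errors$message[i]))
    }
  }
  invisible(x)
}
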