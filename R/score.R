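#' @keywords internal
"_PACKAGE"

# The six preoperative comorbid systemic diseases that each score one point,
# in the canonical column order used throughout the package.
BKA_CONDITIONS <- c(
  "copd", "hypertension", "diabetes_mellitus",
  "prior_mi", "prior_stroke", "prior_limb_infection"
)

# The six Katz activities of daily living, in assessment order.
KATZ_ACTIVITIES <- c(
  "bathing", "dressing", "toileting",
  "transferring", "personal_care", "feeding"
)

KATZ_COLUMNS <- paste0("katz_", KATZ_ACTIVITIES)

MOBILIZATION_LEVELS <- c("early", "late", "bedridden")

AGE_BANDS <- c("under_65", "65_to_79", "over_79")

#' Age-band points of the risk index
#'
#' Assigns 0 points to patients under 65 years, 1 point to ages 65-79,
#' and 2 points to patients over 79, mirroring common perioperative risk
#' stratification bands. Ages are whole years; patients under 18 are not
#' eligible for scoring.
#'
#' @param age_years integer vector of ages in whole years, all >= 18.
#' @return integer vector of points in `{0, 1, 2}`.
#' @examples
#' age_points(c(64, 65, 79, 80))
#' @export
age_points <- function(age_years) {
  age_years <- check_age(age_years)
  pts <- integer(length(age_years))
  pts[age_years >= 65] <- 1L
  pts[age_years >= 80] <- 2L
  pts
}

check_age <- function(age_years) {
  if (length(age_years) == 0L || !is.numeric(age_years) || anyNA(age_years)) {
    stop("`age_years` must be a non-empty numeric vector without NA", call. = FALSE)
  }
  if (any(age_years != as.integer(age_years))) {
    stop("`age_years` must be whole years", call. = FALSE)
  }
  if (any(age_years < 18)) {
    stop("age below 18 violates the adult inclusion criterion", call. = FALSE)
  }
  as.integer(age_years)
}

#' Comorbidity points of the risk index
#'
#' One point per preoperative comorbid systemic disease, from the closed
#' set: chronic obstructive pulmonary disease (`copd`), `hypertension`,
#' `diabetes_mellitus`, previous myocardial infarction (`prior_mi`),
#' previous stroke (`prior_stroke`), and previous lower extremity
#' infection (`prior_limb_infection`).
#'
#' @param conditions character vector naming the conditions present
#'   (duplicates are an error), or a list of such vectors.
#' @return integer count(s) in `[0, 6]`.
#' @examples
#' comorbidity_points(c("hypertension", "diabetes_mellitus"))
#' comorbidity_points(character(0))
#' @export
comorbidity_points <- function(conditions) {
  if (is.list(conditions)) {
    return(vapply(conditions, comorbidity_points, integer(1)))
  }
  conditions <- as.character(conditions)
  unknown <- setdiff(conditions, BKA_CONDITIONS)
  if (length(unknown) > 0L) {
    stop("unknown condition name(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(BKA_CONDITIONS, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(conditions)) {
    stop("duplicated condition name(s) in comorbidity set", call. = FALSE)
  }
  length(conditions)
}

#' Mobilization points of the risk index
#'
#' Early mobilization (within 24 hours of surgery, with a walking aid)
#' scores 0 points, late mobilization (after 24 hours) 1 point, and
#' immobilization (bedridden) 2 points.
#'
#' @param category character vector with values in
#'   `c("early", "late", "bedridden")`.
#' @return integer vector of points in `{0, 1, 2}`.
#' @examples
#' mobilization_points(c("early", "late", "bedridden"))
#' @export
mobilization_points <- function(category) {
  category <- as.character(category)
  idx <- match(category, MOBILIZATION_LEVELS)
  if (anyNA(idx)) {
    bad <- unique(category[is.na(idx)])
    stop("unrecognized mobilization category: ", paste(bad, collapse = ", "),
         "; allowed: ", paste(MOBILIZATION_LEVELS, collapse = "|"), call. = FALSE)
  }
  idx - 1L
}

#' Early-complication points of the risk index
#'
#' One point each for postoperative hypoxia (oxygen saturation < 90% or
#' supplemental-oxygen need beyond baseline within 72 h) and for a
#' clinically actionable metabolic disorder (severe electrolyte imbalance
#' or acid-base disturbance).
#'
#' @param hypoxia,metabolic_disorder logical vectors (recycled to common
#'   length).
#' @return integer vector of points in `{0, 1, 2}`.
#' @examples
#' complication_points(TRUE, FALSE)
#' @export
complication_points <- function(hypoxia, metabolic_disorder) {
  hypoxia <- check_flag(hypoxia, "hypoxia")
  metabolic_disorder <- check_flag(metabolic_disorder, "metabolic_disorder")
  as.integer(hypoxia) + as.integer(metabolic_disorder)
}

check_flag <- function(x, name) {
  if (is.numeric(x) && all(x %in% c(0, 1))) x <- x == 1
  if (!is.logical(x) || anyNA(x)) {
    stop("`", name, "` must be logical (or 0/1) without NA", call. = FALSE)
  }
  x
}

#' Risk-score breakdown for a cohort
#'
#' Computes the four point components (age band, comorbidity count,
#' mobilization category, early complications) and their total
#' (range 0-12) for every patient in a cohort table.
#'
#' @param cohort a cohort `data.frame` in the package's schema (see
#'   [read_cohort()] / [cohort_columns()]). Only the risk-input columns
#'   are required.
#' @return the cohort with five added integer columns: `age_points`,
#'   `comorbidity_points`, `mobilization_points`, `complication_points`,
#'   `total_score`.
#' @examples
#' cohort <- simulate_cohort(paper_like_config(seed = 1))
#' head(score_cohort(cohort)[, c("patient_id", "total_score")])
#' @export
score_cohort <- function(cohort) {
  need <- c("age_years", BKA_CONDITIONS, "mobilization",
            "hypoxia", "metabolic_disorder")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  flags <- vapply(cohort[BKA_CONDITIONS],
                  function(x) as.integer(check_flag(x, "comorbidity flag")),
                  integer(nrow(cohort)))
  if (nrow(cohort) == 1L) flags <- matrix(flags, nrow = 1L)
  cohort$age_points <- age_points(cohort$age_years)
  cohort$comorbidity_points <- as.integer(rowSums(flags))
  cohort$mobilization_points <- mobilization_points(cohort$mobilization)
  cohort$complication_points <-
    complication_points(cohort$hypoxia, cohort$metabolic_disorder)
  cohort$total_score <- cohort$age_points + cohort$comorbidity_points +
    cohort$mobilization_points + cohort$complication_points
  cohort
}

#' Total risk score for a single patient
#'
#' Convenience wrapper returning the per-component breakdown for one
#' patient given as loose arguments rather than a cohort row.
#'
#' @param age_years age in whole years (>= 18).
#' @param conditions character vector of comorbid conditions present
#'   (see [comorbidity_points()]).
#' @param mobilization one of `"early"`, `"late"`, `"bedridden"`.
#' @param hypoxia,metabolic_disorder logical early-complication flags.
#' @return a one-row `data.frame` with the four components and `total`.
#' @examples
#' risk_score(71, c("hypertension", "diabetes_mellitus"), "late",
#'            hypoxia = TRUE, metabolic_disorder = FALSE)
#' @export
risk_score <- function(age_years, conditions = character(0),
                       mobilization = "early",
                       hypoxia = FALSE, metabolic_disorder = FALSE) {
  ap <- age_points(age_years)
  cp <- comorbidity_points(conditions)
  mp <- mobilization_points(mobilization)
  xp <- complication_points(hypoxia, metabolic_disorder)
  data.frame(
    age_points = ap, comorbidity_points = cp,
    mobilization_points = mp, complication_points = xp,
    total = ap + cp + mp + xp
  )
}

#' Katz activities-of-daily-living score
#'
#' Counts how many of the six essential activities (bathing, dressing,
#' toileting, transferring, personal care, feeding) a patient performs
#' independently. A score of 6 indicates full independence, 4 moderate
#' functional ability, and 2 or below severe functional impairment;
#' scores 3 and 5 are reported as `intermediate` rather than given an
#' invented clinical label.
#'
#' @param components logical vector of length 6, `TRUE` where the
#'   activity is performed independently, ordered as in
#'   `bkarisk:::KATZ_ACTIVITIES`.
#' @return a list of class `katz_assessment` with elements `components`,
#'   `score` (0-6) and `category`.
#' @examples
#' katz_score(rep(TRUE, 6))
#' katz_score(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
#' @export
katz_score <- function(components) {
  if (length(components) != 6L) {
    stop("`components` must have exactly six elements", call. = FALSE)
  }
  components <- check_flag(components, "components")
  score <- sum(components)
  category <- if (score == 6L) "full_independence"
  else if (score == 4L) "moderate"
  else if (score <= 2L) "severe_impairment"
  else "intermediate"
  structure(
    list(components = stats::setNames(components, KATZ_ACTIVITIES),
         score = as.integer(score), category = category),
    class = "katz_assessment"
  )
}

#' @export
print.katz_assessment <- function(x, ...) {
  cat("Katz ADL assessment: score", x$score, "of 6 (", x$category, ")\n")
  cat("  independent:",
      if (any(x$components)) paste(names(x$components)[x$components], collapse = ", ")
      else "none", "\n")
  invisible(x)
}
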