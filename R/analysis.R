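OUTCOME_FIELDS <- c(
  "died_within_1yr", "postop_comorbidity", "prosthetic_usage",
  "wound_complication"
)

OUTCOME_TITLES <- c(
  died_within_1yr = "One-year survival status",
  postop_comorbidity = "Postoperative comorbidity",
  prosthetic_usage = "Prosthetic usage",
  wound_complication = "Postoperative wound complications"
)

# group labels, FALSE level first (row layout of a follow-up table)
outcome_levels <- function(field) {
  if (field == "died_within_1yr") c("Survived", "Deceased")
  else c("Absent", "Present")
}

# Quartile convention: linear interpolation between order statistics
# (type 7); small-n quartiles are convention-sensitive, so the report
# footer names the convention.
score_quartiles <- function(x) {
  stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
}

ensure_scored <- function(cohort) {
  if (!("total_score" %in% names(cohort))) score_cohort(cohort) else cohort
}

#' Compare risk scores across the two levels of an outcome
#'
#' Per-group n, median and quartiles of the total risk score, with the
#' Mann-Whitney U comparison between the two outcome levels. The absent /
#' survived group is listed first and U and z refer to it.
#'
#' @param cohort cohort `data.frame` (scored or not).
#' @param outcome_field one of `died_within_1yr`, `postop_comorbidity`,
#'   `prosthetic_usage`, `wound_complication`.
#' @param method passed to [mann_whitney()].
#' @return object of class `group_comparison`: list with `outcome_name`,
#'   `groups` (data.frame: `group`, `n`, `median`, `p25`, `p75`),
#'   `u_statistic`, `z_statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(cohort, outcome_field,
                           method = c("auto", "exact", "normal")) {
  outcome_field <- match.arg(outcome_field, OUTCOME_FIELDS)
  method <- match.arg(method)
  cohort <- ensure_scored(cohort)
  flag <- check_flag(cohort[[outcome_field]], outcome_field)
  if (length(unique(flag)) < 2L) {
    stop("outcome '", outcome_field, "' has a single level in this cohort",
         call. = FALSE)
  }
  s0 <- cohort$total_score[!flag]   # Absent / Survived
  s1 <- cohort$total_score[flag]    # Present / Deceased
  mw <- mann_whitney(s0, s1, method = method)
  q0 <- score_quartiles(s0)
  q1 <- score_quartiles(s1)
  lev <- outcome_levels(outcome_field)
  structure(
    list(outcome_name = unname(OUTCOME_TITLES[outcome_field]),
         outcome_field = outcome_field,
         groups = data.frame(group = lev,
                             n = c(length(s0), length(s1)),
                             median = c(q0[2], q1[2]),
                             p25 = c(q0[1], q1[1]),
                             p75 = c(q0[3], q1[3]),
                             stringsAsFactors = FALSE),
         u_statistic = mw$u_statistic, z_statistic = mw$z_statistic,
         p_value = mw$p_value, method = mw$method),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$outcome_name, "\n")
  g <- x$groups
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %-9s n=%2d  median %.1f  IQR %.1f-%.1f\n",
                g$group[i], g$n[i], g$median[i], g$p25[i], g$p75[i]))
  }
  cat(sprintf("  U = %g, z = %.3f, p = %s (%s)\n",
              x$u_statistic, x$z_statistic, format_p(x$p_value), x$method))
  invisible(x)
}

#' ROC of the risk score for one-year mortality
#'
#' Empirical ROC and AUC of the total score against one-year death. The
#' orientation must be stated explicitly; the result always carries both
#' the requested AUC and its complement.
#'
#' @param cohort cohort `data.frame`.
#' @param direction see [roc_auc()].
#' @return a `bka_roc` object with `positive_label = "died_within_1yr"`.
#' @export
mortality_roc <- function(cohort,
                          direction = c("higher_score_positive",
                                        "lower_score_positive")) {
  direction <- match.arg(direction)
  cohort <- ensure_scored(cohort)
  died <- check_flag(cohort$died_within_1yr, "died_within_1yr")
  if (length(unique(died)) < 2L) {
    stop("cohort contains a single vital status", call. = FALSE)
  }
  roc_auc(cohort$total_score, died,
          positive_label = "died_within_1yr", direction = direction)
}

katz_total <- function(cohort) {
  katz <- as.matrix(cohort[, KATZ_COLUMNS, drop = FALSE])
  ifelse(rowSums(is.na(katz)) > 0L, NA_integer_, rowSums(katz))
}

# alive at the 3-month assessment (day 90)
alive_at_90 <- function(cohort) {
  !cohort$died_within_1yr |
    (!is.na(cohort$days_to_death) & cohort$days_to_death >= 90L)
}

#' Correlation of risk score with the 3-month Katz score
#'
#' Spearman correlation between the total risk score and the Katz ADL
#' score at 3 months. Patients who died within the first three months
#' (day of death < 90) cannot have a 3-month functional assessment and
#' are excluded; patients alive at 3 months but lacking Katz data are
#' also excluded and counted separately rather than imputed.
#'
#' @param cohort cohort `data.frame`.
#' @return list of class `katz_correlation`: `result`
#'   (a [spearman_cor()] object), `excluded_early_death_n`,
#'   `missing_katz_n`, `analyzable_n`.
#' @export
katz_correlation <- function(cohort) {
  cohort <- ensure_scored(cohort)
  early_death <- cohort$died_within_1yr &
    !is.na(cohort$days_to_death) & cohort$days_to_death < 90L
  eligible <- cohort[!early_death, , drop = FALSE]
  kz <- katz_total(eligible)
  keep <- !is.na(kz)
  n_missing <- sum(!keep)
  if (sum(keep) < 3L) {
    stop("fewer than 3 analyzable records with Katz data", call. = FALSE)
  }
  res <- spearman_cor(eligible$total_score[keep], kz[keep])
  structure(
    list(result = res,
         excluded_early_death_n = sum(early_death),
         missing_katz_n = n_missing,
         analyzable_n = sum(keep)),
    class = "katz_correlation"
  )
}

#' @export
print.katz_correlation <- function(x, ...) {
  cat("Score vs 3-month Katz ADL\n")
  cat(sprintf("  analyzable n = %d (excluded: %d deaths before day 90, %d without Katz data)\n",
              x$analyzable_n, x$excluded_early_death_n, x$missing_katz_n))
  cat(sprintf("  Spearman r = %.3f (%s), p = %s\n",
              x$result$r, x$result$band, format_p(x$result$p_value)))
  invisible(x)
}

age_band_of <- function(age) {
  ifelse(age < 65, AGE_BANDS[1], ifelse(age <= 79, AGE_BANDS[2], AGE_BANDS[3]))
}

#' Age-band decomposition of the mean risk score
#'
#' For each age band (<65, 65-79, >79): patient count, mean total score
#' and its exact decomposition into the four mean component points, the
#' early-mobilization fraction, one-year mortality fraction, and the mean
#' 3-month Katz score among patients alive at 3 months with Katz data.
#' Empty bands are reported with `n = 0` and `NA` summaries.
#'
#' @param cohort cohort `data.frame`.
#' @return `data.frame` of class `age_band_summary` with one row per band.
#' @export
age_band_summaries <- function(cohort) {
  cohort <- ensure_scored(cohort)
  band <- age_band_of(cohort$age_years)
  kz <- katz_total(cohort)
  analyzable <- alive_at_90(cohort) & !is.na(kz)
  out <- lapply(AGE_BANDS, function(b) {
    idx <- band == b
    n <- sum(idx)
    if (n == 0L) {
      return(data.frame(band = b, n = 0L, mean_total_score = NA_real_,
                        mean_age_points = NA_real_,
                        mean_comorbidity_points = NA_real_,
                        mean_mobilization_points = NA_real_,
                        mean_complication_points = NA_real_,
                        early_mobilization_fraction = NA_real_,
                        mortality_fraction = NA_real_,
                        mean_katz = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ak <- analyzable & idx
    data.frame(
      band = b, n = n,
      mean_total_score = mean(cohort$total_score[idx]),
      mean_age_points = mean(cohort$age_points[idx]),
      mean_comorbidity_points = mean(cohort$comorbidity_points[idx]),
      mean_mobilization_points = mean(cohort$mobilization_points[idx]),
      mean_complication_points = mean(cohort$complication_points[idx]),
      early_mobilization_fraction = mean(cohort$mobilization[idx] == "early"),
      mortality_fraction = mean(cohort$died_within_1yr[idx]),
      mean_katz = if (any(ak)) mean(kz[ak]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  class(res) <- c("age_band_summary", "data.frame")
  res
}

#' Run the full outcome analysis on a cohort
#'
#' Scores every patient, compares the score across the four binary
#' outcomes (one-year survival, postoperative comorbidity, prosthetic
#' usage, wound complications), computes the mortality ROC in the stated
#' orientation, correlates the score with the 3-month Katz score applying
#' the early-death exclusion, and decomposes mean scores by age band.
#' Sections whose preconditions fail on the given cohort (e.g. a
#' single-level outcome, or no Katz data) are marked not computable
#' instead of failing the whole report. No multiple-testing adjustment is
#' applied.
#'
#' @param cohort validated cohort `data.frame`.
#' @param direction orientation of the mortality ROC (see [roc_auc()]).
#' @param method Mann-Whitney method for the group comparisons.
#' @return object of class `bka_analysis`.
#' @examples
#' report <- run_full_analysis(simulate_cohort(paper_like_config(seed = 42)))
#' print(report)
#' @export
run_full_analysis <- function(cohort,
                              direction = c("higher_score_positive",
                                            "lower_score_positive"),
                              method = c("auto", "exact", "normal")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  scored <- ensure_scored(cohort)

  try_section <- function(expr) {
    tryCatch(expr, error = function(e) {
      structure(list(message = conditionMessage(e)), class = "not_computable")
    })
  }

  comparisons <- lapply(OUTCOME_FIELDS, function(f)
    try_section(compare_groups(scored, f, method = method)))
  names(comparisons) <- OUTCOME_FIELDS

  roc <- try_section(mortality_roc(scored, direction = direction))
  katz <- try_section(katz_correlation(scored))
  bands <- age_band_summaries(scored)

  early_death_n <- sum(scored$died_within_1yr &
                         !is.na(scored$days_to_death) &
                         scored$days_to_death < 90L)

  structure(
    list(
      cohort_summary = list(
        n = nrow(scored),
        mean_age = mean(scored$age_years),
        mean_total_score = mean(scored$total_score),
        mortality_fraction = mean(scored$died_within_1yr),
        source = attr(cohort, "source")
      ),
      scored_cohort = scored,
      comparisons = comparisons,
      roc = roc,
      katz = katz,
      age_bands = bands,
      katz_excluded_n = early_death_n
    ),
    class = "bka_analysis"
  )
}

#' @export
print.bka_analysis <- function(x, ...) {
  cs <- x$cohort_summary
  cat("=== Below-knee amputation risk-score analysis ===\n")
  cat(sprintf("Cohort: n = %d, mean age = %.1f, mean score = %.2f, one-year mortality = %.1f%%\n",
              cs$n, cs$mean_age, cs$mean_total_score,
              100 * cs$mortality_fraction))
  if (!is.null(cs$source)) cat("Source:", cs$source, "\n")
  cat("\n-- Score by outcome group (Mann-Whitney U) --\n")
  for (cmp in x$comparisons) {
    if (inherits(cmp, "not_computable")) {
      cat("  [not computable:", cmp$message, "]\n")
    } else {
      print(cmp)
    }
  }
  cat("\n-- Mortality ROC --\n")
  if (inherits(x$roc, "not_computable")) {
    cat("  [not computable:", x$roc$message, "]\n")
  } else {
    print(x$roc)
  }
  cat("\n-- Functional independence --\n")
  if (inherits(x$katz, "not_computable")) {
    cat("  [not computable:", x$katz$message, "]\n")
  } else {
    print(x$katz)
  }
  cat("\n-- Mean score by age band --\n")
  b <- x$age_bands
  for (i in seq_len(nrow(b))) {
    if (b$n[i] == 0L) {
      cat(sprintf("  %-9s n=0\n", b$band[i]))
    } else {
      cat(sprintf(
        "  %-9s n=%2d  mean score %.2f (age %.2f + comorbidity %.2f + mobilization %.2f + complications %.2f)\n",
        b$band[i], b$n[i], b$mean_total_score[i], b$mean_age_points[i],
        b$mean_comorbidity_points[i], b$mean_mobilization_points[i],
        b$mean_complication_points[i]))
      cat(sprintf("            early mobilization %.0f%%, mortality %.0f%%, mean Katz %s\n",
                  100 * b$early_mobilization_fraction[i],
                  100 * b$mortality_fraction[i],
                  if (is.na(b$mean_katz[i])) "NA"
                  else sprintf("%.2f", b$mean_katz[i])))
    }
  }
  cat("\nQuartiles: linear interpolation between order statistics.\n")
  cat("p-values: two-sided, no multiple-testing adjustment, shown to 3 decimals (<0.001 floored).\n")
  invisible(x)
}

#' @export
summary.bka_analysis <- function(object, ...) {
  print(object, ...)
}

# flatten an analysis into plain lists for JSON serialization
analysis_summary_list <- function(x) {
  cmp_list <- lapply(x$comparisons, function(cmp) {
    if (inherits(cmp, "not_computable")) {
      return(list(status = "not_computable", message = cmp$message))
    }
    list(status = "ok", outcome = cmp$outcome_name,
         groups = cmp$groups,
         u = cmp$u_statistic, z = round(cmp$z_statistic, 6),
         p = round(cmp$p_value, 6), method = cmp$method)
  })
  roc_list <- if (inherits(x$roc, "not_computable")) {
    list(status = "not_computable", message = x$roc$message)
  } else {
    list(status = "ok", direction = x$roc$direction,
         auc = round(x$roc$auc, 6),
         auc_complement = round(x$roc$auc_complement, 6),
         n_pos = x$roc$n_pos, n_neg = x$roc$n_neg)
  }
  katz_list <- if (inherits(x$katz, "not_computable")) {
    list(status = "not_computable", message = x$katz$message)
  } else {
    list(status = "ok", r = round(x$katz$result$r, 6),
         p = round(x$katz$result$p_value, 6),
         band = x$katz$result$band,
         analyzable_n = x$katz$analyzable_n,
         excluded_early_death_n = x$katz$excluded_early_death_n,
         missing_katz_n = x$katz$missing_katz_n)
  }
  bands <- x$age_bands
  bands[] <- lapply(bands, function(col)
    if (is.numeric(col)) round(col, 6) else col)
  list(
    cohort = list(n = x$cohort_summary$n,
                  mean_age = round(x$cohort_summary$mean_age, 6),
                  mean_total_score = round(x$cohort_summary$mean_total_score, 6),
                  mortality_fraction = round(x$cohort_summary$mortality_fraction, 6)),
    comparisons = cmp_list,
    roc = roc_list,
    katz = katz_list,
    age_bands = bands,
    katz_excluded_n = x$katz_excluded_n,
    notes = c("quartiles: linear interpolation between order statistics",
              "no multiple-testing adjustment applied")
  )
}

#' Write an analysis report to disk
#'
#' Writes three artifacts into `dir`: `scored_cohort.csv` (input columns
#' plus the five score columns), `report.txt` (the printed table set) and
#' `summary.json` (machine-readable statistics). Output is deterministic:
#' the same analysis object always produces byte-identical files.
#'
#' @param analysis a `bka_analysis` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scored <- analysis$scored_cohort
  out <- scored[, c(cohort_columns(), "age_points", "comorbidity_points",
                    "mobilization_points", "complication_points",
                    "total_score")]
  for (col in c(BOOL_COLUMNS(), KATZ_COLUMNS)) out[[col]] <- as.integer(out[[col]])
  utils::write.csv(out, file.path(dir, "scored_cohort.csv"),
                   row.names = FALSE, na = "", quote = FALSE)
  txt <- utils::capture.output(print(analysis))
  writeLines(txt, file.path(dir, "report.txt"))
  jsonlite::write_json(analysis_summary_list(analysis),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
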