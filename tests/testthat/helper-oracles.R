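# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: U is counted pair by pair, the exact
# Mann-Whitney p by literal enumeration of group labelings, and the AUC by
# direct concordance counting.

# U for group a by pairwise win counting (ties count 1/2)
oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# exact two-sided Mann-Whitney p by enumerating all C(n1+n2, n1) labelings
oracle_mw_exact_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  n <- length(pooled)
  mu <- n1 * (n - n1) / 2
  obs <- abs(oracle_u(a, b) - mu)
  idx <- utils::combn(n, n1)
  devs <- apply(idx, 2, function(sel) {
    abs(oracle_u(pooled[sel], pooled[-sel]) - mu)
  })
  mean(devs >= obs - 1e-9)
}

# AUC by concordance counting over all positive x negative pairs
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# a tiny fully hand-checkable cohort: deceased patients hold the top scores
toy_cohort <- function() {
  n <- 6L
  df <- data.frame(
    patient_id = sprintf("T%02d", 1:n),
    age_years = c(50L, 60L, 70L, 75L, 82L, 85L),
    copd = FALSE, hypertension = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    diabetes_mellitus = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    prior_mi = FALSE, prior_stroke = FALSE,
    prior_limb_infection = FALSE,
    mobilization = c("early", "early", "late", "late", "bedridden", "bedridden"),
    hypoxia = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    metabolic_disorder = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    died_within_1yr = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    days_to_death = c(NA, NA, NA, 200L, 45L, 300L),
    katz_bathing = TRUE, katz_dressing = TRUE,
    katz_toileting = c(TRUE, TRUE, TRUE, FALSE, NA, FALSE),
    katz_transferring = c(TRUE, TRUE, FALSE, FALSE, NA, FALSE),
    katz_personal_care = c(TRUE, TRUE, FALSE, FALSE, NA, FALSE),
    katz_feeding = c(TRUE, FALSE, FALSE, FALSE, NA, FALSE),
    postop_comorbidity = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    prosthetic_usage = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    wound_complication = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  # patient T05 died on day 45 (< 90): no Katz assessment
  df$katz_bathing[5] <- NA
  df$katz_dressing[5] <- NA
  df
}

# random small datasets with frequent ties (integer-valued)
random_tied_pair <- function(max_n = 6L, values = 1:4) {
  n1 <- sample(1:max_n, 1)
  n2 <- sample(1:max_n, 1)
  list(a = sample(values, n1, replace = TRUE),
       b = sample(values, n2, replace = TRUE))
}
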