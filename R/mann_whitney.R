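# Exact Mann-Whitney machinery. The exact two-sided p-value is defined over
# the permutation distribution of U across all C(n1+n2, n1) labelings of the
# pooled sample:
#
#   p = P( |U - n1*n2/2| >= |U_obs - n1*n2/2| )
#
# which for tie-free data reduces to the classical exact test and with ties
# is the permutation-exact test conditional on the observed value multiset.
# The distribution is computed by the Streitberg-Roehmel shift algorithm over
# doubled midranks (so tied midranks like 2.5 become integers), which counts,
# for every achievable rank total, the number of size-n1 subsets attaining
# it -- identical to full enumeration but polynomial time.

MW_EXACT_MAX_N <- 200L

# Distribution of the doubled rank-sum of a size-n1 subset of `ranks2`
# (doubled midranks, integers). Returns counts indexed by sum offset from
# the minimum achievable; counts[s+1] = number of subsets with doubled
# rank-sum s (s = 0 .. sum(ranks2)).
rank_sum_counts <- function(ranks2, n1) {
  total <- sum(ranks2)
  # f[k+1, s+1] = number of k-subsets with doubled rank-sum s
  f <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
  f[1L, 1L] <- 1
  for (r in ranks2) {
    kmax <- n1
    # update in decreasing k so each rank is used at most once
    for (k in seq.int(kmax, 1L)) {
      nz <- which(f[k, ] > 0)
      if (length(nz) > 0L) {
        f[k + 1L, nz + r] <- f[k + 1L, nz + r] + f[k, nz]
      }
    }
  }
  f[n1 + 1L, ]
}

#' Mann-Whitney U test
#'
#' Rank-based comparison of two independent groups. `U` counts the pairwise
#' wins of `group_a` over `group_b` (ties count one half). The exact
#' two-sided p-value is taken from the permutation distribution of U over
#' all `choose(n1+n2, n1)` group labelings of the pooled values (so ties are
#' handled exactly); the asymptotic p-value uses the normal approximation
#' with the standard tie-corrected variance and a 0.5 continuity correction.
#' The signed normal deviate `z` carries the sign of
#' (mean rank of `group_a` - mean rank of `group_b`) and is reported for
#' both methods; clinical tables often print this signed z in their "U"
#' column.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @param method `"auto"` (exact for `n1+n2 <= 14`, including the
#'   permutation-exact treatment of ties, otherwise the corrected normal
#'   approximation), `"exact"`, or `"normal"`. Requesting `"exact"` beyond
#'   `n1+n2 = 200` is a capability error.
#' @return an object of class `mann_whitney`: a list with `u_statistic`
#'   (U for `group_a`), `z_statistic`, `p_value`, `method`
#'   (`"exact"` or `"normal_approx"`), `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))          # U = 0, exact p = 1/3
#' mann_whitney(rnorm(20), rnorm(20) + 1)  # normal approximation
#' @export
mann_whitney <- function(group_a, group_b, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (anyNA(group_a) || anyNA(group_b)) {
    stop("NA values are not allowed", call. = FALSE)
  }
  n1 <- length(group_a)
  n2 <- length(group_b)
  n <- n1 + n2
  pooled <- c(group_a, group_b)
  rk <- rank(pooled)                      # midranks
  r1 <- sum(rk[seq_len(n1)])
  u1 <- r1 - n1 * (n1 + 1) / 2            # U for group_a
  mu <- n1 * n2 / 2

  # tie-corrected variance and continuity-corrected z (always reported)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  sigma <- sqrt(sigma2)
  d <- u1 - mu
  z <- if (sigma == 0 || d == 0) 0 else (d - sign(d) * 0.5) / sigma

  use_exact <- switch(method,
    exact = TRUE,
    normal = FALSE,
    auto = n <= 14L
  )
  if (use_exact && n > MW_EXACT_MAX_N) {
    stop("exact method not available for n1+n2 > ", MW_EXACT_MAX_N,
         "; use method = \"normal\"", call. = FALSE)
  }

  if (use_exact) {
    # integer arithmetic on doubled quantities avoids float comparisons
    ranks2 <- as.integer(round(2 * rk))
    counts <- rank_sum_counts(ranks2, n1)
    sums2 <- seq_along(counts) - 1L            # doubled rank sums
    offset2 <- n1 * (n1 + 1L)                  # doubled n1(n1+1)/2
    dev2 <- abs(sums2 - offset2 - n1 * n2)     # |2U - n1*n2| per labeling
    obs2 <- abs(as.integer(round(2 * u1)) - n1 * n2)
    p <- sum(counts[dev2 >= obs2]) / sum(counts)
    meth <- "exact"
  } else {
    if (sigma == 0) {
      p <- 1
    } else {
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    meth <- "normal_approx"
  }

  structure(
    list(u_statistic = u1, z_statistic = z, p_value = p,
         method = meth, n1 = n1, n2 = n2),
    class = "mann_whitney"
  )
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat("Mann-Whitney U test (", x$method, ")\n", sep = "")
  cat(sprintf("  n1 = %d, n2 = %d\n", x$n1, x$n2))
  cat(sprintf("  U (group A) = %g, z = %.3f, p = %s\n",
              x$u_statistic, x$z_statistic, format_p(x$p_value)))
  invisible(x)
}

# p-value display convention: three decimals, floored at "<0.001"
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}
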