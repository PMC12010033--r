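#' Interpretation band for a correlation coefficient
#'
#' Maps the magnitude of a correlation coefficient to a qualitative band:
#' `[0, 0.10)` negligible, `[0.10, 0.40)` weak, `[0.40, 0.70)` moderate,
#' `[0.70, 0.90)` strong, `[0.90, 1]` very strong. The published band
#' edges touch (0.39/0.40, 0.69/0.70, ...); half-open intervals closed on
#' the left make every magnitude fall in exactly one band.
#'
#' @param r correlation coefficient(s), `|r| <= 1`.
#' @return character vector of band labels.
#' @examples
#' interpret_correlation(-0.757)  # "strong"
#' interpret_correlation(0.40)    # "moderate"
#' @export
interpret_correlation <- function(r) {
  if (!is.numeric(r) || anyNA(r)) {
    stop("`r` must be numeric without NA", call. = FALSE)
  }
  if (any(abs(r) > 1)) {
    stop("|r| must not exceed 1", call. = FALSE)
  }
  bands <- c("negligible", "weak", "moderate", "strong", "very_strong")
  bands[findInterval(abs(r), c(0, 0.10, 0.40, 0.70, 0.90))]
}

#' Spearman rank correlation
#'
#' Computes the Spearman coefficient as the Pearson product-moment
#' correlation of midranks (so ties are handled by averaging ranks). For
#' `n <= 8` the two-sided p-value is exact, from the full permutation
#' distribution of the coefficient; for larger samples it uses the
#' t-approximation `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
#' freedom. The qualitative band of `|r|` (see [interpret_correlation()])
#' is attached to the result.
#'
#' @param x,y numeric vectors of equal length `n >= 3`; neither may be
#'   constant.
#' @return an object of class `spearman_result`: list with `r`, `p_value`,
#'   `n`, `band`, `method` (`"exact_permutation"` or `"t_approx"`).
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA values are not allowed", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  r <- stats::cor(rx, ry)

  if (n <= 8L) {
    # exact two-sided p over all n! orderings of one rank vector
    perms <- permutations_of(n)
    r_perm <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(r_perm) >= abs(r) - 1e-12)
    method <- "exact_permutation"
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t_approx"
  }

  structure(
    list(r = r, p_value = p, n = n,
         band = interpret_correlation(r), method = method),
    class = "spearman_result"
  )
}

# all permutations of 1..n as rows (n <= 8 -> at most 40320 rows)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      out[row, ] <- append(sub[i, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' @export
print.spearman_result <- function(x, ...) {
  cat("Spearman rank correlation (", x$method, ")\n", sep = "")
  cat(sprintf("  r = %.3f (%s), n = %d, p = %s\n",
              x$r, x$band, x$n, format_p(x$p_value)))
  invisible(x)
}
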