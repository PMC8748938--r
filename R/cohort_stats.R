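# Cohort dichotomization and the nonparametric two-group test used by the
# figure-level comparisons.

#' Dichotomize subjects at the sample median
#'
#' Splits per-subject measurements into `high` (value strictly above the
#' median) and `low` (value at or below the median). The cutoff is the
#' sample median (mean of the two middle order statistics for even n).
#' Values tied with the median go to `low`; with distinct values and even
#' n this yields exact halves. The tie rule is a documented convention —
#' reported cohort splits of exact halves do not pin it down — and can be
#' flipped via `ties`.
#'
#' @param values Numeric per-subject measurements (>= 2, finite, not all
#'   identical).
#' @param ids Optional subject identifiers (defaults to indices).
#' @param ties `"low"` (default) or `"high"`: side receiving values equal
#'   to the cutoff.
#' @return An object of class `dichotomy_labels`: a data frame with
#'   columns `id`, `value`, `label`, and attributes `cutoff`, `n_high`,
#'   `n_low`.
#' @examples
#' dichotomize_by_median(c(1, 2, 3, 4))
#' @export
dichotomize_by_median <- function(values, ids = seq_along(values),
                                  ties = c("low", "high")) {
  ties <- match.arg(ties)
  if (length(values) < 2) stop("need at least 2 subjects", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (length(ids) != length(values)) {
    stop("`ids` and `values` lengths differ", call. = FALSE)
  }
  if (length(unique(values)) == 1L) {
    stop("all values identical: median split is degenerate", call. = FALSE)
  }
  cutoff <- median(values)
  high <- if (ties == "low") values > cutoff else values >= cutoff
  out <- data.frame(id = ids, value = values,
                    label = ifelse(high, "high", "low"),
                    stringsAsFactors = FALSE)
  structure(out, cutoff = cutoff, n_high = sum(high), n_low = sum(!high),
            class = c("dichotomy_labels", "data.frame"))
}

#' Two-tailed Mann-Whitney U test
#'
#' U is computed from midranks; the reported statistic is the smaller of
#' the two one-sided U's. The p value is exact (from the null U
#' distribution) when the pooled sample has at most 12 observations and no
#' ties, and otherwise uses the normal approximation with tie-corrected
#' variance and a continuity correction. The test depends on the data only
#' through ranks, so it is invariant under strictly monotone transforms.
#'
#' @param x,y Numeric samples (each non-empty, finite).
#' @return An object of class `group_comparison`: a list with
#'   `u_statistic`, `p_two_tailed`, `n_x`, `n_y`, `median_x`, `median_y`,
#'   and `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' mann_whitney_two_tailed(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mann_whitney_two_tailed <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("samples must be finite", call. = FALSE)
  }
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  u_x <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  u_y <- nx * ny - u_x
  u <- min(u_x, u_y)

  has_ties <- anyDuplicated(pooled) > 0
  if (!has_ties && nx + ny <= 12) {
    p <- min(1, 2 * pwilcox(u, nx, ny))
    method <- "exact"
  } else {
    n_tot <- nx + ny
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n_tot * (n_tot - 1))
    sigma2 <- nx * ny / 12 * ((n_tot + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1  # all observations tied: no evidence either way
    } else {
      z <- (u - nx * ny / 2 + 0.5) / sqrt(sigma2)  # u <= mean, shift toward it
      p <- min(1, 2 * pnorm(z))
    }
    method <- "normal_approx"
  }
  structure(list(u_statistic = u, p_two_tailed = p,
                 n_x = nx, n_y = ny,
                 median_x = median(x), median_y = median(y),
                 method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Two-tailed Mann-Whitney: U = %g, p = %.4g (%s), n = %d vs %d\n",
    x$u_statistic, x$p_two_tailed, x$method, x$n_x, x$n_y))
  cat(sprintf("  medians: %.4g vs %.4g\n", x$median_x, x$median_y))
  invisible(x)
}
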