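#' D'Agostino-Pearson K-squared normality test
#'
#' Omnibus normality test combining the transformed sample skewness
#' (D'Agostino's Z of sqrt(b1)) and kurtosis (Anscombe-Glynn's Z of b2):
#' K2 = Z_skew^2 + Z_kurt^2, referred to a chi-squared distribution with 2
#' degrees of freedom. Moments are the biased (population) central moments.
#' Requires n >= 8 for the skewness transformation to be defined.
#'
#' @param x Numeric vector (NAs removed), length at least 8.
#' @return A list of class `htest` with `statistic` (K2), `p.value`,
#'   `z_skew` and `z_kurt`.
#' @export
dagostino_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino's test requires at least 8 observations",
                  call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness: D'Agostino (1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * asinh(y / alpha)

  # kurtosis: Anscombe & Glynn (1983)
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - e_b2) / sqrt(var_b2)
  sqrt_beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_beta1 *
    (2 / sqrt_beta1 + sqrt(1 + 4 / sqrt_beta1^2))
  z_kurt <- ((1 - 2 / (9 * a)) -
               ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  structure(
    list(statistic = c(K2 = k2),
         p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
         z_skew = z_skew, z_kurt = z_kurt,
         method = "D'Agostino-Pearson K2 normality test",
         data.name = deparse(substitute(x))),
    class = "htest"
  )
}

#' Significance stars
#'
#' Maps a p-value to the reporting convention: `*` for p < 0.05, `**` for
#' p < 0.01, `***` for p < 0.001, `****` for p < 0.0001, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Two-group comparison with automated test selection
#'
#' Implements the test-selection logic used for pairwise comparisons of
#' per-fly metrics. Both samples are first screened for normality with
#' Shapiro-Wilk and D'Agostino-Pearson tests (both must be non-significant
#' at `alpha_assumptions`; for n < 8 only Shapiro is available and used).
#' If both samples pass, variance homogeneity is assessed with Bartlett's
#' test (the variance gate paired with normally distributed data): equal
#' variances give Student's t-test, unequal variances Welch's t-test.
#' If either sample fails normality, the Mann-Whitney (Wilcoxon rank-sum)
#' test is used. Undefined values (NA) are dropped and counted. No
#' multiple-testing correction is applied: p-values are per-comparison, as
#' in the source analyses.
#'
#' @param values_a,values_b Numeric samples (NAs dropped; at least 3
#'   non-missing values each).
#' @param alpha_assumptions Significance level of the normality and variance
#'   gates (default 0.05).
#' @param labels Length-2 character vector naming the groups.
#' @return An object of class `group_comparison`: test chosen
#'   (`"t"`, `"t_welch"` or `"mann_whitney"`), statistic, p-value, stars,
#'   sample sizes, dropped counts and the full decision trail.
#' @examples
#' cmp <- compare_groups(rnorm(20, 10), rnorm(20, 12))
#' tidy(cmp)
#' @export
compare_groups <- function(values_a, values_b, alpha_assumptions = 0.05,
                           labels = c("a", "b")) {
  dropped <- c(sum(is.na(values_a)), sum(is.na(values_b)))
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 3 || length(b) < 3) {
    stop("each group needs at least 3 non-missing values ",
         "(normality testing is undefined below that)", call. = FALSE)
  }
  norm_check <- function(v) {
    sh <- tryCatch(stats::shapiro.test(v)$p.value, error = function(e) 0)
    da <- if (length(v) >= 8) {
      tryCatch(dagostino_test(v)$p.value, error = function(e) 0)
    } else {
      NA_real_
    }
    list(shapiro_p = sh, dagostino_p = da,
         normal = sh > alpha_assumptions &&
           (is.na(da) || da > alpha_assumptions))
  }
  na <- norm_check(a)
  nb <- norm_check(b)
  both_normal <- na$normal && nb$normal

  bartlett_p <- NA_real_
  if (both_normal) {
    bartlett_p <- stats::bartlett.test(list(a, b))$p.value
    if (bartlett_p > alpha_assumptions) {
      ht <- stats::t.test(a, b, var.equal = TRUE)
      test <- "t"
    } else {
      ht <- stats::t.test(a, b, var.equal = FALSE)
      test <- "t_welch"
    }
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b))
    test <- "mann_whitney"
    statistic <- unname(ht$statistic)
    p <- ht$p.value
    if (is.nan(p)) p <- 1   # zero rank variance (all values tied)
  }

  decisions <- tibble::tibble(
    group = labels,
    n = c(length(a), length(b)),
    n_dropped = dropped,
    shapiro_p = c(na$shapiro_p, nb$shapiro_p),
    dagostino_p = c(na$dagostino_p, nb$dagostino_p),
    normal = c(na$normal, nb$normal)
  )
  structure(
    list(test = test, statistic = statistic, p_value = p,
         stars = significance_stars(p),
         n_a = length(a), n_b = length(b), dropped = dropped,
         bartlett_p = bartlett_p,
         alpha_assumptions = alpha_assumptions,
         labels = labels, decisions = decisions),
    class = "group_comparison"
  )
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided exact test for contingency-table endpoints such as the
#' proportion of dissected females with eggs jammed in the lateral oviducts:
#' the p-value sums the hypergeometric probabilities of all tables (with the
#' observed margins) no more probable than the observed one.
#'
#' @param table A 2x2 matrix (or object coercible to one) of non-negative
#'   counts.
#' @return A `group_comparison` with `test = "fisher_exact"` (the statistic
#'   is the sample odds ratio estimate).
#' @examples
#' fisher_2x2(matrix(c(10, 0, 0, 10), nrow = 2))
#' @export
fisher_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2", call. = FALSE)
  if (any(table < 0)) stop("table entries must be non-negative",
                           call. = FALSE)
  if (sum(table) == 0) stop("table total must be positive", call. = FALSE)
  ht <- stats::fisher.test(table)
  structure(
    list(test = "fisher_exact", statistic = unname(ht$estimate),
         p_value = ht$p.value, stars = significance_stars(ht$p.value),
         n_a = sum(table[, 1]), n_b = sum(table[, 2]),
         dropped = c(0L, 0L), bartlett_p = NA_real_,
         alpha_assumptions = NA_real_,
         labels = colnames(table) %||% c("a", "b"),
         decisions = tibble::tibble(group = character(), n = integer(),
                                    n_dropped = integer(),
                                    shapiro_p = numeric(),
                                    dagostino_p = numeric(),
                                    normal = logical())),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison: %s, statistic = %.4g, p = %.4g %s>\n",
              x$test, x$statistic, x$p_value, x$stars))
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return `tidy()` returns a one-row tibble with the test, statistic,
#'   p-value, stars and group sizes; `glance()` returns the per-group
#'   decision trail (normality p-values and verdicts).
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(
    test = x$test, statistic = x$statistic, p_value = x$p_value,
    stars = x$stars, n_a = x$n_a, n_b = x$n_b,
    n_dropped_a = x$dropped[1], n_dropped_b = x$dropped[2],
    bartlett_p = x$bartlett_p
  )
}

#' @rdname compare_groups
#' @export
glance.group_comparison <- function(x, ...) {
  x$decisions
}

#' Compare a per-fly metric between two groups
#'
#' Convenience wrapper over [compare_groups()] that pulls one metric from a
#' [bout_metric_table()] and compares its defined values between two groups.
#'
#' @param metrics A metric table from [bout_metric_table()].
#' @param metric Metric name to compare.
#' @param group_a,group_b Group labels.
#' @param window Window label (default `"whole"`).
#' @inheritParams compare_groups
#' @return A `group_comparison`.
#' @export
compare_metric <- function(metrics, metric, group_a, group_b,
                           window = "whole", alpha_assumptions = 0.05) {
  pick <- function(g) {
    metrics$value[metrics$metric == metric & metrics$group == g &
                    metrics$window == window]
  }
  compare_groups(pick(group_a), pick(group_b),
                 alpha_assumptions = alpha_assumptions,
                 labels = c(group_a, group_b))
}
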