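# Statistical layer: equal-variance two-tailed t-test and binomial tail
# probabilities for replicate success-count comparisons.

#' Two-tailed equal-variance two-sample t-test
#'
#' Pooled-variance Student t-test with df = n1 + n2 - 2 and the symmetric
#' two-tailed p-value. When the pooled variance is exactly zero the test is
#' undefined; by convention equal means then give t = 0, p = 1 and unequal
#' means give t = +/-Inf, p = 0.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return list (class `ttest_result`) with t, df, p_two_tailed, mean_x,
#'   mean_y.
#' @export
ttest_equal_var_two_tailed <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("both samples need n >= 2")
  df <- n1 + n2 - 2L
  s2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  if (s2 == 0) {
    if (mean(x) == mean(y)) {
      t <- 0; p <- 1
    } else {
      t <- sign(mean(x) - mean(y)) * Inf; p <- 0
    }
  } else {
    ht <- stats::t.test(x, y, var.equal = TRUE)
    t <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(list(t = t, df = df, p_two_tailed = p,
                 mean_x = mean(x), mean_y = mean(y)),
            class = "ttest_result")
}

#' Upper-tail binomial probability P(X >= k)
#'
#' @param k observed success count.
#' @param n number of trials.
#' @param p0 null success probability.
#' @return P(X >= k | n, p0).
#' @export
binomial_upper_tail <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, p0 >= 0, p0 <= 1)
  if (k == 0) return(1)
  stats::pbinom(k - 1, size = n, prob = p0, lower.tail = FALSE)
}

#' Lower-tail binomial probability P(X <= k)
#'
#' @inheritParams binomial_upper_tail
#' @return P(X <= k | n, p0).
#' @export
binomial_lower_tail <- function(k, n, p0) {
  stopifnot(k >= -1, k <= n, p0 >= 0, p0 <= 1)
  if (k < 0) return(0)
  stats::pbinom(k, size = n, prob = p0)
}

#' Compare replicate success counts between two conditions
#'
#' Tests whether the alternative condition shows more successes than
#' expected under the reference condition. The construction is selectable
#' and always reported alongside the p-value:
#' \describe{
#'   \item{upper_ref_rate}{(default) upper tail of k_alt out of n_alt under
#'     p0 = k_ref / n_ref.}
#'   \item{pooled_rate}{upper tail of k_alt under the pooled rate
#'     (k_ref + k_alt) / (n_ref + n_alt).}
#'   \item{lower_ref}{lower tail of k_ref out of n_ref under the
#'     alternative condition's rate k_alt / n_alt.}
#' }
#' A reference count of zero would give a degenerate p0 = 0; a floor of
#' 1 / (2 n_ref) is applied with a warning.
#'
#' @param k_ref,n_ref reference condition successes / trials.
#' @param k_alt,n_alt alternative condition successes / trials.
#' @param construction which Binom.dist-style construction to use.
#' @return list (class `binomial_result`) with k, n, p0, p_upper_tail and
#'   construction.
#' @export
compare_success_counts <- function(k_ref, n_ref, k_alt, n_alt,
                                   construction = c("upper_ref_rate",
                                                    "pooled_rate",
                                                    "lower_ref")) {
  construction <- match.arg(construction)
  stopifnot(k_ref >= 0, k_ref <= n_ref, k_alt >= 0, k_alt <= n_alt)
  if (construction == "upper_ref_rate") {
    p0 <- k_ref / n_ref
    if (k_ref == 0) {
      p0 <- 1 / (2 * n_ref)
      warning("reference count is 0; applying p0 floor 1/(2*n_ref) = ", p0)
    }
    k <- k_alt; n <- n_alt
    p <- binomial_upper_tail(k, n, p0)
  } else if (construction == "pooled_rate") {
    p0 <- (k_ref + k_alt) / (n_ref + n_alt)
    k <- k_alt; n <- n_alt
    p <- binomial_upper_tail(k, n, p0)
  } else {
    p0 <- k_alt / n_alt
    k <- k_ref; n <- n_ref
    p <- binomial_lower_tail(k, n, p0)
  }
  structure(list(k = k, n = n, p0 = p0, p_upper_tail = p,
                 construction = construction),
            class = "binomial_result")
}
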