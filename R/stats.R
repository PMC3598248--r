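#' Mean and standard error of the mean
#'
#' @param x Numeric sample, length at least 2.
#' @return Named vector \code{c(mean = , sem = )} with
#'   sem = sd(x)/sqrt(n) (sample sd, n - 1 denominator).
#' @examples
#' mean_sem(c(2, 4, 6))  # mean 4, sem 2/sqrt(3)
#' @export
mean_sem <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values for mean and s.e.m.")
  c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)))
}

two_sample_test <- function(a, b, var.equal) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 values")
  }
  method <- if (var.equal) "student" else "welch"
  # degenerate cases: both samples constant
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    dof <- if (var.equal) length(a) + length(b) - 2 else
      min(length(a), length(b)) - 1
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(structure(
      list(statistic = if (equal) 0 else sign(mean(a) - mean(b)) * Inf,
           dof = dof, p_value = if (equal) 1 else 0, method = method),
      class = "group_test"))
  }
  ht <- stats::t.test(a, b, var.equal = var.equal)
  structure(
    list(statistic = unname(ht$statistic), dof = unname(ht$parameter),
         p_value = ht$p.value, method = method),
    class = "group_test"
  )
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Two-sided, equal-variance two-sample comparison with
#' \eqn{n_a + n_b - 2} degrees of freedom; used for the morphometric,
#' fluorescence-intensity and qPCR comparisons.
#'
#' @param a,b Numeric samples, each of length at least 2.
#' @return An object of class \code{group_test} with \code{statistic},
#'   \code{dof}, \code{p_value} and \code{method}.
#' @export
student_t <- function(a, b) two_sample_test(a, b, var.equal = TRUE)

#' Two-sample Welch's t-test (unequal variance)
#'
#' Two-sided comparison with Welch--Satterthwaite degrees of freedom; used
#' for the AFM modulus and western-blot comparisons. Reduces exactly to the
#' Student statistic when sample sizes and variances are equal.
#'
#' @inheritParams student_t
#' @return An object of class \code{group_test}.
#' @export
welch_t <- function(a, b) two_sample_test(a, b, var.equal = FALSE)

#' @export
print.group_test <- function(x, ...) {
  nm <- if (x$method == "student") "Student's t (pooled)" else "Welch's t"
  cat(sprintf("%s: t = %.4g, df = %.4g, p = %.4g%s\n",
              nm, x$statistic, x$dof, x$p_value,
              significance_stars(x$p_value)))
  invisible(x)
}

# annotation thresholds as used in figure legends; reporting only
significance_stars <- function(p) {
  if (p < 0.001) " ***" else if (p < 0.01) " **" else if (p < 0.05) " *" else ""
}
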