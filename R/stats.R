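#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with expected
#' agreement from the marginal products. Works for any number of categories;
#' binary prediction-vs-truth comparisons are the common case here.
#'
#' @param pred,truth equal-length categorical vectors.
#' @return object of class `agreement_result` (statistic `"cohen"`); `kappa`
#'   is `NA` when both raters are constant (`p_e = 1`, kappa undefined).
#' @export
cohen_kappa <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 1L)
  lev <- sort(unique(c(as.character(pred), as.character(truth))))
  tab <- table(factor(pred, lev), factor(truth, lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps^0.5) NA_real_ else (po - pe) / (1 - pe)
  structure(list(statistic = "cohen", kappa = kappa, table = tab,
                 p_observed = po, p_expected = pe),
            class = "agreement_result")
}

#' Fleiss' kappa for three or more raters
#'
#' Chance-corrected agreement for a fixed number of raters assigning
#' categorical labels to each subject; used for inter-observer agreement of
#' wall-motion reads among the three expert readers.
#'
#' @param ratings matrix or data.frame, subjects in rows and raters in
#'   columns, categorical entries.
#' @return object of class `agreement_result` (statistic `"fleiss"`);
#'   `kappa` is `NA` when it is undefined (single subject, or all raters use
#'   one category on every subject).
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  stopifnot(ncol(ratings) >= 2L)
  ns <- nrow(ratings); nr <- ncol(ratings)
  lev <- sort(unique(as.character(ratings)))
  counts <- t(apply(ratings, 1, function(r) table(factor(as.character(r), lev))))
  if (length(lev) == 1L) counts <- matrix(nr, ns, 1)
  pj <- colSums(counts) / (ns * nr)
  pi_i <- (rowSums(counts^2) - nr) / (nr * (nr - 1))
  pbar <- mean(pi_i)
  pe <- sum(pj^2)
  kappa <- if (ns < 2L || abs(1 - pe) < .Machine$double.eps^0.5) NA_real_
  else (pbar - pe) / (1 - pe)
  structure(list(statistic = "fleiss", kappa = kappa,
                 category_counts = counts, p_bar = pbar, p_expected = pe),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("%s kappa: %s\n", x$statistic,
              if (is.na(x$kappa)) "undefined" else sprintf("%.4f", x$kappa)))
  invisible(x)
}

#' Two-proportion z-test (pooled)
#'
#' Two-tailed test comparing proportions `x1/n1` and `x2/n2` with the pooled
#' standard error; used for cohort-balance checks (e.g. proportions of
#' abnormal videos between training and testing cohorts).
#'
#' @param x1,n1,x2,n2 successes and totals of the two groups.
#' @return list with `z`, `p`, and the two proportions. Degenerate pooled
#'   proportions (0 or 1) yield `z = 0, p = 1` with a warning.
#' @export
two_prop_ztest <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) {
    warning("pooled proportion is degenerate (0 or 1); z set to 0")
    return(list(z = 0, p = 1, p1 = p1, p2 = p2))
  }
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Compare two correlation coefficients (Fisher r-to-z)
#'
#' Tests the difference of two correlations via the Fisher transform:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-tailed.
#' Used to test whether contour smoothing significantly improves the
#' LS-vs-FAC correlation. The plain (independent-samples) transform is used
#' even when the samples are dependent, which is approximate in that case.
#'
#' @param r1,r2 correlation coefficients, `|r| < 1`.
#' @param n1,n2 sample sizes, both `> 3`.
#' @return list with `z` and two-tailed `p`.
#' @export
compare_correlations <- function(r1, r2, n1, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1 (Fisher transform diverges)")
  stopifnot(n1 > 3, n2 > 3)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Least-squares linear fit with R-squared and confidence band
#'
#' Ordinary least squares of `y` on `x` with the coefficient of
#' determination and the pointwise 95% confidence band of the mean fit
#' (as drawn around LS-vs-FAC scatter plots).
#'
#' @param x,y numeric vectors, `n >= 3`, `x` non-constant.
#' @param band_at x values at which to evaluate the confidence band
#'   (default: sorted `x`).
#' @return object of class `fit_result`: `slope`, `intercept`, `r_squared`,
#'   `n`, and `band` (data.frame `x`, `fit`, `lo`, `hi`).
#' @export
linfit_r2 <- function(x, y, band_at = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0) stop("x is constant: slope undefined")
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  if (is.null(band_at)) band_at <- sort(x)
  ci <- stats::predict(fit, newdata = data.frame(x = band_at),
                       interval = "confidence", level = 0.95)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = summary(fit)$r.squared,
    n = length(x),
    band = data.frame(x = band_at, fit = ci[, "fit"], lo = ci[, "lwr"], hi = ci[, "upr"])
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("linear fit (n = %d): y = %.4f x + %.4f, R^2 = %.4f\n",
              x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}
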