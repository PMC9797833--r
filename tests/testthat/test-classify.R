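make_labels <- function(abnormal = list(), n_readers = 3, studies = "s1") {
  # abnormal: named list study -> data.frame(reader, segment, label)
  g <- expand.grid(study = studies, reader = paste0("r", seq_len(n_readers)),
                   segment = 1:16, stringsAsFactors = FALSE)
  g$label <- "normal"
  for (st in names(abnormal)) {
    for (i in seq_len(nrow(abnormal[[st]]))) {
      row <- abnormal[[st]][i, ]
      sel <- g$study == st & g$reader == row$reader & g$segment == row$segment
      g$label[sel] <- row$label
    }
  }
  g
}

test_that("consensus labelling follows the two-reader rule and propagates upward", {
  # all normal
  res <- consensus_view_labels(make_labels())
  expect_false(any(res$views$abnormal))
  expect_false(any(res$studies$abnormal))

  # one reader alone does not make a segment abnormal
  one <- make_labels(list(s1 = data.frame(reader = "r1", segment = 3,
                                          label = "hypokinetic")))
  res1 <- consensus_view_labels(one)
  expect_false(any(res1$segments$abnormal))
  expect_false(any(res1$studies$abnormal))

  # two readers on a 4CH-mapped segment (3 = basal inferoseptal)
  two <- make_labels(list(s1 = data.frame(reader = c("r1", "r2"), segment = 3,
                                          label = "akinetic")))
  res2 <- consensus_view_labels(two)
  v <- res2$views
  expect_true(v$abnormal[v$view == "4CH"])
  expect_false(any(v$abnormal[v$view != "4CH"]))
  expect_true(res2$studies$abnormal)

  # incomplete grids are rejected with the gap named
  broken <- make_labels()[-1, ]
  expect_error(consensus_view_labels(broken), "incomplete")
  expect_error(consensus_view_labels(transform(make_labels(), label = "bad")),
               "unknown")
})

test_that("the AHA mapping covers all 16 segments across the three views", {
  m <- aha_view_mapping()
  expect_setequal(m$segment, 1:16)
  expect_setequal(unique(m$view), c("2CH", "3CH", "4CH"))
})

test_that("ROC with separable classes reaches AUC 1 and a separating cutoff", {
  scores <- c(-0.35, -0.3, -0.28, -0.1, -0.08, -0.05)
  truth <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  r <- roc_and_optimal_cutoff(scores, truth)
  expect_equal(r$auc, 1)
  expect_true(r$tau > -0.28 && r$tau < -0.1)
  expect_equal(unname(r$operating_point), c(1, 1))

  # four-score worked example: AUC 1 by exhaustive pair counting
  s2 <- c(-0.30, -0.25, -0.10, -0.05)
  t2 <- c(FALSE, FALSE, TRUE, TRUE)
  pairs <- expand.grid(a = s2[t2], n = s2[!t2])
  expect_equal(mean(pairs$a > pairs$n) + 0.5 * mean(pairs$a == pairs$n), 1)
  expect_equal(roc_and_optimal_cutoff(s2, t2)$auc, 1)

  expect_error(roc_and_optimal_cutoff(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC equals Mann-Whitney concordance and is ~0.5 under independence", {
  set.seed(101)
  for (rep in 1:15) {
    n <- sample(20:120, 1)
    scores <- round(rnorm(n), 2)  # ties included
    truth <- runif(n) < 0.4
    if (all(truth) || !any(truth)) next
    r <- roc_and_optimal_cutoff(scores, truth)
    pairs <- expand.grid(a = scores[truth], n = scores[!truth])
    mw <- mean(pairs$a > pairs$n) + 0.5 * mean(pairs$a == pairs$n)
    expect_equal(r$auc, mw, tolerance = 1e-10)
    # sensitivity non-increasing, specificity non-decreasing in tau
    ord <- order(r$thresholds)
    expect_true(all(diff(r$sensitivity[ord]) <= 1e-12))
    expect_true(all(diff(r$specificity[ord]) >= -1e-12))
  }
  set.seed(202)
  scores <- rnorm(200); truth <- runif(200) < 0.5
  expect_lt(abs(roc_and_optimal_cutoff(scores, truth)$auc - 0.5), 0.1)
})

test_that("ROC AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  scores <- rnorm(80)
  truth <- runif(80) < 0.5 | scores > 0.5
  r <- roc_and_optimal_cutoff(scores, truth)
  ref <- suppressMessages(pROC::auc(pROC::roc(truth, scores, direction = "<")))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-10)
})

test_that("view and patient classification apply the fitted cutoffs", {
  taus <- c("2CH" = -0.218, "3CH" = -0.154, "4CH" = -0.166)
  expect_false(classify_view(-0.30, "2CH", taus))   # clearly contracting
  expect_true(classify_view(-0.10, "3CH", taus))    # weak shortening
  expect_true(classify_view(-0.154, "3CH", taus))   # equality counts abnormal
  expect_equal(classify_view(c(-0.3, -0.1), c("2CH", "3CH"), taus),
               c(FALSE, TRUE))
  # single-threshold mode
  expect_true(classify_view(-0.16, thresholds = -0.170))
  expect_error(classify_view(-0.2, "2CH", c("3CH" = -0.1)), "missing threshold")

  expect_false(classify_patient(c(FALSE, FALSE, FALSE)))
  expect_true(classify_patient(c(FALSE, TRUE, FALSE)))
  expect_true(classify_patient(c(TRUE, TRUE, TRUE)))
  expect_error(classify_patient(logical(0)), "no view")
})

test_that("confusion metrics reproduce printed rates and Wald intervals", {
  # testing-cohort per-patient counts
  m <- confusion_metrics(tp = 16, fn = 3, fp = 5, tn = 23)
  r <- split(m$rates, m$rates$metric)
  expect_equal(round(r$accuracy$value, 1), 83.0)
  expect_equal(round(r$sensitivity$value, 1), 84.2)
  expect_equal(round(r$specificity$value, 1), 82.1)
  expect_equal(round(r$ppv$value, 1), 76.2)
  expect_equal(round(c(r$accuracy$lo, r$accuracy$hi), 1), c(72.2, 93.7))

  # training-cohort per-patient counts: upper limits clip at 100
  m2 <- confusion_metrics(tp = 18, fn = 2, fp = 0, tn = 28)
  r2 <- split(m2$rates, m2$rates$metric)
  expect_equal(round(r2$accuracy$value, 1), 95.8)
  expect_equal(round(r2$sensitivity$value, 1), 90.0)
  expect_equal(round(c(r2$sensitivity$lo, r2$sensitivity$hi), 1), c(76.9, 100))
  expect_equal(r2$specificity$value, 100)
  expect_equal(r2$ppv$value, 100)

  # perfect agreement
  m3 <- confusion_metrics(pred = c(TRUE, FALSE, TRUE), truth = c(TRUE, FALSE, TRUE))
  expect_equal(m3$fp + m3$fn, 0)
  expect_equal(m3$rates$value[m3$rates$metric == "accuracy"], 100)

  # undefined rate reported absent, not NaN
  m4 <- confusion_metrics(pred = c(FALSE, FALSE), truth = c(FALSE, FALSE))
  expect_true(is.na(m4$rates$value[m4$rates$metric == "sensitivity"]))
  expect_false(any(is.nan(m4$rates$value)))
})

test_that("Cohen's kappa matches its definition and behaves at the extremes", {
  expect_equal(cohen_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0))$kappa, 1)

  # 2x2 table (a, b, c, d) = (20, 5, 10, 15): direct-formula oracle
  pred <- rep(c(1, 1, 0, 0), c(20, 5, 10, 15))
  truth <- rep(c(1, 0, 1, 0), c(20, 5, 10, 15))
  n <- 50
  po <- (20 + 15) / n
  pe <- (25 / n) * (30 / n) + (25 / n) * (20 / n)
  expect_equal(cohen_kappa(pred, truth)$kappa, (po - pe) / (1 - pe))

  set.seed(11)
  expect_lt(abs(cohen_kappa(runif(1000) < 0.5, runif(1000) < 0.5)$kappa), 0.1)

  expect_true(is.na(cohen_kappa(rep(1, 5), rep(1, 5))$kappa))
})

test_that("Fleiss' kappa matches a hand-computed table and the extremes", {
  expect_equal(fleiss_kappa(matrix("a", 6, 3))$kappa,
               NA_real_)  # constant category: chance agreement is total
  expect_equal(fleiss_kappa(cbind(c("a", "b", "a", "b"), c("a", "b", "a", "b"),
                                  c("a", "b", "a", "b")))$kappa, 1)

  # 4 subjects x 3 raters, categories {a, b}; counts per subject: (3,0),(2,1),(1,2),(0,3)
  tab <- rbind(c("a", "a", "a"), c("a", "a", "b"), c("a", "b", "b"), c("b", "b", "b"))
  # step-by-step published formula:
  pa_i <- c(1, (2 * 1 + 0) / (3 * 2) * 3, 1 / 3, 1)  # per-subject agreement
  pa_i <- c(1, 1 / 3, 1 / 3, 1)
  pbar <- mean(pa_i)
  pj <- c(6, 6) / 12
  pe <- sum(pj^2)
  expect_equal(fleiss_kappa(tab)$kappa, (pbar - pe) / (1 - pe))

  set.seed(21)
  rnd <- matrix(sample(c("x", "y"), 500 * 3, replace = TRUE), 500, 3)
  expect_lt(abs(fleiss_kappa(rnd)$kappa), 0.1)
})

test_that("two-proportion z-test matches the pooled-variance formula", {
  eq <- two_prop_ztest(30, 100, 15, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  r <- two_prop_ztest(30, 100, 45, 100)
  pp <- 75 / 200
  se <- sqrt(pp * (1 - pp) * (1 / 100 + 1 / 100))
  z <- (0.30 - 0.45) / se
  expect_equal(r$z, z)
  expect_equal(r$p, 2 * pnorm(-abs(z)))

  # cohort-balance check: similar abnormal-video proportions do not differ
  expect_gt(two_prop_ztest(59, 150, 54, 150)$p, 0.05)

  expect_warning(d <- two_prop_ztest(0, 10, 0, 10), "degenerate")
  expect_equal(d$p, 1)
})

test_that("Fisher r-to-z comparison is antisymmetric and flags real increases", {
  eq <- compare_correlations(0.5, 0.5, 100, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  # correlations corresponding to R^2 0.38 vs 0.89 at n = 144 differ clearly
  r <- compare_correlations(sqrt(0.38), sqrt(0.89), 144, 144)
  expect_lt(r$p, 0.05)
  expect_equal(compare_correlations(0.3, 0.8, 50, 60)$z,
               -compare_correlations(0.8, 0.3, 60, 50)$z)
  expect_error(compare_correlations(1, 0.5, 10, 10), "diverges")
})

test_that("linear fit reports definitional R^2 with a sane confidence band", {
  # collinear points: R^2 = 1, band collapses onto the line
  f <- suppressWarnings(linfit_r2(1:10, 2 * (1:10) + 1))
  expect_equal(f$r_squared, 1)
  expect_lt(max(f$band$hi - f$band$lo), 1e-8)

  set.seed(31)
  x <- runif(100, -1, 1)
  y <- 2 * x + rnorm(100, sd = 0.3)
  f2 <- linfit_r2(x, y)
  se_slope <- 0.3 / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(f2$slope - 2), 3 * se_slope)
  rss <- sum((y - (f2$intercept + f2$slope * x))^2)
  tss <- sum((y - mean(y))^2)
  expect_equal(f2$r_squared, 1 - rss / tss, tolerance = 1e-12)
  # scale invariance of R^2
  f3 <- linfit_r2(10 * x + 3, y)
  expect_equal(f3$r_squared, f2$r_squared, tolerance = 1e-12)
  expect_error(linfit_r2(rep(1, 5), 1:5), "constant")
})
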