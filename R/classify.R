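#' Default AHA 16-segment to long-axis-view mapping
#'
#' Standard assignment of the 16 AHA segments (basal 1-6, mid 7-12, apical
#' 13-16; no apical cap) to the long-axis view in which each wall is seen:
#' anterior and inferior walls in the 2-chamber view, anteroseptal and
#' inferolateral walls in the 3-chamber view, inferoseptal and anterolateral
#' walls in the 4-chamber view; apical segments follow their wall's view.
#' The mapping is a plain data frame and can be edited and passed to
#' [consensus_view_labels()].
#'
#' @return data.frame with columns `segment` (1-16) and `view`.
#' @export
aha_view_mapping <- function() {
  data.frame(
    segment = 1:16,
    view = c("2CH", "3CH", "4CH", "2CH", "3CH", "4CH",   # basal 1-6
             "2CH", "3CH", "4CH", "2CH", "3CH", "4CH",   # mid 7-12
             "2CH", "4CH", "2CH", "4CH"),                # apical 13-16
    stringsAsFactors = FALSE
  )
}

#' Consensus wall-motion truth at segment, view and study level
#'
#' Applies the reader-consensus rules: a segment is abnormal when two or more
#' of the three readers labelled it non-normal (hypokinetic, akinetic and
#' dyskinetic pooled into one abnormal class); a long-axis view is abnormal
#' when at least one of its mapped segments is consensus-abnormal; a study is
#' abnormal when at least one view is abnormal.
#'
#' @param labels data.frame with columns `study`, `reader`, `segment`
#'   (1-16) and `label` (one of `"normal"`, `"hypokinetic"`, `"akinetic"`,
#'   `"dyskinetic"`). Every study must carry a complete 16-segment grid for
#'   each of the 3 readers.
#' @param mapping segment-to-view table, by default [aha_view_mapping()].
#' @param n_readers expected readers per segment.
#' @return list with `views` (data.frame: study, view, abnormal), `studies`
#'   (data.frame: study, abnormal) and `segments` (consensus per segment).
#' @export
consensus_view_labels <- function(labels, mapping = aha_view_mapping(),
                                  n_readers = 3L) {
  req <- c("study", "reader", "segment", "label")
  if (!all(req %in% names(labels))) stop("labels must have columns: ", paste(req, collapse = ", "))
  ok_lab <- c("normal", "hypokinetic", "akinetic", "dyskinetic")
  if (!all(labels$label %in% ok_lab))
    stop("unknown wall-motion labels: ", paste(setdiff(unique(labels$label), ok_lab), collapse = ", "))
  cnt <- stats::aggregate(reader ~ study + segment, labels, function(r) length(unique(r)))
  bad <- cnt[cnt$reader != n_readers, , drop = FALSE]
  segs_per_study <- stats::aggregate(segment ~ study, labels, function(s) length(unique(s)))
  bad2 <- segs_per_study[segs_per_study$segment != 16L, , drop = FALSE]
  if (nrow(bad) > 0L || nrow(bad2) > 0L) {
    gaps <- c(
      if (nrow(bad) > 0L) sprintf("study %s segment %s: %d/%d readers",
                                  bad$study, bad$segment, bad$reader, n_readers),
      if (nrow(bad2) > 0L) sprintf("study %s: %d/16 segments", bad2$study, bad2$segment)
    )
    stop("incomplete expert label grid:\n  ", paste(gaps, collapse = "\n  "))
  }
  labels$abn <- labels$label != "normal"
  seg <- stats::aggregate(abn ~ study + segment, labels, function(a) sum(a) >= 2L)
  names(seg)[names(seg) == "abn"] <- "abnormal"
  seg <- merge(seg, mapping, by = "segment")
  views <- stats::aggregate(abnormal ~ study + view, seg, any)
  studies <- stats::aggregate(abnormal ~ study, views, any)
  list(segments = seg[order(seg$study, seg$segment), c("study", "segment", "view", "abnormal")],
       views = views[order(views$study, views$view), ],
       studies = studies[order(studies$study), ])
}

#' ROC curve and optimal longitudinal-strain cutoff
#'
#' Builds the ROC curve of per-view LS against the binary wall-motion truth.
#' Candidate thresholds are midpoints between consecutive sorted unique
#' scores plus plus/minus infinity; a view is predicted abnormal when its LS
#' exceeds the threshold (less negative than the cutoff). The optimal
#' operating point is the threshold closest (Euclidean distance) to the
#' upper-left ROC corner (0, 1); ties are broken toward higher specificity.
#' AUC is computed by the trapezoidal rule over (1 - specificity,
#' sensitivity).
#'
#' @param scores numeric LS values (signed fractions).
#' @param truth logical (or 0/1) abnormality truth, same length.
#' @return object of class `roc_result` with `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `tau` (optimal cutoff) and `operating_point`.
#' @export
roc_and_optimal_cutoff <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), !anyNA(scores), !anyNA(truth))
  if (all(truth) || !any(truth)) stop("both classes must be present to build a ROC curve")
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2, Inf)
  np <- sum(truth); nn <- sum(!truth)
  sens <- vapply(thr, function(t) sum(scores > t & truth) / np, numeric(1))
  spec <- vapply(thr, function(t) sum(scores <= t & !truth) / nn, numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  d <- sqrt((1 - sens)^2 + (1 - spec)^2)
  cand <- which(d == min(d))
  best <- cand[which.max(spec[cand] + 1e-12 * thr[cand])]  # prefer higher specificity, then larger tau
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, tau = thr[best],
                 operating_point = c(sensitivity = sens[best], specificity = spec[best])),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.3f, optimal tau %.4f (sens %.3f, spec %.3f)\n",
              x$auc, x$tau, x$operating_point["sensitivity"],
              x$operating_point["specificity"]))
  invisible(x)
}

#' Classify a view from its longitudinal strain
#'
#' A view is called abnormal when its LS exceeds the cutoff (equality counts
#' as abnormal, conservatively toward detection). In per-view mode the
#' cutoff for the view's tag is used; in single-threshold mode one cutoff
#' applies to all views.
#'
#' @param ls LS value(s), signed fraction.
#' @param view view tag(s), required in per-view mode.
#' @param thresholds either a single numeric cutoff or a named numeric
#'   vector/list with entries per view tag.
#' @return logical: `TRUE` = abnormal.
#' @export
classify_view <- function(ls, view = NULL, thresholds) {
  if (is.list(thresholds)) thresholds <- unlist(thresholds)
  if (length(thresholds) == 1L && is.null(names(thresholds))) {
    tau <- rep(unname(thresholds), length(ls))
  } else {
    if (is.null(view)) stop("view tags required with per-view thresholds")
    if (!all(view %in% names(thresholds)))
      stop("missing threshold for view(s): ",
           paste(setdiff(unique(view), names(thresholds)), collapse = ", "))
    tau <- unname(thresholds[view])
  }
  ls >= tau
}

#' Classify a patient from its view classifications
#'
#' A study is abnormal when one or more of its views is abnormal.
#'
#' @param view_classes logical vector of per-view abnormality calls.
#' @return logical.
#' @export
classify_patient <- function(view_classes) {
  if (length(view_classes) == 0L) stop("no view classifications supplied")
  any(as.logical(view_classes))
}

#' Confusion counts and classification metrics with Wald intervals
#'
#' Accuracy, sensitivity, specificity and PPV in percent, each with a 95%
#' Wald (normal-approximation) confidence interval `p +/- 1.96 sqrt(p(1-p)/n)`
#' on its own denominator, clipped to \[0, 100\]%. A rate whose denominator
#' is zero is reported absent (`NA`).
#'
#' @param pred,truth logical vectors (`TRUE` = abnormal) of equal length, or
#'   `NULL` when counts are given directly.
#' @param tp,fp,tn,fn confusion counts, alternative to `pred`/`truth`.
#' @return object of class `class_metrics`: counts plus a data.frame
#'   `rates` with columns `metric`, `value`, `lo`, `hi` (percent).
#' @export
confusion_metrics <- function(pred = NULL, truth = NULL,
                              tp = NULL, fp = NULL, tn = NULL, fn = NULL) {
  if (!is.null(pred)) {
    pred <- as.logical(pred); truth <- as.logical(truth)
    stopifnot(length(pred) == length(truth), length(pred) >= 1L)
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  }
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn >= 1)
  rate <- function(num, den) {
    if (den == 0L) return(c(NA_real_, NA_real_, NA_real_))
    p <- num / den
    half <- 1.96 * sqrt(p * (1 - p) / den)
    c(p, max(0, p - half), min(1, p + half)) * 100
  }
  n <- tp + fp + tn + fn
  rates <- rbind(
    accuracy = rate(tp + tn, n),
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    ppv = rate(tp, tp + fp)
  )
  rates <- data.frame(metric = rownames(rates), value = rates[, 1],
                      lo = rates[, 2], hi = rates[, 3], row.names = NULL)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, n = n, rates = rates),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("class_metrics (n = %d): TP %d  FP %d  TN %d  FN %d\n",
              x$n, x$tp, x$fp, x$tn, x$fn))
  for (i in seq_len(nrow(x$rates))) {
    r <- x$rates[i, ]
    if (is.na(r$value)) cat(sprintf("  %-12s --\n", r$metric))
    else cat(sprintf("  %-12s %5.1f%% (%.1f-%.1f)\n", r$metric, r$value, r$lo, r$hi))
  }
  invisible(x)
}
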