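#' Binary-classification metrics from a confusion matrix
#'
#' Specificity `TN/(TN+FP)`, sensitivity `TP/(TP+FN)`, precision
#' `TP/(TP+FP)` and Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. A metric with a
#' zero denominator is reported as `NA` (never silently 0); the MCC is 0
#' when any marginal is 0 (predictions carry no information).
#'
#' @param tp,fp,tn,fn Non-negative integer counts (total > 0).
#' @return List with specificity, sensitivity, precision, mcc.
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop2("confusion-matrix counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop2("empty confusion matrix")
  div <- function(num, den) if (den > 0) num / den else NA_real_
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(marg == 0)) 0 else
    (tp * tn - fp * fn) / sqrt(prod(marg))
  list(
    specificity = div(tn, tn + fp),
    sensitivity = div(tp, tp + fn),
    precision = div(tp, tp + fp),
    mcc = mcc
  )
}

#' Stepwise threshold calibration curve
#'
#' Sweeps every distinct observed score (plus 0 and 1) as a cutoff,
#' predicting positive when `score >= threshold`, and records the
#' classification metrics and positive/negative counts at each step. The
#' MCC-optimal threshold (lowest on ties) is attached.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) true labels, TRUE = positive.
#' @return Data.frame of class `calibration_curve` with columns threshold,
#'   tp, fp, tn, fn, sensitivity, specificity, precision, mcc;
#'   `attr(, "best_threshold_by_mcc")` holds the selected cutoff.
#' @export
threshold_sweep <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || length(scores) == 0L) {
    stop2("'scores' and 'labels' must be equal-length and non-empty")
  }
  if (anyNA(scores) || anyNA(labels)) stop2("missing scores or labels")
  if (all(labels) || !any(labels)) {
    stop2("both classes must be present to calibrate a threshold")
  }
  thresholds <- sort(unique(c(0, 1, scores)))
  rows <- lapply(thresholds, function(th) {
    pred <- scores >= th
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
    mt <- classification_metrics(tp, fp, tn, fn)
    data.frame(threshold = th, tp = tp, fp = fp, tn = tn, fn = fn,
               sensitivity = mt$sensitivity, specificity = mt$specificity,
               precision = mt$precision, mcc = mt$mcc)
  })
  curve <- do.call(rbind, rows)
  best <- curve$threshold[which.max(curve$mcc)]   # first max = lowest threshold
  attr(curve, "best_threshold_by_mcc") <- best
  class(curve) <- c("calibration_curve", "data.frame")
  curve
}

#' @method print calibration_curve
#' @export
print.calibration_curve <- function(x, digits = 3, ...) {
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat("best threshold by MCC:", attr(x, "best_threshold_by_mcc"), "\n")
  invisible(x)
}

#' Rank correlation of threshold versus precision
#'
#' Quantifies whether higher score cutoffs yield higher prediction
#' precision (the property that makes the score a usable risk gauge):
#' Spearman correlation over the thresholds where precision is defined.
#'
#' @param curve A [threshold_sweep()] result.
#' @return Spearman correlation coefficient.
#' @export
precision_trend <- function(curve) {
  ok <- !is.na(curve$precision)
  if (sum(ok) < 3L) stop2("need at least 3 thresholds with defined precision")
  stats::cor(curve$threshold[ok], curve$precision[ok], method = "spearman")
}

#' Two-sided Fisher's exact test on a confusion matrix
#'
#' Exact p-value (probability-mass definition, fixed margins), odds ratio by
#' conditional maximum likelihood under the noncentral hypergeometric model,
#' and the exact 95 percent confidence interval — the conventions of
#' [stats::fisher.test()], which implements them.
#'
#' @param tp,fp,tn,fn Confusion-matrix counts; the 2x2 table is
#'   `rbind(c(tp, fn), c(fp, tn))`.
#' @return List with p_two_sided, odds_ratio_cmle, ci_low, ci_high.
#' @export
fisher_exact <- function(tp, fp, tn, fn) {
  tab <- rbind(c(tp, fn), c(fp, tn))
  if (any(tab < 0)) stop2("counts must be non-negative")
  ft <- stats::fisher.test(tab, conf.level = 0.95)
  ci <- if (!is.null(ft$conf.int)) ft$conf.int else c(NA_real_, NA_real_)
  list(p_two_sided = ft$p.value,
       odds_ratio_cmle = unname(ft$estimate),
       ci_low = ci[1], ci_high = ci[2])
}

#' Score differences for structurally paired compounds
#'
#' For each (less-risk, more-risk) compound pair and each dose at which both
#' members were scored, computes `delta = score_more - score_less`, and runs
#' a two-sided one-sample t-test of the mean delta against zero. With all
#' deltas equal the t-test is degenerate: p = 1 when the common delta is 0,
#' p = 0 (flagged) otherwise.
#'
#' @param scores Data.frame with columns compound, dose_multiple and a score
#'   column (default `normalized`); scores are averaged over replicates/
#'   donors per compound-dose first.
#' @param pairs Data.frame with columns `less` and `more` (compound labels).
#' @param dose Optional dose filter; default uses every shared dose.
#' @param score_col Name of the score column (default "normalized").
#' @return List of class `pair_ranking`: `deltas` (pair, dose, delta),
#'   `t`, `p`, `mean_delta`, `median_pct_increase`, `degenerate` flag.
#' @export
pair_delta <- function(scores, pairs, dose = NULL, score_col = "normalized") {
  need <- c("compound", "dose_multiple", score_col)
  if (!all(need %in% names(scores))) {
    stop2("scores need columns: ", paste(need, collapse = ", "))
  }
  if (!all(c("less", "more") %in% names(pairs))) {
    stop2("pairs need columns 'less' and 'more'")
  }
  agg <- stats::aggregate(scores[[score_col]],
                          by = list(compound = scores$compound,
                                    dose_multiple = scores$dose_multiple),
                          FUN = mean)
  names(agg)[3] <- "score"
  if (!is.null(dose)) agg <- agg[agg$dose_multiple %in% dose, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- agg[agg$compound == pairs$less[i], ]
    b <- agg[agg$compound == pairs$more[i], ]
    shared <- intersect(a$dose_multiple, b$dose_multiple)
    if (length(shared) == 0L) {
      stop2("pair (", pairs$less[i], ", ", pairs$more[i],
            ") has no dose with both members scored")
    }
    for (dm in shared) {
      sl <- a$score[a$dose_multiple == dm]
      sm <- b$score[b$dose_multiple == dm]
      rows[[length(rows) + 1L]] <- data.frame(
        label_less = pairs$less[i], label_more = pairs$more[i],
        dose_multiple = dm, delta = sm - sl,
        pct_increase = if (sl > 0) 100 * (sm - sl) / sl else NA_real_
      )
    }
  }
  deltas <- do.call(rbind, rows)
  dd <- deltas$delta
  tol <- sqrt(.Machine$double.eps) * max(1, abs(mean(dd)))
  degenerate <- length(dd) < 2L || stats::sd(dd) < tol
  if (degenerate) {
    p <- if (abs(mean(dd)) < tol) 1 else 0
    tt <- if (abs(mean(dd)) < tol) NA_real_ else Inf * sign(mean(dd))
  } else {
    ht <- stats::t.test(dd, mu = 0)
    p <- ht$p.value
    tt <- unname(ht$statistic)
  }
  structure(list(deltas = deltas, t = tt, p = p, mean_delta = mean(dd),
                 median_pct_increase = stats::median(deltas$pct_increase,
                                                     na.rm = TRUE),
                 degenerate = degenerate),
            class = "pair_ranking")
}

#' @method print pair_ranking
#' @export
print.pair_ranking <- function(x, ...) {
  cat(sprintf("pair_ranking: %d pair-dose deltas, mean delta %.4f, p = %.4g%s\n",
              nrow(x$deltas), x$mean_delta, x$p,
              if (x$degenerate) " (degenerate: zero-variance deltas)" else ""))
  invisible(x)
}

#' Write a calibration curve as TSV
#' @param curve A [threshold_sweep()] result.
#' @param path Output path.
#' @export
write_calibration <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
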