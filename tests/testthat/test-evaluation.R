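test_that("classification metrics reproduce the hepatocyte worked example", {
  # 12 most-DILI vs 7 less-DILI compounds: tp 9, fn 3, fp 1, tn 6
  mt <- classification_metrics(tp = 9, fp = 1, tn = 6, fn = 3)
  expect_equal(mt$sensitivity, 0.75)
  expect_equal(mt$specificity, 6 / 7)
  expect_equal(mt$precision, 0.9)
  expect_equal(mt$mcc, 51 / sqrt(10 * 12 * 7 * 9))
  expect_equal(round(mt$mcc, 2), 0.59)
})

test_that("edge confusion matrices: perfect, degenerate, undefined", {
  perfect <- classification_metrics(5, 0, 7, 0)
  expect_equal(unlist(perfect), c(specificity = 1, sensitivity = 1,
                                  precision = 1, mcc = 1))
  allpos <- classification_metrics(tp = 5, fp = 7, tn = 0, fn = 0)
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$precision, 5 / 12)     # prevalence
  expect_equal(allpos$mcc, 0)                # a zero marginal
  nopos <- classification_metrics(tp = 0, fp = 0, tn = 7, fn = 5)
  expect_true(is.na(nopos$precision))        # undefined, not silently 0
  expect_error(classification_metrics(-1, 0, 0, 1), "non-negative")
})

test_that("threshold sweep finds the separating cutoff and matches an oracle", {
  curve <- threshold_sweep(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  at08 <- curve[curve$threshold == 0.8, ]
  expect_equal(at08$mcc, 1)
  expect_equal(attr(curve, "best_threshold_by_mcc"), 0.8)

  # oracle: independent enumeration of all cutoffs
  set.seed(50)
  scores <- round(stats::runif(200), 3)
  labels <- stats::runif(200) < stats::plogis(6 * (scores - 0.5))
  if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
  curve <- threshold_sweep(scores, labels)
  for (i in seq_len(nrow(curve))) {
    th <- curve$threshold[i]
    pred <- scores >= th
    expect_equal(curve$tp[i], sum(pred & labels))
    expect_equal(curve$fp[i], sum(pred & !labels))
    expect_equal(curve$tn[i], sum(!pred & !labels))
    expect_equal(curve$fn[i], sum(!pred & labels))
    prec <- if (sum(pred) > 0) sum(pred & labels) / sum(pred) else NA_real_
    expect_equal(curve$precision[i], prec)
  }
  # structural invariants of the sweep
  expect_true(all(diff(curve$threshold) > 0))
  expect_true(all(diff(curve$tp + curve$fp) <= 0))   # predicted positives
  expect_true(all(diff(curve$sensitivity) <= 0))
  expect_true(all(diff(curve$specificity) >= 0))
})

test_that("shuffled labels give chance-level best MCC", {
  set.seed(51)
  scores <- stats::runif(60)
  mccs <- vapply(1:300, function(i) {
    labels <- sample(rep(c(TRUE, FALSE), each = 30))
    max(threshold_sweep(scores, labels)$mcc, na.rm = TRUE)
  }, 1)
  # best-of-sweep is biased upward; it must still be far from separation
  expect_lt(stats::median(mccs), 0.35)
  expect_gt(stats::median(mccs), 0)
  expect_error(threshold_sweep(scores, rep(TRUE, 60)), "both classes")
})

test_that("precision trend is signed as the separation direction", {
  sep <- threshold_sweep(c(0.9, 0.85, 0.8, 0.2, 0.15, 0.1),
                         c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  # perfectly separable: precision non-decreasing in threshold; the rank
  # correlation is < 1 only through ties at precision 1
  ok <- !is.na(sep$precision)
  expect_true(all(diff(sep$precision[ok]) >= 0))
  expect_gt(precision_trend(sep), 0.9)
  anti <- threshold_sweep(c(0.9, 0.85, 0.8, 0.2, 0.15, 0.1),
                          c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_lt(precision_trend(anti), 0)
  expect_error(precision_trend(data.frame(threshold = 1, precision = 1)),
               "at least 3")
})

test_that("calibrated generators yield positive precision trends", {
  set.seed(52)
  pos_trend <- vapply(1:100, function(i) {
    scores <- stats::runif(80)
    labels <- stats::runif(80) < scores          # higher score => more positive
    if (all(labels) || !any(labels)) return(NA_real_)
    precision_trend(threshold_sweep(scores, labels))
  }, 1)
  expect_gte(mean(pos_trend > 0, na.rm = TRUE), 0.95)
})

test_that("Fisher's exact test reproduces the printed panel statistics", {
  fe <- fisher_exact(tp = 9, fp = 1, tn = 6, fn = 3)
  expect_equal(round(fe$p_two_sided, 2), 0.02)
  expect_equal(round(fe$odds_ratio_cmle, 1), 14.9)
  expect_equal(round(fe$ci_low, 2), 1.15)
  expect_equal(round(fe$ci_high, 1), 910.1)
  expect_true(fe$ci_low <= fe$odds_ratio_cmle &&
                fe$odds_ratio_cmle <= fe$ci_high)
})

test_that("Fisher p equals exhaustive enumeration on small tables", {
  set.seed(53)
  enum_p <- function(a, b, c_, d) {
    m1 <- a + b; m2 <- c_ + d; k <- a + c_
    lo <- max(0, k - m2); hi <- min(k, m1)
    probs <- stats::dhyper(lo:hi, m1, m2, k)
    obs <- stats::dhyper(a, m1, m2, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  for (rep in 1:25) {
    tab <- as.vector(stats::rmultinom(1, sample(8:20, 1), rep(0.25, 4)))
    fe <- fisher_exact(tab[1], tab[2], tab[3], tab[4])
    expect_equal(fe$p_two_sided, enum_p(tab[1], tab[4], tab[2], tab[3]),
                 tolerance = 1e-10)
  }
})

test_that("Fisher p is invariant to transposition and label swaps", {
  fe <- fisher_exact(9, 1, 6, 3)
  fe_t <- fisher_exact(9, 3, 6, 1)           # transpose
  fe_swap <- fisher_exact(6, 3, 9, 1)        # swap both row and column labels
  expect_equal(fe$p_two_sided, fe_t$p_two_sided, tolerance = 1e-12)
  expect_equal(fe$p_two_sided, fe_swap$p_two_sided, tolerance = 1e-12)
  same_rows <- fisher_exact(tp = 4, fp = 4, tn = 6, fn = 6)
  expect_equal(same_rows$p_two_sided, 1)
  expect_equal(same_rows$odds_ratio_cmle, 1, tolerance = 1e-6)
})

test_that("pair ranking handles degenerate and ordinary deltas", {
  scores <- data.frame(
    compound = rep(c("a_less", "a_more", "b_less", "b_more"), each = 1),
    dose_multiple = 10,
    normalized = c(0.2, 0.2, 0.4, 0.4)
  )
  pairs <- data.frame(less = c("a_less", "b_less"), more = c("a_more", "b_more"))
  pr <- pair_delta(scores, pairs)
  expect_true(pr$degenerate)
  expect_equal(pr$p, 1)                      # all deltas zero

  scores$normalized <- c(0.2, 0.5, 0.4, 0.7) # constant positive delta
  pr2 <- pair_delta(scores, pairs)
  expect_true(pr2$degenerate)
  expect_equal(pr2$p, 0)

  set.seed(54)
  n <- 9
  sc <- data.frame(
    compound = c(paste0("L", 1:n), paste0("M", 1:n)),
    dose_multiple = 10,
    normalized = c(stats::runif(n, 0.1, 0.3),
                   stats::runif(n, 0.1, 0.3) + stats::rnorm(n, 0.3, 0.2))
  )
  prs <- pair_delta(sc, data.frame(less = paste0("L", 1:n),
                                   more = paste0("M", 1:n)))
  ht <- stats::t.test(prs$deltas$delta)
  expect_equal(prs$p, ht$p.value)
  expect_error(pair_delta(sc, data.frame(less = "L1", more = "missing")),
               "no dose")
})

test_that("paired t-test power matches the closed-form noncentral-t rate", {
  set.seed(55)
  n <- 9; mu <- 0.3; sdd <- 0.2; nrep <- 600
  rej <- vapply(seq_len(nrep), function(i) {
    d <- stats::rnorm(n, mu, sdd)
    sc <- data.frame(compound = c(paste0("L", 1:n), paste0("M", 1:n)),
                     dose_multiple = 10,
                     normalized = c(rep(0.2, n), 0.2 + d))
    pair_delta(sc, data.frame(less = paste0("L", 1:n),
                              more = paste0("M", 1:n)))$p < 0.05
  }, NA)
  ncp <- mu / (sdd / sqrt(n))
  tc <- stats::qt(0.975, n - 1)
  power <- 1 - stats::pt(tc, n - 1, ncp) + stats::pt(-tc, n - 1, ncp)
  se <- sqrt(power * (1 - power) / nrep)
  expect_lt(abs(mean(rej) - power), 3.3 * se)
})
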