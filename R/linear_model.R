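#' Per-gene linear model of a treatment-vs-control contrast
#'
#' Fits, for every gene, ordinary least squares on a design with an
#' intercept, optional donor/batch fixed effects, and the treatment
#' indicator as the last coefficient. The data are orthogonally transformed
#' (QR) so that the treatment contrast occupies a single coordinate and the
#' residual space the remaining `d = n - p` coordinates; those coordinates
#' are retained because the rotation test resamples within them.
#'
#' @param m Log-scale [expression_matrix()].
#' @param design Sample sheet (see [read_sample_sheet()]) covering exactly
#'   the samples of this contrast; must contain both groups.
#' @param donor_covariate Include donor as additive fixed effect when more
#'   than one donor is present (default TRUE).
#' @return An object of class `contrast_fit` with per-gene `effect` (log2
#'   units), `s2` (residual variance), shared `df_resid` and
#'   `effect_se_unscaled`, `amean`, and the transformed coordinates
#'   `effect_coord` / `resid_coords`.
#' @export
fit_contrast <- function(m, design, donor_covariate = TRUE) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "log") stop2("fit_contrast expects a log-scale matrix")
  design <- read_sample_sheet(design, m)
  y <- m$values[, design$sample_id, drop = FALSE]
  n <- ncol(y)
  if (!all(c("treatment", "control") %in% design$group)) {
    stop2("design must contain both treatment and control samples")
  }
  grp <- as.numeric(design$group == "treatment")
  donors <- as.character(design$donor)
  if (donor_covariate && length(unique(donors)) > 1L) {
    X <- stats::model.matrix(~ factor(donors) + grp)
  } else {
    X <- stats::model.matrix(~ grp)
  }
  p <- ncol(X)
  d <- n - p
  if (d < 1L) stop2("fewer than 1 residual degree of freedom (n = ", n,
                    ", design rank ", p, ")")
  QR <- qr(X)
  if (QR$rank < p) stop2("rank-deficient design (donor confounded with group?)")
  R <- qr.R(QR)
  if (any(QR$pivot != seq_len(p))) stop2("unexpected pivoting in design QR")
  # full orthonormal basis: columns 1..p span the design, p+1..n the residuals
  Q <- qr.Q(QR, complete = TRUE)
  E <- y %*% Q                                  # genes x n effect coordinates
  r_pp <- R[p, p]
  effect_coord <- E[, p] * sign(r_pp)           # signed so +ve = up in treatment
  u <- 1 / abs(r_pp)                            # unscaled SE of the contrast
  resid_coords <- E[, (p + 1):n, drop = FALSE]
  s2 <- rowSums(resid_coords^2) / d
  structure(list(
    genes = rownames(y),
    effect = effect_coord * u,
    effect_se_unscaled = u,
    s2 = s2,
    df_resid = d,
    amean = rowMeans(y),
    effect_coord = effect_coord,
    resid_coords = resid_coords
  ), class = "contrast_fit")
}

#' @method print contrast_fit
#' @export
print.contrast_fit <- function(x, ...) {
  cat("contrast_fit: ", length(x$genes), " genes, ", x$df_resid,
      " residual df\n", sep = "")
  invisible(x)
}

# Newton inversion of the trigamma function (solve trigamma(x) = y).
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2)
      x <- x + dif
      if (-dif / x < 1e-10) break
    }
    x
  }, numeric(1))
}

# Method-of-moments fit of a scaled F-distribution to residual variances:
# log s2 has mean log(s0^2) + digamma(d/2) - log(d/2) and excess variance
# trigamma(d0/2) beyond trigamma(d/2) under s2 ~ s0^2 F(d, d0).
fit_fdist <- function(s2, df) {
  s2 <- s2[s2 > 0 & is.finite(s2)]
  if (length(s2) < 2L) stop2("need at least 2 genes with positive residual variance")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion beyond chi-square sampling: infinite prior df
    d0 <- Inf
    s02 <- mean(s2)
  }
  list(d0 = d0, s02 = s02)
}

# Normal-equivalent score of a t statistic: z = qnorm(pt(t, df)), computed in
# log-space tails so |t| > 37 does not saturate. df = Inf returns t.
zscore_t <- function(t, df) {
  if (!is.finite(df)) return(t)
  lp <- stats::pt(abs(t), df = df, lower.tail = FALSE, log.p = TRUE)
  z <- stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  z * sign(t)
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Estimates a prior `(d0, s0^2)` by fitting a scaled F-distribution to the
#' residual variances (method of moments on `log s^2`, digamma/trigamma
#' inversion), optionally letting `s0^2` follow a smooth mean-variance trend
#' in average log-expression, and shrinks each gene's variance to the
#' posterior `(d0 s0^2 + d s^2) / (d0 + d)`. Moderated t statistics use the
#' posterior variance with `d0 + d` degrees of freedom; z is the standard
#' normal equivalent of t.
#'
#' @param fit A [fit_contrast()] result.
#' @param trend Model `s0^2` as a locally weighted (lowess, span 0.5, one
#'   robustifying iteration) function of average log-expression.
#' @param d0_override Force the prior degrees of freedom (0 gives ordinary
#'   t statistics; Inf gives full shrinkage to the prior).
#' @param d0_cap Estimates above this cap are reported as Inf (default 1e6).
#' @return An object of class `moderation` with `d0`, `s02` (scalar, or
#'   per-gene when `trend`), `s2_post`, `t`, `z`, `df_total`.
#' @export
moderate <- function(fit, trend = FALSE, d0_override = NULL, d0_cap = 1e6) {
  stopifnot(inherits(fit, "contrast_fit"))
  s2 <- fit$s2
  d <- fit$df_resid
  # relative zero guard: exact within-group replicates leave s2 at rounding
  # error of the transform, not exactly 0
  pos <- s2 > 1e-24 * (1 + fit$amean^2)
  if (!any(pos)) {
    stop2("all residual variances are zero: the data are exact replicates; ",
          "moderation (and any variance-based test) is degenerate")
  }
  if (sum(pos) < 2L) stop2("need at least 2 genes with positive residual variance")

  if (trend) {
    A <- fit$amean
    lo <- stats::lowess(A[pos], log(s2[pos]), f = 0.5, iter = 1)
    ltrend <- stats::approx(lo$x, lo$y, xout = A, rule = 2, ties = mean)$y
    prior <- fit_fdist(s2 / exp(ltrend), d)
    s02 <- prior$s02 * exp(ltrend)          # per-gene prior variance
  } else {
    prior <- fit_fdist(s2, d)
    s02 <- prior$s02
  }
  d0 <- prior$d0
  if (!is.null(d0_override)) d0 <- d0_override
  if (is.finite(d0) && d0 > d0_cap) d0 <- Inf

  if (!is.finite(d0)) {
    s2_post <- if (length(s02) > 1L) s02 else rep(s02, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- d
  } else {
    s2_post <- (d0 * s02 + d * s2) / (d0 + d)
    df_total <- d0 + d
  }
  tt <- ifelse(s2_post > 0,
               fit$effect / (fit$effect_se_unscaled * sqrt(s2_post)),
               sign(fit$effect) * Inf)
  names(tt) <- fit$genes
  z <- zscore_t(tt, df_total)
  structure(list(
    genes = fit$genes, d0 = d0, s02 = s02, s2_post = s2_post,
    t = tt, z = z, df_total = df_total, df_resid = d
  ), class = "moderation")
}

#' @method print moderation
#' @export
print.moderation <- function(x, ...) {
  s0 <- if (length(x$s02) > 1L) sprintf("trend (median %.3g)", stats::median(x$s02))
        else sprintf("%.4g", x$s02)
  cat("moderation: d0 = ", format(x$d0), ", s0^2 = ", s0,
      ", df_total = ", format(x$df_total), "\n", sep = "")
  invisible(x)
}

#' Dump per-gene fit diagnostics as TSV
#'
#' @param fit A [fit_contrast()] result.
#' @param mod The matching [moderate()] result.
#' @param path Output path.
#' @export
write_fit_diagnostics <- function(fit, mod, path) {
  df <- data.frame(gene = fit$genes, effect = fit$effect, s2 = fit$s2,
                   amean = fit$amean, t = mod$t, z = mod$z)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
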