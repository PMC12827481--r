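#' Scoring configuration
#'
#' @param norm_min,norm_max Min-max normalisation constants for the raw
#'   score (defaults 0 and 4: with 9999 rotations the p-value floor 1e-4
#'   makes 4 the largest attainable raw score).
#' @param n_noise_iter Noise-injection iterations (default 50).
#' @param ridge_points Size of the normal sample drawn for ridge-plot
#'   visualisation (default 10000).
#' @param seed Master seed for noise and ridge draws.
#' @param clip Clip the normalised score to [0, 1] (default TRUE).
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(norm_min = 0, norm_max = 4, n_noise_iter = 50,
                           ridge_points = 10000, seed = NULL, clip = TRUE) {
  if (norm_max <= norm_min) stop2("'norm_max' must exceed 'norm_min'")
  if (n_noise_iter < 1) stop2("'n_noise_iter' must be >= 1")
  structure(list(norm_min = norm_min, norm_max = norm_max,
                 n_noise_iter = as.integer(n_noise_iter),
                 ridge_points = as.integer(ridge_points),
                 seed = seed, clip = isTRUE(clip)),
            class = "scoring_config")
}

#' DILI score from a rotation-test row
#'
#' `raw = (prop_up + prop_down) * -log10(fdr_mixed)`, then min-max
#' normalised to `[0, 1]` with the configured constants (default min 0,
#' max 4) and clipped.
#'
#' @param r One row of a [rotation_test()] result (or any list providing
#'   `prop_up`, `prop_down`, `fdr_mixed`).
#' @param cfg A [scoring_config()].
#' @return List with `raw` and `normalized`.
#' @export
dili_score <- function(r, cfg = scoring_config()) {
  fdr <- r$fdr_mixed
  if (is.null(fdr) || !is.finite(fdr) || fdr <= 0 || fdr > 1) {
    stop2("fdr_mixed must be in (0, 1]")
  }
  raw <- (r$prop_up + r$prop_down) * -log10(fdr)
  normalized <- (raw - cfg$norm_min) / (cfg$norm_max - cfg$norm_min)
  if (cfg$clip) normalized <- min(1, max(0, normalized))
  list(raw = raw, normalized = normalized)
}

#' Score a single contrast without noise injection
#'
#' One pipeline pass: linear fit, moderation, rotation test, combined-set
#' score. The combined set (`"AEGIS_combined"`) is scored when present,
#' otherwise the first (or named) set.
#'
#' @param m Log-scale [expression_matrix()] for one contrast.
#' @param design Matching sample sheet.
#' @param sig A [gene_signature()].
#' @param rot_cfg A [rotation_config()].
#' @param score_cfg A [scoring_config()].
#' @param set_name Which set to score (default: the combined set).
#' @param rot_seed Override for the rotation seed.
#' @return List with the full rotation `result`, the scored `row`, `raw`
#'   and `normalized`.
#' @export
score_once <- function(m, design, sig, rot_cfg = rotation_config(),
                       score_cfg = scoring_config(),
                       set_name = NULL, rot_seed = NULL) {
  fit <- fit_contrast(m, design)
  mod <- moderate(fit, trend = rot_cfg$trend)
  cfg <- rot_cfg
  cfg$seed <- rot_seed %||% rot_cfg$seed
  res <- rotation_test(fit, mod, sig, cfg)
  nm <- set_name %||% if (AEGIS_COMBINED %in% res$set) AEGIS_COMBINED else res$set[1]
  row <- res[res$set == nm, , drop = FALSE]
  sc <- dili_score(row, score_cfg)
  list(result = res, row = row, raw = sc$raw, normalized = sc$normalized)
}

#' DILI score with noise-injection confidence
#'
#' Re-scores a treatment `n_noise_iter` times after adding Gaussian noise to
#' the (log-scale) expression values, with per-gene SD equal to the sample
#' standard deviation of that gene across all samples of the experiment.
#' The mean and SD of the iterated scores summarise confidence; a normal
#' sample of `ridge_points` values is drawn from them for ridge-plot
#' visualisation (the ridge sample is not clipped).
#'
#' @param m Log-scale [expression_matrix()] for one contrast
#'   (treatment + control samples).
#' @param design Matching sample sheet.
#' @param sig A [gene_signature()].
#' @param rot_cfg A [rotation_config()].
#' @param score_cfg A [scoring_config()]; its `seed` governs noise, the
#'   rotation streams of the iterations and the ridge draw.
#' @param sigma Optional per-gene noise SDs (named or matrix-ordered);
#'   default computed from `m` itself.
#' @return Object of class `score_distribution`: `mean`, `sd`, per-iteration
#'   `scores`, `ridge`, and the no-noise `base` score with its rotation row.
#' @export
score_with_confidence <- function(m, design, sig,
                                  rot_cfg = rotation_config(),
                                  score_cfg = scoring_config(),
                                  sigma = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "log") stop2("score_with_confidence expects a log-scale matrix")
  if (is.null(sigma)) {
    sigma <- apply(m$values, 1, stats::sd)
  } else if (!is.null(names(sigma))) {
    sigma <- sigma[rownames(m$values)]
  }
  if (length(sigma) != nrow(m$values) || anyNA(sigma)) {
    stop2("'sigma' must provide one SD per gene of the matrix")
  }
  base <- score_once(m, design, sig, rot_cfg, score_cfg,
                     rot_seed = derive_seed(score_cfg$seed, 0))
  G <- nrow(m$values); S <- ncol(m$values)
  scores <- numeric(score_cfg$n_noise_iter)
  for (i in seq_len(score_cfg$n_noise_iter)) {
    eps <- with_seed(derive_seed(score_cfg$seed, i),
                     matrix(stats::rnorm(G * S, sd = sigma), G, S))
    mi <- m
    mi$values <- m$values + eps
    # one rotation stream shared with the base run: only the noise varies
    # between iterations, so zero noise reproduces the base score exactly
    scores[i] <- score_once(mi, design, sig, rot_cfg, score_cfg,
                            rot_seed = derive_seed(score_cfg$seed, 0))$normalized
  }
  mu <- mean(scores)
  sdv <- stats::sd(scores)
  if (length(scores) == 1L || !is.finite(sdv)) sdv <- 0
  ridge <- if (sdv == 0) rep(mu, score_cfg$ridge_points) else
    with_seed(derive_seed(score_cfg$seed, 999983),
              stats::rnorm(score_cfg$ridge_points, mu, sdv))
  structure(list(mean = mu, sd = sdv, scores = scores, ridge = ridge,
                 base = base$normalized, base_raw = base$raw,
                 row = base$row),
            class = "score_distribution")
}

#' @method print score_distribution
#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf("score_distribution: mean %.4f, sd %.4f (%d iterations; no-noise score %.4f)\n",
              x$mean, x$sd, length(x$scores), x$base))
  invisible(x)
}

#' Per-transcription-factor score breakdown
#'
#' Runs the rotation test jointly on all per-TF regulon sets of the
#' signature (shared rotations, BH across sets) and scores each regulon.
#'
#' @param fit A [fit_contrast()] result.
#' @param mod The matching [moderate()] result.
#' @param sig A [gene_signature()] with per-TF sets (a combined set, if
#'   present, is excluded from the breakdown).
#' @param rot_cfg A [rotation_config()].
#' @param score_cfg A [scoring_config()].
#' @return Data.frame with one row per TF: set, n_genes, prop_up, prop_down,
#'   fdr_mixed, raw, normalized.
#' @export
regulon_breakdown <- function(fit, mod, sig, rot_cfg = rotation_config(),
                              score_cfg = scoring_config()) {
  sets <- tf_sets(sig)
  if (length(sets) == 0L) stop2("signature has no per-TF sets")
  res <- rotation_test(fit, mod, gene_signature(sets, sig$provenance), rot_cfg)
  sc <- lapply(seq_len(nrow(res)), function(i) dili_score(res[i, ], score_cfg))
  out <- data.frame(
    set = res$set, n_genes = res$n_genes,
    prop_up = res$prop_up, prop_down = res$prop_down,
    fdr_mixed = res$fdr_mixed,
    raw = vapply(sc, `[[`, numeric(1), "raw"),
    normalized = vapply(sc, `[[`, numeric(1), "normalized"),
    stringsAsFactors = FALSE
  )
  out
}
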