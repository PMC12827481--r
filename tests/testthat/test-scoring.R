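test_that("the score formula and normalisation follow their definition", {
  cfg <- scoring_config()
  sc <- dili_score(list(prop_up = 0.5, prop_down = 0.25, fdr_mixed = 1e-4), cfg)
  expect_equal(sc$raw, 3.0)
  expect_equal(sc$normalized, 0.75)

  expect_equal(dili_score(list(prop_up = 0.4, prop_down = 0.2, fdr_mixed = 1),
                          cfg)$raw, 0)
  # maximal case: saturated proportions at the 9999-rotation floor
  top <- dili_score(list(prop_up = 0.6, prop_down = 0.4, fdr_mixed = 1e-4), cfg)
  expect_equal(top$raw, 4)
  expect_equal(top$normalized, 1)
  # clipping guards raw scores beyond the normalisation max
  over <- dili_score(list(prop_up = 1, prop_down = 0, fdr_mixed = 1e-5), cfg)
  expect_equal(over$normalized, 1)
  expect_error(dili_score(list(prop_up = 1, prop_down = 0, fdr_mixed = 0)),
               "fdr_mixed")
})

test_that("score is invariant to gene order and sample order within groups", {
  set.seed(40)
  ex <- shifted_experiment(120, 3, n_shift = 12, delta = 1.5)
  fit <- fit_contrast(ex$m, ex$design)
  sig <- first_genes_signature(12)
  rc <- rotation_config(nrot = 499, seed = 6)
  base <- score_once(ex$m, ex$design, sig, rc, scoring_config())

  perm_g <- sample(nrow(ex$m$values))
  m2 <- expression_matrix(ex$m$values[perm_g, ], "log")
  s2 <- score_once(m2, ex$design, sig, rc, scoring_config())
  expect_equal(s2$normalized, base$normalized)

  # permute samples within each group (design rows follow)
  idx <- c(sample(1:3), sample(4:6))
  m3 <- expression_matrix(ex$m$values[, idx], "log")
  d3 <- ex$design[idx, ]
  s3 <- score_once(m3, d3, sig, rc, scoring_config())
  expect_equal(s3$normalized, base$normalized)
})

test_that("noise injection is deterministic and honest about zero noise", {
  set.seed(41)
  ex <- shifted_experiment(80, 3, n_shift = 8, delta = 2)
  sig <- first_genes_signature(8)
  rc <- rotation_config(nrot = 199)
  sc <- scoring_config(n_noise_iter = 4, ridge_points = 50, seed = 13)
  a <- score_with_confidence(ex$m, ex$design, sig, rc, sc)
  b <- score_with_confidence(ex$m, ex$design, sig, rc, sc)
  expect_identical(a$scores, b$scores)
  expect_identical(a$ridge, b$ridge)
  expect_length(a$ridge, 50)

  # zero gene-level SD: all iterations identical, sd 0, flat ridge
  z <- score_with_confidence(ex$m, ex$design, sig, rc, sc,
                             sigma = rep(0, nrow(ex$m$values)))
  expect_equal(z$sd, 0)
  expect_true(all(z$scores == z$scores[1]))
  expect_true(all(z$ridge == z$mean))
})

test_that("noise-injected means are reproducible within their own sampling error", {
  # the injected noise inflates per-gene variance, so the iterated score is
  # biased at or below the no-noise score by construction; what must hold
  # is that two independent noise streams agree within Monte-Carlo error
  # and that the bias is one-sided
  set.seed(42)
  hits_mc <- 0; hits_bias <- 0
  n_it <- 15
  for (s in 1:10) {
    set.seed(500 + s)
    ex <- shifted_experiment(100, 3, n_shift = 20, delta = 2, sd = 0.6)
    sig <- first_genes_signature(20)
    rc <- rotation_config(nrot = 199)
    d1 <- score_with_confidence(ex$m, ex$design, sig, rc,
                                scoring_config(n_noise_iter = n_it,
                                               ridge_points = 10, seed = s))
    d2 <- score_with_confidence(ex$m, ex$design, sig, rc,
                                scoring_config(n_noise_iter = n_it,
                                               ridge_points = 10,
                                               seed = s + 5000))
    mc_se <- sqrt(d1$sd^2 + d2$sd^2) / sqrt(n_it)
    if (abs(d1$mean - d2$mean) <= 3 * mc_se + 1e-12) hits_mc <- hits_mc + 1
    if (d1$mean <= d1$base + 2 * d1$sd / sqrt(n_it) + 1e-12) {
      hits_bias <- hits_bias + 1
    }
  }
  expect_gte(hits_mc, 8)
  expect_gte(hits_bias, 9)
})

test_that("per-regulon breakdown localises a single perturbed regulon", {
  set.seed(43)
  cfg <- simulation_config(n_genes = 400, n_signature = 80, n_tf_sets = 4,
                           effect_size = 0, dose_levels = 1, seed = 77)
  ex <- simulate_experiment(cfg)
  sets <- ex$signature$sets
  target_set <- setdiff(names(sets), AEGIS_COMBINED)[1]
  jun <- sets[[target_set]]
  Y <- ex$matrix$values
  Y[jun, ex$design$group == "treatment"] <-
    Y[jun, ex$design$group == "treatment"] + 3
  m <- expression_matrix(Y, "log")
  fit <- fit_contrast(m, ex$design)
  mod <- moderate(fit)
  bd <- regulon_breakdown(fit, mod, ex$signature,
                          rotation_config(nrot = 499, seed = 3))
  expect_equal(bd$set[which.max(bd$normalized)], target_set)
  expect_true(all(bd$normalized[bd$set != target_set] <
                    bd$normalized[bd$set == target_set]))

  # single-TF signature: breakdown equals the combined-set score
  sig1 <- gene_signature(list(ONE = jun, AEGIS_combined = jun))
  res_c <- score_once(m, ex$design, sig1, rotation_config(nrot = 499, seed = 5),
                      scoring_config())
  bd1 <- regulon_breakdown(fit, mod, sig1,
                           rotation_config(nrot = 499, seed = 5))
  expect_equal(bd1$normalized, res_c$normalized)
})

test_that("all-null data give uniformly low per-TF scores", {
  set.seed(44)
  lows <- vapply(1:8, function(s) {
    cfg <- simulation_config(n_genes = 300, n_signature = 60, n_tf_sets = 4,
                             effect_size = 0, dose_levels = 1, seed = 900 + s)
    ex <- simulate_experiment(cfg)
    fit <- fit_contrast(ex$matrix, ex$design)
    mod <- moderate(fit)
    bd <- regulon_breakdown(fit, mod, ex$signature,
                            rotation_config(nrot = 199, seed = s))
    max(bd$normalized)
  }, 1)
  expect_gte(mean(lows < 0.25), 0.75)
})

test_that("median score is non-decreasing in dose on Hill-perturbed data", {
  set.seed(45)
  meds <- matrix(NA_real_, 8, 3)
  for (s in 1:8) {
    cfg <- simulation_config(n_genes = 300, n_signature = 50, n_tf_sets = 2,
                             effect_size = 2, frac_perturbed = 0.6,
                             dose_levels = c(0.1, 1, 10), seed = 200 + s)
    ex <- simulate_experiment(cfg)
    sc <- aegis_score(ex$matrix, ex$design, ex$signature,
                      rotation_config(nrot = 199, seed = s),
                      scoring_config(seed = s), noise = FALSE)
    meds[s, ] <- sc$normalized[order(sc$dose_multiple)]
  }
  m <- apply(meds, 2, stats::median)
  expect_true(all(diff(m) >= 0))
})
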