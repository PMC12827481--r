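#' Log-logistic (Hill) dose-response fit
#'
#' Least-squares fit of `f(x) = c + (d - c) / (1 + exp(b * (ln x - ln e)))`
#' to scores versus dose multiples. `b` is the Hill slope (negative when the
#' response rises with dose), `e` the EC50 in dose-multiple units, `c`/`d`
#' the lower/upper asymptotes. The default 4-parameter fit bounds both
#' asymptotes in [0, 1] (the scale of normalised scores); `n_params = 3`
#' fixes `c = 0`, `n_params = 2` fixes `c = 0, d = 1`. Optimisation is
#' Levenberg-Marquardt (via minpack.lm) in `(b, ln e, c, d)` from a
#' data-driven start (asymptotes from the response range, EC50 from the
#' half-range crossing, slope from a logit-linear regression) plus 5
#' jittered restarts; the lowest-SSE converged fit wins. Standard errors
#' come from the asymptotic covariance of the nonlinear LS estimate and the
#' per-parameter p-values from two-sided t-tests; `se(e)` uses the delta
#' method on `ln e`.
#'
#' @param doses Dose multiples, all > 0.
#' @param responses Scores, same length.
#' @param n_params 4 (default), 3 or 2.
#' @param asymptote_bounds Length-2 bounds applied to `c` and `d`
#'   (default `c(0, 1)`; use `c(-Inf, Inf)` for unbounded).
#' @return List of class `dose_response_fit`: `b`, `e`, `c`, `d`, `se`
#'   (named), `p` (named), `sse`, `df`, `converged`, `identifiable`.
#' @export
fit_loglogistic <- function(doses, responses, n_params = 4,
                            asymptote_bounds = c(0, 1)) {
  if (length(doses) != length(responses)) stop2("doses/responses length mismatch")
  if (any(doses <= 0)) stop2("doses must be > 0")
  if (!n_params %in% c(2, 3, 4)) stop2("'n_params' must be 2, 3 or 4")
  n_distinct <- length(unique(doses))
  if (n_distinct < n_params + 1) {
    stop2("need at least n_params + 1 = ", n_params + 1, " distinct doses, got ",
          n_distinct)
  }
  lx <- log(doses)
  y <- responses

  if (stats::sd(y) == 0) {
    # flat response: slope carries no information
    return(structure(list(
      b = 0, e = exp(mean(lx)), c = y[1], d = y[1],
      se = c(b = NA_real_, e = NA_real_, c = NA_real_, d = NA_real_),
      p = c(b = 1, e = NA_real_, c = NA_real_, d = NA_real_),
      sse = 0, df = length(y) - n_params,
      converged = FALSE, identifiable = FALSE, n_params = n_params
    ), class = "dose_response_fit"))
  }

  # data-driven initial values
  mu <- tapply(y, lx, mean)
  mlx <- as.numeric(names(mu))
  o <- order(mlx); mlx <- mlx[o]; mu <- as.numeric(mu)[o]
  d0 <- max(y); c0 <- min(y)
  half <- (c0 + d0) / 2
  cross <- which(diff(sign(mu - half)) != 0)
  le0 <- if (length(cross)) {
    i <- cross[1]
    mlx[i] + (half - mu[i]) * (mlx[i + 1] - mlx[i]) / (mu[i + 1] - mu[i])
  } else mean(mlx)
  fr <- pmin(pmax((y - c0) / (d0 - c0), 1e-3), 1 - 1e-3)
  b0 <- tryCatch(-unname(stats::coef(stats::lm(stats::qlogis(fr) ~ lx))[2]),
                 error = function(e) -1)
  if (!is.finite(b0) || b0 == 0) b0 <- -1

  lower <- c(b = -Inf, le = -Inf, c = asymptote_bounds[1], d = asymptote_bounds[1])
  upper <- c(b = Inf, le = Inf, c = asymptote_bounds[2], d = asymptote_bounds[2])
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  start0 <- c(b = b0, le = le0,
              c = clamp(c0, lower["c"], upper["c"]),
              d = clamp(d0, lower["d"], upper["d"]))

  form <- switch(as.character(n_params),
    "4" = y ~ c + (d - c) / (1 + exp(b * (lx - le))),
    "3" = y ~ 0 + d / (1 + exp(b * (lx - le))),
    "2" = y ~ 1 / (1 + exp(b * (lx - le)))
  )
  keep <- switch(as.character(n_params), "4" = c("b", "le", "c", "d"),
                 "3" = c("b", "le", "d"), "2" = c("b", "le"))

  df_fit <- data.frame(y = y, lx = lx)
  fit_one <- function(st) {
    tryCatch(
      minpack.lm::nlsLM(form, data = df_fit, start = as.list(st[keep]),
                        lower = unname(lower[keep]), upper = unname(upper[keep]),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  starts <- list(start0)
  jit <- with_seed(20317, lapply(1:5, function(i) {
    st <- start0
    st["b"] <- st["b"] * stats::runif(1, 0.4, 2.5)
    st["le"] <- st["le"] + stats::rnorm(1, 0, max(1, stats::sd(lx)))
    st
  }))
  starts <- c(starts, jit)
  fits <- Filter(Negate(is.null), lapply(starts, fit_one))
  if (length(fits) == 0L) {
    return(structure(list(
      b = NA_real_, e = NA_real_, c = NA_real_, d = NA_real_,
      se = c(b = NA_real_, e = NA_real_, c = NA_real_, d = NA_real_),
      p = c(b = NA_real_, e = NA_real_, c = NA_real_, d = NA_real_),
      sse = NA_real_, df = length(y) - n_params,
      converged = FALSE, identifiable = FALSE, n_params = n_params
    ), class = "dose_response_fit"))
  }
  sse <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  best <- fits[[which.min(sse)]]
  cf <- stats::coef(best)
  sm <- summary(best)$coefficients
  get <- function(nm, col) if (nm %in% rownames(sm)) sm[nm, col] else NA_real_
  b_hat <- unname(cf["b"]); le_hat <- unname(cf["le"])
  e_hat <- exp(le_hat)
  c_hat <- if (n_params == 4) unname(cf["c"]) else 0
  d_hat <- if (n_params >= 3) unname(cf["d"]) else 1
  se_le <- get("le", 2)
  se <- c(b = get("b", 2), e = e_hat * se_le, c = get("c", 2), d = get("d", 2))
  df_res <- length(y) - length(cf)
  # parameter-vs-zero t-tests; the EC50 p-value is carried over from ln e
  p <- c(b = get("b", 4), e = get("le", 4), c = get("c", 4), d = get("d", 4))
  ci_b <- unname(cf["b"]) + c(-1, 1) * stats::qt(0.975, df_res) * se["b"]
  structure(list(
    b = b_hat, e = e_hat, c = c_hat, d = d_hat,
    se = se, p = p, sse = min(sse), df = df_res,
    converged = TRUE,
    identifiable = !(is.finite(ci_b[1]) && is.finite(ci_b[2]) &&
                       ci_b[1] < 0 && ci_b[2] > 0) ,
    n_params = n_params
  ), class = "dose_response_fit")
}

#' @method print dose_response_fit
#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("log-logistic fit (%d-parameter): Hill slope b = %.4g, EC50 e = %.4g\n",
              x$n_params, x$b, x$e))
  cat(sprintf("  asymptotes c = %.4g, d = %.4g; SSE = %.4g; converged: %s%s\n",
              x$c, x$d, x$sse, x$converged,
              if (!x$identifiable) " (slope not distinguishable from flat)" else ""))
  invisible(x)
}

#' Serialise a dose-response fit as JSON
#' @param fit A [fit_loglogistic()] result.
#' @param path Output path.
#' @export
write_dose_response <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
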