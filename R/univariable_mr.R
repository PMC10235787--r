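.check_xy <- function(h) {
  stopifnot(inherits(h, "harmonised_set"))
  if (length(h$traits) != 2L) {
    stopf("expected a harmonised set with exactly one exposure and one outcome",
          class = "mr_usage_error")
  }
  invisible(h)
}

.binary_outcome <- function(h) h$trait_types[length(h$trait_types)] == "binary"

#' Per-variant Wald ratio estimates
#'
#' The building block of all summary-data MR estimators: for each variant,
#' the ratio of its outcome association to its exposure association, with
#' the first-order standard error `se_Y / |beta_X|`. Variants with a zero
#' exposure beta are dropped with a warning.
#'
#' @param h a two-trait `harmonised_set` (exposure, outcome).
#' @return data.frame with `variant_id`, `theta`, `se`.
#' @export
ratio_estimates <- function(h) {
  .check_xy(h)
  bx <- h$beta[, 1]; by <- h$beta[, 2]; sy <- h$se[, 2]
  drop <- bx == 0
  if (any(drop)) {
    warnf("ratio_estimates: dropping %d variant(s) with zero exposure beta",
          sum(drop), class = "mr_zero_exposure_beta")
  }
  data.frame(variant_id = h$variant_ids[!drop],
             theta = by[!drop] / bx[!drop],
             se = sy[!drop] / abs(bx[!drop]),
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted MR estimate
#'
#' Meta-analysis of per-variant Wald ratios with inverse-variance weights
#' (first-order: `w_j = beta_Xj^2 / se_Yj^2`), algebraically identical to
#' weighted regression of outcome betas on exposure betas through the
#' origin with weights `se_Yj^-2`. The default random-effects model is
#' multiplicative: the fixed-effect standard error is inflated by
#' `max(1, sqrt(Q / (J - 1)))`, where Q is Cochran's heterogeneity
#' statistic. With a single variant the estimate collapses to the Wald
#' ratio (method tag `"wald_ratio"`, with a warning).
#'
#' @param h a two-trait `harmonised_set`.
#' @param model `"random"` (default) or `"fixed"`.
#' @return An `mr_estimate`.
#' @export
mr_ivw <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  .check_xy(h)
  r <- ratio_estimates(h)
  J <- nrow(r)
  if (J == 0L) stopf("mr_ivw: no usable variants", class = "mr_empty_input")
  if (J == 1L) {
    warnf("mr_ivw: single variant; returning Wald ratio",
          class = "mr_single_variant")
    return(mr_estimate("wald_ratio", r$theta, r$se, 1L,
                       binary_outcome = .binary_outcome(h)))
  }
  w <- 1 / r$se^2
  theta <- sum(w * r$theta) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  Q <- sum(w * (r$theta - theta)^2)
  se <- if (model == "random") se_fixed * max(1, sqrt(Q / (J - 1))) else se_fixed
  mr_estimate(if (model == "random") "ivw" else "ivw_fixed", theta, se, J,
              binary_outcome = .binary_outcome(h), Q = Q, Q_df = J - 1)
}

# interpolated weighted median of theta with weights w (both unsorted)
.weighted_median <- function(theta, w) {
  ord <- order(theta)
  th <- theta[ord]
  p <- cumsum(w[ord] / sum(w)) - w[ord] / sum(w) / 2
  if (p[1] >= 0.5) return(th[1])
  below <- max(which(p < 0.5))
  if (below == length(th)) return(th[length(th)])
  th[below] + (th[below + 1] - th[below]) * (0.5 - p[below]) /
    (p[below + 1] - p[below])
}

#' Weighted-median MR estimate
#'
#' Orders the per-variant Wald ratios and takes the weighted median
#' (inverse-variance weights, linear interpolation of the cumulative weight
#' function at 0.5). Consistent when at least half the weight comes from
#' valid instruments. The standard error comes from a seeded parametric
#' bootstrap: exposure and outcome betas are resampled from their normal
#' sampling distributions and the weighted median recomputed.
#'
#' @param h a two-trait `harmonised_set` with at least 3 variants.
#' @param n_boot bootstrap replicates for the standard error (default 1000).
#' @param seed RNG seed for the bootstrap (required, for reproducibility).
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed) {
  .check_xy(h)
  if (missing(seed)) {
    stopf("mr_weighted_median: a seed is required", class = "mr_usage_error")
  }
  r <- ratio_estimates(h)
  J <- nrow(r)
  if (J < 3L) {
    stopf("mr_weighted_median: needs >= 3 variants (have %d)", J,
          class = "mr_method_unavailable")
  }
  w <- 1 / r$se^2
  theta <- .weighted_median(r$theta, w)
  keep <- match(r$variant_id, h$variant_ids)
  bx <- h$beta[keep, 1]; by <- h$beta[keep, 2]
  sx <- h$se[keep, 1]; sy <- h$se[keep, 2]
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bxs <- stats::rnorm(J, bx, sx)
      bys <- stats::rnorm(J, by, sy)
      ok <- bxs != 0
      .weighted_median(bys[ok] / bxs[ok], (bxs[ok] / sy[ok])^2)
    }, numeric(1))
  })
  mr_estimate("weighted_median", theta, stats::sd(boot), J,
              binary_outcome = .binary_outcome(h))
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# weighted least squares by normal equations; returns coefficients, their
# unscaled covariance (sigma = 1) and the weighted RSS
.wls <- function(X, y, w) {
  XtW <- t(X * w)
  V <- solve(XtW %*% X)
  coef <- drop(V %*% (XtW %*% y))
  rss <- sum(w * (y - drop(X %*% coef))^2)
  list(coef = coef, V = V, rss = rss)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with an intercept,
#' weights `se_Yj^-2`, after orienting every variant so its exposure beta is
#' non-negative. The slope is the pleiotropy-adjusted causal estimate under
#' the InSIDE assumption; the intercept estimates the average directional
#' pleiotropic effect and its p-value is the pleiotropy test. Standard
#' errors are inflated multiplicatively by `max(1, sqrt(RSS / (J - 2)))`.
#'
#' @param h a two-trait `harmonised_set` with at least 3 variants.
#' @return list of class `mr_egger_result` with elements `slope` and
#'   `intercept`, both `mr_estimate` objects.
#' @export
mr_egger <- function(h) {
  .check_xy(h)
  J <- length(h$variant_ids)
  if (J < 3L) {
    stopf("mr_egger: needs >= 3 variants (have %d)", J,
          class = "mr_method_unavailable")
  }
  s <- ifelse(h$beta[, 1] < 0, -1, 1)
  bx <- s * h$beta[, 1]; by <- s * h$beta[, 2]; sy <- h$se[, 2]
  w <- 1 / sy^2
  fit <- .wls(cbind(intercept = 1, slope = bx), by, w)
  phi <- max(1, sqrt(fit$rss / (J - 2)))
  ses <- sqrt(diag(fit$V)) * phi
  binary <- .binary_outcome(h)
  structure(list(
    slope = mr_estimate("egger_slope", fit$coef[["slope"]], ses[["slope"]],
                        J, binary_outcome = binary),
    intercept = mr_estimate("egger_intercept", fit$coef[["intercept"]],
                            ses[["intercept"]], J)),
    class = "mr_egger_result")
}

#' @export
print.mr_egger_result <- function(x, ...) {
  print(x$slope); print(x$intercept)
  invisible(x)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Regression-framework pleiotropy detection. The global test compares the
#' observed leave-one-out weighted residual sum of squares of the
#' through-origin regression of outcome betas on exposure betas against its
#' distribution over `n_sim` datasets simulated under the fitted
#' no-pleiotropy model (betas redrawn from their normal sampling
#' distributions). Each variant's observed squared standardised residual is
#' compared with its simulated counterpart to give a per-variant outlier
#' p-value; variants below the Bonferroni-corrected `outlier_p / J` are
#' flagged. The corrected estimate is the IVW fit excluding flagged
#' variants, and the distortion p-value compares the observed raw-vs-
#' corrected shift with shifts obtained by excluding equally many randomly
#' chosen unflagged variants.
#'
#' @param h a two-trait `harmonised_set` with at least 4 variants.
#' @param n_sim simulated null datasets (default 1000).
#' @param outlier_p familywise outlier threshold before the Bonferroni
#'   correction over J variants (default 0.05).
#' @param seed RNG seed (required).
#' @return list of class `presso_result`: `global_rss_p`, `outliers`
#'   (data.frame `variant_id`, `pval`, `flagged`), `raw` and `corrected`
#'   `mr_estimate`s, `distortion_p`.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_p = 0.05, seed) {
  .check_xy(h)
  if (missing(seed)) stopf("mr_presso: a seed is required", class = "mr_usage_error")
  J <- length(h$variant_ids)
  if (J < 4L) {
    stopf("mr_presso: needs >= 4 variants (have %d)", J,
          class = "mr_method_unavailable")
  }
  if (1 / (n_sim + 1) >= outlier_p / J) {
    warnf("mr_presso: n_sim = %d cannot reach the Bonferroni threshold %g/%d; no variant can be flagged (need n_sim > J/outlier_p)",
          n_sim, outlier_p, J, class = "mr_presso_resolution")
  }
  bx <- h$beta[, 1]; by <- h$beta[, 2]
  sx <- h$se[, 1]; sy <- h$se[, 2]
  w <- 1 / sy^2
  loo_theta <- function(bx, by) {
    num <- sum(w * bx * by); den <- sum(w * bx^2)
    (num - w * bx * by) / (den - w * bx^2)
  }
  th_loo <- loo_theta(bx, by)
  res_obs2 <- w * (by - th_loo * bx)^2   # squared standardised residuals
  rss_obs <- sum(res_obs2)

  sim <- withr_seed(seed, {
    bxs <- matrix(stats::rnorm(J * n_sim, bx, sx), J, n_sim)
    bys <- matrix(stats::rnorm(J * n_sim, th_loo * bx, sy), J, n_sim)
    num <- colSums(w * bxs * bys); den <- colSums(w * bxs^2)
    th_s <- (sweep(-(w * bxs * bys), 2, num, "+")) /
      (sweep(-(w * bxs^2), 2, den, "+"))
    r2 <- w * (bys - th_s * bxs)^2
    list(rss = colSums(r2), res2 = r2)
  })
  global_p <- (1 + sum(sim$rss >= rss_obs)) / (n_sim + 1)
  out_p <- (1 + rowSums(sim$res2 >= res_obs2)) / (n_sim + 1)
  flagged <- out_p < outlier_p / J

  raw <- mr_ivw(h)
  corrected <- raw  # stays the raw IVW when nothing can be excluded
  distortion_p <- NA_real_
  if (any(flagged) && sum(!flagged) >= 2L) {
    corrected <- mr_ivw(subset_harmonised(h, h$variant_ids[!flagged]))
    nf <- sum(flagged)
    keep_pool <- which(!flagged)
    if (length(keep_pool) > nf) {
      d_null <- withr_seed(child_seed(seed, 1L), {
        vapply(seq_len(n_sim), function(i) {
          drop <- sample(keep_pool, nf)
          idx <- setdiff(seq_len(J), drop)
          th <- sum(w[idx] * bx[idx] * by[idx]) / sum(w[idx] * bx[idx]^2)
          raw$theta - th
        }, numeric(1))
      })
      d_obs <- raw$theta - corrected$theta
      distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
    }
  }
  structure(list(
    global_rss_p = global_p,
    outliers = data.frame(variant_id = h$variant_ids, pval = out_p,
                          flagged = flagged, stringsAsFactors = FALSE),
    raw = raw, corrected = corrected, distortion_p = distortion_p,
    n_sim = n_sim), class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<presso_result> global RSS p = %.4g; %d/%d variant(s) flagged; distortion p = %.4g\n",
              x$global_rss_p, sum(x$outliers$flagged), nrow(x$outliers),
              x$distortion_p))
  print(x$corrected)
  invisible(x)
}
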