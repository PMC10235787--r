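#' Multivariable MR fit
#'
#' Direct (conditional) effects of two or more exposures on the outcome:
#' weighted least squares of outcome betas on the exposure-beta columns with
#' the intercept fixed to zero, weighted by the precision of the
#' variant-outcome associations (`se_Yj^-2`). Coefficient standard errors
#' are inflated multiplicatively by `max(1, sqrt(RSS / (J - k)))`.
#'
#' A conditional instrument-strength F statistic is reported per exposure as
#' a diagnostic: the weighted residual variation of that exposure's betas
#' after projecting out the other exposures' betas, standardised by its own
#' standard errors and divided by the residual degrees of freedom. This is a
#' summary-data approximation that ignores cross-trait sampling covariance.
#'
#' @param h a `harmonised_set` with k >= 2 exposures followed by the
#'   outcome (instruments typically from [pool_for_mvmr]).
#' @return list of class `mvmr_result`: `estimates` (named list of
#'   `mr_estimate`, one per exposure), `conditional_F` (named numeric),
#'   `rss`, `n_snps`.
#' @export
mvmr_fit <- function(h) {
  stopifnot(inherits(h, "harmonised_set"))
  K <- length(h$traits)
  if (K < 3L) {
    stopf("mvmr_fit: need >= 2 exposures plus an outcome",
          class = "mr_usage_error")
  }
  k <- K - 1L
  J <- length(h$variant_ids)
  if (J <= k) {
    stopf("mvmr_fit: %d variants cannot identify %d exposures", J, k,
          class = "mr_underdetermined")
  }
  X <- h$beta[, seq_len(k), drop = FALSE]
  y <- h$beta[, K]
  w <- 1 / h$se[, K]^2
  # an exposure whose betas are all zero carries no information: drop it
  # from the regression (its direct effect is unidentifiable) rather than
  # reporting the whole design as collinear
  zero_col <- apply(X, 2, function(col) all(col == 0))
  if (any(zero_col)) {
    warnf("mvmr_fit: exposure(s) with all-zero betas excluded: %s",
          paste(h$traits[seq_len(k)][zero_col], collapse = ", "),
          class = "mr_zero_exposure")
  }
  active <- which(!zero_col)
  if (!length(active)) {
    stopf("mvmr_fit: every exposure column is zero", class = "mr_empty_input")
  }
  Xa <- X[, active, drop = FALSE]
  ka <- length(active)
  qr_X <- qr(Xa * sqrt(w))
  if (qr_X$rank < ka) {
    cc <- abs(stats::cor(Xa))
    diag(cc) <- 0
    worst <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    stopf("mvmr_fit: collinear exposure betas (worst pair: %s, %s)",
          h$traits[active[worst[1]]], h$traits[active[worst[2]]],
          class = "mr_collinear")
  }
  fit <- .wls(Xa, y, w)
  phi <- max(1, sqrt(fit$rss / (J - ka)))
  ses <- sqrt(diag(fit$V)) * phi
  binary <- .binary_outcome_mv(h)
  est <- stats::setNames(vector("list", k), h$traits[seq_len(k)])
  condF <- stats::setNames(rep(NA_real_, k), h$traits[seq_len(k)])
  for (jj in seq_len(ka)) {
    j <- active[jj]
    est[[j]] <- mr_estimate("mvmr_direct", unname(fit$coef[jj]),
                            unname(ses[jj]), J, binary_outcome = binary)
    sx <- h$se[, j]
    if (ka == 1L) {
      condF[j] <- mean((Xa[, jj] / sx)^2)
    } else {
      other <- Xa[, -jj, drop = FALSE]
      pf <- .wls(other, Xa[, jj], 1 / sx^2)
      resid <- Xa[, jj] - drop(other %*% pf$coef)
      condF[j] <- sum((resid / sx)^2) / (J - (ka - 1))
    }
  }
  for (j in which(zero_col)) {
    est[[j]] <- mr_estimate("mvmr_direct", NA_real_, NA_real_, J,
                            binary_outcome = binary, pval = NA_real_)
  }
  structure(list(estimates = est, conditional_F = condF, rss = fit$rss,
                 n_snps = J), class = "mvmr_result")
}

.binary_outcome_mv <- function(h) h$trait_types[length(h$trait_types)] == "binary"

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("<mvmr_result> %d SNPs, weighted RSS = %.3f\n", x$n_snps, x$rss))
  for (nm in names(x$estimates)) {
    cat(sprintf("  %s (conditional F = %.1f):\n", nm, x$conditional_F[[nm]]))
    print(x$estimates[[nm]])
  }
  invisible(x)
}

#' Decompose a total effect into direct and mediated components
#'
#' Difference-method mediation on the outcome link scale: the indirect
#' (mediated) effect is the total effect minus the direct effect, and the
#' proportion mediated is indirect / total. Standard errors follow the
#' propagation-of-error rules for independently estimated quantities:
#' `SE_indirect = sqrt(SE_total^2 + SE_direct^2)` (the covariance between
#' total and direct is taken as zero) and the ratio delta method for the
#' proportion. Confidence intervals are symmetric normal, so the proportion
#' CI may legitimately fall outside [0, 1].
#'
#' @param total univariable `mr_estimate` of the total effect.
#' @param direct `mr_estimate` of the direct effect from [mvmr_fit],
#'   adjusted for the mediator.
#' @param exposure_id,mediator_id,outcome_id labels carried into the result.
#' @param unit_scaling multiplier applied to total and direct effects (and
#'   SEs) before exponentiation, e.g. 10 for per-10-mmHg reporting. The
#'   proportion mediated is invariant to it.
#' @return Object of class `mediation_result` with elements `total`,
#'   `direct`, `indirect` (`theta`, `se`, `ci_low`, `ci_high`),
#'   `proportion_mediated` (same fields), and the labels.
#' @export
mr_decompose <- function(total, direct, exposure_id = "exposure",
                         mediator_id = "mediator", outcome_id = "outcome",
                         unit_scaling = 1) {
  stopifnot(inherits(total, "mr_estimate"), inherits(direct, "mr_estimate"))
  if (unit_scaling != 1) {
    total <- mr_rescale(total, unit_scaling)
    direct <- mr_rescale(direct, unit_scaling)
  }
  if (abs(total$theta) < 1e-10) {
    stopf("mr_decompose: total effect ~ 0; proportion mediated undefined",
          class = "mr_proportion_undefined")
  }
  ind <- total$theta - direct$theta
  se_ind <- sqrt(total$se^2 + direct$se^2)
  prop <- ind / total$theta
  se_prop <- if (ind != 0) {
    abs(prop) * sqrt((se_ind / ind)^2 + (total$se / total$theta)^2)
  } else {
    se_ind / abs(total$theta)
  }
  structure(list(
    exposure_id = exposure_id, mediator_id = mediator_id,
    outcome_id = outcome_id,
    total = total, direct = direct,
    indirect = list(theta = ind, se = se_ind,
                    ci_low = ci95(ind, se_ind)[1],
                    ci_high = ci95(ind, se_ind)[2],
                    pval = z_pval(ind, se_ind)),
    proportion_mediated = list(estimate = prop, se = se_prop,
                               ci_low = ci95(prop, se_prop)[1],
                               ci_high = ci95(prop, se_prop)[2]),
    unit_scaling = unit_scaling,
    covariance_rule = "cov(total, direct) = 0"),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  pm <- x$proportion_mediated
  cat(sprintf("<mediation_result> %s -> %s -> %s\n", x$exposure_id,
              x$mediator_id, x$outcome_id))
  cat(sprintf("  total  %.4f (se %.4f)   direct %.4f (se %.4f)\n",
              x$total$theta, x$total$se, x$direct$theta, x$direct$se))
  cat(sprintf("  indirect %.4f (95%% CI %.4f to %.4f)\n", x$indirect$theta,
              x$indirect$ci_low, x$indirect$ci_high))
  cat(sprintf("  proportion mediated %.2f%% (95%% CI %.2f%% to %.2f%%)\n",
              100 * pm$estimate, 100 * pm$ci_low, 100 * pm$ci_high))
  invisible(x)
}

#' Mediation analysis for one (exposure, mediator, outcome) triple
#'
#' Total effect: univariable random-effects IVW on the exposure's own
#' instruments (genome-wide significant, clumped). Direct effect:
#' multivariable MR on instruments pooled across exposure and mediator and
#' clumped, harmonised across the three traits. Decomposition by
#' [mr_decompose]. Note the total and direct estimates deliberately use
#' different instrument sets, mirroring standard two-sample practice.
#'
#' @param exposure,mediator,outcome [summary_stats] objects.
#' @param ld an [ld_info] or `NULL`.
#' @param p_threshold,r2_threshold instrument-selection parameters.
#' @param unit_scaling reporting multiplier for the exposure unit.
#' @return A `mediation_result` with attribute `n_snps_mvmr`.
#' @export
mr_mediate <- function(exposure, mediator, outcome, ld = NULL,
                       p_threshold = 5e-8, r2_threshold = 0.001,
                       unit_scaling = 1) {
  inst_x <- select_instruments(exposure, p_threshold, ld, r2_threshold)
  h2 <- subset_harmonised(harmonise(list(exposure, outcome)),
                          inst_x$variant_id)
  total <- mr_ivw(h2)
  pooled <- pool_for_mvmr(list(exposure, mediator), p_threshold, ld,
                          r2_threshold)
  h3 <- subset_harmonised(harmonise(list(exposure, mediator, outcome)),
                          pooled$variant_id)
  fit <- mvmr_fit(h3)
  direct <- fit$estimates[[exposure$trait_id]]
  out <- mr_decompose(total, direct, exposure$trait_id, mediator$trait_id,
                      outcome$trait_id, unit_scaling = unit_scaling)
  attr(out, "n_snps_mvmr") <- fit$n_snps
  attr(out, "conditional_F") <- fit$conditional_F
  out
}

#' Mediation grid over every ordered (exposure, mediator) pair
#'
#' Runs [mr_mediate] for each ordered pair of risk factors against a common
#' outcome. Failures in one cell (e.g. a mediator with no genome-wide-
#' significant variants) are logged and recorded as missing cells; they do
#' not abort or alter other cells.
#'
#' @param risk_factors list of [summary_stats] objects (>= 2).
#' @param outcome [summary_stats] for the outcome.
#' @param ld an [ld_info] or `NULL`.
#' @param p_threshold,r2_threshold instrument-selection parameters.
#' @param unit_scalings optional named numeric of per-trait reporting
#'   multipliers (default 1).
#' @return data.frame in long format, one row per ordered pair, with
#'   effects, proportion mediated and its CI, SNP counts, a `status` column
#'   (`"ok"` or `"failed"`) and the error message for failed cells.
#' @export
mediation_grid <- function(risk_factors, outcome, ld = NULL,
                           p_threshold = 5e-8, r2_threshold = 0.001,
                           unit_scalings = NULL) {
  if (!is.list(risk_factors) || length(risk_factors) < 2L) {
    stopf("mediation_grid: need >= 2 risk factors", class = "mr_usage_error")
  }
  ids <- vapply(risk_factors, function(t) t$trait_id, character(1))
  rows <- list()
  for (i in seq_along(risk_factors)) {
    for (j in seq_along(risk_factors)) {
      if (i == j) next
      exp_t <- risk_factors[[i]]; med_t <- risk_factors[[j]]
      scal <- unit_scalings[[exp_t$trait_id]] %||% 1
      cell <- tryCatch({
        m <- mr_mediate(exp_t, med_t, outcome, ld, p_threshold,
                        r2_threshold, unit_scaling = scal)
        data.frame(
          exposure = exp_t$trait_id, mediator = med_t$trait_id,
          total_theta = m$total$theta, total_se = m$total$se,
          total_or = m$total$or %||% NA_real_,
          total_ci_low = m$total$ci_low, total_ci_high = m$total$ci_high,
          direct_theta = m$direct$theta, direct_se = m$direct$se,
          direct_or = m$direct$or %||% NA_real_,
          direct_ci_low = m$direct$ci_low, direct_ci_high = m$direct$ci_high,
          indirect = m$indirect$theta, indirect_se = m$indirect$se,
          proportion_mediated = m$proportion_mediated$estimate,
          pm_se = m$proportion_mediated$se,
          pm_ci_low = m$proportion_mediated$ci_low,
          pm_ci_high = m$proportion_mediated$ci_high,
          n_snps_total = m$total$n_snps,
          n_snps_mvmr = attr(m, "n_snps_mvmr"),
          status = "ok", error = NA_character_, stringsAsFactors = FALSE)
      }, error = function(e) {
        message(sprintf("mediation_grid[%s -> %s]: %s", exp_t$trait_id,
                        med_t$trait_id, conditionMessage(e)))
        out <- data.frame(
          exposure = exp_t$trait_id, mediator = med_t$trait_id,
          total_theta = NA_real_, total_se = NA_real_, total_or = NA_real_,
          total_ci_low = NA_real_, total_ci_high = NA_real_,
          direct_theta = NA_real_, direct_se = NA_real_, direct_or = NA_real_,
          direct_ci_low = NA_real_, direct_ci_high = NA_real_,
          indirect = NA_real_, indirect_se = NA_real_,
          proportion_mediated = NA_real_, pm_se = NA_real_,
          pm_ci_low = NA_real_, pm_ci_high = NA_real_,
          n_snps_total = NA_integer_, n_snps_mvmr = NA_integer_,
          status = "failed", error = conditionMessage(e),
          stringsAsFactors = FALSE)
        out
      })
      rows[[length(rows) + 1L]] <- cell
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
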