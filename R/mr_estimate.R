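#' Construct an MR estimate record
#'
#' @param method estimator label.
#' @param theta causal-effect estimate on the outcome link scale per unit
#'   exposure.
#' @param se standard error of `theta`.
#' @param n_snps number of variants used.
#' @param binary_outcome logical; when `TRUE` an odds-ratio triple
#'   `exp(theta)`, `exp(ci)` is attached.
#' @param Q,Q_df Cochran heterogeneity statistic and its degrees of freedom
#'   (optional).
#' @param pval override for the default two-sided normal p-value.
#' @return Object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, theta, se, n_snps, binary_outcome = FALSE,
                        Q = NA_real_, Q_df = NA_real_, pval = NULL) {
  ci <- ci95(theta, se)
  out <- list(method = method, theta = theta, se = se,
              ci_low = ci[1], ci_high = ci[2],
              pval = pval %||% z_pval(theta, se),
              n_snps = n_snps,
              Q = Q, Q_df = Q_df,
              Q_pval = if (is.na(Q) || Q_df < 1) NA_real_ else
                stats::pchisq(Q, Q_df, lower.tail = FALSE))
  if (binary_outcome) {
    out$or <- exp(theta)
    out$or_ci_low <- exp(ci[1])
    out$or_ci_high <- exp(ci[2])
  }
  structure(out, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("<mr_estimate> %s: theta = %.*f (se %.*f, 95%% CI %.*f to %.*f), p = %.3g, %d SNPs\n",
              x$method, digits, x$theta, digits, x$se, digits, x$ci_low,
              digits, x$ci_high, x$pval, x$n_snps))
  if (!is.null(x$or)) {
    cat(sprintf("  OR = %.3f (95%% CI %.3f-%.3f)\n", x$or, x$or_ci_low,
                x$or_ci_high))
  }
  if (!is.na(x$Q)) {
    cat(sprintf("  Cochran Q = %.2f on %d df (p = %.3g)\n", x$Q, x$Q_df,
                x$Q_pval))
  }
  invisible(x)
}

#' Flatten an mr_estimate to a one-row data.frame
#' @param x an `mr_estimate`.
#' @return one-row data.frame.
#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, theta = x$theta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             or = x$or %||% NA_real_, or_ci_low = x$or_ci_low %||% NA_real_,
             or_ci_high = x$or_ci_high %||% NA_real_,
             n_snps = x$n_snps, Q = x$Q, Q_df = x$Q_df, Q_pval = x$Q_pval,
             stringsAsFactors = FALSE)
}

#' Re-express an MR estimate per a different exposure unit
#'
#' GWAS effect sizes are per source unit (e.g. per mmHg); results are often
#' reported per clinical increment (e.g. per 10 mmHg). Multiplies the effect
#' and its standard error before any odds-ratio exponentiation. Proportions
#' mediated are invariant to this rescaling.
#'
#' @param est an `mr_estimate`.
#' @param multiplier positive unit factor.
#' @return The rescaled `mr_estimate`.
#' @export
mr_rescale <- function(est, multiplier) {
  stopifnot(inherits(est, "mr_estimate"))
  if (!is.numeric(multiplier) || multiplier <= 0) {
    stopf("mr_rescale: multiplier must be > 0", class = "mr_usage_error")
  }
  mr_estimate(est$method, est$theta * multiplier, est$se * multiplier,
              est$n_snps, binary_outcome = !is.null(est$or),
              Q = est$Q, Q_df = est$Q_df, pval = est$pval)
}

#' Significance label under the Bonferroni convention
#'
#' `"significant"` for p below the Bonferroni threshold (default 0.005),
#' `"suggestive"` for p in [bonferroni, 0.05), `"ns"` otherwise.
#'
#' @param pval p-value(s).
#' @param bonferroni multiple-testing threshold.
#' @return character vector of labels.
#' @export
significance_label <- function(pval, bonferroni = 0.005) {
  ifelse(pval < bonferroni, "significant",
         ifelse(pval < 0.05, "suggestive", "ns"))
}
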