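# Shared builders and independent oracles for the test suite.

# quick summary_stats builder with sensible defaults
make_stats <- function(ids, beta, se, pval = NULL, eaf = NULL, n = NULL,
                       ea = "A", oa = "G", trait_id = "X",
                       trait_type = "quantitative", unit_label = "SD") {
  J <- length(ids)
  # tests often pass stylised p-values decoupled from beta/se; silence the
  # consistency advisory for those
  muffle <- function(expr) withCallingHandlers(expr,
    mr_pval_inconsistent = function(w) invokeRestart("muffleWarning"))
  muffle(summary_stats(data.frame(
    variant_id = ids,
    effect_allele = rep_len(ea, J), other_allele = rep_len(oa, J),
    eaf = if (is.null(eaf)) NA_real_ else eaf,
    beta = beta, se = se,
    pval = if (is.null(pval)) 2 * pnorm(-abs(beta / se)) else pval,
    n = if (is.null(n)) NA_real_ else n,
    stringsAsFactors = FALSE),
    trait_id = trait_id, trait_type = trait_type, unit_label = unit_label))
}

# direct harmonised_set construction for estimator math tests
h_set <- function(bx, by, sy, sx = rep(0.01, length(bx)),
                  ids = sprintf("v%02d", seq_along(bx)), binary = TRUE) {
  dimn <- list(ids, c("X", "Y"))
  structure(list(
    traits = c("X", "Y"),
    trait_types = c("quantitative", if (binary) "binary" else "quantitative"),
    unit_labels = c("SD", if (binary) "logOR" else "SD"),
    variant_ids = ids,
    effect_allele = rep("A", length(ids)),
    other_allele = rep("G", length(ids)),
    beta = matrix(c(bx, by), ncol = 2, dimnames = dimn),
    se = matrix(c(sx, sy), ncol = 2, dimnames = dimn),
    eaf = matrix(NA_real_, length(ids), 2, dimnames = dimn),
    pval = matrix(c(2 * pnorm(-abs(bx / sx)), 2 * pnorm(-abs(by / sy))),
                  ncol = 2, dimnames = dimn)),
    class = "harmonised_set")
}

# three-trait (exposure, mediator, outcome) harmonised set
h3_set <- function(bx, bm, by, sy, sx = rep(0.005, length(bx)),
                   sm = rep(0.005, length(bx)),
                   ids = sprintf("v%02d", seq_along(bx))) {
  dimn <- list(ids, c("X", "M", "Y"))
  structure(list(
    traits = c("X", "M", "Y"),
    trait_types = c("quantitative", "quantitative", "binary"),
    unit_labels = c("SD", "SD", "logOR"),
    variant_ids = ids,
    effect_allele = rep("A", length(ids)),
    other_allele = rep("G", length(ids)),
    beta = matrix(c(bx, bm, by), ncol = 3, dimnames = dimn),
    se = matrix(c(sx, sm, sy), ncol = 3, dimnames = dimn),
    eaf = matrix(NA_real_, length(ids), 3, dimnames = dimn),
    pval = matrix(0.5, length(ids), 3, dimnames = dimn)),
    class = "harmonised_set")
}

# --- independent closed-form oracles ---------------------------------------

# IVW as intercept-free weighted regression, via lm()
ivw_oracle <- function(bx, by, sy) {
  fit <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  s <- summary(fit)
  list(theta = unname(coef(fit)[1]),
       se_fixed = unname(s$coefficients[1, 2] / s$sigma))
}

# MR-Egger as weighted regression with intercept, via lm(); multiplicative
# random-effects inflation floored at 1
egger_oracle <- function(bx, by, sy) {
  s <- ifelse(bx < 0, -1, 1)
  fit <- lm((s * by) ~ I(s * bx), weights = 1 / sy^2)
  sm <- summary(fit)
  infl <- max(1, sm$sigma)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       se_intercept = unname(sm$coefficients[1, 2] / sm$sigma * infl),
       se_slope = unname(sm$coefficients[2, 2] / sm$sigma * infl))
}

# MVMR normal equations via lm()
mvmr_oracle <- function(X, y, sy, k = ncol(X)) {
  fit <- lm(y ~ 0 + X, weights = 1 / sy^2)
  sm <- summary(fit)
  infl <- max(1, sm$sigma)
  list(coef = unname(coef(fit)),
       se = unname(sm$coefficients[, 2] / sm$sigma * infl))
}

# weighted median by analytic scan of the cumulative-weight function,
# using stats::approx for the interpolation
wm_oracle <- function(theta, w) {
  ord <- order(theta)
  th <- theta[ord]; w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(th[1])
  approx(p, th, xout = 0.5, rule = 2)$y
}

# matrix-based verification that `kept` is the greedy p-ordered clump of
# `ids`: a variant survives iff it conflicts with no better-ranked survivor
clump_oracle_check <- function(ids, pvals, r2mat, thr, kept) {
  ord <- order(pvals, ids)
  ids <- ids[ord]
  member <- logical(length(ids))
  for (i in seq_along(ids)) {
    prior <- ids[seq_len(i - 1)][member[seq_len(i - 1)]]
    member[i] <- !length(prior) ||
      all(r2mat[ids[i], prior, drop = TRUE] < thr)
  }
  setequal(kept, ids[member])
}

# two-trait harmonised set restricted to an exposure's selected instruments
total_effect_hset <- function(study, p_threshold = 5e-8) {
  inst <- suppressWarnings(
    select_instruments(study$exposure, p_threshold, study$ld))
  subset_harmonised(harmonise(list(study$exposure, study$outcome)),
                    inst$variant_id)
}
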