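#' Ground-truth configuration for the synthetic GWAS generator
#'
#' Describes a mediation directed acyclic graph — exposure -> mediator ->
#' binary outcome on the log-odds scale, plus a direct exposure -> outcome
#' path — together with instrument effect-size distributions, per-study
#' sample sizes, pleiotropy structure and LD blocks. Defaults emulate the
#' setting of large European-ancestry consortium GWAS: exposure and
#' mediator studies of ~700k, an outcome study with an effective sample
#' size of ~240k (a case-control study of ~62k cases / 1.2M controls), and
#' per-variant effects sized so that J = 100 instruments explain roughly
#' 4-5% of a variance-standardised exposure with all F statistics
#' comfortably above 10.
#'
#' `gamma_dist`/`delta_dist` describe the exposure-specific and
#' mediator-specific instrument effects. Two kinds are supported:
#' `list(kind = "uniform_mag", min, max)` — magnitude uniform in
#' [min, max] with random sign (zero-mean, genome-wide significant by
#' construction, the default), and `list(kind = "normal", sd)` — plain
#' zero-mean normal (used for the weak-instrument scenario).
#'
#' @param J exposure-specific instrument count.
#' @param J_med mediator-specific instrument count (default `J`).
#' @param maf_range range of effect-allele frequencies.
#' @param gamma_dist,delta_dist effect-size distributions (see above).
#' @param theta_xm exposure -> mediator causal effect.
#' @param theta_my mediator -> outcome causal effect (log-odds scale).
#' @param theta_direct direct exposure -> outcome effect (log-odds scale).
#' @param pleiotropy list: `mode` one of `"none"`, `"balanced"`,
#'   `"directional"`, `"correlated"`; `mean` and `sd` of the pleiotropic
#'   outcome effect alpha; `fraction` of variants affected; `corr_scale`
#'   (correlated mode) the coefficient of alpha on gamma, violating the
#'   InSIDE assumption.
#' @param n_exp,n_med,n_out per-study (effective) sample sizes of the three
#'   non-overlapping GWAS.
#' @param n_outliers number of exposure instruments given an additional
#'   pleiotropic outcome offset.
#' @param outlier_offset that offset, in units of the outcome standard
#'   error.
#' @param ld_block_size variants per LD block (1 = all independent).
#' @param ld_r2 within-block r-squared.
#' @param seed RNG seed used by [simulate_study] (may be overridden there).
#' @return list of class `truth_config`. The implied proportion mediated
#'   `theta_xm * theta_my / (theta_xm * theta_my + theta_direct)` is
#'   available from [implied_proportion_mediated].
#' @export
truth_config <- function(J = 100, J_med = J, maf_range = c(0.1, 0.4),
                         gamma_dist = list(kind = "uniform_mag",
                                           min = 0.02, max = 0.045),
                         delta_dist = gamma_dist,
                         theta_xm = 0, theta_my = 0, theta_direct = 0,
                         pleiotropy = list(mode = "none", mean = 0.003,
                                           sd = 0.002, fraction = 0.3,
                                           corr_scale = 0.15),
                         n_exp = 700000, n_med = 700000, n_out = 240000,
                         n_outliers = 0, outlier_offset = 0,
                         ld_block_size = 1, ld_r2 = 0.9, seed = NA_integer_) {
  if (maf_range[1] <= 0 || maf_range[2] >= 1 || maf_range[1] > maf_range[2]) {
    stopf("truth_config: maf_range must lie strictly inside (0, 1)",
          class = "mr_config_error")
  }
  pl_default <- list(mode = "none", mean = 0.003, sd = 0.002, fraction = 0.3,
                     corr_scale = 0.15)
  pleiotropy <- utils::modifyList(pl_default, pleiotropy)
  if (!pleiotropy$mode %in% c("none", "balanced", "directional", "correlated")) {
    stopf("truth_config: unknown pleiotropy mode '%s'", pleiotropy$mode,
          class = "mr_config_error")
  }
  structure(list(J = J, J_med = J_med, maf_range = maf_range,
                 gamma_dist = gamma_dist, delta_dist = delta_dist,
                 theta_xm = theta_xm, theta_my = theta_my,
                 theta_direct = theta_direct, pleiotropy = pleiotropy,
                 n_exp = n_exp, n_med = n_med, n_out = n_out,
                 n_outliers = n_outliers, outlier_offset = outlier_offset,
                 ld_block_size = ld_block_size, ld_r2 = ld_r2, seed = seed),
            class = "truth_config")
}

#' Proportion mediated implied by a truth configuration
#'
#' @param cfg a `truth_config`.
#' @return `theta_xm * theta_my / (theta_xm * theta_my + theta_direct)`;
#'   `NA` when the total effect is zero.
#' @export
implied_proportion_mediated <- function(cfg) {
  tot <- cfg$theta_xm * cfg$theta_my + cfg$theta_direct
  if (tot == 0) return(NA_real_)
  cfg$theta_xm * cfg$theta_my / tot
}

.draw_effects <- function(n, dist) {
  if (identical(dist$kind, "uniform_mag")) {
    stats::runif(n, dist$min, dist$max) * sample(c(-1, 1), n, replace = TRUE)
  } else if (identical(dist$kind, "normal")) {
    stats::rnorm(n, 0, dist$sd)
  } else {
    stopf("unknown effect distribution kind '%s'", dist$kind,
          class = "mr_config_error")
  }
}

#' Simulate a three-trait two-sample GWAS study
#'
#' Generates summary statistics for an exposure, a mediator and a binary
#' outcome under the mediation model of a [truth_config]. Per lead variant
#' j: gamma_j (exposure effect) or delta_j (mediator-specific effect) is
#' drawn from the configured distribution; the true mediator effect is
#' `theta_xm * gamma_j + delta_j` and the true outcome effect (log-odds) is
#' `theta_direct * gamma_j + theta_my * b_Mj + alpha_j`, with alpha the
#' pleiotropic component. Observed betas add independent normal noise per
#' study (the three samples are non-overlapping) with standard errors from
#' the standard approximation `se = 1 / sqrt(2 * maf * (1 - maf) * n)`.
#' Planted outliers receive an extra outcome offset of `outlier_offset`
#' outcome-SEs. With `ld_block_size > 1` each lead variant is replicated
#' into a block of tags whose true effects are scaled by `r = sqrt(ld_r2)`
#' and whose noise shares the lead's noise with correlation `r`.
#'
#' @param cfg a [truth_config].
#' @param seed RNG seed; overrides `cfg$seed`. One of the two must be set.
#' @return list of class `synthetic_study`: `exposure`, `mediator`,
#'   `outcome` ([summary_stats]), `ld` ([ld_info]), `truth` (per-variant
#'   data.frame with gamma, delta, alpha, true betas and outlier flag) and
#'   the `config` echo.
#' @export
simulate_study <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "truth_config"))
  if (is.na(seed)) {
    stopf("simulate_study: a seed is required", class = "mr_usage_error")
  }
  cfg$seed <- as.integer(seed)
  withr_seed(cfg$seed, {
    n_lead <- cfg$J + cfg$J_med
    gamma <- c(.draw_effects(cfg$J, cfg$gamma_dist), rep(0, cfg$J_med))
    delta <- c(rep(0, cfg$J), .draw_effects(cfg$J_med, cfg$delta_dist))
    # pleiotropic outcome effects
    alpha <- rep(0, n_lead)
    pl <- cfg$pleiotropy
    if (pl$mode != "none") {
      affected <- stats::runif(n_lead) < pl$fraction
      if (pl$mode == "balanced") {
        alpha[affected] <- stats::rnorm(sum(affected), 0, pl$sd)
      } else if (pl$mode == "directional") {
        alpha[affected] <- stats::rnorm(sum(affected), pl$mean, pl$sd)
      } else { # correlated: alpha tracks gamma, violating InSIDE
        alpha[affected] <- pl$corr_scale * gamma[affected] +
          stats::rnorm(sum(affected), 0, pl$sd / 2)
      }
    }
    bm_true <- cfg$theta_xm * gamma + delta
    by_true <- cfg$theta_direct * gamma + cfg$theta_my * bm_true + alpha

    # expand lead variants into LD blocks
    B <- max(1L, as.integer(cfg$ld_block_size))
    r <- if (B > 1L) sqrt(cfg$ld_r2) else 0
    lead_of <- rep(seq_len(n_lead), each = B)
    tag_in_block <- rep(seq_len(B), times = n_lead)
    M <- length(lead_of)
    scale_tag <- ifelse(tag_in_block == 1L, 1, r)
    maf <- stats::runif(M, cfg$maf_range[1], cfg$maf_range[2])
    bx_true <- gamma[lead_of] * scale_tag
    bm_true_v <- bm_true[lead_of] * scale_tag
    by_true_v <- by_true[lead_of] * scale_tag

    ids <- sprintf("rs%05d", seq_len(M))
    chrom <- as.character((lead_of - 1L) %% 22L + 1L)
    pos <- 1000000L + lead_of * 10000L + tag_in_block

    noisy <- function(truth, n_study) {
      se <- 1 / sqrt(2 * maf * (1 - maf) * n_study)
      z_lead <- stats::rnorm(n_lead)
      z_tag <- stats::rnorm(M)
      z <- ifelse(tag_in_block == 1L, z_lead[lead_of],
                  r * z_lead[lead_of] + sqrt(1 - r^2) * z_tag)
      beta <- truth + se * z
      list(beta = beta, se = se)
    }
    ox <- noisy(bx_true, cfg$n_exp)
    om <- noisy(bm_true_v, cfg$n_med)
    oy <- noisy(by_true_v, cfg$n_out)

    outlier <- rep(FALSE, M)
    if (cfg$n_outliers > 0) {
      lead_x <- which(lead_of <= cfg$J & tag_in_block == 1L)
      chosen <- sample(lead_x, min(cfg$n_outliers, length(lead_x)))
      outlier[chosen] <- TRUE
      oy$beta[chosen] <- oy$beta[chosen] + cfg$outlier_offset * oy$se[chosen]
    }

    alleles <- c("A", "C", "G", "T")
    ea <- sample(alleles, M, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), character(1))

    mk <- function(obs, trait_id, trait_type, unit_label) {
      summary_stats(data.frame(
        variant_id = ids, chrom = chrom, pos = pos,
        effect_allele = ea, other_allele = oa, eaf = maf,
        beta = obs$beta, se = obs$se, pval = z_pval(obs$beta, obs$se),
        n = switch(trait_id, exposure = cfg$n_exp, mediator = cfg$n_med,
                   cfg$n_out),
        stringsAsFactors = FALSE),
        trait_id = trait_id, trait_type = trait_type,
        unit_label = unit_label)
    }
    pairs <- NULL
    if (B > 1L) {
      pairs <- do.call(rbind, lapply(seq_len(n_lead), function(l) {
        members <- ids[lead_of == l]
        idx <- t(utils::combn(members, 2))
        data.frame(id_a = idx[, 1], id_b = idx[, 2], r2 = cfg$ld_r2,
                   stringsAsFactors = FALSE)
      }))
    }
    structure(list(
      exposure = mk(ox, "exposure", "quantitative", "SD"),
      mediator = mk(om, "mediator", "quantitative", "SD"),
      outcome = mk(oy, "outcome", "binary", "logOR"),
      ld = ld_info(pairs %||% data.frame(id_a = character(),
                                         id_b = character(),
                                         r2 = numeric())),
      truth = data.frame(
        variant_id = ids, lead = lead_of, maf = maf,
        gamma = gamma[lead_of] * scale_tag, delta = delta[lead_of] * scale_tag,
        alpha = alpha[lead_of] * scale_tag,
        bx_true = bx_true, bm_true = bm_true_v, by_true = by_true_v,
        outlier = outlier, stringsAsFactors = FALSE),
      config = cfg), class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d variants; theta_xm=%.3g theta_my=%.3g theta_direct=%.3g; pleiotropy=%s; seed=%d\n",
              nrow(x$truth), x$config$theta_xm, x$config$theta_my,
              x$config$theta_direct, x$config$pleiotropy$mode,
              x$config$seed))
  invisible(x)
}

#' Named suite of benchmark scenarios
#'
#' Ready-made [truth_config]s exercising the estimator assumptions:
#' \describe{
#'   \item{null}{exposure instruments only, no effect on the outcome.}
#'   \item{causal}{direct effect 0.2, no mediation, no pleiotropy.}
#'   \item{mediation_half}{theta_xm = 0.5, theta_my = 0.4,
#'     theta_direct = 0.2: implied proportion mediated 0.5.}
#'   \item{balanced_pleiotropy}{causal plus zero-mean pleiotropy.}
#'   \item{directional_pleiotropy}{causal plus mean-shifted pleiotropy
#'     (InSIDE holds).}
#'   \item{correlated_pleiotropy}{causal plus pleiotropy proportional to
#'     the instrument effects (InSIDE violated).}
#'   \item{one_outlier}{causal plus one variant offset by 10 outcome-SEs.}
#'   \item{weak_instruments}{small normal instrument effects giving mean
#'     F below 10.}
#'   \item{ld_blocks}{mediation_half with 4-variant LD blocks at
#'     r-squared 0.9, for clumping tests.}
#' }
#'
#' @return named list of `truth_config` objects (seeds unset; supply one to
#'   [simulate_study]).
#' @export
scenario_suite <- function() {
  list(
    null = truth_config(theta_xm = 0.5),
    causal = truth_config(theta_direct = 0.2),
    mediation_half = truth_config(theta_xm = 0.5, theta_my = 0.4,
                                  theta_direct = 0.2),
    balanced_pleiotropy = truth_config(theta_direct = 0.2,
      pleiotropy = list(mode = "balanced", sd = 0.003, fraction = 0.3)),
    directional_pleiotropy = truth_config(theta_direct = 0.2,
      pleiotropy = list(mode = "directional", mean = 0.003, sd = 0.001,
                        fraction = 1)),
    correlated_pleiotropy = truth_config(theta_direct = 0.2,
      pleiotropy = list(mode = "correlated", corr_scale = 0.15, sd = 0.002,
                        fraction = 0.5)),
    one_outlier = truth_config(theta_direct = 0.2, n_outliers = 1,
                               outlier_offset = 10),
    weak_instruments = truth_config(theta_direct = 0.2,
      gamma_dist = list(kind = "normal", sd = 0.002),
      delta_dist = list(kind = "normal", sd = 0.002)),
    ld_blocks = truth_config(theta_xm = 0.5, theta_my = 0.4,
                             theta_direct = 0.2, ld_block_size = 4,
                             ld_r2 = 0.9)
  )
}

#' Write a synthetic study to disk
#'
#' Writes `exposure.tsv`, `mediator.tsv`, `outcome.tsv`, `ld.tsv` and
#' `truth.tsv` (all plain TSV, directly consumable by [read_gwas] and
#' [read_ld]) plus `config.json`. Output is byte-identical for identical
#' configuration and seed.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gwas(study$exposure, file.path(dir, "exposure.tsv"))
  write_gwas(study$mediator, file.path(dir, "mediator.tsv"))
  write_gwas(study$outcome, file.path(dir, "outcome.tsv"))
  write_ld(study$ld, file.path(dir, "ld.tsv"))
  utils::write.table(study$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- study$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
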