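#' Instrument strength diagnostics
#'
#' Per-variant F statistic and variance explained for a set of instrument
#' variants. The F statistic uses the single-variant summary-data
#' approximation `F = (beta/se)^2`. Variance explained defaults to
#' `R2 = 2 * eaf * (1 - eaf) * beta^2`, valid when the trait is
#' variance-standardised; when `eaf` is unavailable the fallback
#' `R2 = F / (F + n - 2)` is used. When both `eaf` and `n` are missing only
#' F is reported, with a warning.
#'
#' @param variant_ids instrument variant identifiers.
#' @param stats [summary_stats] for the exposure the instruments act on.
#' @return data.frame with `variant_id`, `beta`, `se`, `pval`, `eaf`, `n`,
#'   `F`, `r2`, `r2_formula`, `weak` (F <= 10 flag); totals as attributes
#'   `mean_F` and `total_r2`.
#' @export
instrument_strength <- function(variant_ids, stats) {
  stopifnot(inherits(stats, "summary_stats"))
  v <- stats$variants
  v <- v[match(variant_ids, v$variant_id), , drop = FALSE]
  if (anyNA(v$variant_id)) {
    stopf("instrument_strength: %d variant(s) absent from trait '%s'",
          sum(is.na(v$variant_id)), stats$trait_id, class = "mr_usage_error")
  }
  Fstat <- (v$beta / v$se)^2
  r2 <- ifelse(!is.na(v$eaf), 2 * v$eaf * (1 - v$eaf) * v$beta^2,
               ifelse(!is.na(v$n), Fstat / (Fstat + v$n - 2), NA_real_))
  r2_formula <- ifelse(!is.na(v$eaf), "2p(1-p)b2",
                       ifelse(!is.na(v$n), "F/(F+n-2)", NA_character_))
  if (all(is.na(r2)) && nrow(v) > 0) {
    warnf("instrument_strength[%s]: eaf and n both missing; reporting F only",
          stats$trait_id, class = "mr_strength_unavailable")
  }
  out <- data.frame(variant_id = v$variant_id, beta = v$beta, se = v$se,
                    pval = v$pval, eaf = v$eaf, n = v$n, F = Fstat, r2 = r2,
                    r2_formula = r2_formula, weak = Fstat <= 10,
                    stringsAsFactors = FALSE)
  attr(out, "mean_F") <- mean(Fstat)
  attr(out, "total_r2") <- if (all(is.na(r2))) NA_real_ else sum(r2, na.rm = TRUE)
  out
}

.greedy_clump <- function(ids, pvals, ld, r2_threshold) {
  ord <- order(pvals, ids)  # ties broken by ascending variant_id
  ids <- ids[ord]
  kept <- character(0)
  while (length(ids)) {
    lead <- ids[1]
    kept <- c(kept, lead)
    ids <- ids[-1]
    if (length(ids)) {
      ids <- ids[ld_r2(ld, lead, ids) < r2_threshold]
    }
  }
  kept
}

#' Select genetic instruments by significance and greedy LD clumping
#'
#' Variants passing the genome-wide significance threshold are greedily
#' clumped: repeatedly keep the variant with the smallest p-value and remove
#' all remaining variants in LD with it at or above `r2_threshold`. Equal
#' p-values are broken by ascending variant identifier so clumping is
#' deterministic.
#'
#' @param stats [summary_stats] for the exposure.
#' @param p_threshold selection threshold (default genome-wide, 5e-8).
#' @param ld an [ld_info] object, or `NULL` for no LD.
#' @param r2_threshold clumping threshold (default 0.001).
#' @return An object of class `instrument_set`: the [instrument_strength]
#'   data.frame of survivors, ordered by p-value, with attributes `trait_id`,
#'   `mean_F`, `total_r2`. Instruments with F <= 10 are flagged in the `weak`
#'   column (and a warning is emitted), not dropped.
#' @export
select_instruments <- function(stats, p_threshold = 5e-8, ld = NULL,
                               r2_threshold = 0.001) {
  stopifnot(inherits(stats, "summary_stats"))
  v <- stats$variants
  pass <- v$pval < p_threshold
  if (!any(pass)) {
    stopf("select_instruments: no variant passes p < %g for trait '%s'",
          p_threshold, stats$trait_id, class = "mr_empty_instruments")
  }
  kept <- .greedy_clump(v$variant_id[pass], v$pval[pass], ld, r2_threshold)
  out <- instrument_strength(kept, stats)
  if (any(out$weak)) {
    warnf("select_instruments[%s]: %d instrument(s) with F <= 10 (flagged, kept)",
          stats$trait_id, sum(out$weak), class = "mr_weak_instruments")
  }
  attr(out, "trait_id") <- stats$trait_id
  class(out) <- c("instrument_set", "data.frame")
  out
}

#' Pool and clump instruments across multiple exposures
#'
#' For multivariable MR: the union of variants passing the significance
#' threshold in any of the exposures is clumped as in [select_instruments].
#' The clumping rank statistic is each variant's minimum p-value across the
#' pooled exposures (the rank statistic is recorded in the output).
#'
#' @param exposure_tables list of two or more [summary_stats] objects.
#' @inheritParams select_instruments
#' @return An object of class `instrument_set`: data.frame with
#'   `variant_id`, `pval` (the minimum across exposures) and one logical
#'   `sig_<trait>` column per exposure; attribute `rank_statistic` is
#'   `"min_p_across_exposures"`.
#' @export
pool_for_mvmr <- function(exposure_tables, p_threshold = 5e-8, ld = NULL,
                          r2_threshold = 0.001) {
  if (!is.list(exposure_tables) || length(exposure_tables) < 2L) {
    stopf("pool_for_mvmr: need >= 2 exposure tables", class = "mr_usage_error")
  }
  for (t in exposure_tables) stopifnot(inherits(t, "summary_stats"))
  trait_ids <- vapply(exposure_tables, function(t) t$trait_id, character(1))
  sig_ids <- lapply(exposure_tables, function(t) {
    t$variants$variant_id[t$variants$pval < p_threshold]
  })
  pooled <- unique(unlist(sig_ids))
  if (length(pooled) == 0L) {
    stopf("pool_for_mvmr: no variant passes p < %g in any of: %s",
          p_threshold, paste(trait_ids, collapse = ", "),
          class = "mr_empty_instruments")
  }
  minp <- vapply(pooled, function(id) {
    min(vapply(exposure_tables, function(t) {
      i <- match(id, t$variants$variant_id)
      if (is.na(i)) Inf else t$variants$pval[i]
    }, numeric(1)))
  }, numeric(1))
  kept <- .greedy_clump(pooled, minp, ld, r2_threshold)
  out <- data.frame(variant_id = kept, pval = minp[match(kept, pooled)],
                    stringsAsFactors = FALSE)
  for (k in seq_along(trait_ids)) {
    out[[paste0("sig_", trait_ids[k])]] <- kept %in% sig_ids[[k]]
  }
  out <- out[order(out$pval, out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trait_id") <- paste(trait_ids, collapse = "+")
  attr(out, "rank_statistic") <- "min_p_across_exposures"
  class(out) <- c("instrument_set", "data.frame")
  out
}

#' Write an instrument set as TSV
#'
#' @param x an `instrument_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_instruments <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
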