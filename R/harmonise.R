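#' Harmonise summary statistics across traits
#'
#' Aligns two or more [summary_stats] tables to a shared per-variant effect
#' allele. The first table defines the reference orientation; by convention
#' the exposure(s) come first and the outcome last. Only variants present in
#' every table are retained (no proxy substitution). For each non-reference
#' table a variant is kept as-is when its allele pair matches the reference,
#' has its beta negated (and eaf complemented) when effect and other allele
#' are swapped, and is dropped (with a logged count) when the allele letters
#' match neither orientation. Palindromic variants (A/T, C/G) are aligned by
#' allele letters exactly like any other variant — no frequency-based
#' orientation check and no exclusion.
#'
#' @param tables list of two or more [summary_stats] objects.
#' @return An object of class `harmonised_set`: list with `traits`,
#'   `trait_types`, `unit_labels`, `variant_ids`, `effect_allele`,
#'   `other_allele`, and variants-by-traits matrices `beta`, `se`, `eaf`,
#'   `pval`. Variants dropped for allele mismatch are counted in
#'   `attr(x, "n_dropped_mismatch")`.
#' @export
harmonise <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L) {
    stopf("harmonise: need a list of >= 2 summary_stats tables",
          class = "mr_usage_error")
  }
  for (t in tables) stopifnot(inherits(t, "summary_stats"))
  ids <- Reduce(intersect, lapply(tables, function(t) t$variants$variant_id))
  if (length(ids) == 0L) {
    stopf("harmonise: no variants shared by all tables",
          class = "mr_empty_input")
  }
  ref <- tables[[1]]$variants
  ref <- ref[match(ids, ref$variant_id), , drop = FALSE]
  K <- length(tables)
  beta <- se <- eaf <- pval <- matrix(NA_real_, length(ids), K)
  keep <- rep(TRUE, length(ids))
  n_mismatch <- 0L
  for (k in seq_len(K)) {
    tv <- tables[[k]]$variants
    tv <- tv[match(ids, tv$variant_id), , drop = FALSE]
    same <- tv$effect_allele == ref$effect_allele &
      tv$other_allele == ref$other_allele
    swapped <- tv$effect_allele == ref$other_allele &
      tv$other_allele == ref$effect_allele
    beta[, k] <- ifelse(same, tv$beta, ifelse(swapped, -tv$beta, NA_real_))
    se[, k] <- tv$se
    eaf[, k] <- ifelse(same, tv$eaf, ifelse(swapped, 1 - tv$eaf, NA_real_))
    pval[, k] <- tv$pval
    bad <- !(same | swapped)
    n_mismatch <- n_mismatch + sum(bad & keep)
    keep <- keep & !bad
  }
  if (!any(keep)) {
    stopf("harmonise: all shared variants dropped for allele mismatch",
          class = "mr_empty_input")
  }
  if (n_mismatch > 0) {
    message(sprintf("harmonise: dropped %d variant(s) with incompatible alleles",
                    n_mismatch))
  }
  trait_ids <- vapply(tables, function(t) t$trait_id, character(1))
  dimn <- list(ids[keep], trait_ids)
  out <- structure(
    list(traits = trait_ids,
         trait_types = vapply(tables, function(t) t$trait_type, character(1)),
         unit_labels = vapply(tables, function(t) t$unit_label, character(1)),
         variant_ids = ids[keep],
         effect_allele = ref$effect_allele[keep],
         other_allele = ref$other_allele[keep],
         beta = structure(beta[keep, , drop = FALSE], dimnames = dimn),
         se = structure(se[keep, , drop = FALSE], dimnames = dimn),
         eaf = structure(eaf[keep, , drop = FALSE], dimnames = dimn),
         pval = structure(pval[keep, , drop = FALSE], dimnames = dimn)),
    class = "harmonised_set")
  attr(out, "n_dropped_mismatch") <- n_mismatch
  out
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat(sprintf("<harmonised_set> %d variants x %d traits (%s)\n",
              length(x$variant_ids), length(x$traits),
              paste(x$traits, collapse = ", ")))
  invisible(x)
}

#' Restrict a harmonised set to a subset of variants
#'
#' @param h a `harmonised_set`.
#' @param variant_ids identifiers to keep (order preserved from `h`).
#' @return A `harmonised_set` with only the requested variants.
#' @export
subset_harmonised <- function(h, variant_ids) {
  stopifnot(inherits(h, "harmonised_set"))
  keep <- h$variant_ids %in% variant_ids
  if (!any(keep)) {
    stopf("subset_harmonised: no requested variants present",
          class = "mr_empty_input")
  }
  h$variant_ids <- h$variant_ids[keep]
  h$effect_allele <- h$effect_allele[keep]
  h$other_allele <- h$other_allele[keep]
  for (m in c("beta", "se", "eaf", "pval")) h[[m]] <- h[[m]][keep, , drop = FALSE]
  h
}
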