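#' GWAS summary statistics for one trait
#'
#' Container for per-variant association estimates from a single GWAS:
#' variant identifiers, alleles, effect-allele frequency, effect size on the
#' trait scale (log-odds for binary traits), its standard error, p-value and
#' sample size. This is the unit of input to harmonisation and instrument
#' selection.
#'
#' Validation drops (with a logged count) rows with non-positive standard
#' errors, missing or identical alleles, out-of-range frequencies or
#' duplicated variant identifiers. Reported p-values grossly inconsistent
#' with `2 * pnorm(-|beta/se|)` are flagged with a warning but retained,
#' since published GWAS round and truncate p-values.
#'
#' @param variants data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval` and optionally `chrom`, `pos`
#'   (1-based), `eaf`, `n`.
#' @param trait_id short label for the trait (e.g. `"SBP"`).
#' @param trait_type `"quantitative"` or `"binary"`; binary traits are
#'   interpreted on the log-odds scale.
#' @param unit_label free-text unit of `beta` (e.g. `"mmHg"`, `"SD"`,
#'   `"logOR"`).
#'
#' @return An object of class `summary_stats`: a list with elements
#'   `trait_id`, `trait_type`, `unit_label` and `variants` (the validated
#'   data.frame). The number of rows removed during validation is available
#'   as `attr(x, "n_dropped")`.
#' @export
summary_stats <- function(variants, trait_id,
                          trait_type = c("quantitative", "binary"),
                          unit_label = "SD") {
  trait_type <- match.arg(trait_type)
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    stopf("summary_stats: missing required column(s): %s",
          paste(missing_cols, collapse = ", "), class = "mr_config_error")
  }
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  v$variant_id <- as.character(v$variant_id)
  v$effect_allele <- toupper(as.character(v$effect_allele))
  v$other_allele <- toupper(as.character(v$other_allele))
  for (col in c("beta", "se", "pval")) v[[col]] <- as.numeric(v[[col]])
  if (!"eaf" %in% names(v)) v$eaf <- NA_real_ else v$eaf <- as.numeric(v$eaf)
  if (!"n" %in% names(v)) v$n <- NA_real_ else v$n <- as.numeric(v$n)
  if (!"chrom" %in% names(v)) v$chrom <- NA_character_
  if (!"pos" %in% names(v)) v$pos <- NA_integer_

  n_in <- nrow(v)
  ok <- !is.na(v$variant_id) & nzchar(v$variant_id) &
    !is.na(v$beta) & !is.na(v$se) & v$se > 0 &
    !is.na(v$effect_allele) & nzchar(v$effect_allele) &
    !is.na(v$other_allele) & nzchar(v$other_allele) &
    v$effect_allele != v$other_allele &
    !is.na(v$pval) & v$pval > 0 & v$pval <= 1 &
    (is.na(v$eaf) | (v$eaf > 0 & v$eaf < 1))
  v <- v[ok, , drop = FALSE]
  v <- v[!duplicated(v$variant_id), , drop = FALSE]
  n_dropped <- n_in - nrow(v)
  if (nrow(v) == 0L) {
    stopf("summary_stats: no valid rows for trait '%s'", trait_id,
          class = "mr_empty_input")
  }
  if (n_dropped > 0) {
    message(sprintf("summary_stats[%s]: dropped %d of %d rows during validation",
                    trait_id, n_dropped, n_in))
  }
  # consistency check between reported p and |beta/se| (log10 scale, generous
  # band: published p-values are rounded, truncated or taken from other tests)
  z_p <- z_pval(v$beta, v$se)
  bad <- abs(log10(z_p) - log10(v$pval)) > 2 & (v$pval < 0.99 | z_p < 0.99)
  if (any(bad, na.rm = TRUE)) {
    warnf("summary_stats[%s]: %d p-value(s) inconsistent with beta/se",
          trait_id, sum(bad, na.rm = TRUE), class = "mr_pval_inconsistent")
  }
  rownames(v) <- NULL
  out <- structure(
    list(trait_id = trait_id, trait_type = trait_type,
         unit_label = unit_label,
         variants = v[, c("variant_id", "chrom", "pos", "effect_allele",
                          "other_allele", "eaf", "beta", "se", "pval", "n")]),
    class = "summary_stats")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> trait '%s' (%s, unit %s): %d variants\n",
              x$trait_id, x$trait_type, x$unit_label, nrow(x$variants)))
  invisible(x)
}

.default_column_map <- list(
  variant_id = c("variant_id", "SNP", "snp", "rsid", "rsID", "ID", "MarkerName"),
  chrom = c("chrom", "CHR", "chr", "chromosome"),
  pos = c("pos", "BP", "position", "base_pair_location"),
  effect_allele = c("effect_allele", "EA", "A1", "ALT", "allele1"),
  other_allele = c("other_allele", "OA", "A2", "REF", "allele2"),
  eaf = c("eaf", "EAF", "effect_allele_frequency", "FRQ", "af"),
  beta = c("beta", "BETA", "b", "Effect"),
  se = c("se", "SE", "StdErr", "standard_error"),
  pval = c("pval", "P", "p", "p_value", "pvalue", "P-value"),
  n = c("n", "N", "sample_size", "Neff")
)

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or comma-separated file with a header (gzip accepted) into a
#' validated [summary_stats] object. Column names are resolved through
#' `column_map`, falling back to a built-in list of names commonly used by
#' GWAS consortia.
#'
#' @param path path to the file.
#' @param column_map named list/character vector mapping canonical field
#'   names (`variant_id`, `effect_allele`, `other_allele`, `beta`, `se`,
#'   `pval`, and optionally `chrom`, `pos`, `eaf`, `n`) to the column names
#'   used in the file.
#' @param trait_id,trait_type,unit_label trait metadata passed to
#'   [summary_stats].
#' @return A [summary_stats] object.
#' @export
read_gwas <- function(path, column_map = NULL, trait_id = basename(path),
                      trait_type = c("quantitative", "binary"),
                      unit_label = "SD") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) {
    stopf("read_gwas: file not found: %s", path, class = "mr_config_error")
  }
  header <- readLines(path, n = 1L)  # file() decompresses gz transparently
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pval")
  optional <- c("chrom", "pos", "eaf", "n")
  out <- list()
  for (field in c(required, optional)) {
    candidates <- c(as.character(column_map[[field]] %||% character()),
                    .default_column_map[[field]])
    hit <- candidates[candidates %in% names(raw)][1]
    if (!is.na(hit)) {
      out[[field]] <- raw[[hit]]
    } else if (field %in% required) {
      stopf("read_gwas: cannot resolve required column '%s' in %s",
            field, path, class = "mr_config_error")
    }
  }
  summary_stats(as.data.frame(out, stringsAsFactors = FALSE),
                trait_id = trait_id, trait_type = trait_type,
                unit_label = unit_label)
}

#' Write a summary_stats object to TSV
#'
#' @param x a [summary_stats] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(x, path) {
  stopifnot(inherits(x, "summary_stats"))
  utils::write.table(x$variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
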