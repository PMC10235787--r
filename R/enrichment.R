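#' Read a pathway database in GMT format
#'
#' One pathway per line: identifier, description, then member genes, all
#' tab-separated. The testing universe is the union of all member genes.
#'
#' @param path path to a GMT file.
#' @return list of class `pathway_db` with `pathways` (named list of gene
#'   vectors), `names` (named descriptions) and `universe`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stopf("read_gmt: file not found: %s", path, class = "mr_config_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    stopf("read_gmt: %d line(s) with fewer than 3 fields", sum(bad),
          class = "mr_config_error")
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  descs <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- ids
  structure(list(pathways = sets,
                 names = stats::setNames(descs, ids),
                 universe = unique(unlist(sets))),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("<pathway_db> %d pathways, %d genes in universe\n",
              length(x$pathways), length(x$universe)))
  invisible(x)
}

#' Read a variant-to-gene cis-eQTL table
#'
#' @param path TSV with columns `variant_id`, `gene_id`, `tissue`, `qval`.
#' @return data.frame of class `eqtl_table`; duplicated
#'   (variant, gene, tissue) records are collapsed to their smallest q-value.
#' @export
read_eqtl <- function(path) {
  if (!file.exists(path)) {
    stopf("read_eqtl: file not found: %s", path, class = "mr_config_error")
  }
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("variant_id", "gene_id", "tissue", "qval")
  if (!all(need %in% names(raw))) {
    stopf("read_eqtl: need columns %s", paste(need, collapse = ", "),
          class = "mr_config_error")
  }
  raw <- raw[order(raw$qval), need]
  raw <- raw[!duplicated(raw[, c("variant_id", "gene_id", "tissue")]), ]
  rownames(raw) <- NULL
  class(raw) <- c("eqtl_table", "data.frame")
  raw
}

#' Map instrument variants to cis-eQTL genes
#'
#' Returns the unique genes whose expression is associated (q-value below
#' threshold) with any instrument variant. By default evidence is pooled
#' across tissues ("any tissue" rule); restrict with `tissue`.
#'
#' @param instruments an `instrument_set` or character vector of variant
#'   identifiers.
#' @param eqtl an `eqtl_table` (or data.frame with the same columns).
#' @param q_threshold significance threshold on the eQTL q-value
#'   (default 0.05).
#' @param tissue optional tissue label to restrict to.
#' @return character vector of gene identifiers; per-gene provenance (which
#'   variant and tissue supplied the evidence) in
#'   `attr(x, "provenance")`. An empty result triggers a warning, not an
#'   error.
#' @export
map_eqtl_genes <- function(instruments, eqtl, q_threshold = 0.05,
                           tissue = NULL) {
  ids <- if (is.character(instruments)) instruments else instruments$variant_id
  e <- as.data.frame(eqtl)
  hit <- e$variant_id %in% ids & e$qval < q_threshold
  if (!is.null(tissue)) hit <- hit & e$tissue %in% tissue
  prov <- e[hit, c("gene_id", "variant_id", "tissue", "qval")]
  genes <- unique(prov$gene_id)
  if (length(genes) == 0L) {
    warnf("map_eqtl_genes: no instrument maps to a significant cis-eQTL",
          class = "mr_empty_gene_set")
  }
  structure(genes, provenance = prov)
}

#' Pathway over-representation analysis
#'
#' One-sided hypergeometric test per pathway: with `N` genes in the
#' universe, `K` of them in the pathway and a query of `n` genes (after
#' intersection with the universe), the p-value is `P(X >= k)` for the
#' observed overlap `k`, i.e. Fisher's exact test on the 2x2 table.
#' P-values are Benjamini-Hochberg adjusted across all tested pathways;
#' significance is called at FDR < `fdr`.
#'
#' @param genes character vector of query genes.
#' @param db a `pathway_db` from [read_gmt].
#' @param fdr FDR significance level (default 0.05).
#' @param include_zero_overlap report pathways with no overlap (p = 1)?
#'   Default `FALSE`.
#' @return data.frame with `pathway_id`, `name`, `k`, `K`, `n`, `N`,
#'   `pval`, `fdr`, `significant`, `genes` (comma-separated overlap),
#'   ordered by p-value.
#' @export
ora <- function(genes, db, fdr = 0.05, include_zero_overlap = FALSE) {
  stopifnot(inherits(db, "pathway_db"))
  query <- intersect(unique(genes), db$universe)
  N <- length(db$universe)
  n <- length(query)
  if (n == 0L) {
    warnf("ora: empty query after universe intersection",
          class = "mr_empty_gene_set")
    return(data.frame(pathway_id = character(), name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), pval = numeric(), fdr = numeric(),
                      significant = logical(), genes = character(),
                      stringsAsFactors = FALSE))
  }
  res <- lapply(names(db$pathways), function(pid) {
    set <- db$pathways[[pid]]
    ov <- intersect(query, set)
    k <- length(ov); K <- length(set)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = pid, name = unname(db$names[pid]), k = k, K = K,
               n = n, N = N, pval = p,
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (!include_zero_overlap) res <- res[res$k > 0, , drop = FALSE]
  res$fdr <- stats::p.adjust(res$pval, method = "BH")
  res$significant <- res$fdr < fdr
  res <- res[order(res$pval, res$pathway_id),
             c("pathway_id", "name", "k", "K", "n", "N", "pval", "fdr",
               "significant", "genes")]
  rownames(res) <- NULL
  res
}

#' Attach drugs to significantly enriched pathways
#'
#' Left-joins a pathway-to-drug annotation table onto the FDR-significant
#' rows of an [ora] result and groups drugs by ATC class. Non-significant
#' pathways are never annotated. Drug-map rows referring to pathways absent
#' from the results are logged and skipped.
#'
#' @param results an [ora] result data.frame.
#' @param drug_map data.frame (or TSV path) with columns `pathway_id`,
#'   `drug`, `atc_code`.
#' @return `results` with `drugs` and `atc_classes` columns added
#'   (comma-separated; `NA` where not significant or not annotated).
#' @export
annotate_drugs <- function(results, drug_map) {
  if (is.character(drug_map) && length(drug_map) == 1L) {
    drug_map <- utils::read.table(drug_map, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  }
  need <- c("pathway_id", "drug", "atc_code")
  if (!all(need %in% names(drug_map))) {
    stopf("annotate_drugs: drug map needs columns %s",
          paste(need, collapse = ", "), class = "mr_config_error")
  }
  unknown <- setdiff(unique(drug_map$pathway_id), results$pathway_id)
  if (length(unknown)) {
    message(sprintf("annotate_drugs: skipping %d drug-map pathway id(s) not in results",
                    length(unknown)))
  }
  results$drugs <- NA_character_
  results$atc_classes <- NA_character_
  sig <- which(results$significant)
  for (i in sig) {
    rows <- drug_map[drug_map$pathway_id == results$pathway_id[i], , drop = FALSE]
    if (nrow(rows)) {
      rows <- rows[order(rows$atc_code, rows$drug), ]
      results$drugs[i] <- paste(rows$drug, collapse = ",")
      results$atc_classes[i] <- paste(unique(rows$atc_code), collapse = ",")
    }
  }
  results
}
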