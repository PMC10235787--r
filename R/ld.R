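#' Pairwise linkage-disequilibrium information
#'
#' Sparse symmetric store of pairwise r-squared values between variants, as
#' produced by reference-panel tools (e.g. the long-format output of
#' `plink --r2`). A missing pair is interpreted as r-squared 0 — variants on
#' different chromosomes or outside each other's clumping window.
#'
#' @param pairs data.frame with columns `id_a`, `id_b`, `r2` (r2 in [0, 1]).
#'   May be empty, in which case all variants are treated as independent.
#' @return An object of class `ld_info`.
#' @export
ld_info <- function(pairs = data.frame(id_a = character(), id_b = character(),
                                       r2 = numeric())) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("id_a", "id_b", "r2") %in% names(pairs))) {
    stopf("ld_info: need columns id_a, id_b, r2", class = "mr_config_error")
  }
  pairs$id_a <- as.character(pairs$id_a)
  pairs$id_b <- as.character(pairs$id_b)
  pairs$r2 <- as.numeric(pairs$r2)
  if (any(pairs$r2 < 0 | pairs$r2 > 1, na.rm = TRUE)) {
    stopf("ld_info: r2 outside [0, 1]", class = "mr_config_error")
  }
  index <- new.env(parent = emptyenv(), hash = TRUE)
  if (nrow(pairs)) {
    keys <- ifelse(pairs$id_a <= pairs$id_b,
                   paste(pairs$id_a, pairs$id_b, sep = "\r"),
                   paste(pairs$id_b, pairs$id_a, sep = "\r"))
    for (i in seq_along(keys)) assign(keys[i], pairs$r2[i], envir = index)
  }
  structure(list(pairs = pairs, index = index), class = "ld_info")
}

#' @export
print.ld_info <- function(x, ...) {
  cat(sprintf("<ld_info> %d stored pairs (missing pair => r2 = 0)\n",
              nrow(x$pairs)))
  invisible(x)
}

#' Look up pairwise r-squared
#'
#' @param ld an [ld_info] object (or `NULL`, meaning no LD anywhere).
#' @param a,b variant identifiers; `b` may be a vector.
#' @return Numeric vector of r-squared values; a variant with itself is 1,
#'   unstored pairs are 0.
#' @export
ld_r2 <- function(ld, a, b) {
  if (is.null(ld)) return(ifelse(b == a, 1, 0))
  stopifnot(inherits(ld, "ld_info"))
  keys <- ifelse(a <= b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  vals <- unlist(mget(keys, envir = ld$index, ifnotfound = 0), use.names = FALSE)
  vals[b == a] <- 1
  vals
}

#' Read LD information from a file
#'
#' Accepts either long format (three columns: two variant identifiers and an
#' r-squared, or the `plink --r2` dialect with `SNP_A`, `SNP_B`, `R2`
#' columns), or a dense square matrix whose header row and first column hold
#' variant identifiers.
#'
#' @param path path to a TSV/CSV file (gzip accepted).
#' @return An [ld_info] object.
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) {
    stopf("read_ld: file not found: %s", path, class = "mr_config_error")
  }
  header <- readLines(path, n = 1L)  # file() decompresses gz transparently
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(raw)
  if (all(c("SNP_A", "SNP_B", "R2") %in% nm)) {
    return(ld_info(data.frame(id_a = raw$SNP_A, id_b = raw$SNP_B,
                              r2 = raw$R2, stringsAsFactors = FALSE)))
  }
  # square iff the header ids (beyond the first column) repeat the row ids
  square <- ncol(raw) >= 2L && nrow(raw) == ncol(raw) - 1L &&
    identical(nm[-1], as.character(raw[[1]]))
  if (!square && ncol(raw) == 3L) {
    return(ld_info(data.frame(id_a = as.character(raw[[1]]),
                              id_b = as.character(raw[[2]]),
                              r2 = as.numeric(raw[[3]]),
                              stringsAsFactors = FALSE)))
  }
  if (!square) {
    stopf("read_ld: unrecognised LD format in %s", path,
          class = "mr_config_error")
  }
  # dense square matrix: first column = row ids, remaining header = column ids
  ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  idx <- which(upper.tri(mat), arr.ind = TRUE)
  ld_info(data.frame(id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
                     r2 = as.numeric(mat[idx]), stringsAsFactors = FALSE))
}

#' Write LD information as long-format TSV
#'
#' @param ld an [ld_info] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld <- function(ld, path) {
  stopifnot(inherits(ld, "ld_info"))
  utils::write.table(ld$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
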