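`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed mrmediate error
#'
#' @param fmt sprintf format string.
#' @param ... values for `fmt`.
#' @param class condition class in addition to `mrmediate_error`.
#' @noRd
stopf <- function(fmt, ..., class = "mrmediate_error") {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg, class = unique(c(class, "mrmediate_error", "error"))))
}

warnf <- function(fmt, ..., class = "mrmediate_warning") {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  warning(warningCondition(msg, class = unique(c(class, "mrmediate_warning", "warning"))))
}

#' Two-sided normal p-value from an estimate and its standard error
#' @noRd
z_pval <- function(theta, se) {
  p <- 2 * stats::pnorm(-abs(theta / se))
  pmax(p, .Machine$double.xmin)
}

#' Normal 95% confidence limits
#' @noRd
ci95 <- function(theta, se) {
  q <- stats::qnorm(0.975)
  c(theta - q * se, theta + q * se)
}

#' Derive a child RNG seed from a base seed, kept within 32-bit range
#' @noRd
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587L)
}
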