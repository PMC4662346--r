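#' MCMC chain diagnostics
#'
#' Effective sample size (spectral estimate via an AR fit to the chain) and
#' Geweke convergence z-scores (comparing the first 10% to the last 50% of
#' the chain, with spectral variance estimates) for every stored parameter.
#' Parameters with ESS below 100 or |z| above 3 (or undefined diagnostics)
#' are flagged.
#'
#' @param x A [fit_glmm()] result, or a numeric matrix of draws
#'   (iterations x parameters).
#' @return Data frame with columns `parameter`, `ess`, `geweke_z`, `flagged`,
#'   plus an `accept_unit` attribute when `x` is a fitted model.
#' @export
glmm_diagnostics <- function(x) {
  if (inherits(x, "provgall_glmm")) {
    draws <- cbind(x$fixed_draws, x$variance_draws)
    acc <- x$accept_unit
  } else {
    draws <- as.matrix(x)
    acc <- NULL
  }
  if (nrow(draws) < 100) stop("need at least 100 retained draws", call. = FALSE)
  if (is.null(colnames(draws))) colnames(draws) <- paste0("par", seq_len(ncol(draws)))
  res <- do.call(rbind, lapply(colnames(draws), function(nm) {
    v <- draws[, nm]
    data.frame(parameter = nm, ess = .ess(v), geweke_z = .geweke_z(v))
  }))
  res$flagged <- !is.finite(res$ess) | res$ess < 100 |
    !is.finite(res$geweke_z) | abs(res$geweke_z) > 3
  if (!is.null(acc)) attr(res, "accept_unit") <- acc
  res
}

# spectral density of a chain at frequency zero, via an AR fit
.spectrum0 <- function(x) {
  if (stats::var(x) == 0) return(NaN)
  fit <- stats::ar(x, aic = TRUE, order.max = min(30L, length(x) - 1L))
  fit$var.pred / (1 - sum(fit$ar))^2
}

.ess <- function(x) {
  s0 <- .spectrum0(x)
  if (!is.finite(s0) || s0 <= 0) return(NaN)
  length(x) * stats::var(x) / s0
}

.geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  x1 <- x[seq_len(max(2, floor(frac1 * n)))]
  x2 <- x[seq(floor((1 - frac2) * n) + 1, n)]
  s1 <- .spectrum0(x1); s2 <- .spectrum0(x2)
  if (!is.finite(s1) || !is.finite(s2)) return(NaN)
  (mean(x1) - mean(x2)) / sqrt(s1 / length(x1) + s2 / length(x2))
}
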