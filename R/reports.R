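#' pMCMC: posterior sign probability of a coefficient
#'
#' Twice the smaller of the posterior probabilities that the coefficient is
#' positive or negative, floored at `2/n_draws` (the Bayesian analogue of a
#' two-sided p-value).
#'
#' @param draws Numeric vector of posterior draws (>= 100), or a
#'   [fit_glmm()] object together with `term`.
#' @param term Fixed-effect name when `draws` is a fitted model.
#' @return A probability in (0, 1].
#' @export
pmcmc <- function(draws, term = NULL) {
  if (inherits(draws, "provgall_glmm")) {
    stopifnot(!is.null(term), term %in% colnames(draws$fixed_draws))
    draws <- draws$fixed_draws[, term]
  }
  n <- length(draws)
  if (n < 100) stop("need at least 100 draws", call. = FALSE)
  if (all(draws == 0)) stop("degenerate error: all draws exactly zero", call. = FALSE)
  p <- 2 * min(mean(draws > 0), mean(draws < 0))
  max(p, 2 / n)
}

#' Marginal R-squared of a fitted mixed model
#'
#' Proportion of latent-scale variance attributable to the fixed effects,
#' computed per retained draw as
#' `RsqM = var_f / (var_f + sum(sigma2_random) + sigma2_dist)` where `var_f`
#' is the variance of the fixed-effect linear predictor over the
#' observations, the sum runs over every random-effect variance including
#' the UNIT term, and `sigma2_dist` is the distribution-specific variance:
#' 0 for the Gaussian family and the lognormal approximation
#' `log(1/lambda + 1)` with `lambda = exp(beta0 + sum(sigma2)/2)` for the
#' log-link Poisson.
#'
#' @param fit A [fit_glmm()] result.
#' @return List with `draws` (per-draw RsqM), `mean`, `lower`, `upper`
#'   (95% interval).
#' @export
marginal_r2 <- function(fit) {
  stopifnot(inherits(fit, "provgall_glmm"))
  fd <- fit$fixed_draws
  vd <- fit$variance_draws
  X <- fit$X
  var_f <- apply(fd, 1, function(b) stats::var(drop(X %*% b)))
  sum_s2 <- rowSums(vd)
  if (fit$spec$family == "poisson_log") {
    b0 <- if ("(Intercept)" %in% colnames(fd)) fd[, "(Intercept)"] else 0
    lambda <- exp(b0 + sum_s2 / 2)
    s2_dist <- log(1 / lambda + 1)
  } else {
    s2_dist <- 0
  }
  r <- var_f / (var_f + sum_s2 + s2_dist)
  list(draws = r, mean = mean(r),
       lower = unname(stats::quantile(r, 0.025)),
       upper = unname(stats::quantile(r, 0.975)))
}

#' Variance components on the 0-1 scale
#'
#' Computes, per retained draw, the proportion of variance attributed to
#' each random effect: the term's variance divided by the sum of all random
#' effect variances (including the UNIT term), multiplied by the proportion
#' of variance not explained by the fixed effects (1 - RsqM). For a
#' structured provenance term fitted with a nugget, the structured and
#' nugget components are reported both separately and pooled
#' (`<group>_pooled`), since the biological "provenance" signal is their
#' sum.
#'
#' @param fit A [fit_glmm()] result. The Poisson family requires the UNIT
#'   term to be present.
#' @return Object of class `variance_components`: list with `components`
#'   (data frame: term, mean, lower, upper), `rsqm` (as in
#'   [marginal_r2()]), and `draws` (matrix of per-draw components).
#' @export
variance_components <- function(fit) {
  stopifnot(inherits(fit, "provgall_glmm"))
  vd <- fit$variance_draws
  if (fit$spec$family == "poisson_log" && !"unit" %in% colnames(vd))
    stop("contract error: poisson_log model without UNIT term", call. = FALSE)
  r2 <- marginal_r2(fit)
  comp <- vd / rowSums(vd) * (1 - r2$draws)
  # pool structured + nugget pairs
  nug <- grep("_nugget$", colnames(comp), value = TRUE)
  for (nm in nug) {
    base <- sub("_nugget$", "", nm)
    if (base %in% colnames(comp))
      comp <- cbind(comp,
                    stats::setNames(data.frame(comp[, base] + comp[, nm]),
                                    paste0(base, "_pooled")))
  }
  comp <- as.matrix(comp)
  tab <- data.frame(
    term = colnames(comp),
    mean = colMeans(comp),
    lower = apply(comp, 2, stats::quantile, 0.025),
    upper = apply(comp, 2, stats::quantile, 0.975),
    row.names = NULL)
  structure(list(components = tab, rsqm = r2, draws = comp),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, digits = 3, ...) {
  cat("Variance components (proportion of total, per-draw normalised):\n")
  print(format(x$components, digits = digits), row.names = FALSE)
  cat("RsqM:", signif(x$rsqm$mean, digits), "\n")
  invisible(x)
}

#' Variance inflation factors of a fixed-effect design
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from the least-squares
#' regression of column j on all other columns (with intercept).
#'
#' @param X Numeric matrix or data frame of fixed-effect columns; an
#'   `(Intercept)` column is dropped if present.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  if (ncol(X) < 2) stop("need at least two non-intercept columns", call. = FALSE)
  qrX <- qr(cbind(`(Intercept)` = 1, X))
  if (qrX$rank < ncol(X) + 1) {
    kept <- qrX$pivot[seq_len(qrX$rank)]
    aliased <- setdiff(seq_len(ncol(X)) + 1L, kept) - 1L
    stop("aliasing error: rank-deficient design; aliased term(s): ",
         paste(colnames(X)[aliased], collapse = ", "), call. = FALSE)
  }
  v <- vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  names(v) <- colnames(X)
  v
}

#' False-discovery-rate adjustment
#'
#' Step-up adjustment of p-values following Benjamini-Hochberg (`BH`) or the
#' more conservative Benjamini-Yekutieli (`BY`, which multiplies by
#' `sum(1/i)`), with significance flags at `alpha`.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @param method `"BH"` or `"BY"`.
#' @param alpha Significance level for the flags.
#' @return Data frame with `p`, `adjusted`, `significant_raw`,
#'   `significant_adjusted`.
#' @export
fdr_adjust <- function(p, method = c("BH", "BY"), alpha = 0.05) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("domain error: p-values must lie in (0, 1]", call. = FALSE)
  adj <- stats::p.adjust(p, method = method)
  data.frame(p = p, adjusted = adj,
             significant_raw = p < alpha,
             significant_adjusted = adj < alpha)
}

#' Posterior prediction curve for a phenotype effect
#'
#' Expected count as a function of a phenotypic predictor `x`, evaluated per
#' retained draw i as
#' `y_i(x) = exp(intercept_i + x * coef_i [+ x^2 * coef2_i] +
#' 0.5 * sum(random effect variances_i))`
#' (the last term is the lognormal mean correction for the latent random
#' effects), then summarised as the mean and central 95% interval at each
#' grid point. `literal_x_scaling = TRUE` replaces the correction with
#' `0.5 * x * sum(variances_i)` for sensitivity analysis.
#'
#' @param fit A [fit_glmm()] result (Poisson family).
#' @param term Name of the coefficient for `x`.
#' @param x_grid Numeric grid of predictor values.
#' @param quadratic Optional name of the squared-term coefficient.
#' @param literal_x_scaling See above.
#' @return Data frame with `x`, `mean`, `lower`, `upper`.
#' @export
prediction_curve <- function(fit, term, x_grid, quadratic = NULL,
                             literal_x_scaling = FALSE) {
  stopifnot(inherits(fit, "provgall_glmm"))
  fd <- fit$fixed_draws
  if (!term %in% colnames(fd)) stop("term '", term, "' not in the model", call. = FALSE)
  if (term %in% colnames(fit$X)) {
    rng <- range(fit$X[, term])
    if (any(x_grid < rng[1] | x_grid > rng[2]))
      warning("x_grid extends beyond the observed range of ", term)
  }
  b0 <- if ("(Intercept)" %in% colnames(fd)) fd[, "(Intercept)"] else 0
  b1 <- fd[, term]
  b2 <- if (!is.null(quadratic)) fd[, quadratic] else 0
  s2 <- rowSums(fit$variance_draws)
  out <- lapply(x_grid, function(x) {
    corr <- if (literal_x_scaling) 0.5 * x * s2 else 0.5 * s2
    y <- exp(b0 + x * b1 + x^2 * b2 + corr)
    data.frame(x = x, mean = mean(y),
               lower = unname(stats::quantile(y, 0.025)),
               upper = unname(stats::quantile(y, 0.975)))
  })
  do.call(rbind, out)
}
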