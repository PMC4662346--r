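#' Regression of pairwise F_ST on geographic distance
#'
#' Least-squares fit of pairwise F_ST on pairwise great-circle distance over
#' the upper-triangle provenance pairs. The fitted relationship is used by
#' [predict_geo_fst()] to construct a distance-based pseudo-F_ST (GeoF_ST)
#' for a full provenance set, including provenances without genotype data.
#'
#' The default regresses raw F_ST on raw distance in km; `transform` exposes
#' `log_distance` (F_ST on log km) and `linearized` (F_ST/(1-F_ST) on km,
#' the Rousset linearization) as alternatives.
#'
#' @param fst A [pairwise_fst()] matrix (labels required).
#' @param dist Great-circle distance matrix (km) sharing `fst`'s labels.
#' @param transform One of `"raw"`, `"log_distance"`, `"linearized"`.
#' @return Object of class `geo_fst_fit` wrapping the `lm` fit.
#' @export
fit_geo_fst <- function(fst, dist, transform = c("raw", "log_distance", "linearized")) {
  transform <- match.arg(transform)
  stopifnot(is.matrix(fst), is.matrix(dist))
  labs <- rownames(fst)
  if (is.null(labs) || is.null(rownames(dist)))
    stop("fst and dist must carry provenance labels", call. = FALSE)
  dist <- dist[labs, labs, drop = FALSE]
  ut <- upper.tri(fst)
  if (sum(ut) < 3) stop("underdetermined-fit error: need at least 3 pairs", call. = FALSE)
  df <- data.frame(fst = fst[ut], km = dist[ut])
  df$x <- switch(transform, raw = df$km, log_distance = log(df$km),
                 linearized = df$km)
  df$y <- switch(transform, raw = df$fst, log_distance = df$fst,
                 linearized = df$fst / (1 - df$fst))
  fit <- stats::lm(y ~ x, data = df)
  structure(list(lm = fit, transform = transform, labels = labs,
                 r_squared = summary(fit)$r.squared),
            class = "geo_fst_fit")
}

#' Predict a GeoF_ST pseudo-matrix from geographic distance
#'
#' Applies a fitted F_ST-distance regression to a full distance matrix,
#' producing a complete symmetric GeoF_ST matrix covering every labelled
#' provenance (including those absent from the genotype set). With
#' `replace_observed = FALSE` and an `observed` matrix supplied, predictions
#' only fill pairs missing from the observed set; the default predicts all
#' pairs from the regression so the matrix is a single smooth function of
#' distance.
#'
#' @param model A [fit_geo_fst()] object.
#' @param dist_full Labelled distance matrix (km) for the full provenance set.
#' @param observed Optional observed [pairwise_fst()] matrix (a subset of
#'   `dist_full`'s labels).
#' @param replace_observed If `FALSE`, keep observed pairwise values and only
#'   predict missing pairs.
#' @return A `pairwise_fst`-classed symmetric matrix, zero diagonal. Values
#'   are the raw regression predictions (possibly negative at short
#'   distances); clamping to \[0, 0.999\] happens in [build_covariance()].
#' @export
predict_geo_fst <- function(model, dist_full, observed = NULL,
                            replace_observed = TRUE) {
  stopifnot(inherits(model, "geo_fst_fit"), is.matrix(dist_full))
  labs <- rownames(dist_full)
  if (is.null(labs)) stop("dist_full must carry provenance labels", call. = FALSE)
  x <- switch(model$transform, raw = dist_full, log_distance = log(dist_full),
              linearized = dist_full)
  co <- stats::coef(model$lm)
  pred <- co[[1]] + co[[2]] * x
  if (model$transform == "linearized") pred <- pred / (1 + pred)  # invert F/(1-F)
  pred <- (pred + t(pred)) / 2
  if (!replace_observed && !is.null(observed)) {
    obs_labs <- rownames(observed)
    pred[obs_labs, obs_labs] <- observed
  }
  diag(pred) <- 0
  dimnames(pred) <- list(labs, labs)
  class(pred) <- c("pairwise_fst", class(pred))
  pred
}
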