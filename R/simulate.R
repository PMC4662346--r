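#' Simulate microsatellite genotypes with isolation by distance
#'
#' Draws diploid multiallelic genotypes for the provenances of a trial
#' design. Provenance allele frequencies are spatially autocorrelated: the
#' log-scale (softmax) frequency deviations of each provenance are a draw
#' from a Gaussian process over the origin coordinates with an exponential
#' distance-decay kernel `K_ij = sigma^2 * exp(-ibd_decay * d_ij)` (d in km),
#' so expected pairwise F_ST increases with great-circle distance. With
#' `ibd_decay = 0` all provenances share one frequency vector and expected
#' F_ST is zero.
#'
#' @param design A [trial_design()] object.
#' @param n_loci Number of microsatellite loci (>= 1).
#' @param n_ind_per_prov Genotyped individuals per provenance (>= 5).
#' @param ibd_decay Nonnegative per-km decay rate of the frequency
#'   correlation; larger values give faster build-up of differentiation
#'   with distance.
#' @param sigma Standard deviation of the log-scale frequency deviations;
#'   controls the overall magnitude of differentiation.
#' @param n_alleles Alleles per locus (recycled across loci).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A [genotype_table()].
#' @export
simulate_genotypes <- function(design, n_loci = 10, n_ind_per_prov = 30,
                               ibd_decay = 0.002, sigma = 0.6,
                               n_alleles = 6, seed = 1) {
  stopifnot(inherits(design, "trial_design"))
  if (n_loci < 1) stop("invalid parameter: n_loci must be >= 1", call. = FALSE)
  if (n_ind_per_prov < 5) stop("invalid parameter: n_ind_per_prov must be >= 5", call. = FALSE)
  if (ibd_decay < 0) stop("invalid parameter: ibd_decay must be nonnegative", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  origins <- design$origins
  np <- nrow(origins)
  d <- great_circle_distance(origins)
  K <- sigma^2 * exp(-ibd_decay * d)
  # Cholesky with jitter: K is rank-deficient at ibd_decay = 0 (all-ones)
  L <- t(chol(K + diag(1e-10, np)))
  n_alleles <- rep_len(n_alleles, n_loci)
  out <- vector("list", n_loci)
  ids <- paste(rep(origins$code, each = n_ind_per_prov),
               sprintf("i%03d", seq_len(n_ind_per_prov)), sep = "_")
  provs <- rep(origins$code, each = n_ind_per_prov)
  for (l in seq_len(n_loci)) {
    na <- n_alleles[l]
    base <- log(as.numeric(stats::rmultinom(1, 1000, rep(1, na)) + 1))
    eta <- matrix(base, np, na, byrow = TRUE) + L %*% matrix(stats::rnorm(np * na), np, na)
    p <- exp(eta) / rowSums(exp(eta))  # per-provenance allele frequencies
    a1 <- a2 <- integer(np * n_ind_per_prov)
    for (k in seq_len(np)) {
      idx <- ((k - 1) * n_ind_per_prov + 1):(k * n_ind_per_prov)
      a1[idx] <- sample.int(na, n_ind_per_prov, replace = TRUE, prob = p[k, ])
      a2[idx] <- sample.int(na, n_ind_per_prov, replace = TRUE, prob = p[k, ])
    }
    out[[l]] <- data.frame(individual = ids, provenance = provs,
                           locus = sprintf("L%02d", l),
                           allele1 = pmin(a1, a2), allele2 = pmax(a1, a2),
                           stringsAsFactors = FALSE)
  }
  genotype_table(do.call(rbind, out))
}

#' Simulate tree phenotypes over a trial design
#'
#' Generates the three surveyed phenotypes for every tree:
#' \describe{
#'   \item{budburst}{Ordinal 0-5 spring phenology score (higher = earlier
#'     flush). Provenance means follow a latitudinal cline with slope
#'     `cline_slope` (score per degree latitude; negative, because more
#'     southerly origins flush earlier), anchored so the local provenance
#'     sits near a score of 1.6.}
#'   \item{dbh}{Diameter at breast height (arbitrary growth units, positive).
#'     Declines in expectation with genetic distance from the local
#'     provenance at `vigour_decay` units per unit genetic distance.}
#'   \item{form}{Ordinal 1-10 tree-shape (health) score around a common
#'     baseline.}
#' }
#' Ordinal traits are generated as latent Gaussians, then rounded and clipped
#' to their scales.
#'
#' @param design A [trial_design()] object.
#' @param cline_slope Budburst score change per degree latitude (default
#'   -0.3: southern origins flush markedly earlier).
#' @param vigour_decay DBH decline per unit genetic distance from the local
#'   provenance.
#' @param noise_sd Tree-level latent noise scale. Interpreted as the latent
#'   SD of the ordinal scores; DBH noise is `15 * noise_sd`.
#' @param genetic_dist Optional per-provenance genetic distance from the
#'   local provenance (e.g. a GeoF_ST column, rescaled). Defaults to
#'   `1 - exp(-0.002 * km)` from the origin coordinates, matching the default
#'   isolation-by-distance kernel of [simulate_genotypes()].
#' @param seed Integer seed.
#' @return Data frame with one row per surveyed tree: design identifiers plus
#'   `budburst`, `dbh`, `form`.
#' @export
simulate_phenotypes <- function(design, cline_slope = -0.3, vigour_decay = 35,
                                noise_sd = 1, genetic_dist = NULL, seed = 1) {
  stopifnot(inherits(design, "trial_design"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  origins <- design$origins
  trees <- design_tree_table(design)
  local_lat <- origins$latitude[origins$local]
  if (is.null(genetic_dist)) {
    d <- great_circle_distance(origins)
    genetic_dist <- 1 - exp(-0.002 * d[, which(origins$local)])
  }
  stopifnot(length(genetic_dist) == nrow(origins))
  prov_idx <- match(trees$provenance, origins$code)

  bb_mean <- 1.6 + cline_slope * (origins$latitude - local_lat)
  budburst <- bb_mean[prov_idx] + stats::rnorm(nrow(trees), 0, 0.8 * noise_sd)
  trees$budburst <- pmin(pmax(round(budburst), 0L), 5L)

  dbh_mean <- 115 - vigour_decay * genetic_dist
  dbh <- dbh_mean[prov_idx] + stats::rnorm(nrow(trees), 0, 15 * noise_sd)
  trees$dbh <- pmax(dbh, 1)

  form <- 4.3 + stats::rnorm(nrow(trees), 0, 0.9 * noise_sd)
  trees$form <- pmin(pmax(round(form), 1L), 10L)
  trees
}

#' Ground-truth parameters of the generative gall-count model
#'
#' Bundles the fixed-effect coefficients and random-effect variances used by
#' [simulate_gall_counts()], so that recovery tests can compare posterior
#' estimates against the generating values.
#'
#' @param fixed Named numeric vector of fixed coefficients on the log scale.
#'   `intercept` is required; year contrasts are named `year<label>` (e.g.
#'   `year2009`, relative to the first design year); phenotype terms
#'   (`budburst`, `budburst2`, `dbh`, `form`) multiply the matching phenotype
#'   columns when those are supplied.
#' @param variances Named nonnegative numeric vector of random-effect
#'   variances; recognised names are `provenance_structured`,
#'   `provenance_nugget`, `soil_zone`, `plot`, `tree`, `unit`.
#' @param covariance_mode Label recording which provenance structure the
#'   `provenance_structured` variance refers to.
#' @param seed Integer seed used by the count generator.
#' @return Object of class `truth_params`.
#' @export
truth_params <- function(fixed = c(intercept = log(2)),
                         variances = c(provenance_structured = 0, provenance_nugget = 0,
                                       soil_zone = 0, plot = 0, tree = 0, unit = 0),
                         covariance_mode = "identity", seed = 1) {
  if (!"intercept" %in% names(fixed)) stop("fixed must contain an intercept", call. = FALSE)
  known <- c("provenance_structured", "provenance_nugget", "soil_zone",
             "plot", "tree", "unit")
  bad <- setdiff(names(variances), known)
  if (length(bad)) stop("unknown variance component(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(variances < 0)) stop("variances must be nonnegative", call. = FALSE)
  v <- stats::setNames(numeric(length(known)), known)
  v[names(variances)] <- variances
  structure(list(fixed = fixed, variances = v,
                 covariance_mode = covariance_mode, seed = as.integer(seed)),
            class = "truth_params")
}

#' Simulate per-shoot gall counts from a known generative GLMM
#'
#' Draws shoot-level counts for one gall type from the generative inverse of
#' the analysis model: `count ~ Poisson(exp(eta))` with
#' `eta = fixed terms + structured provenance effect + nugget + soil zone +
#' plot + tree + unit`, where the structured provenance effect is a
#' multivariate normal draw with covariance
#' `sigma^2_prov * C` (`C` from [build_covariance()]), the other random
#' effects are iid normal at their generating variances, and the unit effect
#' is a per-shoot-record draw capturing overdispersion.
#'
#' @param design A [trial_design()] object.
#' @param truth A [truth_params()] object.
#' @param covariance A [build_covariance()] structure whose labels match the
#'   design's provenances (used for the `provenance_structured` term).
#' @param phenotypes Optional phenotype table from [simulate_phenotypes()];
#'   required when `truth$fixed` contains phenotype coefficients.
#' @param gall_type Name written to the `gall_type` column.
#' @param season Which survey season the gall type belongs to
#'   (a species' sexual spring and asexual autumn galls are distinct types).
#' @return Data frame of shoot records (`provenance`, `soil_zone`, `plot`,
#'   `tree`, `shoot`, `year`, `season`, `gall_type`, `count`), with the truth
#'   object and the realised random effects attached as attributes `truth`
#'   and `effects`.
#' @export
simulate_gall_counts <- function(design, truth, covariance, phenotypes = NULL,
                                 gall_type = "synthetic_gall",
                                 season = design$seasons[1]) {
  stopifnot(inherits(design, "trial_design"), inherits(truth, "truth_params"),
            inherits(covariance, "covariance_structure"))
  if (!identical(sort(covariance$labels), sort(design$origins$code)))
    stop("structure error: covariance labels do not match design provenances",
         call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(truth$seed)
  shoots <- design_shoot_table(design)
  shoots <- shoots[shoots$season == season, , drop = FALSE]
  rownames(shoots) <- NULL
  n <- nrow(shoots)
  v <- truth$variances
  fx <- truth$fixed

  eta <- rep(fx[["intercept"]], n)
  yr_terms <- grep("^year", names(fx), value = TRUE)
  for (tm in yr_terms) {
    lev <- sub("^year", "", tm)
    eta <- eta + fx[[tm]] * (as.character(shoots$year) == lev)
  }
  if (!is.null(phenotypes)) {
    ph <- phenotypes[match(shoots$tree, phenotypes$tree), ]
    if ("budburst" %in% names(fx)) eta <- eta + fx[["budburst"]] * ph$budburst
    if ("budburst2" %in% names(fx)) eta <- eta + fx[["budburst2"]] * ph$budburst^2
    if ("dbh" %in% names(fx)) eta <- eta + fx[["dbh"]] * ph$dbh
    if ("form" %in% names(fx)) eta <- eta + fx[["form"]] * ph$form
  } else if (any(c("budburst", "budburst2", "dbh", "form") %in% names(fx))) {
    stop("phenotype coefficients given but no phenotype table", call. = FALSE)
  }

  provs <- design$origins$code
  C <- covariance$matrix[provs, provs]
  ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) stop("structure error: covariance not positive semidefinite",
                           call. = FALSE)
  u_prov <- if (v[["provenance_structured"]] > 0)
    drop(MASS::mvrnorm(1, rep(0, length(provs)), v[["provenance_structured"]] * C))
  else rep(0, length(provs))
  names(u_prov) <- provs
  draw_iid <- function(levels, s2) stats::setNames(stats::rnorm(length(levels), 0, sqrt(s2)), levels)
  u_nug <- draw_iid(provs, v[["provenance_nugget"]])
  u_zone <- draw_iid(unique(shoots$soil_zone), v[["soil_zone"]])
  u_plot <- draw_iid(unique(shoots$plot), v[["plot"]])
  u_tree <- draw_iid(unique(shoots$tree), v[["tree"]])
  e_unit <- stats::rnorm(n, 0, sqrt(v[["unit"]]))

  eta <- eta + u_prov[shoots$provenance] + u_nug[shoots$provenance] +
    u_zone[shoots$soil_zone] + u_plot[shoots$plot] + u_tree[shoots$tree] + e_unit
  shoots$gall_type <- gall_type
  shoots$count <- stats::rpois(n, exp(eta))
  attr(shoots, "truth") <- truth
  attr(shoots, "effects") <- list(provenance_structured = u_prov,
                                  provenance_nugget = u_nug, soil_zone = u_zone,
                                  plot = u_plot, tree = u_tree)
  shoots
}
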