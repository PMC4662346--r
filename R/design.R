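#' Generate provenance origin coordinates
#'
#' Draws `n_prov` provenance origins spread across a latitude/longitude box
#' centred on a trial site, emulating a wide-ranging set of seed sources in a
#' common-garden trial. Sampling is stratified (one draw per equal-width band
#' along each axis, bands paired at random) so small sets still cover the
#' requested spans. The provenance closest to the trial site is flagged
#' `local`.
#'
#' @param n_prov Number of provenances (>= 2).
#' @param lat_span Latitudinal span of the origin box, decimal degrees.
#' @param lon_span Longitudinal span of the origin box, decimal degrees.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param site Named numeric vector `c(lat = , lon = )` of the trial-site
#'   coordinate used to flag the local provenance. Defaults to the
#'   La Petite Charnie trial (48.086 N, 0.168 W).
#' @return A data frame with columns `code`, `latitude`, `longitude`,
#'   `altitude` (m) and logical `local` (exactly one `TRUE`).
#' @examples
#' origins <- generate_origins(20, lat_span = 15, lon_span = 34, seed = 1)
#' sum(origins$local)
#' @export
generate_origins <- function(n_prov, lat_span = 15, lon_span = 34, seed = 1,
                             site = c(lat = 48.086, lon = -0.168)) {
  if (n_prov < 2) stop("invalid design: need at least 2 provenances", call. = FALSE)
  if (lat_span <= 0 || lon_span <= 0) stop("invalid design: spans must be positive", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # stratified uniform draws: one per band, bands shuffled independently per axis
  lat <- site[["lat"]] - lat_span / 2 +
    lat_span * (sample(n_prov) - stats::runif(n_prov)) / n_prov
  lon <- site[["lon"]] - lon_span / 2 +
    lon_span * (sample(n_prov) - stats::runif(n_prov)) / n_prov
  lat <- pmin(pmax(lat, -90), 90)
  lon <- pmin(pmax(lon, -180), 180)
  alt <- round(stats::runif(n_prov, 50, 800))
  origins <- data.frame(
    code = sprintf("P%02d", seq_len(n_prov)),
    latitude = lat, longitude = lon, altitude = alt,
    stringsAsFactors = FALSE
  )
  d <- great_circle_distance(rbind(
    origins[, c("latitude", "longitude")],
    data.frame(latitude = site[["lat"]], longitude = site[["lon"]])
  ))
  to_site <- d[seq_len(n_prov), n_prov + 1]
  origins$local <- seq_len(n_prov) == which.min(to_site)
  origins
}

#' Construct a provenance-trial sampling frame
#'
#' Describes the nested design of a common-garden provenance trial:
#' provenances planted in replicate plots across soil zones, a fixed number of
#' surveyed trees per plot and surveyed terminal shoots per tree, over one or
#' more survey years with spring and autumn survey seasons.
#'
#' Defaults mirror a trial with 20 provenances, 5 soil zones, 2 plots per
#' zone per provenance, 12 surveyed trees per plot (of 24 planted) and
#' 10 shoots per tree: 200 study plots, 2400 surveyed trees, 24 000 shoot
#' records per survey.
#'
#' @param origins Origin table from [generate_origins()] (or a data frame with
#'   `code`, `latitude`, `longitude`, `local` columns).
#' @param n_soil_zones Number of soil zones at the trial site.
#' @param plots_per_zone Plots per soil zone per provenance.
#' @param trees_per_plot Surveyed trees per plot.
#' @param shoots_per_tree Surveyed terminal shoots per tree.
#' @param years Integer vector of survey years.
#' @param seasons Character vector of survey seasons.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(origins, n_soil_zones = 5, plots_per_zone = 2,
                         trees_per_plot = 12,
                         trees_per_plot_planted = 2 * trees_per_plot,
                         shoots_per_tree = 10,
                         years = c(2008L, 2009L),
                         seasons = c("spring", "autumn")) {
  stopifnot(is.data.frame(origins),
            all(c("code", "latitude", "longitude", "local") %in% names(origins)))
  if (anyDuplicated(origins$code)) stop("invalid design: duplicated provenance codes", call. = FALSE)
  if (n_soil_zones < 1 || plots_per_zone < 1 || trees_per_plot < 1 || shoots_per_tree < 1)
    stop("invalid design: design counts must be positive", call. = FALSE)
  if (trees_per_plot_planted < trees_per_plot)
    stop("invalid design: fewer planted than surveyed trees per plot", call. = FALSE)
  structure(list(
    origins = origins,
    n_soil_zones = as.integer(n_soil_zones),
    plots_per_zone = as.integer(plots_per_zone),
    trees_per_plot = as.integer(trees_per_plot),
    trees_per_plot_planted = as.integer(trees_per_plot_planted),
    shoots_per_tree = as.integer(shoots_per_tree),
    years = as.integer(years),
    seasons = seasons
  ), class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  tr <- design_tree_table(x)
  cat("Provenance trial design\n")
  cat("  provenances:", nrow(x$origins),
      " soil zones:", x$n_soil_zones,
      " plots:", length(unique(tr$plot)), "\n")
  cat("  surveyed trees:", nrow(tr),
      " shoots/tree:", x$shoots_per_tree,
      " years:", paste(x$years, collapse = ", "), "\n")
  invisible(x)
}

#' Expand a trial design to its surveyed-tree table
#'
#' One row per surveyed tree, with provenance, soil zone and plot identifiers.
#'
#' @param design A [trial_design()] object.
#' @return Data frame with columns `provenance`, `soil_zone`, `plot`, `tree`.
#' @export
design_tree_table <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  prov <- design$origins$code
  grid <- expand.grid(
    tree_in_plot = seq_len(design$trees_per_plot),
    plot_rep = seq_len(design$plots_per_zone),
    soil_zone = sprintf("Z%d", seq_len(design$n_soil_zones)),
    provenance = prov,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$plot <- sprintf("%s_%s_p%d", grid$provenance, grid$soil_zone, grid$plot_rep)
  grid$tree <- sprintf("%s_t%02d", grid$plot, grid$tree_in_plot)
  grid[, c("provenance", "soil_zone", "plot", "tree")]
}

#' Expand a trial design to its shoot-record table
#'
#' One row per surveyed shoot per survey (year x season): the observation unit
#' of the gall counts.
#'
#' @param design A [trial_design()] object.
#' @return Data frame with columns `provenance`, `soil_zone`, `plot`, `tree`,
#'   `shoot`, `year`, `season`.
#' @export
design_shoot_table <- function(design) {
  trees <- design_tree_table(design)
  shoots <- merge(
    cbind(trees, .k = 1L),
    expand.grid(shoot_n = seq_len(design$shoots_per_tree),
                year = design$years, season = design$seasons,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE, .k = 1L),
    by = ".k"
  )
  shoots$.k <- NULL
  shoots$shoot <- sprintf("%s_s%02d", shoots$tree, shoots$shoot_n)
  shoots$shoot_n <- NULL
  o <- order(shoots$year, shoots$season, shoots$tree, shoots$shoot)
  rownames(shoots) <- NULL
  shoots[o, c("provenance", "soil_zone", "plot", "tree", "shoot", "year", "season")]
}

#' Design arithmetic of a provenance trial
#'
#' The headline counts implied by the nested sampling frame: number of study
#' plots, planted and surveyed trees, and shoot records per survey
#' (year x season).
#'
#' @param design A [trial_design()] object.
#' @return Named list: `n_provenances`, `n_plots`, `planted_trees`,
#'   `surveyed_trees`, `shoot_records_per_survey`.
#' @examples
#' d <- trial_design(generate_origins(20, seed = 1))
#' design_counts(d)  # 200 plots, 4800 planted, 2400 surveyed, 24000 shoots
#' @export
design_counts <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  np <- nrow(design$origins)
  n_plots <- np * design$n_soil_zones * design$plots_per_zone
  list(n_provenances = np,
       n_plots = n_plots,
       planted_trees = n_plots * design$trees_per_plot_planted,
       surveyed_trees = n_plots * design$trees_per_plot,
       shoot_records_per_survey = n_plots * design$trees_per_plot * design$shoots_per_tree)
}

# save/restore the global RNG state so generators are pure given their seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
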