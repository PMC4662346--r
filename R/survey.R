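#' Summarise shoot-level gall counts per gall type and year
#'
#' For each gall type x survey year: the total gall count, the mean number
#' of galls per shoot, and the incidence (proportion of shoot records
#' bearing at least one gall).
#'
#' @param records Shoot-level data frame with columns `gall_type`, `year`,
#'   `count` (one row per shoot record per gall type).
#' @return Data frame of class `gall_survey_summary` with columns
#'   `gall_type`, `year`, `total`, `n_shoots`, `mean_per_shoot`,
#'   `incidence`.
#' @export
survey_summary <- function(records) {
  need <- c("gall_type", "year", "count")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("schema error: missing column(s) ",
                         paste(miss, collapse = ", "), call. = FALSE)
  agg <- stats::aggregate(records["count"],
                          by = records[c("gall_type", "year")],
                          FUN = function(x) c(total = sum(x), n = length(x),
                                              inc = mean(x >= 1)))
  out <- data.frame(gall_type = agg$gall_type, year = agg$year,
                    total = agg$count[, "total"],
                    n_shoots = agg$count[, "n"],
                    mean_per_shoot = agg$count[, "total"] / agg$count[, "n"],
                    incidence = agg$count[, "inc"])
  out <- out[order(out$gall_type, out$year), ]
  rownames(out) <- NULL
  class(out) <- c("gall_survey_summary", "data.frame")
  out
}

#' Between-year ratios of mean galls per shoot
#'
#' For each gall type, the ratio of mean galls per shoot between the first
#' and second survey year, oriented larger:smaller and rendered with the
#' larger side rounded to the nearest integer (`"k:1"` when the first year
#' is larger, `"1:k"` otherwise). When the smaller mean is zero the ratio is
#' undefined and rendered `"-"` (an en dash in print).
#'
#' @param by_year A [survey_summary()] table (or any data frame with
#'   `gall_type`, `year`, `mean_per_shoot`).
#' @return Data frame with `gall_type`, `mean_y1`, `mean_y2`, `ratio`
#'   (numeric larger/smaller, `NA` when undefined) and `ratio_label`.
#' @export
year_ratios <- function(by_year) {
  yrs <- sort(unique(by_year$year))
  if (length(yrs) < 2) stop("need two survey years", call. = FALSE)
  yrs <- yrs[1:2]
  types <- unique(by_year$gall_type)
  out <- lapply(types, function(g) {
    m1 <- by_year$mean_per_shoot[by_year$gall_type == g & by_year$year == yrs[1]]
    m2 <- by_year$mean_per_shoot[by_year$gall_type == g & by_year$year == yrs[2]]
    m1 <- if (length(m1)) m1[1] else NA_real_
    m2 <- if (length(m2)) m2[1] else NA_real_
    if (is.na(m1) || is.na(m2) || min(m1, m2) == 0) {
      ratio <- NA_real_; lab <- "-"
    } else {
      ratio <- max(m1, m2) / min(m1, m2)
      lab <- if (m1 >= m2) sprintf("%d:1", round(ratio))
             else sprintf("1:%d", round(ratio))
    }
    data.frame(gall_type = g, mean_y1 = m1, mean_y2 = m2,
               ratio = ratio, ratio_label = lab)
  })
  do.call(rbind, out)
}

#' Filter gall types by incidence
#'
#' A gall type is excluded if and only if its incidence falls below the
#' threshold in EVERY survey year; a type above threshold in any year is
#' retained.
#'
#' @param by_year A [survey_summary()] table (columns `gall_type`, `year`,
#'   `incidence`).
#' @param threshold Incidence threshold (proportion of shoots; default 1%).
#' @return List with character vectors `retained` and `excluded`.
#' @export
incidence_filter <- function(by_year, threshold = 0.01) {
  stopifnot(all(c("gall_type", "year", "incidence") %in% names(by_year)))
  mx <- tapply(by_year$incidence, by_year$gall_type, max)
  excluded <- names(mx)[mx < threshold]
  retained <- setdiff(unique(as.character(by_year$gall_type)), excluded)
  list(retained = retained, excluded = excluded)
}

#' Compare provenance variance components across covariance structures
#'
#' Fits the same gall-abundance GLMM under several provenance covariance
#' structures (e.g. identity vs 1-F_ST vs 1-GeoF_ST, or 17- vs 20-provenance
#' subsets expressed through the structures' labels) and tabulates the
#' provenance variance component under each. For structured modes the
#' reported provenance component pools the structured and nugget terms
#' (both are also returned separately).
#'
#' @param records Shoot-level survey table (columns `provenance`,
#'   `soil_zone`, `plot`, `tree`, `year`, `gall_type`, `count`).
#' @param gall_type Which gall type to model.
#' @param structures Named list of [build_covariance()] objects; names label
#'   the rows of the output.
#' @param fixed Fixed-effect formula; defaults to `count ~ year` when the
#'   data span more than one year, else `count ~ 1`.
#' @param schedule An [mcmc_schedule()].
#' @param seed Integer seed (shared across modes so fits differ only in
#'   structure).
#' @return Data frame with one row per mode: `mode`, `component` (pooled
#'   provenance proportion), `lower`, `upper`, `structured`, `nugget`,
#'   `rsqm`; the fitted models are attached as attribute `fits`.
#' @export
compare_structures <- function(records, gall_type, structures,
                               fixed = NULL,
                               schedule = mcmc_schedule("desk"), seed = 1) {
  if (length(structures) == 0)
    stop("configuration error: empty structure list", call. = FALSE)
  if (is.null(names(structures)) || any(names(structures) == ""))
    stop("configuration error: structures must be named", call. = FALSE)
  dat <- records[records$gall_type == gall_type, , drop = FALSE]
  if (!nrow(dat)) stop("no records for gall type ", gall_type, call. = FALSE)
  dat$year <- factor(dat$year)
  if (is.null(fixed))
    fixed <- if (nlevels(dat$year) > 1) count ~ year else count ~ 1
  fits <- list()
  rows <- lapply(names(structures), function(md) {
    st <- structures[[md]]
    fit <- fit_glmm(fixed,
                    random = list(provenance = st, soil_zone = "identity",
                                  plot = "identity", tree = "identity"),
                    data = dat, family = "poisson_log",
                    schedule = schedule, seed = seed)
    fits[[md]] <<- fit
    vc <- variance_components(fit)
    tab <- vc$components
    pooled <- if ("provenance_pooled" %in% tab$term) "provenance_pooled" else "provenance"
    pr <- tab[tab$term == pooled, ]
    data.frame(mode = md, component = pr$mean, lower = pr$lower, upper = pr$upper,
               structured = tab$mean[tab$term == "provenance"],
               nugget = if ("provenance_nugget" %in% tab$term)
                 tab$mean[tab$term == "provenance_nugget"] else NA_real_,
               rsqm = vc$rsqm$mean)
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}
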