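#' Great-circle distance matrix between origins
#'
#' Haversine distances on a sphere of radius 6371 km between all pairs of
#' origin coordinates.
#'
#' @param origins Data frame with `latitude` and `longitude` columns in
#'   decimal degrees (WGS84 assumed), optionally a `code` column used as
#'   dimnames.
#' @return Symmetric numeric matrix of distances in kilometres, zero diagonal.
#' @examples
#' great_circle_distance(data.frame(latitude = c(0, 0), longitude = c(0, 180)))
#' @export
great_circle_distance <- function(origins) {
  stopifnot(is.data.frame(origins), all(c("latitude", "longitude") %in% names(origins)))
  lat <- origins$latitude; lon <- origins$longitude
  if (any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180))
    stop("invalid coordinate: latitude must be in [-90, 90], longitude in [-180, 180]",
         call. = FALSE)
  m <- geosphere::distm(cbind(lon, lat), fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  m <- (m + t(m)) / 2  # enforce exact symmetry against float asymmetry
  diag(m) <- 0
  if (!is.null(origins$code)) dimnames(m) <- list(origins$code, origins$code)
  m
}
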