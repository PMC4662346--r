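#' Read a shoot-level gall survey table
#'
#' Long (tidy) CSV layout: one row per shoot x survey x gall type, zeros
#' explicit. Lines starting with `#` are treated as comment headers.
#'
#' @param path CSV file path.
#' @return Validated data frame of shoot records.
#' @export
read_survey <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("provenance", "soil_zone", "plot", "tree", "shoot", "year",
            "season", "gall_type", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("schema error: missing column(s) ",
                         paste(miss, collapse = ", "), call. = FALSE)
  key <- df[, c("tree", "shoot", "year", "season", "gall_type")]
  if (anyDuplicated(key))
    stop("duplicate-record error: repeated (tree, shoot, year, season, gall_type)",
         call. = FALSE)
  if (any(df$count < 0) || any(df$count != round(df$count)))
    stop("validation error: counts must be nonnegative integers", call. = FALSE)
  df
}

#' Read a tree phenotype table
#'
#' @param path CSV with columns `tree`, `budburst` (ordinal 0-5), `dbh`
#'   (positive), `form` (ordinal 1-10).
#' @return Validated data frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("tree", "budburst", "dbh", "form")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("schema error: missing column(s) ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bb <- df$budburst[!is.na(df$budburst)]
  if (any(bb < 0 | bb > 5))
    stop("validation error: budburst scores must lie in 0-5", call. = FALSE)
  fm <- df$form[!is.na(df$form)]
  if (any(fm < 1 | fm > 10))
    stop("validation error: form scores must lie in 1-10", call. = FALSE)
  if (any(df$dbh <= 0, na.rm = TRUE))
    stop("validation error: dbh must be positive", call. = FALSE)
  df
}

#' Read a provenance origin table
#'
#' @param path CSV with columns `code`, `latitude`, `longitude` (decimal
#'   degrees, WGS84 assumed), `altitude`; optional logical `local`.
#' @return Validated data frame (with a `local` flag derived from distance
#'   to `site` if absent).
#' @param site Trial-site coordinate used to flag the local provenance when
#'   the file has no `local` column.
#' @export
read_origins <- function(path, site = c(lat = 48.086, lon = -0.168)) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("code", "latitude", "longitude", "altitude")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("schema error: missing column(s) ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$latitude < -90 | df$latitude > 90) ||
      any(df$longitude < -180 | df$longitude > 180))
    stop("invalid-coordinate error", call. = FALSE)
  if (is.null(df$local)) {
    d <- great_circle_distance(rbind(df[, c("latitude", "longitude")],
                                     data.frame(latitude = site[["lat"]],
                                                longitude = site[["lon"]])))
    df$local <- seq_len(nrow(df)) == which.min(d[seq_len(nrow(df)), nrow(df) + 1])
  }
  df
}

#' Read diploid genotypes
#'
#' Two dialects: `"long_csv"` (columns `individual`, `provenance`, `locus`,
#' `allele1`, `allele2`; `NA`/empty = missing) and `"genepop"` (GENEPOP text
#' with 2- or 3-digit allele codes, one `Pop` block per provenance;
#' provenance codes are taken from the first individual label of each block,
#' using the part before the last `_` when present).
#'
#' @param path File path.
#' @param dialect `"long_csv"` or `"genepop"`.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, dialect = c("long_csv", "genepop")) {
  dialect <- match.arg(dialect)
  if (dialect == "long_csv") {
    df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    return(genotype_table(df))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  # line 1: title; locus names until the first 'Pop'
  pop_idx <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (!length(pop_idx)) stop("not a GENEPOP file: no 'Pop' line", call. = FALSE)
  loci_lines <- lines[2:(pop_idx[1] - 1)]
  loci <- trimws(unlist(strsplit(loci_lines, ",")))
  loci <- loci[nzchar(loci)]
  rows <- list()
  for (b in seq_along(pop_idx)) {
    from <- pop_idx[b] + 1
    to <- if (b < length(pop_idx)) pop_idx[b + 1] - 1 else length(lines)
    if (to < from) next
    for (ln in lines[from:to]) {
      parts <- strsplit(ln, ",")[[1]]
      id <- trimws(parts[1])
      gstr <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
      if (length(gstr) != length(loci))
        stop("GENEPOP parse error: ", length(gstr), " genotypes for ",
             length(loci), " loci on line: ", ln, call. = FALSE)
      w <- nchar(gstr[1]) / 2
      if (!w %in% c(2, 3))
        stop("GENEPOP parse error: allele code width must be 2 or 3 digits",
             call. = FALSE)
      a1 <- as.integer(substr(gstr, 1, w))
      a2 <- as.integer(substr(gstr, w + 1, 2 * w))
      a1[a1 == 0] <- NA; a2[a2 == 0] <- NA
      miss <- is.na(a1) | is.na(a2)
      a1[miss] <- NA; a2[miss] <- NA
      prov <- if (grepl("_", id)) sub("_[^_]*$", "", id) else sprintf("pop%02d", b)
      rows[[length(rows) + 1]] <- data.frame(
        individual = id, provenance = prov, locus = loci,
        allele1 = pmin(a1, a2), allele2 = pmax(a1, a2),
        stringsAsFactors = FALSE)
    }
  }
  genotype_table(do.call(rbind, rows))
}

#' Write genotypes
#'
#' @param gt A [genotype_table()].
#' @param path Output path.
#' @param dialect `"long_csv"` or `"genepop"` (3-digit allele codes).
#' @param header Optional character vector of comment-header lines
#'   (long_csv only).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path, dialect = c("long_csv", "genepop"),
                            header = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "long_csv") {
    return(write_table_csv(gt, path, header))
  }
  loci <- gt_loci(gt)
  provs <- gt_provenances(gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("provgall genotype export", loci), con)
  fmt <- function(a) ifelse(is.na(a), "000", sprintf("%03d", a))
  for (p in provs) {
    writeLines("Pop", con)
    sub <- gt[gt$provenance == p, ]
    for (id in unique(sub$individual)) {
      gi <- sub[sub$individual == id, ]
      g <- gi[match(loci, gi$locus), ]
      writeLines(paste0(id, " , ",
                        paste(paste0(fmt(g$allele1), fmt(g$allele2)), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Write a data frame as CSV with an optional comment header
#'
#' @param df Data frame.
#' @param path Output path.
#' @param header Character vector of header lines (written prefixed `# `).
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a labelled symmetric matrix as CSV
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param header Optional comment-header lines.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path, header = NULL) {
  df <- data.frame(label = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  write_table_csv(df, path, header)
}

#' Write / read ground-truth parameters as YAML
#'
#' Sidecar used by parameter-recovery tests: records the generating fixed
#' coefficients, variance components, covariance mode and seed of a
#' synthetic dataset.
#'
#' @param truth A [truth_params()] object.
#' @param path YAML file path.
#' @return `path` (writer) or a [truth_params()] (reader).
#' @export
write_truth_yaml <- function(truth, path) {
  stopifnot(inherits(truth, "truth_params"))
  yaml::write_yaml(list(fixed = as.list(truth$fixed),
                        variances = as.list(truth$variances),
                        covariance_mode = truth$covariance_mode,
                        seed = truth$seed), path, precision = 15)
  invisible(path)
}

#' @rdname write_truth_yaml
#' @export
read_truth_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  truth_params(fixed = unlist(y$fixed), variances = unlist(y$variances),
               covariance_mode = y$covariance_mode, seed = y$seed)
}

#' Published survey tables bundled with the package
#'
#' `petite_charnie_origins()` returns the 20 studied oak provenances of the
#' La Petite Charnie trial (INRA code, origin, coordinates, altitude,
#' genotype availability and provenance-mean phenotypes).
#' `petite_charnie_gall_summary()` returns the published per-year summary of
#' the 20 recorded gall types (totals, mean galls per shoot, incidence).
#'
#' @return A data frame.
#' @export
petite_charnie_origins <- function() {
  df <- utils::read.csv(system.file("extdata", "petite_charnie_provenances.csv",
                                    package = "provgall"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  df$code <- as.character(df$code)
  df$local <- df$code == "217"  # Foret de Berce, ~50 km from the trial
  df
}

#' @rdname petite_charnie_origins
#' @export
petite_charnie_gall_summary <- function() {
  df <- utils::read.csv(system.file("extdata", "petite_charnie_gall_summary.csv",
                                    package = "provgall"),
                        stringsAsFactors = FALSE)
  df$gall_type <- paste0(df$species, " (", df$generation, ")")
  class(df) <- c("gall_survey_summary", "data.frame")
  df
}
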