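#' Construct and validate a genotype table
#'
#' Long-format diploid genotype calls: one row per individual x locus, with
#' two unordered allele columns. Missing calls are `NA` in both allele
#' columns; allele codes are positive integers (microsatellite fragment
#' codes).
#'
#' @param calls Data frame with columns `individual`, `provenance`, `locus`,
#'   `allele1`, `allele2`.
#' @return The validated data frame with class `genotype_table`.
#' @export
genotype_table <- function(calls) {
  need <- c("individual", "provenance", "locus", "allele1", "allele2")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stop("schema error: missing column(s) ", paste(miss, collapse = ", "),
                         call. = FALSE)
  a <- c(calls$allele1, calls$allele2)
  a <- a[!is.na(a)]
  if (length(a) && (any(a != round(a)) || any(a <= 0)))
    stop("invalid genotype: allele codes must be positive integers", call. = FALSE)
  half <- xor(is.na(calls$allele1), is.na(calls$allele2))
  if (any(half)) stop("invalid genotype: half-missing calls (one allele NA)", call. = FALSE)
  if (anyDuplicated(calls[, c("individual", "locus")]))
    stop("duplicate-record error: repeated individual x locus call", call. = FALSE)
  calls <- as.data.frame(calls)[, c(need, setdiff(names(calls), need))]
  class(calls) <- c("genotype_table", "data.frame")
  calls
}

#' Loci of a genotype table
#' @param gt A [genotype_table()].
#' @return Character vector of locus identifiers.
#' @export
gt_loci <- function(gt) unique(as.character(gt$locus))

#' Provenances of a genotype table
#' @param gt A [genotype_table()].
#' @return Character vector of provenance codes.
#' @export
gt_provenances <- function(gt) unique(as.character(gt$provenance))
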