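#' Pairwise Weir-Cockerham F_ST between provenances
#'
#' Computes the Weir & Cockerham (1984) theta estimator of genetic
#' differentiation for every pair of provenances. For each pair, the a, b and
#' c variance components are evaluated per allele per locus from sample sizes,
#' allele frequencies and observed heterozygote proportions, and combined as
#' the ratio of sums across alleles and loci (theta = sum a / sum (a+b+c),
#' the fstat convention). Individuals with a missing call at a locus are
#' excluded at that locus only. Negative estimates are retained (the
#' estimator is unbiased around zero under panmixia); they are only clamped
#' later when building covariance matrices.
#'
#' @param gt A [genotype_table()].
#' @return Symmetric matrix of pairwise theta estimates with class
#'   `pairwise_fst`; diagonal exactly 0.
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38, 1358-1370.
#' @export
pairwise_fst <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  provs <- gt_provenances(gt)
  if (length(provs) < 2) stop("need at least 2 provenances", call. = FALSE)
  loci <- gt_loci(gt)
  # pre-split calls by provenance x locus for speed
  gt$provenance <- as.character(gt$provenance)
  gt$locus <- as.character(gt$locus)
  ok <- !is.na(gt$allele1)
  split_key <- paste(gt$provenance, gt$locus, sep = "\r")
  calls <- split(gt[ok, c("allele1", "allele2")], split_key[ok])

  np <- length(provs)
  theta <- matrix(0, np, np, dimnames = list(provs, provs))
  for (i in seq_len(np - 1L)) {
    for (j in seq((i + 1L), np)) {
      comp <- c(a = 0, abc = 0)
      any_locus <- FALSE
      for (loc in loci) {
        g1 <- calls[[paste(provs[i], loc, sep = "\r")]]
        g2 <- calls[[paste(provs[j], loc, sep = "\r")]]
        if (is.null(g1) || is.null(g2) || nrow(g1) < 1 || nrow(g2) < 1) next
        any_locus <- TRUE
        comp <- comp + .wc_locus_components(g1, g2)
      }
      if (!any_locus)
        stop("undefined-pair error: no shared genotyped locus for pair ",
             provs[i], " - ", provs[j], call. = FALSE)
      theta[i, j] <- theta[j, i] <- comp[["a"]] / comp[["abc"]]
    }
  }
  diag(theta) <- 0
  class(theta) <- c("pairwise_fst", class(theta))
  theta
}

# Weir-Cockerham a and a+b+c components for one locus, two samples.
# g1, g2: data frames of non-missing diploid calls (allele1, allele2).
.wc_locus_components <- function(g1, g2) {
  n1 <- nrow(g1); n2 <- nrow(g2)
  r <- 2
  nbar <- (n1 + n2) / r
  if (nbar <= 1) return(c(a = 0, abc = 0))
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  alleles <- sort(unique(c(g1$allele1, g1$allele2, g2$allele1, g2$allele2)))
  # per-allele frequency and heterozygote proportion in each sample
  freq_het <- function(g, n) {
    cnt <- colSums(outer(g$allele1, alleles, "==")) +
           colSums(outer(g$allele2, alleles, "=="))
    het <- colSums(outer(g$allele1, alleles, "==") != outer(g$allele2, alleles, "=="))
    list(p = cnt / (2 * n), h = het / n)
  }
  f1 <- freq_het(g1, n1); f2 <- freq_het(g2, n2)
  p1 <- f1$p; p2 <- f2$p; h1 <- f1$h; h2 <- f2$h
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = sum(a), abc = sum(a + b + cc))
}

#' @export
print.pairwise_fst <- function(x, digits = 4, ...) {
  cat("Pairwise Weir-Cockerham F_ST (", nrow(x), " provenances)\n", sep = "")
  print(round(unclass(x), digits), ...)
  invisible(x)
}
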