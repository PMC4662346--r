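#' Mantel permutation test of matrix association
#'
#' Pearson correlation between the upper-triangle entries of two symmetric
#' matrices, with significance assessed by jointly permuting rows and columns
#' of the second matrix. The test is one-sided (greater), matching the
#' isolation-by-distance hypothesis that genetic differentiation increases
#' with geographic distance, with
#' `p = (1 + #[r_perm >= r_obs]) / (n_perm + 1)`.
#'
#' @param A,B Symmetric numeric matrices with the same dimension (and labels,
#'   if any).
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @return List with elements `r` (observed correlation), `p` (permutation
#'   p-value), `n_perm`, and `perm_r` (the permuted statistics).
#' @export
mantel_test <- function(A, B, n_perm = 999, seed = 1) {
  stopifnot(is.matrix(A), is.matrix(B), nrow(A) == ncol(A),
            all(dim(A) == dim(B)))
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  if (!is.null(dimnames(A)) && !is.null(dimnames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop("A and B labels disagree", call. = FALSE)
  ut <- upper.tri(A)
  x <- A[ut]
  y <- B[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined-correlation error: constant matrix", call. = FALSE)
  r_obs <- stats::cor(x, y)
  n <- nrow(A)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm_r <- vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(n)
    stats::cor(x, B[idx, idx][ut])
  }, numeric(1))
  p <- (1 + sum(perm_r >= r_obs)) / (n_perm + 1)
  list(r = r_obs, p = p, n_perm = n_perm, perm_r = perm_r)
}
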