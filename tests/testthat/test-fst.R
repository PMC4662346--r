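test_that("theta is near zero for identical allele frequencies", {
  set.seed(42)
  g <- function(n) paste0(sample(1:2, n, TRUE, c(.6, .4)), sample(1:2, n, TRUE, c(.6, .4)))
  gt <- toy_genotypes(g(400), g(400))
  th <- pairwise_fst(gt)
  expect_lt(abs(th["A", "B"]), 0.02)
})

test_that("theta is one for fixed different alleles", {
  gt <- toy_genotypes(rep("11", 20), rep("22", 20))
  th <- pairwise_fst(gt)
  expect_equal(th["A", "B"], 1)
})

test_that("theta matches the step-by-step variance-component oracle", {
  pop1 <- c("11", "11", "12", "12", "12", "11", "22", "12", "11", "12")
  pop2 <- c("22", "12", "22", "22", "12", "22", "22", "11", "22", "12")
  gt <- toy_genotypes(pop1, pop2)
  th <- pairwise_fst(gt)
  expect_equal(th["A", "B"], wc_theta_oracle(pop1, pop2), tolerance = 1e-10)

  # a second, unbalanced toy with a triallelic locus
  pop3 <- c("11", "13", "23", "12", "33", "13", "11")
  pop4 <- c("22", "23", "12", "22", "23")
  gt2 <- toy_genotypes(pop3, pop4)
  th2 <- pairwise_fst(gt2)
  expect_equal(th2["A", "B"], wc_theta_oracle(pop3, pop4), tolerance = 1e-10)
})

test_that("theta is invariant to allele relabeling and individual order", {
  set.seed(7)
  pop1 <- paste0(sample(1:3, 30, TRUE), sample(1:3, 30, TRUE))
  pop2 <- paste0(sample(1:3, 30, TRUE, c(.7, .2, .1)), sample(1:3, 30, TRUE, c(.7, .2, .1)))
  gt <- toy_genotypes(pop1, pop2)
  th <- pairwise_fst(gt)
  # relabel alleles 1->5, 2->9, 3->7
  map <- c(`1` = 5L, `2` = 9L, `3` = 7L)
  gt2 <- gt
  gt2$allele1 <- map[as.character(gt$allele1)]
  gt2$allele2 <- map[as.character(gt$allele2)]
  a1 <- pmin(gt2$allele1, gt2$allele2); a2 <- pmax(gt2$allele1, gt2$allele2)
  gt2$allele1 <- a1; gt2$allele2 <- a2
  th2 <- pairwise_fst(genotype_table(as.data.frame(gt2)))
  expect_equal(th2["A", "B"], th["A", "B"], tolerance = 1e-12)
  # shuffle row order
  gt3 <- genotype_table(as.data.frame(gt)[sample(nrow(gt)), ])
  th3 <- pairwise_fst(gt3)
  expect_equal(th3["A", "B"], th["A", "B"], tolerance = 1e-12)
})

test_that("split halves of one population are not differentiated", {
  set.seed(11)
  design <- small_design(n_prov = 2)
  gt <- simulate_genotypes(design, n_loci = 8, n_ind_per_prov = 60,
                           ibd_decay = 0, seed = 5)
  th <- pairwise_fst(gt)
  expect_lt(abs(th[1, 2]), 0.02)
})

test_that("missing calls are excluded per locus; empty pairs error", {
  pop1 <- c("11", "12", "22", "11", "12")
  pop2 <- c("22", "22", "12", "22", "11")
  gt <- toy_genotypes(pop1, pop2)
  # add a second locus where population B is entirely missing
  extra <- data.frame(individual = unique(gt$individual),
                      provenance = rep(c("A", "B"), each = 5), locus = "L2",
                      allele1 = c(1L, 1L, 2L, 1L, 2L, rep(NA_integer_, 5)),
                      allele2 = c(1L, 2L, 2L, 1L, 2L, rep(NA_integer_, 5)))
  gt_all <- genotype_table(rbind(as.data.frame(gt), extra))
  th <- pairwise_fst(gt_all)        # L2 contributes nothing for the pair
  expect_equal(th["A", "B"], pairwise_fst(gt)["A", "B"], tolerance = 1e-12)
  # no shared locus at all -> undefined-pair error naming the pair
  lonely <- genotype_table(data.frame(
    individual = c("A_1", "A_2", "B_1", "B_2"),
    provenance = c("A", "A", "B", "B"),
    locus = c("L1", "L1", "L2", "L2"),
    allele1 = c(1L, 1L, 2L, 1L), allele2 = c(1L, 2L, 2L, 2L)))
  expect_error(pairwise_fst(lonely), "undefined-pair.*A.*B")
})

test_that("single-locus small-sample estimates stay in the estimator's range", {
  set.seed(3)
  design <- small_design(n_prov = 2)
  gt <- simulate_genotypes(design, n_loci = 1, n_ind_per_prov = 5,
                           ibd_decay = 0.002, n_alleles = 2, seed = 9)
  th <- pairwise_fst(gt)
  expect_true(is.finite(th[1, 2]))
  expect_gte(th[1, 2], -0.2)
  expect_lte(th[1, 2], 1)
})
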