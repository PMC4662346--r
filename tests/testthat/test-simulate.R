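test_that("genotype simulation is deterministic and honours ibd_decay = 0", {
  design <- small_design(n_prov = 4)
  gt1 <- simulate_genotypes(design, n_loci = 4, n_ind_per_prov = 40,
                            ibd_decay = 0, seed = 2)
  gt2 <- simulate_genotypes(design, n_loci = 4, n_ind_per_prov = 40,
                            ibd_decay = 0, seed = 2)
  expect_identical(gt1, gt2)
  th <- pairwise_fst(gt1)
  expect_lt(mean(abs(th[upper.tri(th)])), 0.02)
  expect_error(simulate_genotypes(design, ibd_decay = -0.1), "invalid parameter")
  expect_error(simulate_genotypes(design, n_ind_per_prov = 3), "invalid parameter")
})

test_that("isolation by distance emerges for positive ibd_decay", {
  # expected pairwise F_ST should increase with distance (rank correlation)
  hits <- 0
  for (k in 1:10) {
    origins <- generate_origins(12, seed = 100 + k)
    design <- trial_design(origins, n_soil_zones = 1, plots_per_zone = 1,
                           trees_per_plot = 2, shoots_per_tree = 1, years = 2008L)
    gt <- simulate_genotypes(design, n_loci = 10, n_ind_per_prov = 25,
                             ibd_decay = 0.002, seed = 200 + k)
    th <- pairwise_fst(gt)
    d <- great_circle_distance(origins)
    ut <- upper.tri(th)
    if (cor(th[ut], d[ut], method = "spearman") > 0) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("phenotypes respect their ordinal scales and the budburst cline", {
  design <- trial_design(generate_origins(15, seed = 6), n_soil_zones = 3,
                         plots_per_zone = 2, trees_per_plot = 6,
                         shoots_per_tree = 2, years = 2008L)
  ph <- simulate_phenotypes(design, cline_slope = -0.3, noise_sd = 0.3, seed = 7)
  expect_true(all(ph$budburst %in% 0:5))
  expect_true(all(ph$form %in% 1:10))
  expect_true(all(ph$dbh > 0))
  # OLS on provenance means recovers the negative cline sign
  pm <- aggregate(budburst ~ provenance, ph, mean)
  pm$lat <- design$origins$latitude[match(pm$provenance, design$origins$code)]
  slope <- coef(lm(budburst ~ lat, pm))[["lat"]]
  expect_lt(slope, 0)
  # no-signal degenerate case: identical provenance baselines
  ph0 <- simulate_phenotypes(design, cline_slope = 0, noise_sd = 0, seed = 8)
  expect_equal(length(unique(ph0$budburst)), 1L)
})

test_that("gall counts reduce to plain Poisson when all variances are zero", {
  design <- trial_design(generate_origins(10, seed = 9), n_soil_zones = 2,
                         plots_per_zone = 2, trees_per_plot = 10,
                         shoots_per_tree = 10, years = 2008L)
  cs <- build_covariance(mode = "identity", labels = design$origins$code)
  truth <- truth_params(fixed = c(intercept = log(2)), seed = 10)
  sur <- simulate_gall_counts(design, truth, cs)
  n <- nrow(sur)
  se <- sqrt(2 / n)
  expect_lt(abs(mean(sur$count) - 2), 3 * se)
  expect_identical(sur, simulate_gall_counts(design, truth, cs))
})

test_that("counts follow the lognormal-Poisson mean identity", {
  # mean = exp(beta0 + total_sigma2 / 2) under log-normal random effects
  origins <- generate_origins(6, seed = 11)
  design <- trial_design(origins, n_soil_zones = 1, plots_per_zone = 1,
                         trees_per_plot = 40, shoots_per_tree = 420, years = 2008L)
  cs <- build_covariance(mode = "identity", labels = origins$code)
  s2 <- 0.5
  truth <- truth_params(fixed = c(intercept = log(1.5)),
                        variances = c(unit = s2), seed = 12)
  sur <- simulate_gall_counts(design, truth, cs)
  expect_gte(nrow(sur), 1e5)
  target <- exp(log(1.5) + s2 / 2)
  # Monte-Carlo SE of the mean of an overdispersed count
  se <- sd(sur$count) / sqrt(nrow(sur))
  expect_lt(abs(mean(sur$count) - target), 4 * se)
})

test_that("with zero variances the counts pass a Poisson goodness-of-fit screen", {
  design0 <- trial_design(generate_origins(4, seed = 1), n_soil_zones = 1,
                          plots_per_zone = 1, trees_per_plot = 25,
                          shoots_per_tree = 6, years = 2008L)
  cs <- build_covariance(mode = "identity", labels = design0$origins$code)
  lam <- 2
  pass <- 0
  n_seeds <- 30
  for (k in seq_len(n_seeds)) {
    truth <- truth_params(fixed = c(intercept = log(lam)), seed = 400 + k)
    y <- simulate_gall_counts(design0, truth, cs)$count
    brk <- 0:7
    obs <- c(vapply(brk, function(b) sum(y == b), numeric(1)), sum(y > max(brk)))
    pr <- c(dpois(brk, lam), 1 - ppois(max(brk), lam))
    pval <- suppressWarnings(chisq.test(obs, p = pr)$p.value)
    if (pval > 0.01) pass <- pass + 1
  }
  expect_gte(pass / n_seeds, 0.95)
})

test_that("structure errors and phenotype requirements are enforced", {
  design <- small_design(n_prov = 4)
  cs <- build_covariance(mode = "identity", labels = c("X1", "X2", "X3", "X4"))
  truth <- truth_params(seed = 1)
  expect_error(simulate_gall_counts(design, truth, cs), "structure error")
  cs2 <- build_covariance(mode = "identity", labels = design$origins$code)
  truth2 <- truth_params(fixed = c(intercept = 0, budburst = 0.1), seed = 1)
  expect_error(simulate_gall_counts(design, truth2, cs2), "phenotype")
  expect_error(truth_params(variances = c(plot = -1)), "nonnegative")
})
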