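test_that("pMCMC follows the two-tail definition with its floor", {
  sym <- c(rnorm(500, 5), rnorm(500, -5))  # half positive, half negative
  expect_equal(pmcmc(sym), 1)
  expect_equal(pmcmc(abs(rnorm(1000)) + 0.01), 0.002)  # all positive, floor 2/n
  set.seed(4)
  z <- rnorm(1e5, 1, 1)
  expect_equal(pmcmc(z), 2 * pnorm(-1), tolerance = 0.02)
  expect_error(pmcmc(rep(0, 200)), "degenerate")
  expect_error(pmcmc(rnorm(50)), "at least 100")
  # direction check: shifting a symmetric posterior fully positive shrinks pMCMC
  set.seed(5)
  z0 <- rnorm(2000)
  expect_lt(pmcmc(z0 + 10), pmcmc(z0) / 2)
})

test_that("variance components follow the normalisation identity", {
  n <- 200
  # one random term sigma2 = 3, UNIT = 1, intercept-only -> RsqM = 0, comp .75
  fit <- fake_fit(matrix(0, n, 1, dimnames = list(NULL, "(Intercept)")),
                  cbind(g = rep(3, n), unit = rep(1, n)))
  vc <- variance_components(fit)
  expect_equal(vc$components$mean[vc$components$term == "g"], 0.75)
  expect_equal(vc$rsqm$mean, 0)
  # per-draw identity: sum of components = 1 - RsqM
  fit2 <- fake_fit(cbind(`(Intercept)` = rnorm(n), x = rnorm(n)),
                   cbind(g = rexp(n), h = rexp(n), unit = rexp(n)),
                   X = cbind(`(Intercept)` = 1, x = rnorm(40)))
  vc2 <- variance_components(fit2)
  sums <- rowSums(vc2$draws)
  expect_equal(unname(sums), 1 - vc2$rsqm$draws, tolerance = 1e-6)
})

test_that("a fixed effect of known share gives the textbook RsqM", {
  n <- 300
  x <- rep(c(0, 1), each = 50)
  X <- cbind(`(Intercept)` = 1, x = x)
  # gaussian: var_f = var(b1*x) = b1^2 * var(x); choose so RsqM = 0.5
  b1 <- 2
  vf <- var(b1 * x)
  fit <- fake_fit(cbind(`(Intercept)` = rep(0, n), x = rep(b1, n)),
                  cbind(g = rep(vf / 2, n), unit = rep(vf / 2, n)),
                  X = X, family = "gaussian")
  r2 <- marginal_r2(fit)
  expect_equal(r2$mean, 0.5, tolerance = 1e-12)
  vc <- variance_components(fit)
  expect_equal(vc$components$mean, c(0.25, 0.25), tolerance = 1e-12)
  # limiting case: a huge binary fixed effect with tiny variances -> RsqM ~ 1
  fit_big <- fake_fit(cbind(`(Intercept)` = rep(0, n), x = rep(100, n)),
                      cbind(g = rep(1e-6, n), unit = rep(1e-6, n)),
                      X = X, family = "gaussian")
  expect_gt(marginal_r2(fit_big)$mean, 0.999)
})

test_that("RsqM matches an independent step-by-step evaluation on a worked fit", {
  set.seed(8)
  d <- data.frame(x = rnorm(50), g = rep(letters[1:5], 10))
  d$y <- 1 + 2 * d$x + rnorm(5, 0, 1)[as.integer(factor(d$g))] + rnorm(50)
  fit <- fit_glmm(y ~ x, list(g = "identity"), d, family = "gaussian",
                  schedule = quick_schedule(), seed = 2)
  r2 <- marginal_r2(fit)
  # independent evaluation, coded from the definition
  X <- cbind(1, d$x)
  manual <- vapply(seq_len(nrow(fit$fixed_draws)), function(i) {
    vf <- var(X %*% fit$fixed_draws[i, ])
    vr <- sum(fit$variance_draws[i, ])
    vf / (vf + vr)
  }, numeric(1))
  expect_equal(r2$draws, manual, tolerance = 1e-10)
  expect_gt(r2$mean, 0.3)  # the slope explains most of the variance here
})

test_that("poisson RsqM includes the lognormal distribution variance", {
  n <- 150
  fit <- fake_fit(cbind(`(Intercept)` = rep(1, n), x = rep(0.5, n)),
                  cbind(g = rep(0.4, n), unit = rep(0.6, n)),
                  X = cbind(`(Intercept)` = 1, x = rnorm(60)),
                  family = "poisson_log")
  r2 <- marginal_r2(fit)
  vf <- var(fit$X %*% c(1, 0.5))[1]
  lam <- exp(1 + 0.5)
  expected <- vf / (vf + 1 + log(1 / lam + 1))
  expect_equal(r2$mean, expected, tolerance = 1e-12)
})

test_that("VIFs are 1 for orthogonal designs and error for aliased ones", {
  X <- cbind(a = rep(c(1, -1), 50), b = rep(c(1, 1, -1, -1), 25))
  expect_equal(unname(vif(X)), c(1, 1), tolerance = 1e-12)
  X2 <- cbind(a = rnorm(30), b = rnorm(30))
  X2 <- cbind(X2, c = X2[, "a"])
  expect_error(vif(X2), "aliasing error.*c")
})

test_that("VIFs of weakly correlated phenotypes are near one and match car", {
  design <- trial_design(generate_origins(20, seed = 10), years = 2008L)
  ph <- simulate_phenotypes(design, seed = 11)
  X <- as.matrix(ph[, c("budburst", "dbh", "form")])
  v <- vif(X)
  expect_true(all(v >= 1 & v < 1.3))
  skip_if_not_installed("car")
  dd <- data.frame(y = rnorm(nrow(X)), X)
  v_car <- car::vif(lm(y ~ budburst + dbh + form, dd))
  expect_equal(unname(v), unname(v_car), tolerance = 1e-8)
})

test_that("FDR adjustment reproduces the step-up enumeration and its properties", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  res <- fdr_adjust(p, "BH")
  # direct step-up oracle: adj_i = min over j >= i of p_(j) * m / j, capped at 1
  m <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(sort(p) * m / seq_len(m))))
  expect_equal(res$adjusted, pmin(adj[match(p, sort(p))], 1))
  expect_equal(res$adjusted, rep(0.04, 4))
  # single p: unchanged under both methods
  expect_equal(fdr_adjust(0.03, "BH")$adjusted, 0.03)
  expect_equal(fdr_adjust(0.03, "BY")$adjusted, 0.03)
  # monotone in sorted raw p, and BY >= BH elementwise
  set.seed(13)
  for (k in 1:20) {
    pr <- runif(sample(3:12, 1))
    bh <- fdr_adjust(pr, "BH")$adjusted
    by <- fdr_adjust(pr, "BY")$adjusted
    expect_true(all(diff(bh[order(pr)]) >= -1e-12))
    expect_true(all(by >= bh - 1e-12))
    expect_true(all(by <= 1))
  }
  expect_error(fdr_adjust(c(0.1, 0)), "domain error")
  expect_error(fdr_adjust(1.2), "domain error")
})

test_that("prediction curves evaluate the posterior mean-count formula", {
  n <- 120
  # coef 0, variances 0 -> flat at exp(intercept)
  fit <- fake_fit(cbind(`(Intercept)` = rep(0.7, n), x = rep(0, n)),
                  cbind(g = rep(0, n), unit = rep(0, n)),
                  X = cbind(`(Intercept)` = 1, x = seq(0, 5, length = 60)))
  pc <- prediction_curve(fit, "x", x_grid = 0:5)
  expect_equal(pc$mean, rep(exp(0.7), 6), tolerance = 1e-12)
  # variances summing to 2, coef 0 -> exp(intercept + 1)
  fit2 <- fake_fit(cbind(`(Intercept)` = rep(0.7, n), x = rep(0, n)),
                   cbind(g = rep(1.5, n), unit = rep(0.5, n)),
                   X = cbind(`(Intercept)` = 1, x = seq(0, 5, length = 60)))
  pc2 <- prediction_curve(fit2, "x", x_grid = c(0, 2))
  expect_equal(pc2$mean, rep(exp(0.7 + 1), 2), tolerance = 1e-12)
  # single draw: intercept 0, coef 1, no variance, x = 1 -> e
  fit3 <- fake_fit(cbind(`(Intercept)` = rep(0, n), x = rep(1, n)),
                   cbind(unit = rep(0, n)),
                   X = cbind(`(Intercept)` = 1, x = seq(0, 2, length = 60)))
  pc3 <- prediction_curve(fit3, "x", x_grid = 1)
  expect_equal(pc3$mean, exp(1), tolerance = 1e-12)
  expect_warning(prediction_curve(fit3, "x", x_grid = 10), "beyond the observed range")
})
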