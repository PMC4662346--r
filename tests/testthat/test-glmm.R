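test_that("gaussian intercept-only posterior matches the conjugate closed form", {
  set.seed(2)
  d <- data.frame(y = rnorm(1000, 5, 2))
  fit <- fit_glmm(y ~ 1, list(), d, family = "gaussian",
                  schedule = mcmc_schedule(n_iter = 12000, burn_in = 2000, thin = 2),
                  seed = 1)
  expect_equal(mean(fit$fixed_draws[, 1]), mean(d$y), tolerance = 0.02)
  expect_equal(var(fit$fixed_draws[, 1]), var(d$y) / nrow(d), tolerance = 0.05)
  expect_equal(mean(fit$variance_draws[, "unit"]), var(d$y), tolerance = 0.05)
})

test_that("poisson with the UNIT variance forced out matches the ML fit", {
  set.seed(3)
  d <- data.frame(y = rpois(5000, 2.5))
  fit <- fit_glmm(y ~ 1, list(), d, family = "poisson_log", include_unit = FALSE,
                  schedule = mcmc_schedule("desk"), seed = 1)
  ml <- glm(y ~ 1, poisson, d)
  expect_equal(mean(fit$fixed_draws[, 1]), unname(coef(ml)[1]), tolerance = 5e-4)
})

test_that("fits are reproducible for a fixed seed and depend on it", {
  d <- data.frame(y = rpois(300, 2), g = rep(letters[1:10], 30))
  f1 <- fit_glmm(y ~ 1, list(g = "identity"), d, schedule = quick_schedule(), seed = 7)
  f2 <- fit_glmm(y ~ 1, list(g = "identity"), d, schedule = quick_schedule(), seed = 7)
  f3 <- fit_glmm(y ~ 1, list(g = "identity"), d, schedule = quick_schedule(), seed = 8)
  expect_identical(f1$fixed_draws, f2$fixed_draws)
  expect_identical(f1$variance_draws, f2$variance_draws)
  expect_false(identical(f1$fixed_draws, f3$fixed_draws))
})

test_that("identity string and identity-matrix structure agree within MCMC error", {
  set.seed(5)
  g <- rep(sprintf("p%02d", 1:12), each = 100)
  u <- rnorm(12, 0, sqrt(0.3))
  d <- data.frame(y = rpois(1200, exp(0.3 + u[as.integer(factor(g))])), g = g)
  sched <- mcmc_schedule(n_iter = 8000, burn_in = 2000, thin = 6)
  f_str <- fit_glmm(y ~ 1, list(g = "identity"), d, schedule = sched, seed = 2)
  cs <- build_covariance(mode = "identity", labels = sort(unique(g)))
  f_mat <- fit_glmm(y ~ 1, list(g = cs), d, schedule = sched, seed = 2)
  expect_equal(mean(f_str$variance_draws[, "g"]), mean(f_mat$variance_draws[, "g"]),
               tolerance = 0.1)
  expect_equal(mean(f_str$fixed_draws[, 1]), mean(f_mat$fixed_draws[, 1]),
               tolerance = 0.05)
})

test_that("row order does not change posterior summaries beyond MCMC noise", {
  set.seed(6)
  g <- rep(letters[1:10], each = 80)
  d <- data.frame(y = rpois(800, exp(0.5 + rnorm(10, 0, 0.5)[as.integer(factor(g))])),
                  g = g)
  sched <- mcmc_schedule(n_iter = 8000, burn_in = 2000, thin = 6)
  f1 <- fit_glmm(y ~ 1, list(g = "identity"), d, schedule = sched, seed = 3)
  f2 <- fit_glmm(y ~ 1, list(g = "identity"), d[sample(nrow(d)), ],
                 schedule = sched, seed = 3)
  expect_lt(abs(mean(f1$fixed_draws[, 1]) - mean(f2$fixed_draws[, 1])), 0.08)
  expect_lt(abs(mean(f1$variance_draws[, "g"]) - mean(f2$variance_draws[, "g"])), 0.1)
})

test_that("prior-only variance draws reproduce the scaled-F(1,1) quantiles", {
  fit <- fit_glmm(y ~ 1, list(g = "identity"),
                  data.frame(y = rpois(4, 1), g = letters[1:4]),
                  family = "poisson_log", prior_only = TRUE,
                  schedule = mcmc_schedule(n_iter = 100000, burn_in = 2000, thin = 7),
                  seed = 1)
  q <- quantile(fit$variance_draws[, "g"], c(0.1, 0.5, 0.9))
  q_theory <- 1000 * qf(c(0.1, 0.5, 0.9), 1, 1)
  # agreement on the log scale within Monte-Carlo error of a heavy tail
  expect_equal(unname(log(q)), log(q_theory), tolerance = 0.15)
})

test_that("contract violations are rejected", {
  d <- data.frame(y = c(1.5, 2, 3), g = c("a", "b", "c"))
  expect_error(fit_glmm(y ~ 1, list(), d, family = "poisson_log",
                        schedule = quick_schedule()), "nonnegative integers")
  expect_error(fit_glmm(y ~ 1, list(), data.frame(y = rep(1, 50)),
                        family = "gaussian", schedule = quick_schedule()),
               "degenerate-data")
  expect_error(mcmc_schedule(n_iter = 1000, burn_in = 950, thin = 1), "schedule error")
  expect_error(mcmc_schedule(n_iter = 1001, burn_in = 500, thin = 2), "schedule error")
  # structure lacking a level
  d2 <- data.frame(y = rpois(40, 1), g = rep(c("a", "b", "c", "d"), 10))
  cs <- build_covariance(structure_from_distance(
    great_circle_distance(generate_origins(3, seed = 1))), mode = "one_minus_geofst")
  expect_error(fit_glmm(y ~ 1, list(g = cs), d2, schedule = quick_schedule()),
               "structure error")
})

test_that("missing phenotype rows are dropped with a message", {
  d <- data.frame(y = rpois(60, 2), x = c(NA, rnorm(59)), g = rep(letters[1:6], 10))
  expect_message(
    fit <- fit_glmm(y ~ x, list(g = "identity"), d, schedule = quick_schedule(),
                    seed = 1),
    "dropping 1 row")
  expect_equal(fit$spec$n_obs, 59)
})
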