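# shared fixtures, built in code at test time

# a small trial design (6 provenances, 2 zones, 1 plot, 4 trees, 3 shoots)
small_design <- function(seed = 1, n_prov = 6, years = 2008L, ...) {
  origins <- generate_origins(n_prov, lat_span = 15, lon_span = 34, seed = seed)
  trial_design(origins, n_soil_zones = 2, plots_per_zone = 1,
               trees_per_plot = 4, shoots_per_tree = 3, years = years, ...)
}

# short MCMC schedule for unit tests (1000 retained draws)
quick_schedule <- function() mcmc_schedule(n_iter = 4000, burn_in = 1000, thin = 3)

# explicit toy genotype table: two populations, one biallelic locus,
# genotype lists given as allele-pair strings like "11", "12", "22"
toy_genotypes <- function(pop1, pop2, locus = "L1") {
  mk <- function(g, pop) {
    data.frame(individual = paste0(pop, "_", seq_along(g)),
               provenance = pop, locus = locus,
               allele1 = as.integer(substr(g, 1, 1)),
               allele2 = as.integer(substr(g, 2, 2)),
               stringsAsFactors = FALSE)
  }
  genotype_table(rbind(mk(pop1, "A"), mk(pop2, "B")))
}

# independent step-by-step Weir & Cockerham (1984) variance components for
# two samples at one biallelic locus; deliberately written as plain loops,
# a separate route from the package implementation
wc_theta_oracle <- function(pop1, pop2) {
  count_allele <- function(g, allele) {
    sum(vapply(g, function(s) sum(strsplit(s, "")[[1]] == allele), numeric(1)))
  }
  het_prop <- function(g, allele) {
    mean(vapply(g, function(s) {
      a <- strsplit(s, "")[[1]]
      sum(a == allele) == 1
    }, logical(1)))
  }
  alleles <- unique(unlist(strsplit(c(pop1, pop2), "")))
  n1 <- length(pop1); n2 <- length(pop2); r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  num <- den <- 0
  for (al in alleles) {
    p1 <- count_allele(pop1, al) / (2 * n1)
    p2 <- count_allele(pop2, al) / (2 * n2)
    h1 <- het_prop(pop1, al)
    h2 <- het_prop(pop2, al)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# construct a minimal fitted-model object with given draws (for report tests)
fake_fit <- function(fixed_draws, variance_draws, X = NULL,
                     family = "poisson_log") {
  if (is.null(X)) X <- matrix(1, 10, 1, dimnames = list(NULL, "(Intercept)"))
  structure(list(fixed_draws = as.matrix(fixed_draws),
                 variance_draws = as.matrix(variance_draws), X = X,
                 spec = list(family = family, n_obs = nrow(X),
                             include_unit = TRUE)),
            class = "provgall_glmm")
}
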