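#' Pipeline run configuration
#'
#' Bundles input paths (or a request to simulate them), the provenance
#' covariance mode, the model preset and the thresholds used by the
#' reporting stage. Referenced files are checked for existence up front so
#' misconfiguration fails before any computation.
#'
#' @param output_dir Directory for the report CSVs (created if needed).
#' @param seed Single integer seed; every stage derives its own stream from
#'   it (`seed` for origins/design, `seed + 1` genotypes, `seed + 2`
#'   phenotypes, `seed + 3` counts, `seed + 4` Mantel, `seed + 5` model
#'   fits).
#' @param covariance_mode `"identity"`, `"one_minus_fst"` or
#'   `"one_minus_geofst"`.
#' @param model_preset `"desk"` or `"paper"` ([mcmc_schedule()]).
#' @param fdr_method `"BH"` or `"BY"`.
#' @param incidence_threshold Gall types below this incidence in every year
#'   are excluded from modelling.
#' @param survey,phenotypes,origins,genotypes Input CSV paths; leave `NULL`
#'   with `simulate = TRUE` to generate synthetic inputs.
#' @param genotype_dialect Dialect for `genotypes` ([read_genotypes()]).
#' @param simulate Generate a synthetic trial instead of reading files.
#' @param truth A [truth_params()] for the synthetic counts (simulate only).
#' @param sim_args Named list of overrides for the synthetic design:
#'   `n_provenances` plus any [trial_design()] argument (used to scale the
#'   simulation down).
#' @param schedule Optional [mcmc_schedule()] overriding `model_preset`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(output_dir, seed = 1,
                       covariance_mode = c("one_minus_geofst", "one_minus_fst", "identity"),
                       model_preset = c("desk", "paper"),
                       fdr_method = c("BH", "BY"),
                       incidence_threshold = 0.01,
                       survey = NULL, phenotypes = NULL, origins = NULL,
                       genotypes = NULL, genotype_dialect = "long_csv",
                       simulate = is.null(survey),
                       truth = NULL, sim_args = list(), schedule = NULL) {
  covariance_mode <- match.arg(covariance_mode)
  model_preset <- match.arg(model_preset)
  fdr_method <- match.arg(fdr_method)
  paths <- c(survey = survey, phenotypes = phenotypes, origins = origins,
             genotypes = genotypes)
  if (!simulate) {
    if (is.null(survey) || is.null(origins))
      stop("configuration error: survey and origins paths required unless simulating",
           call. = FALSE)
    if (covariance_mode != "identity" && is.null(genotypes))
      stop("configuration error: covariance mode ", covariance_mode,
           " requires a genotype path", call. = FALSE)
    missing_files <- paths[!vapply(paths, file.exists, logical(1))]
    if (length(missing_files))
      stop("configuration error: missing input file(s): ",
           paste(missing_files, collapse = ", "), call. = FALSE)
  }
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 covariance_mode = covariance_mode, model_preset = model_preset,
                 fdr_method = fdr_method,
                 incidence_threshold = incidence_threshold,
                 survey = survey, phenotypes = phenotypes, origins = origins,
                 genotypes = genotypes, genotype_dialect = genotype_dialect,
                 simulate = simulate, truth = truth,
                 sim_args = sim_args, schedule = schedule),
            class = "run_config")
}

# stable hash of a config: md5 of its canonical YAML rendering
# (output_dir is excluded: where reports land does not change what they contain)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  cfg$truth <- if (!is.null(cfg$truth)) unclass(cfg$truth) else NULL
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full provenance-gall analysis pipeline
#'
#' Executes, in order: data acquisition (synthetic simulation or file
#' input), pairwise F_ST estimation, isolation-by-distance Mantel test,
#' GeoF_ST regression, covariance construction for the configured mode,
#' a Bayesian Poisson GLMM per retained gall type, and report writing.
#' Three CSVs are written to `output_dir`: `survey_summary.csv`
#' (Table-2-style totals, means, incidences and year ratios),
#' `variance_components.csv` and `fixed_effects.csv` (posterior means,
#' pMCMC and FDR-adjusted significance per term per gall type). Every
#' output carries a comment header with the tool version, config hash and
#' seed, so a rerun with the same config is byte-identical.
#'
#' @param config A [run_config()].
#' @return List with the report paths, the F_ST/Mantel/GeoF_ST objects, the
#'   fitted models and the per-stage timings, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t_all <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    t_all[[name]] <<- proc.time()[["elapsed"]] - t0
    message(sprintf("[%s] done in %.1fs", name, t_all[[name]]))
    res
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  header <- c(paste("provgall", as.character(utils::packageVersion("provgall"))),
              paste("config_hash:", hash), paste("seed:", config$seed))
  seed <- config$seed

  dat <- stage("input", {
    if (config$simulate) {
      sa <- config$sim_args
      origins <- generate_origins(sa$n_provenances %||% 20, seed = seed)
      design <- do.call(trial_design,
                        c(list(origins), sa[setdiff(names(sa), "n_provenances")]))
      gt <- simulate_genotypes(design, seed = seed + 1)
      ph <- simulate_phenotypes(design, seed = seed + 2)
      truth <- config$truth %||% truth_params(
        fixed = c(intercept = log(0.5), year2009 = -0.4),
        variances = c(provenance_structured = 0.3, provenance_nugget = 0.05,
                      soil_zone = 0.05, plot = 0.1, tree = 0.2, unit = 0.3),
        covariance_mode = config$covariance_mode, seed = seed + 3)
      dist_km <- great_circle_distance(origins)
      gen_cov <- build_covariance(
        structure_from_distance(dist_km), mode = "one_minus_geofst")
      survey <- simulate_gall_counts(design, truth, gen_cov, ph)
      list(survey = survey, phenotypes = ph, origins = origins, genotypes = gt)
    } else {
      list(survey = read_survey(config$survey),
           phenotypes = if (!is.null(config$phenotypes)) read_phenotypes(config$phenotypes),
           origins = read_origins(config$origins),
           genotypes = if (!is.null(config$genotypes))
             read_genotypes(config$genotypes, config$genotype_dialect))
    }
  })

  dist_km <- great_circle_distance(dat$origins)
  fst <- mant <- geo <- NULL
  if (config$covariance_mode == "identity") {
    structure_obj <- stage("covariance", build_covariance(
      mode = "identity", labels = dat$origins$code))
  } else {
    fst <- stage("fst", pairwise_fst(dat$genotypes))
    mant <- stage("mantel", {
      labs <- rownames(fst)
      mantel_test(unclass(fst), dist_km[labs, labs], n_perm = 999, seed = seed + 4)
    })
    structure_obj <- stage("covariance", {
      if (config$covariance_mode == "one_minus_fst") {
        build_covariance(fst, mode = "one_minus_fst")
      } else {
        labs <- rownames(fst)
        geo <- fit_geo_fst(fst, dist_km[labs, labs])
        build_covariance(predict_geo_fst(geo, dist_km), mode = "one_minus_geofst")
      }
    })
  }

  summ <- stage("summary", survey_summary(dat$survey))
  keep <- incidence_filter(summ, config$incidence_threshold)$retained
  ratios <- year_ratios(summ)
  summ_out <- merge(summ, ratios[, c("gall_type", "ratio", "ratio_label")],
                    by = "gall_type", all.x = TRUE)

  schedule <- config$schedule %||% mcmc_schedule(config$model_preset)
  fits <- stage("fit", {
    out <- list()
    for (g in keep) {
      d <- dat$survey[dat$survey$gall_type == g, ]
      d$year <- factor(d$year)  # two-level fixed effect, first year reference
      fixed <- if (nlevels(d$year) > 1) count ~ year else count ~ 1
      out[[g]] <- fit_glmm(fixed,
                           random = list(provenance = structure_obj,
                                         soil_zone = "identity",
                                         plot = "identity", tree = "identity"),
                           data = d, family = "poisson_log",
                           schedule = schedule, seed = seed + 5)
    }
    out
  })

  paths <- stage("report", {
    comp <- do.call(rbind, lapply(names(fits), function(g) {
      tab <- variance_components(fits[[g]])$components
      cbind(gall_type = g, tab)
    }))
    fixed_tabs <- lapply(names(fits), function(g) {
      s <- summary(fits[[g]])$fixed
      cbind(gall_type = g, s)
    })
    fx <- do.call(rbind, fixed_tabs)
    # FDR family: within each fixed-effect term across gall types
    fx$adjusted <- NA_real_
    for (tm in unique(fx$term)) {
      i <- fx$term == tm
      fx$adjusted[i] <- fdr_adjust(fx$pMCMC[i], config$fdr_method)$adjusted
    }
    fx$significant <- fx$adjusted < 0.05
    p1 <- write_table_csv(summ_out, file.path(config$output_dir, "survey_summary.csv"), header)
    p2 <- write_table_csv(comp, file.path(config$output_dir, "variance_components.csv"), header)
    p3 <- write_table_csv(fx, file.path(config$output_dir, "fixed_effects.csv"), header)
    c(summary = p1, components = p2, fixed = p3)
  })

  invisible(list(paths = paths, fst = fst, mantel = mant, geo_fst = geo,
                 structure = structure_obj, fits = fits, summary = summ_out,
                 retained = keep, timings = t_all, config_hash = hash))
}

#' Expected differentiation matrix from geographic distance
#'
#' Helper mapping a great-circle distance matrix to the expected pairwise
#' differentiation `1 - exp(-rate * km)` of the default
#' isolation-by-distance kernel, scaled to `fst_max`. Used to build a
#' generating covariance for synthetic data without simulating genotypes
#' first.
#'
#' @param dist_km Labelled distance matrix.
#' @param rate Per-km decay rate.
#' @param fst_max Asymptotic differentiation at large distance.
#' @return A `pairwise_fst`-classed matrix.
#' @export
structure_from_distance <- function(dist_km, rate = 0.002, fst_max = 0.2) {
  m <- fst_max * (1 - exp(-rate * dist_km))
  diag(m) <- 0
  class(m) <- c("pairwise_fst", class(m))
  m
}
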