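#' Build a pipeline configuration
#'
#' Collects every tunable of the analysis chain in one list. `inputs` may
#' name CSV files for the survey, trait, surface-water frequency,
#' groundwater and soil tables; when absent, a synthetic dataset is
#' generated from `scenario`.
#'
#' @param seed root seed for every stochastic step (default 1).
#' @param k_habitats K-means habitat count (default 3).
#' @param n_levels hierarchical water levels per variable for the two-way
#'   design (default 3).
#' @param alpha significance level for the gated habitat tests.
#' @param n_factors factors to extract (default 2, or `"auto"`).
#' @param decomp_formula design formula for the two-way decomposition.
#' @param vif_threshold collinearity screen threshold for soil predictors.
#' @param scenario [synth_scenario()] used when no inputs are given; its
#'   seed is overridden by `seed`.
#' @param inputs optional named list of file paths: `survey`, `traits`,
#'   `freq`, `gwd`, `soil`.
#' @param out_dir optional output directory for stage CSVs and the JSON
#'   report.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, k_habitats = 3, n_levels = 3,
                            alpha = 0.05, n_factors = 2,
                            decomp_formula = ~ sw_level * gw_level,
                            vif_threshold = 10,
                            scenario = synth_scenario(),
                            inputs = NULL, out_dir = NULL) {
  scenario$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), k_habitats = k_habitats,
                 n_levels = n_levels, alpha = alpha, n_factors = n_factors,
                 decomp_formula = decomp_formula,
                 vif_threshold = vif_threshold, scenario = scenario,
                 inputs = inputs, out_dir = out_dir),
            class = "pipeline_config")
}

.load_config <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    y <- yaml::read_yaml(config)
    sc_args <- y$scenario
    sc <- if (is.null(sc_args)) synth_scenario() else
      do.call(synth_scenario, sc_args)
    args <- y[setdiff(names(y), "scenario")]
    if (!is.null(args$decomp_formula)) {
      args$decomp_formula <- stats::as.formula(args$decomp_formula)
    }
    return(do.call(pipeline_config, c(args, list(scenario = sc))))
  }
  stop("config must be a pipeline_config or a YAML file path")
}

#' Run the full analysis chain
#'
#' Executes, in order: data loading or synthesis; importance values and
#' CWM tables; the environment profile (SWD index, K-means habitats, water
#' levels, soil profile means); gated habitat-difference tests per trait;
#' standardized regressions of CWM traits on SWD and groundwater depth;
#' varimax factor analysis of the trait matrix; total and two-way
#' decompositions of every trait; and a piecewise SEM for the
#' interspecific and intraspecific component of every trait. All
#' randomness flows from `config$seed`, so the report is a pure function
#' of (inputs, config).
#'
#' @param config a [pipeline_config()], or the path to a YAML file with
#'   its fields.
#' @return (invisibly) a report list with one element per stage; when
#'   `config$out_dir` is set, stage CSVs and `report.json` are written
#'   there as well.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- .load_config(config)
  set.seed(cfg$seed)

  if (is.null(cfg$inputs)) {
    dat <- synth_community(cfg$scenario)
    survey <- dat$survey; traits <- dat$traits
    freq <- dat$freq; gwd <- dat$gwd; soil <- dat$soil
    truth <- dat$truth
  } else {
    survey <- read_survey(cfg$inputs$survey)
    traits <- utils::read.csv(cfg$inputs$traits, check.names = FALSE,
                              stringsAsFactors = FALSE)
    freq <- utils::read.csv(cfg$inputs$freq, stringsAsFactors = FALSE)
    gwd <- utils::read.csv(cfg$inputs$gwd, stringsAsFactors = FALSE)
    soil <- if (is.null(cfg$inputs$soil)) NULL else
      utils::read.csv(cfg$inputs$soil, stringsAsFactors = FALSE)
    truth <- NULL
  }

  iv <- importance_values(survey)
  fixed <- species_fixed_means(traits)
  cwm <- cwm_table(iv, traits, fixed = fixed)
  env <- env_profile(freq, gwd, soil, k = cfg$k_habitats,
                     n_levels = cfg$n_levels, seed = cfg$seed)

  sub_env <- env[match(cwm$plot_id[!duplicated(cwm$subplot_id)],
                       env$plot_id), , drop = FALSE]
  sub_env$subplot_id <- cwm$subplot_id[!duplicated(cwm$subplot_id)]

  habitat_tests <- lapply(unique(cwm$trait), function(tr) {
    d <- cwm[cwm$trait == tr, ]
    hb <- env$habitat[match(d$plot_id, env$plot_id)]
    habitat_trait_test(d$cwm_specific, hb, alpha = cfg$alpha, trait = tr)
  })
  names(habitat_tests) <- unique(cwm$trait)

  regressions <- regress_cwm(cwm, env)

  wide <- stats::reshape(
    cwm[, c("subplot_id", "trait", "cwm_specific")],
    idvar = "subplot_id", timevar = "trait", direction = "wide")
  names(wide) <- sub("^cwm_specific\\.", "", names(wide))
  mat <- wide[stats::complete.cases(wide), -1L, drop = FALSE]
  factors <- trait_factor_analysis(mat, n_factors = cfg$n_factors)

  decomp_total <- decompose_cwm(cwm)
  decomp_anova <- decompose_cwm(cwm, design = sub_env,
                                formula = cfg$decomp_formula)

  soil_vars <- intersect(c("swc", "stn", "tds", "ph", "om", "tp"),
                         names(env))
  sems <- list()
  if (length(soil_vars) >= 2L) {
    screen <- vif_screen(env, soil_vars, threshold = cfg$vif_threshold)
    sem_soil <- intersect(c("swc", "stn"), screen$keep)
    for (tr in unique(cwm$trait)) {
      d <- cwm[cwm$trait == tr, ]
      e <- env[match(d$plot_id, env$plot_id), , drop = FALSE]
      for (comp in c(interspecific = "cwm_fixed",
                     intraspecific = "intraspecific")) {
        sem_dat <- data.frame(resp = d[[comp]], swd = e$swd, gwd = e$gwd)
        for (sv in sem_soil) sem_dat[[sv]] <- e[[sv]]
        fml <- list()
        if ("swc" %in% sem_soil) fml <- c(fml, list(swc ~ swd))
        fml <- c(fml, list(stats::reformulate(
          c("swd", "gwd", sem_soil), response = "resp")))
        nm <- paste0(tr, ".",
                     names(which(c(interspecific = "cwm_fixed",
                                   intraspecific = "intraspecific") == comp)))
        sems[[nm]] <- fit_psem(fml, sem_dat)
      }
    }
  }

  report <- list(
    config = cfg, n_subplots = length(unique(cwm$subplot_id)),
    iv = iv, cwm = cwm, env = env,
    habitat_tests = habitat_tests, regressions = regressions,
    factors = factors, decomp_total = decomp_total,
    decomp_anova = decomp_anova,
    decomp_summary = decomp_summary(decomp_total),
    sems = sems, truth = truth)

  if (!is.null(cfg$out_dir)) .write_report(report, cfg$out_dir)
  invisible(report)
}

.write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                          row.names = FALSE)
  wcsv(report$iv, "importance_values.csv")
  wcsv(report$cwm, "cwm.csv")
  env_out <- report$env
  attr(env_out, "centroids") <- NULL
  wcsv(env_out, "environment.csv")
  ht <- do.call(rbind, lapply(report$habitat_tests, function(h) {
    data.frame(trait = h$trait, test_used = h$test_used,
               omnibus_p = h$omnibus_p,
               letters = paste(names(h$letters), h$letters, sep = ":",
                               collapse = " "),
               stringsAsFactors = FALSE)
  }))
  wcsv(ht, "habitat_tests.csv")
  wcsv(report$regressions, "regressions.csv")
  ld <- as.data.frame(report$factors$loadings)
  ld$trait <- rownames(ld)
  wcsv(ld[, c(ncol(ld), seq_len(ncol(ld) - 1L))], "factor_loadings.csv")
  wcsv(do.call(rbind, lapply(report$decomp_anova, summary)),
       "decomposition_anova.csv")
  wcsv(report$decomp_summary, "decomposition_summary.csv")
  if (length(report$sems) > 0L) {
    paths <- do.call(rbind, lapply(names(report$sems), function(nm) {
      p <- report$sems[[nm]]$paths
      p$model <- nm
      p
    }))
    wcsv(paths, "sem_paths.csv")
  }
  meta <- list(
    seed = report$config$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("traitpart")),
    n_subplots = report$n_subplots,
    k_habitats = report$config$k_habitats,
    n_levels = report$config$n_levels,
    alpha = report$config$alpha,
    decomp_formula = deparse(report$config$decomp_formula),
    sem_fits = lapply(report$sems, function(s) {
      list(C = s$C, df = s$df, p = s$p, AIC = s$aic, r2 = as.list(s$r2))
    }))
  jsonlite::write_json(meta, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
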