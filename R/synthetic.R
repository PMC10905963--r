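#' Default trait pool for the synthetic generator
#'
#' Five community traits with baseline levels, a between-species baseline
#' trend along the species niche optimum (the turnover signal), a common
#' within-species plasticity slope along wetness (the plasticity signal,
#' aligned in sign with the baseline trend so the two components covary
#' positively by default), and a small per-species baseline jitter.
#' Levels bracket values typical of desert riparian vegetation (H in cm,
#' LT in mm, LNC in mg/g, N/P dimensionless, SPAD in meter units).
#'
#' @return data.frame with columns `trait`, `base_mid`, `base_slope`,
#'   `plast_slope`, `jitter_sd`.
#' @export
default_trait_pool <- function() {
  data.frame(
    trait       = c("H",  "SPAD", "LT",    "LNC", "N/P"),
    base_mid    = c(190,  42,     0.42,    17,    17),
    base_slope  = c(-90,  6,      -0.08,   3.5,   1.6),
    axis2_slope = c(0,    4.0,    -0.055,  0,     0),
    plast_slope = c(-25,  2.0,    -0.025,  1.1,   0.5),
    jitter_sd   = c(8,    0.8,    0.010,   0.4,   0.2),
    stringsAsFactors = FALSE)
}

#' Define a synthetic desert-wetland community scenario
#'
#' Describes a study design of `n_plots` plots x `subplots_per_plot`
#' subplots on a latent wetness gradient. Species abundances respond to
#' wetness through Gaussian niche curves scaled by `turnover_weight`;
#' within-species trait values drift along the same gradient with slope
#' scaled by `plasticity_weight`. Surface-water frequencies rise and
#' groundwater depth falls with wetness; soil water content tracks the
#' surface-water disturbance index while soil total nitrogen is
#' independent of water.
#'
#' @param n_plots number of plots (default 19).
#' @param subplots_per_plot subplots per plot (default 4).
#' @param n_species species-pool size (default 12).
#' @param turnover_weight scales the niche (species-composition) response
#'   to wetness; 0 removes turnover.
#' @param plasticity_weight scales within-species trait drift; 0 removes
#'   plasticity.
#' @param niche_breadth Gaussian niche SD on the wetness axis.
#' @param abundance_scale expected count of a species at its optimum.
#' @param abundance_noise lognormal SD of plot-to-plot abundance noise.
#' @param trait_noise_frac trait measurement noise, as a fraction of the
#'   between-species baseline SD of each trait.
#' @param independent_axes if TRUE, the surface-water and groundwater
#'   scores are fully decoupled (shuffled against each other) so a crossed
#'   two-way design is realizable; default FALSE.
#' @param axis_coupling with `independent_axes = FALSE`, the weight of the
#'   shared wetness axis in the groundwater score (default 0.6): the two
#'   water variables are strongly but not perfectly coupled, as in desert
#'   wetlands where shallow-groundwater sites differ in overflow exposure.
#' @param n_cells surface-water raster cells per plot.
#' @param seed RNG seed; the whole dataset is a deterministic function of
#'   the scenario.
#' @param trait_pool trait parameter table, see [default_trait_pool()].
#' @return object of class `"synth_scenario"` (a list of the above).
#' @export
synth_scenario <- function(n_plots = 19, subplots_per_plot = 4,
                           n_species = 12, turnover_weight = 1,
                           plasticity_weight = 0.5, niche_breadth = 0.6,
                           abundance_scale = 40, abundance_noise = 0.3,
                           trait_noise_frac = 0.02,
                           independent_axes = FALSE, axis_coupling = 0.6,
                           n_cells = 40,
                           seed = 1L, trait_pool = default_trait_pool()) {
  stopifnot(turnover_weight >= 0, plasticity_weight >= 0, niche_breadth > 0,
            n_plots >= 2, subplots_per_plot >= 1, n_species >= 3,
            axis_coupling >= 0, axis_coupling <= 1)
  structure(list(
    n_plots = n_plots, subplots_per_plot = subplots_per_plot,
    n_species = n_species, turnover_weight = turnover_weight,
    plasticity_weight = plasticity_weight, niche_breadth = niche_breadth,
    abundance_scale = abundance_scale, abundance_noise = abundance_noise,
    trait_noise_frac = trait_noise_frac,
    independent_axes = independent_axes, axis_coupling = axis_coupling,
    n_cells = n_cells,
    seed = as.integer(seed), trait_pool = trait_pool,
    swd_base = -1, swd_gain = 2.2, swd_noise = 0.15,
    gwd_base = 4.5, gwd_gain = 2.8, gwd_noise = 0.2),
    class = "synth_scenario")
}

#' Oppose plasticity to the between-species trend for selected traits
#'
#' Flips the within-species plasticity slope of the nominated traits so it
#' runs against the between-species baseline trend along the gradient.
#' Communities then shift toward, say, shorter species while individuals of
#' each species grow taller, which makes the covariation component of the
#' decomposition negative for those traits.
#'
#' @param scenario a [synth_scenario()].
#' @param traits trait names to oppose (default `c("H", "LNC")`).
#' @return the modified scenario.
#' @export
make_negative_covariation <- function(scenario, traits = c("H", "LNC")) {
  stopifnot(inherits(scenario, "synth_scenario"),
            all(traits %in% scenario$trait_pool$trait))
  tp <- scenario$trait_pool
  i <- tp$trait %in% traits
  tp$plast_slope[i] <- -sign(tp$base_slope[i]) * abs(tp$plast_slope[i])
  scenario$trait_pool <- tp
  scenario
}

.species_pool <- function(sc) {
  opt <- seq(-1, 1, length.out = sc$n_species)
  tp <- sc$trait_pool
  # second species-level axis, orthogonal in expectation to the niche
  # optimum: carries the photosynthetic trade-off (SPAD vs LT)
  u <- stats::rnorm(sc$n_species)
  ax2 <- if (is.null(tp$axis2_slope)) rep(0, nrow(tp)) else tp$axis2_slope
  base <- outer(opt, tp$base_slope) + outer(u, ax2) +
    matrix(tp$base_mid, sc$n_species, nrow(tp), byrow = TRUE) +
    matrix(stats::rnorm(sc$n_species * nrow(tp)), sc$n_species) *
      matrix(tp$jitter_sd, sc$n_species, nrow(tp), byrow = TRUE)
  colnames(base) <- tp$trait
  rownames(base) <- sprintf("sp%02d", seq_len(sc$n_species))
  base[, "H"] <- pmax(base[, "H"], 20)
  list(species = rownames(base), opt = opt, base = base,
       crown_area = 0.3 + 0.003 * base[, "H"])
}

.niche_lambda <- function(sc, pool, w) {
  sc$abundance_scale *
    exp(sc$turnover_weight * (-(w - pool$opt)^2 / (2 * sc$niche_breadth^2)))
}

#' Generate a synthetic dataset from a scenario
#'
#' Draws the survey, trait, surface-water frequency, groundwater and soil
#' tables implied by the scenario, together with the ground truth of the
#' noiseless construction: per-trait sums of squares of the interspecific
#' and intraspecific components obtained by pushing the *expected* (noise-
#' free) abundances and trait values through the same CWM algebra. Every
#' subplot is guaranteed at least two species.
#'
#' @param scenario a [synth_scenario()].
#' @return object of class `"synth_data"`: `survey`, `traits`, `freq`,
#'   `gwd`, `soil` (data.frames), `truth` (list per trait), `wetness`
#'   (per-plot scores), `scenario`.
#' @export
synth_community <- function(scenario) {
  sc <- scenario
  stopifnot(inherits(sc, "synth_scenario"))
  set.seed(sc$seed)
  pool <- .species_pool(sc)
  tp <- sc$trait_pool
  noise_sd <- sc$trait_noise_frac *
    apply(pool$base, 2L, stats::sd)

  sw_score <- seq(-1, 1, length.out = sc$n_plots)
  gw_score <- if (sc$independent_axes) {
    sample(sw_score)
  } else {
    cpl <- sc$axis_coupling
    g <- cpl * sw_score + (1 - cpl) * sample(sw_score)
    as.vector(scale(g)) * stats::sd(sw_score)  # same scale as sw_score
  }
  wetness <- (sw_score + gw_score) / 2
  plot_ids <- sprintf("P%02d", seq_len(sc$n_plots))

  # feasibility: some species must be viable on every plot
  lam0 <- sapply(wetness, function(w) max(.niche_lambda(sc, pool, w)))
  if (any(lam0 < 0.5)) {
    stop("infeasible scenario: expected communities are empty on some plots")
  }

  survey <- list(); traits <- list()
  for (p in seq_len(sc$n_plots)) {
    lam <- .niche_lambda(sc, pool, wetness[p])
    for (q in seq_len(sc$subplots_per_plot)) {
      sub_id <- sprintf("%sS%d", plot_ids[p], q)
      n <- stats::rpois(sc$n_species,
                        lam * exp(stats::rnorm(sc$n_species, 0,
                                               sc$abundance_noise)))
      if (sum(n > 0) < 2L) {  # rescue: seed the two most viable species
        top <- order(lam, decreasing = TRUE)[1:2]
        n[top] <- pmax(n[top], 1L)
      }
      pres <- which(n > 0)
      tv <- pool$base[pres, , drop = FALSE] +
        sc$plasticity_weight * wetness[p] *
          matrix(tp$plast_slope, length(pres), nrow(tp), byrow = TRUE) +
        matrix(stats::rnorm(length(pres) * nrow(tp)), length(pres)) *
          matrix(noise_sd, length(pres), nrow(tp), byrow = TRUE)
      tv[, "H"] <- pmax(tv[, "H"], 5)
      survey[[length(survey) + 1L]] <- data.frame(
        plot_id = plot_ids[p], subplot_id = sub_id,
        species = pool$species[pres], n_individuals = n[pres],
        mean_height = tv[, "H"],
        coverage = n[pres] * pool$crown_area[pres] *
          exp(stats::rnorm(length(pres), 0, 0.1)),
        stringsAsFactors = FALSE)
      traits[[length(traits) + 1L]] <- data.frame(
        subplot_id = sub_id,
        species = rep(pool$species[pres], times = nrow(tp)),
        trait = rep(tp$trait, each = length(pres)),
        value = as.vector(tv), stringsAsFactors = FALSE)
    }
  }
  survey <- do.call(rbind, c(survey, list(make.row.names = FALSE)))
  traits <- do.call(rbind, c(traits, list(make.row.names = FALSE)))

  swd_true <- sc$swd_base + sc$swd_gain * sw_score +
    stats::rnorm(sc$n_plots, 0, sc$swd_noise)
  freq <- do.call(rbind, lapply(seq_len(sc$n_plots), function(p) {
    u <- stats::runif(sc$n_cells)
    w <- exp(swd_true[p]) * u / sum(u)
    data.frame(plot_id = plot_ids[p], cell_id = seq_len(sc$n_cells),
               frequency = pmin(w, 1), stringsAsFactors = FALSE)
  }))
  gwd <- data.frame(
    plot_id = plot_ids,
    gwd = pmax(sc$gwd_base - sc$gwd_gain * gw_score +
                 stats::rnorm(sc$n_plots, 0, sc$gwd_noise), 0.3),
    stringsAsFactors = FALSE)

  z_sw <- zscore(swd_true)
  soil_plot <- data.frame(
    plot_id = plot_ids,
    swc = 9 + 3.5 * z_sw + stats::rnorm(sc$n_plots, 0, 0.8),
    stn = 0.45 + stats::rnorm(sc$n_plots, 0, 0.08),
    tds = 2.5 + 0.9 * z_sw + stats::rnorm(sc$n_plots, 0, 0.5),
    ph = 8.2 - 0.12 * z_sw + stats::rnorm(sc$n_plots, 0, 0.08),
    om = 5.5 + 1.2 * z_sw + stats::rnorm(sc$n_plots, 0, 0.7),
    tp = 0.62 + stats::rnorm(sc$n_plots, 0, 0.05))
  layers <- c("0-5", "5-20", "20-40", "40-60", "60-80", "80-100")
  soil <- do.call(rbind, lapply(layers, function(ly) {
    v <- c("swc", "stn", "tds", "ph", "om", "tp")
    data.frame(plot_id = rep(soil_plot$plot_id, times = length(v)),
               layer = ly,
               variable = rep(v, each = nrow(soil_plot)),
               value = unlist(lapply(v, function(vv) {
                 soil_plot[[vv]] + stats::rnorm(nrow(soil_plot), 0,
                                                0.03 * abs(soil_plot[[vv]]))
               }), use.names = FALSE),
               stringsAsFactors = FALSE)
  }))

  truth <- .synth_truth(sc, pool, wetness, plot_ids)
  structure(list(survey = survey, traits = traits, freq = freq, gwd = gwd,
                 soil = soil, truth = truth,
                 wetness = data.frame(plot_id = plot_ids,
                                      sw_score = sw_score,
                                      gw_score = gw_score,
                                      wetness = wetness, swd_true = swd_true),
                 scenario = sc),
            class = "synth_data")
}

# ground truth of the noiseless construction: expected abundances, expected
# trait values, deterministic presence (expected count >= 0.5)
.synth_truth <- function(sc, pool, wetness, plot_ids) {
  tp <- sc$trait_pool
  iv <- list(); tr <- list()
  for (p in seq_along(wetness)) {
    lam <- .niche_lambda(sc, pool, wetness[p])
    pres <- which(lam >= 0.5)
    if (length(pres) < 2L) pres <- order(lam, decreasing = TRUE)[1:2]
    tv <- pool$base[pres, , drop = FALSE] +
      sc$plasticity_weight * wetness[p] *
        matrix(tp$plast_slope, length(pres), nrow(tp), byrow = TRUE)
    tv[, "H"] <- pmax(tv[, "H"], 5)
    sub_id <- sprintf("%sS0", plot_ids[p])
    a <- lam[pres]; h <- tv[, "H"]; cv <- lam[pres] * pool$crown_area[pres]
    iv[[p]] <- data.frame(plot_id = plot_ids[p], subplot_id = sub_id,
                          species = pool$species[pres],
                          Ar = a / sum(a), Hr = h / sum(h),
                          Cr = cv / sum(cv), stringsAsFactors = FALSE)
    iv[[p]]$IV <- (iv[[p]]$Ar + iv[[p]]$Hr + iv[[p]]$Cr) / 3
    tr[[p]] <- data.frame(subplot_id = sub_id,
                          species = rep(pool$species[pres], nrow(tp)),
                          trait = rep(tp$trait, each = length(pres)),
                          value = as.vector(tv), stringsAsFactors = FALSE)
  }
  iv <- do.call(rbind, c(iv, list(make.row.names = FALSE)))
  tr <- do.call(rbind, c(tr, list(make.row.names = FALSE)))
  cwm <- cwm_table(iv, tr)
  out <- lapply(unique(tr$trait), function(t0) {
    d <- cwm[cwm$trait == t0, ]
    dec <- trait_decomp(d$cwm_specific, d$cwm_fixed, trait = t0)
    list(ss_fixed = unname(dec$ss["total", "fixed"]),
         ss_intra = unname(dec$ss["total", "intra"]),
         ss_cov = unname(dec$ss["total", "cov"]),
         ratio_fixed_intra = unname(dec$ss["total", "fixed"] /
                                      dec$ss["total", "intra"]))
  })
  names(out) <- unique(tr$trait)
  out
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `survey.csv`, `traits.csv`, `freq.csv`, `gwd.csv`, `soil.csv` and
#' `truth.json` into `dir`.
#'
#' @param x a [synth_community()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth <- function(x, dir) {
  stopifnot(inherits(x, "synth_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("survey", "traits", "freq", "gwd", "soil")) {
    utils::write.csv(x[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(x$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
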