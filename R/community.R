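#' Crown coverage from crown diameters
#'
#' Projected crown area of one individual, treating the crown outline as an
#' ellipse with the measured crown length and width as its axes.
#'
#' @param length crown length (same length unit as `width`).
#' @param width crown width.
#' @return projected area, `pi * (length/2) * (width/2)`.
#' @export
crown_coverage <- function(length, width) {
  stopifnot(all(length > 0), all(width > 0))
  pi * (length / 2) * (width / 2)
}

#' Read a vegetation survey table
#'
#' Reads a CSV/TSV with one row per (plot, subplot, species). Columns are
#' renamed to the canonical names `plot_id`, `subplot_id`, `species`,
#' `n_individuals`, `mean_height`, `coverage` via `mapping`. If the file has
#' `crown_length` and `crown_width` columns instead of `coverage`, per-species
#' coverage is derived as `n_individuals * crown_coverage(L, W)`.
#'
#' @param path file path.
#' @param mapping named character vector or list, canonical name -> column
#'   name in the file; or path to a YAML file holding such a map. `NULL` means
#'   the file already uses canonical names.
#' @param sep field separator (default `","`).
#' @return a data.frame of species records.
#' @export
read_survey <- function(path, mapping = NULL, sep = ",") {
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         check.names = FALSE, stringsAsFactors = FALSE)
  x <- .apply_mapping(x, mapping)
  if (is.null(x$coverage) && !is.null(x$crown_length) && !is.null(x$crown_width)) {
    x$coverage <- x$n_individuals * crown_coverage(x$crown_length, x$crown_width)
  }
  need <- c("plot_id", "subplot_id", "species", "n_individuals",
            "mean_height", "coverage")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop("survey table is missing column(s): ", paste(miss, collapse = ", "))
  }
  validate_survey(x)
  x
}

.apply_mapping <- function(x, mapping) {
  if (is.null(mapping)) return(x)
  if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping)) {
    mapping <- yaml::read_yaml(mapping)
  }
  mapping <- unlist(mapping)
  for (canon in names(mapping)) {
    src <- mapping[[canon]]
    if (!src %in% names(x)) stop("mapped column not in file: ", src)
    names(x)[names(x) == src] <- canon
  }
  x
}

#' Validate a survey (species record) table
#'
#' Checks the structural invariants of the survey: non-negative integer
#' counts, positive heights, non-negative coverage, and uniqueness of
#' (subplot, species) pairs.
#'
#' @param survey data.frame with canonical survey columns.
#' @return the survey, invisibly; errors describe the first violation found.
#' @export
validate_survey <- function(survey) {
  stopifnot(is.data.frame(survey))
  n <- survey$n_individuals
  if (any(n < 0) || any(n != round(n))) {
    stop("n_individuals must be non-negative integers")
  }
  if (any(survey$mean_height <= 0)) stop("mean_height must be positive")
  if (any(survey$coverage < 0)) stop("coverage must be non-negative")
  key <- paste(survey$subplot_id, survey$species, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (subplot, species) record(s): ",
         paste(unique(survey$species[duplicated(key)]), collapse = ", "))
  }
  invisible(survey)
}

#' Species importance values per subplot
#'
#' For every subplot, relative abundance `Ar`, relative height `Hr` and
#' relative coverage `Cr` of each species are the species' share of the
#' subplot totals, and the importance value is their mean,
#' `IV = (Ar + Hr + Cr) / 3`. Within a subplot each of the four columns sums
#' to one.
#'
#' Subplots with a single species are excluded (a community-scale quantity is
#' undefined there), as are subplots whose total abundance, height or
#' coverage is zero; both exclusions are reported via `message()`/`warning()`.
#'
#' @param survey data.frame of species records (see [read_survey()]).
#' @return data.frame with columns `plot_id`, `subplot_id`, `species`, `Ar`,
#'   `Hr`, `Cr`, `IV`.
#' @export
importance_values <- function(survey) {
  validate_survey(survey)
  keep <- survey$n_individuals > 0
  survey <- survey[keep, , drop = FALSE]
  counts <- table(survey$subplot_id)
  single <- names(counts)[counts < 2]
  if (length(single) > 0L) {
    message("excluding ", length(single),
            " single-species subplot(s): ", paste(single, collapse = ", "))
    survey <- survey[!survey$subplot_id %in% single, , drop = FALSE]
  }
  if (nrow(survey) == 0L) stop("no multi-species subplots left")

  out <- do.call(rbind, lapply(split(survey, survey$subplot_id), function(s) {
    tn <- sum(s$n_individuals); th <- sum(s$mean_height); tc <- sum(s$coverage)
    if (tn <= 0 || th <= 0 || tc <= 0) {
      warning("subplot ", s$subplot_id[1L],
              " rejected: zero total abundance, height or coverage")
      return(NULL)
    }
    data.frame(plot_id = s$plot_id, subplot_id = s$subplot_id,
               species = s$species,
               Ar = s$n_individuals / tn,
               Hr = s$mean_height / th,
               Cr = s$coverage / tc,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$IV <- (out$Ar + out$Hr + out$Cr) / 3
  out
}

#' Fixed (species-level) trait means
#'
#' The fixed trait value of a species is the unweighted mean of its trait
#' values over all subplots in which it was measured. Species lacking any
#' value for a trait are simply absent from that trait's map.
#'
#' @param traits long data.frame with columns `subplot_id`, `species`,
#'   `trait`, `value`.
#' @return data.frame with columns `species`, `trait`, `fixed_mean`,
#'   `n_subplots`.
#' @export
species_fixed_means <- function(traits) {
  .check_traits(traits)
  ok <- is.finite(traits$value)
  if (!all(ok)) {
    message("dropping ", sum(!ok), " non-finite trait value(s)")
    traits <- traits[ok, , drop = FALSE]
  }
  agg <- stats::aggregate(value ~ species + trait, data = traits,
                          FUN = mean)
  nobs <- stats::aggregate(value ~ species + trait, data = traits,
                           FUN = length)
  out <- data.frame(species = agg$species, trait = agg$trait,
                    fixed_mean = agg$value, n_subplots = nobs$value,
                    stringsAsFactors = FALSE)
  out[order(out$trait, out$species), , drop = FALSE]
}

.check_traits <- function(traits) {
  need <- c("subplot_id", "species", "trait", "value")
  miss <- setdiff(need, names(traits))
  if (length(miss) > 0L) {
    stop("trait table is missing column(s): ", paste(miss, collapse = ", "))
  }
  invisible(traits)
}

#' Check ratio traits against their components
#'
#' Where a subplot x species combination carries both components of a ratio
#' trait (C/N = LCC/LNC, C/P = LCC/LPC, N/P = LNC/LPC) as well as the ratio
#' itself, the stored ratio must equal the recomputed one.
#'
#' @param traits long trait table.
#' @param tol relative tolerance (default `1e-6`).
#' @return data.frame of violations (zero rows when consistent).
#' @export
check_trait_ratios <- function(traits, tol = 1e-6) {
  .check_traits(traits)
  ratios <- list("C/N" = c("LCC", "LNC"),
                 "C/P" = c("LCC", "LPC"),
                 "N/P" = c("LNC", "LPC"))
  wide <- stats::reshape(traits, idvar = c("subplot_id", "species"),
                         timevar = "trait", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  bad <- list()
  for (r in names(ratios)) {
    comp <- ratios[[r]]
    if (!all(c(r, comp) %in% names(wide))) next
    have <- stats::complete.cases(wide[, c(r, comp)])
    expect <- wide[[comp[1L]]][have] / wide[[comp[2L]]][have]
    got <- wide[[r]][have]
    off <- abs(got - expect) > tol * pmax(abs(expect), 1)
    if (any(off)) {
      bad[[r]] <- data.frame(subplot_id = wide$subplot_id[have][off],
                             species = wide$species[have][off],
                             trait = r, stored = got[off],
                             recomputed = expect[off])
    }
  }
  if (length(bad) == 0L) {
    return(data.frame(subplot_id = character(), species = character(),
                      trait = character(), stored = numeric(),
                      recomputed = numeric()))
  }
  do.call(rbind, c(bad, list(make.row.names = FALSE)))
}

#' Community-weighted mean traits, specific and fixed
#'
#' For each subplot and trait, the specific CWM weights the subplot-specific
#' trait values by species importance values, `sum(IV_j * trait_j)`; the
#' fixed CWM weights the species fixed means instead; and the intraspecific
#' component is their difference, so that
#' `cwm_specific = cwm_fixed + intraspecific` holds exactly by construction.
#' The fixed CWM is the interspecific (species turnover) component of the
#' community trait.
#'
#' When a species carrying importance in a subplot has no specific trait
#' value, either the subplot is dropped for that trait (default: keeps the
#' weights faithful to the survey) or the species is dropped and the
#' remaining IVs renormalized.
#'
#' @param iv importance values from [importance_values()].
#' @param traits long trait table (`subplot_id`, `species`, `trait`, `value`).
#' @param fixed optional fixed means from [species_fixed_means()]; computed
#'   from `traits` when `NULL`.
#' @param missing `"drop_subplot"` (default) or `"renormalize"`.
#' @return data.frame with columns `plot_id`, `subplot_id`, `trait`,
#'   `cwm_specific`, `cwm_fixed`, `intraspecific`.
#' @export
cwm_table <- function(iv, traits, fixed = NULL,
                      missing = c("drop_subplot", "renormalize")) {
  missing <- match.arg(missing)
  .check_traits(traits)
  if (is.null(fixed)) fixed <- species_fixed_means(traits)
  plot_of <- iv$plot_id[!duplicated(iv$subplot_id)]
  names(plot_of) <- iv$subplot_id[!duplicated(iv$subplot_id)]

  trait_names <- unique(traits$trait)
  rows <- vector("list", 0L)
  dropped <- character(0)
  for (tr in trait_names) {
    tt <- traits[traits$trait == tr & is.finite(traits$value), , drop = FALSE]
    fm <- fixed[fixed$trait == tr, , drop = FALSE]
    spec_val <- stats::setNames(tt$value, paste(tt$subplot_id, tt$species, sep = "\r"))
    fix_val <- stats::setNames(fm$fixed_mean, fm$species)
    for (sp in split(iv, iv$subplot_id)) {
      v <- spec_val[paste(sp$subplot_id, sp$species, sep = "\r")]
      f <- fix_val[sp$species]
      w <- sp$IV
      ok <- is.finite(v) & is.finite(f)
      if (!all(ok)) {
        if (missing == "drop_subplot" || !any(ok)) {
          dropped <- c(dropped, paste0(sp$subplot_id[1L], ":", tr))
          next
        }
        v <- v[ok]; f <- f[ok]; w <- w[ok] / sum(w[ok])
      }
      cs <- sum(w * v)
      cf <- sum(w * f)
      rows[[length(rows) + 1L]] <- data.frame(
        plot_id = unname(plot_of[as.character(sp$subplot_id[1L])]),
        subplot_id = sp$subplot_id[1L], trait = tr,
        cwm_specific = cs, cwm_fixed = cf, intraspecific = cs - cf,
        stringsAsFactors = FALSE)
    }
  }
  if (length(dropped) > 0L) {
    message("dropped ", length(dropped),
            " subplot x trait combination(s) with missing trait values")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
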