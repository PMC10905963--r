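#' Surface-water disturbance index
#'
#' For each plot, SWD is the natural log of the summed per-cell surface-water
#' occurrence frequencies within the 1-ha neighbourhood of the plot point,
#' `SWD = ln(sum(w_i))`. Plots where no overflow was ever observed
#' (`sum(w_i) = 0`) have no finite log; they are kept in the analysis at a
#' sentinel one unit below the smallest observed SWD, and flagged.
#'
#' @param freq data.frame with columns `plot_id` and `frequency`, one row per
#'   raster cell; a plot with no rows (or all-zero frequencies) is a
#'   zero-overflow plot. Alternatively a named list of frequency vectors.
#' @return data.frame with columns `plot_id`, `swd`, `floored` (logical).
#' @export
swd_index <- function(freq) {
  if (is.list(freq) && !is.data.frame(freq)) {
    plots <- names(freq)
    freq <- data.frame(
      plot_id = factor(rep(plots, lengths(freq)), levels = plots),
      frequency = unlist(freq, use.names = FALSE))
  }
  stopifnot(all(c("plot_id", "frequency") %in% names(freq)))
  w <- freq$frequency
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    stop("cell frequencies must lie in [0, 1]")
  }
  sums <- tapply(w, freq$plot_id, sum)
  sums[is.na(sums)] <- 0  # plots with no cells: no overflow observed
  swd <- ifelse(sums > 0, log(sums), NA_real_)
  floored <- !is.finite(swd)
  if (all(floored)) stop("no plot has positive surface-water frequency")
  if (any(floored)) {
    floor_val <- min(swd, na.rm = TRUE) - 1
    swd[floored] <- floor_val
    message(sum(floored), " zero-overflow plot(s) floored at SWD = ",
            format(floor_val, digits = 4))
  }
  data.frame(plot_id = names(sums), swd = as.numeric(swd),
             floored = as.vector(floored), stringsAsFactors = FALSE)
}

#' Standardize to z-scores
#'
#' Centres to mean zero and scales to unit sample standard deviation
#' (denominator n - 1). Constant input has no scale and is an error.
#'
#' @param x numeric vector without NAs.
#' @return z-scores, same length as `x`.
#' @export
zscore <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  s <- stats::sd(x)
  if (length(unique(x)) < 2L || s == 0) {
    stop("cannot standardize a constant vector")
  }
  (x - mean(x)) / s
}

#' K-means habitat typing from water variables
#'
#' Clusters plots on standardized SWD and groundwater depth with Lloyd's
#' K-means (best of `nstart` restarts by total within-cluster SS) and
#' relabels clusters deterministically by centroid semantics. With `k = 3`:
#' type A = low SWD, deep groundwater; type B = low SWD, shallow groundwater;
#' type C = high SWD, shallow groundwater. For other `k`, letters follow
#' increasing centroid SWD.
#'
#' @param env data.frame with columns `plot_id`, `swd`, `gwd` (groundwater
#'   depth in m, positive downward).
#' @param k number of habitat types (default 3).
#' @param nstart random restarts (default 50).
#' @param seed RNG seed for the restarts (default 20240215).
#' @param max_retry re-seeding attempts if a restart yields an empty cluster.
#' @return `env` with added columns `z_swd`, `z_gwd`, `habitat` (factor), and
#'   attributes `centroids` (k x 2, z-units) and `tot_withinss`.
#' @export
kmeans_habitats <- function(env, k = 3, nstart = 50, seed = 20240215,
                            max_retry = 10) {
  stopifnot(all(c("plot_id", "swd", "gwd") %in% names(env)), k <= nrow(env))
  z <- cbind(z_swd = zscore(env$swd), z_gwd = zscore(env$gwd))
  km <- NULL
  for (try in seq_len(max_retry)) {
    km <- withr::with_seed(seed + try - 1L, tryCatch(
      stats::kmeans(z, centers = k, nstart = nstart,
                    algorithm = "Lloyd", iter.max = 200),
      error = function(e) NULL, warning = function(w) NULL))
    if (!is.null(km) && length(unique(km$cluster)) == k) break
    km <- NULL
  }
  if (is.null(km)) stop("k-means failed to produce ", k, " non-empty clusters")

  cen <- km$centers
  if (k == 3) {
    idx_c <- which.max(cen[, "z_swd"])
    rest <- setdiff(seq_len(3), idx_c)
    idx_a <- rest[which.max(cen[rest, "z_gwd"])]  # deep groundwater
    idx_b <- setdiff(rest, idx_a)
    relab <- integer(3)
    relab[c(idx_a, idx_b, idx_c)] <- 1:3
  } else {
    relab <- rank(cen[, "z_swd"], ties.method = "first")
  }
  lab <- LETTERS[relab][km$cluster]
  env$z_swd <- z[, "z_swd"]
  env$z_gwd <- z[, "z_gwd"]
  env$habitat <- factor(lab, levels = LETTERS[seq_len(k)])
  cen_out <- cen[order(relab), , drop = FALSE]
  rownames(cen_out) <- LETTERS[seq_len(k)]
  attr(env, "centroids") <- cen_out
  attr(env, "tot_withinss") <- km$tot.withinss
  env
}

#' Hierarchical level clustering of a gradient variable
#'
#' Cuts a Ward-linkage (Euclidean) dendrogram of a single standardized
#' variable into `n_levels` groups and relabels them 1..n by increasing
#' group mean, turning a continuous water variable into an ordered factor
#' for the two-way design.
#'
#' @param x numeric vector (one value per plot or subplot).
#' @param n_levels number of levels, `2 <= n_levels <= length(x)`.
#' @return ordered factor of levels `1..n_levels`.
#' @export
cluster_levels <- function(x, n_levels = 3) {
  stopifnot(is.numeric(x), n_levels >= 2, n_levels <= length(x))
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  grp <- stats::cutree(hc, k = n_levels)
  mu <- tapply(x, grp, mean)
  relab <- rank(mu, ties.method = "first")
  factor(relab[as.character(grp)], levels = seq_len(n_levels), ordered = TRUE)
}

#' Soil profile means
#'
#' Averages each soil variable over the available depth layers of each plot
#' (full-profile mean), returning one row per plot.
#'
#' @param soil long data.frame with columns `plot_id`, `layer`, `variable`,
#'   `value`.
#' @return wide data.frame, one row per plot, one column per soil variable.
#' @export
soil_profile_means <- function(soil) {
  stopifnot(all(c("plot_id", "layer", "variable", "value") %in% names(soil)))
  agg <- stats::aggregate(value ~ plot_id + variable, data = soil, FUN = mean)
  wide <- stats::reshape(agg, idvar = "plot_id", timevar = "variable",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide[order(wide$plot_id), , drop = FALSE]
}

#' Assemble the per-plot environment profile
#'
#' Combines the SWD index, groundwater depth and soil profile means, then
#' derives z-scores, K-means habitat types and hierarchical water levels.
#'
#' @param freq surface-water frequency table (see [swd_index()]).
#' @param gwd data.frame with columns `plot_id`, `gwd`.
#' @param soil optional long soil table (see [soil_profile_means()]).
#' @param k habitat count for [kmeans_habitats()].
#' @param n_levels level count for [cluster_levels()], applied to each of
#'   z-SWD and z-GWD.
#' @param seed seed for the K-means restarts.
#' @return per-plot data.frame with `swd`, `floored`, `gwd`, z-scores,
#'   `habitat`, `sw_level`, `gw_level` and any soil-mean columns.
#' @export
env_profile <- function(freq, gwd, soil = NULL, k = 3, n_levels = 3,
                        seed = 20240215) {
  stopifnot(all(c("plot_id", "gwd") %in% names(gwd)))
  env <- merge(swd_index(freq), gwd, by = "plot_id")
  env <- kmeans_habitats(env, k = k, seed = seed)
  cent <- attr(env, "centroids")
  env$sw_level <- cluster_levels(env$z_swd, n_levels)
  env$gw_level <- cluster_levels(env$z_gwd, n_levels)
  if (!is.null(soil)) env <- merge(env, soil_profile_means(soil), by = "plot_id")
  attr(env, "centroids") <- cent
  env
}
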