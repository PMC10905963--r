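#' Choose the habitat-difference test from normality and variance gates
#'
#' Shapiro-Wilk is run per group and Levene's test (mean-centered) across
#' groups, both at `alpha`. All groups normal and variances homogeneous ->
#' LSD (pooled-variance pairwise t); normal but heteroscedastic -> Tamhane's
#' T2 (Welch pairwise t with Sidak-style adjustment); any group non-normal ->
#' Kruskal-Wallis with Dunn pairwise comparisons. Groups too small for
#' Shapiro-Wilk (n < 3) fall through to Kruskal-Wallis with a warning.
#'
#' @param values numeric vector.
#' @param groups grouping factor, same length.
#' @param alpha gate significance level (default 0.05).
#' @return one of `"LSD"`, `"TamhaneT2"`, `"KruskalWallis"`.
#' @export
select_test <- function(values, groups, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2L)
  ns <- tapply(values, groups, length)
  if (any(ns < 3L)) {
    warning("group(s) too small for a normality test; using Kruskal-Wallis")
    return("KruskalWallis")
  }
  sw <- tapply(values, groups, function(v) {
    if (length(unique(v)) < 3L) return(0)  # degenerate: treat as non-normal
    stats::shapiro.test(v)$p.value
  })
  if (any(sw <= alpha)) return("KruskalWallis")
  lev <- car::leveneTest(values ~ groups, center = "mean")
  if (lev[1L, "Pr(>F)"] <= alpha) return("TamhaneT2") else "LSD"
}

# pairwise p-value matrix helpers ------------------------------------------

.pairwise_lsd <- function(values, groups) {
  pt <- stats::pairwise.t.test(values, groups, p.adjust.method = "none",
                               pool.sd = TRUE)
  .square_pmat(pt$p.value, levels(groups))
}

.pairwise_tamhane <- function(values, groups) {
  lev <- levels(groups)
  m <- utils::combn(lev, 2L)
  p <- apply(m, 2L, function(pr) {
    stats::t.test(values[groups == pr[1L]], values[groups == pr[2L]],
                  var.equal = FALSE)$p.value
  })
  p <- 1 - (1 - p)^ncol(m)  # Sidak-style multiplicity adjustment
  .fill_pmat(lev, m, pmin(p, 1))
}

.pairwise_dunn <- function(values, groups) {
  lev <- levels(groups)
  r <- rank(values)
  n <- length(values)
  ties <- table(r)
  tiecor <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  m <- utils::combn(lev, 2L)
  p <- apply(m, 2L, function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tiecor) *
                 (1 / ns[pr[1L]] + 1 / ns[pr[2L]]))
    z <- (rbar[pr[1L]] - rbar[pr[2L]]) / se
    2 * stats::pnorm(-abs(z))
  })
  .fill_pmat(lev, m, p)
}

.fill_pmat <- function(lev, pairs, p) {
  out <- matrix(NA_real_, length(lev), length(lev),
                dimnames = list(lev, lev))
  for (i in seq_len(ncol(pairs))) {
    out[pairs[1L, i], pairs[2L, i]] <- p[i]
    out[pairs[2L, i], pairs[1L, i]] <- p[i]
  }
  diag(out) <- 1
  out
}

.square_pmat <- function(tri, lev) {
  out <- matrix(NA_real_, length(lev), length(lev),
                dimnames = list(lev, lev))
  for (i in rownames(tri)) for (j in colnames(tri)) {
    if (!is.na(tri[i, j])) out[i, j] <- out[j, i] <- tri[i, j]
  }
  diag(out) <- 1
  out
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: start from one letter covering all groups;
#' for every significant pair, split each letter column containing both
#' members; absorb columns that became subsets of others. Groups sharing a
#' letter do not differ at `alpha`. The display depends only on the
#' significance pattern, not on group order.
#'
#' @param pmat symmetric matrix of pairwise p-values with group dimnames.
#' @param alpha significance level (default 0.05).
#' @return named character vector of letter strings, one per group.
#' @export
cld_letters <- function(pmat, alpha = 0.05) {
  lev <- rownames(pmat)
  cols <- list(lev)
  pairs <- which(upper.tri(pmat) & pmat < alpha, arr.ind = TRUE)
  # process significant pairs in a canonical order for determinism
  if (nrow(pairs) > 0L) {
    ord <- order(pairs[, 1L], pairs[, 2L])
    for (k in ord) {
      a <- lev[pairs[k, 1L]]; b <- lev[pairs[k, 2L]]
      new_cols <- list()
      for (cc in cols) {
        if (all(c(a, b) %in% cc)) {
          new_cols <- c(new_cols, list(setdiff(cc, a)), list(setdiff(cc, b)))
        } else {
          new_cols <- c(new_cols, list(cc))
        }
      }
      # absorb subsets
      keep <- rep(TRUE, length(new_cols))
      for (i in seq_along(new_cols)) for (j in seq_along(new_cols)) {
        if (i != j && keep[i] && keep[j] &&
            all(new_cols[[i]] %in% new_cols[[j]]) &&
            (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j)) {
          keep[i] <- FALSE
        }
      }
      cols <- new_cols[keep]
    }
  }
  # order columns by the first group they contain, then letter them
  first <- vapply(cols, function(cc) min(match(cc, lev)), 1L)
  cols <- cols[order(first)]
  out <- stats::setNames(rep("", length(lev)), lev)
  for (i in seq_along(cols)) {
    for (g in cols[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  out
}

#' Habitat-difference test for one trait
#'
#' Runs the gated test-selection of [select_test()], the matching omnibus
#' test (one-way ANOVA for LSD, Welch ANOVA for Tamhane's T2,
#' Kruskal-Wallis otherwise), the matching pairwise comparisons, and a
#' compact letter display. Note that LSD is by design *unadjusted* pairwise
#' testing; interpret its letters accordingly.
#'
#' @param values numeric trait values (e.g. per-subplot CWM).
#' @param groups habitat factor.
#' @param alpha significance level (default 0.05).
#' @param trait optional trait name carried into the output.
#' @return object of class `"habitat_test"`: `test_used`, `omnibus_p`,
#'   `pairwise_p` (matrix), `letters`, `groups` (per-group n/mean/median/sd).
#' @export
habitat_trait_test <- function(values, groups, alpha = 0.05,
                               trait = NA_character_) {
  groups <- droplevels(as.factor(groups))
  test_used <- select_test(values, groups, alpha = alpha)
  omni <- switch(test_used,
    LSD = stats::oneway.test(values ~ groups, var.equal = TRUE)$p.value,
    TamhaneT2 = stats::oneway.test(values ~ groups, var.equal = FALSE)$p.value,
    KruskalWallis = stats::kruskal.test(values, groups)$p.value)
  pmat <- switch(test_used,
    LSD = .pairwise_lsd(values, groups),
    TamhaneT2 = .pairwise_tamhane(values, groups),
    KruskalWallis = .pairwise_dunn(values, groups))
  gs <- data.frame(
    habitat = levels(groups),
    n = as.vector(tapply(values, groups, length)),
    mean = as.vector(tapply(values, groups, mean)),
    median = as.vector(tapply(values, groups, stats::median)),
    sd = as.vector(tapply(values, groups, stats::sd)),
    stringsAsFactors = FALSE)
  structure(list(trait = trait, test_used = test_used, omnibus_p = omni,
                 pairwise_p = pmat, letters = cld_letters(pmat, alpha),
                 groups = gs, alpha = alpha),
            class = "habitat_test")
}

#' @export
print.habitat_test <- function(x, ...) {
  cat("Habitat-difference test",
      if (!is.na(x$trait)) paste0("(", x$trait, ")"), "\n")
  cat("test:", x$test_used, "  omnibus p =", signif(x$omnibus_p, 3), "\n")
  gs <- x$groups
  gs$letters <- x$letters[gs$habitat]
  print(gs, row.names = FALSE)
  invisible(x)
}

#' Standardized simple linear regression
#'
#' Both variables are z-scored before an OLS fit, so the slope equals the
#' Pearson correlation and the squared slope equals R-squared.
#'
#' @param x predictor (e.g. SWD or groundwater depth).
#' @param y response (e.g. a CWM trait).
#' @return list with `slope`, `se`, `p` (two-sided), `r2`, `n`.
#' @export
standardized_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired observations")
  fit <- stats::lm(zscore(y) ~ zscore(x))
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       se = sm$coefficients[2L, 2L],
       p = sm$coefficients[2L, 4L],
       r2 = sm$r.squared,
       n = length(x))
}

#' Standardized regressions of every CWM trait on environment variables
#'
#' @param cwm CWM table from [cwm_table()].
#' @param env per-plot environment table with `plot_id` plus the predictor
#'   columns (broadcast to subplots).
#' @param predictors predictor column names (default `c("swd", "gwd")`).
#' @param component which CWM series to regress (default `"cwm_specific"`).
#' @return data.frame with one row per trait x predictor.
#' @export
regress_cwm <- function(cwm, env, predictors = c("swd", "gwd"),
                        component = "cwm_specific") {
  stopifnot(component %in% names(cwm))
  rows <- list()
  for (tr in unique(cwm$trait)) {
    d <- cwm[cwm$trait == tr, , drop = FALSE]
    e <- env[match(d$plot_id, env$plot_id), , drop = FALSE]
    for (pv in predictors) {
      r <- standardized_regression(e[[pv]], d[[component]])
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, predictor = pv, slope = r$slope, p = r$p, r2 = r$r2,
        n = r$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Factor analysis of CWM traits with varimax rotation
#'
#' Extracts `n_factors` by principal components of the trait correlation
#' matrix (or iterated principal axis when `method = "pa"`), then applies a
#' varimax rotation with Kaiser normalization so each trait loads mainly on
#' one trade-off axis. Traits are assigned to the factor with the largest
#' absolute rotated loading. Factor signs are fixed so that the largest
#' loading of each factor is positive.
#'
#' @param x matrix or data.frame, subplots x traits; standardized internally.
#' @param n_factors number of factors, or `"auto"` for the eigenvalue > 1
#'   rule.
#' @param rotate apply varimax rotation (default TRUE).
#' @param method `"pc"` (principal components, default) or `"pa"`
#'   (principal axis with iterated communalities).
#' @return object of class `"trait_factor"`: `loadings` (traits x factors),
#'   `unrotated`, `rotmat`, `variance_pct`, `cumulative_pct`, `assignment`,
#'   `communality`.
#' @export
trait_factor_analysis <- function(x, n_factors = 2, rotate = TRUE,
                                  method = c("pc", "pa")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  stopifnot(nrow(x) > ncol(x))
  z <- scale(x)
  R <- stats::cor(z)
  ee <- eigen(R, symmetric = TRUE)
  if (min(ee$values) < 1e-12) stop("singular trait correlation matrix")
  if (identical(n_factors, "auto")) n_factors <- sum(ee$values > 1)
  stopifnot(n_factors >= 1, n_factors <= ncol(x))
  if (method == "pc") {
    L <- ee$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(ee$values[seq_len(n_factors)]), n_factors)
  } else {
    # principal axis: iterate communalities on the diagonal
    h2 <- 1 - 1 / diag(solve(R))  # SMC start
    for (it in seq_len(100L)) {
      Rh <- R
      diag(Rh) <- h2
      eh <- eigen(Rh, symmetric = TRUE)
      L <- eh$vectors[, seq_len(n_factors), drop = FALSE] %*%
        diag(sqrt(pmax(eh$values[seq_len(n_factors)], 0)), n_factors)
      h2_new <- rowSums(L^2)
      if (max(abs(h2_new - h2)) < 1e-7) break
      h2 <- h2_new
    }
  }
  rownames(L) <- colnames(x)
  rot <- diag(n_factors)
  Lr <- L
  if (rotate && n_factors > 1L) {
    v <- stats::varimax(L, normalize = TRUE, eps = 1e-10)
    Lr <- L %*% v$rotmat
    rot <- v$rotmat
  }
  # sign convention: biggest |loading| per factor is positive
  sgn <- apply(Lr, 2L, function(col) sign(col[which.max(abs(col))]))
  sgn[sgn == 0] <- 1
  Lr <- sweep(Lr, 2L, sgn, `*`)
  rot <- sweep(rot, 2L, sgn, `*`)
  colnames(Lr) <- paste0("Factor", seq_len(n_factors))
  varp <- 100 * colSums(Lr^2) / ncol(x)
  assign_f <- colnames(Lr)[apply(abs(Lr), 1L, which.max)]
  names(assign_f) <- rownames(Lr)
  structure(list(loadings = Lr, unrotated = L, rotmat = rot,
                 variance_pct = varp, cumulative_pct = cumsum(varp),
                 assignment = assign_f, communality = rowSums(Lr^2),
                 n_factors = n_factors, method = method),
            class = "trait_factor")
}

#' @export
print.trait_factor <- function(x, digits = 3, ...) {
  cat("Trait factor analysis (", x$method, " extraction, varimax)\n", sep = "")
  print(round(x$loadings, digits))
  cat("\nvariance explained (%):",
      paste(sprintf("%.1f", x$variance_pct), collapse = ", "),
      " cumulative:", sprintf("%.1f", max(x$cumulative_pct)), "\n")
  cat("assignment:",
      paste(names(x$assignment), "->", x$assignment, collapse = "; "), "\n")
  invisible(x)
}
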