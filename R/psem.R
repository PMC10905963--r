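# DAG utilities over a list of component-model formulas --------------------

.psem_dag <- function(formulas) {
  stopifnot(is.list(formulas), length(formulas) >= 1L,
            all(vapply(formulas, inherits, TRUE, "formula")))
  resp <- vapply(formulas, function(f) all.vars(f)[1L], "")
  if (anyDuplicated(resp)) {
    stop("every endogenous variable must have exactly one component model")
  }
  edges <- do.call(rbind, lapply(formulas, function(f) {
    v <- all.vars(f)
    if (length(v) < 2L) stop("component model with no predictors: ",
                             deparse(f))
    data.frame(from = v[-1L], to = v[1L], stringsAsFactors = FALSE)
  }))
  vars <- unique(c(edges$from, edges$to))
  parents <- lapply(stats::setNames(vars, vars), function(v) {
    edges$from[edges$to == v]
  })
  # Kahn topological sort; leftovers mean a cycle
  indeg <- vapply(parents, length, 1L)
  order_out <- character(0)
  active <- vars
  while (length(active) > 0L) {
    src <- active[vapply(active, function(v) {
      length(intersect(parents[[v]], active)) == 0L
    }, TRUE)]
    if (length(src) == 0L) stop("component models imply a cyclic graph")
    order_out <- c(order_out, src)
    active <- setdiff(active, src)
  }
  list(vars = vars, edges = edges, parents = parents,
       responses = resp, topo = order_out,
       exogenous = setdiff(vars, resp))
}

#' d-separation basis set of a DAG
#'
#' Enumerates the independence claims a piecewise SEM must test: every
#' unordered non-adjacent pair of variables yields one claim
#' `x _||_ y | parents(x) U parents(y)`. The claim is attached to (and later
#' tested in the model of) the endogenous member of the pair, or the
#' topologically later one when both are endogenous. Pairs of exogenous
#' variables are skipped: their association is left free (they may
#' correlate, and no component model exists to test them in).
#'
#' @param formulas list of component-model formulas (`response ~ predictors`).
#' @return list of claims, each a list with elements `x`, `y` (the response
#'   of the test regression) and `cond` (conditioning set).
#' @export
dsep_basis_set <- function(formulas) {
  g <- .psem_dag(formulas)
  pos <- stats::setNames(seq_along(g$topo), g$topo)
  adj <- paste(g$edges$from, g$edges$to)
  claims <- list()
  vs <- g$vars
  if (length(vs) >= 2L) {
    for (i in seq_len(length(vs) - 1L)) for (j in (i + 1L):length(vs)) {
      u <- vs[i]; v <- vs[j]
      if (paste(u, v) %in% adj || paste(v, u) %in% adj) next
      u_end <- u %in% g$responses
      v_end <- v %in% g$responses
      if (!u_end && !v_end) next
      if (u_end && v_end) {
        y <- if (pos[u] > pos[v]) u else v
      } else {
        y <- if (u_end) u else v
      }
      x <- setdiff(c(u, v), y)
      cond <- setdiff(union(g$parents[[u]], g$parents[[v]]), c(u, v))
      claims[[length(claims) + 1L]] <- list(x = x, y = y, cond = cond)
    }
  }
  claims
}

#' Fisher's C from independence-claim p-values
#'
#' `C = -2 * sum(log p_i)` over the k claims of the basis set, compared to a
#' chi-squared distribution with `2k` degrees of freedom. A model with an
#' empty basis set (saturated DAG) has `C = 0` and fit p-value 1. A claim
#' p-value of exactly zero makes C infinite; it is returned as `Inf`.
#'
#' @param p numeric vector of claim p-values in (0, 1].
#' @return list with `C`, `df`, `p`.
#' @export
fisher_c <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  k <- length(p)
  if (k == 0L) return(list(C = 0, df = 0L, p = 1))
  if (any(p == 0)) {
    warning("claim p-value of 0: Fisher's C is infinite")
    return(list(C = Inf, df = 2L * k, p = 0))
  }
  C <- -2 * sum(log(p))
  list(C = C, df = 2L * k,
       p = stats::pchisq(C, df = 2L * k, lower.tail = FALSE))
}

#' Fit a piecewise structural equation model
#'
#' Fits one OLS regression per endogenous variable, evaluates the DAG's
#' d-separation basis set (each claim tested by adding the claimed-
#' independent variable to the conditioning regression of the claim's
#' response), combines the claim p-values into Fisher's C, and scores the
#' model with `AIC = C + 2K`, where `K` counts path coefficients,
#' intercepts and error variances. With `standardize = TRUE` (default) all
#' variables are z-scored first, so path coefficients are standardized
#' effects.
#'
#' @param formulas list of component-model formulas.
#' @param data data.frame holding every model variable (one row per
#'   analysis unit); rows with any NA among model variables are dropped.
#' @param standardize z-score all variables before fitting (default TRUE).
#' @return object of class `"psem"`: `paths` (data.frame from/to/estimate/
#'   se/p), `models` (lm fits), `claims` (basis set with p-values),
#'   `C`, `df`, `p`, `aic`, `K`, `r2` (per endogenous variable), `n`.
#' @export
fit_psem <- function(formulas, data, standardize = TRUE) {
  g <- .psem_dag(formulas)
  miss <- setdiff(g$vars, names(data))
  if (length(miss) > 0L) stop("data lacks variable(s): ",
                              paste(miss, collapse = ", "))
  d <- data[, g$vars, drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  npred <- max(vapply(formulas, function(f) length(all.vars(f)) - 1L, 1L))
  if (nrow(d) <= npred + 1L) stop("too few rows for the largest model")
  if (standardize) d[] <- lapply(d, zscore)

  models <- lapply(formulas, function(f) stats::lm(f, data = d))
  names(models) <- g$responses
  for (nm in names(models)) {
    if (anyNA(stats::coef(models[[nm]]))) {
      bad <- names(which(is.na(stats::coef(models[[nm]]))))
      stop("rank-deficient model for ", nm, ": aliased ",
           paste(bad, collapse = ", "))
    }
  }
  paths <- do.call(rbind, lapply(names(models), function(nm) {
    cf <- summary(models[[nm]])$coefficients
    cf <- cf[setdiff(rownames(cf), "(Intercept)"), , drop = FALSE]
    data.frame(from = rownames(cf), to = nm,
               estimate = cf[, 1L], se = cf[, 2L], p = cf[, 4L],
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  claims <- dsep_basis_set(formulas)
  claims <- lapply(claims, function(cl) {
    rhs <- c(cl$cond, cl$x)
    fit <- stats::lm(stats::reformulate(rhs, response = cl$y), data = d)
    cf <- summary(fit)$coefficients
    cl$p <- cf[cl$x, 4L]
    cl$estimate <- cf[cl$x, 1L]
    cl
  })
  fc <- fisher_c(vapply(claims, `[[`, 1.0, "p"))
  K <- nrow(paths) + 2L * length(models)
  r2 <- vapply(models, function(m) summary(m)$r.squared, 1.0)
  structure(list(formulas = formulas, paths = paths, models = models,
                 claims = claims, C = fc$C, df = fc$df, p = fc$p,
                 K = K, aic = fc$C + 2 * K, r2 = r2, n = nrow(d),
                 dag = g, standardized = standardize),
            class = "psem")
}

#' @export
print.psem <- function(x, digits = 3, ...) {
  cat("Piecewise SEM:", length(x$models), "component model(s), n =", x$n, "\n")
  p <- x$paths
  p$estimate <- round(p$estimate, digits)
  p$se <- round(p$se, digits)
  p$p <- signif(p$p, 3)
  p$sig <- ifelse(x$paths$p < 0.01, "**", ifelse(x$paths$p < 0.05, "*", ""))
  print(p, row.names = FALSE)
  cat(sprintf("\nFisher's C = %.3f, df = %d, p = %.3f; AIC (C + 2K) = %.2f\n",
              x$C, x$df, x$p, x$aic))
  cat("R2:", paste(names(x$r2), "=", sprintf("%.3f", x$r2), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.psem <- function(object, ...) {
  cl <- do.call(rbind, lapply(object$claims, function(c0) {
    data.frame(claim = paste0(c0$x, " _||_ ", c0$y, " | {",
                              paste(c0$cond, collapse = ","), "}"),
               estimate = c0$estimate, p = c0$p, stringsAsFactors = FALSE)
  }))
  list(paths = object$paths, claims = cl,
       fit = data.frame(C = object$C, df = object$df, p = object$p,
                        K = object$K, AIC = object$aic, n = object$n),
       r2 = object$r2)
}

#' @export
coef.psem <- function(object, ...) object$paths

#' @export
AIC.psem <- function(object, ...) object$aic

#' Direct, indirect and total effects along a fitted DAG
#'
#' The indirect effect of `from` on `to` is the sum over all directed paths
#' of length >= 2 of the products of their standardized path coefficients;
#' the direct effect is the coefficient of the `from -> to` edge (0 when
#' absent).
#'
#' @param fit a fitted [fit_psem()] object.
#' @param from source variable.
#' @param to target variable.
#' @return list with `direct`, `indirect`, `total`, and `paths` (each
#'   chain with its product).
#' @export
path_effects <- function(fit, from, to) {
  stopifnot(inherits(fit, "psem"))
  p <- fit$paths
  coef_of <- function(a, b) {
    i <- which(p$from == a & p$to == b)
    if (length(i) == 0L) NA_real_ else p$estimate[i]
  }
  chains <- list()
  walk <- function(node, path, prod) {
    nxt <- p[p$from == node, , drop = FALSE]
    for (i in seq_len(nrow(nxt))) {
      tgt <- nxt$to[i]
      pr <- prod * nxt$estimate[i]
      if (tgt == to) {
        chains[[length(chains) + 1L]] <<- list(chain = c(path, tgt),
                                               product = pr)
      } else if (!tgt %in% path) {
        walk(tgt, c(path, tgt), pr)
      }
    }
  }
  walk(from, from, 1)
  direct <- coef_of(from, to)
  lens <- vapply(chains, function(ch) length(ch$chain), 1L)
  indirect <- sum(vapply(chains[lens > 2L], `[[`, 1.0, "product"))
  list(direct = if (is.na(direct)) 0 else direct, indirect = indirect,
       total = (if (is.na(direct)) 0 else direct) + indirect,
       paths = chains)
}

#' Variance-inflation screen for soil predictors
#'
#' Iteratively drops the predictor with the largest variance inflation
#' factor until all remaining VIFs are at or below the threshold. Used to
#' screen collinear soil variables before building SEM candidates.
#'
#' @param data data.frame holding the candidate predictors.
#' @param predictors predictor column names.
#' @param threshold VIF threshold (default 10).
#' @return list with `keep` (retained predictors), `dropped`, and `vif`
#'   (final VIFs).
#' @export
vif_screen <- function(data, predictors, threshold = 10) {
  stopifnot(all(predictors %in% names(data)))
  keep <- predictors
  dropped <- character(0)
  vifs <- function(vars) {
    vapply(vars, function(v) {
      r2 <- summary(stats::lm(
        stats::reformulate(setdiff(vars, v), response = v),
        data = data))$r.squared
      1 / (1 - min(r2, 1 - 1e-12))
    }, 1.0)
  }
  while (length(keep) > 1L) {
    v <- vifs(keep)
    if (max(v) <= threshold) break
    worst <- names(which.max(v))
    dropped <- c(dropped, worst)
    keep <- setdiff(keep, worst)
  }
  list(keep = keep, dropped = dropped,
       vif = if (length(keep) > 1L) vifs(keep) else
         stats::setNames(1, keep))
}

#' Compare candidate piecewise SEMs by AIC
#'
#' Fits every candidate (a named list of formula lists) on the same data
#' rows and ranks them by `AIC = C + 2K`. Candidates whose variable sets
#' imply different complete-case row sets are an error, because their AICs
#' would not be comparable.
#'
#' @param candidates named list; each element a list of component-model
#'   formulas.
#' @param data data.frame.
#' @param standardize passed to [fit_psem()].
#' @return list with `ranking` (data.frame sorted by AIC), `fits` (named
#'   list of psem objects), `best` (name of the lowest-AIC candidate).
#' @export
psem_compare <- function(candidates, data, standardize = TRUE) {
  stopifnot(is.list(candidates), length(candidates) >= 1L)
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("model", seq_along(candidates))
  }
  rowsets <- lapply(candidates, function(fl) {
    v <- unique(unlist(lapply(fl, all.vars)))
    which(stats::complete.cases(data[, v, drop = FALSE]))
  })
  if (length(unique(rowsets)) > 1L) {
    stop("candidates use different complete-case row sets; AIC not comparable")
  }
  fits <- lapply(candidates, fit_psem, data = data,
                 standardize = standardize)
  rk <- data.frame(
    model = names(fits),
    C = vapply(fits, `[[`, 1.0, "C"),
    df = vapply(fits, function(f) as.numeric(f$df), 1.0),
    p = vapply(fits, `[[`, 1.0, "p"),
    K = vapply(fits, function(f) as.numeric(f$K), 1.0),
    AIC = vapply(fits, `[[`, 1.0, "aic"),
    stringsAsFactors = FALSE, row.names = NULL)
  rk <- rk[order(rk$AIC), , drop = FALSE]
  rk$delta_AIC <- rk$AIC - rk$AIC[1L]
  list(ranking = rk, fits = fits, best = rk$model[1L])
}
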