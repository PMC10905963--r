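#' Decompose CWM trait variation into turnover, plasticity and covariation
#'
#' Partitions the variation of a community-weighted mean trait into an
#' interspecific component (species turnover, carried by the fixed-mean CWM),
#' an intraspecific component (plasticity, the specific-minus-fixed
#' difference) and their covariation, following the sum-of-squares logic of
#' the trait.flex approach.
#'
#' With no design (`formula = NULL` or `~ 1`) the decomposition is of the
#' total variation: over subplots,
#' `SS_specific = SS_fixed + SS_intra + SS_cov`, where each SS is the
#' centered sum of squares of the corresponding CWM series and the
#' covariation term is the signed remainder (twice the sum of centered
#' cross-products). With a factorial design (e.g. `~ sw_level * gw_level`)
#' three parallel ANOVAs with sequential (Type I) sums of squares are fitted
#' to the specific CWM, the fixed CWM and the intraspecific component, and
#' the same identity is reported per term (including the residual). Because
#' the design may be unbalanced, the term order matters and is taken from
#' the formula as written.
#'
#' Percentages ("explanatory rates") are always relative to the total SS of
#' the specific CWM, so for the total decomposition they sum to exactly 100
#' across the three components.
#'
#' @param specific numeric vector of specific CWM values (one per subplot).
#' @param fixed numeric vector of fixed CWM values, same length.
#' @param formula one-sided formula giving the factorial design, or `NULL`
#'   for the total decomposition.
#' @param data data.frame holding the design factors (one row per subplot).
#' @param trait optional trait name carried into the output.
#' @return an object of class `"trait_decomp"` with components `ss`, `pct`
#'   (matrices term x {specific, fixed, intra, cov}), `p` (term x
#'   {specific, fixed, intra} F-test p-values, NA for total/residual),
#'   `trait`, `formula`, `n`.
#' @seealso [decompose_cwm()] for mapping over a CWM table.
#' @export
trait_decomp <- function(specific, fixed, formula = NULL, data = NULL,
                         trait = NA_character_) {
  stopifnot(is.numeric(specific), is.numeric(fixed),
            length(specific) == length(fixed))
  ok <- is.finite(specific) & is.finite(fixed)
  specific <- specific[ok]
  fixed <- fixed[ok]
  if (length(specific) < 3L) stop("need at least 3 subplots")
  intra <- specific - fixed
  comp <- cbind(specific = specific, fixed = fixed, intra = intra)
  total_ss <- apply(comp, 2L, function(y) sum((y - mean(y))^2))

  no_design <- is.null(formula) ||
    (length(all.vars(formula)) == 0L)
  if (no_design) {
    ss <- rbind(total = c(total_ss, cov = unname(
      total_ss["specific"] - total_ss["fixed"] - total_ss["intra"])))
    colnames(ss) <- c("specific", "fixed", "intra", "cov")
    p <- rbind(total = c(specific = NA_real_, fixed = NA_real_,
                         intra = NA_real_))
  } else {
    if (is.null(data)) stop("a design formula needs `data`")
    data <- data[ok, , drop = FALSE]
    fml <- stats::update.formula(formula, y ~ .)
    tl <- attr(stats::terms(fml), "term.labels")
    # unbalanced designs with empty cells cannot support the interaction
    fac <- all.vars(formula)
    if (length(fac) == 2L &&
        any(table(data[[fac[1L]]], data[[fac[2L]]]) == 0L) &&
        any(grepl(":", tl, fixed = TRUE))) {
      warning("empty factor cell(s): dropping interaction term(s)")
      tl <- tl[!grepl(":", tl, fixed = TRUE)]
      fml <- stats::reformulate(tl, response = "y")
    }
    anovas <- lapply(colnames(comp), function(nm) {
      d <- data
      d$y <- comp[, nm]
      fit <- stats::lm(fml, data = d)
      if (anyNA(stats::coef(fit))) stop("collinear design: aliased terms")
      stats::anova(fit)
    })
    names(anovas) <- colnames(comp)
    terms_out <- rownames(anovas$specific)
    ss3 <- sapply(anovas, function(a) a[["Sum Sq"]])
    rownames(ss3) <- terms_out
    ss3 <- rbind(ss3, total = colSums(ss3))
    ss <- cbind(ss3, cov = ss3[, "specific"] - ss3[, "fixed"] - ss3[, "intra"])
    p3 <- sapply(anovas, function(a) a[["Pr(>F)"]])
    rownames(p3) <- terms_out
    p <- rbind(p3, total = NA_real_)
    rownames(ss)[rownames(ss) == "Residuals"] <- "residual"
    rownames(p)[rownames(p) == "Residuals"] <- "residual"
  }
  denom <- ss["total", "specific"]
  if (denom <= 0) {
    warning("zero total variation in the specific CWM; percentages undefined")
    pct <- ss * NA_real_
  } else {
    pct <- 100 * ss / denom
  }
  structure(list(ss = ss, pct = pct, p = p, trait = trait,
                 formula = formula, n = length(specific)),
            class = "trait_decomp")
}

#' @export
print.trait_decomp <- function(x, digits = 4, ...) {
  cat("Decomposition of CWM trait variation",
      if (!is.na(x$trait)) paste0("(", x$trait, ")"), "\n")
  cat("n =", x$n, "subplots;",
      if (is.null(x$formula)) "total variation only"
      else paste("design:", deparse(x$formula)), "\n\n")
  tab <- cbind(x$ss,
               `%fixed` = x$pct[, "fixed"],
               `%intra` = x$pct[, "intra"],
               `%cov` = x$pct[, "cov"])
  print(round(tab, digits))
  if (nrow(x$p) > 1L) {
    cat("\nF-test p-values (sequential SS):\n")
    print(signif(x$p[setdiff(rownames(x$p), c("residual", "total")), ,
                     drop = FALSE], 3))
  }
  invisible(x)
}

#' @export
summary.trait_decomp <- function(object, ...) {
  ss <- object$ss
  long <- data.frame(
    trait = object$trait,
    term = rep(rownames(ss), times = ncol(ss)),
    component = rep(colnames(ss), each = nrow(ss)),
    ss = as.vector(ss),
    pct = as.vector(object$pct),
    stringsAsFactors = FALSE)
  pl <- data.frame(term = rep(rownames(object$p), times = ncol(object$p)),
                   component = rep(colnames(object$p), each = nrow(object$p)),
                   p = as.vector(object$p), stringsAsFactors = FALSE)
  out <- merge(long, pl, by = c("term", "component"), all.x = TRUE,
               sort = FALSE)
  out[order(match(out$term, rownames(ss)),
            match(out$component, colnames(ss))), ]
}

#' @export
plot.trait_decomp <- function(x, ...) {
  h <- x$pct["total", c("fixed", "intra", "cov")]
  graphics::barplot(h, names.arg = c("interspecific", "intraspecific",
                                     "covariation"),
                    ylab = "% of total specific-CWM SS",
                    main = if (is.na(x$trait)) "CWM decomposition" else x$trait,
                    ...)
  invisible(x)
}

#' Decompose every trait of a CWM table
#'
#' Applies [trait_decomp()] to each trait of a long CWM table, optionally
#' under a factorial design whose factors live in a per-subplot data.frame.
#'
#' @param cwm CWM table from [cwm_table()].
#' @param design optional per-subplot data.frame with a `subplot_id` column
#'   and the design factors.
#' @param formula one-sided design formula over columns of `design`, or
#'   `NULL` for total decompositions.
#' @param traits traits to decompose (default: all in `cwm`).
#' @return named list of `trait_decomp` objects.
#' @export
decompose_cwm <- function(cwm, design = NULL, formula = NULL, traits = NULL) {
  if (is.null(traits)) traits <- unique(cwm$trait)
  out <- lapply(traits, function(tr) {
    d <- cwm[cwm$trait == tr, , drop = FALSE]
    dd <- NULL
    if (!is.null(design)) {
      dd <- design[match(d$subplot_id, design$subplot_id), , drop = FALSE]
    }
    trait_decomp(d$cwm_specific, d$cwm_fixed, formula = formula, data = dd,
                 trait = tr)
  })
  names(out) <- traits
  out
}

#' Summary table of total decompositions
#'
#' One row per trait with the percentage contributions of the
#' interspecific, intraspecific and covariation components to total
#' specific-CWM variation.
#'
#' @param decomps list of `trait_decomp` objects (from [decompose_cwm()]).
#' @return data.frame with columns `trait`, `pct_fixed`, `pct_intra`,
#'   `pct_cov`, `ratio_fixed_intra`.
#' @export
decomp_summary <- function(decomps) {
  do.call(rbind, lapply(decomps, function(d) {
    data.frame(trait = d$trait,
               pct_fixed = d$pct["total", "fixed"],
               pct_intra = d$pct["total", "intra"],
               pct_cov = d$pct["total", "cov"],
               ratio_fixed_intra = d$ss["total", "fixed"] /
                 d$ss["total", "intra"],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
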