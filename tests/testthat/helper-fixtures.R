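# small in-code fixtures shared across tests

make_survey <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(plot_id = r[[1]], subplot_id = r[[2]], species = r[[3]],
               n_individuals = r[[4]], mean_height = r[[5]],
               coverage = r[[6]], stringsAsFactors = FALSE)
  }))
}

# a random multi-species survey + matching trait table
random_community <- function(n_subplots = 4, n_species = 5, seed = 1,
                             traits = c("LNC", "SLA")) {
  withr::with_seed(seed, {
    survey <- do.call(rbind, lapply(seq_len(n_subplots), function(s) {
      sp <- sample(paste0("sp", seq_len(n_species)),
                   size = sample(2:n_species, 1))
      data.frame(plot_id = paste0("P", (s + 1) %/% 2),
                 subplot_id = paste0("S", s), species = sp,
                 n_individuals = sample(1:20, length(sp), replace = TRUE),
                 mean_height = stats::runif(length(sp), 20, 300),
                 coverage = stats::runif(length(sp), 0.1, 5),
                 stringsAsFactors = FALSE)
    }))
    trait_tab <- do.call(rbind, lapply(traits, function(tr) {
      data.frame(subplot_id = survey$subplot_id, species = survey$species,
                 trait = tr, value = stats::runif(nrow(survey), 5, 40),
                 stringsAsFactors = FALSE)
    }))
    list(survey = survey, traits = trait_tab)
  })
}

# sequential (Type I) sums of squares by explicit projection onto nested
# design matrices -- independent of anova()/aov()
seq_ss_projection <- function(y, data, terms) {
  proj <- function(X) X %*% solve(crossprod(X), t(X))
  X0 <- matrix(1, length(y), 1)
  fitted_prev <- proj(X0) %*% y
  ss <- numeric(length(terms))
  for (i in seq_along(terms)) {
    fml <- stats::reformulate(terms[seq_len(i)])
    X <- stats::model.matrix(fml, data = data)
    fitted_cur <- proj(X) %*% y
    ss[i] <- sum(fitted_cur^2) - sum(fitted_prev^2)
    fitted_prev <- fitted_cur
  }
  resid_ss <- sum((y - fitted_prev)^2)
  c(stats::setNames(ss, terms), residual = resid_ss)
}

# varimax criterion (Kaiser-normalized) for a loading matrix
varimax_criterion <- function(L) {
  h <- sqrt(rowSums(L^2))
  W <- L / h
  sum(apply(W^2, 2, function(c2) mean(c2^2) - mean(c2)^2))
}

# brute-force enumeration of d-separation claims straight from the
# definition: every non-adjacent unordered pair with an endogenous member,
# conditioned on the union of both parent sets
brute_basis <- function(edges, vars) {
  resp <- unique(edges$to)
  pa <- function(v) edges$from[edges$to == v]
  out <- list()
  if (length(vars) < 2) return(out)
  for (i in seq_len(length(vars) - 1)) for (j in (i + 1):length(vars)) {
    u <- vars[i]; v <- vars[j]
    adj <- any(edges$from == u & edges$to == v) ||
      any(edges$from == v & edges$to == u)
    if (adj) next
    if (!(u %in% resp) && !(v %in% resp)) next
    out[[length(out) + 1]] <- list(
      pair = sort(c(u, v)),
      cond = sort(setdiff(union(pa(u), pa(v)), c(u, v))))
  }
  out
}
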