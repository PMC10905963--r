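test_that("test gate routes by normality and variance homogeneity", {
  groups <- factor(rep(c("A", "B", "C"), each = 30))
  # under the null of both gates each of the four tests (three Shapiro-Wilk,
  # one Levene) passes with probability 1 - alpha, so LSD is selected in
  # about 0.95^4 ~ 81% of draws
  picks <- sapply(1:40, function(s) withr::with_seed(s, {
    select_test(rnorm(90), groups)
  }))
  expect_gte(mean(picks == "LSD"), 0.7)

  # grossly heteroscedastic but normal data goes to Tamhane's T2
  picks2 <- sapply(1:20, function(s) withr::with_seed(s, {
    v <- c(rnorm(30, 0, 1), rnorm(30, 0, 1), rnorm(30, 0, 12))
    select_test(v, groups)
  }))
  expect_gte(mean(picks2 == "TamhaneT2"), 0.9)

  # an exponential group fails normality with near-certain power at n = 30
  picks3 <- sapply(1:20, function(s) withr::with_seed(s, {
    v <- c(rnorm(30), rnorm(30), rexp(30))
    select_test(v, groups)
  }))
  expect_gte(mean(picks3 == "KruskalWallis"), 0.9)

  # the gate is pure: identical input, identical branch
  v <- withr::with_seed(1, rnorm(90))
  expect_identical(select_test(v, groups), select_test(v, groups))

  # tiny groups fall through to Kruskal-Wallis with a warning
  expect_warning(
    pick <- select_test(c(1, 2, 1.5, 2.5), factor(c("a", "a", "b", "b"))),
    "too small")
  expect_identical(pick, "KruskalWallis")
})

test_that("compact letter displays encode the significance pattern", {
  # overwhelming separation of the third group
  v <- withr::with_seed(2, c(rnorm(20, 0), rnorm(20, 0), rnorm(20, 5)))
  g <- factor(rep(c("A", "B", "C"), each = 20))
  ht <- habitat_trait_test(v, g)
  expect_identical(unname(ht$letters[c("A", "B")]), c("a", "a"))
  expect_identical(unname(ht$letters["C"]), "b")

  # identical groups share one letter and the omnibus p is ~1
  v0 <- withr::with_seed(3, rep(rnorm(20), 3))
  ht0 <- habitat_trait_test(v0, g)
  expect_equal(ht0$omnibus_p, 1, tolerance = 1e-10)
  expect_identical(unname(unique(ht0$letters)), "a")

  # overlap case straight from a p-value matrix: 1 vs 3 differ, 2 straddles
  pmat <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  pmat["A", "C"] <- pmat["C", "A"] <- 0.001
  lt <- cld_letters(pmat)
  expect_identical(unname(lt), c("a", "ab", "b"))

  # relabelling invariance: permuting groups permutes letters consistently
  perm <- c("C", "A", "B")
  lt2 <- cld_letters(pmat[perm, perm])
  same <- function(l, i, j) {
    length(intersect(strsplit(l[[i]], "")[[1]], strsplit(l[[j]], "")[[1]])) > 0
  }
  for (i in c("A", "B", "C")) for (j in c("A", "B", "C")) {
    expect_identical(same(lt, i, j), same(lt2, i, j))
  }
})

test_that("pairwise machinery matches reference implementations", {
  v <- withr::with_seed(8, c(rnorm(15, 0), rnorm(15, 1), rnorm(15, 2)))
  g <- factor(rep(c("A", "B", "C"), each = 15))
  # Welch pairwise with Sidak adjustment vs direct computation
  p_ab <- t.test(v[g == "A"], v[g == "B"])$p.value
  tam <- traitpart:::.pairwise_tamhane(v, g)
  expect_equal(tam["A", "B"], 1 - (1 - p_ab)^3, tolerance = 1e-12)
  # Dunn z-test for two of three groups vs hand computation (no ties)
  dunn <- traitpart:::.pairwise_dunn(v, g)
  r <- rank(v); n <- length(v)
  z <- (mean(r[g == "A"]) - mean(r[g == "C"])) /
    sqrt(n * (n + 1) / 12 * (1 / 15 + 1 / 15))
  expect_equal(dunn["A", "C"], 2 * pnorm(-abs(z)), tolerance = 1e-12)
})

test_that("standardized regression equals Pearson correlation", {
  x <- withr::with_seed(4, rnorm(30))
  r <- suppressWarnings(standardized_regression(x, x))
  expect_equal(r$slope, 1)
  expect_equal(r$r2, 1)

  for (seed in 1:5) {
    d <- withr::with_seed(seed, list(x = rnorm(25), y = rnorm(25, 2, 3)))
    r <- standardized_regression(d$x, d$y)
    expect_equal(r$slope, cor(d$x, d$y))
    expect_equal(r$slope^2, r$r2, tolerance = 1e-12)
  }

  # under independence the p-value is roughly uniform
  ps <- sapply(1:200, function(s) withr::with_seed(s + 500, {
    standardized_regression(rnorm(20), rnorm(20))$p
  }))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)

  expect_error(standardized_regression(rep(1, 10), rnorm(10)), "constant")
})

test_that("factor analysis recovers a planted two-factor block structure", {
  n <- 300
  dat <- withr::with_seed(10, {
    f1 <- rnorm(n); f2 <- rnorm(n)
    cbind(t1 = 0.9 * f1, t2 = 0.85 * f1, t3 = 0.8 * f1,
          t4 = 0.9 * f2, t5 = 0.85 * f2) +
      matrix(rnorm(n * 5, 0, 0.2), n)
  })
  fa <- trait_factor_analysis(dat, n_factors = 2)
  expect_length(unique(fa$assignment[c("t1", "t2", "t3")]), 1L)
  expect_length(unique(fa$assignment[c("t4", "t5")]), 1L)
  expect_false(fa$assignment[["t1"]] == fa$assignment[["t4"]])

  # communalities are rotation-invariant
  expect_equal(rowSums(fa$loadings^2), rowSums(fa$unrotated^2),
               tolerance = 1e-8, ignore_attr = TRUE)
  # rotated = unrotated %*% orthogonal matrix
  expect_equal(crossprod(fa$rotmat), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fa$unrotated %*% fa$rotmat, fa$loadings,
               tolerance = 1e-12, ignore_attr = TRUE)

  # a loading matrix that is already varimax-simple is a fixed point
  # (up to sign and column order)
  fa2 <- trait_factor_analysis(dat[, c("t4", "t5", "t1", "t2", "t3")],
                               n_factors = 2)
  cross <- abs(crossprod(fa$loadings[c("t4","t5","t1","t2","t3"), ],
                         fa2$loadings))
  # one dominant match per column
  expect_true(all(apply(cross, 2, max) >
                    2 * apply(cross, 2, function(x) sort(x)[1])))

  # eigenvalue>1 auto mode finds two factors here
  fa_auto <- trait_factor_analysis(dat, n_factors = "auto")
  expect_equal(fa_auto$n_factors, 2L)
})

test_that("varimax rotation maximizes the criterion (grid-search oracle)", {
  dat <- withr::with_seed(11, {
    f1 <- rnorm(200); f2 <- rnorm(200)
    cbind(0.9 * f1 + 0.3 * f2, 0.7 * f1, 0.5 * f1 + 0.5 * f2,
          0.9 * f2, 0.6 * f2 + 0.2 * f1) + matrix(rnorm(1000, 0, 0.3), 200)
  })
  fa <- trait_factor_analysis(dat, n_factors = 2)
  L <- fa$unrotated
  crit_grid <- sapply(seq(0, pi / 2, by = 0.001), function(th) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
    varimax_criterion(L %*% R)
  })
  expect_gte(varimax_criterion(fa$loadings), max(crit_grid) - 1e-4)
})

test_that("regress_cwm ties traits to plot-level environment", {
  d <- synth_community(synth_scenario(seed = 6))
  cwm <- suppressMessages(cwm_table(importance_values(d$survey), d$traits))
  env <- suppressMessages(env_profile(d$freq, d$gwd, seed = 6))
  rg <- regress_cwm(cwm, env)
  expect_setequal(unique(rg$trait), unique(cwm$trait))
  expect_setequal(unique(rg$predictor), c("swd", "gwd"))
  expect_true(all(rg$r2 >= 0 & rg$r2 <= 1))
  expect_equal(rg$slope^2, rg$r2, tolerance = 1e-12)
})
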