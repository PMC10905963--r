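test_that("importance values: shares, symmetry, and normalization", {
  # two identical species split everything equally
  sv <- make_survey(list("P1", "S1", "X", 2, 100, 0.2),
                    list("P1", "S1", "Y", 2, 100, 0.2))
  iv <- importance_values(sv)
  expect_equal(iv$IV, c(0.5, 0.5))

  # IV is the arithmetic mean of the three relative shares
  sv <- make_survey(list("P1", "S1", "X", 1, 3, 4),
                    list("P1", "S1", "Y", 1, 7, 6))
  iv <- importance_values(sv)
  x <- iv[iv$species == "X", ]
  expect_equal(c(x$Ar, x$Hr, x$Cr), c(0.5, 0.3, 0.4))
  expect_equal(x$IV, 0.4)

  # each share column and IV sum to one per subplot, for arbitrary data
  for (seed in 1:5) {
    com <- random_community(n_subplots = 6, seed = seed)
    iv <- importance_values(com$survey)
    for (col in c("Ar", "Hr", "Cr", "IV")) {
      sums <- tapply(iv[[col]], iv$subplot_id, sum)
      expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-12)
    }
  }
})

test_that("importance values: exclusions and row-order invariance", {
  sv <- make_survey(list("P1", "S1", "X", 2, 10, 1),
                    list("P1", "S1", "Y", 1, 20, 2),
                    list("P1", "S2", "Z", 4, 15, 1))
  expect_message(iv <- importance_values(sv), "single-species")
  expect_false("S2" %in% iv$subplot_id)

  # zero total coverage rejects the subplot
  sv0 <- make_survey(list("P1", "S1", "X", 2, 10, 0),
                     list("P1", "S1", "Y", 1, 20, 0),
                     list("P1", "S2", "X", 2, 10, 1),
                     list("P1", "S2", "Y", 5, 25, 2))
  expect_warning(iv0 <- importance_values(sv0), "zero total")
  expect_identical(unique(iv0$subplot_id), "S2")

  # permuting rows changes nothing
  com <- random_community(n_subplots = 5, seed = 42)
  iv1 <- importance_values(com$survey)
  perm <- withr::with_seed(9, sample(nrow(com$survey)))
  iv2 <- importance_values(com$survey[perm, ])
  key <- function(d) d[order(d$subplot_id, d$species), c("Ar", "Hr", "Cr", "IV")]
  expect_equal(key(iv1), key(iv2), ignore_attr = TRUE)

  # malformed records are refused
  bad <- make_survey(list("P1", "S1", "X", 1.5, 10, 1),
                     list("P1", "S1", "Y", 1, 20, 2))
  expect_error(importance_values(bad), "integer")
  dup <- make_survey(list("P1", "S1", "X", 1, 10, 1),
                     list("P1", "S1", "X", 2, 20, 2))
  expect_error(importance_values(dup), "duplicate")
})

test_that("species fixed means are unweighted subplot means", {
  tr <- data.frame(subplot_id = c("S1", "S2"), species = "X",
                   trait = "LNC", value = c(10, 20))
  fm <- species_fixed_means(tr)
  expect_equal(fm$fixed_mean, 15)

  # single occurrence: identity
  tr1 <- data.frame(subplot_id = "S1", species = "Y", trait = "LNC",
                    value = 12.34)
  expect_equal(species_fixed_means(tr1)$fixed_mean, 12.34)

  # five values: equals independently computed sum/5
  v <- withr::with_seed(3, runif(5, 1, 50))
  tr5 <- data.frame(subplot_id = paste0("S", 1:5), species = "Z",
                    trait = "SLA", value = v)
  expect_equal(species_fixed_means(tr5)$fixed_mean, sum(v) / 5)

  # non-finite values are dropped with a note
  trna <- rbind(tr, data.frame(subplot_id = "S3", species = "X",
                               trait = "LNC", value = NA_real_))
  expect_message(fmna <- species_fixed_means(trna), "non-finite")
  expect_equal(fmna$fixed_mean, 15)
})

test_that("CWM: weighting, identity, bounds, and missing-trait policy", {
  sv <- make_survey(list("P1", "S1", "X", 3, 10, 1),
                    list("P1", "S1", "Y", 2, 10, 1))
  iv <- importance_values(sv)
  iv$IV <- c(0.6, 0.4)  # prescribe weights to check the arithmetic
  tr <- data.frame(subplot_id = "S1", species = c("X", "Y"),
                   trait = "LNC", value = c(10, 20))
  fm <- data.frame(species = c("X", "Y"), trait = "LNC",
                   fixed_mean = c(10, 20), n_subplots = 1)
  cwm <- cwm_table(iv, tr, fixed = fm)
  expect_equal(cwm$cwm_specific, 14)
  # specific values equal to fixed means force zero intraspecific shift
  expect_equal(cwm$intraspecific, 0)

  # identity and bounds on random communities
  for (seed in 1:5) {
    com <- random_community(n_subplots = 6, seed = seed)
    iv <- importance_values(com$survey)
    cwm <- cwm_table(iv, com$traits)
    expect_equal(cwm$cwm_specific, cwm$cwm_fixed + cwm$intraspecific)
    for (i in seq_len(nrow(cwm))) {
      vals <- com$traits$value[com$traits$subplot_id == cwm$subplot_id[i] &
                                 com$traits$trait == cwm$trait[i]]
      expect_gte(cwm$cwm_specific[i], min(vals) - 1e-12)
      expect_lte(cwm$cwm_specific[i], max(vals) + 1e-12)
    }
  }
})

test_that("missing specific trait values follow the configured policy", {
  com <- random_community(n_subplots = 4, n_species = 4, seed = 11)
  iv <- importance_values(com$survey)
  traits <- com$traits
  # remove one species' LNC in one subplot
  s1 <- iv$subplot_id[1]
  sp1 <- iv$species[iv$subplot_id == s1][1]
  drop_row <- traits$subplot_id == s1 & traits$species == sp1 &
    traits$trait == "LNC"
  traits2 <- traits[!drop_row, ]

  expect_message(cwm_drop <- cwm_table(iv, traits2), "dropped")
  expect_false(any(cwm_drop$subplot_id == s1 & cwm_drop$trait == "LNC"))
  # other traits of that subplot survive
  expect_true(any(cwm_drop$subplot_id == s1 & cwm_drop$trait == "SLA"))

  cwm_renorm <- cwm_table(iv, traits2, missing = "renormalize")
  row <- cwm_renorm[cwm_renorm$subplot_id == s1 & cwm_renorm$trait == "LNC", ]
  expect_equal(nrow(row), 1L)
  # manual renormalized expectation
  keep <- iv$subplot_id == s1 & iv$species != sp1
  w <- iv$IV[keep] / sum(iv$IV[keep])
  v <- traits2$value[traits2$subplot_id == s1 & traits2$trait == "LNC"]
  v <- v[match(iv$species[keep], traits2$species[traits2$subplot_id == s1 &
                                                   traits2$trait == "LNC"])]
  expect_equal(row$cwm_specific, sum(w * v))
})

test_that("ratio traits are checked against their components", {
  tr <- data.frame(
    subplot_id = "S1", species = c("X", "X", "X"),
    trait = c("LNC", "LPC", "N/P"), value = c(20, 2, 10))
  expect_equal(nrow(check_trait_ratios(tr)), 0L)
  tr$value[3] <- 11  # inconsistent ratio
  bad <- check_trait_ratios(tr)
  expect_equal(nrow(bad), 1L)
  expect_equal(bad$trait, "N/P")
})

test_that("survey files are read with column mapping and crown geometry", {
  f <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(Plot = "P1", Quad = c("S1", "S1"), Sp = c("X", "Y"),
                  Count = c(2, 3), Height = c(50, 70),
                  CL = c(1, 2), CW = c(0.5, 1))
  write.csv(d, f, row.names = FALSE)
  sv <- read_survey(f, mapping = list(
    plot_id = "Plot", subplot_id = "Quad", species = "Sp",
    n_individuals = "Count", mean_height = "Height",
    crown_length = "CL", crown_width = "CW"))
  expect_equal(sv$coverage, d$Count * pi * (d$CL / 2) * (d$CW / 2))
  expect_error(read_survey(f, mapping = list(plot_id = "nope")),
               "nope")
})
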