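test_that("neocorticalization percentages reproduce printed cells", {
  # Adapis cell printed as 43.23; the quotient itself is 43.2214
  expect_equal(pct_neocortex(10.17, 23.53), 43.23, tolerance = 0.05 / 43.23)
  expect_equal(round(pct_neocortex(4.86, 21.6), 1), 22.5)    # Arctocyon
  expect_equal(round(pct_neocortex(18.98, 135.06), 2), 14.05) # Titanoides
  expect_equal(pct_neocortex(7, 7), 100)
  expect_error(pct_neocortex(10, 9), "mis-paired")
  expect_error(pct_neocortex(0, 9), "positive")
})

test_that("the percentage is a pure ratio: invariant under common rescaling", {
  set.seed(2)
  nc <- runif(20, 1, 50)
  s <- nc + runif(20, 0, 100)
  for (k in c(0.01, 3, 1e4)) {
    expect_equal(pct_neocortex(k * nc, k * s), pct_neocortex(nc, s),
                 tolerance = 1e-12)
  }
  expect_true(all(pct_neocortex(nc, s) > 0 & pct_neocortex(nc, s) <= 100))
})

test_that("the time trend recovers a noiseless linear truth exactly", {
  cfg <- synthetic_config(n_species = 40, sd_log10E = 0, nc_model = "linear",
                          nc_params = c(intercept = 58, slope = 0.7), seed = 3)
  d <- generate_dataset(cfg)
  tr <- nc_trend(d, predict_at = c(0, -10))
  expect_equal(tr$slope, 0.7, tolerance = 1e-9)
  expect_equal(tr$intercept, 58, tolerance = 1e-9)
  expect_equal(tr$predictions$pct, c(58, 51), tolerance = 1e-9)
  expect_equal(predict(tr, -20), 44, tolerance = 1e-9)
})

test_that("shifting all ages moves the intercept reference, never the slope", {
  d <- generate_dataset(synthetic_config(n_species = 50, seed = 8))
  t0 <- nc_trend(d)
  shifted <- d
  shifted$age_Ma <- shifted$age_Ma - 15
  t1 <- nc_trend(shifted)
  expect_equal(t1$slope, t0$slope, tolerance = 1e-9)
  expect_equal(t1$intercept, t0$intercept + 15 * t0$slope, tolerance = 1e-6)
})

test_that("the fixture trend is positive and tar-pit exclusion is available", {
  tab <- load_table1()
  tr <- nc_trend(tab)
  expect_gt(tr$slope, 0)
  tr_nolabrea <- nc_trend(tab, exclude_recent_Ma = 1)
  expect_lt(tr_nolabrea$n, tr$n)
  # excluded rows are the young fossils, not the extant column at age 0
  expect_gt(tr_nolabrea$n, sum(tab$section != "fossil") )
  tr_clean <- nc_trend(tab, exclude_failed = TRUE)
  expect_equal(tr$n - tr_clean$n, 3) # the three pinned %NC inconsistencies
  expect_error(nc_trend(tab[1:2, ]), "at least 3")
})

test_that("the EQ profile handles constant, saturating and fixture shapes", {
  # constant percentage: every bin mean equals it, plateau at the first bin
  d <- data.frame(NC_cm2 = c(6, 6, 6, 6), S_minus_OB_cm2 = rep(12, 4),
                  pctNC = NA, E_ml = c(2, 10, 40, 80),
                  P_g = rep(1000, 4), EQ = NA)
  pr <- nc_eq_profile(d, bin_width = 0.5)
  occ <- pr$bin_counts > 0
  expect_true(all(abs(pr$bin_means[occ] - 50) < 1e-9))
  expect_equal(pr$eq_at_plateau, pr$bin_edges[which(occ)[1]])

  # saturating generating curve: occupied-bin means monotone nondecreasing
  set.seed(13)
  eq <- runif(300, 0.05, 5)
  pct <- 80 * eq / (0.5 + eq)
  s <- runif(300, 20, 200)
  d2 <- data.frame(NC_cm2 = pct / 100 * s, S_minus_OB_cm2 = s, pctNC = NA,
                   E_ml = 0.12 * 1000^(2 / 3) * eq, P_g = 1000, EQ = NA)
  pr2 <- nc_eq_profile(d2, bin_width = 0.5)
  m <- pr2$bin_means[pr2$bin_counts > 0]
  expect_true(all(diff(m) >= -1e-9))
  expect_true(all(m >= 0 & m <= 100))

  # fixture: the ceiling is the chimpanzee braincast at 80.76
  pr3 <- nc_eq_profile(load_table1())
  expect_equal(pr3$max_pct, 80.76, tolerance = 1e-4)
  expect_lt(pr3$max_pct, 81)
  expect_error(nc_eq_profile(d[1, ]), "at least 3")
})

test_that("recomputed percentages shield the trend from the bad printed cell", {
  tab <- load_table1()
  pct <- paleoneuro:::recomputed_pct_nc(tab)
  equus <- which(tab$species == "Equus occidentalis")
  expect_equal(pct[equus], 58.66, tolerance = 1e-3) # not the printed 85.19
  # fall-back to the printed column where areas are missing
  plag <- which(tab$species == "Plagiolophus minor")
  expect_equal(pct[plag], 100 * 29.51 / 48.96, tolerance = 1e-9)
  till <- which(tab$species == "Tillyhorse")
  expect_equal(pct[till], 100 * 5.84 / 44.69, tolerance = 1e-9)
})
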