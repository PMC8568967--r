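test_that("generation is deterministic with independent substreams", {
  cfg <- scenario_config()
  a <- simulate_dataset(cfg, seed = 8)
  b <- simulate_dataset(cfg, seed = 8)
  expect_identical(a$flora, b$flora)
  expect_identical(a$surveys, b$surveys)
  expect_identical(a$parasitism, b$parasitism)
  expect_false(identical(simulate_dataset(cfg, seed = 9)$parasitism,
                         a$parasitism))
  # the parasitoid substream does not depend on the flora draws
  expect_identical(simulate_parasitoids(cfg, seed = 8), a$insects)
})

test_that("the design realizes the field layout", {
  sim <- simulate_dataset(scenario_config(), seed = 12)
  expect_equal(nrow(sim$covariates), 27)            # 9 treatments x 3 strips
  expect_equal(length(unique(sim$surveys$treatment)), 9)
  expect_equal(nrow(sim$insects), 7)
  expect_setequal(unique(sim$parasitism$distance), c(5, 20))
  expect_equal(length(unique(sim$parasitism$herbivore)), 5)
  expect_equal(nrow(sim$parasitism), 27 * 2 * 5)
  # covers valid
  tot <- tapply(sim$surveys$cover, sim$surveys$plot, sum)
  expect_true(all(sim$surveys$cover >= 0))
  expect_true(all(tot <= 100))
  # counts bounded by trials, all insect lengths positive, windows ordered
  expect_true(all(sim$parasitism$n_parasitized <= sim$parasitism$n_examined))
  expect_true(all(sim$insects$head_width > 0 &
                    sim$insects$proboscis_length > 0 &
                    sim$insects$proboscis_width > 0))
  expect_true(all(sim$insects$activity_start <= sim$insects$activity_end))
  expect_true(all(sim$surveys$stage >= 0 & sim$surveys$stage <= 10))
})

test_that("high-FD assemblages disperse more than low-FD assemblages", {
  hits <- 0
  for (s in 1:15) {
    fl <- simulate_flora(scenario_config(), seed = 300 + s)
    traits <- fl$flora[setdiff(names(fl$flora), "species")]
    rownames(traits) <- fl$flora$species
    dism <- gower_dissimilarity(traits)
    fd <- sapply(unique(fl$surveys$plot), function(pl) {
      sub <- fl$surveys[fl$surveys$plot == pl, ]
      fdis(setNames(sub$cover, sub$species), dism)
    })
    tr <- fl$surveys$treatment[match(names(fd), fl$surveys$plot)]
    hits <- hits + (mean(fd[grepl("^HF", tr)]) > mean(fd[grepl("^LF", tr)]))
  }
  expect_gte(hits, 13)
})

test_that("binomial draws match the inverse-logit means", {
  cfg0 <- scenario_config(effects = list(beta0 = rep(0, 5), beta_nectar = 0,
                                         beta_fdis2 = 0, sigma_strip = 0,
                                         distance_mult = c("5" = 0, "20" = 0)))
  sim0 <- simulate_dataset(cfg0, seed = 31)
  rate <- with(sim0$parasitism, n_parasitized / n_examined)
  se <- sd(rate) / sqrt(length(rate))
  expect_lt(abs(weighted.mean(rate, sim0$parasitism$n_examined) - 0.5),
            4 * se + 0.01)

  cfg2 <- scenario_config(effects = list(beta0 = rep(-2, 5), beta_nectar = 0,
                                         beta_fdis2 = 0, sigma_strip = 0,
                                         distance_mult = c("5" = 0, "20" = 0)))
  sim2 <- simulate_dataset(cfg2, seed = 32)
  rate2 <- with(sim2$parasitism, weighted.mean(n_parasitized / n_examined,
                                               n_examined))
  expect_lt(abs(rate2 - plogis(-2)), 0.02)
})

test_that("the miniature fixture is stable and hand-consistent", {
  fx1 <- fixture_small()
  fx2 <- fixture_small()
  expect_identical(fx1, fx2)
  expect_equal(nrow(fx1$flora), 4)
  expect_equal(nrow(fx1$insects), 2)
  expect_equal(length(unique(fx1$surveys$plot)), 6)
  # documented hand-computed accessible covers on plot p1
  p1 <- fx1$surveys[fx1$surveys$plot == "p1", ]
  expect_equal(accessible_cover(p1, fx1$flora,
                                insect_from_df(fx1$insects, "P1")), 50)
  expect_equal(accessible_cover(p1, fx1$flora,
                                insect_from_df(fx1$insects, "P2")), 30)
  # every analysis stage accepts it end to end
  cov <- plot_covariates(fx1$surveys, fx1$flora, fx1$insects)
  expect_equal(nrow(cov), 6)
  expect_true(all(c("richness", "fdis", "rao", "nectar") %in% names(cov)))
  asm <- run_assemblage_analysis(fx1$parasitism, distances = 5,
                                 candidates = c("strip"))
  expect_equal(nrow(asm), 2)
  expect_true(all(asm$p >= 0 & asm$p <= 1))
})
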