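test_that("decision tree resolves the worked single-pair cases", {
  # extrafloral nectar short-circuits geometry for any insect
  v <- nectar_accessible(insect_morphology(0.4, 0.1, 0.9),
                         flower_morphology(0.1, 9, 9, 0.01,
                                           nectar_type = "extrafloral"))
  expect_true(v$accessible)
  expect_identical(v$reason, "extrafloral")

  # head enters but proboscis cannot span the nectar tube
  v <- nectar_accessible(insect_morphology(0.4, 0.3, 0.05),
                         flower_morphology(1.0, 2.0, 1.0, 0.2))
  expect_false(v$accessible)
  expect_identical(v$reason, "fail_penetration_reach")

  # head excluded, proboscis spans corolla + tube from the opening
  v <- nectar_accessible(insect_morphology(2.0, 1.5, 0.1),
                         flower_morphology(1.0, 0.5, 0.8, 0.3))
  expect_true(v$accessible)
  expect_identical(v$reason, "open_reach")

  # proboscis wider than the nectar tube
  v <- nectar_accessible(insect_morphology(0.4, 5, 0.4),
                         flower_morphology(2, 0.5, 0.5, 0.3))
  expect_false(v$accessible)
  expect_identical(v$reason, "fail_tube_width")

  # no nectar at all
  expect_identical(nectar_accessible(insect_morphology(0.4, 5, 0.1),
                                     flower_morphology(2, 1, 1, NA,
                                                       nectar_type = "none"))$reason,
                   "fail_no_nectar")
})

test_that("tree agrees with the nested-conditional oracle on a subgrid", {
  vals <- c(0.1, 0.4, 0.9, 1.6, 3.0)
  g <- expand.grid(hw = vals[c(1, 3, 5)], x = vals[c(1, 3, 5)],
                   z = vals[c(1, 3, 5)], w = vals[c(1, 3, 5)],
                   h = vals[c(1, 3, 5)], p = vals[c(1, 3, 5)],
                   d = c(vals[c(1, 3)], NA))
  got <- mapply(pkg_accessible, g$hw, g$x, g$z, g$w, g$h, g$p, g$d)
  want <- mapply(oracle_accessible, g$hw, g$x, g$z, g$w, g$h, g$p, g$d)
  expect_identical(got, want)
})

test_that("accessibility is monotone in reach-related dimensions", {
  set.seed(42)
  for (i in 1:200) {
    pars <- list(head_width = runif(1, 0.1, 3), x = runif(1, 0.1, 3),
                 z = runif(1, 0.02, 0.6), w = runif(1, 0.1, 3),
                 h = runif(1, 0, 3), p = runif(1, 0, 3),
                 d = sample(c(runif(1, 0.05, 0.8), NA), 1))
    base <- do.call(pkg_accessible, pars)
    longer <- pars; longer$x <- pars$x + runif(1, 0, 2)
    if (base) expect_true(do.call(pkg_accessible, longer))
    deeper <- pars; deeper$p <- pars$p + runif(1, 0, 2)
    if (!base) expect_false(do.call(pkg_accessible, deeper))
    taller <- pars; taller$h <- pars$h + runif(1, 0, 2)
    if (!base) expect_false(do.call(pkg_accessible, taller))
    thinner <- pars; thinner$z <- pars$z * runif(1, 0.1, 1)
    if (base) expect_true(do.call(pkg_accessible, thinner))
  }
})

test_that("missing traits fail conservatively; negative lengths error", {
  v <- nectar_accessible(insect_morphology(0.4, 0.3, 0.05),
                         flower_morphology(NA, 2, 1, 0.2))
  expect_false(v$accessible)
  expect_identical(v$reason, "fail_missing_trait")
  expect_error(nectar_accessible(list(head_width = -1, proboscis_length = 1,
                                      proboscis_width = 0.1),
                                 flower_morphology(1, 1, 1, NA)),
               "> 0")
  expect_error(flower_morphology(-0.5, 1, 1), ">= 0")
})

test_that("temporal availability follows window overlap and survey stages", {
  fl <- function(on, dur, type = "floral")
    flower_morphology(1, 1, 0.5, NA, nectar_type = type,
                      flower_onset = on, flower_duration = dur)
  ins <- insect_morphology(0.5, 1, 0.05, 140, 160)
  expect_true(nectar_available(fl(100, 50), ins))   # [100,150] x [140,160]
  expect_false(nectar_available(fl(100, 20), ins))  # disjoint
  expect_true(nectar_available(fl(100, 50), insect_morphology(0.5, 1, 0.05,
                                                              150, 160)))
  # extrafloral producers secrete through the season
  expect_true(nectar_available(fl(100, 5, "extrafloral"),
                               insect_morphology(0.5, 1, 0.05, 300, 320)))
  # survey mode: stage must be in the flowering range and date in activity
  expect_true(nectar_available(fl(100, 50), ins, mode = "survey",
                               survey_stage = 6, survey_date = 150))
  expect_false(nectar_available(fl(100, 50), ins, mode = "survey",
                                survey_stage = 3, survey_date = 150))
  expect_false(nectar_available(fl(100, 50), ins, mode = "survey",
                                survey_stage = 6, survey_date = 100))
  expect_error(nectar_available(fl(100, 50), ins, mode = "survey",
                                survey_stage = 11, survey_date = 150),
               "11-point")
})

test_that("accessible cover sums the right species and degrades gracefully", {
  fx <- fixture_small()
  p1 <- fx$surveys[fx$surveys$plot == "p1", ]
  expect_equal(accessible_cover(p1, fx$flora,
                                insect_from_df(fx$insects, "P1")), 50)
  expect_equal(accessible_cover(p1, fx$flora,
                                insect_from_df(fx$insects, "P2")), 30)
  # no accessible species -> 0; all accessible -> total cover
  none <- p1[p1$species == "D", ]
  expect_equal(accessible_cover(none, fx$flora,
                                insect_from_df(fx$insects, "P1")), 0)
  all_acc <- p1[p1$species %in% c("A", "B"), ]
  expect_equal(accessible_cover(all_acc, fx$flora,
                                insect_from_df(fx$insects, "P1")),
               sum(all_acc$cover))
  # additive over disjoint species sets, invariant to ordering
  ins <- insect_from_df(fx$insects, "P1")
  expect_equal(accessible_cover(p1, fx$flora, ins),
               accessible_cover(p1[c("3", "1", "4", "2"), ], fx$flora, ins))
  expect_equal(accessible_cover(p1[1:2, ], fx$flora, ins) +
                 accessible_cover(p1[3:4, ], fx$flora, ins),
               accessible_cover(p1, fx$flora, ins))
  # unknown species contribute zero with a warning
  p1x <- rbind(p1, data.frame(plot = "p1", treatment = "t1", strip = "s1",
                              block = "b1", species = "mystery", cover = 99,
                              stage = 6))
  expect_warning(cv <- accessible_cover(p1x, fx$flora, ins), "mystery")
  expect_equal(cv, 50)
})

test_that("accessibility matrix matches per-pair verdicts on the fixture", {
  fx <- fixture_small()
  m <- accessibility_matrix(fx$flora, fx$insects)
  expect_identical(m["A", ], c(P1 = 1L, P2 = 1L))
  expect_identical(m["B", ], c(P1 = 1L, P2 = 0L))
  expect_identical(unname(m["C", ]), c(0L, 0L))
  expect_identical(unname(m["D", ]), c(0L, 0L))
})

test_that("trait coverage report counts completeness", {
  fx <- fixture_small()
  rep_full <- trait_coverage_report(fx$flora[2:3, ])
  expect_equal(unname(rep_full$species_complete), 1)
  ten <- do.call(rbind, replicate(5, fx$flora[2:3, ], simplify = FALSE))
  ten$species <- paste0("s", 1:10)
  ten$d[1] <- NA
  expect_equal(trait_coverage_report(ten)$species_complete, 0.9)
  empty <- trait_coverage_report(fx$flora[0, ])
  expect_equal(empty$n, 0L)
})
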