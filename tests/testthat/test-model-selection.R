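test_that("candidate enumeration respects marginality and caps", {
  expect_length(build_term_sets("x"), 3)                       # {}, L, L+Q
  expect_length(build_term_sets(c("a", "b", "c"), quadratic = FALSE,
                                interactions = FALSE), 8)      # 2^3
  expect_length(build_term_sets("x", marginality = FALSE), 4)  # free 2^2
  sets <- build_term_sets(c("a", "b", "c"))
  expect_equal(length(sets), 95)  # 27 quad patterns x admissible interactions
  expect_identical(sets[[1]], character(0))
  # every quadratic has its linear parent, every interaction both parents
  for (s in sets) {
    for (p in c("a", "b", "c")) {
      if (paste0("I(", p, "^2)") %in% s) expect_true(p %in% s)
    }
    if ("a:b" %in% s) expect_true(all(c("a", "b") %in% s))
  }
  capped <- build_term_sets(c("a", "b", "c"), max_terms = 5)
  expect_true(all(lengths(capped) <= 5))
  # threshold universe carries interactions with linear and quadratic terms
  ts <- build_term_sets("f", threshold = "tau")
  expect_true(any(vapply(ts, function(s) "tau:I(f^2)" %in% s, logical(1))))
})

test_that("AIC ranking produces normalized Akaike weights", {
  fits <- list(m1 = fake_fit("(Intercept)", 0, 1, aic = 100),
               m2 = fake_fit(c("(Intercept)", "x"), c(0, 1), c(1, 1),
                             aic = 100))
  r <- rank_by_aic(fits)
  expect_equal(r$weight, c(0.5, 0.5))
  expect_equal(sum(r$weight), 1)

  # strict delta < 2 at the boundary
  fits2 <- list(m1 = fake_fit("(Intercept)", 0, 1, aic = 10),
                m2 = fake_fit(c("(Intercept)", "x"), c(0, 1), c(1, 1),
                              aic = 12))
  r2 <- rank_by_aic(fits2)
  expect_identical(r2$selected, c(TRUE, FALSE))
  expect_equal(r2$delta, c(0, 2))
})

test_that("conditional averaging reproduces hand-weighted estimates", {
  # single selected model: averaging is the identity
  one <- list(m = fake_fit(c("(Intercept)", "x"), c(0.3, 1.2), c(0.1, 0.2),
                           aic = 50))
  av1 <- conditional_average(one)
  expect_equal(av1$coefficients$estimate,
               one$m$coefficients$estimate)
  expect_equal(av1$coefficients$se, one$m$coefficients$se)
  expect_equal(av1$coefficients$importance, c(1, 1))

  # two members with weights 0.6/0.4; shared term averages to 1.4 and a
  # member-only term keeps its own estimate with importance 0.6
  d_aic <- 2 * log(0.6 / 0.4)
  fits <- list(
    big = fake_fit(c("(Intercept)", "shared", "only"), c(0, 1.0, 2.5),
                   c(1, 0.2, 0.3), aic = 100),
    small = fake_fit(c("(Intercept)", "shared"), c(0, 2.0), c(1, 0.2),
                     aic = 100 + d_aic))
  av <- conditional_average(fits)
  co <- av$coefficients
  expect_equal(co$estimate[co$term == "shared"], 1.4, tolerance = 1e-10)
  expect_equal(co$importance[co$term == "shared"], 1, tolerance = 1e-10)
  expect_equal(co$estimate[co$term == "only"], 2.5)
  expect_equal(co$importance[co$term == "only"], 0.6, tolerance = 1e-10)
  # revised unconditional variance estimator for the shared term
  se_hand <- 0.6 * sqrt(0.2^2 + (1.0 - 1.4)^2) +
    0.4 * sqrt(0.2^2 + (2.0 - 1.4)^2)
  expect_equal(co$se[co$term == "shared"], se_hand, tolerance = 1e-10)

  # invariant to enumeration order
  av_rev <- conditional_average(rev(fits))
  co_rev <- av_rev$coefficients
  expect_equal(co$estimate[order(co$term)],
               co_rev$estimate[order(co_rev$term)])

  expect_error(conditional_average(fits, delta_cutoff = -1), "empty")
})

test_that("fitted candidates over a fixture rank sensibly", {
  set.seed(9)
  d <- sim_binom_data(beta1 = 1.2, sigma = 0.3, re = "strip", trials = 100)
  names(d)[names(d) == "x"] <- "a"
  d$b <- rnorm(nrow(d))
  sets <- build_term_sets(c("a", "b"), quadratic = FALSE,
                          interactions = FALSE)
  fits <- fit_candidates(sets, "cbind(k, n - k)", d, grouping = "strip",
                         nAGQ = 1)
  r <- rank_by_aic(fits)
  expect_equal(sum(r$weight), 1, tolerance = 1e-12)
  expect_true(grepl("a", r$model[1]))   # true predictor in the best model
  av <- conditional_average(fits, r)
  expect_gte(av$coefficients$importance[av$coefficients$term == "a"], 0.9)
})
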