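test_that("neutral draws are uniform without replacement", {
  pool <- c("a", "b", "c", "d")
  set.seed(1)
  expect_setequal(neutral_draw(pool, 4), pool)
  expect_identical(neutral_draw(pool, 0), character(0))
  expect_error(neutral_draw(pool, 5), "pool size")
  draws <- replicate(10000, neutral_draw(pool, 2))
  freq <- table(factor(draws, levels = pool)) / 10000
  expect_true(all(abs(freq - 0.5) < 0.02))  # hypergeometric expectation
  # mean neutral cover equals (k/N) x total eligible cover
  covers <- c(a = 40, b = 20, c = 10, d = 2)
  mean_cover <- mean(replicate(5000, sum(covers[neutral_draw(pool, 2)])))
  expect_equal(mean_cover, 0.5 * sum(covers), tolerance = 0.03)
})

neutral_setup <- function(beta_nectar = 0.9, seed = 2) {
  set.seed(seed)
  fx <- fixture_small()
  surveys <- fx$surveys
  insect <- insect_from_df(fx$insects, "P1")
  cov <- plot_covariates(surveys, fx$flora, fx$insects)
  dat <- data.frame(plot = cov$plot, strip = cov$strip,
                    nectar = as.numeric(scale(cov$nectar_P1)))
  dat$n <- 80
  dat$k <- rbinom(6, 80, plogis(-1 + beta_nectar * dat$nectar))
  fit <- fit_glmm(cbind(k, n - k) ~ nectar + (1 | strip), dat,
                  family = "binomial", nAGQ = 1)
  list(fit = fit, dat = dat, surveys = surveys, flora = fx$flora,
       insect = insect)
}

test_that("reports are reproducible and degenerate draws give equality", {
  s <- neutral_setup()
  r1 <- neutral_aic_comparison(s$fit, s$dat, s$surveys, s$flora, s$insect,
                               mode = "all", iterations = 20, seed = 99)
  r2 <- neutral_aic_comparison(s$fit, s$dat, s$surveys, s$flora, s$insect,
                               mode = "all", iterations = 20, seed = 99)
  expect_identical(r1$aics, r2$aics)
  r3 <- neutral_aic_comparison(s$fit, s$dat, s$surveys, s$flora, s$insect,
                               mode = "all", iterations = 20, seed = 100)
  expect_false(identical(r3$aics, r1$aics))

  # k = |pool|: every draw is the full pool, and because the full-pool
  # cover is perfectly correlated with itself the refit AIC is constant
  r_full <- neutral_aic_comparison(s$fit, s$dat, s$surveys, s$flora,
                                   s$insect, mode = "all", iterations = 5,
                                   seed = 1, k = 4)
  expect_equal(diff(range(r_full$aics)), 0, tolerance = 1e-8)

  # when every species is accessible, the full-pool draw reproduces the
  # observed covariate exactly: mean neutral AIC equals the observed AIC
  fx <- fixture_small()
  fx$flora$nectar_type <- "extrafloral"
  cov <- plot_covariates(fx$surveys, fx$flora, fx$insects)
  set.seed(5)
  dat <- data.frame(plot = cov$plot, strip = cov$strip,
                    nectar = as.numeric(scale(cov$nectar_P1)), n = 80)
  dat$k <- rbinom(6, 80, plogis(-1 + 0.8 * dat$nectar))
  fit <- fit_glmm(cbind(k, n - k) ~ nectar + (1 | strip), dat,
                  family = "binomial", nAGQ = 1)
  r_id <- neutral_aic_comparison(fit, dat, fx$surveys, fx$flora,
                                 insect_from_df(fx$insects, "P1"),
                                 mode = "all", iterations = 4, seed = 1,
                                 k = 4)
  expect_equal(r_id$mean_neutral_aic, r_id$observed_aic, tolerance = 1e-8)
})

test_that("trait-matched accessible count sets the default draw size", {
  s <- neutral_setup()
  r <- neutral_aic_comparison(s$fit, s$dat, s$surveys, s$flora, s$insect,
                              mode = "flowering", iterations = 3, seed = 1)
  # P1 accesses A and B among the flowering pool {A, B, C}
  expect_equal(r$k, 2)
  expect_equal(r$pool_size, 3)
  r_all <- neutral_aic_comparison(s$fit, s$dat, s$surveys, s$flora,
                                  s$insect, mode = "all", iterations = 3,
                                  seed = 1)
  expect_equal(r_all$pool_size, 4)
})

test_that("a real nectar signal beats its own randomizations", {
  s <- neutral_setup(beta_nectar = 1.5, seed = 4)
  r <- neutral_aic_comparison(s$fit, s$dat, s$surveys, s$flora, s$insect,
                              mode = "all", iterations = 60, seed = 7)
  expect_lt(r$observed_aic, r$mean_neutral_aic)
  expect_gt(r$empirical_quantile, 0.5)
})
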