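## Independently coded nested-conditional oracle for nectar accessibility.
## Deliberately structured as one nested if-cascade (not the package's
## flat-constraint logic) so agreement is informative.
oracle_accessible <- function(head_width, x, z, w, h, p, d,
                              nectar_type = "floral") {
  if (nectar_type == "none") {
    FALSE
  } else if (nectar_type == "extrafloral" || nectar_type == "both") {
    TRUE
  } else if (!is.na(d) && z > d) {
    FALSE
  } else if (w >= head_width) {        # head (diameter = 2r) fits opening
    if (x >= p) TRUE else FALSE
  } else {
    if (x >= h + p) TRUE else FALSE
  }
}

## Quick wrapper: package verdict as a bare logical
pkg_accessible <- function(head_width, x, z, w, h, p, d,
                           nectar_type = "floral") {
  nectar_accessible(
    list(head_width = head_width, proboscis_length = x, proboscis_width = z),
    list(w = w, h = h, p = p, d = d, nectar_type = nectar_type))$accessible
}

## Minimal hand-made glmm_fit stand-in for averaging arithmetic tests
fake_fit <- function(terms, estimates, ses, aic, n = 27) {
  structure(list(coefficients = data.frame(term = terms,
                                           estimate = estimates, se = ses,
                                           z = estimates / ses,
                                           p = 2 * pnorm(-abs(estimates / ses))),
                 AIC = aic, logLik = -(aic - 2 * (length(terms) + 1)) / 2,
                 k = length(terms) + 1L, n = n, sigma_u = 0.1,
                 converged = TRUE, degenerate = FALSE,
                 family = "binomial"),
            class = "glmm_fit")
}

## Simulated one-covariate binomial mixed dataset; the random intercept sits
## on `re` ("plot": one level per observation, 27 levels; "strip": 3 levels)
sim_binom_data <- function(beta0 = -1, beta1 = 0.5, sigma = 0.3,
                           n_groups = 27, trials = 50, n_strips = 3,
                           re = "plot") {
  strip <- factor(rep(seq_len(n_strips), length.out = n_groups))
  plot <- factor(seq_len(n_groups))
  x <- rnorm(n_groups)
  g <- if (re == "plot") plot else strip
  u <- rnorm(nlevels(g), 0, sigma)
  eta <- beta0 + beta1 * x + u[as.integer(g)]
  data.frame(plot = plot, strip = strip, x = x,
             n = trials, k = rbinom(n_groups, trials, plogis(eta)))
}
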