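#' Fit a binomial or Poisson mixed model with one random intercept
#'
#' Maximum-likelihood fit of a generalized linear mixed model with a single
#' random intercept, by adaptive Gauss--Hermite quadrature (`nAGQ` nodes;
#' `nAGQ = 1` is the Laplace approximation).  When the grouping factor has a
#' single level the random intercept is inestimable and the model degrades
#' to the corresponding GLM with `sigma_u = 0` (the returned log-likelihood
#' then equals the GLM's).  Non-convergence is flagged, not thrown; the
#' optimizer is restarted from up to three starting points before flagging.
#'
#' The reported AIC always satisfies `AIC = -2 logLik + 2 k` with
#' `k = n_fixed + 1` (one variance parameter), including in the degenerate
#' single-group case, so candidate models remain comparable.
#'
#' @param formula Model formula including exactly one `(1 | group)` term for
#'   mixed fits, e.g. `cbind(k, n - k) ~ nectar + I(fdis^2) + (1 | strip)`.
#'   Binomial responses use the `cbind(successes, failures)` form.
#' @param data Data frame with complete cases for all terms.
#' @param family `"binomial"` (logit link) or `"poisson"` (log link).
#' @param nAGQ Number of adaptive quadrature nodes (default 15; lme4 caps
#'   this at 25).  `0` uses the faster penalized-least-squares approximation.
#' @return An object of class `glmm_fit`: list with `model`, `coefficients`
#'   (data frame: term, estimate, se, z, p), `vcov`, `sigma_u`, `logLik`,
#'   `AIC`, `n`, `k`, `converged`, `family`, `formula`, `grouping`, `nAGQ`.
#' @export
fit_glmm <- function(formula, data, family = c("binomial", "poisson"),
                     nAGQ = 15) {
  family <- match.arg(family)
  fam <- if (family == "binomial") stats::binomial() else stats::poisson()
  bars <- lme4::findbars(formula)
  grouping <- if (length(bars)) deparse(bars[[1]][[3]]) else NA_character_
  if (length(bars) > 1) stop("a single random intercept is supported")

  degenerate <- !is.na(grouping) &&
    length(unique(data[[grouping]])) < 2L
  if (is.na(grouping) || degenerate) {
    ff <- if (is.na(grouping)) formula else lme4::nobars(formula)
    m <- stats::glm(ff, family = fam, data = data)
    co <- summary(m)$coefficients
    ll <- as.numeric(stats::logLik(m))
    k <- nrow(co) + 1L  # sigma_u counted even when pinned at 0
    fit <- list(model = m, sigma_u = 0,
                logLik = ll, AIC = -2 * ll + 2 * k,
                converged = m$converged, degenerate = TRUE)
  } else {
    ## skip the finite-difference derivative check: these are small, well-
    ## conditioned models and the optimizer return code is authoritative
    ctrl <- function(opt = NULL)
      if (is.null(opt)) lme4::glmerControl(calc.derivs = FALSE)
      else lme4::glmerControl(optimizer = opt, calc.derivs = FALSE)
    m <- tryCatch(
      suppressMessages(lme4::glmer(formula, data = data, family = fam,
                                   nAGQ = nAGQ, control = ctrl())),
      error = function(e) e)
    ok <- function(m) !inherits(m, "error") &&
      isTRUE(m@optinfo$conv$opt == 0) &&
      !any(grepl("failed to converge",
                 unlist(m@optinfo$conv$lme4$messages)))
    if (!ok(m)) {  # fixed restart ladder
      for (opt in c("bobyqa", "Nelder_Mead")) {
        m2 <- tryCatch(
          suppressMessages(lme4::glmer(formula, data = data, family = fam,
                                       nAGQ = nAGQ, control = ctrl(opt))),
          error = function(e) e)
        if (ok(m2)) { m <- m2; break }
      }
    }
    if (inherits(m, "error")) stop("glmm fit failed: ", conditionMessage(m))
    co <- summary(m)$coefficients
    ll <- as.numeric(stats::logLik(m))
    k <- nrow(co) + 1L
    fit <- list(model = m,
                sigma_u = sqrt(as.numeric(lme4::VarCorr(m)[[grouping]])),
                logLik = ll, AIC = -2 * ll + 2 * k,
                converged = ok(m), degenerate = FALSE)
  }
  fit$coefficients <- data.frame(term = rownames(co),
                                 estimate = co[, 1], se = co[, 2],
                                 z = co[, 1] / co[, 2],
                                 p = 2 * stats::pnorm(-abs(co[, 1] / co[, 2])),
                                 row.names = NULL)
  fit$vcov <- as.matrix(stats::vcov(fit$model))
  fit$n <- stats::nobs(fit$model)
  fit$k <- k
  fit$family <- family
  fit$formula <- formula
  fit$grouping <- grouping
  fit$nAGQ <- nAGQ
  class(fit) <- "glmm_fit"
  fit
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("GLMM (", x$family, "), grouping: ", x$grouping,
      ", sigma_u = ", signif(x$sigma_u, 4),
      ", AIC = ", signif(x$AIC, 6),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Choose the random-effect grouping by AIC
#'
#' Fits the same fixed-effect structure once per candidate grouping factor
#' and returns the one with the lowest AIC (ties resolved in candidate
#' order, with a message).
#'
#' @param fixed Fixed-effect formula without a random term, e.g.
#'   `cbind(k, n - k) ~ treatment`.
#' @param data Data frame containing all candidate grouping columns.
#' @param candidates Character vector of grouping column names, in
#'   preference order.
#' @param ... Passed to [fit_glmm()].
#' @return List with `grouping` (chosen name), `aic` (named vector) and
#'   `fits` (list of `glmm_fit`).
#' @export
select_random_effect <- function(fixed, data,
                                 candidates = c("plot", "strip", "block"),
                                 ...) {
  fits <- lapply(candidates, function(g) {
    f <- stats::update(fixed, paste(". ~ . + (1 |", g, ")"))
    fit_glmm(f, data, ...)
  })
  names(fits) <- candidates
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  best <- which.min(aic)
  if (sum(aic == aic[best]) > 1)
    message("AIC tie among random-effect candidates; keeping '",
            candidates[best], "' (first in candidate order)")
  list(grouping = candidates[best], aic = aic, fits = fits)
}

#' Type II Wald chi-square tests
#'
#' Per-term Wald chi-square tests respecting marginality (each term is
#' tested after all other terms that do not contain it), as produced by
#' `car::Anova(type = "II")`.
#'
#' @param fit A `glmm_fit`.
#' @return Data frame with columns `term`, `chisq`, `df`, `p`.
#' @export
wald_type2 <- function(fit) {
  a <- if (fit$degenerate)
    car::Anova(fit$model, type = "II", test.statistic = "Wald")
  else
    car::Anova(fit$model, type = "II")
  keep <- rownames(a) != "(Intercept)"
  chisq_col <- grep("Chisq", names(a), value = TRUE)[1]
  data.frame(term = rownames(a)[keep],
             chisq = a[[chisq_col]][keep],
             df = a$Df[keep],
             p = a[[grep("^Pr", names(a), value = TRUE)[1]]][keep],
             row.names = NULL)
}

#' Marginal and conditional pseudo-R-squared
#'
#' Variance-partition pseudo-R2 for one-random-intercept GLMMs.  The fixed
#' -effect variance is the variance of the linear predictor built from the
#' fixed effects over the estimation data; the distribution-specific
#' variance is `pi^2 / 3` for the binomial-logit family and
#' `log(1 + 1/exp(beta0))` for the Poisson-log family.  Marginal R2 is the
#' fixed share, conditional R2 the fixed-plus-random share; marginal <=
#' conditional always.
#'
#' @param fit A `glmm_fit`.
#' @return Named vector `c(marginal, conditional)`.
#' @export
pseudo_r2 <- function(fit) {
  m <- fit$model
  X <- if (fit$degenerate) stats::model.matrix(m) else lme4::getME(m, "X")
  beta <- fit$coefficients$estimate
  var_f <- stats::var(as.numeric(X %*% beta))
  var_u <- fit$sigma_u^2
  var_d <- if (fit$family == "binomial") pi^2 / 3
           else log(1 + 1 / exp(beta[1]))
  tot <- var_f + var_u + var_d
  c(marginal = var_f / tot, conditional = (var_f + var_u) / tot)
}
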