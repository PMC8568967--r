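#' Enumerate candidate fixed-effect term sets
#'
#' Builds the all-subsets candidate list over a set of community predictors:
#' each predictor contributes a linear term and optionally its quadratic
#' term `I(x^2)`; pairwise interactions between the linear terms can be
#' added; and an optional continuous threshold variable contributes its main
#' effect plus interactions with every community term (linear and
#' quadratic).  With `marginality = TRUE` (default) a quadratic term
#' requires its linear term and an interaction requires both parents, which
#' keeps averaged coefficients interpretable; the switch disables this.
#' `max_terms` caps the number of fixed-effect variables per model.
#'
#' @param predictors Character vector of predictor (column) names.
#' @param quadratic Include `I(x^2)` terms.
#' @param interactions Include pairwise interactions of the linear terms.
#' @param threshold Optional name of a threshold variable; adds its main
#'   effect and its interaction with every community term.
#' @param max_terms Maximum number of fixed-effect terms per model.
#' @param marginality Enforce marginality constraints.
#' @return List of character vectors of term labels, in deterministic
#'   order; the first element is `character(0)` (the intercept-only model).
#' @examples
#' length(build_term_sets("x"))                                   # 3
#' length(build_term_sets(c("a", "b", "c"), quadratic = FALSE,
#'                        interactions = FALSE))                  # 8
#' @export
build_term_sets <- function(predictors, quadratic = TRUE,
                            interactions = TRUE, threshold = NULL,
                            max_terms = Inf, marginality = TRUE) {
  terms <- predictors
  parents <- stats::setNames(vector("list", length(predictors)), predictors)
  add <- function(term, par) {
    terms <<- c(terms, term)
    parents[[term]] <<- par
  }
  if (quadratic)
    for (p in predictors) add(paste0("I(", p, "^2)"), p)
  if (interactions && length(predictors) > 1) {
    cmb <- utils::combn(predictors, 2)
    for (j in seq_len(ncol(cmb)))
      add(paste0(cmb[1, j], ":", cmb[2, j]), cmb[, j])
  }
  if (!is.null(threshold)) {
    community <- terms
    add(threshold, character(0))
    for (tm in community)
      add(paste0(threshold, ":", tm), c(threshold, tm))
  }
  nt <- length(terms)
  if (nt > 25) stop("term universe too large to enumerate")
  out <- list()
  for (mask in 0:(2^nt - 1)) {
    inc <- terms[bitwAnd(mask, bitwShiftL(1L, seq_len(nt) - 1L)) != 0L]
    if (length(inc) > max_terms) next
    if (marginality) {
      ok <- all(vapply(inc, function(tm)
        all(parents[[tm]] %in% inc), logical(1)))
      if (!ok) next
    }
    out[[length(out) + 1L]] <- inc
  }
  ## deterministic order: by size, then lexicographic
  key <- vapply(out, function(s) paste(sort(s), collapse = "+"), "")
  out[order(lengths(out), key)]
}

#' Fit every candidate model of a term-set list
#'
#' @param term_sets List from [build_term_sets()].
#' @param response Left-hand side as a string, e.g. `"cbind(k, n - k)"`.
#' @param data Data frame.
#' @param grouping Random-intercept grouping column name.
#' @param family,nAGQ Passed to [fit_glmm()].
#' @return Named list of `glmm_fit` (names are the fixed formulas);
#'   non-converged fits are dropped with a warning giving the count.
#' @export
fit_candidates <- function(term_sets, response, data, grouping,
                           family = "binomial", nAGQ = 1) {
  fits <- lapply(term_sets, function(tms) {
    rhs <- paste(c("1", tms, paste0("(1 | ", grouping, ")")), collapse = " + ")
    f <- stats::as.formula(paste(response, "~", rhs))
    tryCatch(fit_glmm(f, data, family = family, nAGQ = nAGQ),
             error = function(e) NULL)
  })
  names(fits) <- vapply(term_sets, function(tms)
    paste(c("1", tms), collapse = " + "), "")
  ok <- vapply(fits, function(f) !is.null(f) && f$converged, logical(1))
  if (any(!ok))
    warning(sum(!ok), " candidate model(s) failed to converge; dropped")
  fits[ok]
}

#' Rank candidate fits by AIC
#'
#' Computes delta-AIC and Akaike weights
#' `w_m = exp(-delta_m / 2) / sum exp(-delta / 2)` over the candidate set,
#' and marks the selected confidence set `delta < 2` (strict).
#'
#' @param fits Named list of `glmm_fit`, as from [fit_candidates()].
#' @return Data frame (one row per model, sorted by AIC) with columns
#'   `model`, `k`, `logLik`, `AIC`, `delta`, `weight`, `selected`.
#' @export
rank_by_aic <- function(fits) {
  if (!length(fits)) stop("no fitted candidate models")
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  tab <- data.frame(model = names(fits),
                    k = vapply(fits, `[[`, integer(1), "k"),
                    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
                    AIC = aic, row.names = NULL)
  tab <- tab[order(tab$AIC, tab$model), ]
  tab$delta <- tab$AIC - tab$AIC[1]
  tab$weight <- exp(-tab$delta / 2) / sum(exp(-tab$delta / 2))
  tab$selected <- tab$delta < 2
  rownames(tab) <- NULL
  tab
}

#' Conditional model averaging over the delta-AIC confidence set
#'
#' Averages each coefficient over only those selected models (`delta < 2`)
#' that contain it, with Akaike weights renormalized first within the
#' selected set and then within the containing members (conditional
#' averaging).  The adjusted standard error uses the revised unconditional
#' variance estimator
#' `se_adj = sum_m w_m sqrt(se_m^2 + (b_m - b_bar)^2)`, which folds
#' between-model variance into the reported uncertainty.  A term's relative
#' importance is the summed (renormalized) weight of the selected models
#' containing it.
#'
#' @param fits Named list of `glmm_fit`.
#' @param ranking Optional precomputed [rank_by_aic()] table.
#' @param delta_cutoff Confidence-set cutoff (strict `<`), default 2.
#' @return Object of class `averaged_model`: list with `coefficients`
#'   (term, estimate, se, z, p, importance, n_models), `members` (the
#'   selected ranking rows with renormalized weights), and `ranking`.
#' @export
conditional_average <- function(fits, ranking = rank_by_aic(fits),
                                delta_cutoff = 2) {
  sel <- ranking[ranking$delta < delta_cutoff, ]
  if (!nrow(sel)) stop("empty confidence set")
  sel$weight <- sel$weight / sum(sel$weight)
  member_fits <- fits[sel$model]
  terms <- unique(unlist(lapply(member_fits,
                                function(f) f$coefficients$term)))
  rows <- lapply(terms, function(tm) {
    has <- vapply(member_fits, function(f)
      tm %in% f$coefficients$term, logical(1))
    w <- sel$weight[has] / sum(sel$weight[has])
    b <- vapply(member_fits[has], function(f)
      f$coefficients$estimate[f$coefficients$term == tm], numeric(1))
    s <- vapply(member_fits[has], function(f)
      f$coefficients$se[f$coefficients$term == tm], numeric(1))
    bbar <- sum(w * b)
    se <- sum(w * sqrt(s^2 + (b - bbar)^2))
    data.frame(term = tm, estimate = bbar, se = se,
               z = bbar / se, p = 2 * stats::pnorm(-abs(bbar / se)),
               importance = sum(sel$weight[has]),
               n_models = sum(has))
  })
  out <- list(coefficients = do.call(rbind, rows),
              members = sel, ranking = ranking)
  class(out) <- "averaged_model"
  out
}

#' @export
print.averaged_model <- function(x, ...) {
  cat("Conditional model average over", nrow(x$members),
      "model(s) with delta-AIC < 2\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}
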