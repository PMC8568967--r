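#' Reference maximum parasitism rate per herbivore
#'
#' For each herbivore at one distance, the reference maximum is the mean of
#' its three highest plot-level parasitism rates (a guard against a single
#' outlying plot defining the maximum).  When fewer than three rates exist
#' the mean of what is available is used, with a warning.
#'
#' @param table Parasitism data frame with columns `plot`, `distance`,
#'   `herbivore`, `n_examined`, `n_parasitized`.
#' @param distance Distance (m) to subset on.
#' @return Named vector of reference maxima, one per herbivore.
#' @examples
#' tab <- data.frame(plot = 1:4, distance = 5, herbivore = "H",
#'                   n_examined = 10, n_parasitized = c(9, 8, 7, 1))
#' herbivore_maxima(tab, 5)  # 0.8
#' @export
herbivore_maxima <- function(table, distance) {
  tab <- table[table$distance == distance, ]
  rates <- tab$n_parasitized / tab$n_examined
  out <- tapply(rates, as.character(tab$herbivore), function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 3)
      warning("fewer than 3 rates for a herbivore; using mean of ",
              length(r))
    mean(sort(r, decreasing = TRUE)[seq_len(min(3, length(r)))])
  })
  c(out)
}

#' Multi-species parasitism counts over a threshold sweep
#'
#' For each plot and each threshold `tau`, counts the number of herbivores
#' whose local parasitism rate strictly exceeds `tau` times that herbivore's
#' reference maximum ([herbivore_maxima()]).  By default only complete-case
#' plots (a rate observed for every herbivore at that distance) enter the
#' dataset; with `complete_only = FALSE` counts are taken over the
#' herbivores available.
#'
#' @inheritParams herbivore_maxima
#' @param thresholds Threshold sweep, default `seq(0.1, 0.9, by = 0.1)`.
#' @param maxima Optional precomputed reference maxima.
#' @param complete_only Drop plots missing any herbivore's rate.
#' @return Data frame `plot` (plus `strip`/`treatment` when present in the
#'   input), `threshold`, `count`, with `length(thresholds)` rows per
#'   retained plot; counts are non-increasing in the threshold.
#' @export
multispecies_counts <- function(table, distance,
                                thresholds = seq(0.1, 0.9, by = 0.1),
                                maxima = NULL, complete_only = TRUE) {
  tab <- table[table$distance == distance & !is.na(table$n_examined), ]
  if (is.null(maxima)) maxima <- herbivore_maxima(table, distance)
  tab$rate <- tab$n_parasitized / tab$n_examined
  herb <- sort(unique(as.character(table$herbivore)))
  plots <- unique(as.character(tab$plot))
  keep_cols <- intersect(c("strip", "treatment"), names(tab))
  out <- list()
  for (pl in plots) {
    sub <- tab[as.character(tab$plot) == pl, ]
    r <- stats::setNames(sub$rate, as.character(sub$herbivore))[herb]
    if (complete_only && any(is.na(r))) next
    r <- r[!is.na(r)]
    counts <- vapply(thresholds, function(tau)
      sum(r > tau * maxima[names(r)]), numeric(1))
    row <- data.frame(plot = pl, threshold = thresholds, count = counts)
    for (cc in keep_cols) row[[cc]] <- sub[[cc]][1]
    out[[pl]] <- row
  }
  if (!length(out))
    return(data.frame(plot = character(0), threshold = numeric(0),
                      count = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the multi-threshold multi-species parasitism model
#'
#' Joins the threshold-sweep counts to standardized plot-level community
#' covariates, builds the candidate set (community predictors with linear
#' and quadratic terms, the continuous threshold main effect, and
#' threshold-by-predictor interactions, capped at `max_terms` fixed-effect
#' variables per model), fits every candidate as a Poisson mixed model with
#' a strip random intercept, and conditionally averages the delta-AIC < 2
#' confidence set.
#'
#' @param counts Output of [multispecies_counts()] (must carry `strip`).
#' @param covariates Data frame with `plot` and the predictor columns
#'   (raw scale; standardized internally).
#' @param predictors Community predictor names, default
#'   `c("nectar", "richness", "fdis")`.
#' @param max_terms Cap on fixed-effect variables per model, default 5.
#' @param nAGQ Quadrature setting for the candidate fits.
#' @param interactions Pairwise interactions among the community linear
#'   terms (default `FALSE`: the threshold interactions already span the
#'   hypothesis space and the cap keeps models small).
#' @return List with `averaged` (an `averaged_model`), `ranking`, `fits`,
#'   and `data` (the standardized analysis dataset).
#' @export
fit_multithreshold <- function(counts, covariates,
                               predictors = c("nectar", "richness", "fdis"),
                               max_terms = 5, nAGQ = 1,
                               interactions = FALSE) {
  if (!nrow(counts)) stop("empty multi-threshold dataset")
  dat <- merge(counts, covariates, by = "plot")
  for (p in predictors) dat[[p]] <- as.numeric(scale(dat[[p]]))
  dat$tau <- as.numeric(scale(dat$threshold))
  sets <- build_term_sets(predictors, quadratic = TRUE,
                          interactions = interactions, threshold = "tau",
                          max_terms = max_terms)
  fits <- fit_candidates(sets, "count", dat, grouping = "strip",
                         family = "poisson", nAGQ = nAGQ)
  ranking <- rank_by_aic(fits)
  list(averaged = conditional_average(fits, ranking),
       ranking = ranking, fits = fits, data = dat)
}

#' Predicted count-versus-FDis curves per threshold
#'
#' Population-level predictions of the averaged multi-threshold model along
#' a predictor gradient, one curve per threshold, holding the other
#' predictors at zero (their standardized mean).
#'
#' @param mt Result of [fit_multithreshold()].
#' @param predictor Predictor to sweep (standardized scale), default "fdis".
#' @param grid Gradient of standardized predictor values.
#' @return Data frame `threshold`, `predictor` value, `predicted` count.
#' @export
partial_effect_curves <- function(mt, predictor = "fdis",
                                  grid = seq(-2, 2, length.out = 41)) {
  co <- mt$averaged$coefficients
  taus <- sort(unique(mt$data$threshold))
  tau_z <- (taus - mean(mt$data$threshold)) / stats::sd(mt$data$threshold)
  eff <- function(term) {
    ## coefficient labels may carry either component order for interactions
    alt <- paste(rev(strsplit(term, ":", fixed = TRUE)[[1]]), collapse = ":")
    hit <- co$term %in% c(term, alt)
    if (any(hit)) co$estimate[hit][1] else 0
  }
  out <- expand.grid(threshold = taus, x = grid)
  out$tau_z <- tau_z[match(out$threshold, taus)]
  q <- paste0("I(", predictor, "^2)")
  eta <- eff("(Intercept)") +
    eff(predictor) * out$x + eff(q) * out$x^2 +
    eff("tau") * out$tau_z +
    eff(paste0("tau:", predictor)) * out$tau_z * out$x +
    eff(paste0("tau:", q)) * out$tau_z * out$x^2
  data.frame(threshold = out$threshold, predictor = out$x,
             predicted = exp(eta))
}
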