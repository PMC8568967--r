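#' Per-herbivore assemblage-factor analysis
#'
#' For each herbivore at each distance (analysed strictly separately), fits
#' a binomial mixed model of the parasitism rate on the assemblage treatment
#' factor, with the random intercept chosen by AIC among the candidate
#' groupings, and reports the type II Wald chi-square test of the treatment
#' effect.
#'
#' @param parasitism Parasitism table (`plot, treatment, strip, block,
#'   distance, herbivore, n_examined, n_parasitized`).
#' @param distances Distances to analyse, default all present.
#' @param candidates Random-effect candidates in preference order.
#' @param nAGQ Quadrature setting.
#' @return Data frame: `distance, herbivore, grouping, chisq, df, p,
#'   r2_marginal, r2_conditional`.
#' @export
run_assemblage_analysis <- function(parasitism,
                                    distances = sort(unique(parasitism$distance)),
                                    candidates = c("plot", "strip", "block"),
                                    nAGQ = 1) {
  out <- list()
  for (d in distances) for (h in sort(unique(as.character(parasitism$herbivore)))) {
    dat <- parasitism[parasitism$distance == d & parasitism$herbivore == h, ]
    dat <- dat[stats::complete.cases(dat[c("n_examined", "n_parasitized")]), ]
    dat$treatment <- factor(dat$treatment)
    sel <- select_random_effect(
      cbind(n_parasitized, n_examined - n_parasitized) ~ treatment,
      dat, candidates = intersect(candidates, names(dat)),
      family = "binomial", nAGQ = nAGQ)
    fit <- sel$fits[[sel$grouping]]
    wt <- wald_type2(fit)
    r2 <- pseudo_r2(fit)
    out[[paste(d, h)]] <- data.frame(
      distance = d, herbivore = h, grouping = sel$grouping,
      chisq = wt$chisq[wt$term == "treatment"],
      df = wt$df[wt$term == "treatment"],
      p = wt$p[wt$term == "treatment"],
      r2_marginal = r2[["marginal"]], r2_conditional = r2[["conditional"]])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Assemble the standardized per-plot analysis dataset for one herbivore x
## distance: response counts plus z-scored nectar (focal taxa), richness,
## fdis.
herbivore_dataset <- function(parasitism, covariates, herbivore, distance,
                              taxa) {
  dat <- parasitism[parasitism$distance == distance &
                      parasitism$herbivore == herbivore, ]
  dat <- merge(dat, covariates[, c("plot", "richness", "fdis",
                                   paste0("nectar_", taxa))], by = "plot")
  dat$nectar <- rowMeans(as.data.frame(dat[paste0("nectar_", taxa)]))
  for (v in c("nectar", "richness", "fdis"))
    dat[[v]] <- if (stats::sd(dat[[v]]) == 0) dat[[v]] * 0
                else as.numeric(scale(dat[[v]]))
  dat
}

#' Per-herbivore covariate analysis with multimodel inference
#'
#' Builds, per herbivore and distance, the standardized community
#' covariates (accessible-nectar cover for the herbivore's parasitoid taxa,
#' species richness, functional dispersion), enumerates all additive
#' combinations of the nine predictors (three linear, three quadratic,
#' three pairwise linear interactions), ranks binomial mixed fits by AIC,
#' and conditionally averages the delta-AIC < 2 set.  Optionally runs the
#' neutral randomization validating the nectar covariate.
#'
#' @param parasitism Parasitism table.
#' @param covariates Output of [plot_covariates()].
#' @param insects Parasitoid trait table (needed for the neutral stage).
#' @param surveys,flora Survey and trait tables (neutral stage).
#' @param distances Distances to analyse.
#' @param neutral `FALSE`, or a list of options for the neutral stage:
#'   `iterations` (default 200 in the pipeline), `modes`, `distances`
#'   (default 5 m), `seed`.
#' @param nAGQ Quadrature setting for candidate fits.
#' @return List with one element per `distance:herbivore`: `averaged`,
#'   `ranking`, `best` (top-ranked `glmm_fit`), `r2` of the best model, and
#'   `neutral` (list of `neutral_report` per mode, when run).
#' @export
run_covariate_analysis <- function(parasitism, covariates, insects = NULL,
                                   surveys = NULL, flora = NULL,
                                   distances = sort(unique(parasitism$distance)),
                                   neutral = FALSE, nAGQ = 1) {
  hmap <- herbivore_taxa(length(unique(parasitism$herbivore)))
  sets <- build_term_sets(c("nectar", "richness", "fdis"))
  nopt <- if (isTRUE(neutral)) list() else neutral
  if (!is.list(nopt)) nopt <- NULL
  if (!is.null(nopt)) {
    nopt <- utils::modifyList(list(iterations = 200,
                                   modes = c("flowering", "all"),
                                   distances = 5, seed = 1), nopt)
  }
  out <- list()
  for (d in distances) for (h in names(hmap)) {
    dat <- herbivore_dataset(parasitism, covariates, h, d, hmap[[h]])
    fits <- fit_candidates(sets, "cbind(n_parasitized, n_examined - n_parasitized)",
                           dat, grouping = "strip", family = "binomial",
                           nAGQ = nAGQ)
    ranking <- rank_by_aic(fits)
    best <- fits[[ranking$model[1]]]
    res <- list(distance = d, herbivore = h,
                averaged = conditional_average(fits, ranking),
                ranking = ranking, best = best, r2 = pseudo_r2(best))
    if (!is.null(nopt) && d %in% nopt$distances &&
        !is.null(surveys) && !is.null(flora) && !is.null(insects)) {
      focal <- insect_from_df(insects, hmap[[h]][1])
      res$neutral <- lapply(nopt$modes, function(md)
        neutral_aic_comparison(best, dat, surveys, flora, focal,
                               covariate = "nectar", mode = md,
                               iterations = nopt$iterations,
                               seed = nopt$seed))
      names(res$neutral) <- nopt$modes
    }
    out[[paste(d, h, sep = ":")]] <- res
  }
  out
}

#' Multi-threshold multi-species parasitism analysis
#'
#' Per distance: computes the threshold-sweep counts over complete-case
#' plots, fits the Poisson candidate set with threshold interactions via
#' [fit_multithreshold()], and emits the predicted count-versus-FDis curve
#' for each threshold.
#'
#' @inheritParams run_covariate_analysis
#' @param max_terms Cap on fixed-effect variables per candidate model.
#' @return List per distance: `counts`, `averaged`, `ranking`, `curves`.
#' @export
run_multithreshold_analysis <- function(parasitism, covariates,
                                        distances = sort(unique(parasitism$distance)),
                                        max_terms = 5, nAGQ = 1) {
  out <- list()
  for (d in distances) {
    counts <- multispecies_counts(parasitism, d)
    mt <- fit_multithreshold(counts, covariates, max_terms = max_terms,
                             nAGQ = nAGQ)
    out[[as.character(d)]] <- list(distance = d, counts = counts,
                                   averaged = mt$averaged,
                                   ranking = mt$ranking,
                                   curves = partial_effect_curves(mt))
  }
  out
}

#' Run the complete analysis pipeline on a synthetic scenario
#'
#' Simulates a dataset from `config` under `seed`, then runs the
#' assemblage-factor analysis, the covariate multimodel analysis (with the
#' neutral randomization at 5 m), and the multi-threshold multi-species
#' analysis, writing deterministic CSV/JSON artifacts to `outdir`.
#'
#' @param config A [scenario_config()].
#' @param seed Master seed.
#' @param outdir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param neutral_iterations Iterations of the neutral stage (pipeline
#'   default 200; see [neutral_aic_comparison()] for the standalone
#'   default of 1000).
#' @param stages Character subset of
#'   `c("assemblage", "covariate", "neutral", "multithreshold")`.
#' @param nAGQ Quadrature setting used throughout.
#' @return Invisibly, a list with the simulated data and all stage results.
#' @export
run_all <- function(config = scenario_config(), seed = 1, outdir = NULL,
                    neutral_iterations = 200,
                    stages = c("assemblage", "covariate", "neutral",
                               "multithreshold"),
                    nAGQ = 1) {
  sim <- simulate_dataset(config, seed)
  res <- list(data = sim, seed = seed)
  if ("assemblage" %in% stages)
    res$assemblage <- run_assemblage_analysis(sim$parasitism, nAGQ = nAGQ)
  if ("covariate" %in% stages)
    res$covariate <- run_covariate_analysis(
      sim$parasitism, sim$covariates, sim$insects, sim$surveys, sim$flora,
      neutral = if ("neutral" %in% stages)
        list(iterations = neutral_iterations, seed = seed) else FALSE,
      nAGQ = nAGQ)
  if ("multithreshold" %in% stages)
    res$multithreshold <- run_multithreshold_analysis(
      sim$parasitism, sim$covariates, nAGQ = nAGQ)
  if (!is.null(outdir)) write_run(res, outdir)
  invisible(res)
}

num <- function(x, digits = 10) round(x, digits)

averaged_to_list <- function(av)
  list(coefficients = lapply(seq_len(nrow(av$coefficients)), function(i)
    as.list(av$coefficients[i, ])),
    members = av$members$model,
    member_weights = num(av$members$weight))

#' Write pipeline artifacts
#'
#' Serializes a [run_all()] result to CSV tables and JSON model reports
#' with fixed numeric formatting, so identical seeds give byte-identical
#' files.
#'
#' @param res A [run_all()] result.
#' @param outdir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_run <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(outdir, name)
    nums <- vapply(df, is.numeric, logical(1))
    df[nums] <- lapply(df[nums], num)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wjson <- function(x, name) {
    p <- file.path(outdir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = 10, pretty = TRUE)
    paths <<- c(paths, p)
  }
  wcsv(res$data$covariates, "covariates.csv")
  wcsv(res$data$parasitism, "parasitism.csv")
  if (!is.null(res$assemblage)) wcsv(res$assemblage, "assemblage_tests.csv")
  if (!is.null(res$covariate)) {
    wjson(lapply(res$covariate, function(r) {
      o <- list(distance = r$distance, herbivore = r$herbivore,
                averaged = averaged_to_list(r$averaged),
                best_model = r$ranking$model[1],
                best_aic = num(r$ranking$AIC[1]),
                r2_marginal = num(r$r2[["marginal"]]),
                r2_conditional = num(r$r2[["conditional"]]))
      if (!is.null(r$neutral))
        o$neutral <- lapply(r$neutral, function(n)
          list(mode = n$mode, k = n$k, pool_size = n$pool_size,
               observed_aic = num(n$observed_aic),
               mean_neutral_aic = num(n$mean_neutral_aic),
               sd_neutral_aic = num(n$sd_neutral_aic),
               empirical_quantile = num(n$empirical_quantile)))
      o
    }), "covariate_models.json")
  }
  if (!is.null(res$multithreshold)) {
    for (d in names(res$multithreshold)) {
      wcsv(res$multithreshold[[d]]$counts,
           paste0("multithreshold_counts_", d, "m.csv"))
      wcsv(res$multithreshold[[d]]$curves,
           paste0("multithreshold_curves_", d, "m.csv"))
    }
    wjson(lapply(res$multithreshold, function(r)
      list(distance = r$distance,
           averaged = averaged_to_list(r$averaged),
           best_model = r$ranking$model[1])),
      "multithreshold_models.json")
  }
  wjson(list(seed = res$seed,
             config = res$data$config[setdiff(names(res$data$config),
                                              "effects")],
             effects = res$data$config$effects), "run_config.json")
  invisible(paths)
}
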