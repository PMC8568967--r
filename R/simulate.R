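#' Scenario configuration for the synthetic flower-strip experiment
#'
#' Defines the generative conditions of the emulated field design: 8 sown
#' assemblages (four richness/functional-diversity categories x two species
#' -identity variants) plus an unsown control, each replicated on 3 strips
#' (27 plots in 3 blocks), parasitism of 5 herbivores measured at 5 and 20 m
#' from the strip, a pool of ~85 plant species with mixed-type traits, and 7
#' parasitoid taxa (the fifth herbivore hosts three morphospecies).
#'
#' The default effects mirror the structure the analyses target: parasitism
#' driven by the accessible-nectar cover (`beta_nectar`) with a negative
#' quadratic functional-dispersion effect (`beta_fdis2`, the hump) on the
#' logit scale, a strip random intercept `sigma_strip`, and attenuated
#' covariate effects at 20 m (`distance_mult`).
#'
#' @param pool_size Number of plant species in the regional pool.
#' @param richness Named sown richness per assemblage category:
#'   `LFMS = 14, HFLS = 9, HFMS = 14, HFHS = 29`.
#' @param n_strips Replicates per treatment (and blocks), default 3.
#' @param distances Sampling distances from the strip (m).
#' @param n_herbivores Number of herbivore species, default 5.
#' @param survey_date Day of year of the botanical survey.
#' @param effects List of generative coefficients: `beta0` (per-herbivore
#'   logit intercepts), `beta_nectar`, `beta_richness`, `beta_fdis`,
#'   `beta_fdis2` (on standardized covariates), `sigma_strip`,
#'   `distance_mult` (named multiplier of covariate effects per distance).
#' @param trials Range of hosts examined per plot x herbivore x distance.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(pool_size = 85,
                            richness = c(LFMS = 14, HFLS = 9,
                                         HFMS = 14, HFHS = 29),
                            n_strips = 3,
                            distances = c(5, 20),
                            n_herbivores = 5,
                            survey_date = 135,
                            effects = list(),
                            trials = c(20, 200)) {
  eff <- list(beta0 = c(-2.1, -1.1, -0.7, -1.5, -0.3),
              beta_nectar = 0.5, beta_richness = 0,
              beta_fdis = 0, beta_fdis2 = -0.3,
              sigma_strip = 0.3,
              distance_mult = c("5" = 1, "20" = 0.4))
  eff[names(effects)] <- effects
  stopifnot(pool_size > 0, n_strips > 0, eff$sigma_strip >= 0,
            all(richness > 0))
  structure(list(pool_size = pool_size, richness = richness,
                 n_strips = n_strips, distances = distances,
                 n_herbivores = n_herbivores, survey_date = survey_date,
                 effects = eff, trials = trials),
            class = "scenario_config")
}

sub_seed <- function(seed, offset) (abs(seed) + offset) %% .Machine$integer.max

#' Simulate the plant side of the experiment
#'
#' Draws a trait pool (log-normal floral dimensions in mm, categorical
#' nectar type and flower colour, uniform flowering onset and duration over
#' the season, log-normal heights), assembles the sown treatments --- low
#' functional diversity by nearest-neighbour clustering in Gower trait
#' space, high functional diversity by greedy maximin dispersion --- and
#' generates one botanical survey per plot: sown species establish with
#' probability 0.85, a few spontaneous species invade at low cover, covers
#' are Dirichlet-style gamma weights rescaled so total cover is below 100%,
#' and the phenological stage (11-point scale) is consistent with each
#' species' flowering window at the survey date.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed for this substream.
#' @return List with `flora` (trait table), `surveys` (plot x species cover
#'   and stage, with `treatment`, `strip`, `block`), and `assemblages`
#'   (species sets per treatment).
#' @export
simulate_flora <- function(config = scenario_config(), seed = 1) {
  set.seed(sub_seed(seed, 11L))
  n <- config$pool_size
  flora <- data.frame(
    species = sprintf("sp%03d", seq_len(n)),
    w = round(stats::rlnorm(n, log(3), 0.6), 2),
    h = round(stats::rlnorm(n, log(2), 0.7), 2),
    p = round(stats::rlnorm(n, log(1.2), 0.8), 2),
    d = ifelse(stats::runif(n) < 0.6,
               round(stats::rlnorm(n, log(0.6), 0.5), 2), NA_real_),
    nectar_type = sample(c("floral", "extrafloral", "both", "none"), n,
                         replace = TRUE, prob = c(0.65, 0.08, 0.04, 0.23)),
    flower_onset = round(stats::runif(n, 75, 170)),
    flower_duration = round(stats::runif(n, 25, 70)),
    color = sample(c("white", "yellow", "blue", "purple", "pink"), n,
                   replace = TRUE),
    height = round(stats::rlnorm(n, log(40), 0.5), 1),
    leaf_distribution = sample(c("rosette", "semi-rosette", "erect"), n,
                               replace = TRUE),
    nectar_quantity = sample(0:3, n, replace = TRUE),
    stringsAsFactors = FALSE)

  match_traits <- flora[, c("w", "h", "p", "d", "nectar_type",
                            "flower_onset", "flower_duration")]
  rownames(match_traits) <- flora$species
  dism <- gower_dissimilarity(match_traits)

  pick_clustered <- function(k) {    # low functional diversity
    seed_sp <- sample(flora$species, 1)
    names(sort(dism[seed_sp, ]))[seq_len(k)]
  }
  pick_dispersed <- function(k) {    # high functional diversity (maximin)
    chosen <- sample(flora$species, 1)
    while (length(chosen) < k) {
      rest <- setdiff(flora$species, chosen)
      mind <- apply(dism[rest, chosen, drop = FALSE], 1, min)
      chosen <- c(chosen, rest[which.max(mind)])
    }
    chosen
  }
  cats <- names(config$richness)
  assemblages <- list()
  for (cat in cats) for (v in 1:2) {
    k <- config$richness[[cat]]
    assemblages[[paste0(cat, v)]] <-
      if (startsWith(cat, "LF")) pick_clustered(k) else pick_dispersed(k)
  }
  assemblages[["control"]] <- character(0)

  stage_at <- function(onset, duration, date) {
    if (date < onset) max(1, min(4, 4 - floor((onset - date) / 14)))
    else if (date <= onset + duration)
      min(8, 5 + floor(4 * (date - onset) / max(duration, 1)))
    else min(10, 9 + (date > onset + duration + 21))
  }

  treatments <- names(assemblages)
  surveys <- list()
  for (ti in seq_along(treatments)) for (s in seq_len(config$n_strips)) {
    tr <- treatments[ti]
    plot_id <- paste0(tr, "_s", s)
    sown <- assemblages[[tr]]
    sown <- sown[stats::runif(length(sown)) < 0.85]
    n_spont <- sample(4:10, 1)
    spont <- sample(setdiff(flora$species, sown), n_spont)
    sp <- c(sown, spont)
    wgt <- stats::rgamma(length(sp), shape = 1.5) *
      c(rep(3, length(sown)), rep(0.5, length(spont)))
    total <- stats::runif(1, 60, 95)
    cover <- round(total * wgt / sum(wgt), 2)
    idx <- match(sp, flora$species)
    surveys[[plot_id]] <- data.frame(
      plot = plot_id, treatment = tr,
      strip = paste0("s", s),
      block = paste0("b", (ti + s - 2L) %% config$n_strips + 1L),
      species = sp, cover = cover,
      stage = vapply(idx, function(i)
        stage_at(flora$flower_onset[i], flora$flower_duration[i],
                 config$survey_date), numeric(1)),
      sown = sp %in% sown, stringsAsFactors = FALSE)
  }
  surveys <- do.call(rbind, surveys)
  rownames(surveys) <- NULL
  list(flora = flora, surveys = surveys, assemblages = assemblages)
}

#' Simulate the parasitoid community
#'
#' Seven taxa with log-normal head and proboscis dimensions (mm) and
#' staggered activity windows across the season.
#'
#' @inheritParams simulate_flora
#' @return Data frame `taxon, head_width, proboscis_length,
#'   proboscis_width, activity_start, activity_end`.
#' @export
simulate_parasitoids <- function(config = scenario_config(), seed = 1) {
  set.seed(sub_seed(seed, 23L))
  n <- 7
  starts <- round(90 + 12 * (seq_len(n) - 1) + stats::runif(n, -5, 5))
  data.frame(
    taxon = paste0("P", seq_len(n)),
    head_width = round(stats::rlnorm(n, log(0.55), 0.35), 3),
    proboscis_length = round(stats::rlnorm(n, log(0.3), 0.5), 3),
    proboscis_width = round(stats::rlnorm(n, log(0.05), 0.3), 3),
    activity_start = starts,
    activity_end = starts + round(stats::runif(n, 30, 50)),
    stringsAsFactors = FALSE)
}

## Herbivore -> parasitoid taxa map: one focal taxon each, the fifth
## herbivore is attacked by three morphospecies.
herbivore_taxa <- function(n_herbivores = 5)
  stats::setNames(c(as.list(paste0("P", seq_len(n_herbivores - 1))),
                    list(c("P5", "P6", "P7"))),
                  paste0("H", seq_len(n_herbivores)))

#' Simulate parasitism records from plot-level covariates
#'
#' Generative mirror of the fitted binomial mixed model: on the logit
#' scale, `beta0[h] + m_d * (beta_nectar Z_nectar + beta_richness Z_rich +
#' beta_fdis Z_fdis + beta_fdis2 Z_fdis^2) + u_strip`, with
#' `u ~ N(0, sigma_strip^2)` and `m_d` the per-distance attenuation;
#' parasitized counts are binomial draws with hosts-examined uniform over
#' `config$trials`.  The nectar covariate of a herbivore is the accessible
#' cover for its parasitoid taxa (mean over morphospecies), standardized
#' across plots.
#'
#' @param config A [scenario_config()].
#' @param covariates Output of [plot_covariates()] (with `strip`).
#' @param seed Integer seed for this substream.
#' @return `ParasitismTable` data frame: `plot, treatment, strip, block,
#'   distance, herbivore, n_examined, n_parasitized`.
#' @export
simulate_parasitism <- function(config = scenario_config(), covariates,
                                seed = 1) {
  set.seed(sub_seed(seed, 37L))
  eff <- config$effects
  hmap <- herbivore_taxa(config$n_herbivores)
  zs <- function(x) if (stats::sd(x) == 0) x * 0 else as.numeric(scale(x))
  z_rich <- zs(covariates$richness)
  z_fdis <- zs(covariates$fdis)
  if (is.null(covariates$block)) covariates$block <- covariates$strip
  strips <- sort(unique(covariates$strip))
  u <- stats::setNames(stats::rnorm(length(strips), 0, eff$sigma_strip),
                       strips)
  out <- list()
  for (h in names(hmap)) {
    nec <- rowMeans(as.data.frame(
      covariates[paste0("nectar_", hmap[[h]])]))
    z_nec <- zs(nec)
    for (d in config$distances) {
      m <- eff$distance_mult[[as.character(d)]]
      eta <- eff$beta0[[match(h, names(hmap))]] +
        m * (eff$beta_nectar * z_nec + eff$beta_richness * z_rich +
               eff$beta_fdis * z_fdis + eff$beta_fdis2 * z_fdis^2) +
        u[covariates$strip]
      n_ex <- sample(config$trials[1]:config$trials[2],
                     nrow(covariates), replace = TRUE)
      out[[paste(h, d)]] <- data.frame(
        plot = covariates$plot, treatment = covariates$treatment,
        strip = covariates$strip, block = covariates$block,
        distance = d, herbivore = h,
        n_examined = n_ex,
        n_parasitized = stats::rbinom(nrow(covariates), n_ex,
                                      stats::plogis(eta)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a complete synthetic experiment
#'
#' Orchestrates [simulate_flora()], [simulate_parasitoids()],
#' [plot_covariates()] and [simulate_parasitism()] with independent seed
#' substreams derived from one master seed (changing the flora stream does
#' not move the parasitoid draws).
#'
#' @inheritParams simulate_flora
#' @return List `flora`, `surveys`, `assemblages`, `insects`,
#'   `covariates`, `parasitism`, `config`, `seed`.
#' @export
simulate_dataset <- function(config = scenario_config(), seed = 1) {
  fl <- simulate_flora(config, seed)
  ins <- simulate_parasitoids(config, seed)
  cov <- plot_covariates(fl$surveys, fl$flora, ins)
  cov$block <- fl$surveys$block[match(cov$plot, fl$surveys$plot)]
  par <- simulate_parasitism(config, cov, seed)
  list(flora = fl$flora, surveys = fl$surveys,
       assemblages = fl$assemblages, insects = ins,
       covariates = cov, parasitism = par,
       config = config, seed = seed)
}

#' Deterministic miniature fixture
#'
#' A hand-built 4-species x 2-parasitoid x 6-plot dataset, with no random
#' numbers, for fast end-to-end checks.  Accessibility by hand: species A
#' produces extrafloral nectar (accessible to both parasitoids); B
#' (`w = 1.2, h = 1.0, p = 0.5, d = 0.2`) is accessible to P1 (head 0.5
#' enters, proboscis 0.6 >= 0.5, width 0.05 <= 0.2) but not to P2
#' (proboscis width 0.3 > 0.2); C (`w = 0.3, h = 3, p = 2`) is too narrow
#' and deep for either; D produces no nectar.  Hence the accessible cover
#' of plot p1 (A 30, B 20, C 10, D 5) is 50 for P1 and 30 for P2.
#'
#' @return List `flora`, `insects`, `surveys`, `parasitism`.
#' @export
fixture_small <- function() {
  flora <- data.frame(
    species = c("A", "B", "C", "D"),
    w = c(NA, 1.2, 0.3, NA), h = c(NA, 1.0, 3.0, NA),
    p = c(NA, 0.5, 2.0, NA), d = c(NA, 0.2, 0.1, NA),
    nectar_type = c("extrafloral", "floral", "floral", "none"),
    flower_onset = c(95, 100, 110, 120),
    flower_duration = c(60, 50, 40, 30),
    color = c("white", "yellow", "blue", "white"),
    height = c(30, 50, 20, 60),
    nectar_quantity = c(1, 3, 2, 0),
    stringsAsFactors = FALSE)
  insects <- data.frame(
    taxon = c("P1", "P2"),
    head_width = c(0.5, 1.0),
    proboscis_length = c(0.6, 0.3),
    proboscis_width = c(0.05, 0.3),
    activity_start = c(100, 100), activity_end = c(160, 160),
    stringsAsFactors = FALSE)
  plots <- paste0("p", 1:6)
  covers <- rbind(c(30, 20, 10, 5), c(10, 40, 5, 0), c(0, 25, 20, 10),
                  c(45, 5, 5, 5), c(20, 20, 20, 20), c(5, 0, 30, 25))
  surveys <- do.call(rbind, lapply(1:6, function(i) {
    keep <- covers[i, ] > 0
    data.frame(plot = plots[i],
               treatment = rep(c("t1", "t2"), each = 3)[i],
               strip = paste0("s", (i - 1) %% 3 + 1),
               block = paste0("b", (i - 1) %% 3 + 1),
               species = flora$species[keep], cover = covers[i, keep],
               stage = c(6, 6, 5, 2)[keep], stringsAsFactors = FALSE)
  }))
  rownames(surveys) <- NULL
  parasitism <- expand.grid(plot = plots, distance = c(5, 20),
                            herbivore = c("H1", "H2"),
                            stringsAsFactors = FALSE)
  parasitism$treatment <- surveys$treatment[match(parasitism$plot,
                                                  surveys$plot)]
  parasitism$strip <- surveys$strip[match(parasitism$plot, surveys$plot)]
  parasitism$block <- surveys$block[match(parasitism$plot, surveys$plot)]
  parasitism$n_examined <- rep(c(40, 50, 60, 40, 50, 60), 4)
  parasitism$n_parasitized <- c(18, 12, 10, 22, 20, 8,  15, 10, 9, 20, 18, 7,
                                 8,  6,  7, 12, 11, 5,   7,  5, 6, 10,  9, 4)
  list(flora = flora, insects = insects, surveys = surveys,
       parasitism = parasitism)
}
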