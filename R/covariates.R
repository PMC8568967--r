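#' Plot-level community covariates
#'
#' Builds, for every surveyed plot, the three community descriptors used by
#' the parasitism analyses: plant species richness, functional dispersion
#' (FDis, with Rao quadratic entropy alongside for the correlation check)
#' computed from the mixed-type functional-trait matrix, and the percent
#' cover providing available and accessible nectar, one column per
#' parasitoid taxon (`nectar_<taxon>`) plus their mean (`nectar`).
#'
#' @param surveys Survey data frame: `plot`, `species`, `cover`, optionally
#'   `stage`, `strip`, `treatment`.
#' @param flora Flower-trait data frame (see [accessibility_matrix()]); any
#'   extra columns beyond the morphology set are treated as additional
#'   functional traits.
#' @param insects Parasitoid trait data frame.
#' @param trait_cols Columns of `flora` entering the trait matrix for
#'   FDis/Rao; defaults to every column except `species`.
#' @param mode Availability mode for the nectar covariate.
#' @return Data frame with one row per plot: `plot`, carried-over `strip` /
#'   `treatment`, `richness`, `fdis`, `rao`, `nectar_<taxon>`..., `nectar`.
#' @export
plot_covariates <- function(surveys, flora, insects,
                            trait_cols = setdiff(names(flora), "species"),
                            mode = "window") {
  traits <- flora[, trait_cols, drop = FALSE]
  rownames(traits) <- as.character(flora$species)
  dism <- gower_dissimilarity(traits)
  plots <- unique(as.character(surveys$plot))
  taxa <- as.character(insects$taxon)
  keep_cols <- intersect(c("strip", "treatment"), names(surveys))

  ## species x taxon indicator of available-and-accessible nectar, computed
  ## once; per-plot covers then reduce to weighted column sums
  flsp <- as.character(flora$species)
  ok <- matrix(FALSE, length(flsp), length(taxa),
               dimnames = list(flsp, taxa))
  for (j in seq_along(taxa)) {
    ins <- insect_from_row(insects[j, ])
    for (i in seq_along(flsp)) {
      fl <- flower_from_row(flora[i, ])
      ok[i, j] <- nectar_available(fl, ins, mode = mode) &&
        nectar_accessible(ins, fl)$accessible
    }
  }
  unknown <- setdiff(unique(as.character(surveys$species)), flsp)
  if (length(unknown))
    warning("no morphology for species: ",
            paste(unknown, collapse = ", "), "; contributing 0 cover")

  rows <- lapply(plots, function(pl) {
    sub <- surveys[as.character(surveys$plot) == pl, ]
    ab <- stats::setNames(sub$cover, as.character(sub$species))
    known <- names(ab)[names(ab) %in% flsp]
    row <- data.frame(plot = pl,
                      richness = species_richness(ab),
                      fdis = fdis(ab[known], dism),
                      rao = rao_q(ab[known], dism))
    for (cc in keep_cols) row[[cc]] <- sub[[cc]][1]
    nect <- as.numeric(ab[known] %*% ok[known, , drop = FALSE])
    for (k in seq_along(taxa)) row[[paste0("nectar_", taxa[k])]] <- nect[k]
    row$nectar <- mean(nect)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
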