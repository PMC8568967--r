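#' Construct a parasitoid morphology record
#'
#' Bundles the three head/mouthpart measurements that constrain floral nectar
#' access, together with the adult flight (activity) window.  All lengths are
#' in millimetres; the activity window is a day-of-year interval.
#'
#' @param head_width Maximum dorsal head width including the eyes (mm).  The
#'   head radius used by the geometric accessibility model is
#'   `head_width / 2`.
#' @param proboscis_length Proboscis length (mm).
#' @param proboscis_width Proboscis width at mid-length (mm).
#' @param activity_start,activity_end Day-of-year interval of adult activity,
#'   `activity_start <= activity_end`.
#' @param taxon Optional taxon label.
#' @return A list of class `insect_morphology`.
#' @examples
#' insect_morphology(0.6, 0.25, 0.05, 120, 160, taxon = "T. heterocerus")
#' @export
insect_morphology <- function(head_width, proboscis_length, proboscis_width,
                              activity_start = 1, activity_end = 366,
                              taxon = NA_character_) {
  for (v in c(head_width, proboscis_length, proboscis_width))
    if (!is.na(v) && v <= 0) stop("insect lengths must be > 0")
  if (activity_start > activity_end)
    stop("activity_start must be <= activity_end")
  structure(list(taxon = taxon,
                 head_width = head_width,
                 proboscis_length = proboscis_length,
                 proboscis_width = proboscis_width,
                 activity_start = activity_start,
                 activity_end = activity_end),
            class = "insect_morphology")
}

#' Construct a flower morphology record
#'
#' The four floral dimensions that gate nectar accessibility (all mm), the
#' nectar type, and the flowering window used for temporal availability.
#'
#' @param w Width of the flower opening (mm).
#' @param h Corolla height (mm): depth of the corolla above the nectar tube.
#' @param p Nectar depth (mm): depth of the nectar below the corolla, i.e.
#'   the length of the structure holding the nectar.  `h` and `p` are
#'   disjoint segments; the total depth from the opening is `h + p`.
#' @param d Nectar tube diameter (mm); `NA` when the nectary is open (no
#'   narrow tube), in which case the proboscis-width constraint is skipped.
#' @param nectar_type One of `"floral"`, `"extrafloral"`, `"both"`, `"none"`.
#'   Extrafloral nectar is produced outside the perianth (on bracts or
#'   stipules) and is treated as accessible to every visitor.
#' @param flower_onset,flower_duration Flowering onset (day of year) and
#'   duration (days).
#' @param nectar_quantity Ordinal qualitative nectar quantity (a functional
#'   trait only; not used by the accessibility model).
#' @param species Optional species label.
#' @return A list of class `flower_morphology`.
#' @examples
#' flower_morphology(1.2, 2.0, 1.0, 0.4, "floral", 110, 40)
#' @export
flower_morphology <- function(w = NA_real_, h = NA_real_, p = NA_real_,
                              d = NA_real_, nectar_type = "floral",
                              flower_onset = NA_real_,
                              flower_duration = NA_real_,
                              nectar_quantity = NA_integer_,
                              species = NA_character_) {
  nectar_type <- match.arg(nectar_type,
                           c("floral", "extrafloral", "both", "none"))
  for (v in c(w, h, p, d))
    if (!is.na(v) && v < 0) stop("flower lengths must be >= 0")
  structure(list(species = species, w = w, h = h, p = p, d = d,
                 nectar_type = nectar_type,
                 flower_onset = flower_onset,
                 flower_duration = flower_duration,
                 nectar_quantity = nectar_quantity),
            class = "flower_morphology")
}

#' Geometric nectar-accessibility decision tree
#'
#' Decides whether one parasitoid can access the nectar of one plant species,
#' from the insect's head radius `r = head_width / 2`, proboscis length `x`
#' and proboscis width `z`, and the flower's opening width `w`, corolla
#' height `h`, nectar depth `p` and nectar tube diameter `d`.  Three
#' constraints are evaluated:
#'
#' 1. *Penetration*: the head enters the corolla iff `w >= 2 r`.
#' 2. *Reach*: if the head enters, the proboscis only needs to span the
#'    nectar tube (`x >= p`); if the head is excluded it must span corolla
#'    and tube from the opening (`x >= h + p`).
#' 3. *Tube width*: when a narrow nectar tube is present (`d` defined) the
#'    proboscis must fit it, `z <= d`; open nectaries skip this check.
#'
#' Extrafloral nectar, being produced outside the perianth, short-circuits
#' the tree and is accessible to every insect.  Missing morphology is
#' conservative: the verdict is inaccessible with reason
#' `"fail_missing_trait"`, never an error.
#'
#' @param insect An [insect_morphology()] (or any list with its fields).
#' @param flower A [flower_morphology()] (or any list with its fields).
#' @return A list of class `accessibility_verdict` with elements
#'   `accessible` (logical) and `reason`, one of `"extrafloral"`,
#'   `"open_reach"` (head excluded, proboscis spans `h + p`),
#'   `"head_entry_reach"` (head enters, proboscis spans `p`),
#'   `"fail_penetration_reach"`, `"fail_tube_width"`, `"fail_no_nectar"`,
#'   `"fail_missing_trait"`.
#' @examples
#' wasp <- insect_morphology(2.0, 1.5, 0.1)
#' nectar_accessible(wasp, flower_morphology(1.0, 0.5, 0.8, 0.3)) # accessible
#' @export
nectar_accessible <- function(insect, flower) {
  verdict <- function(ok, why) structure(list(accessible = ok, reason = why),
                                         class = "accessibility_verdict")
  nt <- flower$nectar_type
  if (is.null(nt) || is.na(nt)) nt <- "none"
  if (nt == "none") return(verdict(FALSE, "fail_no_nectar"))
  if (nt %in% c("extrafloral", "both")) return(verdict(TRUE, "extrafloral"))

  need_i <- c(insect$head_width, insect$proboscis_length,
              insect$proboscis_width)
  need_f <- c(flower$w, flower$h, flower$p)
  if (any(is.na(need_i)) || any(is.na(need_f)))
    return(verdict(FALSE, "fail_missing_trait"))
  if (any(need_i <= 0)) stop("insect lengths must be > 0")
  if (any(need_f < 0) || (!is.na(flower$d) && flower$d < 0))
    stop("flower lengths must be >= 0")

  r <- insect$head_width / 2
  x <- insect$proboscis_length
  z <- insect$proboscis_width
  head_enters <- flower$w >= 2 * r
  reach <- if (head_enters) x >= flower$p else x >= flower$h + flower$p
  tube_ok <- is.na(flower$d) || z <= flower$d

  if (!tube_ok) return(verdict(FALSE, "fail_tube_width"))
  if (!reach) return(verdict(FALSE, "fail_penetration_reach"))
  verdict(TRUE, if (head_enters) "head_entry_reach" else "open_reach")
}

#' Temporal nectar availability
#'
#' Nectar is available when it is produced during the parasitoid's activity
#' period.  In `"window"` mode the flowering window (onset, onset + duration)
#' must overlap the insect's activity window by at least one day; extrafloral
#' producers are taken to secrete throughout the season, so they are always
#' available.  In `"survey"` mode availability is read off a botanical
#' survey: the species must be at a flowering phenological stage (on the
#' 11-point 0--10 scale; stages `flowering_stages` count as flowering) and
#' the survey date must fall in the activity window.
#'
#' @param flower A [flower_morphology()].
#' @param insect An [insect_morphology()].
#' @param mode `"window"` or `"survey"`.
#' @param survey_stage Phenological stage 0--10 (survey mode).
#' @param survey_date Day of year of the survey (survey mode).
#' @param flowering_stages Integer stages counted as flowering; default 5:8.
#' @return Logical scalar.
#' @export
nectar_available <- function(flower, insect, mode = c("window", "survey"),
                             survey_stage = NULL, survey_date = NULL,
                             flowering_stages = 5:8) {
  mode <- match.arg(mode)
  nt <- flower$nectar_type
  if (is.null(nt) || is.na(nt) || nt == "none") return(FALSE)
  if (mode == "window") {
    if (nt %in% c("extrafloral", "both")) return(TRUE)
    if (is.na(flower$flower_onset) || is.na(flower$flower_duration))
      return(FALSE)
    a <- max(flower$flower_onset, insect$activity_start)
    b <- min(flower$flower_onset + flower$flower_duration,
             insect$activity_end)
    return(b - a >= 0)  # closed-interval overlap of >= 1 day
  }
  if (is.null(survey_stage) || is.null(survey_date))
    stop("survey mode requires survey_stage and survey_date")
  if (is.na(survey_stage) || survey_stage < 0 || survey_stage > 10)
    stop("survey_stage must lie on the 11-point scale 0-10")
  in_activity <- survey_date >= insect$activity_start &&
    survey_date <= insect$activity_end
  if (nt %in% c("extrafloral", "both")) return(in_activity)
  (survey_stage %in% flowering_stages) && in_activity
}

flower_from_row <- function(row) {
  flower_morphology(w = row$w, h = row$h, p = row$p, d = row$d,
                    nectar_type = as.character(row$nectar_type),
                    flower_onset = row$flower_onset,
                    flower_duration = row$flower_duration,
                    species = as.character(row$species))
}

insect_from_row <- function(row) {
  insect_morphology(head_width = row$head_width,
                    proboscis_length = row$proboscis_length,
                    proboscis_width = row$proboscis_width,
                    activity_start = row$activity_start,
                    activity_end = row$activity_end,
                    taxon = as.character(row$taxon))
}

#' Plant-by-parasitoid accessibility matrix
#'
#' Applies [nectar_accessible()] to every (plant species, parasitoid) pair.
#'
#' @param flora Data frame of flower traits, one row per species, with
#'   columns `species, w, h, p, d, nectar_type, flower_onset,
#'   flower_duration`.
#' @param insects Data frame of parasitoid traits with columns `taxon,
#'   head_width, proboscis_length, proboscis_width, activity_start,
#'   activity_end`.
#' @return 0/1 integer matrix, plants in rows, parasitoids in columns.
#' @export
accessibility_matrix <- function(flora, insects) {
  m <- matrix(0L, nrow(flora), nrow(insects),
              dimnames = list(as.character(flora$species),
                              as.character(insects$taxon)))
  for (j in seq_len(nrow(insects))) {
    ins <- insect_from_row(insects[j, ])
    for (i in seq_len(nrow(flora)))
      m[i, j] <- as.integer(nectar_accessible(ins,
                                              flower_from_row(flora[i, ]))$accessible)
  }
  m
}

#' Percent plant cover providing available and accessible nectar
#'
#' Sums, over the species surveyed in one plot, the percent ground cover of
#' plants whose nectar is both temporally available and morphologically
#' accessible to the focal parasitoid.  Species with no morphology record in
#' `flora` contribute zero cover and raise a warning (conservative
#' degradation, never silent accessibility).
#'
#' @param survey Data frame for one plot with columns `species`, `cover`
#'   (percent), and optionally `stage` (phenological stage, survey mode).
#' @param flora Flower-trait data frame as in [accessibility_matrix()].
#' @param insect An [insect_morphology()] or one-row insect data frame.
#' @param mode Availability mode passed to [nectar_available()].
#' @param survey_date Day of year of the survey (survey mode).
#' @param flowering_stages Stages counted as flowering (survey mode).
#' @return Scalar percent cover, between 0 and the plot's total cover.
#' @examples
#' fx <- fixture_small()
#' accessible_cover(fx$surveys[fx$surveys$plot == "p1", ], fx$flora,
#'                  insect_from_df(fx$insects, "P1"))
#' @export
accessible_cover <- function(survey, flora, insect, mode = "window",
                             survey_date = NULL, flowering_stages = 5:8) {
  if (inherits(insect, "data.frame")) insect <- insect_from_row(insect[1, ])
  total <- 0
  missing_sp <- character(0)
  for (i in seq_len(nrow(survey))) {
    sp <- as.character(survey$species[i])
    k <- match(sp, as.character(flora$species))
    if (is.na(k)) {
      missing_sp <- c(missing_sp, sp)
      next
    }
    fl <- flower_from_row(flora[k, ])
    avail <- nectar_available(fl, insect, mode = mode,
                              survey_stage = if (mode == "survey") survey$stage[i],
                              survey_date = survey_date,
                              flowering_stages = flowering_stages)
    if (!avail) next
    if (nectar_accessible(insect, fl)$accessible)
      total <- total + survey$cover[i]
  }
  if (length(missing_sp))
    warning("no morphology for species: ",
            paste(unique(missing_sp), collapse = ", "),
            "; contributing 0 cover")
  total
}

#' Completeness report for a flower trait matrix
#'
#' @param flora Flower-trait data frame.
#' @param traits Columns counted towards completeness.
#' @return List with `per_trait` (fraction of species with that trait),
#'   `per_species` (fraction of traits present per species),
#'   `species_complete` (fraction of species with every trait), and `n`.
#' @export
trait_coverage_report <- function(flora,
                                  traits = c("w", "h", "p", "d", "nectar_type",
                                             "flower_onset", "flower_duration")) {
  traits <- intersect(traits, names(flora))
  n <- nrow(flora)
  if (n == 0L || length(traits) == 0L)
    return(list(per_trait = stats::setNames(numeric(length(traits)), traits),
                per_species = numeric(0), species_complete = NA_real_, n = 0L))
  present <- !sapply(flora[traits], is.na)
  present <- matrix(present, nrow = n, dimnames = list(flora$species, traits))
  list(per_trait = colMeans(present),
       per_species = stats::setNames(rowMeans(present), flora$species),
       species_complete = mean(rowSums(present) == length(traits)),
       n = n)
}

#' Extract one parasitoid from an insect trait table
#'
#' @param insects Insect trait data frame.
#' @param taxon Taxon label to extract.
#' @return An [insect_morphology()].
#' @export
insect_from_df <- function(insects, taxon) {
  k <- match(taxon, as.character(insects$taxon))
  if (is.na(k)) stop("unknown taxon: ", taxon)
  insect_from_row(insects[k, ])
}
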