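#' Read and write the tabular interchange formats
#'
#' Thin CSV readers for the four input tables, with column checks, and a
#' writer for the plant-by-parasitoid accessibility matrix.  Column names
#' follow the package's canonical schemas (see [fixture_small()] for
#' worked examples of each table).
#'
#' @param path CSV file path.
#' @return A data frame with the checked schema.
#' @name io
NULL

check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname io
#' @export
read_flora <- function(path)
  check_cols(utils::read.csv(path, stringsAsFactors = FALSE),
             c("species", "w", "h", "p", "d", "nectar_type",
               "flower_onset", "flower_duration"), "flora table")

#' @rdname io
#' @export
read_parasitoids <- function(path)
  check_cols(utils::read.csv(path, stringsAsFactors = FALSE),
             c("taxon", "head_width", "proboscis_length", "proboscis_width",
               "activity_start", "activity_end"), "parasitoid table")

#' @rdname io
#' @export
read_surveys <- function(path)
  check_cols(utils::read.csv(path, stringsAsFactors = FALSE),
             c("plot", "species", "cover"), "survey table")

#' @rdname io
#' @export
read_parasitism <- function(path)
  check_cols(utils::read.csv(path, stringsAsFactors = FALSE),
             c("plot", "distance", "herbivore", "n_examined",
               "n_parasitized"), "parasitism table")

#' @rdname io
#' @param m Accessibility matrix from [accessibility_matrix()].
#' @export
write_accessibility <- function(m, path) {
  df <- data.frame(species = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
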