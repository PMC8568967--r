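#' Gower dissimilarity for a mixed-type trait matrix
#'
#' Computes the pairwise Gower dissimilarity between species described by a
#' mixture of quantitative, categorical and binary traits, with pairwise
#' deletion of missing values.  Quantitative traits (numeric columns) are
#' range-scaled on the observed range of the supplied matrix, so their
#' per-trait contribution is `|x_i - x_j| / range`; categorical
#' (character/factor) and binary (logical) traits contribute 0/1 mismatch.
#' For each species pair the contributions are averaged over the traits
#' observed in both species (equal trait weights); a constant quantitative
#' trait contributes 0 with full weight.
#'
#' @param traits Data frame, one row per species (row names are species
#'   labels), one column per trait.  Column class determines trait kind.
#' @return Symmetric matrix in `[0, 1]` with zero diagonal.
#' @examples
#' tr <- data.frame(size = c(0, 1, 2), col = c("y", "y", "b"),
#'                  row.names = c("A", "B", "C"))
#' gower_dissimilarity(tr)
#' @export
gower_dissimilarity <- function(traits) {
  n <- nrow(traits)
  if (is.null(n) || n < 2) stop("need at least 2 species")
  sp <- rownames(traits)
  if (is.null(sp)) sp <- as.character(seq_len(n))
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (j in seq_along(traits)) {
    x <- traits[[j]]
    ok <- !is.na(x)
    wjk <- outer(ok, ok, "&")
    if (is.numeric(x)) {
      rng <- diff(range(x[ok]))
      contrib <- if (rng > 0) abs(outer(x, x, "-")) / rng
                 else matrix(0, n, n)
    } else {
      contrib <- outer(as.character(x), as.character(x), "!=") * 1
    }
    contrib[!wjk] <- 0
    num <- num + contrib
    den <- den + wjk
  }
  bad <- which(den == 0 & upper.tri(den), arr.ind = TRUE)
  if (nrow(bad))
    stop("species pair with no shared traits: ",
         sp[bad[1, 1]], " / ", sp[bad[1, 2]])
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(sp, sp)
  d
}

## Principal-coordinates embedding of a dissimilarity matrix, with Cailliez
## correction when negative eigenvalues exceed 1e-8 of the largest one.
pcoa_embed <- function(d, tol = 1e-8) {
  n <- nrow(d)
  a <- -0.5 * d^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen(g, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values))) {
    p <- ape::pcoa(stats::as.dist(d), correction = "cailliez")
    return(p$vectors.cor)
  }
  keep <- e$values > tol * max(abs(e$values), 1)
  if (!any(keep)) return(matrix(0, n, 1))
  e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                           nrow = sum(keep))
}

align_weights <- function(abund, dism) {
  if (!is.null(names(abund)) && !is.null(rownames(dism))) {
    if (!all(names(abund) %in% rownames(dism)))
      stop("abundance names not all present in the dissimilarity matrix")
    dism <- dism[names(abund), names(abund), drop = FALSE]
  }
  if (length(abund) != nrow(dism))
    stop("abundance vector and dissimilarity matrix do not align")
  if (any(abund < 0)) stop("abundances must be non-negative")
  keep <- abund > 0
  if (!any(keep)) stop("at least one positive abundance is required")
  list(w = abund[keep] / sum(abund[keep]),
       d = dism[keep, keep, drop = FALSE])
}

#' Functional dispersion (FDis)
#'
#' Abundance-weighted mean distance of species to the abundance-weighted
#' centroid of the community in trait space.  Species are embedded by
#' principal-coordinates analysis of the dissimilarity matrix (Cailliez
#' correction when material negative eigenvalues arise), the centroid is the
#' weighted mean of the embedded points, and FDis is the weighted mean
#' Euclidean distance to it.  A single-species community has FDis 0.
#'
#' @param abund Named vector of percent cover (non-negative; zero-cover
#'   species are dropped).  Weights are the renormalized abundances.
#' @param dism Symmetric dissimilarity matrix, e.g. from
#'   [gower_dissimilarity()].
#' @return Non-negative scalar.
#' @examples
#' d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' fdis(c(A = 50, B = 50), d)  # 0.5
#' fdis(c(A = 80, B = 20), d)  # 0.32
#' @export
fdis <- function(abund, dism) {
  al <- align_weights(abund, dism)
  if (length(al$w) == 1L) return(0)
  x <- pcoa_embed(al$d)
  centroid <- colSums(x * al$w)
  dist_c <- sqrt(rowSums(sweep(x, 2, centroid)^2))
  sum(al$w * dist_c)
}

#' Rao quadratic entropy
#'
#' Expected dissimilarity between two individuals drawn at random with
#' abundance weights: `Q = sum_ij w_i w_j d_ij` (using `d`, not `d^2`).
#'
#' @inheritParams fdis
#' @return Non-negative scalar.
#' @export
rao_q <- function(abund, dism) {
  al <- align_weights(abund, dism)
  as.numeric(t(al$w) %*% al$d %*% al$w)
}

#' Species richness of a cover vector
#'
#' @param abund Vector of percent cover.
#' @return Number of species with cover strictly above zero.
#' @export
species_richness <- function(abund) sum(abund > 0, na.rm = TRUE)
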