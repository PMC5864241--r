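#' Patristic (cophenetic) distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths on the path between tips i
#' and j; the substrate of every MNTD-family metric.
#'
#' @param tree `ape::phylo` tree with >= 2 tips and branch lengths.
#' @return labelled symmetric matrix of patristic distances.
#' @export
cophenetic_dist <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object", call. = FALSE)
  if (length(tree$tip.label) < 2L) stop("tree needs >= 2 tips", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  bad <- which(is.na(tree$edge.length))
  if (length(bad)) {
    stop("missing branch length on edge ", bad[1L], call. = FALSE)
  }
  if (any(tree$edge.length < 0)) stop("negative branch length", call. = FALSE)
  ape::cophenetic.phylo(tree)
}

#' Mean nearest taxon distance of one community
#'
#' For each taxon present in the sample, the distance to its closest
#' relative also present; averaged plainly (unweighted) or weighted by
#' relative abundance.
#'
#' @param x named abundance vector (or one community-table column) aligned
#'   to `dist`.
#' @param dist taxon distance matrix.
#' @param abundance_weighted weight nearest-neighbour distances by relative
#'   abundance.
#' @return MNTD, or `NA` (with a warning) when fewer than two taxa are
#'   present.
#' @export
mntd <- function(x, dist, abundance_weighted = FALSE) {
  if (is.null(names(x))) stop("abundance vector must be named", call. = FALSE)
  d <- align_dist(dist, names(x))
  out <- cpp_mntd(matrix(as.numeric(x), ncol = 1L), d, abundance_weighted)[1L]
  if (is.na(out)) warning("fewer than 2 taxa present; MNTD undefined", call. = FALSE)
  out
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For each taxon in one community, the distance to its nearest taxon in the
#' other community (a shared taxon matches itself at distance zero). With
#' abundance weighting the two directional relative-abundance-weighted means
#' are averaged; unweighted, the nearest-taxon distances from both
#' directions are pooled into one plain mean (the comdistnt convention).
#'
#' @param x,y named abundance vectors over the same taxon set.
#' @param dist taxon distance matrix.
#' @param abundance_weighted abundance weighting (default `TRUE`, the
#'   convention for betaNTI).
#' @return betaMNTD value.
#' @export
beta_mntd <- function(x, y, dist, abundance_weighted = TRUE) {
  if (is.null(names(x)) || !identical(names(x), names(y))) {
    stop("x and y must be named over the same taxa", call. = FALSE)
  }
  if (sum(x > 0) == 0L || sum(y > 0) == 0L) {
    stop("empty sample", call. = FALSE)
  }
  d <- align_dist(dist, names(x))
  m <- cpp_bmntd(cbind(as.numeric(x), as.numeric(y)), d, abundance_weighted)
  m[1L, 2L]
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `sum |x_i - y_i| / sum (x_i + y_i)` on counts; in \[0, 1\].
#'
#' @param x,y abundance vectors of equal length.
#' @return Bray-Curtis dissimilarity.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both samples are all-zero", call. = FALSE)
  if (sum(x) == 0 || sum(y) == 0) stop("empty sample", call. = FALSE)
  sum(abs(x - y)) / tot
}
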