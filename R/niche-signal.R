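#' Abundance-weighted environmental optima of OTUs
#'
#' For each OTU, the mean of the environmental values (e.g. soil pH) of the
#' samples in which it occurs, weighted by its abundance there — a rough
#' estimate of its niche optimum.
#'
#' @param table community table (taxa x samples).
#' @param env numeric per-sample environmental values, aligned with the
#'   table columns (or named by sample id).
#' @return data frame `otu`, `optimum`, `n_occ` (occupancy); OTUs absent
#'   everywhere are excluded with a warning.
#' @export
weighted_mean_optima <- function(table, env) {
  table <- as_community_table(table)
  if (!is.null(names(env))) env <- env[colnames(table)]
  if (length(env) != ncol(table) || anyNA(env)) {
    stop("env must provide a value for every sample", call. = FALSE)
  }
  tot <- rowSums(table)
  absent <- tot == 0
  if (any(absent)) {
    warning("excluding ", sum(absent), " OTU(s) absent from every sample",
            call. = FALSE)
  }
  x <- table[!absent, , drop = FALSE]
  opt <- as.numeric(x %*% env) / rowSums(x)
  data.frame(otu = rownames(x), optimum = opt, n_occ = rowSums(x > 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Euclidean distances between niche optima
#'
#' @param optima data frame from [weighted_mean_optima()] or [hof_optima()];
#'   rows with `included == FALSE` are dropped first when that column exists.
#' @return labelled symmetric matrix of absolute optimum differences.
#' @export
optima_distance <- function(optima) {
  if ("included" %in% names(optima)) optima <- optima[optima$included, ]
  if (nrow(optima) < 2L) stop("need >= 2 included OTUs", call. = FALSE)
  d <- as.matrix(dist(optima$optimum))
  dimnames(d) <- list(optima$otu, optima$otu)
  d
}

#' Mantel test between two distance matrices
#'
#' The statistic is the correlation of the unfolded lower triangles;
#' significance by permuting the rows and columns of the first matrix
#' simultaneously. Two-tailed by default (the direction of a
#' turnover-environment association is not fixed a priori).
#'
#' @param A,B labelled symmetric matrices over the same samples.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @param method `"pearson"` or `"spearman"`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list of class `"mantel_result"` with `r`, `p`, `n_perm`,
#'   `method`, `alternative`.
#' @export
mantel_test <- function(A, B, n_perm = 999, seed = NULL,
                        method = c("pearson", "spearman"),
                        alternative = c("two.sided", "greater", "less")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  check_pairwise(A); check_pairwise(B)
  if (!identical(rownames(A), rownames(B))) {
    B <- B[rownames(A), rownames(A)]
  }
  a <- lower_tri(A)
  b <- lower_tri(B)
  ok <- !is.na(a) & !is.na(b)
  if (sd(a[ok]) < 1e-14 || sd(b[ok]) < 1e-14) {
    stop("degenerate matrix (zero-variance lower triangle)", call. = FALSE)
  }
  r_obs <- cor(a[ok], b[ok], method = method)
  n <- nrow(A)
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      ap <- lower_tri(A[p, p])
      # permutation can relocate missing cells
      cor(ap[ok], b[ok], method = method, use = "pairwise.complete.obs")
    }, numeric(1))
  })
  hits <- switch(alternative,
                 two.sided = sum(abs(r_perm) >= abs(r_obs) - 1e-14),
                 greater = sum(r_perm >= r_obs - 1e-14),
                 less = sum(r_perm <= r_obs + 1e-14))
  structure(list(r = r_obs, p = (1 + hits) / (n_perm + 1), n_perm = n_perm,
                 method = method, alternative = alternative),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  lab <- if (is.null(x$controlling)) "Mantel" else
    paste0("Partial Mantel (controlling ", x$controlling, ")")
  cat(sprintf("%s r = %.4f, p = %.4g (%d permutations, %s)\n",
              lab, x$r, x$p, x$n_perm, x$alternative))
  invisible(x)
}

#' Partial Mantel test
#'
#' Correlation between A and B controlling for C:
#' `r_AB.C = (r_AB - r_AC r_BC) / sqrt((1 - r_AC^2)(1 - r_BC^2))`,
#' with significance from simultaneous row/column permutations of A.
#'
#' @param A,B,C labelled symmetric matrices over the same samples; C is the
#'   controlled matrix.
#' @inheritParams mantel_test
#' @return list of class `"mantel_result"` with `r` (partial), `p`, the
#'   simple correlations, and `controlling = "C"`.
#' @export
partial_mantel <- function(A, B, C, n_perm = 999, seed = NULL,
                           method = c("pearson", "spearman"),
                           alternative = c("two.sided", "greater", "less")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  check_pairwise(A); check_pairwise(B); check_pairwise(C)
  B <- B[rownames(A), rownames(A)]
  C <- C[rownames(A), rownames(A)]
  a <- lower_tri(A); b <- lower_tri(B); cc <- lower_tri(C)
  ok <- !is.na(a) & !is.na(b) & !is.na(cc)
  pcor <- function(av) {
    r_ab <- cor(av, b[ok], method = method, use = "pairwise.complete.obs")
    r_ac <- cor(av, cc[ok], method = method, use = "pairwise.complete.obs")
    r_bc <- cor(b[ok], cc[ok], method = method)
    if (abs(r_ac) >= 1 - 1e-12) {
      stop("collinear control matrix", call. = FALSE)
    }
    # B carrying no information beyond C: residuals vanish, partial r -> 0
    if (abs(r_bc) >= 1 - 1e-12) return(0)
    (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
  }
  r_obs <- pcor(a[ok])
  n <- nrow(A)
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      ap <- lower_tri(A[p, p])
      pcor(ap[ok])
    }, numeric(1))
  })
  hits <- switch(alternative,
                 two.sided = sum(abs(r_perm) >= abs(r_obs) - 1e-14),
                 greater = sum(r_perm >= r_obs - 1e-14),
                 less = sum(r_perm <= r_obs + 1e-14))
  structure(list(r = r_obs, p = (1 + hits) / (n_perm + 1), n_perm = n_perm,
                 r_ab = cor(a[ok], b[ok], method = method),
                 r_ac = cor(a[ok], cc[ok], method = method),
                 r_bc = cor(b[ok], cc[ok], method = method),
                 method = method, alternative = alternative,
                 controlling = "C"),
            class = "mantel_result")
}

#' Mantel correlogram of phylogenetic signal in niche optima
#'
#' Phylogenetic distances are cut into equal-width classes; per class, a
#' Mantel statistic between the niche-difference matrix and the class
#' membership indicator, with the sign flipped so positive r means "pairs
#' at this phylogenetic distance have MORE similar optima than average".
#' Significance by permuting taxon labels of the niche matrix; Bonferroni
#' correction (plain by default, progressive optionally).
#'
#' @param niche_d taxon matrix of niche-optimum differences.
#' @param phylo_d patristic distance matrix over the same taxa.
#' @param n_classes number of distance classes; default Sturges' rule on
#'   the pair count.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @param correction `"bonferroni"` (plain, default) or `"progressive"`
#'   (class k corrected by factor k in order of increasing distance).
#' @return data frame of class `"mantel_correlogram"`: per class `midpoint`,
#'   `n_pairs`, `r`, `p`, `p_corrected`.
#' @export
mantel_correlogram <- function(niche_d, phylo_d, n_classes = NULL,
                               n_perm = 999, seed = NULL,
                               correction = c("bonferroni", "progressive")) {
  correction <- match.arg(correction)
  check_pairwise(niche_d); check_pairwise(phylo_d)
  common <- intersect(rownames(niche_d), rownames(phylo_d))
  if (length(common) < 3L) stop("need >= 3 shared taxa", call. = FALSE)
  niche_d <- niche_d[common, common]
  phylo_d <- phylo_d[common, common]
  pv <- lower_tri(phylo_d)
  m <- length(pv)
  if (is.null(n_classes)) n_classes <- max(2L, ceiling(1 + log2(m)))
  edges <- seq(min(pv), max(pv), length.out = n_classes + 1L)
  cls <- findInterval(pv, edges, rightmost.closed = TRUE)
  keep <- which(tabulate(cls, n_classes) >= 2L)
  if (length(keep) < length(unique(cls))) {
    warning("dropping ", length(unique(cls)) - length(keep),
            " distance class(es) with < 2 pairs", call. = FALSE)
  }
  if (length(keep) < 1L) stop("no usable distance class", call. = FALSE)
  nv <- lower_tri(niche_d)
  # sign flipped: small niche difference within a class -> positive r
  class_r <- function(v) {
    vapply(keep, function(k) -cor(v, as.numeric(cls == k)), numeric(1))
  }
  r_obs <- class_r(nv)
  n <- length(common)
  exceed <- rep(0L, length(keep))
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      p <- sample.int(n)
      rp <- class_r(lower_tri(niche_d[p, p]))
      exceed <- exceed + (abs(rp) >= abs(r_obs) - 1e-14)
    }
  })
  p_raw <- (1 + exceed) / (n_perm + 1)
  p_corr <- if (correction == "bonferroni") {
    pmin(1, p_raw * length(keep))
  } else {
    pmin(1, p_raw * seq_along(keep))
  }
  out <- data.frame(class = seq_along(keep),
                    midpoint = (edges[keep] + edges[keep + 1L]) / 2,
                    n_pairs = tabulate(cls, n_classes)[keep],
                    r = r_obs, p = p_raw, p_corrected = p_corr,
                    row.names = NULL)
  attr(out, "edges") <- edges
  attr(out, "correction") <- correction
  class(out) <- c("mantel_correlogram", "data.frame")
  out
}
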