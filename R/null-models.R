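#' Standardized effect size of MNTD (SES.MNTD)
#'
#' Null model: in each of `n_iter` iterations the taxon labels of the
#' distance matrix are permuted once (the "taxa.labels" scheme) and MNTD is
#' recomputed for every sample. SES is the z-score of the observed MNTD
#' against the null draws; negative values indicate phylogenetic clustering,
#' positive values overdispersion.
#'
#' @param table community table (taxa x samples).
#' @param dist taxon distance matrix covering the table's taxa.
#' @param n_iter number of null iterations (default 999).
#' @param seed RNG seed.
#' @param abundance_weighted weight MNTD by relative abundance
#'   (default `FALSE`).
#' @return data frame with per-sample `n_taxa`, `mntd_obs`, `null_mean`,
#'   `null_sd`, `ses_mntd`. SES is `NA` where the null sd is zero or fewer
#'   than two taxa are present.
#' @export
ses_mntd <- function(table, dist, n_iter = 999, seed = NULL,
                     abundance_weighted = FALSE) {
  table <- as_community_table(table)
  d <- align_dist(dist, rownames(table))
  X <- matrix(as.numeric(table), nrow = nrow(table))
  nt <- nrow(table)
  obs <- cpp_mntd(X, d, abundance_weighted)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      p <- sample.int(nt)
      cpp_mntd(X, d[p, p], abundance_weighted)
    }, numeric(ncol(table)))
  })
  if (ncol(table) == 1L) nulls <- matrix(nulls, nrow = 1L)
  null_mean <- rowMeans(nulls)
  null_sd <- apply(nulls, 1L, sd)
  ses <- (obs - null_mean) / null_sd
  degen <- !is.na(null_sd) & null_sd < 1e-12
  if (any(degen)) {
    ses[degen] <- NA_real_
    warning("null sd is zero for ", sum(degen),
            " sample(s); SES.MNTD undefined there", call. = FALSE)
  }
  if (anyNA(obs)) {
    warning(sum(is.na(obs)), " sample(s) with < 2 taxa; SES.MNTD undefined",
            call. = FALSE)
  }
  data.frame(sample_id = colnames(table),
             n_taxa = colSums(table > 0),
             mntd_obs = obs, null_mean = null_mean, null_sd = null_sd,
             ses_mntd = ses, row.names = NULL, stringsAsFactors = FALSE)
}

#' Beta nearest taxon index (betaNTI)
#'
#' Observed abundance-weighted betaMNTD for every sample pair, standardized
#' against a null in which the taxon labels of the distance matrix are
#' permuted once per iteration (shared by all pairs). betaNTI < -2 indicates
#' significantly less phylogenetic turnover than expected (homogeneous
#' selection); betaNTI > +2 significantly more (variable selection).
#'
#' @inheritParams ses_mntd
#' @param abundance_weighted weight betaMNTD by relative abundance
#'   (default `TRUE`).
#' @return object of class `"beta_nti"`: list with symmetric matrices
#'   `bmntd` (observed), `bnti`, `null_mean`, `null_sd` and the iteration
#'   count.
#' @export
beta_nti <- function(table, dist, n_iter = 999, seed = NULL,
                     abundance_weighted = TRUE) {
  table <- as_community_table(table)
  if (ncol(table) < 2L) stop("need >= 2 samples", call. = FALSE)
  d <- align_dist(dist, rownames(table))
  X <- matrix(as.numeric(table), nrow = nrow(table))
  nt <- nrow(table)
  ns <- ncol(table)
  obs <- cpp_bmntd(X, d, abundance_weighted)
  acc <- matrix(0, ns, ns)
  acc2 <- matrix(0, ns, ns)
  with_seed(seed, {
    for (i in seq_len(n_iter)) {
      p <- sample.int(nt)
      b <- cpp_bmntd(X, d[p, p], abundance_weighted)
      b[is.na(b)] <- 0
      acc <- acc + b
      acc2 <- acc2 + b * b
    }
  })
  null_mean <- acc / n_iter
  null_var <- (acc2 - n_iter * null_mean^2) / (n_iter - 1)
  null_var[null_var < 0] <- 0
  null_sd <- sqrt(null_var)
  bnti <- (obs - null_mean) / null_sd
  off <- upper.tri(obs) | lower.tri(obs)
  degen <- off & !is.na(null_sd) & null_sd < 1e-12
  if (any(degen)) {
    bnti[degen] <- NA_real_
    warning("null sd is zero for ", sum(degen) / 2,
            " pair(s); betaNTI undefined there", call. = FALSE)
  }
  diag(bnti) <- NA_real_
  diag(null_mean) <- NA_real_
  diag(null_sd) <- NA_real_
  labs <- colnames(table)
  dimnames(obs) <- dimnames(bnti) <- dimnames(null_mean) <-
    dimnames(null_sd) <- list(labs, labs)
  structure(list(bmntd = obs, bnti = bnti, null_mean = null_mean,
                 null_sd = null_sd, n_iter = n_iter,
                 abundance_weighted = abundance_weighted),
            class = "beta_nti")
}

#' @export
print.beta_nti <- function(x, ...) {
  v <- lower_tri(x$bnti)
  cat(sprintf("betaNTI over %d samples (%d pairs, %d null iterations)\n",
              ncol(x$bnti), length(v), x$n_iter))
  cat(sprintf("  < -2: %d pairs; |bNTI| <= 2: %d pairs; > +2: %d pairs; NA: %d\n",
              sum(v < -2, na.rm = TRUE),
              sum(abs(v) <= 2, na.rm = TRUE),
              sum(v > 2, na.rm = TRUE), sum(is.na(v))))
  invisible(x)
}

# One Raup-Crick null realization of a single sample: fix observed richness
# S and depth N; draw S taxa from the pool weighted by occupancy; give each
# drawn taxon one read, then distribute the remaining N - S reads
# multinomially with probability proportional to dataset-wide relative
# abundance.
rc_null_sample <- function(S, N, occupancy, rel_abund) {
  pool <- length(occupancy)
  idx <- sample.int(pool, S, replace = FALSE, prob = occupancy)
  counts <- integer(pool)
  counts[idx] <- 1L
  if (N > S) {
    pr <- rel_abund[idx]
    counts[idx] <- counts[idx] + as.integer(rmultinom(1L, N - S, pr))
  }
  counts
}

#' Bray-Curtis based Raup-Crick metric (RC-bray)
#'
#' For every sample pair, the observed Bray-Curtis dissimilarity is compared
#' with a null distribution obtained by probabilistically re-assembling both
#' communities from the dataset-wide taxon pool, preserving each sample's
#' richness and read depth (taxa drawn weighted by occupancy, reads by
#' dataset-wide relative abundance). The rank of the observed value, with
#' half-weight for ties, is rescaled to \[-1, +1\]. RC > +0.95 (with
#' |betaNTI| < 2) indicates dispersal limitation, RC < -0.95 homogenizing
#' dispersal.
#'
#' @param table community table, typically rarefied to equal depth.
#' @param n_iter number of null iterations (default 999).
#' @param seed RNG seed.
#' @return labelled symmetric matrix of RC-bray values, diagonal `NA`.
#' @export
rc_bray <- function(table, n_iter = 999, seed = NULL) {
  table <- as_community_table(table)
  if (ncol(table) < 2L) stop("need >= 2 samples", call. = FALSE)
  present <- rowSums(table) > 0
  x <- table[present, , drop = FALSE]
  occupancy <- rowSums(x > 0)
  rel_abund <- rowSums(x) / sum(x)
  S <- colSums(x > 0)
  N <- colSums(x)
  if (any(S == 0L)) stop("empty sample", call. = FALSE)
  if (any(S > nrow(x))) stop("pool smaller than a sample's richness", call. = FALSE)
  ns <- ncol(x)
  obs <- as.matrix(vegan::vegdist(t(x), method = "bray"))
  less <- matrix(0, ns, ns)
  equal <- matrix(0, ns, ns)
  eps <- 1e-12
  with_seed(seed, {
    for (i in seq_len(n_iter)) {
      nul <- vapply(seq_len(ns), function(s)
        rc_null_sample(S[s], N[s], occupancy, rel_abund), integer(nrow(x)))
      bc <- as.matrix(vegan::vegdist(t(nul), method = "bray"))
      less <- less + (bc < obs - eps)
      equal <- equal + (abs(bc - obs) <= eps)
    }
  })
  rc_raw <- (less + 0.5 * equal) / n_iter
  rc <- 2 * (rc_raw - 0.5)
  diag(rc) <- NA_real_
  dimnames(rc) <- list(colnames(x), colnames(x))
  rc
}
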