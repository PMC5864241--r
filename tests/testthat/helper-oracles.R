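# Independent brute-force oracles, deliberately naive implementations used
# only to verify the package's optimized paths.

# Patristic distance by explicit root-to-tip path walking.
oracle_cophenetic <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen[tree$edge[, 2L]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  path_to_root <- function(i) {
    nodes <- integer(0)
    while (i != root) {
      nodes <- c(nodes, i)
      i <- parent[i]
    }
    nodes
  }
  d <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1L)) {
    pi <- path_to_root(i)
    for (j in (i + 1L):ntip) {
      pj <- path_to_root(j)
      sym <- c(setdiff(pi, pj), setdiff(pj, pi))
      d[i, j] <- d[j, i] <- sum(elen[sym])
    }
  }
  d
}

# MNTD by exhaustive nearest-neighbour scan.
oracle_mntd <- function(x, d, weighted = FALSE) {
  present <- names(x)[x > 0]
  if (length(present) < 2L) return(NA_real_)
  nnd <- sapply(present, function(i) {
    min(sapply(setdiff(present, i), function(j) d[i, j]))
  })
  if (weighted) {
    f <- x[present] / sum(x[present])
    sum(f * nnd)
  } else {
    mean(nnd)
  }
}

# betaMNTD by explicit double loop.
oracle_bmntd <- function(x, y, d, weighted = TRUE) {
  px <- names(x)[x > 0]
  py <- names(y)[y > 0]
  nnd_x <- sapply(px, function(i) min(sapply(py, function(j) d[i, j])))
  nnd_y <- sapply(py, function(j) min(sapply(px, function(i) d[j, i])))
  if (weighted) {
    fx <- x[px] / sum(x[px])
    fy <- y[py] / sum(y[py])
    0.5 * (sum(fx * nnd_x) + sum(fy * nnd_y))
  } else {
    mean(c(nnd_x, nnd_y))  # pooled, the comdistnt convention
  }
}

oracle_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

# Random community table over the tips of a tree.
random_table <- function(tree, n_samples, min_rich = 2, max_count = 20) {
  nt <- length(tree$tip.label)
  x <- sapply(seq_len(n_samples), function(s) {
    k <- sample(min_rich:nt, 1L)
    v <- integer(nt)
    v[sample.int(nt, k)] <- sample.int(max_count, k, replace = TRUE)
    v
  })
  rownames(x) <- tree$tip.label
  colnames(x) <- paste0("S", seq_len(n_samples))
  storage.mode(x) <- "integer"
  x
}

# Communities drawn uniformly at random from the tip pool (for null
# calibration): fixed richness, equal counts.
uniform_random_table <- function(taxa, n_samples, richness, count = 10L) {
  x <- sapply(seq_len(n_samples), function(s) {
    v <- integer(length(taxa))
    v[sample.int(length(taxa), richness)] <- count
    v
  })
  rownames(x) <- taxa
  colnames(x) <- paste0("S", seq_len(n_samples))
  storage.mode(x) <- "integer"
  x
}
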