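test_that("null engines are deterministic given a seed", {
  set.seed(20)
  tree <- simulate_tree(20, seed = 3)
  x <- random_table(tree, 6)
  d <- cophenetic_dist(tree)
  a <- ses_mntd(x, d, n_iter = 49, seed = 5)
  b <- ses_mntd(x, d, n_iter = 49, seed = 5)
  expect_identical(a, b)
  bn1 <- beta_nti(x, d, n_iter = 49, seed = 6)
  bn2 <- beta_nti(x, d, n_iter = 49, seed = 6)
  expect_identical(bn1$bnti, bn2$bnti)
  r1 <- rc_bray(x, n_iter = 49, seed = 7)
  r2 <- rc_bray(x, n_iter = 49, seed = 7)
  expect_identical(r1, r2)
  # engines do not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(ses_mntd(x, d, n_iter = 9, seed = 1))
  expect_identical(runif(1), before)
})

test_that("degenerate trees yield undefined SES.MNTD with a warning", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  d <- cophenetic_dist(star)
  x <- matrix(c(1L, 1L, 1L, 0L), ncol = 1,
              dimnames = list(letters[1:4], "S1"))
  expect_warning(res <- ses_mntd(x, d, n_iter = 29, seed = 1), "null sd")
  expect_true(is.na(res$ses_mntd))
  expect_equal(res$mntd_obs, 2)
})

test_that("communities confined to a tight clade give negative SES.MNTD", {
  # two clades joined by a long branch; samples only use clade one
  tree <- ape::read.tree(text = paste0(
    "(((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1):5,",
    "((e:0.1,f:0.1):0.1,(g:0.1,h:0.1):0.1):5);"))
  d <- cophenetic_dist(tree)
  set.seed(21)
  x <- sapply(1:6, function(s) {
    v <- integer(8); v[sample(1:4, 3)] <- 10L; v
  })
  dimnames(x) <- list(tree$tip.label, paste0("S", 1:6))
  res <- ses_mntd(x, d, n_iter = 199, seed = 2)
  expect_true(all(res$ses_mntd < 0))
})

test_that("observed statistics agree with picante", {
  skip_if_not_installed("picante")
  set.seed(22)
  tree <- simulate_tree(15, seed = 9)
  x <- random_table(tree, 5)
  d <- cophenetic_dist(tree)
  comm <- t(x)  # picante wants samples x species
  expect_equal(ses_mntd(x, d, n_iter = 5, seed = 1)$mntd_obs,
               unname(picante::mntd(comm, d, abundance.weighted = FALSE)),
               tolerance = 1e-10)
  expect_equal(
    suppressWarnings(ses_mntd(x, d, n_iter = 5, seed = 1,
                              abundance_weighted = TRUE))$mntd_obs,
    unname(picante::mntd(comm, d, abundance.weighted = TRUE)),
    tolerance = 1e-10)
  for (w in c(TRUE, FALSE)) {
    ours <- beta_nti(x, d, n_iter = 5, seed = 1, abundance_weighted = w)$bmntd
    theirs <- as.matrix(picante::comdistnt(comm, d, abundance.weighted = w))
    theirs <- theirs[rownames(ours), colnames(ours)]
    expect_equal(ours[lower.tri(ours)], theirs[lower.tri(theirs)],
                 tolerance = 1e-10)
  }
})

test_that("taxon relabelling leaves the null engines invariant", {
  set.seed(23)
  tree <- simulate_tree(12, seed = 4)
  x <- random_table(tree, 5)
  d <- cophenetic_dist(tree)
  relab <- setNames(paste0("X", 1:12), rownames(x))
  x2 <- x; rownames(x2) <- relab[rownames(x)]
  d2 <- d; dimnames(d2) <- list(relab[rownames(d)], relab[colnames(d)])
  a <- ses_mntd(x, d, n_iter = 29, seed = 8)
  b <- ses_mntd(x2, d2, n_iter = 29, seed = 8)
  expect_equal(a$ses_mntd, b$ses_mntd)
  expect_equal(beta_nti(x, d, n_iter = 29, seed = 8)$bnti,
               beta_nti(x2, d2, n_iter = 29, seed = 8)$bnti,
               ignore_attr = TRUE)
})

test_that("RC-bray respects its bounds, symmetry and extreme signatures", {
  # pool of 60 taxa over 12 samples at equal depth 150; samples are rich
  # enough that null membership draws are almost never disjoint
  set.seed(24)
  taxa <- paste0("t", 1:60)
  x <- matrix(0L, 60, 12, dimnames = list(taxa, paste0("S", 1:12)))
  # S1 and S2: identical, confined to taxa rare in the pool
  x[1:6, 1] <- x[1:6, 2] <- 25L
  # S3 and S4: disjoint 15-taxon sets
  x[7:21, 3] <- 10L
  x[22:36, 4] <- 10L
  # remaining samples spread over the rest of the pool
  for (s in 5:12) x[cbind(sample(37:60, 15), s)] <- 10L
  rc <- rc_bray(x, n_iter = 299, seed = 9)
  off <- rc[lower.tri(rc)]
  expect_true(all(off >= -1 & off <= 1))
  expect_equal(rc, t(rc))
  expect_lt(rc["S1", "S2"], -0.9)
  expect_gt(rc["S3", "S4"], 0.9)
})
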