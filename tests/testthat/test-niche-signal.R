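test_that("abundance-weighted optima follow the stated formula", {
  x <- matrix(c(3L, 1L,
                0L, 4L), nrow = 2, byrow = TRUE,
              dimnames = list(c("t1", "t2"), c("S1", "S2")))
  opt <- weighted_mean_optima(x, c(S1 = 4, S2 = 7))
  expect_equal(opt$optimum[opt$otu == "t1"], (3 * 4 + 1 * 7) / 4)
  expect_equal(opt$optimum[opt$otu == "t2"], 7)

  # matches a loop-based oracle; invariant to rescaling a row
  set.seed(41)
  tab <- matrix(rpois(50, 2), nrow = 10,
                dimnames = list(paste0("t", 1:10), paste0("S", 1:5)))
  storage.mode(tab) <- "integer"
  tab[1, ] <- c(1L, 2L, 3L, 4L, 5L)
  ph <- runif(5, 3, 9)
  res <- suppressWarnings(weighted_mean_optima(tab, ph))
  for (k in seq_len(nrow(res))) {
    i <- res$otu[k]
    w <- tab[i, ]
    expect_equal(res$optimum[k], sum(w * ph) / sum(w))
  }
  tab2 <- tab
  tab2[1, ] <- tab2[1, ] * 6L
  res2 <- suppressWarnings(weighted_mean_optima(tab2, ph))
  expect_equal(res2$optimum[res2$otu == "t1"],
               res$optimum[res$otu == "t1"])
  expect_true(all(res$optimum >= min(ph) & res$optimum <= max(ph)))
})

test_that("optima distances are absolute differences with aligned labels", {
  opt <- data.frame(otu = c("x", "y", "z"), optimum = c(4.75, 6.75, 6.75))
  d <- optima_distance(opt)
  expect_equal(d["x", "y"], 2)
  expect_equal(d["y", "z"], 0)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  opt$included <- c(TRUE, TRUE, FALSE)
  expect_equal(dim(optima_distance(opt)), c(2L, 2L))
})

test_that("Mantel statistic equals the lower-triangle correlation", {
  set.seed(42)
  a <- matrix(runif(25), 5); A <- a + t(a); diag(A) <- 0
  b <- matrix(runif(25), 5); B <- b + t(b); diag(B) <- 0
  dimnames(A) <- dimnames(B) <- list(letters[1:5], letters[1:5])
  m <- mantel_test(A, B, n_perm = 99, seed = 1)
  expect_equal(m$r, cor(A[lower.tri(A)], B[lower.tri(B)]))
  # identity gives r = 1; reproducible p
  expect_equal(mantel_test(A, A + 0.001 * B, n_perm = 99, seed = 2)$r,
               cor(lowerA <- A[lower.tri(A)], (A + 0.001 * B)[lower.tri(A)]))
  expect_equal(mantel_test(A, A, n_perm = 99, seed = 3)$r, 1)
  expect_identical(mantel_test(A, B, n_perm = 99, seed = 4)$p,
                   mantel_test(A, B, n_perm = 99, seed = 4)$p)
  # agreement with vegan on the statistic
  skip_if_not_installed("vegan")
  expect_equal(m$r, unname(vegan::mantel(as.dist(A), as.dist(B),
                                         permutations = 2)$statistic))
  C <- matrix(1, 5, 5); diag(C) <- 0
  dimnames(C) <- dimnames(A)
  expect_error(mantel_test(A, C, n_perm = 9), "degenerate")
})

test_that("partial Mantel equals the closed form and its algebraic limits", {
  set.seed(43)
  rnd <- function() {
    x <- matrix(runif(64), 8); x <- x + t(x); diag(x) <- 0
    dimnames(x) <- list(letters[1:8], letters[1:8])
    x
  }
  for (i in 1:5) {
    A <- rnd(); B <- rnd(); C <- rnd()
    pm <- partial_mantel(A, B, C, n_perm = 19, seed = i)
    direct <- (pm$r_ab - pm$r_ac * pm$r_bc) /
      sqrt((1 - pm$r_ac^2) * (1 - pm$r_bc^2))
    expect_equal(pm$r, direct, tolerance = 1e-12)
  }
  # B = C: controlling for B itself leaves nothing
  A <- rnd(); B <- rnd()
  expect_equal(partial_mantel(A, B, B, n_perm = 19, seed = 1)$r, 0,
               tolerance = 1e-12)
  # C orthogonal to both (constructed by residualization): r_AB.C = r_AB
  a <- A[lower.tri(A)]; b <- B[lower.tri(B)]
  cr <- residuals(lm(runif(length(a)) ~ a + b))
  C0 <- matrix(0, 8, 8); C0[lower.tri(C0)] <- cr
  C0 <- C0 + t(C0); dimnames(C0) <- dimnames(A)
  pm0 <- partial_mantel(A, B, C0, n_perm = 19, seed = 1)
  expect_equal(pm0$r, pm0$r_ab, tolerance = 1e-10)
  expect_error(partial_mantel(A, B, A, n_perm = 9), "collinear")
})

test_that("correlogram classes partition the distance range; correction sane", {
  tree <- simulate_tree(40, seed = 51)
  d <- cophenetic_dist(tree)
  opt <- evolve_optima(tree, sigma2 = 0.5, seed = 52)
  nd <- optima_distance(data.frame(otu = names(opt), optimum = as.numeric(opt)))
  cg <- mantel_correlogram(nd, d, n_perm = 99, seed = 53)
  expect_true(all(cg$p_corrected >= cg$p))
  edges <- attr(cg, "edges")
  pv <- d[lower.tri(d)]
  expect_equal(min(edges), min(pv))
  expect_equal(max(edges), max(pv))
  expect_true(all(diff(edges) > 0))
  expect_true(sum(cg$n_pairs) <= length(pv))
  # progressive correction multiplies by the class rank
  cg2 <- mantel_correlogram(nd, d, n_perm = 99, seed = 53,
                            correction = "progressive")
  expect_equal(cg2$p_corrected, pmin(1, cg2$p * seq_len(nrow(cg2))))
})

test_that("Brownian optima show short-distance signal; noise does not", {
  tree <- simulate_tree(60, seed = 54)
  d <- cophenetic_dist(tree)
  opt <- evolve_optima(tree, sigma2 = 0.5, seed = 55)
  nd <- optima_distance(data.frame(otu = names(opt), optimum = as.numeric(opt)))
  cg <- mantel_correlogram(nd, d, n_perm = 199, seed = 56)
  expect_gt(cg$r[1], 0)
  expect_lt(cg$p[1], 0.05)

  noise <- setNames(rnorm(60, 6.5, 0.7), tree$tip.label)
  ndn <- optima_distance(data.frame(otu = names(noise),
                                    optimum = as.numeric(noise)))
  cgn <- mantel_correlogram(ndn, d, n_perm = 199, seed = 57)
  expect_true(all(cgn$p_corrected > 0.05))
})
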