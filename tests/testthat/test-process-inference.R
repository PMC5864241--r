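test_that("pairwise classification tiles the (betaNTI, RC) plane", {
  expect_equal(as.character(classify_pair(-3, NA)), "homogeneous_selection")
  expect_equal(as.character(classify_pair(3, NA)), "variable_selection")
  expect_equal(as.character(classify_pair(1.5, 0.97)), "dispersal_limitation")
  expect_equal(as.character(classify_pair(-1, -0.99)), "homogenizing_dispersal")
  expect_equal(as.character(classify_pair(0.4, 0.2)), "undominated")

  # boundary convention: |betaNTI| = 2 goes to the stochastic branch,
  # |RC| = 0.95 to undominated
  expect_equal(as.character(classify_pair(2, 0.99)), "dispersal_limitation")
  expect_equal(as.character(classify_pair(-2, 0.5)), "undominated")
  expect_equal(as.character(classify_pair(0, 0.95)), "undominated")
  expect_equal(as.character(classify_pair(0, -0.95)), "undominated")

  # grid sweep: every defined input gets exactly one non-missing label
  grid <- expand.grid(b = c(-3, -2.01, -2, -1, 0, 1, 2, 2.01, 3),
                      r = c(-1, -0.96, -0.95, 0, 0.95, 0.96, 1))
  lab <- classify_pair(grid$b, grid$r)
  expect_false(any(is.na(lab)))
  expect_false(any(lab == "unclassifiable"))
  # the deterministic branches ignore RC entirely
  expect_true(all(lab[abs(grid$b) > 2] %in%
                    c("variable_selection", "homogeneous_selection")))

  expect_warning(u <- classify_pair(c(0, NA), c(NA, 0.2)), "missing RC")
  expect_equal(as.character(u), c("unclassifiable", "unclassifiable"))
})

test_that("process fractions tally per group and sum to 100", {
  lab <- classify_pair(c(-3, -4, 3, 0), c(NA, NA, NA, 0.1))
  f <- partition_fractions(lab)
  expect_equal(f$pct_homogeneous_selection, 50)
  expect_equal(f$pct_variable_selection, 25)
  expect_equal(f$pct_undominated, 25)
  expect_equal(f$n_pairs, 4L)
  pct <- as.numeric(f[1, grep("^pct_", names(f))])
  expect_equal(sum(pct), 100)

  all_hs <- classify_pair(rep(-5, 7))
  expect_equal(partition_fractions(all_hs)$pct_homogeneous_selection, 100)

  # random labels, two groups: fractions match an independent tally,
  # and are invariant to pair order
  set.seed(31)
  b <- runif(60, -4, 4); r <- runif(60, -1, 1)
  lab2 <- classify_pair(b, r)
  grp <- sample(c("g1", "g2"), 60, replace = TRUE)
  f2 <- partition_fractions(lab2, grp)
  for (g in c("g1", "g2")) {
    tab <- table(lab2[grp == g])
    expect_equal(f2$pct_dispersal_limitation[f2$group == g],
                 100 * tab[["dispersal_limitation"]] / sum(tab))
  }
  p <- sample(60)
  f3 <- partition_fractions(lab2[p], grp[p])
  expect_equal(f2[order(f2$group), ], f3[order(f3$group), ],
               ignore_attr = TRUE)
})

test_that("pair binning keys within- and between-category comparisons", {
  meta <- data.frame(sample_id = c("a", "b", "c", "d"),
                     pH = c(4.1, 4.3, 6.9, 6.4),
                     age = c(10, 10, 50, 120))
  bp <- bin_pairs(meta, "pH", edges = c(4, 5, 6, 7))
  key <- function(i, j) bp$group[(bp$sample_i == i & bp$sample_j == j) |
                                   (bp$sample_i == j & bp$sample_j == i)]
  expect_equal(key("a", "b"), "[4,5)")
  expect_match(key("a", "c"), "^between:")
  expect_equal(key("c", "d"), "[6,7]")  # last bin closed on the right

  # discrete ages bin by identity
  ba <- bin_pairs(meta, "age")
  expect_equal(key2 <- ba$group[ba$sample_i == "a" & ba$sample_j == "b" |
                                  ba$sample_i == "b" & ba$sample_j == "a"],
               "age:10")

  # brute-force assignment check on random metadata
  set.seed(32)
  m <- data.frame(sample_id = paste0("s", 1:9), pH = runif(9, 3, 9))
  edges <- c(3, 5, 7, 9.01)
  bp2 <- bin_pairs(m, "pH", edges = edges)
  binof <- function(v) findInterval(v, edges, rightmost.closed = TRUE)
  for (k in seq_len(nrow(bp2))) {
    vi <- m$pH[m$sample_id == bp2$sample_i[k]]
    vj <- m$pH[m$sample_id == bp2$sample_j[k]]
    same <- binof(vi) == binof(vj)
    expect_equal(!startsWith(bp2$group[k], "between:"), same)
  }
  expect_equal(nrow(bp2), choose(9, 2))
  expect_error(bin_pairs(m, "pH", edges = c(5, 4)), "strictly increasing")
})

test_that("depth sensitivity reruns the pipeline per depth deterministically", {
  b <- scenario("neutral", seed = 17, n_taxa = 25, n_samples = 8, depth = 400)
  s1 <- suppressWarnings(
    depth_sensitivity(b$table, b$tree, b$meta, depths = c(150, 300),
                      n_iter = 49, seed = 5))
  s2 <- suppressWarnings(
    depth_sensitivity(b$table, b$tree, b$meta, depths = c(150, 300),
                      n_iter = 49, seed = 5))
  expect_identical(s1$summary, s2$summary)
  expect_equal(nrow(s1$summary), 2L)
  expect_true(all(s1$summary$depth == c(150, 300)))

  # unreachable depth skipped with a warning, run completes
  expect_warning(
    s3 <- depth_sensitivity(b$table, b$tree, b$meta,
                            depths = c(300, 10^6), n_iter = 19, seed = 5),
    "unreachable")
  expect_equal(s3$summary$depth, 300)
})
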