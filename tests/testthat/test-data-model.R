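test_that("TSV community tables parse, validate and round-trip", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tS1\tS2", "t1\t5\t0", "t2\t1\t2", "t3\t0\t7"), tmp)
  tab <- read_community_table(tmp)
  expect_identical(dim(tab), c(3L, 2L))
  expect_identical(unname(colSums(tab)), c(6, 9))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("taxon_id\tS1", empty)
  expect_error(read_community_table(empty), "no taxa")

  out <- withr::local_tempfile(fileext = ".tsv")
  write_community_table(tab, out)
  expect_identical(read_community_table(out), tab)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tS1", "t1\tfive"), bad)
  expect_error(read_community_table(bad), "t1")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tS1", "t1\t3", "t1\t4"), dup)
  expect_error(read_community_table(dup), "duplicate")
})

test_that("singleton removal drops dataset-wide singletons only, idempotently", {
  x <- matrix(c(1L, 0L, 0L,
                1L, 1L, 0L,
                5L, 3L, 2L), nrow = 3, byrow = TRUE,
              dimnames = list(c("single", "double", "common"),
                              c("S1", "S2", "S3")))
  f <- remove_singletons(x)
  expect_identical(rownames(f), c("double", "common"))
  expect_identical(colnames(f), colnames(x))
  expect_identical(remove_singletons(f), f)

  all_single <- matrix(c(1L, 0L), nrow = 1,
                       dimnames = list("s", c("S1", "S2")))
  expect_error(remove_singletons(all_single), "empty table")
})

test_that("rarefaction subsamples without replacement to exact depth", {
  set.seed(1)
  x <- matrix(rpois(60, 30) + 1L, nrow = 10,
              dimnames = list(paste0("t", 1:10), paste0("S", 1:6)))
  storage.mode(x) <- "integer"
  r <- rarefy(x, 100, seed = 7)
  expect_true(all(colSums(r) == 100))
  expect_true(all(r <= x[, colnames(r)]))
  # deterministic under the same seed, different under another
  expect_identical(r, rarefy(x, 100, seed = 7))

  # sample already at depth is untouched
  y <- matrix(c(4L, 6L), nrow = 2, dimnames = list(c("A", "B"), "S1"))
  expect_identical(rarefy(y, 10, seed = 1), y)

  # hypergeometric expectation: depth 5 from (A:4, B:6) leaves E[A] = 2
  draws <- vapply(1:10000, function(i) rarefy(y, 5, seed = i)["A", 1], numeric(1))
  expect_equal(mean(draws), 2.0, tolerance = 0.02)

  # shallow samples are dropped with a warning; unreachable depth errors
  expect_warning(r2 <- rarefy(cbind(y, S2 = c(2L, 1L)), 10, seed = 1),
                 "dropping")
  expect_identical(colnames(r2), "S1")
  expect_error(suppressWarnings(rarefy(y, 1000, seed = 1)), "no sample")
})

test_that("table-tree reconciliation prunes both sides to the shared taxa", {
  tree <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,extra:1):1);")
  x <- matrix(c(3L, 1L, 2L, 4L, 5L, 6L, 9L, 2L), nrow = 4,
              dimnames = list(c("t1", "t2", "t3", "orphan"), c("S1", "S2")))
  expect_warning(rec <- reconcile(x, tree), "orphan")
  expect_setequal(rownames(rec$table), rec$tree$tip.label)
  expect_setequal(rownames(rec$table), c("t1", "t2", "t3"))
  # idempotent once matched
  rec2 <- reconcile(rec$table, rec$tree)
  expect_identical(rec2$table, rec$table)
  expect_identical(rec2$tree$tip.label, rec$tree$tip.label)

  expect_error(
    suppressWarnings(reconcile(x[c("t1", "orphan"), ], tree)), "fewer than 2")
})

test_that("environmental distance is 1-D absolute difference / multivariate norm", {
  meta <- data.frame(sample_id = c("a", "b", "c"),
                     pH = c(4, 7, 7.5), moisture = c(10, 12, 11))
  d <- env_distance(meta, "pH")
  expect_equal(d["a", "b"], 3.0)
  expect_equal(d["b", "c"], 0.5)
  expect_true(all(diag(d) == 0))
  # constant variable
  meta$k <- 1
  expect_true(all(env_distance(meta, "k") == 0))
  # multivariate: hand expansion
  d2 <- env_distance(meta, c("pH", "moisture"))
  expect_equal(d2["a", "b"], sqrt(3^2 + 2^2))
  # triangle inequality in 1-D
  set.seed(2)
  m <- data.frame(sample_id = paste0("s", 1:8), pH = runif(8, 3, 9))
  dd <- env_distance(m, "pH")
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    expect_lte(dd[i, j], dd[i, k] + dd[k, j] + 1e-12)
  }
  expect_error(env_distance(data.frame(sample_id = "a", pH = NA_real_)), "a")
})

test_that("spatial distance is haversine great-circle in metres", {
  meta <- data.frame(sample_id = c("a", "b", "c"),
                     lat = c(0, 0, 0), lon = c(0, 1, 0))
  d <- spatial_distance(meta)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], 111195, tolerance = 0.001)
  expect_equal(d["a", "b"], d["b", "a"])
  expect_error(spatial_distance(data.frame(sample_id = "a", lat = NA, lon = 1)),
               "missing coordinates")
})
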