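test_that("rarefy is a uniform without-replacement subsample", {
  s <- make_sample(c(5L, 3L, 2L))
  expect_identical(withr::with_seed(1, rarefy(s, 10)), c(5L, 3L, 2L))
  one <- withr::with_seed(2, rarefy(s, 1))
  expect_equal(sum(one), 1L)
  expect_error(rarefy(s, 11), "depth")
  expect_error(rarefy(s, 0), "depth")

  # hypergeometric expectation: a 90%-abundance clonotype subsampled to
  # 1000 has mean count 900
  big <- c(9000L, rep(10L, 100))
  means <- withr::with_seed(3, {
    replicate(1000, rarefy(big, 1000)[1])
  })
  # SD of the mean of 1000 hypergeometric draws
  n_pop <- sum(big)
  v <- 1000 * 0.9 * 0.1 * (n_pop - 1000) / (n_pop - 1)
  expect_lt(abs(mean(means) - 900), 3 * sqrt(v / 1000))
})

test_that("shannon_entropy matches closed forms and the oracle", {
  expect_equal(shannon_entropy(5), 0)
  expect_equal(shannon_entropy(rep(3, 4)), log(4))
  expect_equal(shannon_entropy(c(2, 1, 1)), 1.039721, tolerance = 1e-6)
  expect_equal(shannon_entropy(c(2, 1, 1), base = 2),
               1.039721 / log(2), tolerance = 1e-6)
  for (seed in 1:20) {
    x <- withr::with_seed(seed, sample(0:5, 8, replace = TRUE))
    if (sum(x) == 0) next
    expect_equal(shannon_entropy(x), oracle_shannon(x), tolerance = 1e-12)
  }
  expect_error(shannon_entropy(c(0, 0)), "positive sum")
})

test_that("shannon_entropy agrees with vegan", {
  skip_if_not_installed("vegan")
  for (seed in 1:10) {
    x <- withr::with_seed(seed, sample(1:50, 12, replace = TRUE))
    expect_equal(shannon_entropy(x),
                 unname(vegan::diversity(x, index = "shannon")),
                 tolerance = 1e-10)
  }
})

test_that("gini_index matches the pairwise-difference oracle", {
  expect_equal(gini_index(rep(7, 5)), 0)
  expect_equal(gini_index(c(1, 1, 2)), 1 / 6, tolerance = 1e-12)
  for (seed in 1:20) {
    x <- withr::with_seed(seed, sample(0:9, sample(2:10, 1),
                                       replace = TRUE))
    if (sum(x) == 0) x[1] <- 1
    g <- gini_index(x)
    expect_equal(g, oracle_gini(x), tolerance = 1e-12)
    expect_gte(g, 0)
    expect_lte(g, (length(x) - 1) / length(x))
  }
  expect_error(gini_index(5), "at least 2")
})

test_that("jaccard_similarity is the intersection-over-union", {
  expect_equal(jaccard_similarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_similarity(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard_similarity(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_similarity(c("a", "a", "b"), c("a", "b")), 1)
  expect_error(jaccard_similarity(character(0), character(0)), "empty")
})

test_that("merging equal clonotypes lowers H and raises G", {
  # H never increases under any merge; G never decreases when the merged
  # pair sits at the top of the distribution (the unrestricted claim is
  # false: (8, 8, 4, 4) -> (8, 8, 8) lowers G from 1/6 to 0)
  for (seed in 1:10) {
    rest <- withr::with_seed(seed, sample(1:10, 6, replace = TRUE))
    expect_lte(shannon_entropy(c(rest, 8)), shannon_entropy(c(rest, 4, 4)))
  }
  for (seed in 1:10) {
    rest <- withr::with_seed(seed, sample(1:4, 6, replace = TRUE))
    expect_gte(gini_index(c(rest, 8)), gini_index(c(rest, 4, 4)) - 1e-12)
  }
  expect_lt(gini_index(c(8, 8, 8)), gini_index(c(8, 8, 4, 4)))
})

test_that("rarefied_index degenerates to the plain index and is seeded", {
  s <- make_sample(c(8L, 4L, 2L, 2L))
  total <- sum(s$clonotypes$abundance)
  r <- rarefied_index(s, "shannon", depth = total, n_repeats = 1, seed = 1)
  expect_equal(r$mean, shannon_entropy(s$clonotypes$abundance))
  g <- rarefied_index(s, "gini", depth = total, n_repeats = 1, seed = 1)
  expect_equal(g$mean, gini_index(s$clonotypes$abundance))

  r1 <- rarefied_index(s, "shannon", depth = 8, n_repeats = 50, seed = 42)
  r2 <- rarefied_index(s, "shannon", depth = 8, n_repeats = 50, seed = 42)
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_equal(r1$mean, mean(r1$per_repeat))
  expect_length(r1$per_repeat, 50L)
  r3 <- rarefied_index(s, "shannon", depth = 8, n_repeats = 50, seed = 43)
  expect_false(identical(r1$per_repeat, r3$per_repeat))
})

test_that("rarefaction is unbiased for clonotype proportions", {
  counts <- c(50L, 30L, 15L, 5L)
  props <- withr::with_seed(11, {
    rowMeans(replicate(2000, rarefy(counts, 20))) / 20
  })
  se <- sqrt(props * (1 - props) / (2000 * 20))  # loose binomial bound
  expect_true(all(abs(props - counts / 100) < 4 * pmax(se, 1e-3)))
})

test_that("jaccard rarefied_index subsamples distinct CDR3 sets", {
  aa <- sprintf("CASS%02dF", 1:30)
  nt <- sprintf("TGTGCC%02dTTTTT", 1:30)   # placeholder distinct keys
  mk <- function(id, idx) {
    make_sample(rep(2L, length(idx)),
                v_name = rep("TRBV1", length(idx)),
                j_name = rep("TRBJ1", length(idx)),
                junction_nt = nt[idx], junction_aa = aa[idx],
                productive = rep(TRUE, length(idx)), sample_id = id)
  }
  a <- mk("a", 1:20)
  b <- mk("b", 11:30)
  expect_error(rarefied_index(a, "jaccard", depth = 5, n_repeats = 2,
                              seed = 1), "sample2")
  # identical samples at full depth: similarity exactly 1
  r <- rarefied_index(a, "jaccard", depth = 20, n_repeats = 3, seed = 1,
                      sample2 = a)
  expect_equal(r$per_repeat, rep(1, 3))
  # full-depth overlap of 10/30
  r2 <- rarefied_index(a, "jaccard", depth = 20, n_repeats = 5, seed = 1,
                       sample2 = b)
  expect_equal(r2$per_repeat, rep(10 / 30, 5))
  expect_error(rarefied_index(a, "jaccard", depth = 25, n_repeats = 2,
                              seed = 1, sample2 = b), "distinct CDR3s")
})

test_that("intra_group_jaccard builds a symmetric pair matrix", {
  aa <- sprintf("CASS%02dF", 1:30)
  nt <- sprintf("TGTGCC%02dTTTTT", 1:30)
  mk <- function(id, idx) {
    make_sample(rep(1L, length(idx)),
                junction_nt = nt[idx], junction_aa = aa[idx],
                productive = rep(TRUE, length(idx)), sample_id = id)
  }
  same <- list(mk("x", 1:15), mk("y", 1:15))
  res <- intra_group_jaccard(same, depth = 15, n_repeats = 3, seed = 1)
  expect_equal(unname(res$per_sample_mean), c(1, 1))
  disj <- list(mk("x", 1:15), mk("y", 16:30))
  res2 <- intra_group_jaccard(disj, depth = 15, n_repeats = 3, seed = 1)
  expect_equal(unname(res2$matrix[1, 2]), 0)
  tri <- list(mk("a", 1:15), mk("b", 6:20), mk("c", 11:25))
  res3 <- intra_group_jaccard(tri, depth = 10, n_repeats = 20, seed = 2)
  expect_equal(res3$matrix, t(res3$matrix))
  expect_true(all(is.na(diag(res3$matrix))))
  expect_error(intra_group_jaccard(list(mk("a", 1:5)), depth = 2,
                                   n_repeats = 1, seed = 1), "at least 2")
})
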