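catalog <- toy_catalog()

test_that("usage_vector respects weighting and chromosomal order", {
  s <- make_sample(c(1L, 9L, 2L),
                   v_name = c("TRBV1", "TRBV1", "TRBV3"),
                   j_name = c("TRBJ1", "TRBJ2", "TRBJ1"))
  u <- usage_vector(s, "V", "unique", catalog)
  expect_equal(sum(u), 1)
  expect_equal(unname(u["TRBV1"]), 2 / 3)
  expect_equal(unname(u["TRBV3"]), 1 / 3)
  expect_equal(names(u),
               catalog_segments(catalog, "TRB", "V")$name)

  ut <- usage_vector(s, "V", "total", catalog)
  expect_equal(unname(ut["TRBV1"]), 10 / 12)
  expect_equal(sum(ut), 1)

  bad <- make_sample(1L, v_name = "TRBV99")
  expect_error(usage_vector(bad, "V", "unique", catalog), "TRBV99")
})

test_that("vxj_matrix marginals reproduce usage counts", {
  s <- make_sample(c(1L, 9L, 2L, 4L),
                   v_name = c("TRBV1", "TRBV1", "TRBV3", "TRBV2"),
                   j_name = c("TRBJ1", "TRBJ2", "TRBJ1", "TRBJ4"))
  m <- vxj_matrix(s, "total", catalog)
  expect_equal(rowSums(m) / sum(m), unname(usage_vector(s, "V", "total",
                                                        catalog)),
               ignore_attr = TRUE)
  expect_equal(colSums(m) / sum(m), unname(usage_vector(s, "J", "total",
                                                        catalog)),
               ignore_attr = TRUE)

  single <- make_sample(5L, v_name = "TRBV2", j_name = "TRBJ3")
  ms <- vxj_matrix(single, "unique", catalog)
  expect_equal(sum(ms), 1)
  expect_equal(ms["TRBV2", "TRBJ3"], 1)

  empty <- make_sample(integer(0), v_name = character(0),
                       j_name = character(0), junction_nt = character(0),
                       junction_aa = character(0), productive = logical(0))
  expect_true(all(vxj_matrix(empty, "unique", catalog) == 0))
})

test_that("group_mean_heatmap averages members and clusters columns", {
  mk <- function(v, id) make_sample(c(2L, 2L), v_name = c(v, "TRBV2"),
                                    j_name = c("TRBJ1", "TRBJ2"),
                                    sample_id = id)
  samples <- list(mk("TRBV1", "a1"), mk("TRBV3", "a2"),
                  mk("TRBV1", "b1"), mk("TRBV3", "b2"))
  hm <- group_mean_heatmap(samples, c("A", "A", "B", "B"), axis = "V",
                           weighting = "unique", catalog = catalog)
  expect_equal(colnames(hm$matrix), c("A", "B"))
  expect_equal(hm$matrix[, "A"],
               (usage_vector(samples[[1]], "V", "unique", catalog) +
                  usage_vector(samples[[2]], "V", "unique", catalog)) / 2)
  # identical groups merge at height zero
  expect_equal(hm$dendrogram$height, 0)
  # rows stay in chromosomal order
  expect_equal(rownames(hm$matrix),
               catalog_segments(catalog, "TRB", "V")$name)

  one <- group_mean_heatmap(samples[1:2], c("A", "A"), axis = "J",
                            weighting = "unique", catalog = catalog)
  expect_null(one$dendrogram)
  expect_error(group_mean_heatmap(list(), character(0), "V", "unique",
                                  catalog), ">= 1 sample")
})

test_that("benjamini_hochberg reproduces the step-up oracle", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  grid <- seq(0, 1, by = 0.005)
  for (seed in 1:50) {
    p <- withr::with_seed(seed, sample(grid, sample(1:8, 1),
                                       replace = TRUE))
    q <- benjamini_hochberg(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
    # monotone non-decreasing along sorted p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q >= p - 1e-12))
  }
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(benjamini_hochberg(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("differential_vxj assigns tiles per the detection rules", {
  mks <- function(vs, js, ab, id) {
    make_sample(ab, v_name = vs, j_name = js, sample_id = id)
  }
  # group A uses (V1,J1) and (V2,J2); group B uses (V1,J1) and (V3,J3)
  a <- lapply(1:3, function(i) {
    mks(c("TRBV1", "TRBV2"), c("TRBJ1", "TRBJ2"), c(10L, 5L + i),
        paste0("a", i))
  })
  b <- lapply(1:3, function(i) {
    mks(c("TRBV1", "TRBV3"), c("TRBJ1", "TRBJ3"), c(10L, 20L + i),
        paste0("b", i))
  })
  d <- differential_vxj(a, b, catalog, min_detected = 3)
  tile_of <- function(v, j) d$tile[d$v == v & d$j == j]
  expect_equal(tile_of("TRBV2", "TRBJ2"), "absent_B")
  expect_equal(tile_of("TRBV3", "TRBJ3"), "absent_A")
  expect_equal(tile_of("TRBV4", "TRBJ4"), "absent_both")
  expect_true(tile_of("TRBV1", "TRBJ1") %in%
                c("increased", "decreased", "no_change"))
  # tiles partition the grid
  expect_equal(nrow(d), 16L)
  expect_true(all(d$tile %in% c("increased", "decreased", "no_change",
                                "absent_A", "absent_B", "absent_both",
                                "not_compared")))
  # q >= p wherever compared
  cmp <- !is.na(d$p_value)
  expect_true(all(d$q_value[cmp] >= d$p_value[cmp] - 1e-12))

  # identical groups: every compared tile is no_change
  d0 <- differential_vxj(a, a, catalog, min_detected = 3)
  expect_true(all(d0$tile[!is.na(d0$p_value)] == "no_change"))

  # min_detected only moves cells between compared and not_compared
  a2 <- c(a, list(mks("TRBV2", "TRBJ1", 4L, "a4")))
  b2 <- c(b, list(mks("TRBV2", "TRBJ1", 4L, "b4")))
  d3 <- differential_vxj(a2, b2, catalog, min_detected = 3)
  d4 <- differential_vxj(a2, b2, catalog, min_detected = 4)
  moved <- d3$tile != d4$tile
  expect_true(all(d4$tile[moved] == "not_compared" |
                    d3$tile[moved] == "not_compared" |
                    (d3$tile[moved] %in% c("increased", "decreased",
                                           "no_change") &
                       d4$tile[moved] %in% c("increased", "decreased",
                                             "no_change"))))
  expect_error(differential_vxj(a[1:2], b, catalog), "min_detected")
})

test_that("differential_vxj p-values match stats::t.test", {
  a <- lapply(1:4, function(i) {
    make_sample(c(10L + 3L * i, 5L), v_name = c("TRBV1", "TRBV2"),
                j_name = c("TRBJ1", "TRBJ2"), sample_id = paste0("a", i))
  })
  b <- lapply(1:4, function(i) {
    make_sample(c(10L, 5L + 2L * i), v_name = c("TRBV1", "TRBV2"),
                j_name = c("TRBJ1", "TRBJ2"), sample_id = paste0("b", i))
  })
  d <- differential_vxj(a, b, catalog, min_detected = 3)
  prop <- function(ss, v, j) {
    vapply(ss, function(s) {
      m <- vxj_matrix(s, "total", catalog)
      m[v, j] / sum(m)
    }, numeric(1))
  }
  ref <- t.test(prop(a, "TRBV1", "TRBJ1"), prop(b, "TRBV1", "TRBJ1"),
                var.equal = TRUE)$p.value
  expect_equal(d$p_value[d$v == "TRBV1" & d$j == "TRBJ1"], ref,
               tolerance = 1e-12)
})
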