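catalog <- build_catalog(seed = 11)

test_that("draw_tra_pair degenerate limits and clamping", {
  # huge proximal bias, no extra rounds: always the most-3' V, most-5' J
  cfg <- simulation_config("adult", "DP", "TRA", 10, proximal_bias = 50,
                          rearrangement_rounds_mean = 0,
                          insert_mean = 1, deletion_mean = 1,
                          clone_size_alpha = 2, selection_strength = 0,
                          nonproductive_rate = 0)
  pairs <- withr::with_seed(1, draw_tra_pair(catalog, cfg, 200))
  expect_true(all(pairs[, "v_index"] == 97L))
  expect_true(all(pairs[, "j_index"] == 0L))

  # absurd round count clamps at the array bounds without error
  cfg$rearrangement_rounds_mean <- 1000
  pairs <- withr::with_seed(1, draw_tra_pair(catalog, cfg, 50))
  expect_true(all(pairs[, "v_index"] == 0L))
  expect_true(all(pairs[, "j_index"] == 59L))
})

test_that("progressive rounds shift TRA usage 5'-ward in V, 3'-ward in J", {
  pf <- withr::with_seed(2, draw_tra_pair(catalog, preset("foetal",
                                                          chain = "TRA"),
                                          10000))
  pa <- withr::with_seed(2, draw_tra_pair(catalog, preset("adult",
                                                          chain = "TRA"),
                                          10000))
  expect_lt(mean(pa[, "v_index"]), mean(pf[, "v_index"]))
  expect_gt(mean(pa[, "j_index"]), mean(pf[, "j_index"]))
})

test_that("rearrangement_rounds_mean monotonically increases displacement", {
  mean_idx <- vapply(c(0, 0.5, 1, 2, 4), function(r) {
    cfg <- simulation_config("adult", "DP", "TRA", 10, proximal_bias = 0.2,
                            rearrangement_rounds_mean = r, insert_mean = 1,
                            deletion_mean = 0.1, clone_size_alpha = 2,
                            selection_strength = 0, nonproductive_rate = 0)
    p <- withr::with_seed(5, draw_tra_pair(catalog, cfg, 5000))
    c(v = mean(p[, "v_index"]), j = mean(p[, "j_index"]))
  }, numeric(2))
  expect_true(all(diff(mean_idx["v", ]) <= 0))
  expect_true(all(diff(mean_idx["j", ]) >= 0))
})

test_that("draw_trb_pair cluster choice and uniform limit", {
  cfg <- preset("adult", chain = "TRB")
  cfg$trbj_cluster1_weight <- 1.0
  trbj <- catalog_segments(catalog, "TRB", "J")
  p1 <- withr::with_seed(3, draw_trb_pair(catalog, cfg, 500))
  cl <- trbj$cluster_id[match(p1[, "j_index"], trbj$chromosomal_index)]
  expect_true(all(cl == 1L))

  cfg$trbj_cluster1_weight <- 0.5
  p2 <- withr::with_seed(3, draw_trb_pair(catalog, cfg, 10000))
  cl2 <- trbj$cluster_id[match(p2[, "j_index"], trbj$chromosomal_index)]
  frac1 <- mean(cl2 == 1L)
  expect_lt(abs(frac1 - 0.5), 3 * sqrt(0.25 / 10000))

  # proximal_bias = 0 means uniform V usage (chi-square GOF)
  cfg$proximal_bias <- 0
  p3 <- withr::with_seed(4, draw_trb_pair(catalog, cfg, 10000))
  gof <- suppressWarnings(
    stats::chisq.test(tabulate(p3[, "v_index"] + 1L, nbins = 22)))
  expect_gt(gof$p.value, 0.001)
})

test_that("make_junction respects degenerate and distributional contracts", {
  v <- catalog_segments(catalog, "TRB", "V")[3, ]
  j <- catalog_segments(catalog, "TRB", "J")[5, ]
  cfg0 <- simulation_config("foetal", "DP", "TRB", 10, proximal_bias = 1,
                           rearrangement_rounds_mean = 0, insert_mean = 0,
                           deletion_mean = 0, clone_size_alpha = 2,
                           selection_strength = 0, nonproductive_rate = 0)
  out <- withr::with_seed(1, make_junction(v, j, cfg0))
  expect_identical(out$junction_nt, paste0(v$junction_seq, j$junction_seq))
  expect_identical(unname(unlist(out$truth[c("v_deleted", "j_deleted",
                                             "insert_len")])),
                   c(0L, 0L, 0L))

  cfg4 <- cfg0
  cfg4$insert_mean <- 4
  draws <- withr::with_seed(2, replicate(10000, {
    make_junction(v, j, cfg4)$truth$insert_len
  }))
  se <- sqrt(4 * 5 / 10000)  # geometric variance = mean * (mean + 1)
  expect_lt(abs(mean(draws) - 4), 3 * se)

  # truth invariant: insert_len always equals nchar(insert_seq)
  cfgm <- cfg4
  cfgm$deletion_mean <- 2
  res <- withr::with_seed(3, replicate(200, {
    o <- make_junction(v, j, cfgm)
    o$truth$insert_len == nchar(o$truth$insert_seq)
  }))
  expect_true(all(res))
})

test_that("assign_clone_sizes follows the zeta distribution", {
  expect_error(assign_clone_sizes(100, 1.0), "alpha")
  expect_error(assign_clone_sizes(100, 0.5), "alpha")
  expect_identical(withr::with_seed(1, assign_clone_sizes(50, Inf)),
                   rep(1L, 50))
  # round trip at moderate n (the full 50k recovery is in acceptance)
  ab <- withr::with_seed(7, assign_clone_sizes(20000, 2.5))
  expect_lt(abs(fit_power_law(ab)$alpha - 2.5), 0.1)
  # singleton fraction matches the pmf: P(1) = 1/zeta(2.5)
  expect_lt(abs(mean(ab == 1L) - 1 / hurwitz_zeta(2.5)), 0.01)
})

test_that("apply_selection is conservative and lineage-divergent", {
  pool <- withr::with_seed(8, {
    pairs <- draw_trb_pair(catalog, preset("adult"), 4000)
    v <- catalog_segments(catalog, "TRB", "V")
    data.frame(v_name = v$name[match(pairs[, 1], v$chromosomal_index)],
               stringsAsFactors = FALSE)
  })
  expect_identical(apply_selection(pool, "DP", 2, catalog), pool)
  expect_identical(withr::with_seed(1,
                                    apply_selection(pool, "SP4", 0,
                                                    catalog)), pool)
  kept <- withr::with_seed(2, apply_selection(pool, "SP8", 2, catalog))
  expect_true(nrow(kept) <= nrow(pool))
  expect_true(all(kept$v_name %in% pool$v_name))

  # stronger selection drives SP4 and SP8 V-usage further apart
  js_div <- function(strength) {
    usage <- lapply(c("SP4", "SP8"), function(ct) {
      k <- withr::with_seed(3, apply_selection(pool, ct, strength, catalog))
      tab <- table(factor(k$v_name, levels = sort(unique(pool$v_name))))
      p <- as.numeric(tab) / sum(tab)
    })
    m <- (usage[[1]] + usage[[2]]) / 2
    kl <- function(p, q) sum(ifelse(p > 0, p * log(p / q), 0))
    (kl(usage[[1]], m) + kl(usage[[2]], m)) / 2
  }
  expect_gt(js_div(2), js_div(0.5))
})

test_that("simulate_sample is deterministic and well-composed", {
  cfg <- preset("foetal", "DP", "TRB", n_clonotypes = 1000, seed = 99)
  s1 <- simulate_sample(cfg, catalog)
  s2 <- simulate_sample(cfg, catalog)
  expect_identical(s1, s2)
  expect_identical(validate_sample(s1), character(0))
  expect_equal(nrow(s1$clonotypes), 1000L)

  # non-productive composition: binomial around the configured rate
  cfg10 <- preset("adult", "DP", "TRB", n_clonotypes = 10000, seed = 5)
  cfg10$nonproductive_rate <- 0.1
  s3 <- simulate_sample(cfg10, catalog)
  frac <- nonproductive_fraction(s3, weighting = "unique")
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 10000))
  # productive clonotypes carry a translated CDR3, non-productive none
  cl <- s3$clonotypes
  expect_true(all(nchar(cl$junction_aa[cl$productive]) > 0))
  expect_true(all(cl$junction_aa[!cl$productive] == ""))
})

test_that("presets encode the documented parameter ordering", {
  expect_lt(preset("foetal")$insert_mean, preset("adult")$insert_mean)
  expect_lt(preset("foetal", chain = "TRA")$insert_mean,
            preset("adult", chain = "TRA")$insert_mean)
  expect_equal(preset("adult_hc")$rearrangement_rounds_mean,
               preset("foetal")$rearrangement_rounds_mean)
  expect_equal(preset("adult_hc")$insert_mean, preset("adult")$insert_mean)
  expect_lt(preset("foetal")$clone_size_alpha,
            preset("adult")$clone_size_alpha)
  expect_lt(preset("foetal")$selection_strength,
            preset("adult")$selection_strength)
  expect_gt(preset("foetal")$trbj_cluster1_weight,
            preset("adult")$trbj_cluster1_weight)
  expect_error(preset("neonatal"), "unknown preset")
})

test_that("simulation_config rejects invalid parameters", {
  base <- function(...) {
    args <- utils::modifyList(
      list(life_stage = "adult", cell_type = "DP", chain = "TRB",
           n_clonotypes = 10, proximal_bias = 0.1,
           rearrangement_rounds_mean = 1, insert_mean = 1,
           deletion_mean = 1, clone_size_alpha = 2,
           selection_strength = 1, nonproductive_rate = 0.1),
      list(...))
    do.call(simulation_config, args)
  }
  expect_s3_class(base(), "simulation_config")
  expect_error(base(clone_size_alpha = 1), "clone_size_alpha")
  expect_error(base(insert_mean = -1), "insert_mean")
  expect_error(base(nonproductive_rate = 1.2), "nonproductive_rate")
  expect_error(base(n_clonotypes = 0), "n_clonotypes")
})
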