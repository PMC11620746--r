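# End-to-end cohort orchestration: simulate or load groups, run every
# statistic, emit tidy result tables.

#' Two-group scalar comparison (Student or Welch as appropriate)
#'
#' A Levene pre-test at `var_test_alpha` (two-group form: pooled t-test on
#' absolute deviations from group means) selects between the equal-variance
#' Student t-test and Welch's t-test; both are two-sided. Identical constant
#' groups return p = 1.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param method `"auto"` (Levene pre-test), `"student"`, or `"welch"`.
#' @param var_test_alpha significance level of the pre-test.
#' @return List with `statistic`, `p_value`, `test_name`, `levene_p`.
#' @export
scalar_group_test <- function(values_a, values_b,
                              method = c("auto", "student", "welch"),
                              var_test_alpha = 0.05) {
  method <- match.arg(method)
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (var(values_a) == 0 && var(values_b) == 0) {
    same <- mean(values_a) == mean(values_b)
    return(list(statistic = if (same) 0 else Inf,
                p_value = if (same) 1 else 0,
                test_name = "student", levene_p = 1))
  }
  lev_p <- if (method == "auto") {
    za <- abs(values_a - mean(values_a))
    zb <- abs(values_b - mean(values_b))
    tryCatch(t.test(za, zb, var.equal = TRUE)$p.value,
             error = function(e) 1)
  } else {
    NA_real_
  }
  use_welch <- switch(method,
                      auto = lev_p < var_test_alpha,
                      student = FALSE,
                      welch = TRUE)
  tt <- t.test(values_a, values_b, var.equal = !use_welch)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       test_name = if (use_welch) "welch" else "student",
       levene_p = lev_p)
}

#' Cohort configuration
#'
#' Defaults mirror a typical two-life-stage design (7 foetal vs 6 adult
#' individuals, DP and SP populations, both chains) at simulator scale.
#' Rarefaction depths are deliberately smaller than sequencing-scale ones
#' (50,000 DP / 750 SP molecules) because simulated repertoires are
#' generated at desk scale; override `depths` to taste.
#'
#' @param groups named integer vector: individuals per life stage.
#' @param cell_types,chains populations and chains to simulate/analyse.
#' @param n_clonotypes per-sample clonotype counts, named by cell-type
#'   class.
#' @param depths rarefaction depths: `shannon_dp`, `shannon_sp` (also used
#'   for gini), `jaccard_dp`, `jaccard_sp` (distinct CDR3s).
#' @param n_repeats resampling repeats (1000 by convention).
#' @param catalog_seed,seed seeds for the shared catalog and the run.
#' @param out_dir optional output directory for TSV/JSON tables.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(groups = c(foetal = 7L, adult = 6L),
                          cell_types = c("DP", "SP4", "SP8"),
                          chains = c("TRB", "TRA"),
                          n_clonotypes = c(DP = 12000L, SP = 3000L),
                          depths = c(shannon_dp = 10000L, shannon_sp = 750L,
                                     jaccard_dp = 2000L, jaccard_sp = 300L),
                          n_repeats = 1000L, catalog_seed = 20260909L,
                          seed = 1L, out_dir = NULL) {
  stopifnot(length(groups) >= 1L, all(groups >= 1L),
            all(depths > 0L), n_repeats >= 1L)
  structure(list(groups = groups, cell_types = cell_types, chains = chains,
                 n_clonotypes = n_clonotypes, depths = depths,
                 n_repeats = as.integer(n_repeats),
                 catalog_seed = as.integer(catalog_seed),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "cohort_config")
}

is_sp <- function(cell_type) cell_type %in% c("SP4", "SP8")

#' Run the full cohort analysis
#'
#' Simulates every (life stage x cell type x chain) group from presets under
#' a shared catalog, then computes: per-sample power-law fits, top-1%
#' clonality, rarefied Shannon/Gini, non-productive fraction, weighted mean
#' insertion length and mean CDR3 length; intra-group Jaccard sharing;
#' between-group scalar comparisons (first two groups, Student/Welch via
#' Levene pre-test); differential VxJ tiles; group-mean V/J heatmap
#' matrices; and PCAs (joint and per life stage) of VxJ counts. Entirely
#' deterministic under `config$seed`. Analyses infeasible at the simulated
#' scale (e.g. a rarefaction depth exceeding a sample) are skipped with a
#' logged reason, and the run continues.
#'
#' @param config a [cohort_config()].
#' @param quiet suppress progress messages.
#' @return A result bundle (list): `catalog`, `samples`, `summary`,
#'   `intra_jaccard`, `scalar_tests`, `differential`, `heatmaps`, `pca`,
#'   `log`. If `config$out_dir` is set, tables are also written there as
#'   TSV/JSON plus a `run_manifest.json` capturing seeds and versions.
#' @export
run_cohort <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  say <- function(...) if (!quiet) message(...)
  log <- character(0)
  note <- function(...) {
    log <<- c(log, sprintf(...))
    say(sprintf(...))
  }
  catalog <- build_catalog(seed = config$catalog_seed)
  stages <- names(config$groups)

  samples <- list()
  for (stage in stages) {
    for (ct in config$cell_types) {
      for (ch in config$chains) {
        ncl <- unname(config$n_clonotypes[[if (is_sp(ct)) "SP" else "DP"]])
        key <- paste(stage, ct, ch, sep = ".")
        say("simulating ", key)
        samples[[key]] <- simulate_group(
          stage, config$groups[[stage]], ct, ch, catalog,
          seed = substream_seed(config$seed, key), n_clonotypes = ncl)
      }
    }
  }

  summary_rows <- list()
  intra <- list()
  for (key in names(samples)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    stage <- parts[1]; ct <- parts[2]; ch <- parts[3]
    depth_sg <- unname(config$depths[[if (is_sp(ct)) "shannon_sp"
                                      else "shannon_dp"]])
    depth_j <- unname(config$depths[[if (is_sp(ct)) "jaccard_sp"
                                     else "jaccard_dp"]])
    for (s in samples[[key]]) {
      cl <- s$clonotypes
      fit <- tryCatch(fit_power_law(cl$abundance),
                      error = function(e) NULL)
      clon <- tryCatch(clonality_stats(s), error = function(e) NULL)
      feasible <- sum(cl$abundance) >= depth_sg
      if (!feasible) {
        note("skip rarefied shannon/gini for %s (depth %d > total %d)",
             s$sample_id, depth_sg, sum(cl$abundance))
      }
      sh <- if (feasible) {
        rarefied_index(s, "shannon", depth_sg, config$n_repeats,
                       seed = substream_seed(config$seed,
                                             paste0("sh.", s$sample_id)))
      } else NULL
      gi <- if (feasible) {
        rarefied_index(s, "gini", depth_sg, config$n_repeats,
                       seed = substream_seed(config$seed,
                                             paste0("gi.", s$sample_id)))
      } else NULL
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        sample_id = s$sample_id, life_stage = stage, cell_type = ct,
        chain = ch, n_clonotypes = nrow(cl),
        total_abundance = sum(cl$abundance),
        alpha = if (is.null(fit)) NA_real_ else fit$alpha,
        top1_share = if (is.null(clon)) NA_real_ else clon$top_share,
        mean_top_abundance = if (is.null(clon)) NA_real_ else
          clon$mean_top_abundance,
        shannon = if (is.null(sh)) NA_real_ else sh$mean,
        gini = if (is.null(gi)) NA_real_ else gi$mean,
        nonproductive = nonproductive_fraction(s),
        mean_insert_bp = weighted_mean_insert_length(s, catalog),
        mean_cdr3_aa = mean_unique_cdr3_length(s),
        stringsAsFactors = FALSE
      )
    }
    if (length(samples[[key]]) >= 2L) {
      ncdr3 <- vapply(samples[[key]], function(s) length(cdr3_set(s)),
                      integer(1))
      if (min(ncdr3) >= depth_j) {
        intra[[key]] <- intra_group_jaccard(
          samples[[key]], depth = depth_j, n_repeats = config$n_repeats,
          seed = substream_seed(config$seed, paste0("jac.", key)))
      } else {
        note("skip intra-group jaccard for %s (depth %d > min CDR3s %d)",
             key, depth_j, min(ncdr3))
      }
    } else {
      note("skip intra-group jaccard for %s (single sample)", key)
    }
  }
  summary_df <- do.call(rbind, summary_rows)

  # between-group comparisons for the first two life stages
  scalar_tests <- NULL
  differential <- list()
  heatmaps <- list()
  if (length(stages) >= 2L) {
    gA <- stages[1]; gB <- stages[2]
    metrics <- c("alpha", "top1_share", "mean_top_abundance", "shannon",
                 "gini", "nonproductive", "mean_insert_bp", "mean_cdr3_aa")
    rows <- list()
    for (ct in config$cell_types) {
      for (ch in config$chains) {
        keyA <- paste(gA, ct, ch, sep = ".")
        keyB <- paste(gB, ct, ch, sep = ".")
        dres <- tryCatch(
          differential_vxj(samples[[keyA]], samples[[keyB]], catalog),
          error = function(e) {
            note("skip differential VxJ for %s %s (%s)", ct, ch,
                 conditionMessage(e))
            NULL
          })
        if (!is.null(dres)) {
          differential[[paste(ct, ch, sep = ".")]] <- dres
        }
        sub <- summary_df[summary_df$cell_type == ct &
                            summary_df$chain == ch, ]
        a <- sub[sub$life_stage == gA, ]
        b <- sub[sub$life_stage == gB, ]
        if (nrow(a) < 2L || nrow(b) < 2L) {
          note("skip scalar tests for %s %s (group size < 2)", ct, ch)
          next
        }
        for (mm in metrics) {
          va <- a[[mm]][is.finite(a[[mm]])]
          vb <- b[[mm]][is.finite(b[[mm]])]
          if (length(va) < 2L || length(vb) < 2L) next
          st <- scalar_group_test(va, vb)
          ci <- function(v) qt(0.975, length(v) - 1) * sd(v) /
            sqrt(length(v))
          rows[[length(rows) + 1L]] <- data.frame(
            cell_type = ct, chain = ch, metric = mm,
            mean_a = mean(va), ci95_a = ci(va),
            mean_b = mean(vb), ci95_b = ci(vb),
            statistic = st$statistic, p_value = st$p_value,
            test = st$test_name, stringsAsFactors = FALSE)
        }
      }
    }
    scalar_tests <- if (length(rows)) do.call(rbind, rows) else NULL
  }

  # group-mean heatmap matrices per chain/axis over (stage x cell type)
  for (ch in config$chains) {
    chain_samples <- list(); labels <- character(0)
    for (key in names(samples)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      if (parts[3] != ch) next
      chain_samples <- c(chain_samples, samples[[key]])
      labels <- c(labels, rep(paste(parts[1], parts[2], sep = "."),
                              length(samples[[key]])))
    }
    for (axis in c("V", "J")) {
      heatmaps[[paste(ch, axis, sep = ".")]] <-
        group_mean_heatmap(chain_samples, labels, axis = axis,
                           weighting = "unique", catalog = catalog)
    }
  }

  # PCA of VxJ counts: joint and per life stage
  pca <- list()
  for (ch in config$chains) {
    subsets <- c(list(all = stages), as.list(setNames(stages, stages)))
    for (nm in names(subsets)) {
      sel <- list()
      for (key in names(samples)) {
        parts <- strsplit(key, ".", fixed = TRUE)[[1]]
        if (parts[3] == ch && parts[1] %in% subsets[[nm]]) {
          sel <- c(sel, samples[[key]])
        }
      }
      if (length(sel) < 3L) next
      fm <- feature_matrix(sel, catalog, features = "vxj",
                           weighting = "unique")
      tm <- suppressWarnings(log_z_transform(fm))
      pca[[paste(ch, nm, sep = ".")]] <- run_pca(tm)
    }
  }

  bundle <- list(catalog = catalog, samples = samples,
                 summary = summary_df, intra_jaccard = intra,
                 scalar_tests = scalar_tests, differential = differential,
                 heatmaps = heatmaps, pca = pca, log = log)

  if (!is.null(config$out_dir)) {
    write_bundle(bundle, config)
  }
  bundle
}

# Emit the tidy tables of a result bundle plus a manifest of seeds/versions.
write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    write.table(df, file.path(config$out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  wt(bundle$summary, "sample_summary.tsv")
  if (!is.null(bundle$scalar_tests)) {
    wt(bundle$scalar_tests, "scalar_tests.tsv")
  }
  for (nm in names(bundle$differential)) {
    wt(bundle$differential[[nm]], paste0("differential_vxj.", nm, ".tsv"))
  }
  for (nm in names(bundle$heatmaps)) {
    m <- bundle$heatmaps[[nm]]$matrix
    wt(data.frame(segment = rownames(m), m, check.names = FALSE),
       paste0("heatmap.", nm, ".tsv"))
  }
  pca_out <- lapply(bundle$pca, function(p) {
    list(variance_fraction = as.list(p$variance_fraction),
         scores = as.data.frame(p$scores))
  })
  jsonlite::write_json(pca_out, file.path(config$out_dir, "pca.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("thymorep")),
    r_version = R.version.string,
    seed = config$seed, catalog_seed = config$catalog_seed,
    groups = as.list(config$groups), depths = as.list(config$depths),
    n_repeats = config$n_repeats, log = bundle$log
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE)
  invisible(NULL)
}
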