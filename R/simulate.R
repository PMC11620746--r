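# V(D)J rearrangement simulator.
#
# The generator emulates the life-stage-dependent structure of thymocyte
# repertoires: geometric chromosomal-proximity bias of the initial V-J draw,
# progressive TRA rearrangement rounds that walk V usage 5'-ward and J usage
# 3'-ward, TRBJ cluster choice, geometric germline trimming and non-template
# insertion (TdT-driven, short in foetal life), zeta-distributed clone sizes,
# per-V lineage selection in SP populations, and a retained out-of-frame
# fraction mimicking incomplete nonsense-mediated decay.

.LIFE_STAGES <- c("foetal", "adult", "adult_hc")
.CELL_TYPES <- c("DP", "CD69negDP", "CD69posDP", "CD3loDP", "CD3hiDP",
                 "SP4", "SP8")
.SP_TYPES <- c("SP4", "SP8")

#' Construct a simulation configuration
#'
#' Low-level constructor with full validation; most users want [preset()].
#'
#' @param life_stage one of `"foetal"`, `"adult"`, `"adult_hc"`.
#' @param cell_type thymocyte population; one of `r paste(.CELL_TYPES,
#'   collapse = ", ")`. Selection acts only on SP4/SP8.
#' @param chain `"TRA"` or `"TRB"`.
#' @param n_clonotypes number of unique clonotypes to emit.
#' @param proximal_bias rate (>= 0) of the geometric preference for
#'   3'-proximal V and 5'-proximal J segments in the initial draw; 0 means
#'   uniform segment choice.
#' @param rearrangement_rounds_mean mean number of additional progressive TRA
#'   rearrangement rounds (Poisson); ignored for TRB.
#' @param insert_mean mean non-template insertion length (bp, geometric).
#' @param deletion_mean mean germline trimming per segment end (bp,
#'   geometric, capped so anchor codons survive).
#' @param clone_size_alpha power-law exponent (> 1) of the clone-size
#'   distribution.
#' @param selection_strength scale (>= 0) of per-V selection in SP
#'   populations.
#' @param nonproductive_rate fraction in \[0, 1\] of the emitted repertoire
#'   consisting of retained out-of-frame rearrangements.
#' @param trbj_cluster1_weight probability that a TRB J segment is drawn from
#'   the 5' TRBJ1 cluster.
#' @param seed integer root seed, split internally into named substreams.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(life_stage, cell_type, chain, n_clonotypes,
                              proximal_bias, rearrangement_rounds_mean,
                              insert_mean, deletion_mean, clone_size_alpha,
                              selection_strength, nonproductive_rate,
                              trbj_cluster1_weight = 0.5, seed = 1L) {
  life_stage <- match.arg(life_stage, .LIFE_STAGES)
  cell_type <- match.arg(cell_type, .CELL_TYPES)
  chain <- match.arg(chain, c("TRA", "TRB"))
  if (!is_count(n_clonotypes, 1L)) {
    stop("'n_clonotypes' must be a positive integer", call. = FALSE)
  }
  rates <- c(proximal_bias = proximal_bias,
             rearrangement_rounds_mean = rearrangement_rounds_mean,
             insert_mean = insert_mean, deletion_mean = deletion_mean,
             selection_strength = selection_strength)
  bad <- !is.finite(rates) | rates < 0
  if (any(bad)) {
    stop("non-finite or negative rate(s): ",
         paste(names(rates)[bad], collapse = ", "), call. = FALSE)
  }
  if (!is.finite(clone_size_alpha) || clone_size_alpha <= 1) {
    stop("'clone_size_alpha' must be finite and > 1", call. = FALSE)
  }
  if (nonproductive_rate < 0 || nonproductive_rate > 1) {
    stop("'nonproductive_rate' must lie in [0, 1]", call. = FALSE)
  }
  if (trbj_cluster1_weight < 0 || trbj_cluster1_weight > 1) {
    stop("'trbj_cluster1_weight' must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    life_stage = life_stage, cell_type = cell_type, chain = chain,
    n_clonotypes = as.integer(n_clonotypes),
    proximal_bias = proximal_bias,
    rearrangement_rounds_mean = rearrangement_rounds_mean,
    insert_mean = insert_mean, deletion_mean = deletion_mean,
    clone_size_alpha = clone_size_alpha,
    selection_strength = selection_strength,
    nonproductive_rate = nonproductive_rate,
    trbj_cluster1_weight = trbj_cluster1_weight,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# Default parameter bundles. Directions follow the described biology: the
# foetal thymus lacks TdT (short insertions), undergoes fewer progressive TRA
# rearrangement rounds (stronger 3'V/5'J proximal usage), shows more clonal
# expansion (lower alpha), weaker MHC-driven selection, a mild TRBJ1-cluster
# preference, and retains a higher out-of-frame fraction. The
# hydrocortisone-recovery preset combines adult insertion machinery with
# foetal-like (synchronised, early) rearrangement round counts. Magnitudes
# are simulator choices, documented in the methods vignette.
# insert_mean is chain-aware: beta-chain "inserts" fold in D-region
# nucleotides, so they stay non-zero even in the TdT-free foetal thymus.
.PRESETS <- list(
  foetal = list(proximal_bias = 0.25, rearrangement_rounds_mean = 0.3,
                insert_mean = c(TRA = 1.0, TRB = 2.0), deletion_mean = 0.08,
                clone_size_alpha = 2.2, selection_strength = 0.5,
                nonproductive_rate = 0.12, trbj_cluster1_weight = 0.65),
  adult = list(proximal_bias = 0.10, rearrangement_rounds_mean = 2.0,
               insert_mean = c(TRA = 3.5, TRB = 4.5), deletion_mean = 0.08,
               clone_size_alpha = 3.2, selection_strength = 2.0,
               nonproductive_rate = 0.08, trbj_cluster1_weight = 0.50),
  adult_hc = list(proximal_bias = 0.10, rearrangement_rounds_mean = 0.3,
                  insert_mean = c(TRA = 3.5, TRB = 4.5),
                  deletion_mean = 0.08,
                  clone_size_alpha = 3.2, selection_strength = 2.0,
                  nonproductive_rate = 0.08, trbj_cluster1_weight = 0.50)
)

#' Default simulation configurations per life stage
#'
#' @param name `"foetal"`, `"adult"` or `"adult_hc"` (hydrocortisone-treated
#'   young adult, recovering DP cohort).
#' @param cell_type,chain as in [simulation_config()].
#' @param n_clonotypes optional override. Defaults reflect the smaller, less
#'   diverse foetal repertoires: 4500 (foetal DP), 12000 (adult DP), 1500
#'   (foetal SP), 3000 (adult SP).
#' @param seed root seed.
#' @return A `simulation_config`.
#' @export
#' @examples
#' preset("foetal")$insert_mean < preset("adult")$insert_mean
preset <- function(name, cell_type = "DP", chain = "TRB",
                   n_clonotypes = NULL, seed = 1L) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.PRESETS)) {
    stop("unknown preset; use one of: ",
         paste(names(.PRESETS), collapse = ", "), call. = FALSE)
  }
  cell_type <- match.arg(cell_type, .CELL_TYPES)
  chain <- match.arg(chain, c("TRA", "TRB"))
  if (is.null(n_clonotypes)) {
    n_clonotypes <- if (cell_type %in% .SP_TYPES) {
      if (name == "foetal") 1500L else 3000L
    } else {
      if (name == "foetal") 4500L else 12000L
    }
  }
  p <- .PRESETS[[name]]
  simulation_config(
    life_stage = name, cell_type = cell_type, chain = chain,
    n_clonotypes = n_clonotypes,
    proximal_bias = p$proximal_bias,
    rearrangement_rounds_mean = p$rearrangement_rounds_mean,
    insert_mean = unname(p$insert_mean[[chain]]),
    deletion_mean = p$deletion_mean,
    clone_size_alpha = p$clone_size_alpha,
    selection_strength = p$selection_strength,
    nonproductive_rate = p$nonproductive_rate,
    trbj_cluster1_weight = p$trbj_cluster1_weight,
    seed = seed
  )
}

# geometric distance from the proximal end; bias 0 -> uniform over n ranks
proximal_distance <- function(n_draw, bias, n_ranks) {
  if (bias == 0) {
    sample.int(n_ranks, n_draw, replace = TRUE) - 1L
  } else {
    pmin(rgeom(n_draw, 1 - exp(-bias)), n_ranks - 1L)
  }
}

#' Draw TRA V-J segment pairs with progressive rearrangement
#'
#' The initial draw prefers the 3' end of the TRAV array and the 5' end of
#' the TRAJ array (geometric in rank distance, rate `proximal_bias`). Each of
#' `Poisson(rearrangement_rounds_mean)` additional rounds then moves the V
#' index 5'-ward and the J index 3'-ward by independent `1 + geometric(0.5)`
#' steps, clamped to the array bounds; only the final pair is emitted,
#' matching excision of intermediate rearrangements. Uses the current RNG
#' stream.
#'
#' @param catalog a `segment_catalog` with TRA segments.
#' @param config a `simulation_config`.
#' @param n number of pairs to draw.
#' @return Integer matrix with columns `v_index`, `j_index` (0-based
#'   chromosomal indices).
#' @export
draw_tra_pair <- function(catalog, config, n = 1L) {
  v <- catalog_segments(catalog, "TRA", "V")
  j <- catalog_segments(catalog, "TRA", "J")
  if (nrow(v) == 0L || nrow(j) == 0L) {
    stop("catalog has no TRA segments", call. = FALSE)
  }
  n_v <- nrow(v); n_j <- nrow(j)
  d_v <- proximal_distance(n, config$proximal_bias, n_v)
  d_j <- proximal_distance(n, config$proximal_bias, n_j)
  v_idx <- (n_v - 1L) - d_v
  j_idx <- d_j
  rounds <- rpois(n, config$rearrangement_rounds_mean)
  # each round moves by 1 + geometric(0.5); rnbinom needs size > 0
  geom_steps <- function(r) {
    s <- integer(length(r))
    pos <- r > 0L
    s[pos] <- r[pos] + rnbinom(sum(pos), size = r[pos], prob = 0.5)
    s
  }
  step_v <- geom_steps(rounds)
  step_j <- geom_steps(rounds)
  cbind(v_index = pmax(v_idx - step_v, 0L),
        j_index = pmin(j_idx + step_j, n_j - 1L))
}

#' Draw TRB V-J segment pairs
#'
#' Single-round draw: V position is biased toward the 3' end of the TRBV
#' array as in [draw_tra_pair()]; J is drawn by first choosing the TRBJ
#' cluster (cluster 1 with probability `trbj_cluster1_weight`) and then
#' uniformly within the cluster. Uses the current RNG stream.
#'
#' @inheritParams draw_tra_pair
#' @return Integer matrix with columns `v_index`, `j_index` (0-based).
#' @export
draw_trb_pair <- function(catalog, config, n = 1L) {
  v <- catalog_segments(catalog, "TRB", "V")
  j <- catalog_segments(catalog, "TRB", "J")
  if (nrow(v) == 0L || nrow(j) == 0L) {
    stop("catalog has no TRB segments", call. = FALSE)
  }
  n_v <- nrow(v)
  d_v <- proximal_distance(n, config$proximal_bias, n_v)
  v_idx <- (n_v - 1L) - d_v
  c1 <- which(j$cluster_id == 1L)
  c2 <- which(j$cluster_id == 2L)
  use1 <- runif(n) < config$trbj_cluster1_weight
  j_pos <- integer(n)
  j_pos[use1] <- c1[sample.int(length(c1), sum(use1), replace = TRUE)]
  j_pos[!use1] <- c2[sample.int(length(c2), sum(!use1), replace = TRUE)]
  cbind(v_index = v_idx, j_index = j$chromosomal_index[j_pos])
}

# Vectorised junction former over germline junction-region sequences.
# Trimming and insertion are purely geometric; deletion is capped so the
# anchor codon at each end always survives.
make_junctions <- function(vseq, jseq, config) {
  n <- length(vseq)
  p_del <- 1 / (1 + config$deletion_mean)
  p_ins <- 1 / (1 + config$insert_mean)
  v_del <- pmin(rgeom(n, p_del), nchar(vseq) - 3L)
  j_del <- pmin(rgeom(n, p_del), nchar(jseq) - 3L)
  ins <- rgeom(n, p_ins)
  ins_seq <- random_nt_vec(ins)
  junction <- paste0(substr(vseq, 1L, nchar(vseq) - v_del), ins_seq,
                     substr(jseq, j_del + 1L, nchar(jseq)))
  list(junction_nt = junction,
       truth = data.frame(v_deleted = v_del, j_deleted = j_del,
                          insert_len = ins, insert_seq = ins_seq,
                          stringsAsFactors = FALSE))
}

#' Form a single V-J junction with ground truth
#'
#' Trims a geometric(`deletion_mean`) number of basepairs from the V 3' end
#' and the J 5' end (capped so the conserved anchor codons survive), inserts
#' a geometric(`insert_mean`) number of uniform-random nucleotides, and
#' returns the concatenation together with the true decomposition. For the
#' beta chain the D-region nucleotides are folded into the insert, matching
#' the measurement convention used downstream. Uses the current RNG stream.
#'
#' @param v,j single rows of the catalog `segments` table (a V and a J of
#'   the same chain).
#' @param config a `simulation_config`.
#' @return List with elements `junction_nt` and `truth` (fields `v_deleted`,
#'   `j_deleted`, `insert_len`, `insert_seq`).
#' @export
make_junction <- function(v, j, config) {
  stopifnot(v$kind == "V", j$kind == "J", v$chain == j$chain)
  out <- make_junctions(v$junction_seq, j$junction_seq, config)
  list(junction_nt = out$junction_nt, truth = as.list(out$truth[1L, ]))
}

#' Draw clone sizes from a discrete power law
#'
#' I.i.d. draws from the zeta distribution on `k >= 1`,
#' \eqn{P(K = k) \propto k^{-\alpha}}, via inverse-CDF on the
#' Hurwitz-zeta-normalised pmf. Uses the current RNG stream.
#'
#' @param n_clonotypes number of draws.
#' @param alpha exponent, must be > 1 (`Inf` gives all ones).
#' @return Integer vector of abundances.
#' @export
assign_clone_sizes <- function(n_clonotypes, alpha) {
  if (!is_count(n_clonotypes, 1L)) {
    stop("'n_clonotypes' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 1) {
    stop("'alpha' must be > 1", call. = FALSE)
  }
  rzeta(n_clonotypes, alpha)
}

#' Thin a clonotype table by per-V lineage selection
#'
#' Models MHC-restricted positive selection: each V segment carries fixed
#' per-lineage weights (seeded in the catalog); a clonotype with V weight `w`
#' is retained with probability `(w / max(w))^selection_strength` for the
#' SP4 or SP8 lineage. DP-class populations pass through unchanged, and
#' `selection_strength = 0` retains everything. Uses the current RNG stream.
#'
#' @param clonotypes data frame with at least a `v_name` column.
#' @param cell_type thymocyte population.
#' @param selection_strength non-negative scale.
#' @param catalog a `segment_catalog`.
#' @return Subset of `clonotypes` (never invents rows).
#' @export
apply_selection <- function(clonotypes, cell_type, selection_strength,
                            catalog) {
  cell_type <- match.arg(cell_type, .CELL_TYPES)
  if (!cell_type %in% .SP_TYPES || selection_strength == 0 ||
      nrow(clonotypes) == 0L) {
    return(clonotypes)
  }
  wtab <- catalog$selection_weights
  col <- if (cell_type == "SP4") "w_sp4" else "w_sp8"
  idx <- match(clonotypes$v_name, wtab$name)
  if (anyNA(idx)) {
    stop("V segment(s) absent from catalog: ",
         paste(unique(clonotypes$v_name[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  w <- wtab[[col]][idx]
  p_keep <- (w / max(wtab[[col]]))^selection_strength
  clonotypes[runif(nrow(clonotypes)) < p_keep, , drop = FALSE]
}

#' Simulate one repertoire sample
#'
#' Composes the full generative model: V-J pair draws, junction formation,
#' lineage selection (SP populations), deduplication to unique clonotypes,
#' composition of the productive/non-productive mix (the retained
#' out-of-frame fraction is Binomial(`n_clonotypes`, `nonproductive_rate`),
#' mimicking incomplete nonsense-mediated decay), and zeta-distributed clone
#' sizes. Fully deterministic given (`config`, `catalog`): the root seed in
#' `config` is split into named substreams per stage.
#'
#' @param config a `simulation_config`.
#' @param catalog a `segment_catalog`.
#' @param sample_id optional identifier; a descriptive default is built from
#'   the configuration.
#' @return A [repertoire_sample()] whose `clonotypes` table carries
#'   ground-truth columns `insert_len`, `v_deleted`, `j_deleted`,
#'   `insert_seq`.
#' @export
simulate_sample <- function(config, catalog, sample_id = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(catalog, "segment_catalog"))
  n <- config$n_clonotypes
  vseg <- catalog_segments(catalog, config$chain, "V")
  jseg <- catalog_segments(catalog, config$chain, "J")
  n_nonprod <- with_seed(substream_seed(config$seed, "compose"),
                         rbinom(1L, n, config$nonproductive_rate))
  n_prod <- n - n_nonprod

  prod_pool <- NULL
  nonprod_pool <- NULL
  seen <- character(0)
  round <- 0L
  yield <- 0.3   # unique-clonotype yield per candidate, updated per round
  while ((is.null(prod_pool) || nrow(prod_pool) < n_prod ||
          nrow(nonprod_pool) < n_nonprod) && round < 15L) {
    round <- round + 1L
    short_p <- max(0L, n_prod -
                     if (is.null(prod_pool)) 0L else nrow(prod_pool))
    short_n <- max(0L, n_nonprod -
                     if (is.null(nonprod_pool)) 0L else nrow(nonprod_pool))
    m <- max(2000L, min(300000L,
                        ceiling(3 * (short_p + short_n) /
                                  max(yield, 0.005))))
    pairs <- with_seed(substream_seed(config$seed, paste0("segments", round)),
      if (config$chain == "TRA") draw_tra_pair(catalog, config, m)
      else draw_trb_pair(catalog, config, m))
    vrow <- match(pairs[, "v_index"], vseg$chromosomal_index)
    jrow <- match(pairs[, "j_index"], jseg$chromosomal_index)
    jn <- with_seed(substream_seed(config$seed, paste0("junction", round)),
                    make_junctions(vseg$junction_seq[vrow],
                                   jseg$junction_seq[jrow], config))
    cand <- data.frame(
      v_name = vseg$name[vrow], j_name = jseg$name[jrow],
      junction_nt = jn$junction_nt,
      stringsAsFactors = FALSE
    )
    cand <- cbind(cand, jn$truth)
    cand <- with_seed(substream_seed(config$seed, paste0("selection", round)),
                      apply_selection(cand, config$cell_type,
                                      config$selection_strength, catalog))
    key <- paste(cand$v_name, cand$j_name, cand$junction_nt, sep = "\r")
    keep <- !duplicated(key) & !(key %in% seen)
    cand <- cand[keep, , drop = FALSE]
    seen <- c(seen, key[keep])
    flags <- productivity_flags(cand$junction_nt)
    prod_pool <- rbind(prod_pool, cand[flags, , drop = FALSE])
    nonprod_pool <- rbind(nonprod_pool, cand[!flags, , drop = FALSE])
    yield <- max(nrow(cand) / m, 0.5 * yield)
  }
  if (nrow(prod_pool) < n_prod || nrow(nonprod_pool) < n_nonprod) {
    warning("catalog too small to supply ", n, " unique clonotypes; ",
            "emitting ", nrow(prod_pool) + nrow(nonprod_pool), call. = FALSE)
    n_prod <- min(n_prod, nrow(prod_pool))
    n_nonprod <- min(n_nonprod, nrow(nonprod_pool))
  }
  cl <- rbind(head(prod_pool, n_prod), head(nonprod_pool, n_nonprod))
  rownames(cl) <- NULL
  cl$productive <- rep(c(TRUE, FALSE), c(n_prod, n_nonprod))
  cl$junction_aa <- ""
  cl$junction_aa[cl$productive] <- translate_nt(cl$junction_nt[cl$productive])
  cl$abundance <- with_seed(substream_seed(config$seed, "abundance"),
                            assign_clone_sizes(nrow(cl),
                                               config$clone_size_alpha))
  if (is.null(sample_id)) {
    sample_id <- paste(config$life_stage, config$cell_type, config$chain,
                       config$seed, sep = "_")
  }
  repertoire_sample(
    sample_id = sample_id, life_stage = config$life_stage,
    cell_type = config$cell_type, chain = config$chain,
    clonotypes = cl[, c("v_name", "j_name", "junction_nt", "junction_aa",
                        "abundance", "productive", "insert_len", "v_deleted",
                        "j_deleted", "insert_seq")]
  )
}

#' Simulate a group of individuals
#'
#' Convenience wrapper producing one sample per individual with
#' per-individual sub-seeds derived from `seed`.
#'
#' @param name preset name (`"foetal"`, `"adult"`, `"adult_hc"`).
#' @param n_individuals number of mice/embryos.
#' @param cell_type,chain passed to [preset()].
#' @param catalog a `segment_catalog`.
#' @param seed root seed for the group.
#' @param n_clonotypes optional per-sample clonotype count override.
#' @return List of `repertoire_sample` objects.
#' @export
simulate_group <- function(name, n_individuals, cell_type, chain, catalog,
                           seed, n_clonotypes = NULL) {
  lapply(seq_len(n_individuals), function(i) {
    cfg <- preset(name, cell_type = cell_type, chain = chain,
                  n_clonotypes = n_clonotypes,
                  seed = substream_seed(seed, paste(name, cell_type, chain,
                                                    i, sep = "|")))
    simulate_sample(cfg, catalog,
                    sample_id = paste(name, cell_type, chain, i, sep = "_"))
  })
}
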