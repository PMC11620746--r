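# Proportional V/J and VxJ usage in chromosomal order, group-mean heatmap
# assembly, and the differential VxJ tiling procedure with BH-FDR control.

#' Proportional V or J segment usage of one sample
#'
#' Proportions over the full catalog axis in chromosomal (5'->3') order;
#' segments unused by the sample get 0. `"unique"` weighting counts each
#' clonotype once; `"total"` weights clonotypes by abundance.
#'
#' @param sample a `repertoire_sample`.
#' @param axis `"V"` or `"J"`.
#' @param weighting `"unique"` or `"total"`.
#' @param catalog a `segment_catalog`.
#' @return Named numeric vector summing to 1, ordered by
#'   `chromosomal_index`.
#' @export
usage_vector <- function(sample, axis = c("V", "J"),
                         weighting = c("unique", "total"), catalog) {
  axis <- match.arg(axis)
  weighting <- match.arg(weighting)
  segs <- catalog_segments(catalog, sample$chain, axis)
  cl <- sample$clonotypes
  key <- if (axis == "V") cl$v_name else cl$j_name
  idx <- match(key, segs$name)
  if (anyNA(idx)) {
    stop("segment name(s) not in catalog: ",
         paste(unique(key[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  w <- if (weighting == "unique") rep(1, nrow(cl)) else cl$abundance
  counts <- vapply(seq_len(nrow(segs)), function(i) sum(w[idx == i]),
                   numeric(1))
  setNames(counts / sum(counts), segs$name)
}

#' V x J combination counts of one sample
#'
#' Counts over the full V x J grid of the sample's chain, rows and columns in
#' chromosomal order. Marginal sums reproduce the (unnormalised)
#' [usage_vector()] counts.
#'
#' @inheritParams usage_vector
#' @return Numeric matrix (V segments x J segments).
#' @export
vxj_matrix <- function(sample, weighting = c("unique", "total"), catalog) {
  weighting <- match.arg(weighting)
  vsegs <- catalog_segments(catalog, sample$chain, "V")
  jsegs <- catalog_segments(catalog, sample$chain, "J")
  cl <- sample$clonotypes
  m <- matrix(0, nrow(vsegs), ncol = nrow(jsegs),
              dimnames = list(vsegs$name, jsegs$name))
  if (nrow(cl) == 0L) return(m)
  vi <- match(cl$v_name, vsegs$name)
  ji <- match(cl$j_name, jsegs$name)
  if (anyNA(vi) || anyNA(ji)) {
    bad <- unique(c(cl$v_name[is.na(vi)], cl$j_name[is.na(ji)]))
    stop("segment name(s) not in catalog: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  w <- if (weighting == "unique") rep(1, nrow(cl)) else cl$abundance
  cell <- (ji - 1L) * nrow(vsegs) + vi
  acc <- rowsum(as.numeric(w), cell)
  m[as.integer(rownames(acc))] <- acc[, 1L]
  m
}

#' Group-mean usage matrix with column dendrogram
#'
#' Columns are group-mean proportional usage vectors (one per group, the
#' arithmetic mean of member samples' [usage_vector()]s), clustered by
#' average-linkage hierarchical clustering on Euclidean distance. Rows stay
#' in fixed chromosomal order and are never clustered.
#'
#' @param samples list of `repertoire_sample` objects (one chain).
#' @param groups character vector of group labels, one per sample.
#' @param axis,weighting,catalog as in [usage_vector()].
#' @return List with `matrix` (segments x groups) and `dendrogram` (an
#'   `hclust` object, or `NULL` for a single group).
#' @export
group_mean_heatmap <- function(samples, groups, axis = c("V", "J"),
                               weighting = c("unique", "total"), catalog) {
  axis <- match.arg(axis)
  weighting <- match.arg(weighting)
  if (length(samples) != length(groups) || length(samples) == 0L) {
    stop("'groups' must label each sample; need >= 1 sample", call. = FALSE)
  }
  lvls <- unique(groups)
  cols <- lapply(lvls, function(g) {
    members <- samples[groups == g]
    vecs <- vapply(members, usage_vector, numeric(length(
      catalog_segments(catalog, members[[1]]$chain, axis)$name)),
      axis = axis, weighting = weighting, catalog = catalog)
    rowMeans(as.matrix(vecs))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- lvls
  dend <- if (length(lvls) >= 2L) {
    hclust(dist(t(m), method = "euclidean"), method = "average")
  } else {
    NULL
  }
  list(matrix = m, dendrogram = dend)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values `q_(i) = min_{j >= i} (m p_(j) / j)` on the sorted
#' p-values, mapped back to input order and capped at 1.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return Numeric vector of q-values in input order.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.04, 0.03, 0.002))
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  ord <- order(p_values)
  q_sorted <- rev(cummin(rev(m * p_values[ord] / seq_len(m))))
  pmin(q_sorted, 1)[order(ord)]
}

#' Differential V x J usage tiling between two groups
#'
#' Per combination: a sample "detects" it iff its count is > 0. Combinations
#' undetected in a whole group get tile `absent_A`/`absent_B`/`absent_both`;
#' combinations detected in fewer than `min_detected` samples of either
#' group are `not_compared`; the rest are compared by an unpaired Student's
#' t-test on per-sample proportions, with Benjamini-Hochberg adjustment
#' applied jointly across all compared combinations of this panel. Tiles
#' with `q < alpha` are `increased` (higher mean proportion in group A) or
#' `decreased`; other compared tiles are `no_change`.
#'
#' @param samples_a,samples_b lists of `repertoire_sample` objects.
#' @param catalog a `segment_catalog`.
#' @param weighting `"total"` (abundance-weighted, the convention of VxJ
#'   tile panels)
#'   or `"unique"`.
#' @param min_detected minimum detecting samples per group for comparison.
#' @param alpha FDR threshold.
#' @return Data frame with one row per V x J cell: `v`, `j`, `v_index`,
#'   `j_index`, `mean_a`, `mean_b`, `p_value`, `q_value`, `tile`.
#' @export
differential_vxj <- function(samples_a, samples_b, catalog,
                             weighting = c("total", "unique"),
                             min_detected = 3L, alpha = 0.05) {
  weighting <- match.arg(weighting)
  if (length(samples_a) < min_detected || length(samples_b) < min_detected) {
    stop("each group needs at least 'min_detected' samples", call. = FALSE)
  }
  chain <- samples_a[[1]]$chain
  vsegs <- catalog_segments(catalog, chain, "V")
  jsegs <- catalog_segments(catalog, chain, "J")
  prop_mats <- function(samps) {
    vapply(samps, function(s) {
      m <- vxj_matrix(s, weighting = weighting, catalog = catalog)
      as.vector(m) / sum(m)
    }, numeric(nrow(vsegs) * nrow(jsegs)))
  }
  pa <- prop_mats(samples_a)   # cells x samples
  pb <- prop_mats(samples_b)
  det_a <- rowSums(pa > 0)
  det_b <- rowSums(pb > 0)
  n_cells <- nrow(pa)
  tile <- rep("not_compared", n_cells)
  tile[det_a == 0 & det_b == 0] <- "absent_both"
  tile[det_a == 0 & det_b > 0] <- "absent_A"
  tile[det_a > 0 & det_b == 0] <- "absent_B"
  cmp <- det_a >= min_detected & det_b >= min_detected
  p <- rep(NA_real_, n_cells)
  if (any(cmp)) {
    na <- ncol(pa); nb <- ncol(pb)
    ma <- rowMeans(pa[cmp, , drop = FALSE])
    mb <- rowMeans(pb[cmp, , drop = FALSE])
    va <- apply(pa[cmp, , drop = FALSE], 1L, var)
    vb <- apply(pb[cmp, , drop = FALSE], 1L, var)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    tstat <- (ma - mb) / se
    pv <- 2 * pt(-abs(tstat), df = na + nb - 2)
    pv[se == 0] <- 1  # identical constant proportions
    p[cmp] <- pv
  }
  q <- rep(NA_real_, n_cells)
  if (any(cmp)) q[cmp] <- benjamini_hochberg(p[cmp])
  mean_a <- rowMeans(pa)
  mean_b <- rowMeans(pb)
  sig <- cmp & !is.na(q) & q < alpha
  tile[cmp] <- "no_change"
  tile[sig & mean_a > mean_b] <- "increased"
  tile[sig & mean_a < mean_b] <- "decreased"
  data.frame(
    v = rep(vsegs$name, times = nrow(jsegs)),
    j = rep(jsegs$name, each = nrow(vsegs)),
    v_index = rep(vsegs$chromosomal_index, times = nrow(jsegs)),
    j_index = rep(jsegs$chromosomal_index, each = nrow(vsegs)),
    mean_a = mean_a, mean_b = mean_b, p_value = p, q_value = q,
    tile = tile, stringsAsFactors = FALSE
  )
}
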