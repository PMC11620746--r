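# The multivariate procedure: log10 transform with pseudocount on zeros,
# per-feature z-scoring, PCA by SVD, variance explained, top contributors.

#' Assemble a samples x features count matrix
#'
#' Flattens each sample's V x J grid (or CDR1 x CDR2 distribution scaled to
#' counts) into one feature row per sample. Features that are zero in every
#' sample are removed.
#'
#' @param samples list of `repertoire_sample` objects of one chain.
#' @param catalog a `segment_catalog`.
#' @param features `"vxj"` or `"cdr12"`.
#' @param weighting `"unique"` (counts of unique clonotypes, the usual PCA
#'   input) or `"total"`.
#' @return Numeric matrix, rownames = sample ids.
#' @export
feature_matrix <- function(samples, catalog, features = c("vxj", "cdr12"),
                           weighting = c("unique", "total")) {
  features <- match.arg(features)
  weighting <- match.arg(weighting)
  rows <- lapply(samples, function(s) {
    if (features == "vxj") {
      m <- vxj_matrix(s, weighting = weighting, catalog = catalog)
      v <- as.vector(m)
      names(v) <- as.vector(outer(rownames(m), colnames(m), paste,
                                  sep = "."))
      v
    } else {
      p <- cdr12_counts(s, catalog, weighting = weighting)
      n <- nrow(s$clonotypes)
      w <- if (weighting == "unique") n else sum(s$clonotypes$abundance)
      p * w
    }
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(samples, function(s) s$sample_id, character(1))
  m[, colSums(m) > 0, drop = FALSE]
}

#' Log10 + pseudocount + z-score transform
#'
#' Zero counts are replaced by `pseudocount` (applied to zeros only), all
#' values are log10-transformed, and each feature (column) is centred and
#' scaled to unit standard deviation. Features with zero standard deviation
#' are dropped with a warning.
#'
#' @param count_matrix samples x features matrix of non-negative counts.
#' @param pseudocount value substituted for unobserved counts (default
#'   0.01, i.e. log10 value -2).
#' @return Transformed matrix; dropped feature names are recorded in the
#'   `"dropped"` attribute.
#' @export
log_z_transform <- function(count_matrix, pseudocount = 0.01) {
  m <- as.matrix(count_matrix)
  if (any(m < 0)) stop("negative counts", call. = FALSE)
  m[m == 0] <- pseudocount
  m <- log10(m)
  sds <- apply(m, 2L, sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warning(sum(drop), " constant feature(s) dropped", call. = FALSE)
  }
  m <- m[, !drop, drop = FALSE]
  out <- scale(m)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "dropped") <- colnames(count_matrix)[drop]
  out
}

#' Principal component analysis by singular-value decomposition
#'
#' Columns are centred, the SVD taken, and per-component variance fractions
#' computed as \eqn{\sigma_k^2 / \sum \sigma^2}. The sign of each component
#' is fixed so that its largest-magnitude loading is positive.
#'
#' @param m numeric matrix, samples x features (>= 2 of each); typically the
#'   output of [log_z_transform()].
#' @return Object of class `pca_result`: list with `scores`
#'   (samples x components), `loadings` (features x components),
#'   `variance_fraction`, `contributions` (squared-loading share per
#'   component), `feature_names`, `sample_ids`.
#' @export
run_pca <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 samples and 2 features", call. = FALSE)
  }
  centred <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(centred)
  flip <- vapply(seq_len(ncol(sv$v)), function(k) {
    l <- sv$v[, k]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(sv$v, 2L, flip, `*`)
  scores <- sweep(sv$u %*% diag(sv$d, nrow = length(sv$d)), 2L, flip, `*`)
  varfrac <- sv$d^2 / sum(sv$d^2)
  contrib <- loadings^2
  rownames(loadings) <- colnames(m)
  rownames(contrib) <- colnames(m)
  rownames(scores) <- rownames(m)
  cn <- paste0("PC", seq_along(varfrac))
  colnames(loadings) <- colnames(scores) <- colnames(contrib) <- cn
  names(varfrac) <- cn
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = varfrac, contributions = contrib,
                 feature_names = colnames(m), sample_ids = rownames(m)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5L, length(x$variance_fraction))
  cat("<pca_result>", length(x$sample_ids), "samples x",
      length(x$feature_names), "features\n")
  cat("variance explained:",
      paste(sprintf("%s %.1f%%", names(x$variance_fraction)[1:k],
                    100 * x$variance_fraction[1:k]), collapse = ", "), "\n")
  invisible(x)
}

#' Features contributing most to a principal component
#'
#' Ranks features by squared-loading share of the component, reporting the
#' signed loading so the positive/negative side is identifiable.
#'
#' @param result a `pca_result`.
#' @param component component index or `"PCk"` name.
#' @param n number of features to return; truncated with a warning if it
#'   exceeds the feature count.
#' @return Data frame with `feature`, `loading`, `contribution`, ordered by
#'   decreasing contribution.
#' @export
top_contributors <- function(result, component = 1L, n = 10L) {
  stopifnot(inherits(result, "pca_result"))
  if (is.character(component)) {
    component <- match(component, colnames(result$loadings))
  }
  if (is.na(component) || component < 1L ||
      component > ncol(result$loadings)) {
    stop("no such component", call. = FALSE)
  }
  p <- nrow(result$loadings)
  if (n > p) {
    warning("only ", p, " features available", call. = FALSE)
    n <- p
  }
  contrib <- result$contributions[, component]
  ord <- order(contrib, decreasing = TRUE)[seq_len(n)]
  data.frame(feature = result$feature_names[ord],
             loading = result$loadings[ord, component],
             contribution = contrib[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}
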