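# Rarefaction engine and resampled diversity indices.

#' Rarefy a repertoire to a fixed molecule depth
#'
#' Samples `depth` molecules without replacement from the UMI-level multiset
#' (each molecule equally likely), returning per-clonotype counts that sum to
#' `depth`. Uses the current RNG stream.
#'
#' @param sample a `repertoire_sample`, or a bare numeric abundance vector.
#' @param depth subsample size; at most the total abundance.
#' @return Integer vector of per-clonotype counts (same order and length as
#'   the input clonotypes; zeros where a clonotype was not drawn).
#' @export
rarefy <- function(sample, depth) {
  counts <- if (inherits(sample, "repertoire_sample")) {
    sample$clonotypes$abundance
  } else {
    sample
  }
  total <- sum(counts)
  if (!is_count(depth, 1L) || depth > total) {
    stop("'depth' must be a positive integer <= total abundance (",
         total, ")", call. = FALSE)
  }
  if (depth == total) return(as.integer(counts))
  draws <- sample.int(total, depth)
  cs <- cumsum(counts)
  idx <- findInterval(draws - 0.5, cs) + 1L
  tabulate(idx, nbins = length(counts))
}

#' Shannon entropy of an abundance vector
#'
#' \eqn{H = -\sum p_i \log p_i} with natural logarithm by default and the
#' convention \eqn{0 \log 0 = 0}.
#'
#' @param counts non-negative abundances, positive sum.
#' @param base logarithm base (natural log by default, as in vegan).
#' @return Numeric scalar.
#' @export
#' @examples
#' shannon_entropy(c(2, 1, 1))
shannon_entropy <- function(counts, base = exp(1)) {
  if (any(counts < 0) || sum(counts) <= 0) {
    stop("'counts' must be non-negative with positive sum", call. = FALSE)
  }
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Gini index of an abundance vector
#'
#' Mean absolute difference form
#' \eqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x)} over the
#' unique-clonotype abundance vector, computed via the equivalent sorted-sum
#' formula. 0 means a perfectly even repertoire.
#'
#' @param counts non-negative abundances, positive sum, length >= 2.
#' @return Numeric scalar in `[0, (n - 1) / n]`.
#' @export
gini_index <- function(counts) {
  n <- length(counts)
  if (n < 2L) stop("need at least 2 counts", call. = FALSE)
  if (any(counts < 0) || sum(counts) <= 0) {
    stop("'counts' must be non-negative with positive sum", call. = FALSE)
  }
  x <- sort(as.numeric(counts))
  (2 * sum(seq_len(n) * x) - (n + 1) * sum(x)) / (n * sum(x))
}

#' Jaccard similarity of two sets
#'
#' \eqn{|A \cap B| / |A \cup B|} on the distinct elements of each input.
#'
#' @param set_a,set_b character vectors (e.g. CDR3 amino-acid sequences);
#'   duplicates are ignored.
#' @return Numeric scalar in `[0, 1]`.
#' @export
jaccard_similarity <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  if (length(a) == 0L && length(b) == 0L) {
    stop("both sets empty", call. = FALSE)
  }
  length(intersect(a, b)) / length(union(a, b))
}

# distinct CDR3 strings of a sample (amino-acid default; nucleotide mode
# uses the junction; aa mode uses productive clonotypes only)
cdr3_set <- function(sample, level = c("aa", "nt")) {
  level <- match.arg(level)
  cl <- sample$clonotypes
  if (level == "aa") {
    unique(cl$junction_aa[cl$productive & !is.na(cl$junction_aa) &
                            cl$junction_aa != ""])
  } else {
    unique(cl$junction_nt)
  }
}

#' Rarefied diversity index
#'
#' For `shannon` and `gini`, each repeat rarefies the sample to `depth`
#' molecules and evaluates the index on the subsampled abundance vector
#' (clonotypes absent from the subsample are excluded, not zero-padded). For
#' `jaccard`, each repeat subsamples `depth` distinct CDR3 strings uniformly
#' without replacement from each of two samples and evaluates the set
#' similarity; set `weighted = TRUE` for abundance-weighted CDR3 draws.
#'
#' @param sample a `repertoire_sample`.
#' @param statistic `"shannon"`, `"gini"`, or `"jaccard"`.
#' @param depth molecule depth (shannon/gini) or number of distinct CDR3s
#'   (jaccard).
#' @param n_repeats number of resampling repeats (1000 by convention).
#' @param seed integer seed; the caller's RNG state is untouched.
#' @param sample2 second sample (jaccard only).
#' @param level CDR3 level for jaccard: `"aa"` (default) or `"nt"`.
#' @param weighted abundance-weighted CDR3 subsampling for jaccard.
#' @return Object of class `rarefied_statistic`: list with `statistic`,
#'   `depth`, `n_repeats`, `seed`, `mean`, `per_repeat`.
#' @export
rarefied_index <- function(sample, statistic = c("shannon", "gini",
                                                 "jaccard"),
                           depth, n_repeats = 1000L, seed = 1L,
                           sample2 = NULL, level = "aa", weighted = FALSE) {
  statistic <- match.arg(statistic)
  if (!is_count(n_repeats, 1L)) {
    stop("'n_repeats' must be a positive integer", call. = FALSE)
  }
  per <- with_seed(seed, {
    if (statistic == "jaccard") {
      if (is.null(sample2)) {
        stop("'sample2' is required for the jaccard statistic",
             call. = FALSE)
      }
      sets <- lapply(list(sample, sample2), cdr3_set, level = level)
      wts <- if (weighted) {
        lapply(list(sample, sample2), function(s) {
          cl <- s$clonotypes
          keep <- if (level == "aa") {
            cl$productive & cl$junction_aa != ""
          } else rep(TRUE, nrow(cl))
          v <- tapply(cl$abundance[keep],
                      if (level == "aa") cl$junction_aa[keep]
                      else cl$junction_nt[keep], sum)
          v
        })
      } else NULL
      if (any(vapply(sets, length, integer(1)) < depth)) {
        stop("'depth' exceeds the number of distinct CDR3s", call. = FALSE)
      }
      vapply(seq_len(n_repeats), function(r) {
        sub <- lapply(seq_along(sets), function(i) {
          if (weighted) {
            w <- wts[[i]][sets[[i]]]
            sample(sets[[i]], depth, prob = w)
          } else {
            sample(sets[[i]], depth)
          }
        })
        jaccard_similarity(sub[[1]], sub[[2]])
      }, numeric(1))
    } else {
      vapply(seq_len(n_repeats), function(r) {
        cnt <- rarefy(sample, depth)
        cnt <- cnt[cnt > 0L]
        if (statistic == "shannon") {
          shannon_entropy(cnt)
        } else if (length(cnt) < 2L) {
          0
        } else {
          gini_index(cnt)
        }
      }, numeric(1))
    }
  })
  structure(list(statistic = statistic, depth = as.integer(depth),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 mean = mean(per), per_repeat = per),
            class = "rarefied_statistic")
}

#' @export
print.rarefied_statistic <- function(x, ...) {
  cat(sprintf(
    "<rarefied_statistic> %s @ depth %d: mean %.4f (%d repeats, seed %d)\n",
    x$statistic, x$depth, x$mean, x$n_repeats, x$seed))
  invisible(x)
}

#' Intra-group pairwise rarefied Jaccard similarity
#'
#' All unordered pairs within one group of samples; the diagonal is excluded
#' from per-sample means.
#'
#' @param samples list of >= 2 `repertoire_sample` objects.
#' @param depth number of distinct CDR3s subsampled per repeat.
#' @param n_repeats,seed,level,weighted as in [rarefied_index()].
#' @return List with `matrix` (symmetric mean similarity, `NA` diagonal) and
#'   `per_sample_mean`.
#' @export
intra_group_jaccard <- function(samples, depth, n_repeats = 1000L,
                                seed = 1L, level = "aa", weighted = FALSE) {
  k <- length(samples)
  if (k < 2L) stop("need at least 2 samples", call. = FALSE)
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  m <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      r <- rarefied_index(samples[[i]], "jaccard", depth = depth,
                          n_repeats = n_repeats,
                          seed = substream_seed(seed, paste0(i, "x", j)),
                          sample2 = samples[[j]], level = level,
                          weighted = weighted)
      m[i, j] <- m[j, i] <- r$mean
    }
  }
  list(matrix = m, per_sample_mean = rowMeans(m, na.rm = TRUE))
}
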