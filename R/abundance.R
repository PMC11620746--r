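# Clone-size spectrum, discrete power-law MLE, top-percentile clonality.

#' Clone-size spectrum of a repertoire
#'
#' For each distinct abundance value `k`, the proportion of all molecules
#' carried by clonotypes of that size:
#' `k * n_clonotypes(k) / total_abundance`. Proportions sum to 1; plotted on
#' log-log axes this is the familiar L-shaped clone-size distribution.
#'
#' @param sample a `repertoire_sample` with at least one clonotype.
#' @return Data frame with columns `abundance`, `proportion`.
#' @export
clone_size_spectrum <- function(sample) {
  stopifnot(inherits(sample, "repertoire_sample"))
  ab <- sample$clonotypes$abundance
  if (length(ab) == 0L) stop("empty sample", call. = FALSE)
  tab <- table(ab)
  k <- as.integer(names(tab))
  prop <- k * as.integer(tab) / sum(ab)
  data.frame(abundance = k, proportion = prop)
}

#' Fit a discrete power law to clone sizes by maximum likelihood
#'
#' Fits \eqn{f(k) = C k^{-\alpha}} on `k >= xmin` (the zeta/Zipf model) by
#' maximising the log-likelihood
#' \eqn{-\alpha \sum \ln k_i - n \ln \zeta(\alpha, xmin)} with bounded
#' one-dimensional numerical optimisation over `alpha` in (1.01, 30].
#' `converged = FALSE` flags degenerate inputs (all observations equal to
#' `xmin`, where the likelihood increases without bound) or a maximiser at
#' the upper bound. `xmin` is fixed at 1 by default; an optional Clauset-style
#' `estimate_xmin` mode picks the `xmin` minimising the Kolmogorov-Smirnov
#' distance between the tail ECDF and the fitted model.
#'
#' @param abundances integer clone sizes (one entry per unique clonotype).
#' @param xmin minimum abundance included in the fit.
#' @param estimate_xmin if `TRUE`, scan candidate `xmin` values.
#' @return Object of class `power_law_fit`: list with `alpha`, `xmin`,
#'   `n_tail`, `log_likelihood`, `converged`.
#' @export
fit_power_law <- function(abundances, xmin = 1L, estimate_xmin = FALSE) {
  if (!is.numeric(abundances) || any(!is.finite(abundances)) ||
      any(abundances < 1)) {
    stop("'abundances' must be finite counts >= 1", call. = FALSE)
  }
  if (estimate_xmin) {
    cands <- sort(unique(abundances))
    cands <- cands[vapply(cands, function(x) sum(abundances >= x) >= 10L,
                          logical(1))]
    if (!length(cands)) stop("fewer than 10 tail points", call. = FALSE)
    fits <- lapply(cands, function(x) fit_power_law(abundances, xmin = x))
    ks <- mapply(function(f, x) {
      tail <- sort(abundances[abundances >= x])
      ecdf_tail <- seq_along(tail) / length(tail)
      kmax <- max(tail)
      pmf <- (x:kmax)^(-f$alpha) / hurwitz_zeta(f$alpha, x)
      cdf_model <- cumsum(pmf)[tail - x + 1L]
      max(abs(ecdf_tail - cdf_model))
    }, fits, cands)
    return(fits[[which.min(ks)]])
  }
  tail <- abundances[abundances >= xmin]
  n <- length(tail)
  if (n < 10L) stop("fewer than 10 observations >= xmin", call. = FALSE)
  if (all(tail == xmin)) {
    return(structure(list(alpha = NA_real_, xmin = as.integer(xmin),
                          n_tail = n, log_likelihood = NA_real_,
                          converged = FALSE),
                     class = "power_law_fit"))
  }
  slogk <- sum(log(tail))
  negll <- function(a) a * slogk + n * log(hurwitz_zeta(a, xmin))
  opt <- optimize(negll, interval = c(1.01, 30), tol = 1e-8)
  alpha <- opt$minimum
  structure(list(alpha = alpha, xmin = as.integer(xmin), n_tail = n,
                 log_likelihood = -opt$objective,
                 converged = alpha < 30 - 1e-3),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit> alpha = %.4f (xmin = %d, n_tail = %d, %s)\n",
    x$alpha, x$xmin, x$n_tail,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Top-percentile clonality statistics
#'
#' The abundance threshold is the nearest-rank `(1 - top_fraction)` empirical
#' percentile of the unique-clonotype abundance vector; the "top" set is
#' every clonotype strictly above it. `top_share` is the proportion of all
#' molecules carried by that set and `mean_top_abundance` its mean clone
#' size. When no clonotype is strictly above the threshold (ties), the
#' `ceiling(top_fraction * n)` largest clonotypes are used instead and a
#' message is emitted.
#'
#' @param sample a `repertoire_sample` with at least `1 / top_fraction`
#'   unique clonotypes.
#' @param top_fraction fraction defining the top set (default 1%).
#' @return List with `top_share`, `threshold`, `mean_top_abundance`, `n_top`.
#' @export
clonality_stats <- function(sample, top_fraction = 0.01) {
  stopifnot(inherits(sample, "repertoire_sample"))
  ab <- sample$clonotypes$abundance
  n <- length(ab)
  if (n < ceiling(1 / top_fraction)) {
    stop(sprintf("need at least %d unique clonotypes for top_fraction = %g",
                 ceiling(1 / top_fraction), top_fraction), call. = FALSE)
  }
  s <- sort(ab)
  threshold <- s[ceiling((1 - top_fraction) * n)]  # nearest-rank percentile
  top <- ab[ab > threshold]
  if (length(top) == 0L) {
    k <- ceiling(top_fraction * n)
    top <- sort(ab, decreasing = TRUE)[seq_len(k)]
    message("no clonotype strictly above threshold; using the ", k,
            " largest")
  }
  list(top_share = sum(top) / sum(ab), threshold = threshold,
       mean_top_abundance = mean(top), n_top = length(top))
}
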