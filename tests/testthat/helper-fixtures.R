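# Shared fixtures and independent oracles, built in code at test time.

toy_catalog <- function(seed = 42L) build_catalog(8L, 6L, 4L, 4L, seed = seed)

# a repertoire_sample from bare vectors (junctions defaulted to unique
# in-frame strings when not supplied)
make_sample <- function(abundance,
                        v_name = NULL, j_name = NULL,
                        junction_nt = NULL, junction_aa = NULL,
                        productive = NULL, chain = "TRB",
                        sample_id = "s1", life_stage = "adult",
                        cell_type = "DP") {
  n <- length(abundance)
  if (is.null(v_name)) v_name <- rep("TRBV1", n)
  if (is.null(j_name)) j_name <- rep("TRBJ1", n)
  if (is.null(junction_nt)) {
    # unique productive junctions: C (TGT) + distinct middle codons + F (TTT)
    mids <- expand.grid(c("GCC", "GGA", "CTG", "AGA"),
                        c("ACC", "TCC", "GAA", "CAT"),
                        c("GCA", "GGT", "CTT", "AGG"),
                        stringsAsFactors = FALSE)
    stopifnot(n <= nrow(mids))
    junction_nt <- paste0("TGT", mids[seq_len(n), 1], mids[seq_len(n), 2],
                          mids[seq_len(n), 3], "TTT")
  }
  if (is.null(productive)) {
    productive <- vapply(junction_nt, function(x) {
      classify_productivity(x)$productive
    }, logical(1), USE.NAMES = FALSE)
  }
  if (is.null(junction_aa)) {
    junction_aa <- ifelse(productive, vapply(junction_nt, function(x) {
      if (nchar(x) %% 3 == 0) translate_nt(x) else ""
    }, character(1), USE.NAMES = FALSE), "")
  }
  repertoire_sample(
    sample_id = sample_id, life_stage = life_stage, cell_type = cell_type,
    chain = chain,
    clonotypes = data.frame(v_name = v_name, j_name = j_name,
                            junction_nt = junction_nt,
                            junction_aa = junction_aa,
                            abundance = as.integer(abundance),
                            productive = productive,
                            stringsAsFactors = FALSE)
  )
}

# ---- independent oracles -------------------------------------------------

# grid-search maximiser of the zeta log-likelihood (powers of the same
# formula, but an exhaustive search rather than numerical optimisation)
oracle_power_law_alpha <- function(abundances, xmin = 1L,
                                   grid = seq(1.01, 30, by = 0.01)) {
  tail <- abundances[abundances >= xmin]
  slogk <- sum(log(tail))
  ll <- vapply(grid, function(a) {
    -a * slogk - length(tail) * log(hurwitz_zeta(a, xmin))
  }, numeric(1))
  grid[which.max(ll)]
}

# pairwise-difference Gini, brute force
oracle_gini <- function(x) {
  n <- length(x)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) tot <- tot + abs(x[i] - x[j])
  tot / (2 * n^2 * mean(x))
}

# direct-summation Shannon entropy
oracle_shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  s <- 0
  for (pi in p) s <- s - pi * log(pi)
  s
}

# BH step-up by the definition q_(i) = min_{j>=i} m p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[ord[i]] <- min(1, min(vapply(i:m, function(j) {
      m * p[ord[j]] / j
    }, numeric(1))))
  }
  q
}

# exhaustive-split junction decomposition: try every (v_match, j_match)
# split of the junction into germline-prefix + insert + germline-suffix and
# keep the one maximising v_match, then j_match
oracle_decompose <- function(junction, vseq, jseq) {
  n <- nchar(junction)
  best <- NULL
  for (vm in min(n, nchar(vseq)):0) {
    if (substr(junction, 1, vm) != substr(vseq, 1, vm)) next
    rest_len <- n - vm
    for (jm in min(rest_len, nchar(jseq)):0) {
      if (substr(junction, n - jm + 1, n) !=
          substr(jseq, nchar(jseq) - jm + 1, nchar(jseq))) next
      cand <- list(v_match_len = vm, j_match_len = jm,
                   insert_len = n - vm - jm)
      if (is.null(best) || vm > best$v_match_len ||
          (vm == best$v_match_len && jm > best$j_match_len)) {
        best <- cand
      }
      break  # largest jm for this vm found
    }
  }
  best
}

# all multisets of size n from values 1..maxv (for exhaustive index sweeps)
enumerate_multisets <- function(n, maxv) {
  if (n == 0L) return(list(integer(0)))
  out <- list()
  recurse <- function(prefix, lo) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (v in lo:maxv) recurse(c(prefix, v), v)
  }
  recurse(integer(0), 1L)
  out
}
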