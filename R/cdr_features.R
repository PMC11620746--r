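# Junction decomposition, productivity classification, CDR3-length
# statistics, and CDR1xCDR2 recoding of V usage.

#' Classify a junction as productive or non-productive
#'
#' A junction is productive iff its length is divisible by 3, its
#' translation contains no stop codon, its first codon translates to the
#' conserved cysteine (C), and its last codon to phenylalanine or tryptophan
#' (F/W). `reason` names the first failed criterion in that order
#' (`"frame"`, `"stop"`, `"anchor_c"`, `"anchor_fw"`), or `"ok"`.
#'
#' @param junction_nt a single nucleotide string over `ACGT`.
#' @return List with `productive` (logical) and `reason`.
#' @export
#' @examples
#' classify_productivity("TGTGCCAGCTTT")  # C-A-S-F: productive
classify_productivity <- function(junction_nt) {
  if (length(junction_nt) != 1L || !is.character(junction_nt) ||
      !grepl("^[ACGT]+$", junction_nt)) {
    stop("'junction_nt' must be a single non-empty ACGT string",
         call. = FALSE)
  }
  n <- nchar(junction_nt)
  if (n %% 3L != 0L) return(list(productive = FALSE, reason = "frame"))
  aa <- translate_nt(junction_nt)
  if (grepl("\\*", aa)) return(list(productive = FALSE, reason = "stop"))
  if (substr(aa, 1L, 1L) != "C") {
    return(list(productive = FALSE, reason = "anchor_c"))
  }
  if (!substr(aa, nchar(aa), nchar(aa)) %in% c("F", "W")) {
    return(list(productive = FALSE, reason = "anchor_fw"))
  }
  list(productive = TRUE, reason = "ok")
}

# Vectorised productivity over many junctions (same criteria).
productivity_flags <- function(junctions) {
  n <- nchar(junctions)
  ok <- n %% 3L == 0L & n >= 6L
  if (any(ok)) {
    aa <- translate_nt(junctions[ok])
    last <- substr(aa, nchar(aa), nchar(aa))
    ok[ok] <- !grepl("\\*", aa, fixed = FALSE) &
      substr(aa, 1L, 1L) == "C" & (last == "F" | last == "W")
  }
  ok
}

# longest common prefix length of x with y (scalars)
lcp_len <- function(x, y) {
  nmax <- min(nchar(x), nchar(y))
  if (nmax == 0L) return(0L)
  xs <- substring(x, 1:nmax, 1:nmax)
  ys <- substring(y, 1:nmax, 1:nmax)
  mism <- which(xs != ys)
  if (length(mism)) mism[1L] - 1L else nmax
}

#' Decompose a junction into V match, insert, and J match
#'
#' Greedy maximal contiguous matching: `v_match_len` is the longest prefix of
#' the junction equal to a prefix of the V germline junction region;
#' `j_match_len` is the longest suffix of the *remaining* junction equal to a
#' suffix of the J germline junction region; the remainder is the insert
#' (which for the beta chain includes any D-region nucleotides). V takes
#' precedence when the junction is shorter than the combined germline
#' regions. Deletions are germline region length minus match length.
#'
#' @param junction_nt nucleotide string.
#' @param v,j single rows of the catalog `segments` table.
#' @return List with `v_match_len`, `j_match_len`, `insert_len`,
#'   `v_deleted`, `j_deleted`.
#' @export
decompose_junction <- function(junction_nt, v, j) {
  vseq <- v$junction_seq
  jseq <- j$junction_seq
  v_match <- lcp_len(junction_nt, vseq)
  rest <- substr(junction_nt, v_match + 1L, nchar(junction_nt))
  # suffix match = prefix match of the reversed strings
  rev_str <- function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }
  j_match <- lcp_len(rev_str(rest), rev_str(jseq))
  list(v_match_len = v_match, j_match_len = j_match,
       insert_len = nchar(junction_nt) - v_match - j_match,
       v_deleted = nchar(vseq) - v_match,
       j_deleted = nchar(jseq) - j_match)
}

# Vectorised insert-length inference for a whole sample.
inferred_inserts <- function(sample, catalog) {
  cl <- sample$clonotypes
  vsegs <- catalog_segments(catalog, sample$chain, "V")
  jsegs <- catalog_segments(catalog, sample$chain, "J")
  vi <- match(cl$v_name, vsegs$name)
  ji <- match(cl$j_name, jsegs$name)
  if (anyNA(vi) || anyNA(ji)) {
    stop("segment name(s) not in catalog", call. = FALSE)
  }
  vapply(seq_len(nrow(cl)), function(r) {
    decompose_junction(cl$junction_nt[r], vsegs[vi[r], ],
                       jsegs[ji[r], ])$insert_len
  }, numeric(1))
}

#' Abundance-weighted mean inferred insertion length
#'
#' \eqn{\sum_i a_i \ell_i / \sum_i a_i} over all clonotypes, where
#' \eqn{\ell_i} is the insert length inferred by [decompose_junction()]
#' ("all TCRs" = abundance-weighted).
#'
#' @param sample a non-empty `repertoire_sample`.
#' @param catalog a `segment_catalog`.
#' @return Numeric scalar (basepairs).
#' @export
weighted_mean_insert_length <- function(sample, catalog) {
  cl <- sample$clonotypes
  if (nrow(cl) == 0L) stop("empty sample", call. = FALSE)
  ins <- inferred_inserts(sample, catalog)
  sum(cl$abundance * ins) / sum(cl$abundance)
}

#' Mean CDR3 length of unique productive clonotypes
#'
#' Unweighted mean of `junction_aa` length over unique productive
#' clonotypes (amino acids); abundances are ignored.
#'
#' @param sample a `repertoire_sample` with >= 1 productive clonotype.
#' @return Numeric scalar (amino acids).
#' @export
mean_unique_cdr3_length <- function(sample) {
  cl <- sample$clonotypes
  keep <- cl$productive & !is.na(cl$junction_aa) & cl$junction_aa != ""
  # clonotypes are unique on (v, j, junction); drop any duplicate rows so
  # that re-adding a clonotype cannot shift the mean
  keep <- keep & !duplicated(paste(cl$v_name, cl$j_name, cl$junction_nt,
                                   sep = "\r"))
  if (!any(keep)) stop("no productive clonotypes", call. = FALSE)
  mean(nchar(cl$junction_aa[keep]))
}

#' Non-productive fraction of a repertoire
#'
#' Fraction of rearrangements that are non-productive, abundance-weighted by
#' default ("from total rearrangements"); `weighting = "unique"` counts each
#' clonotype once.
#'
#' @param sample a non-empty `repertoire_sample`.
#' @param weighting `"total"` or `"unique"`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
nonproductive_fraction <- function(sample,
                                   weighting = c("total", "unique")) {
  weighting <- match.arg(weighting)
  cl <- sample$clonotypes
  if (nrow(cl) == 0L) stop("empty sample", call. = FALSE)
  w <- if (weighting == "total") cl$abundance else rep(1, nrow(cl))
  sum(w[!cl$productive]) / sum(w)
}

#' CDR1 x CDR2 usage distribution
#'
#' Maps each clonotype to its V segment's (CDR1, CDR2) amino-acid pair; V
#' segments sharing a pair pool into one bin. Proportions sum to 1 and cover
#' every pair present in the catalog for the sample's chain (zeros
#' included).
#'
#' @param sample a `repertoire_sample`.
#' @param catalog a `segment_catalog`.
#' @param weighting `"unique"` or `"total"`.
#' @return Named numeric vector of proportions, names `CDR1-CDR2`.
#' @export
cdr12_counts <- function(sample, catalog,
                         weighting = c("unique", "total")) {
  weighting <- match.arg(weighting)
  vsegs <- catalog_segments(catalog, sample$chain, "V")
  pair <- paste(vsegs$cdr1_aa, vsegs$cdr2_aa, sep = "-")
  bins <- unique(pair)
  cl <- sample$clonotypes
  vi <- match(cl$v_name, vsegs$name)
  if (anyNA(vi)) {
    stop("V segment(s) not in catalog: ",
         paste(unique(cl$v_name[is.na(vi)]), collapse = ", "),
         call. = FALSE)
  }
  w <- if (weighting == "unique") rep(1, nrow(cl)) else cl$abundance
  counts <- setNames(numeric(length(bins)), bins)
  acc <- rowsum(as.numeric(w), pair[vi])
  counts[rownames(acc)] <- acc[, 1L]
  counts / sum(counts)
}
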