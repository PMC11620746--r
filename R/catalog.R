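# Germline V/J segment catalog: construction, accessors, TSV round trip.
#
# The catalog is a synthetic, mouse-scale stand-in for the TRA/TRB loci: it
# carries chromosomal order, junction-proximal germline sequence, CDR1/CDR2
# annotations for V segments and the two-cluster organisation of TRBJ, but no
# IMGT-faithful alleles. Segment names are opaque keys; chromosomal order
# always comes from `chromosomal_index` (TRAJ names deliberately descend
# 5'->3', as at the real locus, so that nothing is tempted to parse names).

#' Build a synthetic germline segment catalog
#'
#' Generates a deterministic, seeded catalog of TRAV/TRAJ/TRBV/TRBJ segments.
#' Each V junction region starts with a cysteine codon (TGT/TGC) and each J
#' junction region ends with a phenylalanine codon (TTT/TTC); all germline
#' junction regions have length divisible by 3 and are stop-free in the
#' reading frame anchored on those codons, so that frame and productivity of
#' a simulated junction are governed by the junction-forming process alone.
#' TRBJ segments are split evenly into clusters 1 (5') and 2 (3'). Per-V
#' CDR1/CDR2 amino-acid tags are unique within a chain, and per-V positive
#' selection weights for the SP4 and SP8 lineages are drawn once from the
#' same seed.
#'
#' @param n_trav,n_traj,n_trbv,n_trbj segment counts per locus (all >= 2).
#'   Defaults are mouse-like scale.
#' @param seed integer seed; identical inputs yield byte-identical catalogs.
#' @return An object of class `segment_catalog`: a list with elements
#'   `segments` (data frame with columns `name`, `chain`, `kind`,
#'   `chromosomal_index` (0-based, 5'->3'), `junction_seq`, `frame_offset`,
#'   `cdr1_aa`, `cdr2_aa`, `cluster_id`) and `selection_weights` (per-V
#'   lognormal weights `w_sp4`, `w_sp8`).
#' @export
#' @examples
#' cat <- build_catalog(8, 6, 4, 4, seed = 1)
#' catalog_segments(cat, "TRB", "J")$cluster_id
build_catalog <- function(n_trav = 98L, n_traj = 60L, n_trbv = 22L,
                          n_trbj = 12L, seed = 1L) {
  counts <- c(n_trav = n_trav, n_traj = n_traj, n_trbv = n_trbv,
              n_trbj = n_trbj)
  for (nm in names(counts)) {
    if (!is_count(counts[[nm]], min = 2L)) {
      stop(sprintf("'%s' must be an integer >= 2", nm), call. = FALSE)
    }
  }
  with_seed(substream_seed(seed, "catalog"), {
    mk_v <- function(chain, n, names) {
      data.frame(
        name = names,
        chain = chain,
        kind = "V",
        chromosomal_index = seq_len(n) - 1L,
        junction_seq = v_junction_seqs(n),
        frame_offset = 0L,
        cdr1_aa = unique_aa_tags(n, 5L),
        cdr2_aa = unique_aa_tags(n, 6L),
        cluster_id = NA_integer_,
        stringsAsFactors = FALSE
      )
    }
    mk_j <- function(chain, n, names, clusters) {
      data.frame(
        name = names,
        chain = chain,
        kind = "J",
        chromosomal_index = seq_len(n) - 1L,
        junction_seq = j_junction_seqs(n),
        frame_offset = 0L,
        cdr1_aa = "",
        cdr2_aa = "",
        cluster_id = clusters,
        stringsAsFactors = FALSE
      )
    }
    segs <- rbind(
      mk_v("TRA", n_trav, sprintf("TRAV%d", seq_len(n_trav))),
      # real TRAJ numbering descends 5'->3'; mimic that trap on purpose
      mk_j("TRA", n_traj, sprintf("TRAJ%d", rev(seq_len(n_traj))),
           NA_integer_),
      mk_v("TRB", n_trbv, sprintf("TRBV%d", seq_len(n_trbv))),
      mk_j("TRB", n_trbj, sprintf("TRBJ%d", seq_len(n_trbj)),
           ifelse(seq_len(n_trbj) <= ceiling(n_trbj / 2), 1L, 2L))
    )
    rownames(segs) <- NULL
    vmask <- segs$kind == "V"
    weights <- data.frame(
      name = segs$name[vmask],
      chain = segs$chain[vmask],
      w_sp4 = rlnorm(sum(vmask), meanlog = 0, sdlog = 0.5),
      w_sp8 = rlnorm(sum(vmask), meanlog = 0, sdlog = 0.5),
      stringsAsFactors = FALSE
    )
    structure(
      list(segments = segs, selection_weights = weights, seed = seed),
      class = "segment_catalog"
    )
  })
}

# V junction regions: Cys codon + 2-3 extra codons, stop-free in frame 0.
v_junction_seqs <- function(n) {
  vapply(seq_len(n), function(i) {
    cys <- sample(c("TGT", "TGC"), 1L)
    paste0(cys, paste0(stop_free_codons(sample(2:3, 1L)), collapse = ""))
  }, character(1))
}

# J junction regions: 2-4 codons + Phe codon, stop-free in frame 0.
j_junction_seqs <- function(n) {
  vapply(seq_len(n), function(i) {
    phe <- sample(c("TTT", "TTC"), 1L)
    paste0(paste0(stop_free_codons(sample(2:4, 1L)), collapse = ""), phe)
  }, character(1))
}

stop_free_codons <- function(k) {
  ok <- setdiff(names(.GENETIC_CODE), .STOP_CODONS)
  sample(ok, k, replace = TRUE)
}

unique_aa_tags <- function(n, len) {
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  out <- character(0)
  while (length(out) < n) {
    cand <- vapply(seq_len(n - length(out)), function(i) {
      paste0(sample(alphabet, len, replace = TRUE), collapse = "")
    }, character(1))
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

#' Extract catalog segments for one chain and kind
#'
#' @param catalog a `segment_catalog`.
#' @param chain `"TRA"` or `"TRB"`.
#' @param kind `"V"` or `"J"`.
#' @return Data frame of segments sorted by `chromosomal_index`.
#' @export
catalog_segments <- function(catalog, chain, kind) {
  stopifnot(inherits(catalog, "segment_catalog"))
  chain <- match.arg(chain, c("TRA", "TRB"))
  kind <- match.arg(kind, c("V", "J"))
  s <- catalog$segments
  s <- s[s$chain == chain & s$kind == kind, , drop = FALSE]
  s[order(s$chromosomal_index), , drop = FALSE]
}

#' @export
print.segment_catalog <- function(x, ...) {
  tab <- table(x$segments$chain, x$segments$kind)
  cat("<segment_catalog>", sum(tab), "segments\n")
  print(tab)
  invisible(x)
}

#' Write a segment catalog to TSV
#'
#' Two tables are written: `<path>` with the segments and
#' `<path>.weights.tsv` with the per-V selection weights.
#'
#' @param catalog a `segment_catalog`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "segment_catalog"))
  write.table(catalog$segments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(catalog$selection_weights, paste0(path, ".weights.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a segment catalog written by [write_catalog()]
#'
#' @param path TSV path previously written by [write_catalog()].
#' @return A `segment_catalog`.
#' @export
read_catalog <- function(path) {
  segs <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "chain", "kind", "chromosomal_index", "junction_seq",
            "frame_offset", "cdr1_aa", "cdr2_aa", "cluster_id")
  miss <- setdiff(need, names(segs))
  if (length(miss)) {
    stop("catalog file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  segs$cdr1_aa[is.na(segs$cdr1_aa)] <- ""
  segs$cdr2_aa[is.na(segs$cdr2_aa)] <- ""
  wpath <- paste0(path, ".weights.tsv")
  weights <- if (file.exists(wpath)) {
    read.delim(wpath, stringsAsFactors = FALSE)
  } else {
    # fall back to neutral weights when no sidecar is present
    v <- segs[segs$kind == "V", , drop = FALSE]
    data.frame(name = v$name, chain = v$chain, w_sp4 = 1, w_sp8 = 1,
               stringsAsFactors = FALSE)
  }
  structure(list(segments = segs, selection_weights = weights, seed = NA),
            class = "segment_catalog")
}
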