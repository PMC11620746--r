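# Internal helpers: seeded RNG scoping, substream derivation, translation.

# Standard genetic code keyed by codon, first base slowest (TTT, TTC, ...).
.GENETIC_CODE <- local({
  b <- c("T", "C", "A", "G")
  codons <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
  aa <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    ""
  )[[1]]
  setNames(aa, codons)
})

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate nucleotide sequences in frame 0
#'
#' Translates in-frame nucleotide strings to amino acids using the standard
#' genetic code; stop codons become `*`.
#'
#' @param nt character vector of nucleotide strings over `ACGT`, each with
#'   length divisible by 3.
#' @return Character vector of amino-acid strings.
#' @export
#' @examples
#' translate_nt("TGTGCCAGCTTT")
translate_nt <- function(nt) {
  n <- nchar(nt)
  if (any(n %% 3L != 0L)) {
    stop("sequence length not divisible by 3", call. = FALSE)
  }
  out <- character(length(nt))
  maxcod <- if (length(n)) max(n) %/% 3L else 0L
  aas <- matrix("", nrow = length(nt), ncol = maxcod)
  for (k in seq_len(maxcod)) {
    cod <- substr(nt, 3L * k - 2L, 3L * k)
    hit <- nchar(cod) == 3L
    aa <- .GENETIC_CODE[cod[hit]]
    if (anyNA(aa)) stop("non-ACGT codon encountered", call. = FALSE)
    aas[hit, k] <- aa
  }
  apply(aas, 1L, paste0, collapse = "")
}

# Deterministic 31-bit sub-seed for a named substream of a root seed, so that
# adding a simulation stage never perturbs the draws of earlier stages.
substream_seed <- function(seed, stream) {
  cs <- utf8ToInt(stream)
  h <- sum(cs * seq_along(cs) * 131)
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483629)
}

# Evaluate expr under a fixed seed (and pinned RNG kind for cross-platform
# reproducibility), restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

random_nt <- function(n) {
  if (n == 0L) return("")
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# n random nucleotide strings with given lengths (vectorised).
random_nt_vec <- function(lens) {
  total <- sum(lens)
  pool <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  out <- character(length(lens))
  at <- 1L
  for (i in seq_along(lens)) {
    if (lens[i] > 0L) {
      out[i] <- paste0(pool[at:(at + lens[i] - 1L)], collapse = "")
      at <- at + lens[i]
    }
  }
  out
}
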