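# Clonotype-level repertoire containers and AIRR Rearrangement TSV I/O.

.AIRR_REQUIRED <- c("v_call", "j_call", "junction", "duplicate_count")

#' Construct a repertoire sample
#'
#' A repertoire sample is one (individual x cell type x chain) clonotype
#' table plus metadata. Clonotypes are unique on
#' (`v_name`, `j_name`, `junction_nt`).
#'
#' @param sample_id identifier.
#' @param life_stage `"foetal"`, `"adult"`, `"adult_hc"`, or `NA`.
#' @param cell_type thymocyte population or `NA`.
#' @param chain `"TRA"`, `"TRB"`, or `NA`.
#' @param clonotypes data frame with columns `v_name`, `j_name`,
#'   `junction_nt`, `junction_aa`, `abundance`, `productive`; optional
#'   columns `insert_len`, `v_deleted`, `j_deleted`, `insert_seq`.
#' @return Object of class `repertoire_sample`.
#' @export
repertoire_sample <- function(sample_id, life_stage = NA, cell_type = NA,
                              chain = NA, clonotypes) {
  stopifnot(is.data.frame(clonotypes))
  need <- c("v_name", "j_name", "junction_nt", "junction_aa", "abundance",
            "productive")
  miss <- setdiff(need, names(clonotypes))
  if (length(miss)) {
    stop("clonotypes missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  structure(list(sample_id = as.character(sample_id),
                 life_stage = life_stage, cell_type = cell_type,
                 chain = chain, clonotypes = clonotypes),
            class = "repertoire_sample")
}

#' @export
print.repertoire_sample <- function(x, ...) {
  cl <- x$clonotypes
  cat(sprintf(
    "<repertoire_sample> %s (%s %s %s): %d clonotypes, %d molecules\n",
    x$sample_id, x$life_stage, x$cell_type, x$chain, nrow(cl),
    sum(cl$abundance)))
  invisible(x)
}

#' Read an AIRR Rearrangement TSV into a repertoire sample
#'
#' Requires columns `v_call`, `j_call`, `junction`, `duplicate_count`;
#' `junction_aa` and `productive` are used when present (`productive` is
#' otherwise derived from the junction with [classify_productivity()] rules).
#' Rows sharing (`v_call`, `j_call`, `junction`) are merged by summing
#' `duplicate_count`.
#'
#' @param path TSV file path.
#' @param sample_id identifier; defaults to the file name.
#' @param life_stage,cell_type,chain sample metadata.
#' @return A `repertoire_sample`.
#' @export
read_airr <- function(path, sample_id = NULL, life_stage = NA,
                      cell_type = NA, chain = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(read.delim(path, stringsAsFactors = FALSE,
                            colClasses = NA),
                 error = function(e) {
                   stop("cannot parse AIRR TSV ", path, ": ",
                        conditionMessage(e), call. = FALSE)
                 })
  miss <- setdiff(.AIRR_REQUIRED, names(df))
  if (length(miss)) {
    stop("AIRR file missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    cl <- data.frame(v_name = character(0), j_name = character(0),
                     junction_nt = character(0), junction_aa = character(0),
                     abundance = integer(0), productive = logical(0),
                     stringsAsFactors = FALSE)
    return(repertoire_sample(sample_id %||% basename(path), life_stage,
                             cell_type, chain, cl))
  }
  df$junction <- toupper(as.character(df$junction))
  key <- paste(df$v_call, df$j_call, df$junction, sep = "\r")
  first <- !duplicated(key)
  abundance <- as.vector(rowsum(as.numeric(df$duplicate_count), key,
                                reorder = FALSE))
  out <- df[first, , drop = FALSE]
  out$abundance <- abundance
  if (any(out$abundance < 1)) {
    warning("merged abundances below 1 present", call. = FALSE)
  }
  productive <- if ("productive" %in% names(out)) {
    p <- toupper(as.character(out$productive))
    p %in% c("T", "TRUE", "1")
  } else {
    vapply(out$junction, function(x) {
      ok <- grepl("^[ACGT]*$", x) && nchar(x) > 0
      ok && classify_productivity(x)$productive
    }, logical(1), USE.NAMES = FALSE)
  }
  junction_aa <- if ("junction_aa" %in% names(out)) {
    ifelse(is.na(out$junction_aa), "", as.character(out$junction_aa))
  } else {
    ifelse(productive, NA_character_, "")
  }
  cl <- data.frame(v_name = as.character(out$v_call),
                   j_name = as.character(out$j_call),
                   junction_nt = out$junction,
                   junction_aa = junction_aa,
                   abundance = as.integer(round(out$abundance)),
                   productive = productive,
                   stringsAsFactors = FALSE)
  for (extra in c("insert_len", "v_deleted", "j_deleted")) {
    if (extra %in% names(out)) cl[[extra]] <- out[[extra]]
  }
  rownames(cl) <- NULL
  repertoire_sample(sample_id %||% basename(path), life_stage, cell_type,
                    chain, cl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a repertoire sample as AIRR Rearrangement TSV
#'
#' Emits one row per clonotype with AIRR column names in deterministic
#' (`v_call`, `j_call`, `junction`) lexicographic order. Ground-truth columns
#' present in the clonotype table (`insert_len`, `v_deleted`, `j_deleted`)
#' are carried along.
#'
#' @param sample a `repertoire_sample`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(sample, path) {
  stopifnot(inherits(sample, "repertoire_sample"))
  cl <- sample$clonotypes
  if (nrow(cl) && any(!grepl("^[ACGT]*$", cl$junction_nt))) {
    warning("non-ACGT junction(s) written verbatim", call. = FALSE)
  }
  ord <- order(cl$v_name, cl$j_name, cl$junction_nt, method = "radix")
  cl <- cl[ord, , drop = FALSE]
  out <- data.frame(
    sequence_id = if (nrow(cl)) {
      sprintf("%s.%06d", sample$sample_id, seq_len(nrow(cl)))
    } else character(0),
    v_call = cl$v_name, j_call = cl$j_name, junction = cl$junction_nt,
    junction_aa = cl$junction_aa, duplicate_count = cl$abundance,
    productive = ifelse(cl$productive, "T", "F"),
    stringsAsFactors = FALSE
  )
  for (extra in c("insert_len", "v_deleted", "j_deleted")) {
    if (extra %in% names(cl)) out[[extra]] <- cl[[extra]]
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path,
                                           call. = FALSE))
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a repertoire sample
#'
#' Reports structural issues without stopping: duplicate clonotype keys,
#' non-positive abundances, and productivity/frame/translation
#' inconsistencies.
#'
#' @param sample a `repertoire_sample`.
#' @return Character vector of issues; empty means valid.
#' @export
validate_sample <- function(sample) {
  stopifnot(inherits(sample, "repertoire_sample"))
  cl <- sample$clonotypes
  issues <- character(0)
  key <- paste(cl$v_name, cl$j_name, cl$junction_nt, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    issues <- c(issues, sprintf("%d duplicate clonotype key(s)",
                                length(dup)))
  }
  bad_ab <- which(!is.finite(cl$abundance) | cl$abundance < 1)
  if (length(bad_ab)) {
    issues <- c(issues, sprintf("abundance < 1 in %d row(s) (first: row %d)",
                                length(bad_ab), bad_ab[1]))
  }
  frame_bad <- which(cl$productive & nchar(cl$junction_nt) %% 3L != 0L)
  if (length(frame_bad)) {
    issues <- c(issues,
                sprintf("productive clonotype(s) out of frame: %d row(s)",
                        length(frame_bad)))
  }
  aa_bad <- which(cl$productive & (is.na(cl$junction_aa) |
                                     cl$junction_aa == ""))
  if (length(aa_bad)) {
    issues <- c(issues,
                sprintf("productive clonotype(s) without junction_aa: %d",
                        length(aa_bad)))
  }
  issues
}

#' Read a sample manifest
#'
#' A manifest is a TSV with columns `path`, `sample_id`, `life_stage`,
#' `cell_type`, `chain`; relative paths are resolved against the manifest's
#' directory.
#'
#' @param path manifest TSV.
#' @return List of `repertoire_sample` objects.
#' @export
read_manifest <- function(path) {
  mf <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("path", "sample_id", "life_stage", "cell_type", "chain")
  miss <- setdiff(need, names(mf))
  if (length(miss)) {
    stop("manifest missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(path)
  lapply(seq_len(nrow(mf)), function(i) {
    p <- mf$path[i]
    if (!file.exists(p)) p <- file.path(base, mf$path[i])
    read_airr(p, sample_id = mf$sample_id[i], life_stage = mf$life_stage[i],
              cell_type = mf$cell_type[i], chain = mf$chain[i])
  })
}
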