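# Protospacer extraction from screen reads and guide counting.
#
# Reads from the lentiviral sgRNA vector carry the protospacer between the
# hU6 backbone anchor CACCG and the scaffold start GTTT; the 20-mer between
# the anchors is matched exactly (case-insensitively) against the library.
# Quality scores are ignored.

#' Extract protospacers from screen reads via backbone anchors
#'
#' For each read, locates the first exact occurrence of `CACCG` and emits the
#' following 20 nt if and only if they are immediately followed by `GTTT`.
#' Reads failing either anchor, or ending fewer than 24 nt after the anchor,
#' emit nothing. Only a single orientation is searched (vector amplicons are
#' directional); a warning is raised when fewer than half the reads anchor,
#' which can indicate reversed reads.
#'
#' @param reads Path to a FASTQ file (plain or gzipped), or a character
#'   vector of read sequences.
#' @return Character vector of extracted 20-mers, with attributes
#'   `n_scanned` (reads examined) and `n_anchored` (reads emitting a
#'   protospacer).
#' @examples
#' extract_protospacers(c("AACACCGACGTACGTACGTACGTACGTGTTTAA"))
#' @export
extract_protospacers <- function(reads) {
  if (length(reads) == 1L && file.exists(reads)) {
    reads <- tryCatch(
      as.character(Biostrings::readDNAStringSet(reads, format = "fastq")),
      error = function(e) stop("malformed FASTQ input: ", conditionMessage(e),
                               call. = FALSE))
  }
  reads <- toupper(as.character(reads))
  n <- length(reads)
  if (n == 0L) {
    out <- character(0)
    attr(out, "n_scanned") <- 0L
    attr(out, "n_anchored") <- 0L
    return(out)
  }
  pos <- regexpr("CACCG", reads, fixed = TRUE)
  ok <- pos > 0L & (pos + 28L) <= nchar(reads)
  spacer <- substr(reads[ok], pos[ok] + 5L, pos[ok] + 24L)
  ok2 <- substr(reads[ok], pos[ok] + 25L, pos[ok] + 28L) == "GTTT"
  out <- spacer[ok2]
  attr(out, "n_scanned") <- n
  attr(out, "n_anchored") <- length(out)
  if (length(out) < n / 2) {
    warning(sprintf("anchored yield %d/%d reads (< 50%%); check read orientation",
                    length(out), n), call. = FALSE)
  }
  out
}

#' Count extracted protospacers against a library manifest
#'
#' Exact, case-insensitive matching of 20-mers to the library protospacers;
#' sequences matching no library guide are tallied separately as unmatched
#' and excluded from the matched total (the denominator used for guide
#' frequencies).
#'
#' @param protospacers Character vector of extracted 20-mers.
#' @param library Library manifest (see [read_library()]); protospacers must
#'   be unique.
#' @return A list with `counts` (named integer vector in library order),
#'   `total_matched` and `unmatched`.
#' @export
count_guides <- function(protospacers, library) {
  lib_ps <- toupper(library$protospacer)
  if (anyDuplicated(lib_ps)) {
    stop("duplicate protospacers in library manifest", call. = FALSE)
  }
  m <- match(toupper(as.character(protospacers)), lib_ps)
  counts <- tabulate(m, nbins = length(lib_ps))
  names(counts) <- library$guide_id
  list(counts = counts,
       total_matched = sum(counts),
       unmatched = sum(is.na(m)))
}

#' Count a set of screen samples into a guide-by-sample matrix
#'
#' Convenience wrapper running [extract_protospacers()] and [count_guides()]
#' per FASTQ file. Sample names follow the `cellline_timepoint_repN`
#' convention (e.g. `HepG2_d0_rep1`).
#'
#' @param library Library manifest.
#' @param fastq Character vector of FASTQ paths.
#' @param samples Character vector of sample names, same length as `fastq`.
#' @return Integer matrix (guides x samples) with an `unmatched` attribute
#'   (named integer vector per sample).
#' @export
count_screen <- function(library, fastq, samples) {
  stopifnot(length(fastq) == length(samples), !anyDuplicated(samples))
  cols <- lapply(fastq, function(f) count_guides(extract_protospacers(f),
                                                 library))
  counts <- do.call(cbind, lapply(cols, `[[`, "counts"))
  colnames(counts) <- samples
  attr(counts, "unmatched") <-
    stats::setNames(vapply(cols, `[[`, integer(1), "unmatched"), samples)
  counts
}

#' Convert raw guide counts to per-sample frequencies
#'
#' Each guide's frequency is its read count divided by the sample's total
#' reads matched to the library, so every column sums to 1.
#'
#' @param counts Non-negative count matrix (guides x samples) or vector.
#' @return Matrix (or vector) of frequencies.
#' @export
to_frequencies <- function(counts) {
  if (is.null(dim(counts))) {
    tot <- sum(counts)
    if (tot <= 0) stop("sample has zero matched reads", call. = FALSE)
    return(counts / tot)
  }
  tot <- colSums(counts)
  zero <- tot <= 0
  if (any(zero)) {
    stop("sample(s) with zero matched reads: ",
         paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  }
  sweep(counts, 2L, tot, `/`)
}

#' Build and parse sample names
#'
#' Samples are keyed by cell line, timepoint (`d0` / `d24`) and replicate;
#' the flat name is `cellline_timepoint_repN`.
#'
#' @param cell_line,timepoint,replicate Key components (vectorised).
#' @return `sample_key` returns the flat names; `parse_sample_keys` returns a
#'   data frame with columns `sample`, `cell_line`, `timepoint`, `replicate`.
#' @export
sample_key <- function(cell_line, timepoint, replicate) {
  stopifnot(all(timepoint %in% c("d0", "d24")))
  sprintf("%s_%s_rep%d", cell_line, timepoint, as.integer(replicate))
}

#' @rdname sample_key
#' @param samples Character vector of flat sample names.
#' @export
parse_sample_keys <- function(samples) {
  m <- regmatches(samples,
                  regexec("^(.+)_(d0|d24)_rep([0-9]+)$", samples))
  bad <- lengths(m) != 4L
  if (any(bad)) {
    stop("unparseable sample name(s): ",
         paste(samples[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(sample = samples,
             cell_line = vapply(m, `[`, character(1), 2L),
             timepoint = vapply(m, `[`, character(1), 3L),
             replicate = as.integer(vapply(m, `[`, character(1), 4L)),
             stringsAsFactors = FALSE)
}

#' Write / read a guide count table (TSV)
#'
#' Rows are guides (first column `guide_id`), remaining columns are samples
#' named `cellline_timepoint_repN`.
#'
#' @param counts Count matrix with guide rownames.
#' @param file Path.
#' @return `read_counts` returns an integer matrix with guide rownames.
#' @export
write_counts <- function(counts, file) {
  df <- data.frame(guide_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_counts
#' @export
read_counts <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  m
}
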