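# CRISPR-hypersensitive element calling on smoothed residue profiles.
#
# An element is a maximal run of consecutive residues whose smoothed NCS is
# at or below the calling threshold (default -1.0, the positive-control
# anchor); runs shorter than min_length are discarded. Boundaries are pure
# threshold crossings of the smoothed curve; no gap merging is performed, so
# profile continuity is governed entirely by the smoothing bandwidth.

#' Call CRISPR-hypersensitive elements from a residue profile
#'
#' @param profile A `residue_profile` (see [smooth_profile()]), complete
#'   over residues 1..protein length.
#' @param threshold Calling threshold on the smoothed NCS (default -1.0).
#' @param min_length Minimum element length in residues (default 5).
#' @param label_prefix Prefix for element labels, assigned N- to C-terminal
#'   as `<prefix>1`, `<prefix>2`, ... (default `"E"`).
#' @return Data frame with columns `gene_id`, `label`, `start_residue`,
#'   `end_residue` (1-based inclusive), `min_ncs`, `mean_ncs`. Zero rows
#'   when nothing falls below threshold.
#' @examples
#' prof <- structure(list(value = c(rep(0, 10), rep(-1.5, 8), rep(0, 10)),
#'                        residue = 1:28, gene_id = "toy", cell_line = "A"),
#'                   class = "residue_profile")
#' call_elements(prof)
#' @export
call_elements <- function(profile, threshold = -1.0, min_length = 5L,
                          label_prefix = "E") {
  stopifnot(inherits(profile, "residue_profile"), min_length >= 1L)
  v <- profile$value
  below <- !is.na(v) & v <= threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  starts <- starts[keep]; ends <- ends[keep]
  out <- data.frame(
    gene_id = rep(profile$gene_id, length(starts)),
    label = if (length(starts)) paste0(label_prefix, seq_along(starts))
            else character(0),
    start_residue = as.integer(starts),
    end_residue = as.integer(ends),
    min_ncs = vapply(seq_along(starts),
                     function(i) min(v[starts[i]:ends[i]]), numeric(1)),
    mean_ncs = vapply(seq_along(starts),
                      function(i) mean(v[starts[i]:ends[i]]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compare tiling-scan profiles of two cell lines
#'
#' Calls elements on the profile of cell line A, then classifies each
#' against the profile of cell line B over the same interval:
#' `selective` when B's mean over the interval stays above `rescue_floor`
#' (B is not sensitive there), `shared` when B also dips to or below the
#' calling threshold anywhere in the interval, otherwise `none`
#' (intermediate depletion in B). When both conditions hold — a brief deep
#' dip in B inside an interval whose mean is still high — `selective`
#' takes precedence. Both profile means are reported.
#'
#' @param profile_a,profile_b `residue_profile`s over the same gene and
#'   length.
#' @param threshold Calling threshold applied to A (and the dip test in B).
#' @param rescue_floor Mean-NCS floor in B above which an element of A is
#'   called selective (default -0.5).
#' @param min_length,label_prefix Passed to [call_elements()].
#' @return The element frame of A plus columns `mean_ncs_b`, `min_ncs_b`,
#'   `specificity` and `comparator` (B's cell line).
#' @export
compare_cell_lines <- function(profile_a, profile_b, threshold = -1.0,
                               rescue_floor = -0.5, min_length = 5L,
                               label_prefix = "E") {
  stopifnot(inherits(profile_b, "residue_profile"))
  if (length(profile_a$value) != length(profile_b$value)) {
    stop("profiles have different lengths", call. = FALSE)
  }
  el <- call_elements(profile_a, threshold, min_length, label_prefix)
  vb <- profile_b$value
  el$mean_ncs_b <- vapply(seq_len(nrow(el)), function(i)
    mean(vb[el$start_residue[i]:el$end_residue[i]]), numeric(1))
  el$min_ncs_b <- vapply(seq_len(nrow(el)), function(i)
    min(vb[el$start_residue[i]:el$end_residue[i]]), numeric(1))
  el$specificity <- ifelse(el$mean_ncs_b > rescue_floor, "selective",
                           ifelse(el$min_ncs_b <= threshold, "shared",
                                  "none"))
  el$comparator <- rep(profile_b$cell_line, nrow(el))
  el
}

#' Write called elements to TSV or BED-like text
#'
#' The TSV keeps 1-based inclusive residue intervals. The BED-like file uses
#' 0-based half-open residue coordinates (stated in its header comment),
#' with the gene id in the chrom column.
#'
#' @param elements Element data frame from [call_elements()] or
#'   [compare_cell_lines()].
#' @param file Path.
#' @export
write_elements <- function(elements, file) {
  utils::write.table(elements, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_elements
#' @export
write_elements_bed <- function(elements, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# residue coordinates, 0-based half-open", con)
  if (nrow(elements)) {
    bed <- data.frame(elements$gene_id,
                      elements$start_residue - 1L,
                      elements$end_residue,
                      elements$label,
                      sprintf("%.4f", elements$mean_ncs))
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(file)
}
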