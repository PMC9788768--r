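# Control-anchored normalized CRISPR scores (NCS) and residue-coordinate
# smoothing.
#
# The NCS of a guide is its log10 fold change in library frequency between
# day 0 and day 24, linearly rescaled per replicate so the median of the
# negative-control guides is 0.0 and the median of the positive-control
# guides is -1.0. Guides underrepresented at baseline (day-0 frequency below
# 5% of the library average) are excluded.

#' Per-guide raw log10 frequency fold change
#'
#' `L = log10(f_d24 / f_d0)` with a pseudocount `a` added to every count
#' before frequency conversion:
#' `L = log10((c24 + a) / (T24 + aN)) - log10((c0 + a) / (T0 + aN))`,
#' where `T` is the sample's matched-read total and `N` the library size.
#' With `a = 0`, extinct guides yield `-Inf`.
#'
#' @param c0,c24 Integer count vectors for the paired day-0 / day-24 samples
#'   of one replicate (same guide order).
#' @param pseudocount Pseudocount `a` (default 0.5; 0 allowed).
#' @return Numeric vector of raw log10 fold changes.
#' @export
compute_raw_lfc <- function(c0, c24, pseudocount = 0.5) {
  stopifnot(length(c0) == length(c24), pseudocount >= 0)
  n <- length(c0)
  t0 <- sum(c0); t24 <- sum(c24)
  log10((c24 + pseudocount) / (t24 + pseudocount * n)) -
    log10((c0 + pseudocount) / (t0 + pseudocount * n))
}

#' Flag guides underrepresented at baseline
#'
#' A guide is flagged when its day-0 frequency is below
#' `threshold_fraction` times the mean day-0 frequency. With frequencies
#' normalised to sum 1 over `N` guides the cutoff equals
#' `threshold_fraction / N`.
#'
#' @param f_d0 Day-0 frequency vector (sums to 1).
#' @param threshold_fraction Fraction of the mean frequency below which a
#'   guide is excluded; must lie in `[0, 1)` (default 0.05; 0 disables the
#'   filter).
#' @return Logical vector, `TRUE` = filtered out.
#' @export
filter_underrepresented <- function(f_d0, threshold_fraction = 0.05) {
  if (!is.numeric(threshold_fraction) || length(threshold_fraction) != 1L ||
      is.na(threshold_fraction) ||
      threshold_fraction < 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must lie in [0, 1)", call. = FALSE)
  }
  f_d0 < threshold_fraction * mean(f_d0)
}

#' Anchor raw log fold changes to control medians
#'
#' Applies the unique linear map sending the median raw score of the
#' negative controls to 0.0 and that of the positive controls to -1.0:
#' `NCS(L) = (M_neg - L) / (M_pos - M_neg)`.
#'
#' @param L Raw log10 fold-change vector (one replicate).
#' @param neg,pos Index or logical vectors selecting the unfiltered
#'   negative / positive control guides within `L`.
#' @return List with `ncs` (vector, same length as `L`) and `anchors`
#'   (named vector `m_neg`, `m_pos`).
#' @export
normalize_ncs <- function(L, neg, pos) {
  ln <- L[neg]; lp <- L[pos]
  if (!length(ln) || !length(lp) || all(is.na(ln)) || all(is.na(lp))) {
    stop("need at least one unfiltered negative and positive control",
         call. = FALSE)
  }
  m_neg <- anchor_median(ln[!is.na(ln)])
  m_pos <- anchor_median(lp[!is.na(lp)])
  if (!is.finite(m_neg) || !is.finite(m_pos) || m_pos == m_neg) {
    stop("degenerate control anchors (M_pos == M_neg or non-finite)",
         call. = FALSE)
  }
  list(ncs = (m_neg - L) / (m_pos - m_neg),
       anchors = c(m_neg = m_neg, m_pos = m_pos))
}

#' Average per-replicate NCS over retained replicates
#'
#' Arithmetic mean per guide over the replicates in which the guide passed
#' the underrepresentation filter; guides filtered in every replicate get
#' `NA` and are listed in the `dropped` attribute.
#'
#' @param ncs Matrix (guides x replicates) of anchored scores.
#' @param filtered Logical matrix of the same shape (`TRUE` = excluded).
#' @return Numeric vector of per-guide means with attribute `dropped`.
#' @export
aggregate_replicates <- function(ncs, filtered = NULL) {
  ncs <- as.matrix(ncs)
  if (is.null(filtered)) filtered <- matrix(FALSE, nrow(ncs), ncol(ncs))
  stopifnot(identical(dim(ncs), dim(filtered)))
  ncs[filtered] <- NA_real_
  out <- rowMeans(ncs, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  dropped <- rownames(ncs)[rowSums(!filtered & !is.na(ncs)) == 0L]
  attr(out, "dropped") <- dropped
  out
}

#' Smooth guide scores onto protein residue coordinates
#'
#' Two steps: (1) codon averaging — guides cutting within the same codon are
#' averaged into a single value at that residue; (2) Nadaraya-Watson kernel
#' regression with a Gaussian kernel of bandwidth `sigma` residues,
#' evaluated at every integer residue 1..`protein_length`:
#' `value(r) = sum_k w_k v_k / sum_k w_k`, `w_k = exp(-(r - r_k)^2 / (2 sigma^2))`.
#' The normalisation makes edge weights sum to one by construction, and the
#' output is always bounded by the range of the codon-averaged inputs.
#'
#' @param residue_index Integer residue positions of the guides' cut codons.
#' @param ncs Per-guide scores (e.g. replicate-averaged NCS); `NA`s dropped.
#' @param protein_length Protein length in residues.
#' @param sigma Kernel bandwidth in residues (> 0; default 5).
#' @param gene_id,cell_line Labels stored in the profile.
#' @return An object of class `residue_profile`: list with `value` (numeric,
#'   length `protein_length`), `residue`, `sigma`, `n_guides_used`,
#'   `gene_id`, `cell_line`, and the codon-averaged support points
#'   (`support_residue`, `support_value`).
#' @export
smooth_profile <- function(residue_index, ncs, protein_length, sigma = 5,
                           gene_id = NA_character_,
                           cell_line = NA_character_) {
  stopifnot(length(residue_index) == length(ncs), sigma > 0,
            protein_length >= 1L)
  keep <- !is.na(ncs) & !is.na(residue_index)
  residue_index <- as.integer(residue_index[keep])
  ncs <- as.numeric(ncs[keep])
  if (length(ncs) < 2L) {
    stop("need at least 2 scored guides to smooth", call. = FALSE)
  }
  if (any(residue_index < 1L | residue_index > protein_length)) {
    stop("residue_index outside 1..protein_length", call. = FALSE)
  }
  v <- tapply(ncs, residue_index, mean)
  rk <- as.integer(names(v))
  v <- as.numeric(v)
  if (length(rk) == 1L) {
    warning("all guides map to one residue; profile is constant",
            call. = FALSE)
    value <- rep(v, protein_length)
  } else {
    value <- nw_smooth(seq_len(protein_length), rk, v, sigma)
  }
  structure(list(value = value, residue = seq_len(protein_length),
                 sigma = sigma, n_guides_used = length(ncs),
                 gene_id = gene_id, cell_line = cell_line,
                 support_residue = rk, support_value = v),
            class = "residue_profile")
}

# Nadaraya-Watson estimate at arbitrary coordinates x given support (rk, v).
# Weights are rescaled per evaluation point by the nearest support's weight
# (NW is invariant to row scaling); this keeps the estimate finite at small
# bandwidths where all raw weights would underflow to zero, converging to
# the nearest-support value in the sigma -> 0 limit.
#' @noRd
nw_smooth <- function(x, rk, v, sigma) {
  d2 <- outer(x, rk, `-`)^2
  d2 <- d2 - apply(d2, 1L, min)
  w <- exp(-d2 / (2 * sigma^2))
  as.numeric((w %*% v) / rowSums(w))
}

#' @export
print.residue_profile <- function(x, ...) {
  cat(sprintf("Residue profile%s%s: %d residues, sigma = %g, %d guides; range [%.3f, %.3f]\n",
              if (is.na(x$gene_id)) "" else paste0(" ", x$gene_id),
              if (is.na(x$cell_line)) "" else paste0(" (", x$cell_line, ")"),
              length(x$value), x$sigma, x$n_guides_used,
              min(x$value), max(x$value)))
  invisible(x)
}

#' @export
as.data.frame.residue_profile <- function(x, ...) {
  data.frame(gene_id = x$gene_id, cell_line = x$cell_line,
             residue = x$residue, smoothed_ncs = x$value,
             stringsAsFactors = FALSE)
}

#' Write a residue profile to TSV
#'
#' Columns: `gene_id`, `cell_line`, `residue`, `smoothed_ncs`.
#' @param profile A `residue_profile`.
#' @param file Path.
#' @export
write_profile <- function(profile, file) {
  utils::write.table(as.data.frame(profile), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_profile
#' @export
read_profile <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("residue", "smoothed_ncs") %in% names(df)))
  df <- df[order(df$residue), ]
  structure(list(value = df$smoothed_ncs, residue = df$residue,
                 sigma = NA_real_, n_guides_used = NA_integer_,
                 gene_id = df$gene_id[1L], cell_line = df$cell_line[1L],
                 support_residue = NULL, support_value = NULL),
            class = "residue_profile")
}

#' Fit a CRISPR gene-body tiling scan
#'
#' The central model fit: from a guide-by-sample count matrix and a library
#' manifest, computes per-replicate raw log10 frequency fold changes between
#' day 0 and day 24, applies the baseline underrepresentation filter,
#' anchors scores per replicate to the control medians (negative -> 0.0,
#' positive -> -1.0), averages the anchored scores over replicates, and
#' smooths the tiling-guide scores onto protein residue coordinates with a
#' Gaussian kernel.
#'
#' @param counts Integer matrix, guides x samples; rownames are guide ids
#'   and column names follow `cellline_timepoint_repN` (see [sample_key()]).
#' @param library Library manifest matching the rownames of `counts`.
#' @param cell_line Cell line whose samples to analyse (default: the single
#'   cell line present).
#' @param sigma Smoothing bandwidth in residues (default 5).
#' @param pseudocount Pseudocount for [compute_raw_lfc()] (default 0.5).
#' @param threshold_fraction Underrepresentation cutoff as a fraction of the
#'   mean day-0 frequency (default 0.05).
#' @param protein_length Protein length in residues; defaults to the largest
#'   tiling-guide residue index in the manifest.
#' @return An object of class `tiling_scan` with components `ncs_mean`
#'   (per-guide replicate-averaged NCS), `profile` (a `residue_profile`),
#'   per-replicate matrices `raw_lfc`, `ncs`, `filtered`, the per-replicate
#'   `anchors`, and bookkeeping fields. Methods: [print()], [summary()],
#'   [coef()], [predict()], [fitted()], [residuals()], [plot()].
#' @examples
#' sim <- simulate_screen(seed = 1)
#' fit <- tiling_scan(sim$counts, sim$truth$manifest)
#' fit
#' head(coef(fit))
#' @export
tiling_scan <- function(counts, library, cell_line = NULL, sigma = 5,
                        pseudocount = 0.5, threshold_fraction = 0.05,
                        protein_length = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop("`counts` must have guide_id rownames", call. = FALSE)
  }
  idx <- match(rownames(counts), library$guide_id)
  if (anyNA(idx)) {
    stop("counts contain guides absent from the library manifest",
         call. = FALSE)
  }
  lib <- library[idx, , drop = FALSE]

  keys <- parse_sample_keys(colnames(counts))
  if (is.null(cell_line)) {
    cl <- unique(keys$cell_line)
    if (length(cl) != 1L) {
      stop("counts contain ", length(cl),
           " cell lines; specify `cell_line`", call. = FALSE)
    }
    cell_line <- cl
  }
  keys <- keys[keys$cell_line == cell_line, , drop = FALSE]
  reps <- sort(intersect(keys$replicate[keys$timepoint == "d0"],
                         keys$replicate[keys$timepoint == "d24"]))
  if (!length(reps)) {
    stop("no replicate with both d0 and d24 samples for cell line ",
         cell_line, call. = FALSE)
  }

  n <- nrow(counts)
  neg <- lib$category == "neg_control"
  pos <- lib$category == "pos_control"
  L <- ncsm <- matrix(NA_real_, n, length(reps),
                      dimnames = list(rownames(counts),
                                      paste0("rep", reps)))
  flt <- matrix(FALSE, n, length(reps), dimnames = dimnames(L))
  anchors <- matrix(NA_real_, 2L, length(reps),
                    dimnames = list(c("m_neg", "m_pos"), paste0("rep", reps)))

  for (j in seq_along(reps)) {
    s0 <- sample_key(cell_line, "d0", reps[j])
    s24 <- sample_key(cell_line, "d24", reps[j])
    c0 <- counts[, s0]; c24 <- counts[, s24]
    L[, j] <- compute_raw_lfc(c0, c24, pseudocount)
    flt[, j] <- filter_underrepresented(to_frequencies(c0),
                                        threshold_fraction)
    Lj <- L[, j]
    Lj[flt[, j]] <- NA_real_
    nrm <- normalize_ncs(Lj, neg, pos)
    ncsm[, j] <- nrm$ncs
    anchors[, j] <- nrm$anchors
  }

  ncs_mean <- aggregate_replicates(ncsm, flt)

  tiling <- !is.na(lib$residue_index)
  if (is.null(protein_length)) {
    protein_length <- max(lib$residue_index[tiling])
  }
  use <- tiling & !is.na(ncs_mean)
  profile <- smooth_profile(lib$residue_index[use], ncs_mean[use],
                            protein_length, sigma,
                            gene_id = stats::na.omit(unique(lib$gene_id[tiling]))[1L],
                            cell_line = cell_line)

  structure(list(call = match.call(), cell_line = cell_line,
                 replicates = reps, library = lib,
                 raw_lfc = L, filtered = flt, ncs = ncsm,
                 anchors = anchors, ncs_mean = ncs_mean,
                 dropped = attr(ncs_mean, "dropped"),
                 profile = profile, sigma = sigma,
                 pseudocount = pseudocount,
                 threshold_fraction = threshold_fraction,
                 protein_length = protein_length),
            class = "tiling_scan")
}

#' @export
print.tiling_scan <- function(x, ...) {
  cat("CRISPR gene-body tiling scan\n")
  cat(sprintf("  gene: %s   cell line: %s   replicates: %s\n",
              x$profile$gene_id, x$cell_line,
              paste(x$replicates, collapse = ", ")))
  cat(sprintf("  %d guides (%d tiling, %d neg ctrl, %d pos ctrl), %d filtered in >=1 replicate\n",
              nrow(x$library), sum(x$library$category == "tiling"),
              sum(x$library$category == "neg_control"),
              sum(x$library$category == "pos_control"),
              sum(rowSums(x$filtered) > 0L)))
  cat(sprintf("  smoothed profile over %d residues (sigma = %g), range [%.3f, %.3f]\n",
              x$protein_length, x$sigma,
              min(x$profile$value), max(x$profile$value)))
  invisible(x)
}

#' @export
summary.tiling_scan <- function(object, threshold = -1.0, min_length = 5L,
                                ...) {
  ncs_ctrl <- function(cat) {
    stats::median(object$ncs_mean[object$library$category == cat],
                  na.rm = TRUE)
  }
  out <- list(cell_line = object$cell_line,
              anchors = object$anchors,
              median_ncs_neg = ncs_ctrl("neg_control"),
              median_ncs_pos = ncs_ctrl("pos_control"),
              n_filtered = colSums(object$filtered),
              n_dropped = length(object$dropped),
              elements = call_elements(object$profile, threshold, min_length),
              threshold = threshold, sigma = object$sigma)
  class(out) <- "summary.tiling_scan"
  out
}

#' @export
print.summary.tiling_scan <- function(x, ...) {
  cat(sprintf("Tiling scan summary (%s)\n", x$cell_line))
  cat("  raw LFC anchors per replicate:\n")
  print(round(x$anchors, 4))
  cat(sprintf("  median NCS: negative controls %.4f, positive controls %.4f\n",
              x$median_ncs_neg, x$median_ncs_pos))
  cat(sprintf("  guides dropped (filtered in all replicates): %d\n",
              x$n_dropped))
  cat(sprintf("  CRISPR-hypersensitive elements (NCS <= %.2f):\n",
              x$threshold))
  if (nrow(x$elements)) print(x$elements, row.names = FALSE) else
    cat("    none\n")
  invisible(x)
}

#' @export
coef.tiling_scan <- function(object, ...) {
  stats::setNames(as.numeric(object$ncs_mean), rownames(object$raw_lfc))
}

#' @export
fitted.tiling_scan <- function(object, ...) object$profile$value

#' Evaluate the smoothed scan profile at arbitrary residue coordinates
#'
#' @param object A `tiling_scan` fit.
#' @param residues Numeric residue coordinates (default: every integer
#'   residue, i.e. the fitted profile).
#' @param ... Unused.
#' @return Numeric vector of smoothed NCS values.
#' @export
predict.tiling_scan <- function(object, residues = NULL, ...) {
  if (is.null(residues)) return(object$profile$value)
  nw_smooth(as.numeric(residues), object$profile$support_residue,
            object$profile$support_value, object$sigma)
}

#' @export
residuals.tiling_scan <- function(object, ...) {
  tiling <- !is.na(object$library$residue_index)
  r <- object$ncs_mean[tiling] -
    object$profile$value[object$library$residue_index[tiling]]
  stats::setNames(r, object$library$guide_id[tiling])
}

#' Plot a tiling scan: guide scores and the smoothed profile
#'
#' @param x A `tiling_scan` fit.
#' @param threshold Horizontal calling threshold to draw (default -1).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tiling_scan <- function(x, threshold = -1.0, ...) {
  tiling <- !is.na(x$library$residue_index)
  graphics::plot(x$library$residue_index[tiling], x$ncs_mean[tiling],
                 pch = 16, cex = 0.5, col = "grey50",
                 xlab = "Peptide position (residue)",
                 ylab = "Normalized CRISPR score",
                 main = sprintf("%s (%s)", x$profile$gene_id, x$cell_line),
                 ...)
  graphics::lines(x$profile$residue, x$profile$value, col = "firebrick",
                  lwd = 2)
  graphics::abline(h = c(0, -1), lty = 3, col = "grey30")
  graphics::abline(h = threshold, lty = 2, col = "steelblue")
  invisible(x)
}

#' Per-guide score table of a tiling scan
#'
#' Flat export with one row per guide: raw LFC and NCS per replicate,
#' filter flags, and the replicate-averaged NCS.
#'
#' @param fit A `tiling_scan`.
#' @return Data frame.
#' @export
score_table <- function(fit) {
  stopifnot(inherits(fit, "tiling_scan"))
  reps <- paste0("rep", fit$replicates)
  out <- data.frame(guide_id = fit$library$guide_id,
                    gene_id = fit$library$gene_id,
                    category = fit$library$category,
                    residue_index = fit$library$residue_index,
                    stringsAsFactors = FALSE)
  for (j in seq_along(reps)) {
    out[[paste0("raw_lfc_", reps[j])]] <- fit$raw_lfc[, j]
    out[[paste0("filtered_", reps[j])]] <- fit$filtered[, j]
    out[[paste0("ncs_", reps[j])]] <- fit$ncs[, j]
  }
  out$ncs_mean <- as.numeric(fit$ncs_mean)
  out
}
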