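# Gene-level essentiality ranking for TSS-targeting (CRISPRi) screens.
#
# A deliberately simple, fully deterministic ranking: the gene statistic is
# the median replicate-averaged raw log10 fold change of its guides, tested
# for depletion against a permutation null built from the negative-control
# guides. This is not an implementation of the published robust-rank
# algorithms used for such screens; it is an honest in-package ranking so
# that simulated TSS screens can be analysed end to end.

#' Gene-level depletion scores by negative-control permutation
#'
#' For each gene with `k` guides, the statistic `beta` is the median of the
#' guides' scores. The null distribution for size `k` is the median of
#' `n_perm` random `k`-subsets drawn with replacement from the
#' negative-control guide scores; the one-sided depletion p-value is
#' `(1 + #\{null <= beta\}) / (1 + n_perm)`. P-values are BH-adjusted across
#' genes. Enrichment (`beta > 0`) is reported without a p-value — the test
#' is depletion-only.
#'
#' @param scores Per-guide scores, typically replicate-mean raw log10 fold
#'   changes (filtered guides already removed or `NA`).
#' @param gene_ids Gene id per guide (`NA` for controls).
#' @param categories Guide categories; guides with category `"neg_control"`
#'   form the permutation pool.
#' @param n_perm Permutations per gene size (default 10000).
#' @param seed Integer seed for the permutation draws.
#' @return Data frame sorted by `p_value` then `beta`: `gene_id`,
#'   `n_guides`, `beta`, `p_value`, `fdr`, `rank`.
#' @export
gene_level_scores <- function(scores, gene_ids, categories,
                              n_perm = 10000L, seed = NULL) {
  stopifnot(length(scores) == length(gene_ids),
            length(scores) == length(categories), n_perm >= 1L)
  neg <- scores[categories == "neg_control" & !is.na(scores)]
  if (!length(neg)) stop("no negative-control guides available", call. = FALSE)

  is_gene <- !is.na(gene_ids) & !(categories %in%
                                    c("neg_control", "pos_control"))
  keep <- is_gene & !is.na(scores)
  gl <- split(scores[keep], gene_ids[keep])
  if (!length(gl)) stop("no scored gene-targeting guides", call. = FALSE)

  beta <- vapply(gl, stats::median, numeric(1))
  k <- lengths(gl)

  p <- with_seed(seed, {
    ks <- sort(unique(k))
    null_by_k <- lapply(ks, function(kk) {
      m <- matrix(sample(neg, n_perm * kk, replace = TRUE), nrow = n_perm)
      apply(m, 1L, stats::median)
    })
    names(null_by_k) <- as.character(ks)
    vapply(seq_along(gl), function(i) {
      null <- null_by_k[[as.character(k[i])]]
      (1 + sum(null <= beta[i])) / (1 + n_perm)
    }, numeric(1))
  })

  out <- data.frame(gene_id = names(gl), n_guides = as.integer(k),
                    beta = as.numeric(beta), p_value = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$beta), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Rank genes of a TSS-targeting screen from counts
#'
#' Computes per-replicate raw log10 fold changes (day 0 vs day 24), applies
#' the baseline underrepresentation filter, averages over retained
#' replicates, and runs [gene_level_scores()].
#'
#' @inheritParams tiling_scan
#' @inheritParams gene_level_scores
#' @return See [gene_level_scores()].
#' @export
rank_screen <- function(counts, library, cell_line = NULL,
                        pseudocount = 0.5, threshold_fraction = 0.05,
                        n_perm = 10000L, seed = NULL) {
  counts <- as.matrix(counts)
  idx <- match(rownames(counts), library$guide_id)
  if (anyNA(idx)) stop("counts contain guides absent from the manifest",
                       call. = FALSE)
  lib <- library[idx, , drop = FALSE]
  keys <- parse_sample_keys(colnames(counts))
  if (is.null(cell_line)) {
    cl <- unique(keys$cell_line)
    if (length(cl) != 1L) stop("specify `cell_line`", call. = FALSE)
    cell_line <- cl
  }
  keys <- keys[keys$cell_line == cell_line, , drop = FALSE]
  reps <- sort(intersect(keys$replicate[keys$timepoint == "d0"],
                         keys$replicate[keys$timepoint == "d24"]))
  if (!length(reps)) stop("no paired d0/d24 replicates", call. = FALSE)
  L <- matrix(NA_real_, nrow(counts), length(reps))
  for (j in seq_along(reps)) {
    c0 <- counts[, sample_key(cell_line, "d0", reps[j])]
    c24 <- counts[, sample_key(cell_line, "d24", reps[j])]
    Lj <- compute_raw_lfc(c0, c24, pseudocount)
    Lj[filter_underrepresented(to_frequencies(c0), threshold_fraction)] <-
      NA_real_
    L[, j] <- Lj
  }
  lbar <- rowMeans(L, na.rm = TRUE)
  lbar[!is.finite(lbar)] <- NA_real_
  gene_level_scores(lbar, lib$gene_id, lib$category,
                    n_perm = n_perm, seed = seed)
}
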