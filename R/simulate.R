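# Synthetic pooled dropout screens: ground-truth fitness over a tiled
# protein, Dirichlet-multinomial sequencing counts, and backbone-structured
# FASTQ reads, so every analysis stage can be exercised without real data.
#
# The generative model: each guide carries a fitness deficit s <= 0
# (doublings per generation lost); over g generations a guide's latent
# abundance scales by 2^(g * s). Day-0 composition noise is Dirichlet
# around uniform; sequencing depth is finite multinomial sampling.

#' Simulation configuration
#'
#' Defaults mirror a saturating single-gene tiling screen: a 600-residue
#' protein tiled by 290 guides plus 50 negative and 50 positive controls,
#' three replicates, two million reads per sample, eight generations of
#' growth between day 0 and day 24, positive-control fitness -1
#' doubling/generation, and Dirichlet concentration 10 per guide at day 0
#' (coefficient of variation about 32%, a typical plasmid-library skew).
#'
#' @param n_tiling,n_neg,n_pos Guide counts by category.
#' @param depth_d0,depth_d24 Sequencing depth (reads) per sample.
#' @param concentration Per-guide Dirichlet concentration for day-0
#'   composition noise (> 0; larger = more uniform).
#' @param n_replicates Number of independent replicates.
#' @param generations Growth generations between day 0 and day 24.
#' @param s_pos Positive-control fitness deficit (default -1).
#' @param cell_line Sample label used in count column names.
#' @param seed Base seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_tiling = 290L, n_neg = 50L, n_pos = 50L,
                       depth_d0 = 2e6, depth_d24 = 2e6,
                       concentration = 10, n_replicates = 3L,
                       generations = 8, s_pos = -1,
                       cell_line = "simA", seed = 1L) {
  stopifnot(depth_d0 > 0, depth_d24 > 0, concentration > 0,
            n_replicates >= 1L, s_pos <= 0)
  structure(list(n_tiling = as.integer(n_tiling), n_neg = as.integer(n_neg),
                 n_pos = as.integer(n_pos), depth_d0 = depth_d0,
                 depth_d24 = depth_d24, concentration = concentration,
                 n_replicates = as.integer(n_replicates),
                 generations = generations, s_pos = s_pos,
                 cell_line = cell_line, seed = as.integer(seed)),
            class = "sim_config")
}

#' Ground truth for a synthetic tiling dropout screen
#'
#' Places `n_tiling` guides uniformly (with +/-3 nt jitter) over the coding
#' sequence of a `protein_length`-residue protein and assigns each a fitness
#' deficit: `s = s*` of the covering essential interval; guides outside any
#' interval get the nearest interval's depth attenuated by a half-Gaussian
#' of the residue distance (scale 3 residues) minus half-normal baseline
#' noise (sd 0.05, truncated at 0), so `s <= 0` always. Controls get
#' `s = 0` (negative) and `s = s_pos` (positive).
#'
#' @param protein_length Protein length in residues (default 600).
#' @param intervals Data frame with columns `start`, `end`, `s` (fitness
#'   depth in `[-1.5, 0]`); non-overlapping, within `[1, protein_length]`.
#'   Default: two planted essential elements at residues 114-129 and
#'   502-519 with depth -1.2. Pass a zero-row frame for a null screen.
#' @param config A [sim_config()].
#' @param seed Seed (default `config$seed`).
#' @return List of class `sim_truth`: `manifest` (library manifest data
#'   frame), `guide_effects` (named fitness vector), `intervals`,
#'   `protein_length`, `generations`, `config`.
#' @export
make_truth <- function(protein_length = 600L,
                       intervals = data.frame(start = c(114L, 502L),
                                              end = c(129L, 519L),
                                              s = c(-1.2, -1.2)),
                       config = sim_config(), seed = config$seed) {
  protein_length <- as.integer(protein_length)
  stopifnot(protein_length >= 1L)
  if (nrow(intervals)) {
    stopifnot(all(intervals$start >= 1L),
              all(intervals$end <= protein_length),
              all(intervals$start <= intervals$end),
              all(intervals$s >= -1.5), all(intervals$s <= 0))
    o <- order(intervals$start)
    intervals <- intervals[o, , drop = FALSE]
    if (nrow(intervals) > 1L &&
        any(intervals$start[-1L] <= intervals$end[-nrow(intervals)])) {
      stop("essential intervals overlap", call. = FALSE)
    }
  }
  cds_len <- 3L * protein_length

  truth <- with_seed(seed, {
    base <- round(seq(1, cds_len, length.out = config$n_tiling))
    jitter <- sample(-3:3, config$n_tiling, replace = TRUE)
    cut_left <- pmin(pmax(as.integer(base + jitter), 1L), cds_len)
    residue <- map_cut_to_residue(cut_left, cds_len)

    if (nrow(intervals)) {
      d <- vapply(residue, function(r) {
        min(pmax(0L, pmax(intervals$start - r, r - intervals$end)))
      }, numeric(1))
      nearest <- vapply(residue, function(r) {
        which.min(pmax(0L, pmax(intervals$start - r, r - intervals$end)))
      }, integer(1))
      s_star <- intervals$s[nearest]
      s <- ifelse(d == 0, s_star,
                  s_star * exp(-d^2 / (2 * 3^2)) -
                    abs(stats::rnorm(length(residue), 0, 0.05)))
      s[d == 0] <- s_star[d == 0]
    } else {
      s <- -abs(stats::rnorm(config$n_tiling, 0, 0.05))
    }

    # unique protospacers for the whole library
    n_total <- config$n_tiling + config$n_neg + config$n_pos
    ps <- character(0)
    while (length(ps) < n_total) {
      ps <- unique(c(ps, random_protospacers(n_total - length(ps))))
    }
    tiling <- data.frame(
      guide_id = sprintf("sim_t%04d", seq_len(config$n_tiling)),
      gene_id = "simGene",
      protospacer = ps[seq_len(config$n_tiling)],
      strand = "+",
      pam_cds_start = pmin(cut_left + 4L, cds_len),
      cut_left = cut_left, residue_index = residue,
      category = "tiling", stringsAsFactors = FALSE)
    ctrl_ps <- ps[-seq_len(config$n_tiling)]
    ctrl <- data.frame(
      guide_id = c(sprintf("neg_ctrl_%04d", seq_len(config$n_neg)),
                   sprintf("pos_ctrl_%04d", seq_len(config$n_pos))),
      gene_id = NA_character_,
      protospacer = ctrl_ps,
      strand = NA_character_, pam_cds_start = NA_integer_,
      cut_left = NA_integer_, residue_index = NA_integer_,
      category = rep(c("neg_control", "pos_control"),
                     c(config$n_neg, config$n_pos)),
      stringsAsFactors = FALSE)
    manifest <- rbind(tiling, ctrl)
    effects <- stats::setNames(
      c(s, rep(0, config$n_neg), rep(config$s_pos, config$n_pos)),
      manifest$guide_id)
    list(manifest = manifest, guide_effects = effects)
  })

  structure(list(manifest = truth$manifest,
                 guide_effects = truth$guide_effects,
                 intervals = intervals, protein_length = protein_length,
                 generations = config$generations, config = config),
            class = "sim_truth")
}

#' Simulate screen counts from a ground truth
#'
#' Per replicate: day-0 proportions are drawn Dirichlet(`concentration`)
#' around uniform; latent day-24 abundance is `p0 * 2^(g * s)`; observed
#' counts are multinomial at the configured depths. Replicates are
#' independent.
#'
#' @param truth A [make_truth()] result.
#' @param config A [sim_config()] (default: the one stored in `truth`).
#' @param seed Seed (default `config$seed + 1`).
#' @return Integer count matrix, guides x samples, columns
#'   `cellline_d0_repJ` / `cellline_d24_repJ`.
#' @export
simulate_counts <- function(truth, config = truth$config,
                            seed = config$seed + 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  if (config$depth_d0 <= 0 || config$depth_d24 <= 0) {
    stop("sequencing depth must be positive", call. = FALSE)
  }
  s <- truth$guide_effects
  n <- length(s)
  g <- truth$generations
  with_seed(seed, {
    cols <- list()
    for (r in seq_len(config$n_replicates)) {
      p0 <- stats::rgamma(n, shape = config$concentration)
      p0 <- p0 / sum(p0)
      c0 <- as.integer(stats::rmultinom(1L, config$depth_d0, p0))
      w <- p0 * 2^(g * s)
      c24 <- as.integer(stats::rmultinom(1L, config$depth_d24, w / sum(w)))
      cols[[sample_key(config$cell_line, "d0", r)]] <- c0
      cols[[sample_key(config$cell_line, "d24", r)]] <- c24
    }
    m <- do.call(cbind, cols)
    rownames(m) <- truth$manifest$guide_id
    m
  })
}

#' Write simulated reads for one sample as FASTQ
#'
#' Each guide contributes `counts[i]` reads of a fixed total length:
#' random prefix + `CACCG` + protospacer + `GTTT` + random suffix, with
#' constant Phred 'I' qualities. Prefixes are redrawn if they contain the
#' `CACCG` anchor, so extraction by first-anchor search recovers the
#' generating counts exactly. Read order is shuffled.
#'
#' @param counts Named integer vector (one count-table column).
#' @param library Library manifest supplying the protospacers.
#' @param file Output path; a `.gz` suffix gzips the output.
#' @param read_length Total read length (>= 29; default 75).
#' @param seed Seed.
#' @return The path, invisibly.
#' @export
emit_fastq <- function(counts, library, file, read_length = 75L,
                       seed = NULL) {
  read_length <- as.integer(read_length)
  if (read_length < 29L) {
    stop("read_length must be >= 29 (anchors + protospacer)", call. = FALSE)
  }
  idx <- match(names(counts), library$guide_id)
  if (anyNA(idx)) stop("counts name guides absent from the manifest",
                       call. = FALSE)
  ps <- toupper(library$protospacer[idx])
  pad <- read_length - 29L
  total <- sum(counts)
  seqs <- with_seed(seed, {
    out <- character(total)
    k <- 0L
    for (i in seq_along(counts)) {
      ci <- counts[[i]]
      if (ci <= 0L) next
      for (j in seq_len(ci)) {
        plen <- if (pad > 0L) sample.int(pad + 1L, 1L) - 1L else 0L
        repeat {
          prefix <- paste(sample(DNA_BASES, plen, replace = TRUE),
                          collapse = "")
          if (!grepl("CACCG", prefix, fixed = TRUE)) break
        }
        suffix <- paste(sample(DNA_BASES, pad - plen, replace = TRUE),
                        collapse = "")
        k <- k + 1L
        out[k] <- paste0(prefix, "CACCG", ps[i], "GTTT", suffix)
      }
    }
    out[sample.int(total)]
  })
  con <- if (grepl("\\.gz$", file)) gzfile(file, "w") else file(file, "w")
  on.exit(close(con))
  if (total > 0L) {
    qual <- strrep("I", read_length)
    writeLines(paste0("@read_", seq_len(total), "\n", seqs, "\n+\n", qual),
               con)
  }
  invisible(file)
}

#' Simulate a complete tiling dropout screen
#'
#' Convenience wrapper: [make_truth()] at `seed`, [simulate_counts()] at
#' `seed + 1`. FASTQ emission is left to [emit_fastq()] (per sample).
#'
#' @inheritParams make_truth
#' @param seed Base seed, overriding `config$seed`.
#' @return List with `truth` and `counts`.
#' @examples
#' sim <- simulate_screen(config = sim_config(depth_d0 = 1e5, depth_d24 = 1e5),
#'                        seed = 1)
#' dim(sim$counts)
#' @export
simulate_screen <- function(protein_length = 600L,
                            intervals = data.frame(start = c(114L, 502L),
                                                   end = c(129L, 519L),
                                                   s = c(-1.2, -1.2)),
                            config = sim_config(), seed = config$seed) {
  config$seed <- as.integer(seed)
  truth <- make_truth(protein_length, intervals, config, seed = seed)
  counts <- simulate_counts(truth, config, seed = seed + 1L)
  list(truth = truth, counts = counts)
}
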