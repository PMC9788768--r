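# Saturating sgRNA tiling-library design over a coding sequence.
#
# Coordinates are 1-based, inclusive, on the coding strand. The blunt Cas9
# cut is placed between protospacer positions 17 and 18 (3 bp 5' of the
# NGG PAM); `cut_left` is the CDS coordinate of the base immediately 5' of
# the cut in coding-strand orientation.

#' Coding-sequence template for tiling-library design
#'
#' Bundles a gene's coding sequence with optional flanking sequence so that
#' protospacers or PAMs overhanging the CDS ends remain resolvable. The CDS
#' must be given 5'->3' on the coding strand and have length a positive
#' multiple of 3.
#'
#' @param gene_id Gene identifier used to label guides.
#' @param cds Coding sequence (A/C/G/T), length a positive multiple of 3.
#' @param flank5,flank3 Optional flanking sequence immediately up-/downstream
#'   of the CDS (may be `""`).
#' @return An object of class `coding_template` with fields `gene_id`, `cds`,
#'   `flank5`, `flank3` and `protein_length` (`nchar(cds) / 3`).
#' @seealso [enumerate_guides()], [read_cds_fasta()]
#' @examples
#' tmpl <- coding_template("toy", "ATGACGTACGATCAGTTAGCTGGATCCTAA")
#' tmpl$protein_length
#' @export
coding_template <- function(gene_id, cds, flank5 = "", flank3 = "") {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  cds <- assert_dna(cds, "cds")
  if (nzchar(flank5)) flank5 <- assert_dna(flank5, "flank5")
  if (nzchar(flank3)) flank3 <- assert_dna(flank3, "flank3")
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L) {
    stop("cds length must be a positive multiple of 3", call. = FALSE)
  }
  structure(list(gene_id = gene_id, cds = cds, flank5 = flank5,
                 flank3 = flank3, protein_length = n %/% 3L),
            class = "coding_template")
}

#' @export
print.coding_template <- function(x, ...) {
  cat(sprintf("Coding template '%s': %d nt CDS (%d residues), flanks %d/%d nt\n",
              x$gene_id, nchar(x$cds), x$protein_length,
              nchar(x$flank5), nchar(x$flank3)))
  invisible(x)
}

#' Read a coding template from a FASTA file
#'
#' The first word of the FASTA header is the gene id (unless overridden);
#' `key=value` tokens later in the header may supply `flank5=` / `flank3=`
#' sequences.
#'
#' @param file Path to a FASTA file (first record is used).
#' @param gene_id Optional override for the gene identifier.
#' @return A [coding_template()].
#' @export
read_cds_fasta <- function(file, gene_id = NULL) {
  seqs <- Biostrings::readDNAStringSet(file)
  if (length(seqs) == 0L) stop("no sequences in ", file, call. = FALSE)
  header <- names(seqs)[1L]
  tokens <- strsplit(header, "\\s+")[[1L]]
  if (is.null(gene_id)) gene_id <- tokens[1L]
  kv <- tokens[grepl("=", tokens, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  flank5 <- if ("flank5" %in% keys) vals[match("flank5", keys)] else ""
  flank3 <- if ("flank3" %in% keys) vals[match("flank3", keys)] else ""
  coding_template(gene_id, as.character(seqs[[1L]]), flank5, flank3)
}

#' Map a CDS cut coordinate to a protein residue index
#'
#' A cut between CDS bases `cut_left` and `cut_left + 1` is assigned to the
#' codon containing `cut_left`: `residue = floor((cut_left - 1) / 3) + 1`.
#'
#' @param cut_left 1-based CDS coordinate(s) of the base immediately 5' of
#'   the blunt cut.
#' @param cds_length CDS length in nucleotides (for range validation).
#' @return Integer residue indices (1-based).
#' @examples
#' map_cut_to_residue(c(1, 3, 4), 30)
#' @export
map_cut_to_residue <- function(cut_left, cds_length) {
  cut_left <- as.integer(cut_left)
  if (any(is.na(cut_left)) || any(cut_left < 1L) || any(cut_left > cds_length)) {
    stop("cut_left out of range 1..", cds_length, call. = FALSE)
  }
  (cut_left - 1L) %/% 3L + 1L
}

#' Enumerate every NGG-anchored sgRNA over a coding sequence
#'
#' Scans both strands of `flank5 + cds + flank3` for 20-nt protospacers
#' immediately 5' of an NGG PAM and keeps each guide whose blunt cut site
#' (between protospacer positions 17 and 18) lies strictly inside the CDS,
#' i.e. between coding bases `cut_left` and `cut_left + 1` with
#' `1 <= cut_left <= L - 1` — a rule symmetric under strand reversal, so
#' reverse-complementing the template yields the mirrored guide set. Guides are
#' retained even when the protospacer or PAM overhangs into flanking
#' sequence, since the lesion itself lands in the coding exons. PAMs too
#' close to the sequence start for a full protospacer are skipped.
#'
#' @param template A [coding_template()].
#' @return A data frame of tiling guide records with columns `guide_id`,
#'   `gene_id`, `protospacer`, `strand` (+/- relative to the coding strand),
#'   `pam_cds_start` (CDS coordinate of the PAM's first base; can fall
#'   outside 1..CDS length when the PAM overhangs a flank), `cut_left`,
#'   `residue_index` and `category` (`"tiling"`), deduplicated on
#'   (protospacer, strand, PAM position) and ordered by `cut_left` then
#'   strand. A CDS too short to host any guide yields an empty frame with a
#'   warning.
#' @examples
#' g <- enumerate_guides(coding_template("toy", "ATGACGTACGATCAGTTAGCTGGATCCTAA"))
#' g[, c("protospacer", "strand", "cut_left", "residue_index")]
#' @export
enumerate_guides <- function(template) {
  stopifnot(inherits(template, "coding_template"))
  full <- paste0(template$flank5, template$cds, template$flank3)
  off <- nchar(template$flank5)
  L <- nchar(template$cds)
  n <- nchar(full)
  ch <- strsplit(full, "")[[1L]]

  recs <- list()
  if (n >= 3L) {
    # plus strand: PAM N-G-G at p..p+2, protospacer at p-20..p-1
    p <- which(ch == "G")
    p <- p[p >= 2L & p <= n - 1L]
    p <- p[ch[p + 1L] == "G"] - 1L       # p = PAM first base (the N)
    p <- p[p >= 21L]
    if (length(p)) {
      cut <- p - 4L - off
      keep <- cut >= 1L & cut <= L - 1L
      p <- p[keep]; cut <- cut[keep]
      if (length(p)) {
        recs[["+"]] <- data.frame(
          protospacer = substring(full, p - 20L, p - 1L),
          strand = "+", pam_cds_start = p - off, cut_left = cut,
          stringsAsFactors = FALSE)
      }
    }
    # minus strand: PAM on the reverse strand reads NGG, i.e. C-C-N on the
    # coding strand at q..q+2; protospacer occupies coding q+3..q+22
    q <- which(ch == "C")
    q <- q[q <= n - 2L]
    q <- q[ch[q + 1L] == "C"]
    q <- q[q + 22L <= n]
    if (length(q)) {
      cut <- q + 5L - off
      keep <- cut >= 1L & cut <= L - 1L
      q <- q[keep]; cut <- cut[keep]
      if (length(q)) {
        recs[["-"]] <- data.frame(
          protospacer = revcomp(substring(full, q + 3L, q + 22L)),
          strand = "-", pam_cds_start = q + 2L - off, cut_left = cut,
          stringsAsFactors = FALSE)
      }
    }
  }

  g <- if (length(recs)) do.call(rbind, recs) else
    data.frame(protospacer = character(0), strand = character(0),
               pam_cds_start = integer(0), cut_left = integer(0),
               stringsAsFactors = FALSE)
  g <- g[!duplicated(g[c("protospacer", "strand", "pam_cds_start")]), ,
         drop = FALSE]
  g <- g[order(g$cut_left, g$strand), , drop = FALSE]
  rownames(g) <- NULL

  if (nrow(g) == 0L && L < 23L && off == 0L && !nzchar(template$flank3)) {
    warning("CDS shorter than 23 nt with no flanks: no guides possible",
            call. = FALSE)
  }
  n_g <- nrow(g)
  data.frame(
    guide_id = if (n_g) sprintf("%s_t%04d", template$gene_id, seq_len(n_g))
               else character(0),
    gene_id = rep(template$gene_id, n_g),
    protospacer = g$protospacer,
    strand = g$strand,
    pam_cds_start = as.integer(g$pam_cds_start),
    cut_left = as.integer(g$cut_left),
    residue_index = if (n_g) map_cut_to_residue(g$cut_left, L) else integer(0),
    category = rep("tiling", n_g),
    stringsAsFactors = FALSE)
}

#' Assemble a screen library from tiling guides plus control guides
#'
#' Adds negative-control guides (targeting nonessential sequences; expected
#' neutral, NCS anchor 0.0) and positive-control guides (targeting
#' pan-essential genes; expected strong depletion, NCS anchor -1.0) with
#' randomly generated 20-nt protospacers that do not collide with the tiling
#' protospacers or each other.
#'
#' @param tiling Data frame of tiling guides from [enumerate_guides()] (may
#'   have zero rows).
#' @param n_neg,n_pos Numbers of negative / positive controls (each >= 1).
#' @param seed Integer seed making the control protospacers reproducible.
#' @param max_tries Bound on redraws per control before giving up.
#' @return A library manifest: one data frame with the tiling records
#'   followed by control records (`pam_cds_start`, `cut_left`,
#'   `residue_index` are `NA` for controls; `category` is `neg_control` /
#'   `pos_control`).
#' @export
assemble_library <- function(tiling, n_neg, n_pos, seed = NULL,
                             max_tries = 1000L) {
  stopifnot(n_neg >= 1L, n_pos >= 1L)
  taken <- toupper(tiling$protospacer)
  draw_controls <- function(n, prefix, category) {
    out <- character(n)
    for (i in seq_len(n)) {
      for (try in seq_len(max_tries)) {
        cand <- random_protospacers(1L)
        if (!(cand %in% taken)) break
        if (try == max_tries) {
          stop("could not draw a non-colliding control protospacer",
               call. = FALSE)
        }
      }
      out[i] <- cand
      taken <<- c(taken, cand)
    }
    data.frame(guide_id = sprintf("%s_%04d", prefix, seq_len(n)),
               gene_id = NA_character_, protospacer = out,
               strand = NA_character_, pam_cds_start = NA_integer_,
               cut_left = NA_integer_, residue_index = NA_integer_,
               category = category, stringsAsFactors = FALSE)
  }
  ctrl <- with_seed(seed, rbind(
    draw_controls(n_neg, "neg_ctrl", "neg_control"),
    draw_controls(n_pos, "pos_ctrl", "pos_control")))
  out <- rbind(tiling, ctrl)
  if (anyDuplicated(out$guide_id)) {
    stop("guide_id not unique within library", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

MANIFEST_COLS <- c("guide_id", "gene_id", "protospacer", "strand",
                   "pam_cds_start", "cut_left", "residue_index", "category")

#' Write / read a guide library manifest (TSV)
#'
#' Tab-separated with the fixed header `guide_id, gene_id, protospacer,
#' strand, pam_cds_start, cut_left, residue_index, category`.
#'
#' @param library Library manifest data frame.
#' @param file Path.
#' @return `read_library` returns the manifest data frame.
#' @export
write_library <- function(library, file) {
  stopifnot(all(MANIFEST_COLS %in% names(library)))
  utils::write.table(library[MANIFEST_COLS], file, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_library
#' @export
read_library <- function(file) {
  lib <- utils::read.delim(file, stringsAsFactors = FALSE, na.strings = "",
                           colClasses = c(pam_cds_start = "integer",
                                          cut_left = "integer",
                                          residue_index = "integer"))
  missing <- setdiff(MANIFEST_COLS, names(lib))
  if (length(missing)) {
    stop("manifest missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lib
}

#' Tiling density of a guide library
#'
#' Targeting density of a saturating tiling library, expressed both as amino
#' acids per sgRNA and coding base pairs per sgRNA. The base-pair figure
#' uses the full coding region including the stop codon,
#' `3 * (protein_length + 1)` nt: a 607-residue protein tiled by 284 guides
#' gives 2.1 aa/sgRNA and 6.4 bp/sgRNA.
#' @param n_guides Number of tiling guides.
#' @param protein_length Protein length in residues.
#' @return Named numeric vector `c(aa_per_guide, bp_per_guide)`.
#' @export
guide_density <- function(n_guides, protein_length) {
  stopifnot(n_guides >= 1L, protein_length >= 1L)
  c(aa_per_guide = protein_length / n_guides,
    bp_per_guide = (3 * protein_length + 3) / n_guides)
}
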