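# Projection of per-residue scan scores onto 3D structure models: the
# Chimera "Defined Attribute" file format for Render-by-Attribute coloring,
# and B-factor-column rewriting of a PDB model as an alternative carrier.

#' Write a per-residue attribute file for molecular viewers
#'
#' Emits the defattr format consumed by UCSF Chimera's Define Attribute /
#' Render by Attribute tools: header lines `attribute: <name>`,
#' `match mode: 1-to-1`, `recipient: residues`, then one data line per
#' scored residue of the form `<TAB>:<index><TAB><value>`. Residues without
#' a score are omitted; values are written at full precision.
#'
#' @param profile A `residue_profile`, or a numeric vector of scores named
#'   (or indexed) by residue.
#' @param file Path to write.
#' @param name Attribute name: no whitespace, starting with a lowercase
#'   letter (viewer requirement). Default `"ncs"`.
#' @return The path, invisibly.
#' @export
write_residue_attributes <- function(profile, file, name = "ncs") {
  if (!grepl("^[a-z][A-Za-z0-9_]*$", name)) {
    stop("invalid attribute name: must start with a lowercase letter and ",
         "contain no whitespace", call. = FALSE)
  }
  if (inherits(profile, "residue_profile")) {
    idx <- profile$residue
    val <- profile$value
  } else {
    val <- as.numeric(profile)
    idx <- if (!is.null(names(profile))) as.integer(names(profile))
           else seq_along(val)
  }
  keep <- !is.na(val)
  idx <- idx[keep]; val <- val[keep]
  if (!length(idx)) stop("profile has no scored residues", call. = FALSE)
  if (any(idx < 1L)) stop("residue indices must be positive", call. = FALSE)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("attribute: %s", name),
               "match mode: 1-to-1",
               "recipient: residues",
               sprintf("\t:%d\t%.17g", idx, val)), con)
  invisible(file)
}

#' Parse a per-residue attribute file
#'
#' Inverse of [write_residue_attributes()].
#'
#' @param file Path to a defattr-style file.
#' @return Named numeric vector (names are residue indices) with attribute
#'   `name` carrying the attribute name.
#' @export
read_residue_attributes <- function(file) {
  lines <- readLines(file)
  name_line <- grep("^attribute:", lines, value = TRUE)
  if (!length(name_line)) stop("not an attribute file", call. = FALSE)
  nm <- sub("^attribute:\\s*", "", name_line[1L])
  data <- grep("^\t:", lines, value = TRUE)
  parts <- strsplit(data, "\t", fixed = TRUE)
  idx <- as.integer(sub("^:", "", vapply(parts, `[`, character(1), 2L)))
  val <- as.numeric(vapply(parts, `[`, character(1), 3L))
  out <- stats::setNames(val, idx)
  attr(out, "name") <- nm
  out
}

#' Rewrite the B-factor column of a PDB model with residue scores
#'
#' Copies the model text verbatim, replacing only the B-factor field
#' (columns 61-66) of every `ATOM` record in the requested chain with the
#' score of its residue. Residues without a score get 0.00. All other
#' columns — coordinates included — are byte-identical between input and
#' output. Values outside the fixed-width range [-99.99, 999.99] are
#' clamped with a warning.
#'
#' @param profile A `residue_profile` (scores indexed by residue number).
#' @param pdb Path to a PDB file, or a character vector of PDB lines.
#' @param chain Chain identifier (default `"A"`). A chain absent from the
#'   model modifies zero records, with a warning.
#' @param file Optional output path; when `NULL` the annotated lines are
#'   returned.
#' @return The annotated PDB lines (invisibly when written to `file`).
#' @export
write_bfactor_model <- function(profile, pdb, chain = "A", file = NULL) {
  lines <- if (length(pdb) == 1L && file.exists(pdb)) readLines(pdb) else
    as.character(pdb)
  atom <- which(startsWith(lines, "ATOM"))
  if (!length(atom)) stop("input does not look like a PDB model (no ATOM records)",
                          call. = FALSE)
  scores <- profile$value
  in_chain <- atom[substr(lines[atom], 22L, 22L) == chain]
  if (!length(in_chain)) {
    warning("chain '", chain, "' not present; no records modified",
            call. = FALSE)
  } else {
    resseq <- suppressWarnings(as.integer(substr(lines[in_chain], 23L, 26L)))
    val <- rep(0, length(resseq))
    ok <- !is.na(resseq) & resseq >= 1L & resseq <= length(scores)
    val[ok] <- scores[resseq[ok]]
    val[is.na(val)] <- 0
    out_of_range <- val < -99.99 | val > 999.99
    if (any(out_of_range)) {
      warning(sum(out_of_range),
              " B-factor value(s) clamped to [-99.99, 999.99]",
              call. = FALSE)
      val <- pmin(pmax(val, -99.99), 999.99)
    }
    field <- sprintf("%6.2f", val)
    lines[in_chain] <- paste0(substr(lines[in_chain], 1L, 60L), field,
                              substring(lines[in_chain], 67L))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
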