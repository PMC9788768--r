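# Independent brute-force oracles used to cross-check the implementation.
# Everything here is written naively (explicit loops, no shared helpers from
# the package internals) on purpose.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Position-by-position scan for every NGG (plus strand) and CCN (minus
# strand, i.e. NGG on the reverse complement) PAM whose guide cut site lands
# in the CDS. Returns a data frame keyed like enumerate_guides() output.
oracle_enumerate <- function(cds, flank5 = "", flank3 = "") {
  full <- paste0(flank5, cds, flank3)
  off <- nchar(flank5)
  L <- nchar(cds)
  n <- nchar(full)
  rows <- list()
  at <- function(s, i, j) substr(s, i, j)
  for (p in seq_len(n)) {
    # plus strand PAM at p..p+2
    if (p + 2 <= n && at(full, p + 1, p + 2) == "GG" && p - 20 >= 1) {
      cut <- (p - 4) - off
      if (cut >= 1 && cut <= L - 1) {
        rows[[length(rows) + 1]] <- data.frame(
          protospacer = at(full, p - 20, p - 1), strand = "+",
          pam_cds_start = p - off, cut_left = cut,
          stringsAsFactors = FALSE)
      }
    }
    # minus strand PAM: CCN at p..p+2 on the coding strand
    if (p + 2 <= n && at(full, p, p + 1) == "CC" && p + 22 <= n) {
      cut <- (p + 5) - off
      if (cut >= 1 && cut <= L - 1) {
        rows[[length(rows) + 1]] <- data.frame(
          protospacer = oracle_revcomp(at(full, p + 3, p + 22)),
          strand = "-", pam_cds_start = p + 2 - off, cut_left = cut,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(protospacer = character(0), strand = character(0),
                      pam_cds_start = integer(0), cut_left = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("protospacer", "strand", "pam_cds_start")]), ]
  out <- out[order(out$cut_left, out$strand), ]
  rownames(out) <- NULL
  out
}

# Direct double-loop Nadaraya-Watson weighted average over codon-averaged
# guide values.
oracle_smooth <- function(residue_index, ncs, protein_length, sigma) {
  occ <- sort(unique(residue_index))
  v <- sapply(occ, function(r) mean(ncs[residue_index == r]))
  out <- numeric(protein_length)
  for (r in seq_len(protein_length)) {
    dmin <- min((r - occ)^2)  # rescale by the nearest support weight so the
    num <- 0; den <- 0        # ratio stays finite at tiny bandwidths
    for (k in seq_along(occ)) {
      w <- exp(-((r - occ[k])^2 - dmin) / (2 * sigma^2))
      num <- num + w * v[k]
      den <- den + w
    }
    out[r] <- num / den
  }
  out
}

# One-pass linear run scanner for sub-threshold intervals.
oracle_runs <- function(values, threshold, min_length) {
  runs <- list()
  start <- NA
  for (i in seq_along(values)) {
    if (values[i] <= threshold) {
      if (is.na(start)) start <- i
    } else if (!is.na(start)) {
      runs[[length(runs) + 1]] <- c(start, i - 1)
      start <- NA
    }
  }
  if (!is.na(start)) runs[[length(runs) + 1]] <- c(start, length(values))
  runs <- Filter(function(r) r[2] - r[1] + 1 >= min_length, runs)
  if (!length(runs)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = sapply(runs, `[`, 1), end = sapply(runs, `[`, 2))
}

# Character-level anchored extraction, one read at a time.
oracle_extract <- function(reads) {
  out <- character(0)
  for (rd in toupper(reads)) {
    hit <- NA
    for (i in seq_len(max(0, nchar(rd) - 4))) {
      if (substr(rd, i, i + 4) == "CACCG") { hit <- i; break }
    }
    if (is.na(hit)) next
    if (hit + 28 > nchar(rd)) next
    if (substr(rd, hit + 25, hit + 28) != "GTTT") next
    out <- c(out, substr(rd, hit + 5, hit + 24))
  }
  out
}

# Strict reader for the residue-attribute grammar: three exact header lines
# then TAB ':' index TAB value lines.
strict_parse_defattr <- function(file) {
  lines <- readLines(file)
  stopifnot(grepl("^attribute: \\S+$", lines[1]),
            identical(lines[2], "match mode: 1-to-1"),
            identical(lines[3], "recipient: residues"))
  vals <- numeric(0)
  for (ln in lines[-(1:3)]) {
    m <- regmatches(ln, regexec("^\t:([0-9]+)\t(\\S+)$", ln))[[1]]
    stopifnot(length(m) == 3)
    vals[m[2]] <- as.numeric(m[3])
  }
  vals
}

# Benjamini-Hochberg step-up, written out explicitly.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- prev
  }
  adj
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Jaccard index of two 1-based inclusive residue intervals.
interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  union <- (a[2] - a[1] + 1) + (b[2] - b[1] + 1) - inter
  inter / union
}
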