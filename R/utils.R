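# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded library assembly and
#' simulation do not perturb the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' @noRd
assert_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters", what), call. = FALSE)
  }
  x
}

#' @noRd
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
random_protospacers <- function(n, width = 20L) {
  vapply(seq_len(n),
         function(i) paste(sample(DNA_BASES, width, replace = TRUE),
                           collapse = ""),
         character(1))
}

# median as midpoint of the two central order statistics (even n);
# stats::median already does this for numeric input, kept as a named wrapper
# so the anchoring convention is explicit at the call sites.
#' @noRd
anchor_median <- function(x) stats::median(x)
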