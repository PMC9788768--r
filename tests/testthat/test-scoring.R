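# A small deterministic screen for anchoring tests: counts chosen so every
# arithmetic step can be checked by hand.
toy_screen <- function() {
  guide_ids <- c("t1", "t2", "t3", "n1", "n2", "n3", "p1", "p2", "p3")
  lib <- data.frame(
    guide_id = guide_ids, gene_id = c(rep("g", 3), rep(NA, 6)),
    protospacer = replicate(9, random_dna(20)),
    strand = c(rep("+", 3), rep(NA, 6)),
    pam_cds_start = c(25L, 40L, 55L, rep(NA, 6)),
    cut_left = c(21L, 36L, 51L, rep(NA, 6)),
    residue_index = c(7L, 12L, 17L, rep(NA, 6)),
    category = c(rep("tiling", 3), rep("neg_control", 3),
                 rep("pos_control", 3)),
    stringsAsFactors = FALSE)
  c0 <- c(100L, 100L, 100L, 100L, 100L, 100L, 100L, 100L, 100L)
  c24 <- c(100L, 10L, 50L, 100L, 100L, 100L, 10L, 10L, 10L)
  counts <- cbind(A_d0_rep1 = c0, A_d24_rep1 = c24)
  rownames(counts) <- guide_ids
  list(lib = lib, counts = counts)
}

test_that("raw log fold changes follow the frequency-ratio definition", {
  # identical columns -> all zero (a = 0)
  c0 <- c(10L, 20L, 70L)
  expect_equal(compute_raw_lfc(c0, c0, pseudocount = 0), rep(0, 3))
  # tenfold frequency drop with constant totals -> exactly -1
  expect_equal(
    compute_raw_lfc(c(100L, 450L, 450L), c(10L, 495L, 495L),
                    pseudocount = 0)[1],
    -1)
  # extinct guide stays finite with a = 0.5; hand computation on 3 guides
  c0 <- c(50L, 30L, 20L)
  c24 <- c(0L, 60L, 40L)
  a <- 0.5
  L <- compute_raw_lfc(c0, c24, pseudocount = a)
  exp_L <- log10((c24 + a) / (sum(c24) + a * 3)) -
    log10((c0 + a) / (sum(c0) + a * 3))
  expect_equal(L, exp_L)
  expect_true(all(is.finite(L)))
  # without pseudocount the extinct guide is -Inf
  expect_identical(compute_raw_lfc(c0, c24, pseudocount = 0)[1], -Inf)
})

test_that("underrepresentation cutoff is 5% of the mean frequency", {
  # uniform library: nothing flagged
  expect_false(any(filter_underrepresented(rep(1 / 50, 50))))
  # N = 100 with one guide below 0.05/100
  f <- rep((1 - 0.0004) / 99, 100)
  f[37] <- 0.0004
  flags <- filter_underrepresented(f)
  expect_identical(which(flags), 37L)
  # boundary: exactly the cutoff is not flagged (strict less-than)
  f2 <- rep(1, 100) / 100
  f2[1] <- 0.05 * mean(f2)
  f2[2] <- f2[2] + 1 / 100 - f2[1]
  expect_false(filter_underrepresented(f2)[1])
  # threshold 0 disables the filter
  expect_false(any(filter_underrepresented(f, threshold_fraction = 0)))
  expect_error(filter_underrepresented(f, threshold_fraction = 1), "0, 1")
  expect_error(filter_underrepresented(f, threshold_fraction = -0.1), "0, 1")
})

test_that("control anchoring maps control medians to 0 and -1 exactly", {
  L <- c(-0.3, -1.0, 0.1, 0.05, -0.05, 0, -2.1, -1.9, -2.0)
  neg <- 4:6; pos <- 7:9
  nrm <- normalize_ncs(L, neg, pos)
  expect_identical(unname(nrm$anchors), c(0, -2))
  expect_equal(median(nrm$ncs[neg]), 0)
  expect_equal(median(nrm$ncs[pos]), -1)
  # linear midpoint: L = -1 with anchors 0 / -2 -> -0.5
  expect_equal(nrm$ncs[2], -0.5)
  expect_equal(nrm$ncs[neg[3]], 0)
  # degenerate anchors error
  expect_error(normalize_ncs(rep(0, 6), 1:3, 4:6), "degenerate")
  expect_error(normalize_ncs(L, integer(0), pos), "control")
})

test_that("anchoring is invariant to adding a constant to every raw score", {
  set.seed(31)
  for (i in 1:20) {
    L <- rnorm(60)
    neg <- 1:20; pos <- 21:40
    shift <- rnorm(1, sd = 5)
    a <- normalize_ncs(L, neg, pos)$ncs
    b <- normalize_ncs(L + shift, neg, pos)$ncs
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("NCS is monotone in the day-24 count with anchors fixed", {
  scr <- toy_screen()
  fit1 <- tiling_scan(scr$counts, scr$lib, sigma = 3)
  counts2 <- scr$counts
  counts2["t3", "A_d24_rep1"] <- 5L  # deeper dropout of one tiling guide
  fit2 <- tiling_scan(counts2, scr$lib, sigma = 3)
  expect_lt(fit2$ncs_mean[["t3"]], fit1$ncs_mean[["t3"]])
  # the total-count shift adds the same constant to every raw score, so the
  # anchored NCS of untouched guides is unchanged (affine invariance)
  expect_equal(fit2$ncs_mean[["t2"]], fit1$ncs_mean[["t2"]],
               tolerance = 1e-10)
})

test_that("replicate aggregation is a masked arithmetic mean", {
  ncs <- cbind(rep1 = c(-1, -1, -1), rep2 = c(-0.5, NA, -0.5),
               rep3 = c(0, 0, 0))
  rownames(ncs) <- c("a", "b", "c")
  expect_equal(unname(aggregate_replicates(ncs)[c("a", "c")]),
               c(-0.5, -0.5))
  expect_equal(unname(aggregate_replicates(ncs)[["b"]]), -0.5)
  flt <- matrix(FALSE, 3, 3, dimnames = dimnames(ncs))
  flt[1, 2] <- TRUE  # filtered replicate is excluded from the mean
  agg <- aggregate_replicates(ncs, flt)
  expect_equal(unname(agg[["a"]]), mean(c(-1, 0)))
  # identical replicates: mean equals each replicate
  same <- cbind(r1 = c(-1, 0.2), r2 = c(-1, 0.2))
  expect_equal(unname(aggregate_replicates(same)), c(-1, 0.2))
  # guide filtered everywhere is dropped
  flt_all <- flt; flt_all[1, ] <- TRUE
  agg2 <- aggregate_replicates(ncs, flt_all)
  expect_true(is.na(agg2[["a"]]))
  expect_identical(attr(agg2, "dropped"), "a")
})

test_that("Gaussian smoothing matches the double-loop oracle", {
  set.seed(17)
  for (i in 1:30) {
    P <- sample(30:120, 1)
    n <- sample(5:40, 1)
    res <- sample(P, n, replace = TRUE)
    v <- rnorm(n)
    sigma <- runif(1, 0.5, 10)
    prof <- smooth_profile(res, v, P, sigma)
    expect_equal(prof$value, oracle_smooth(res, v, P, sigma),
                 tolerance = 1e-10)
    # bounded by the codon-averaged inputs
    expect_true(all(prof$value >= min(prof$support_value) - 1e-12))
    expect_true(all(prof$value <= max(prof$support_value) + 1e-12))
  }
})

test_that("smoothing limits behave: constants, midpoints, sigma -> 0", {
  # constant input -> constant profile
  prof <- smooth_profile(c(5L, 20L, 40L), rep(-0.7, 3), 50, sigma = 4)
  expect_equal(prof$value, rep(-0.7, 50))
  # symmetric pair: midpoint is the average for any sigma
  for (s in c(1, 3, 8)) {
    prof <- smooth_profile(c(10L, 20L), c(0, -1), 30, sigma = s)
    expect_equal(prof$value[15], -0.5)
  }
  # sigma -> 0+ returns the codon-averaged values at occupied residues
  res <- c(10L, 10L, 25L)
  v <- c(-1, -0.5, 0.3)
  prof0 <- smooth_profile(res, v, 40, sigma = 1e-3)
  expect_equal(prof0$value[10], -0.75)
  expect_equal(prof0$value[25], 0.3)
  # guides sharing a codon are averaged before smoothing
  expect_identical(prof0$support_residue, c(10L, 25L))
  expect_equal(prof0$support_value, c(-0.75, 0.3))
  # degenerate inputs
  expect_error(smooth_profile(1L, -1, 10, 5), "at least 2")
  expect_warning(smooth_profile(c(3L, 3L), c(-1, 0), 10, 5), "one residue")
})

test_that("the toy screen fit reproduces hand-computed scores end to end", {
  scr <- toy_screen()
  fit <- tiling_scan(scr$counts, scr$lib, sigma = 3, pseudocount = 0)
  # by construction: neg-control counts are unchanged, pos controls drop
  # tenfold; totals 900 -> 490
  L_t2 <- log10((10 / 490) / (100 / 900))
  L_pos <- log10((10 / 490) / (100 / 900))
  m_neg <- log10((100 / 490) / (100 / 900))
  expect_equal(unname(fit$anchors[, 1]),
               c(m_neg, L_pos))
  expect_equal(fit$ncs_mean[["t2"]],
               (m_neg - L_t2) / (L_pos - m_neg))
  expect_equal(median(fit$ncs_mean[scr$lib$category == "neg_control"]), 0)
  expect_equal(median(fit$ncs_mean[scr$lib$category == "pos_control"]), -1)
})

test_that("score table and profile exports round-trip", {
  scr <- toy_screen()
  fit <- tiling_scan(scr$counts, scr$lib, sigma = 3)
  tab <- score_table(fit)
  expect_identical(nrow(tab), 9L)
  expect_true(all(c("raw_lfc_rep1", "ncs_rep1", "filtered_rep1",
                    "ncs_mean") %in% names(tab)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile(fit$profile, f)
  back <- read_profile(f)
  expect_equal(back$value, fit$profile$value)
  expect_identical(back$gene_id, "g")
})
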