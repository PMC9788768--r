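small_config <- function(n_tiling = 60, ...) {
  sim_config(n_tiling = n_tiling, n_neg = 15, n_pos = 15,
             depth_d0 = 1e5, depth_d24 = 1e5, n_replicates = 2, ...)
}

test_that("truth generation is reproducible and respects the fitness rules", {
  cfg <- small_config()
  t1 <- make_truth(200, config = cfg, seed = 5,
                   intervals = data.frame(start = 50, end = 70, s = -1.2))
  t2 <- make_truth(200, config = cfg, seed = 5,
                   intervals = data.frame(start = 50, end = 70, s = -1.2))
  expect_identical(t1, t2)
  expect_identical(nrow(t1$manifest), 90L)
  expect_identical(anyDuplicated(t1$manifest$protospacer), 0L)
  s <- t1$guide_effects
  expect_true(all(s <= 0))
  tiling <- t1$manifest[t1$manifest$category == "tiling", ]
  inside <- tiling$residue_index >= 50 & tiling$residue_index <= 70
  expect_true(all(s[tiling$guide_id[inside]] == -1.2))
  # far-outside guides carry only truncated baseline noise
  far <- tiling$residue_index < 30 | tiling$residue_index > 90
  expect_true(all(abs(s[tiling$guide_id[far]]) <= 0.2))
  # controls
  expect_true(all(s[t1$manifest$category == "neg_control"] == 0))
  expect_true(all(s[t1$manifest$category == "pos_control"] == cfg$s_pos))
})

test_that("null truth keeps all tiling fitness near zero", {
  t0 <- make_truth(150, intervals = data.frame(start = integer(0),
                                               end = integer(0),
                                               s = numeric(0)),
                   config = small_config(), seed = 2)
  s <- t0$guide_effects[t0$manifest$category == "tiling"]
  expect_true(all(s <= 0 & s >= -0.15))  # half-normal sd 0.05, 3-sigma
})

test_that("a whole-protein essential interval depresses every guide", {
  tr <- make_truth(100, intervals = data.frame(start = 1, end = 100, s = -1),
                   config = small_config(), seed = 3)
  s <- tr$guide_effects[tr$manifest$category == "tiling"]
  expect_true(all(s <= -0.8))
})

test_that("overlapping intervals and bad depths are rejected", {
  expect_error(make_truth(100,
                          intervals = data.frame(start = c(10, 30),
                                                 end = c(40, 60),
                                                 s = c(-1, -1)),
                          config = small_config()),
               "overlap")
  tr <- make_truth(100, config = small_config(), seed = 1,
                   intervals = data.frame(start = 10, end = 40, s = -1))
  bad <- small_config(); bad$depth_d0 <- 0
  expect_error(simulate_counts(tr, bad), "depth")
})

test_that("simulated counts are reproducible with the expected shape", {
  cfg <- small_config()
  tr <- make_truth(200, intervals = data.frame(start = 50, end = 70, s = -1),
                   config = cfg, seed = 7)
  m1 <- simulate_counts(tr, cfg, seed = 8)
  m2 <- simulate_counts(tr, cfg, seed = 8)
  expect_identical(m1, m2)
  expect_identical(dim(m1), c(90L, 4L))
  expect_identical(colnames(m1),
                   c("simA_d0_rep1", "simA_d24_rep1",
                     "simA_d0_rep2", "simA_d24_rep2"))
  expect_identical(unname(colSums(m1)), rep(1e5, 4))
  expect_true(all(m1 >= 0))
})

test_that("neutral screens conserve frequencies at high depth", {
  # all s = 0: day-24 frequencies should match day-0 up to sampling error
  ok <- 0
  for (seed in 1:5) {
    cfg <- sim_config(n_tiling = 100, n_neg = 10, n_pos = 10,
                      depth_d0 = 1e6, depth_d24 = 1e6, n_replicates = 1,
                      s_pos = 0)
    tr <- make_truth(120, intervals = data.frame(start = integer(0),
                                                 end = integer(0),
                                                 s = numeric(0)),
                     config = cfg, seed = seed)
    tr$guide_effects[] <- 0
    m <- simulate_counts(tr, cfg, seed = seed + 100)
    f <- to_frequencies(m)
    if (max(abs(f[, 2] - f[, 1])) < 0.005) ok <- ok + 1
  }
  expect_gte(ok, 5)
})

test_that("positive controls land at NCS -1 through the expected raw LFC", {
  # s_pos = -1 over 8 generations: expected raw L relative to the neutral
  # controls is log10(2^-8) ~ -2.408 before anchoring; anchoring then fixes
  # the pos-control median at -1 exactly
  cfg <- sim_config(n_tiling = 50, n_neg = 25, n_pos = 25,
                    depth_d0 = 1e6, depth_d24 = 1e6, n_replicates = 2)
  sim <- simulate_screen(300,
                         intervals = data.frame(start = 80, end = 100,
                                                s = -1.2),
                         config = cfg, seed = 11)
  fit <- tiling_scan(sim$counts, sim$truth$manifest)
  raw_neg <- apply(fit$raw_lfc[fit$library$category == "neg_control", ], 2,
                   median)
  raw_pos <- apply(fit$raw_lfc[fit$library$category == "pos_control", ], 2,
                   median)
  expect_equal(unname(raw_pos - raw_neg), rep(log10(2^-8), 2),
               tolerance = 0.02)
  for (j in 1:2) {
    ncs_pos <- fit$ncs[fit$library$category == "pos_control", j]
    expect_equal(median(ncs_pos[!is.na(ncs_pos)]), -1)
  }
})

test_that("FASTQ emission is seeded, sized and round-trips exactly", {
  lib <- make_truth(60, intervals = data.frame(start = integer(0),
                                               end = integer(0),
                                               s = numeric(0)),
                    config = small_config(n_tiling = 10),
                    seed = 4)$manifest
  counts <- stats::setNames(c(3L, 0L, 1L, rep(2L, 7), rep(0L, 30)),
                            lib$guide_id)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq(counts, lib, f1, read_length = 75, seed = 9)
  emit_fastq(counts, lib, f2, read_length = 75, seed = 9)
  expect_identical(readLines(f1), readLines(f2))
  lines <- readLines(f1)
  expect_identical(length(lines), 4L * 18L)
  expect_true(all(nchar(lines[seq(2, length(lines), 4)]) == 75))
  got <- suppressWarnings(count_guides(extract_protospacers(f1), lib))
  expect_identical(got$counts, counts)
  # degenerate inputs
  expect_error(emit_fastq(counts, lib, f1, read_length = 20), ">= 29")
  f3 <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq(stats::setNames(integer(40), lib$guide_id), lib, f3, seed = 1)
  expect_identical(length(readLines(f3)), 0L)
})
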