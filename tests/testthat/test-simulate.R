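# Simulator: provenance accounting, determinism, variant mixing and the
# statistical structure the pipeline assumes.

test_that("synthetic genome construction honours NUMT specs", {
  g <- mini_genome(seed = 3, numt_span = c(500, 1499), divergence = 0.02)
  ann <- g$decoys[[1]]$numt_annotations
  expect_equal(nrow(ann), 1)
  n_div <- length(ann$diverged_offsets[[1]])
  # ~20 substituted sites over 1,000 bases (exact binomial 99.9% band)
  expect_gte(n_div, qbinom(0.0005, 1000, 0.02))
  expect_lte(n_div, qbinom(0.9995, 1000, 0.02))
  # the insert really is a mutated copy of the mito segment
  seg <- substr(g$mito$sequence, 500, 1499)
  ins <- substr(g$decoys[[1]]$sequence, ann$insert_pos,
                ann$insert_pos + 999)
  diff <- which(strsplit(seg, "")[[1]] != strsplit(ins, "")[[1]])
  expect_identical(diff, as.integer(ann$diverged_offsets[[1]]))
  # targets never touch the mitochondrial contig
  expect_false(any(g$targets$mito))
  expect_error(build_synthetic_genome(
    1, 2000, data.frame(mt_start = 900, mt_end = 800, divergence = 0),
    seed = 1), "mt_start > mt_end")
  expect_error(build_synthetic_genome(
    1, 500, data.frame(mt_start = 1, mt_end = 1000, divergence = 0),
    seed = 1), "longer than the decoy")
})

test_that("provenance counts sum to emitted reads and are deterministic", {
  g <- mini_genome(seed = 5)
  prof <- sample_profile("s", 2000, off_target_fraction = 0.5,
                         mito_weight = 0.2, numt_weight = 0.1)
  sim1 <- simulate_sample(g, prof, seed = 42)
  sim2 <- simulate_sample(g, prof, seed = 42)
  expect_identical(sim1$reads, sim2$reads)       # determinism contract
  expect_equal(sum(sim1$truth$counts), nrow(sim1$reads))
  expect_equal(sim1$truth$total_fragments, nrow(sim1$reads))

  # FASTQ output is byte-identical across runs with the same seed
  p1 <- tempfile(); p2 <- tempfile()
  write_fastq(sim1, p1); write_fastq(sim2, p2)
  expect_identical(readLines(paste0(p1, "_R1.fastq")),
                   readLines(paste0(p2, "_R1.fastq")))

  # FASTQ round-trips into the read-table shape
  back <- read_fastq_pair(paste0(p1, "_R1.fastq"), paste0(p1, "_R2.fastq"))
  expect_identical(back$seq1, sim1$reads$seq1)
  expect_identical(back$seq2, sim1$reads$seq2)
})

test_that("error-free mito reads match the variant-substituted haplotype", {
  g <- mini_genome(seed = 5, divergence = 0.05)
  prof <- sample_profile("s", 800, off_target_fraction = 0.9,
                         mito_weight = 0.8, numt_weight = 0,
                         error_rate = 0, duplicate_rate = 0)
  gt <- genotype_spec(1555, "G", 1)  # homoplasmic alternative
  sim <- simulate_sample(g, prof, gt, seed = 9)
  hap <- g$mito$sequence
  substr(hap, 1555, 1555) <- "G"
  hap2 <- paste0(hap, hap)
  r <- sim$reads[sim$reads$class == "mito", ]
  expect_gt(nrow(r), 50)
  exp_r1 <- substring(hap2, r$start0 + 1, r$start0 + 100)
  expect_identical(r$seq1, exp_r1)
  exp_r2 <- revcomp(substring(hap2, r$start0 + r$frag_len - 99,
                              r$start0 + r$frag_len))
  expect_identical(r$seq2, exp_r2)
})

test_that("heteroplasmic mixing follows the binomial model at h = 0.5", {
  g <- mini_genome(seed = 5)
  prof <- sample_profile("s", 4000, off_target_fraction = 1,
                         mito_weight = 1, numt_weight = 0,
                         error_rate = 0, duplicate_rate = 0)
  sim <- simulate_sample(g, prof, genotype_spec(1555, "G", 0.5), seed = 13)
  r <- sim$reads
  # fragments covering position 1555 (circular offset)
  off <- (1554 - r$start0) %% g$mito$length
  cov <- off < r$frag_len
  base <- ifelse(off[cov] < 100,
                 substring(r$seq1[cov], off[cov] + 1, off[cov] + 1),
                 NA)
  base <- base[!is.na(base)]
  n <- length(base)
  k <- sum(base == "G")
  expect_gt(n, 100)
  ci <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
  expect_error(simulate_sample(g, prof, genotype_spec(1555, "G", 1.2)),
               "\\[0,1\\]")
})

test_that("realized off-target fraction converges to the profile value", {
  g <- mini_genome(seed = 5)
  prof <- sample_profile("s", 100000, off_target_fraction = 0.5,
                         mito_weight = 0.001, numt_weight = 0.001,
                         duplicate_rate = 0)
  sim <- simulate_sample(g, prof, seed = 21)
  cn <- sim$truth$counts
  off <- (cn[["off_target_nuclear"]] + cn[["mito"]] + cn[["numt"]])
  realized <- off / 100000
  se <- sqrt(0.5 * 0.5 / 100000)
  expect_lt(abs(realized - 0.5), 3 * se)
})

test_that("degenerate profiles behave as stated", {
  g <- mini_genome(seed = 5)
  prof <- sample_profile("s", 500, off_target_fraction = 0.5,
                         mito_weight = 0, numt_weight = 0)
  sim <- simulate_sample(g, prof, seed = 3)
  expect_equal(sim$truth$counts[["mito"]], 0)
  ex <- two_step_mito_extract(sim, g$mito, g$decoys, g$targets)
  p <- build_pileup(ex$mito, g$mito)
  expect_equal(coverage_summary(p)$median, 0)
  expect_error(sample_profile("s", 100, 0.5, mito_weight = 0.7,
                              numt_weight = 0.6), "off-target mass")
})

test_that("FFPE panel preset yields more off-target and mito mass than blood", {
  g <- mini_genome(seed = 5)
  blood <- profile_preset("blood_panel", total_read_pairs = 20000)
  ffpe <- profile_preset("ffpe_panel", total_read_pairs = 20000)
  sb <- simulate_sample(g, blood, seed = 31)$truth$counts
  sf <- simulate_sample(g, ffpe, seed = 31)$truth$counts
  off_frac <- function(cn) {
    (cn[["off_target_nuclear"]] + cn[["mito"]] + cn[["numt"]]) / 20000
  }
  expect_gt(off_frac(sf), off_frac(sb))
  expect_gt(sf[["mito"]], sb[["mito"]])
})

test_that("cohort simulation tracks truth and enforces unique ids", {
  g <- mini_genome(seed = 5)
  cohort <- data.frame(
    sample = sprintf("S%02d", 1:11), preset = "blood_panel",
    total_read_pairs = 200,
    pos = c(rep(NA, 10), 1555), alt = c(rep(NA, 10), "G"),
    h = c(rep(NA, 10), 1), stringsAsFactors = FALSE
  )
  out <- simulate_cohort(g, cohort, seed = 77)
  expect_equal(nrow(out$truth), 11)
  expect_equal(sum(!is.na(out$truth$pos)), 1)
  expect_identical(out$truth$ref[11], "A")

  # same master seed twice: byte-identical FASTQ output
  d1 <- tempfile(); d2 <- tempfile()
  simulate_cohort(g, cohort[1:2, ], seed = 77, dir = d1)
  simulate_cohort(g, cohort[1:2, ], seed = 77, dir = d2)
  expect_identical(readLines(file.path(d1, "S01_R1.fastq")),
                   readLines(file.path(d2, "S01_R1.fastq")))

  expect_error(simulate_cohort(g, cohort[c(1, 1), ], seed = 1), "duplicate")
  empty <- simulate_cohort(g, cohort[0, ], seed = 1)
  expect_equal(nrow(empty$truth), 0)
})
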