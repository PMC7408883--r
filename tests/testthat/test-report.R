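# Annotation, prevalence arithmetic, heteroplasmy evidence, VCF output and
# the end-to-end pipeline runner.

test_that("annotation is a left join onto the knowledge base", {
  kb <- load_kb()
  calls <- data.frame(
    pos = c(1555, 827, 5000), ref = c("A", "A", "C"),
    alt = c("G", "G", "T"), vaf = c(1, 0.71, 0.2),
    stringsAsFactors = FALSE
  )
  ann <- annotate_calls(calls, kb)
  expect_equal(nrow(ann), nrow(calls))  # every input call appears once
  expect_equal(ann$tier, c("strong", "needs_further_study", "not_in_kb"))

  # homopolymer caution attaches near m.961
  ref <- mito_reference(synthetic_mito_sequence())
  calls2 <- data.frame(pos = 961, ref = "T", alt = "C", vaf = 0.5)
  ann2 <- annotate_calls(calls2, kb, mito_ref = ref)
  expect_match(ann2$note, "homopolymer")
})

test_that("prevalence arithmetic matches the printed cohort numbers", {
  # 3 homoplasmic carriers in a cohort of 1245
  gt <- genotype_table_from_counts(
    ref_reads = c(rep(0, 3), rep(50, 1242)),
    alt_reads = c(26, 54, 66, rep(0, 1242))
  )
  prev <- cohort_prevalence(gt)
  expect_equal(prev$n_carriers, 3)
  expect_equal(prev$n_samples, 1245)
  expect_equal(prev$percent, 0.24)
  expect_equal(prev$ratio, 415)

  # 7 of 1688: one-decimal style and the 1:N ratio
  gt2 <- genotype_table_from_counts(
    ref_reads = c(rep(0, 7), rep(50, 1681)),
    alt_reads = c(rep(40, 7), rep(0, 1681))
  )
  prev2 <- cohort_prevalence(gt2)
  expect_equal(prev2$percent, 0.41)
  expect_equal(prev2$percent_1dp, 0.4)
  expect_equal(prev2$ratio, 241)

  # no carriers: percent 0, ratio undefined
  gt3 <- genotype_table_from_counts(rep(50, 100), rep(0, 100))
  prev3 <- cohort_prevalence(gt3)
  expect_equal(prev3$percent, 0)
  expect_true(is.na(prev3$ratio))
  expect_error(cohort_prevalence(gt3[0, ]), "empty")

  # undetermined samples stay in the denominator
  gt4 <- genotype_table_from_counts(c(0, 0, 50), c(30, 0, 0))
  prev4 <- cohort_prevalence(gt4)
  expect_equal(prev4$n_samples, 3)
  expect_equal(prev4$percent, 33.33)
  expect_equal(length(prev4$undetermined_samples), 1)
})

test_that("heteroplasmy evidence lists automatic and promoted entries", {
  vafs <- c(0.71, 0.12, 0.86, 0.86, 0.89, 0.719)
  alt <- round(100 * vafs)
  gt <- genotype_table_from_counts(
    ref_reads = c(100 - alt, 12, rep(50, 3)),
    alt_reads = c(alt, 156, rep(0, 3))
  )
  ev <- heteroplasmy_evidence(gt)
  expect_equal(nrow(ev), 6)     # the six in-window cases, none else
  expect_true(all(ev$provenance == "automatic"))
  expect_setequal(ev$vaf_reported, c(0.71, 0.12, 0.86, 0.89, 0.72))

  # the VAF 0.93 / 168x case joins only when promoted by review
  manual_sample <- gt$sample[gt$genotype_class == "manual_review"]
  ev2 <- heteroplasmy_evidence(gt, promote = manual_sample)
  expect_equal(nrow(ev2), 7)
  expect_equal(sum(ev2$provenance == "manual_review"), 1)
  expect_equal(ev2$vaf_reported[ev2$provenance == "manual_review"], 0.93)

  # no heteroplasmic calls: empty evidence list
  gt_wt <- genotype_table_from_counts(rep(50, 4), rep(0, 4))
  expect_equal(nrow(heteroplasmy_evidence(gt_wt)), 0)
})

test_that("VCF output carries header metadata and PASS semantics", {
  ref <- mito_reference(synthetic_mito_sequence())
  p <- pileup_at(ref, 1555, A = 9, G = 22)
  calls <- call_variants(p)
  f <- tempfile(fileext = ".vcf")
  write_vcf(calls, ref, f, mode = "clinical", vaf_min = 0.10)
  lines <- readLines(f)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  expect_true(any(grepl("##offmito_mode=clinical", lines)))
  expect_true(any(grepl("##contig=<ID=MT,length=16569>", lines)))
  rec <- lines[!startsWith(lines, "#")]
  expect_equal(length(rec), 1)
  fields <- strsplit(rec, "\t")[[1]]
  expect_equal(fields[c(1, 2, 4, 5, 7)], c("MT", "1555", "A", "G", "PASS"))
  expect_match(fields[8], "VAF=0.7097;DP=31")
})

test_that("the pipeline runner is deterministic and reports undetermined samples", {
  cfg <- list(
    out_dir = tempfile(), mode = "clinical", seed = 5, n_samples = 2,
    preset = "clinical_wes", total_read_pairs = 400,
    carrier_sample = "S001", carrier_pos = 1555, carrier_alt = "G",
    carrier_h = 1
  )
  res1 <- run_pipeline(cfg)
  cfg2 <- cfg; cfg2$out_dir <- tempfile()
  res2 <- run_pipeline(cfg2)
  # byte-identical outputs for a fixed config
  expect_identical(readLines(res1$files[["genotype"]]),
                   readLines(res2$files[["genotype"]]))
  expect_identical(readLines(res1$files[["prevalence"]]),
                   readLines(res2$files[["prevalence"]]))
  expect_true(file.exists(file.path(res1$out_dir, "pipeline.log")))
  expect_true(file.exists(file.path(res1$out_dir, "S001.vcf")))
  # clinical_wes at this scale leaves m.1555 below the clinical depth floor:
  # those samples are listed as undetermined, not dropped
  prev_txt <- readLines(res1$files[["prevalence"]])
  expect_true(any(grepl("n_samples=2", prev_txt)))
  gt <- res1$genotypes
  expect_true(all(c("S001", "S002") %in% gt$sample))

  # config file round-trip drives the same pipeline
  f <- tempfile(fileext = ".cfg")
  writeLines(c("# comment", paste0("out_dir = ", tempfile()),
               "mode = clinical", "seed = 5", "n_samples = 2",
               "preset = clinical_wes", "total_read_pairs = 400",
               "carrier_sample = S001"), f)
  res3 <- run_pipeline(f)
  expect_equal(sort(unique(res3$genotypes$sample)), c("S001", "S002"))
})

test_that("the pipeline accepts SAM input in place of FASTQ", {
  g <- build_synthetic_genome(seed = 5)
  prof <- sample_profile("sam1", 400, off_target_fraction = 1,
                         mito_weight = 1, numt_weight = 0,
                         error_rate = 0, duplicate_rate = 0)
  sim <- simulate_sample(g, prof, genotype_spec(1555, "G", 1), seed = 6)
  ex <- two_step_mito_extract(sim, g$mito, g$decoys, g$targets)
  sam <- tempfile(fileext = ".sam")
  write_sam(ex$mito, g$mito, sam)
  cfg <- list(out_dir = tempfile(), mode = "research_low_coverage",
              seed = 5, sam = sam, sample_ids = "sam1")
  res <- run_pipeline(cfg)
  gt <- res$genotypes
  call <- gt[gt$pos == 1555 & gt$sample == "sam1", ]
  expect_equal(call$genotype_class, "carrier_homoplasmic")
})
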