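# Seeded alignment, two-step NUMT relocation, deduplication and SAM
# interoperability.

test_that("exact reads place at their true origin with zero mismatches", {
  g <- mini_genome(seed = 11)
  idx <- seed_index(c(list(g$mito), g$decoys), k = 15)
  L <- g$mito$length
  starts <- c(0, 700, 1500, 2500)
  reads <- substring(g$mito$sequence, starts + 1, starts + 100)
  res <- align_reads(reads, idx)
  expect_true(all(res$mapped))
  expect_equal(res$contig, rep("MT", 4))
  expect_equal(res$start0, starts)
  expect_equal(res$mismatches, rep(0L, 4))
  expect_equal(res$strand, rep("+", 4))

  # reverse-complement reads place at the same coordinates on minus strand
  res_rc <- align_reads(revcomp(reads), idx)
  expect_equal(res_rc$start0, starts)
  expect_equal(res_rc$strand, rep("-", 4))

  # origin-spanning read on the circular contig
  wrap <- paste0(substr(g$mito$sequence, L - 49, L),
                 substr(g$mito$sequence, 1, 50))
  res_w <- align_reads(wrap, idx)
  expect_true(res_w$mapped)
  expect_equal(res_w$start0, L - 50)
  expect_equal(res_w$mismatches, 0L)
})

test_that("index construction validates its inputs", {
  expect_error(seed_index(character(0)), "no sequences")
  expect_error(seed_index(c(short = "ACGTACGT"), k = 15), "shortest contig")
  g <- mini_genome(seed = 11)
  idx <- seed_index(list(g$mito), k = 15)
  expect_warning(res <- align_reads("ACGT", idx), "shorter than k")
  expect_false(res$mapped)
  # a read with no seed hit anywhere is unmapped
  res2 <- align_reads(strrep("AC", 50), idx)
  expect_false(res2$mapped)
})

test_that("NUMT reads overlapping diverged sites relocate to nuclear", {
  g <- mini_genome(seed = 11, divergence = 0.05)
  ann <- g$decoys[[1]]$numt_annotations
  ins0 <- ann$insert_pos - 1
  # reads drawn from the NUMT copy in the decoy
  set.seed(101)
  starts <- ins0 + sort(sample(0:(1000 - 100), 400, replace = TRUE))
  reads <- data.frame(
    fragment = sprintf("n%03d", seq_along(starts)), mate = 1L,
    seq = substring(g$decoys[[1]]$sequence, starts + 1, starts + 100),
    qual = strrep("?", 100), stringsAsFactors = FALSE
  )
  ex <- two_step_mito_extract(reads, g$mito, g$decoys, g$targets)
  # every read overlapping >= 1 diverged site scores strictly higher on the
  # nuclear copy; zero-diagnostic reads tie and relocate by the tie rule
  expect_equal(nrow(ex$mito), 0)
  div <- ann$diverged_offsets[[1]]
  zero_diag <- vapply(starts - ins0, function(s) {
    !any(div > s & div <= s + 100)
  }, logical(1))
  expect_equal(ex$ambiguous, sum(zero_diag))
})

test_that("zero-diagnostic true mito reads are relocated by the tie rule", {
  # exact NUMT copy (divergence 0): every read from the copied span ties
  g <- mini_genome(seed = 11, numt_span = c(1000, 1399), divergence = 0)
  starts <- seq(1000, 1280, by = 40) - 1
  reads <- data.frame(
    fragment = sprintf("m%02d", seq_along(starts)), mate = 1L,
    seq = substring(g$mito$sequence, starts + 1, starts + 100),
    qual = strrep("?", 100), stringsAsFactors = FALSE
  )
  ex <- two_step_mito_extract(reads, g$mito, g$decoys, g$targets)
  expect_equal(nrow(ex$mito), 0)
  expect_equal(ex$ambiguous, length(starts))
  expect_equal(ex$relocated, length(starts))
})

test_that("extraction with no NUMTs retains exactly the mito-origin reads", {
  g <- build_synthetic_genome(n_decoys = 2, decoy_length = 5000,
                              numt_specs = NULL, seed = 4,
                              mito_length = 3000)
  prof <- sample_profile("s", 600, off_target_fraction = 0.6,
                         mito_weight = 0.4, numt_weight = 0,
                         error_rate = 0, duplicate_rate = 0)
  sim <- simulate_sample(g, prof, seed = 8)
  ex <- two_step_mito_extract(sim, g$mito, g$decoys, g$targets)
  truth_mito <- sim$reads$id[sim$reads$class == "mito"]
  expect_setequal(unique(ex$mito$fragment), truth_mito)
  expect_equal(nrow(ex$mito), 2 * length(truth_mito))
  expect_equal(ex$relocated, 0)
  # conservation invariants
  t <- ex$tally
  expect_equal(t$on_target + t$off_target, t$mapped)
  expect_lte(t$mito_mapped, t$off_target)
})

test_that("unmappable reads stay in the total but out of the mapped tally", {
  g <- mini_genome(seed = 11)
  reads <- data.frame(
    fragment = c("r1", "r2"), mate = 1L,
    seq = c(substr(g$mito$sequence, 1, 100), strrep("AC", 50)),
    qual = strrep("?", 100), stringsAsFactors = FALSE
  )
  ex <- two_step_mito_extract(reads, g$mito, g$decoys, g$targets)
  expect_equal(ex$tally$total_reads, 2)
  expect_equal(ex$tally$mapped, 1)
  expect_equal(ex$tally$mito_mapped, 1)
})

test_that("deduplication keeps one fragment per coordinate signature", {
  aln <- data.frame(
    fragment = rep(c("f1", "f2", "f3"), each = 2),
    mate = rep(1:2, 3), contig = "MT",
    start0 = c(100, 250, 100, 250, 101, 250),
    strand = rep(c("+", "-"), 3),
    seq = strrep("A", 100), qual = strrep("?", 100),
    stringsAsFactors = FALSE
  )
  dd <- deduplicate_alignments(aln)
  # f1 and f2 share both mates' coordinates -> one survives; f3 differs by 1
  expect_setequal(unique(dd$fragment), c("f1", "f3"))
  expect_equal(attr(dd, "removed"), 2L)
  # idempotence
  dd2 <- deduplicate_alignments(dd)
  expect_equal(attr(dd2, "removed"), 0L)
  attr(dd2, "removed") <- attr(dd, "removed") <- NULL
  expect_equal(dd2, dd)
  # empty input passes through
  expect_equal(nrow(deduplicate_alignments(aln[0, ])), 0)
})

test_that("SAM import tallies on/off-target and mito reads", {
  f <- tempfile(fileext = ".sam")
  tgt <- target_regions(data.frame(contig = "chr1", start = 100, end = 200))
  sam <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:10000",
    "@SQ\tSN:chrM\tLN:16569",
    # on-target: overlaps [100,200) by >= 1 base (POS is 1-based)
    sprintf("r%d\t0\tchr1\t%d\t60\t50M\t*\t0\t0\t%s\t%s", 1:3,
            c(120, 160, 151), strrep("A", 50), strrep("I", 50)),
    # overlap by exactly one base: 0-based [199,249) vs target [100,200)
    sprintf("r4\t0\tchr1\t200\t60\t50M\t*\t0\t0\t%s\t%s",
            strrep("A", 50), strrep("I", 50)),
    # off-target nuclear
    sprintf("r5\t16\tchr1\t5000\t60\t50M\t*\t0\t0\t%s\t%s",
            strrep("C", 50), strrep("I", 50)),
    # mitochondrial (case-insensitive contig match)
    sprintf("r%d\t0\tchrM\t%d\t60\t50M\t*\t0\t0\t%s\t%s", 6:7,
            c(1500, 1540), strrep("G", 50), strrep("I", 50)),
    # unmapped: excluded from on/off but counted in total
    sprintf("r8\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
            strrep("T", 50), strrep("I", 50))
  )
  writeLines(sam, f)
  imp <- import_alignments(f, tgt)
  expect_equal(imp$tally$total_reads, 8)
  expect_equal(imp$tally$mapped, 7)
  expect_equal(imp$tally$on_target, 4)   # r4 overlaps by exactly 1 base
  expect_equal(imp$tally$off_target, 3)
  expect_equal(imp$tally$mito_mapped, 2)

  # unknown expected mito contig: warning by default, error when strict
  expect_warning(import_alignments(f, tgt, mito_contig = "NC_012920"),
                 "not found")
  expect_error(import_alignments(f, tgt, mito_contig = "NC_012920",
                                 strict = TRUE), "not found")
})

test_that("written SAM re-imports with identical coordinates", {
  g <- mini_genome(seed = 11)
  prof <- sample_profile("s", 150, off_target_fraction = 1,
                         mito_weight = 1, numt_weight = 0,
                         error_rate = 0, duplicate_rate = 0)
  sim <- simulate_sample(g, prof, seed = 2)
  ex <- two_step_mito_extract(sim, g$mito, g$decoys, g$targets)
  f <- tempfile(fileext = ".sam")
  write_sam(ex$mito, g$mito, f)
  imp <- import_alignments(f)
  expect_equal(nrow(imp$alignments), nrow(ex$mito))
  expect_equal(sort(imp$alignments$start0), sort(ex$mito$start0))
  expect_equal(imp$tally$mito_mapped, nrow(ex$mito))
})
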