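# End-to-end composition: simulate -> extract -> dedup -> pileup ->
# genotype -> report, driven by a flat key=value config. Every output file
# carries a header with the package version, a config hash and the active
# thresholds; a plain-text log records read tallies per stage.

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are kept
#' as strings; numeric coercion happens at the point of use.
#'
#' @param file config path.
#' @return named list.
#' @export
read_config <- function(file) {
  lines <- readLines(file)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                  vapply(kv, `[[`, character(1), 1))
}

config_hash <- function(config) {
  # hash only analysis-relevant keys: output location does not change results
  config <- config[setdiff(sort(names(config)), "out_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(config), unlist(lapply(config, as.character)),
                   sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

output_header <- function(config, extra = character(0)) {
  c(sprintf("# offmito version=%s config_hash=%s", offmito_version(),
            config_hash(config)),
    sprintf("# mode=%s vaf_min=%s min_alt_reads=%s",
            config$mode %||% "clinical", config$vaf_min %||% "0.1",
            config$min_alt_reads %||% "2"),
    extra)
}

#' Run the full off-target genotyping pipeline
#'
#' Composes the pipeline stages over a simulated cohort (or FASTQ/SAM
#' inputs) and writes `tally.tsv`, per-sample pileup TSVs, `genotype.tsv`,
#' per-sample VCFs, `prevalence.txt` and `pipeline.log` into `out_dir`.
#' Deterministic for a fixed config (including its seed).
#'
#' @param config named list or path to a key=value file. Recognised keys:
#'   `out_dir` (required), `mode` (`clinical`/`research_low_coverage`),
#'   `seed`, `vaf_min`, `min_alt_reads`, `min_bq`, `min_mq`; simulation
#'   keys `n_samples`, `preset`, `total_read_pairs`, `carrier_sample`,
#'   `carrier_pos`, `carrier_alt`, `carrier_h`; or input keys `sam` (one
#'   SAM/BAM per sample, comma-separated) and `sample_ids`.
#' @return invisibly, a list with the genotype table, prevalence report,
#'   metrics and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- read_config(config)
  }
  if (is.null(config$out_dir)) stop("config needs out_dir")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mode <- config$mode %||% "clinical"
  seed <- as.integer(config$seed %||% 1)
  vaf_min <- as.numeric(config$vaf_min %||% 0.10)
  min_alt <- as.integer(config$min_alt_reads %||% 2)
  min_bq <- as.integer(config$min_bq %||% 20)
  min_mq <- as.numeric(config$min_mq %||% 1)
  log_lines <- character(0)
  log <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  log("stage=start version=", offmito_version(),
      " config_hash=", config_hash(config), " seed=", seed)

  genome <- build_synthetic_genome(seed = seed)
  pileups <- list()
  tallies <- list()

  if (!is.null(config$sam)) {
    files <- strsplit(config$sam, ",")[[1]]
    ids <- if (!is.null(config$sample_ids)) {
      strsplit(config$sample_ids, ",")[[1]]
    } else {
      tools::file_path_sans_ext(basename(files))
    }
    for (i in seq_along(files)) {
      imp <- import_alignments(files[i], genome$targets)
      aln <- imp$alignments
      aln <- aln[is_mito_contig(aln$contig), , drop = FALSE]
      aln <- deduplicate_alignments(aln)
      aln$mapq_proxy <- aln$mapq
      pileups[[ids[i]]] <- build_pileup(aln, genome$mito, min_bq, min_mq)
      tallies[[ids[i]]] <- imp$tally
      log("stage=import sample=", ids[i], " total=", imp$tally$total_reads,
          " mito=", imp$tally$mito_mapped,
          " dup_removed=", attr(aln, "removed"))
    }
  } else {
    n_samples <- as.integer(config$n_samples %||% 3)
    cohort <- data.frame(
      sample = sprintf("S%03d", seq_len(n_samples)),
      preset = config$preset %||% "clinical_wes",
      total_read_pairs = as.integer(config$total_read_pairs %||% 4000),
      pos = NA_integer_, alt = NA_character_, h = NA_real_,
      stringsAsFactors = FALSE
    )
    if (!is.null(config$carrier_sample)) {
      i <- match(config$carrier_sample, cohort$sample)
      cohort$pos[i] <- as.integer(config$carrier_pos %||% 1555)
      cohort$alt[i] <- config$carrier_alt %||% "G"
      cohort$h[i] <- as.numeric(config$carrier_h %||% 1)
    }
    sims <- simulate_cohort(genome, cohort, seed = seed)
    for (nm in names(sims$samples)) {
      ex <- two_step_mito_extract(sims$samples[[nm]], genome$mito,
                                  genome$decoys, genome$targets)
      dd <- deduplicate_alignments(ex$mito)
      ex$tally$duplicates_removed <- attr(dd, "removed")
      pileups[[nm]] <- build_pileup(dd, genome$mito, min_bq, min_mq)
      tallies[[nm]] <- ex$tally
      log("stage=extract sample=", nm, " total=", ex$tally$total_reads,
          " mito_retained=", nrow(ex$mito), " relocated=", ex$relocated,
          " ambiguous=", ex$ambiguous, " dup_removed=", attr(dd, "removed"))
    }
  }

  hdr <- output_header(config)
  samples <- lapply(names(pileups), function(nm) {
    list(pileup = pileups[[nm]], tally = tallies[[nm]])
  })
  names(samples) <- names(pileups)
  cov <- cohort_coverage_table(samples)
  tally_path <- file.path(out_dir, "tally.tsv")
  con <- file(tally_path, "w")
  writeLines(hdr, con)
  utils::write.table(cov$metrics, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)

  for (nm in names(pileups)) {
    write_pileup_tsv(pileups[[nm]], file.path(out_dir,
                                              paste0(nm, ".pileup.tsv")),
                     region = mt_rnr1_region())
  }

  kb <- load_kb(mito_ref = genome$mito)
  gt <- genotype_cohort(pileups, mode = mode, kb = kb)
  gt_path <- file.path(out_dir, "genotype.tsv")
  con <- file(gt_path, "w")
  writeLines(hdr, con)
  utils::write.table(as.data.frame(gt), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)

  for (nm in names(pileups)) {
    calls <- call_variants(pileups[[nm]], vaf_min = vaf_min,
                           min_alt_reads = min_alt)
    write_vcf(calls, genome$mito, file.path(out_dir, paste0(nm, ".vcf")),
              mode = mode, vaf_min = vaf_min)
  }

  prev <- cohort_prevalence(gt)
  prev_path <- file.path(out_dir, "prevalence.txt")
  prev_txt <- c(
    hdr,
    sprintf("n_samples=%d", prev$n_samples),
    sprintf("n_carriers=%d", prev$n_carriers),
    sprintf("percent=%.2f", prev$percent),
    sprintf("percent_1dp=%.1f", prev$percent_1dp),
    sprintf("ratio=%s", if (is.na(prev$ratio)) "NA"
            else paste0("1:", prev$ratio)),
    if (length(prev$undetermined_samples)) c(
      "[undetermined]",
      paste0("sample=", prev$undetermined_samples)
    ) else character(0)
  )
  writeLines(prev_txt, prev_path)
  log("stage=report n_samples=", prev$n_samples,
      " n_carriers=", prev$n_carriers)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))

  invisible(list(genotypes = gt, prevalence = prev, metrics = cov$metrics,
                 out_dir = out_dir,
                 files = c(tally = tally_path, genotype = gt_path,
                           prevalence = prev_path)))
}
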