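# Per-position base counts over the mitochondrial genome and the coverage /
# off-target metrics computed from them. Counts are quality-filtered at
# build time (minimum base quality, minimum mapping-quality proxy); both
# filter values are recorded in the object and echoed into every output
# header. Overlapping mates are counted independently (naive readcount
# behaviour) — a documented VAF bias source at coverage near the fragment
# length scale.

#' Build a quality-filtered mitochondrial pileup
#'
#' Each aligned base with base quality >= `min_bq`, from a read with mapping
#' quality proxy >= `min_mq`, increments its base counter at its 1-based
#' position. Depth at a position is the sum of the four base counts.
#'
#' @param aln mitochondrial alignments (fragment, start0, strand, seq, qual,
#'   optionally mapq_proxy), e.g. the `mito` element of
#'   [two_step_mito_extract()].
#' @param mito_ref a [mito_reference()].
#' @param min_bq minimum Phred base quality (default 20).
#' @param min_mq minimum mapping-quality proxy (default 1).
#' @return object of class `mito_pileup`: a 4 x L count matrix (rows
#'   A/C/G/T) plus the reference and the applied filters.
#' @export
build_pileup <- function(aln, mito_ref, min_bq = 20, min_mq = 1) {
  stopifnot(inherits(mito_ref, "mito_reference"))
  L <- mito_ref$length
  counts <- matrix(0L, nrow = 4, ncol = L, dimnames = list(DNA_BASES, NULL))
  n_used <- 0L
  if (!is.null(aln) && nrow(aln) > 0) {
    if (!is.null(aln$mapq_proxy)) {
      aln <- aln[is.na(aln$mapq_proxy) | aln$mapq_proxy >= min_mq, ,
                 drop = FALSE]
    }
    n_used <- nrow(aln)
    if (n_used > 0) {
      lens <- nchar(aln$seq)
      if (!mito_ref$circular && any(aln$start0 + lens > L)) {
        stop("alignment extends beyond the contig end (non-circular mode)")
      }
      pos <- rep(aln$start0, lens) + sequence(lens)  # 1-based
      if (mito_ref$circular) pos <- (pos - 1L) %% L + 1L
      bases <- unlist(strsplit(aln$seq, ""), use.names = FALSE)
      quals <- as.integer(charToRaw(paste(aln$qual, collapse = ""))) - 33L
      code <- base_codes(bases)
      keep <- quals >= min_bq & code > 0L
      idx <- (pos[keep] - 1L) * 4L + code[keep]
      tab <- tabulate(idx, nbins = 4L * L)
      counts <- matrix(as.integer(tab), nrow = 4,
                       dimnames = list(DNA_BASES, NULL))
    }
  }
  structure(
    list(counts = counts, ref = mito_ref,
         filters = list(min_bq = min_bq, min_mq = min_mq),
         n_alignments = n_used),
    class = "mito_pileup"
  )
}

#' Build a pileup directly from per-position base counts
#'
#' For summarising externally counted data (or constructing worked
#' examples): positions absent from `df` get zero counts.
#'
#' @param df data.frame with column `pos` (1-based) and any of `A`, `C`,
#'   `G`, `T` count columns.
#' @param mito_ref a [mito_reference()].
#' @return a `mito_pileup`.
#' @export
pileup_from_counts <- function(df, mito_ref) {
  stopifnot(inherits(mito_ref, "mito_reference"))
  L <- mito_ref$length
  counts <- matrix(0L, nrow = 4, ncol = L, dimnames = list(DNA_BASES, NULL))
  if (any(df$pos < 1 | df$pos > L)) stop("counts outside 1..", L)
  for (b in DNA_BASES) {
    if (!is.null(df[[b]])) counts[b, df$pos] <- as.integer(df[[b]])
  }
  structure(
    list(counts = counts, ref = mito_ref,
         filters = list(min_bq = NA, min_mq = NA),
         n_alignments = NA_integer_),
    class = "mito_pileup"
  )
}

#' @export
print.mito_pileup <- function(x, ...) {
  d <- pileup_depth(x)
  cat(sprintf(
    "<mito_pileup> %s: %d positions, median depth %.0f (filters: bq>=%s, mq>=%s)\n",
    x$ref$name, ncol(x$counts), stats::median(d),
    x$filters$min_bq, x$filters$min_mq))
  invisible(x)
}

#' Per-position depth of a pileup
#'
#' @param pileup a `mito_pileup`.
#' @return integer vector of depths (A+C+G+T per position).
#' @export
pileup_depth <- function(pileup) {
  colSums(pileup$counts)
}

#' Off-target mitochondrial read fraction
#'
#' The fraction between the number of reads mapping to the mitochondrial
#' contig and the number of reads mapping off-target. Undefined (NA) when no
#' off-target reads exist.
#'
#' @param tally an [alignment_tally()].
#' @return numeric fraction, or NA when `off_target == 0`.
#' @export
off_target_fraction <- function(tally) {
  if (tally$off_target == 0) return(NA_real_)
  tally$mito_mapped / tally$off_target
}

#' Coverage summary over a region
#'
#' Median depth (zero-depth positions included), fraction of positions at or
#' above each threshold, and depth at named positions of pharmacogenetic
#' interest.
#'
#' @param pileup a `mito_pileup`.
#' @param region a [mt_rnr1_region()], `c(start, end)`, or NULL for the
#'   whole contig.
#' @param thresholds depth thresholds for the position fractions.
#' @param at named positions whose depth is reported individually.
#' @return list of class `coverage_summary`.
#' @export
coverage_summary <- function(pileup, region = NULL,
                             thresholds = c(5, 20, 30, 40),
                             at = c(1555, 1494, 1095)) {
  d <- pileup_depth(pileup)
  b <- region_bounds(region, pileup$ref$length)
  dr <- d[b[1]:b[2]]
  at <- at[at >= 1 & at <= pileup$ref$length]
  structure(
    list(
      region = b,
      n_positions = length(dr),
      median = stats::median(dr),
      frac_ge = stats::setNames(
        vapply(thresholds, function(t) mean(dr >= t), numeric(1)),
        paste0("ge", thresholds)),
      depth_at = stats::setNames(d[at], paste0("m", at))
    ),
    class = "coverage_summary"
  )
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("<coverage_summary> %d-%d: median %.0fx; ", x$region[1],
              x$region[2], x$median))
  cat(paste(sprintf(">=%s: %.2g", sub("ge", "", names(x$frac_ge)),
                    x$frac_ge), collapse = ", "), "\n")
  if (length(x$depth_at)) {
    cat("  depth at ", paste(names(x$depth_at), x$depth_at, sep = "=",
                             collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Cohort coverage metrics and per-position median track
#'
#' @param samples named list; each element a list with `pileup`
#'   (a `mito_pileup`) and `tally` (an [alignment_tally()], optional).
#' @return list with `metrics` (per-sample data.frame: sample,
#'   off_target_fraction, median_mito_coverage, depth_m1555) and
#'   `median_track` (per-position across-sample median depth).
#' @export
cohort_coverage_table <- function(samples) {
  if (length(samples) == 0) stop("need at least one sample")
  depth_mat <- vapply(samples, function(s) as.numeric(pileup_depth(s$pileup)),
                      numeric(ncol(samples[[1]]$pileup$counts)))
  metrics <- data.frame(
    sample = names(samples),
    off_target_fraction = vapply(samples, function(s) {
      if (is.null(s$tally)) NA_real_ else off_target_fraction(s$tally)
    }, numeric(1)),
    median_mito_coverage = apply(depth_mat, 2, stats::median),
    depth_m1555 = if (nrow(depth_mat) >= 1555) depth_mat[1555, ] else NA,
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(metrics = metrics,
       median_track = apply(depth_mat, 1, stats::median))
}

#' Write per-position counts to TSV
#'
#' Columns `pos ref A C G T depth`; the header comments record the applied
#' filters.
#'
#' @param pileup a `mito_pileup`.
#' @param file output path.
#' @param region optional restriction.
#' @return `file`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, file, region = NULL) {
  b <- region_bounds(region, pileup$ref$length)
  pos <- b[1]:b[2]
  df <- data.frame(
    pos = pos,
    ref = mito_base(pileup$ref, pos),
    A = pileup$counts["A", pos], C = pileup$counts["C", pos],
    G = pileup$counts["G", pos], T = pileup$counts["T", pos],
    depth = pileup_depth(pileup)[pos]
  )
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# offmito version=%s min_bq=%s min_mq=%s",
                     offmito_version(), pileup$filters$min_bq,
                     pileup$filters$min_mq), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
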