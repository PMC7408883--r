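# Two-step mitochondrial extraction: (1) align all reads to the
# mitochondrial contig alone; (2) competitively realign the mito-mapped
# subset against the combined nuclear+mito reference and relocate back to
# the nuclear genome every read whose best combined placement is nuclear.
# Ties go to nuclear (conservative: minimises false mitochondrial
# retention); tied reads are counted and reported as ambiguous.

#' Alignment tally
#'
#' Read-accounting container. Invariants: `on_target + off_target = mapped`;
#' `mito_mapped <= off_target` (the mitochondrial contig is never part of a
#' capture design, so mitochondrial reads are off-target by definition).
#'
#' @param total_reads,mapped,on_target,off_target,mito_mapped,duplicates_removed
#'   integer counts.
#' @return list of class `alignment_tally`.
#' @export
alignment_tally <- function(total_reads, mapped, on_target, off_target,
                            mito_mapped, duplicates_removed = 0L) {
  if (on_target + off_target != mapped) {
    stop("tally violates on_target + off_target = mapped")
  }
  if (mito_mapped > off_target) {
    stop("tally violates mito_mapped <= off_target")
  }
  structure(
    list(total_reads = as.integer(total_reads), mapped = as.integer(mapped),
         on_target = as.integer(on_target),
         off_target = as.integer(off_target),
         mito_mapped = as.integer(mito_mapped),
         duplicates_removed = as.integer(duplicates_removed)),
    class = "alignment_tally"
  )
}

#' @export
print.alignment_tally <- function(x, ...) {
  cat(sprintf(
    "<alignment_tally> total=%d mapped=%d on=%d off=%d mito=%d dup_removed=%d\n",
    x$total_reads, x$mapped, x$on_target, x$off_target, x$mito_mapped,
    x$duplicates_removed))
  invisible(x)
}

# Flatten a paired read table (id, seq1, qual1, seq2, qual2) or sim_sample
# into one row per mate.
flatten_reads <- function(reads) {
  if (inherits(reads, "sim_sample")) reads <- reads$reads
  if (!is.null(reads$seq1)) {
    data.frame(
      fragment = rep(reads$id, 2L),
      mate = rep(c(1L, 2L), each = nrow(reads)),
      seq = c(reads$seq1, reads$seq2),
      qual = c(reads$qual1, reads$qual2),
      stringsAsFactors = FALSE
    )
  } else {
    stopifnot(all(c("fragment", "mate", "seq") %in% names(reads)))
    if (is.null(reads$qual)) reads$qual <- strrep("?", nchar(reads$seq))
    reads
  }
}

#' Two-step mitochondrial read extraction
#'
#' Step 1 aligns every read to the mitochondrial reference alone; step 2
#' realigns the step-1 hits against the combined reference. A read is
#' retained as mitochondrial iff its best combined placement is on the
#' mitochondrial contig with a strictly higher score than any nuclear
#' placement; score ties relocate to nuclear and are reported as
#' `ambiguous`. Reads never mapped to the mitochondrial contig are aligned
#' to the nuclear contigs for the on/off-target tally.
#'
#' @param reads paired read table (`sim_sample`, its `$reads`, or a
#'   flattened fragment/mate/seq/qual data.frame).
#' @param mito_ref a [mito_reference()].
#' @param decoys list of [nuclear_decoy()] contigs (the nuclear reference).
#' @param targets a [target_regions()] object (for the tally).
#' @param scoring an [alignment_scoring()].
#' @param k seed k-mer size.
#' @return list of class `mito_extraction`: `mito` (retained alignments:
#'   fragment, mate, contig, start0, strand, score, mismatches, mapq_proxy,
#'   seq, qual), `relocated` (count), `ambiguous` (count), `tally`
#'   (an [alignment_tally()]).
#' @export
two_step_mito_extract <- function(reads, mito_ref, decoys, targets,
                                  scoring = alignment_scoring(), k = 15) {
  stopifnot(inherits(mito_ref, "mito_reference"))
  rt <- flatten_reads(reads)
  n <- nrow(rt)

  mito_idx <- seed_index(list(mito_ref), k = k)
  step1 <- align_reads(rt$seq, mito_idx, scoring, ids = rt$fragment)
  hit1 <- which(step1$mapped)

  combined_idx <- seed_index(c(list(mito_ref), decoys), k = k)
  if (!(mito_ref$name %in% combined_idx$contigs)) {
    stop("combined reference lacks the mitochondrial contig")
  }
  comp <- align_competitive(rt$seq[hit1], combined_idx, scoring,
                            mito_ref$name)
  retained <- comp$mito_score > comp$nuc_score & comp$mito_score > 0
  ambiguous <- sum(comp$mito_score == comp$nuc_score &
                     is.finite(comp$mito_score) & comp$mito_score > 0)
  relocated <- length(hit1) - sum(retained)

  keep <- hit1[retained]
  # store reference-oriented sequence/quality (SAM convention), so the
  # pileup can count bases directly
  seq_keep <- rt$seq[keep]
  qual_keep <- rt$qual[keep]
  minus <- which(comp$mito_strand[retained] == "-")
  if (length(minus)) {
    seq_keep[minus] <- revcomp(seq_keep[minus])
    qual_keep[minus] <- vapply(qual_keep[minus], function(q) {
      paste(rev(strsplit(q, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  mito_aln <- data.frame(
    fragment = rt$fragment[keep], mate = rt$mate[keep],
    contig = rep(mito_ref$name, length(keep)),
    start0 = comp$mito_start0[retained], strand = comp$mito_strand[retained],
    score = comp$mito_score[retained], mismatches = comp$mito_mm[retained],
    mapq_proxy = ifelse(is.finite(comp$nuc_score[retained]),
                        comp$mito_score[retained] - comp$nuc_score[retained],
                        comp$mito_score[retained]),
    seq = seq_keep, qual = qual_keep, stringsAsFactors = FALSE
  )

  # nuclear placements for the tally: relocated reads use their step-2
  # nuclear placement; reads unmapped on mito are aligned to nuclear only
  nuc_contig <- character(0); nuc_start0 <- integer(0); nuc_len <- integer(0)
  reloc_idx <- hit1[!retained]
  if (length(reloc_idx)) {
    sel <- !retained & is.finite(comp$nuc_score) & comp$nuc_score > 0
    nuc_contig <- comp$nuc_contig[sel]
    nuc_start0 <- comp$nuc_start0[sel]
    nuc_len <- nchar(rt$seq[hit1[sel]])
  }
  rest <- setdiff(seq_len(n), hit1)
  n_nuc_mapped <- length(nuc_contig)
  if (length(rest) && length(decoys)) {
    nuc_idx <- seed_index(decoys, k = k)
    a <- align_reads(rt$seq[rest], nuc_idx, scoring)
    m <- which(a$mapped)
    nuc_contig <- c(nuc_contig, a$contig[m])
    nuc_start0 <- c(nuc_start0, a$start0[m])
    nuc_len <- c(nuc_len, nchar(rt$seq[rest][m]))
    n_nuc_mapped <- length(nuc_contig)
  }
  on_target <- sum(overlaps_targets(nuc_contig, nuc_start0,
                                    nuc_start0 + nuc_len, targets))
  mapped <- n_nuc_mapped + nrow(mito_aln)
  tally <- alignment_tally(
    total_reads = n, mapped = mapped, on_target = on_target,
    off_target = mapped - on_target, mito_mapped = nrow(mito_aln)
  )
  structure(
    list(mito = mito_aln, relocated = relocated, ambiguous = ambiguous,
         tally = tally),
    class = "mito_extraction"
  )
}

#' @export
print.mito_extraction <- function(x, ...) {
  cat("<mito_extraction> retained=", nrow(x$mito), " relocated=",
      x$relocated, " ambiguous=", x$ambiguous, "\n", sep = "")
  print(x$tally)
  invisible(x)
}

#' Coordinate-based duplicate removal
#'
#' Fragments (read pairs) sharing contig, both mates' start coordinates,
#' strand orientation and read lengths are duplicates; one representative
#' (the lexicographically first fragment id) is retained. Idempotent.
#'
#' @param aln alignment data.frame with `fragment`, `mate`, `contig`,
#'   `start0`, `strand`, `seq` columns.
#' @return the deduplicated data.frame; the number of alignments removed is
#'   attached as attribute `removed`.
#' @export
deduplicate_alignments <- function(aln) {
  if (nrow(aln) == 0) {
    attr(aln, "removed") <- 0L
    return(aln)
  }
  if (is.null(aln$fragment)) aln$fragment <- aln$id %||% seq_len(nrow(aln))
  if (is.null(aln$mate)) aln$mate <- 1L
  o <- order(aln$fragment, aln$mate, aln$start0)
  a <- aln[o, , drop = FALSE]
  row_key <- paste(a$mate, a$contig, a$start0, a$strand, nchar(a$seq),
                   sep = ":")
  frag_key <- tapply(row_key, a$fragment, paste, collapse = "|")
  keep_frags <- names(frag_key)[!duplicated(as.character(frag_key))]
  out <- aln[aln$fragment %in% keep_frags, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- nrow(aln) - nrow(out)
  out
}
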