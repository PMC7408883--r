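# SAM interoperability. Minimal dialect: QNAME FLAG RNAME POS MAPQ CIGAR
# (M-only consumed) RNEXT PNEXT TLEN SEQ QUAL. BAM import goes through
# Rsamtools when installed.

#' Import external alignments and tally on/off-target reads
#'
#' Reads a SAM (text) or BAM file and classifies mapped records as on- or
#' off-target by interval overlap of at least one base; the mitochondrial
#' contig is matched case-insensitively among `MT`, `chrM`, `chrMT`.
#' Unmapped records are counted in the total but excluded from the on/off
#' classification.
#'
#' @param file SAM or BAM path (`.bam` requires Rsamtools).
#' @param targets a [target_regions()] object (NULL = everything
#'   off-target).
#' @param mito_contig expected mitochondrial contig name; NULL
#'   auto-detects among the standard names.
#' @param strict when the expected mitochondrial contig is absent: error if
#'   TRUE, warn otherwise.
#' @return list with `alignments` (data.frame: fragment, mate, contig,
#'   start0, strand, mapq, seq, qual, span) and `tally`
#'   (an [alignment_tally()]).
#' @export
import_alignments <- function(file, targets = NULL, mito_contig = NULL,
                              strict = FALSE) {
  df <- if (grepl("\\.bam$", file, ignore.case = TRUE)) {
    read_bam_records(file)
  } else {
    read_sam_records(file)
  }
  contigs <- unique(df$contig[df$mapped])
  if (!is.null(mito_contig) && !(mito_contig %in% contigs)) {
    msg <- paste0("mitochondrial contig '", mito_contig,
                  "' not found among mapped contigs")
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  is_mito <- df$mapped & is_mito_contig(df$contig)
  if (is.null(targets)) {
    on <- rep(FALSE, nrow(df))
  } else {
    on <- rep(FALSE, nrow(df))
    sel <- df$mapped & !is_mito
    on[sel] <- overlaps_targets(df$contig[sel], df$start0[sel],
                                df$start0[sel] + df$span[sel], targets)
  }
  mapped <- sum(df$mapped)
  tally <- alignment_tally(
    total_reads = nrow(df), mapped = mapped, on_target = sum(on),
    off_target = mapped - sum(on), mito_mapped = sum(is_mito)
  )
  list(alignments = df[df$mapped, , drop = FALSE], tally = tally)
}

read_sam_records <- function(file) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(fragment = character(0), mate = integer(0),
                      mapped = logical(0), contig = character(0),
                      start0 = integer(0), strand = character(0),
                      mapq = integer(0), seq = character(0),
                      qual = character(0), span = integer(0)))
  }
  fields <- strsplit(lines, "\t")
  if (any(lengths(fields) < 11)) {
    stop("SAM record(s) with fewer than 11 fields at line(s): ",
         paste(utils::head(which(lengths(fields) < 11), 5), collapse = ","))
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- as.integer(get(2))
  seq <- get(10)
  cigar <- get(6)
  data.frame(
    fragment = get(1),
    mate = ifelse(bitwAnd(flag, 128L) > 0, 2L, 1L),
    mapped = bitwAnd(flag, 4L) == 0,
    contig = get(3),
    start0 = as.integer(get(4)) - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0, "-", "+"),
    mapq = as.integer(get(5)),
    seq = seq, qual = get(11),
    span = cigar_ref_span(cigar, nchar(seq)),
    stringsAsFactors = FALSE
  )
}

# Reference span consumed by a CIGAR string (M/=/X/D/N consume reference);
# "*" falls back to the read length.
cigar_ref_span <- function(cigar, fallback_len) {
  out <- integer(length(cigar))
  for (i in seq_along(cigar)) {
    if (cigar[i] == "*") { out[i] <- fallback_len[i]; next }
    ops <- regmatches(cigar[i], gregexpr("[0-9]+[MIDNSHP=X]", cigar[i]))[[1]]
    lens <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    out[i] <- sum(lens[op %in% c("M", "=", "X", "D", "N")])
  }
  out
}

read_bam_records <- function(file) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("BAM import requires the Rsamtools package")
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(file, param = p)[[1]]
  flag <- b$flag
  seq <- as.character(b$seq)
  data.frame(
    fragment = b$qname,
    mate = ifelse(bitwAnd(flag, 128L) > 0, 2L, 1L),
    mapped = bitwAnd(flag, 4L) == 0,
    contig = as.character(b$rname),
    start0 = b$pos - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0, "-", "+"),
    mapq = b$mapq,
    seq = seq, qual = as.character(b$qual),
    span = cigar_ref_span(ifelse(is.na(b$cigar), "*", b$cigar), nchar(seq)),
    stringsAsFactors = FALSE
  )
}

#' Write alignments as SAM
#'
#' Minimal dialect: FLAG carries strand and mate bits, CIGAR is
#' `<length>M`, MAPQ is the capped mapq proxy.
#'
#' @param aln alignment data.frame (fragment, mate, contig, start0, strand,
#'   seq, qual, optionally mapq_proxy).
#' @param refs named integer vector of reference lengths for `@SQ` lines,
#'   or a `mito_reference`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_sam <- function(aln, refs, file) {
  if (inherits(refs, "mito_reference")) {
    refs <- stats::setNames(refs$length, refs$name)
  }
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(refs)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, refs[[nm]]), con)
  }
  if (nrow(aln) > 0) {
    mate <- aln$mate %||% rep(1L, nrow(aln))
    flag <- ifelse(aln$strand == "-", 16L, 0L) +
      ifelse(mate == 2L, 128L, ifelse(mate == 1L, 64L, 0L)) + 1L
    mapq <- pmin(60L, as.integer(round(aln$mapq_proxy %||% 60)))
    writeLines(sprintf(
      "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
      aln$fragment, flag, aln$contig, aln$start0 + 1L, mapq,
      nchar(aln$seq), aln$seq, aln$qual), con)
  }
  invisible(file)
}
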