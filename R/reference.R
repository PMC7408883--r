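# Reference sequences: the circular mitochondrial contig and nuclear decoys.
#
# Coordinate conventions owned here: external formats keep their native
# conventions (FASTA/rCRS positions 1-based, BED 0-based half-open); internal
# alignment coordinates are 0-based half-open with conversion at the boundary.

#' Read a FASTA file into validated uppercase sequences
#'
#' Sequences are uppercased; the alphabet is restricted to A/C/G/T/N. Record
#' order is preserved.
#'
#' @param file path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_reference_fasta <- function(file) {
  set <- tryCatch(
    Biostrings::readDNAStringSet(file),
    error = function(e) stop("cannot parse FASTA '", file, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0) {
    stop("FASTA '", file, "' contains no records", call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  for (i in seq_along(seqs)) {
    bad <- gsub("[ACGTN]", "", seqs[[i]])
    if (nchar(bad) > 0) {
      stop("record '", names(seqs)[i], "' contains non-ACGTN characters: ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ","),
           call. = FALSE)
    }
    if (nchar(seqs[[i]]) == 0) {
      stop("record '", names(seqs)[i], "' is empty", call. = FALSE)
    }
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector, or a `mito_reference` /
#'   list of `nuclear_decoy` objects.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_reference_fasta <- function(seqs, file) {
  if (inherits(seqs, "mito_reference")) {
    seqs <- stats::setNames(seqs$sequence, seqs$name)
  } else if (is.list(seqs) && !is.null(seqs[[1]]$sequence)) {
    seqs <- stats::setNames(
      vapply(seqs, function(d) d$sequence, character(1)),
      vapply(seqs, function(d) d$name, character(1))
    )
  }
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, file, width = 70)
  invisible(file)
}

#' Mitochondrial reference object
#'
#' A circular mitochondrial contig with 1-based rCRS-style coordinates:
#' position p corresponds to `substr(sequence, p, p)`.
#'
#' @param sequence uppercase base string (A/C/G/T/N).
#' @param name contig identifier (default "MT").
#' @param circular logical; the mitochondrial genome is circular.
#' @return an object of class `mito_reference` with fields `name`,
#'   `sequence`, `length`, `circular`.
#' @export
mito_reference <- function(sequence, name = "MT", circular = TRUE) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("mitochondrial sequence is empty")
  if (grepl("[^ACGTN]", sequence)) {
    stop("mitochondrial sequence contains non-ACGTN characters")
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence),
         circular = isTRUE(circular)),
    class = "mito_reference"
  )
}

#' @export
print.mito_reference <- function(x, ...) {
  cat("<mito_reference> ", x$name, ": ", x$length, " bp",
      if (x$circular) " (circular)" else "", "\n", sep = "")
  invisible(x)
}

#' Reference base at 1-based mitochondrial positions
#'
#' @param ref a `mito_reference`.
#' @param pos integer vector of 1-based positions.
#' @return character vector of bases.
#' @export
mito_base <- function(ref, pos) {
  stopifnot(inherits(ref, "mito_reference"))
  if (any(pos < 1 | pos > ref$length)) {
    stop("position outside 1..", ref$length)
  }
  substring(ref$sequence, pos, pos)
}

#' Nuclear decoy contig
#'
#' A nuclear contig that may carry NUMT inserts (diverged copies of
#' mitochondrial segments). `numt_annotations` is a data.frame with columns
#' `mt_start`, `mt_end` (1-based inclusive source span on the mitochondrial
#' genome), `divergence` (substitution fraction in \[0,1\]) and `insert_pos`
#' (1-based position of the insert within the decoy); an optional
#' `diverged_offsets` list-column records which offsets of the inserted
#' segment were actually substituted.
#'
#' @param sequence base string.
#' @param name contig identifier.
#' @param numt_annotations data.frame as described, or NULL.
#' @return an object of class `nuclear_decoy`.
#' @export
nuclear_decoy <- function(sequence, name, numt_annotations = NULL) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("decoy sequence is empty")
  if (!is.null(numt_annotations) && nrow(numt_annotations) > 0) {
    a <- numt_annotations
    if (any(a$divergence < 0 | a$divergence > 1)) {
      stop("NUMT divergence must lie in [0,1]")
    }
    seg_len <- a$mt_end - a$mt_start + 1
    if (any(a$insert_pos < 1 | a$insert_pos + seg_len - 1 > nchar(sequence))) {
      stop("NUMT annotation extends beyond decoy '", name, "'")
    }
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence),
         numt_annotations = numt_annotations),
    class = "nuclear_decoy"
  )
}

#' @export
print.nuclear_decoy <- function(x, ...) {
  n_numt <- if (is.null(x$numt_annotations)) 0 else nrow(x$numt_annotations)
  cat("<nuclear_decoy> ", x$name, ": ", x$length, " bp, ",
      n_numt, " NUMT insert(s)\n", sep = "")
  invisible(x)
}

#' Load the mitochondrial reference from FASTA
#'
#' The first record is used; it is validated and wrapped as a
#' [mito_reference()].
#'
#' @param file FASTA path.
#' @param circular logical.
#' @return a `mito_reference`.
#' @export
load_mito_reference <- function(file, circular = TRUE) {
  seqs <- read_reference_fasta(file)
  mito_reference(seqs[[1]], name = names(seqs)[1], circular = circular)
}

#' Load nuclear decoy contigs from FASTA
#'
#' @param file FASTA path.
#' @return list of `nuclear_decoy` objects, record order preserved.
#' @export
load_nuclear_decoys <- function(file) {
  seqs <- read_reference_fasta(file)
  lapply(seq_along(seqs), function(i) nuclear_decoy(seqs[[i]], names(seqs)[i]))
}

#' MT-RNR1 gene span
#'
#' Default 1-based span 648-1601, the standard rCRS annotation of the 12S
#' rRNA gene; overridable since coverage summaries are span-dependent.
#'
#' @param start,end 1-based inclusive bounds.
#' @param gene gene label.
#' @return an object of class `mito_region`.
#' @export
mt_rnr1_region <- function(start = 648, end = 1601, gene = "MT-RNR1") {
  if (start < 1 || start > end) stop("invalid region: need 1 <= start <= end")
  structure(list(gene = gene, start = as.integer(start), end = as.integer(end)),
            class = "mito_region")
}

#' @export
print.mito_region <- function(x, ...) {
  cat("<mito_region> ", x$gene, ": ", x$start, "-", x$end, "\n", sep = "")
  invisible(x)
}

# Normalise a region argument into c(start, end), defaulting to whole contig.
region_bounds <- function(region, L) {
  if (is.null(region)) return(c(1L, L))
  if (inherits(region, "mito_region")) region <- c(region$start, region$end)
  region <- as.integer(region)
  if (length(region) != 2 || region[1] < 1 || region[2] > L ||
      region[1] > region[2]) {
    stop("region must be within 1..", L)
  }
  region
}
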