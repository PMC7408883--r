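# Capture target intervals (BED 0-based half-open at the interface and
# internally). Intervals are merged per contig on load; mitochondrial
# intervals are accepted but flagged, since the extraction strategy assumes
# the mitochondrial genome is never part of the capture design.

MITO_CONTIG_NAMES <- c("MT", "chrM", "chrMT")

is_mito_contig <- function(contig) {
  tolower(contig) %in% tolower(MITO_CONTIG_NAMES)
}

#' Build a target-region set
#'
#' @param df data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open).
#' @return object of class `target_regions`: a data.frame of merged,
#'   non-overlapping intervals sorted by (contig, start), with a logical
#'   `mito` column flagging intervals on a mitochondrial contig name.
#' @export
target_regions <- function(df) {
  stopifnot(all(c("contig", "start", "end") %in% names(df)))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start >= df$end)) {
    bad <- which(df$start >= df$end)
    stop("invalid interval(s) with start >= end at row(s): ",
         paste(utils::head(bad, 5), collapse = ","))
  }
  if (nrow(df) == 0) {
    out <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), mito = logical(0))
    return(structure(out, class = c("target_regions", "data.frame")))
  }
  merged <- do.call(rbind, lapply(split(df, df$contig), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.frame(contig = d$contig[1],
               start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir))
  }))
  merged <- merged[order(merged$contig, merged$start), , drop = FALSE]
  rownames(merged) <- NULL
  merged$mito <- is_mito_contig(merged$contig)
  if (any(merged$mito)) {
    warning("target intervals on a mitochondrial contig were flagged; ",
            "the extraction model treats mtDNA as off-target by design",
            call. = FALSE)
  }
  structure(merged, class = c("target_regions", "data.frame"))
}

#' Load capture targets from a BED file
#'
#' Accepts 3+ column BED (0-based half-open). Lines with `start >= end` are
#' rejected with the offending line numbers. Intervals are merged per contig.
#'
#' @param file BED path.
#' @return a [target_regions()] object.
#' @export
load_targets <- function(file) {
  lines <- readLines(file)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(target_regions(data.frame(
    contig = character(0), start = integer(0), end = integer(0))))
  fields <- strsplit(lines, "\t| +")
  ncols <- lengths(fields)
  if (any(ncols < 3)) {
    stop("BED line(s) with fewer than 3 columns: ",
         paste(utils::head(which(ncols < 3), 5), collapse = ","))
  }
  df <- data.frame(
    contig = vapply(fields, `[[`, character(1), 1),
    start = suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2))),
    end = suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
  )
  if (anyNA(df$start) || anyNA(df$end)) {
    stop("non-numeric BED coordinates at line(s): ",
         paste(utils::head(which(is.na(df$start) | is.na(df$end)), 5),
               collapse = ","))
  }
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stop("BED line(s) with start >= end: ",
         paste(utils::head(bad, 5), collapse = ","))
  }
  target_regions(df)
}

#' Total targeted bases
#'
#' @param targets a `target_regions` object.
#' @return integer sum of merged interval widths.
#' @export
target_size <- function(targets) {
  sum(targets$end - targets$start)
}

#' Write targets to BED
#'
#' @param targets a `target_regions` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_targets <- function(targets, file) {
  utils::write.table(targets[, c("contig", "start", "end")], file,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}

# Does each query interval (contig, start0, end0; 0-based half-open) overlap
# any target by >= 1 base?
overlaps_targets <- function(contig, start0, end0, targets) {
  out <- logical(length(contig))
  if (length(contig) == 0 || nrow(targets) == 0) return(out)
  for (ctg in unique(contig)) {
    t <- targets[targets$contig == ctg, , drop = FALSE]
    sel <- contig == ctg
    if (nrow(t) == 0) next
    q <- IRanges::IRanges(start = start0[sel] + 1L, end = end0[sel])
    s <- IRanges::IRanges(start = t$start + 1L, end = t$end)
    out[sel] <- IRanges::overlapsAny(q, s)
  }
  out
}
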