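# Variant retention and genotype/heteroplasmy classification at MT-RNR1
# positions.
#
# Two gates operate in sequence: a retention filter (variants with VAF >=
# 10% are considered) and a classification rule set. Clinical mode:
#   depth < min_depth                                -> undetermined
#   alt == 0                                         -> wild_type
#   alt == 1 and depth > artifact_depth              -> wild_type_artifact
#   VAF in [0.10, 0.90], ref > 5 and alt > 5         -> carrier_heteroplasmic
#   VAF > 0.90 and ref <= 5                          -> carrier_homoplasmic
#   VAF > 0.90 and ref > 5                           -> manual_review
#   anything else                                    -> manual_review
# Research (low-coverage) mode assumes homoplasmy: any alternative reads
# with zero reference reads call a homoplasmic carrier (flagged
# low_coverage); mixtures route to manual_review.

GENOTYPE_CLASSES <- c("wild_type", "carrier_homoplasmic",
                      "carrier_heteroplasmic", "wild_type_artifact",
                      "undetermined", "manual_review")

#' Classification parameters
#'
#' Defaults: clinical minimum depth 5; research minimum depth 1; the
#' single-alternative-read artifact rule fires at depth strictly above 40;
#' the heteroplasmy window is the inclusive VAF interval \[0.10, 0.90\] and
#' requires more than `min_side_reads` reads supporting each allele.
#'
#' @param min_depth_clinical,min_depth_research minimum depth per mode.
#' @param artifact_depth depth above which a single alternative read is
#'   classed as wild-type artifact.
#' @param het_window inclusive VAF window for heteroplasmy.
#' @param min_side_reads reads required (exclusive) on each allele for a
#'   heteroplasmic call.
#' @return list of class `classify_params`.
#' @export
classify_params <- function(min_depth_clinical = 5, min_depth_research = 1,
                            artifact_depth = 40,
                            het_window = c(0.10, 0.90),
                            min_side_reads = 5) {
  structure(
    list(min_depth_clinical = min_depth_clinical,
         min_depth_research = min_depth_research,
         artifact_depth = artifact_depth, het_window = het_window,
         min_side_reads = min_side_reads),
    class = "classify_params"
  )
}

#' Classify a site from reference/alternative read counts
#'
#' Total over non-negative count pairs: every (ref, alt) combination maps to
#' exactly one genotype class per mode. The VAF is the fraction of
#' alternative reads among reads supporting either allele; it is reported
#' rounded half-up to two decimals, while raw fractions drive all
#' comparisons.
#'
#' @param ref_reads,alt_reads non-negative read counts (vectorised).
#' @param mode `"clinical"` or `"research_low_coverage"`.
#' @param params a [classify_params()].
#' @return data.frame of class `site_call`: ref_reads, alt_reads, depth,
#'   vaf (raw), vaf_reported (2 decimals, half-up), genotype_class, flags.
#' @export
classify_site <- function(ref_reads, alt_reads,
                          mode = c("clinical", "research_low_coverage"),
                          params = classify_params()) {
  mode <- match.arg(mode)
  if (any(ref_reads < 0) || any(alt_reads < 0)) {
    stop("read counts must be non-negative")
  }
  n <- max(length(ref_reads), length(alt_reads))
  r <- rep_len(as.numeric(ref_reads), n)
  a <- rep_len(as.numeric(alt_reads), n)
  depth <- r + a
  vaf <- ifelse(depth > 0, a / depth, NA_real_)
  cls <- character(n)
  flags <- character(n)
  if (mode == "clinical") {
    w <- params$het_window
    s <- params$min_side_reads
    cls <- ifelse(
      depth < params$min_depth_clinical, "undetermined",
      ifelse(a == 0, "wild_type",
      ifelse(a == 1 & depth > params$artifact_depth, "wild_type_artifact",
      ifelse(vaf >= w[1] & vaf <= w[2] & r > s & a > s,
             "carrier_heteroplasmic",
      ifelse(vaf > w[2] & r <= s, "carrier_homoplasmic",
      ifelse(vaf > w[2] & r > s, "manual_review", "manual_review"))))))
  } else {
    cls <- ifelse(
      depth < params$min_depth_research, "undetermined",
      ifelse(a == 0, "wild_type",
      ifelse(r == 0, "carrier_homoplasmic", "manual_review")))
    flags <- ifelse(cls == "carrier_homoplasmic", "low_coverage", "")
  }
  structure(
    data.frame(
      ref_reads = r, alt_reads = a, depth = depth, vaf = vaf,
      vaf_reported = round_half_up(vaf, 2), genotype_class = cls,
      flags = flags, stringsAsFactors = FALSE
    ),
    class = c("site_call", "data.frame")
  )
}

#' Retain candidate variants from a pileup
#'
#' At each position of the region, the most frequent non-reference base is a
#' candidate (alphabetical tie-break). Candidates with fewer than
#' `min_alt_reads` supporting reads are filtered `below_depth`; retained
#' candidates PASS iff their VAF (alt / (ref + alt)) reaches `vaf_min`,
#' otherwise `below_vaf`.
#'
#' @param pileup a `mito_pileup`.
#' @param region region restriction (default the MT-RNR1 span).
#' @param vaf_min retention threshold (default 0.10).
#' @param min_alt_reads minimum alternative read support (default 2).
#' @return data.frame: pos, ref, alt, ref_reads, alt_reads, depth, vaf,
#'   filter (PASS / below_vaf / below_depth).
#' @export
call_variants <- function(pileup, region = mt_rnr1_region(),
                          vaf_min = 0.10, min_alt_reads = 2) {
  b <- region_bounds(region, pileup$ref$length)
  pos <- b[1]:b[2]
  counts <- pileup$counts[, pos, drop = FALSE]
  refb <- mito_base(pileup$ref, pos)
  ref_idx <- base_codes(refb)
  cm <- counts
  # mask the reference base so the max picks the top non-reference base
  cm[cbind(ref_idx, seq_along(pos))] <- -1L
  alt_idx <- apply(cm, 2, which.max)  # ties: first in A<C<G<T order
  alt_reads <- cm[cbind(alt_idx, seq_along(pos))]
  keep <- which(alt_reads >= 1)
  if (!length(keep)) {
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), ref_reads = integer(0),
                      alt_reads = integer(0), depth = integer(0),
                      vaf = numeric(0), filter = character(0)))
  }
  ref_reads <- counts[cbind(ref_idx[keep], keep)]
  ar <- alt_reads[keep]
  vaf <- ar / (ref_reads + ar)
  data.frame(
    pos = pos[keep],
    ref = refb[keep],
    alt = DNA_BASES[alt_idx[keep]],
    ref_reads = as.integer(ref_reads),
    alt_reads = as.integer(ar),
    depth = as.integer(colSums(counts)[keep]),
    vaf = vaf,
    filter = ifelse(ar < min_alt_reads, "below_depth",
                    ifelse(vaf >= vaf_min, "PASS", "below_vaf")),
    stringsAsFactors = FALSE
  )
}

#' Positions in (or adjacent to) homopolymer runs
#'
#' A position is flagged when a run of `min_run` or more identical reference
#' bases lies within `flank` bases of it; with the default flank of 1 this
#' covers both positions inside a run and positions sandwiched against one,
#' such as m.961T against its flanking cytosine runs.
#'
#' @param sequence reference base string, or a `mito_reference`.
#' @param min_run minimum run length (default 4).
#' @param flank adjacency margin in bases (default 1).
#' @return sorted integer vector of 1-based flagged positions.
#' @export
homopolymer_positions <- function(sequence, min_run = 4, flank = 1) {
  if (inherits(sequence, "mito_reference")) sequence <- sequence$sequence
  r <- rle(strsplit(sequence, "")[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$lengths >= min_run)
  if (!length(runs)) return(integer(0))
  pos <- unlist(lapply(runs, function(i) {
    max(1L, starts[i] - flank):min(nchar(sequence), ends[i] + flank)
  }))
  sort(unique(pos))
}

#' Genotype a cohort at selected positions
#'
#' One site call per (sample, position). The reference and alternative read
#' counts come from each sample's pileup: the alternative is the most
#' frequent non-reference base (the knowledge-base alternative takes
#' precedence when supplied and supported). Positions in homopolymer
#' context are flagged.
#'
#' @param pileups named list of `mito_pileup` objects (one per sample).
#' @param positions integer positions to genotype (default: knowledge-base
#'   positions).
#' @param mode classification mode.
#' @param params a [classify_params()].
#' @param kb optional `mtrnr1_kb` used for the default positions.
#' @return data.frame of class `genotype_table`: sample, pos, ref, alt,
#'   ref_reads, alt_reads, vaf, genotype_class, flags.
#' @export
genotype_cohort <- function(pileups, positions = NULL,
                            mode = c("clinical", "research_low_coverage"),
                            params = classify_params(), kb = NULL) {
  mode <- match.arg(mode)
  empty <- data.frame(sample = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      ref_reads = integer(0), alt_reads = integer(0),
                      vaf = numeric(0), genotype_class = character(0),
                      flags = character(0))
  if (length(pileups) == 0) {
    return(structure(empty, class = c("genotype_table", "data.frame")))
  }
  ref <- pileups[[1]]$ref
  if (is.null(positions)) {
    if (is.null(kb)) kb <- load_kb(mito_ref = ref)
    positions <- sort(unique(kb$position))
  }
  hp <- homopolymer_positions(ref)
  rows <- vector("list", 0)
  for (nm in names(pileups)) {
    p <- pileups[[nm]]
    refb <- mito_base(ref, positions)
    ref_idx <- base_codes(refb)
    counts <- p$counts[, positions, drop = FALSE]
    cm <- counts
    cm[cbind(ref_idx, seq_along(positions))] <- -1L
    alt_idx <- apply(cm, 2, which.max)
    alt_reads <- pmax(0L, cm[cbind(alt_idx, seq_along(positions))])
    ref_reads <- counts[cbind(ref_idx, seq_along(positions))]
    call <- classify_site(ref_reads, alt_reads, mode, params)
    fl <- call$flags
    fl <- ifelse(positions %in% hp,
                 ifelse(nzchar(fl), paste0(fl, ",homopolymer_context"),
                        "homopolymer_context"), fl)
    rows[[length(rows) + 1]] <- data.frame(
      sample = nm, pos = positions, ref = refb,
      alt = ifelse(alt_reads > 0, DNA_BASES[alt_idx], NA_character_),
      ref_reads = as.integer(ref_reads), alt_reads = as.integer(alt_reads),
      vaf = call$vaf, genotype_class = call$genotype_class, flags = fl,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("genotype_table", "data.frame"))
}

#' Concordance between two genotype tables
#'
#' Pairs are matched on (sample, position). Pairs where either side is
#' undetermined are excluded from the concordance denominator and counted
#' separately.
#'
#' @param a,b `genotype_table` data.frames (or any data.frame with sample,
#'   pos, genotype_class).
#' @return list of class `concordance_summary`: n_compared, concordant,
#'   discordant, unilaterally_undetermined, discordant_pairs (data.frame).
#' @export
genotype_concordance <- function(a, b) {
  key_a <- paste(a$sample, a$pos)
  key_b <- paste(b$sample, b$pos)
  shared <- intersect(key_a, key_b)
  if (!length(shared)) {
    warning("no shared (sample, position) pairs to compare", call. = FALSE)
  }
  ia <- match(shared, key_a)
  ib <- match(shared, key_b)
  ca <- a$genotype_class[ia]
  cb <- b$genotype_class[ib]
  undet <- ca == "undetermined" | cb == "undetermined"
  comp <- !undet
  disc <- comp & ca != cb
  structure(
    list(n_compared = sum(comp), concordant = sum(comp & ca == cb),
         discordant = sum(disc),
         unilaterally_undetermined = sum(undet),
         discordant_pairs = data.frame(
           sample = a$sample[ia][disc], pos = a$pos[ia][disc],
           class_a = ca[disc], class_b = cb[disc])),
    class = "concordance_summary"
  )
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf(
    "<concordance_summary> %d compared: %d concordant, %d discordant, %d undetermined-excluded\n",
    x$n_compared, x$concordant, x$discordant, x$unilaterally_undetermined))
  invisible(x)
}
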