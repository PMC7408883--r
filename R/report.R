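# Knowledge-base annotation, cohort prevalence and heteroplasmy evidence.
# Prevalence arithmetic stays exact rational until the formatting boundary;
# formatted strings never feed back into computation.

#' Annotate variant calls against the knowledge base
#'
#' Left join on (position, ref, alt): every input call appears exactly once
#' in the output, with its knowledge-base tier or `not_in_kb`. Calls at
#' homopolymer-context positions carry the homopolymer caution note.
#'
#' @param calls data.frame from [call_variants()] (needs pos, ref, alt).
#' @param kb an `mtrnr1_kb` data.frame from [load_kb()].
#' @param mito_ref optional [mito_reference()] for homopolymer flagging.
#' @return `calls` with added `tier` and `note` columns.
#' @export
annotate_calls <- function(calls, kb, mito_ref = NULL) {
  key_c <- paste(calls$pos, calls$ref, calls$alt)
  key_k <- paste(kb$position, kb$ref, kb$alt)
  m <- match(key_c, key_k)
  calls$tier <- ifelse(is.na(m), "not_in_kb", kb$tier[m])
  calls$note <- ifelse(is.na(m), ".", kb$note[m])
  if (!is.null(mito_ref) && nrow(calls) > 0) {
    hp <- homopolymer_positions(mito_ref)
    in_hp <- calls$pos %in% hp
    caution <- "homopolymer context: indel calls unreliable"
    calls$note[in_hp] <- ifelse(
      calls$note[in_hp] == "." | !nzchar(calls$note[in_hp]),
      caution, paste(calls$note[in_hp], caution, sep = "; "))
  }
  calls
}

#' Cohort carrier prevalence
#'
#' Samples carrying at least one homoplasmic or heteroplasmic carrier call
#' count as carriers; undetermined samples stay in the denominator. Percent
#' is reported both at two decimals (table style) and one decimal (prose
#' style); the carrier ratio is `1:N` with `N = round(n_samples /
#' n_carriers)`.
#'
#' @param genotype_table a `genotype_table` data.frame.
#' @param carrier_classes classes counting as carrier.
#' @return list of class `prevalence_report`: n_samples, n_carriers,
#'   percent (2 dp), percent_1dp, ratio, per_variant (data.frame),
#'   undetermined_samples.
#' @export
cohort_prevalence <- function(genotype_table,
                              carrier_classes = c("carrier_homoplasmic",
                                                  "carrier_heteroplasmic")) {
  g <- genotype_table
  n_samples <- length(unique(g$sample))
  if (n_samples == 0) stop("prevalence undefined for an empty cohort")
  is_carrier_row <- g$genotype_class %in% carrier_classes
  carriers <- unique(g$sample[is_carrier_row])
  n_carriers <- length(carriers)
  pv <- if (any(is_carrier_row)) {
    stats::aggregate(
      sample ~ pos + ref + alt, data = g[is_carrier_row, , drop = FALSE],
      FUN = function(s) length(unique(s)))
  } else {
    data.frame(pos = integer(0), ref = character(0), alt = character(0),
               sample = integer(0))
  }
  names(pv)[names(pv) == "sample"] <- "n_carriers"
  undet <- g$sample[g$genotype_class == "undetermined"]
  structure(
    list(
      n_samples = n_samples, n_carriers = n_carriers,
      carrier_samples = carriers,
      percent = round_half_up(100 * n_carriers / n_samples, 2),
      percent_1dp = round_half_up(100 * n_carriers / n_samples, 1),
      ratio = if (n_carriers > 0) round(n_samples / n_carriers) else NA,
      per_variant = pv,
      undetermined_samples = unique(undet)
    ),
    class = "prevalence_report"
  )
}

#' @export
print.prevalence_report <- function(x, ...) {
  ratio <- if (is.na(x$ratio)) "undefined" else paste0("1:", x$ratio)
  cat(sprintf("<prevalence_report> %d of %d samples (%.2f%%; ratio %s)\n",
              x$n_carriers, x$n_samples, x$percent, ratio))
  if (nrow(x$per_variant)) {
    for (i in seq_len(nrow(x$per_variant))) {
      cat(sprintf("  m.%d%s>%s: %d carrier(s)\n", x$per_variant$pos[i],
                  x$per_variant$ref[i], x$per_variant$alt[i],
                  x$per_variant$n_carriers[i]))
    }
  }
  if (length(x$undetermined_samples)) {
    cat("  undetermined:", paste(x$undetermined_samples, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Heteroplasmy evidence list
#'
#' Automatic entries are carrier_heteroplasmic calls (the inclusive VAF
#' window with read support on both alleles); manual_review calls for
#' samples listed in `promote` are added with manual_review provenance —
#' the route for a reviewer promoting a high-VAF, high-coverage case.
#'
#' @param genotype_table a `genotype_table` data.frame.
#' @param promote character vector of sample ids whose manual_review calls
#'   are promoted into the evidence list.
#' @return data.frame: sample, pos, ref, alt, vaf, vaf_reported, provenance.
#' @export
heteroplasmy_evidence <- function(genotype_table, promote = character(0)) {
  g <- genotype_table
  auto <- g$genotype_class == "carrier_heteroplasmic"
  man <- g$genotype_class == "manual_review" & g$sample %in% promote
  sel <- auto | man
  out <- data.frame(
    sample = g$sample[sel], pos = g$pos[sel], ref = g$ref[sel],
    alt = g$alt[sel], vaf = g$vaf[sel],
    vaf_reported = round_half_up(g$vaf[sel], 2),
    provenance = ifelse(auto[sel], "automatic", "manual_review"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$sample, out$pos), , drop = FALSE]
}

#' Write calls as VCF v4.2
#'
#' Single-sample records with `VAF` and `DP` INFO fields and
#' `below_vaf`/`below_depth` FILTER values; the active mode and thresholds
#' are echoed into the header.
#'
#' @param calls data.frame from [call_variants()] (pos, ref, alt,
#'   ref_reads, alt_reads, depth, vaf, filter).
#' @param mito_ref a [mito_reference()].
#' @param file output path.
#' @param mode classification mode recorded in the header.
#' @param vaf_min retention threshold recorded in the header.
#' @return `file`, invisibly.
#' @export
write_vcf <- function(calls, mito_ref, file, mode = "clinical",
                      vaf_min = 0.10) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=offmito %s", offmito_version()),
    sprintf("##contig=<ID=%s,length=%d>", mito_ref$name, mito_ref$length),
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction (alt / (ref + alt))\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Filtered read depth\">",
    sprintf("##FILTER=<ID=below_vaf,Description=\"VAF below %s\">", vaf_min),
    "##FILTER=<ID=below_depth,Description=\"Insufficient alternative read support\">",
    sprintf("##offmito_mode=%s", mode),
    sprintf("##offmito_vaf_min=%s", vaf_min),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(calls) > 0) {
    writeLines(sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t%s\tVAF=%.4f;DP=%d",
      mito_ref$name, calls$pos, calls$ref, calls$alt, calls$filter,
      calls$vaf, calls$depth), con)
  }
  invisible(file)
}
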