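# The MT-RNR1 ototoxicity variant knowledge base. Shipped as data (TSV with a
# schema version), not code, so users can extend it beyond the bundled set.

KB_TIERS <- c("strong", "needs_further_study")

#' Load the MT-RNR1 variant knowledge base
#'
#' With no `file`, loads the bundled table of 16 MT-RNR1 substitutions
#' reported in connection with aminoglycoside-induced ototoxicity:
#' m.1555A>G and m.1494C>T (tier `strong`) plus 14 variants of still
#' unclear significance (tier `needs_further_study`). When a
#' `mito_reference` is supplied, every entry's `ref` base is validated
#' against the reference sequence.
#'
#' @param file TSV path with header `position ref alt tier note pmid_refs`
#'   (comment lines start with `#`), or NULL for the bundled table.
#' @param mito_ref optional [mito_reference()] for ref-base validation.
#' @return data.frame of class `mtrnr1_kb`.
#' @export
load_kb <- function(file = NULL, mito_ref = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "mtrnr1_kb.tsv", package = "offmito",
                        mustWork = TRUE)
  }
  kb <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("position", "ref", "alt", "tier")
  if (!all(required %in% names(kb))) {
    stop("knowledge base must have columns: ", paste(required, collapse = ", "))
  }
  kb$position <- as.integer(kb$position)
  kb$ref <- toupper(kb$ref)
  kb$alt <- toupper(kb$alt)
  if (is.null(kb$note)) kb$note <- "."
  if (any(kb$ref == kb$alt)) {
    stop("knowledge-base entries with alt equal to ref at position(s): ",
         paste(kb$position[kb$ref == kb$alt], collapse = ","))
  }
  key <- paste(kb$position, kb$ref, kb$alt)
  if (anyDuplicated(key)) {
    stop("duplicate knowledge-base entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (!all(kb$tier %in% KB_TIERS)) {
    stop("unknown tier value(s): ",
         paste(setdiff(unique(kb$tier), KB_TIERS), collapse = ","))
  }
  if (!is.null(mito_ref)) {
    actual <- mito_base(mito_ref, kb$position)
    bad <- which(actual != kb$ref)
    if (length(bad)) {
      stop("knowledge-base ref base mismatch vs reference at position(s): ",
           paste(sprintf("%d (kb=%s, ref=%s)", kb$position[bad],
                         kb$ref[bad], actual[bad]), collapse = "; "))
    }
  }
  structure(kb, class = c("mtrnr1_kb", "data.frame"))
}

#' Write a knowledge base to TSV
#'
#' @param kb an `mtrnr1_kb` data.frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_kb <- function(kb, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# mtrnr1_kb schema_version=1", con)
  utils::write.table(as.data.frame(kb), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
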