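# Shared helpers: rounding, seeding, sequence utilities.

#' Round half away from zero
#'
#' Reporting-boundary rounding for VAFs and percentages. Unlike [round()],
#' which rounds half to even, `.5` always rounds up in magnitude, so a VAF of
#' 0.925 reports as 0.93.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Derive a per-sample seed from a master seed
#'
#' Deterministic hash of (master seed, sample id) so cohorts reproduce
#' per-sample output regardless of sample ordering. Result is a positive
#' integer below 2^31.
#'
#' @param master integer master seed.
#' @param id character sample identifier.
#' @return integer seed.
#' @export
derive_seed <- function(master, id) {
  h <- as.double(master) %% 2147483647
  for (code in utf8ToInt(as.character(id))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h + 1)
}

# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

# Map base characters to 1..4 (A,C,G,T); 0 for anything else (N etc.).
base_codes <- function(chars) {
  match(chars, DNA_BASES, nomatch = 0L)
}

# Random DNA string(s) using the current RNG stream.
random_dna <- function(n_bases) {
  paste(sample(DNA_BASES, n_bases, replace = TRUE), collapse = "")
}

offmito_version <- function() {
  as.character(utils::packageVersion("offmito"))
}
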