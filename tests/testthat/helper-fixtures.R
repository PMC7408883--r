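# Shared fixtures: miniature genomes, constructed pileups, and the
# exhaustive competitive-alignment oracle used to validate the seeded
# two-step extraction.

# Miniature circular mito-like contig plus one decoy carrying a NUMT copy of
# mito span `numt_span` at the given divergence.
mini_genome <- function(seed = 1, mito_len = 3000, decoy_len = 2000,
                        numt_span = c(500, 1499), divergence = 0.05,
                        target_fraction = 0.2) {
  build_synthetic_genome(
    n_decoys = 1, decoy_length = decoy_len,
    numt_specs = data.frame(mt_start = numt_span[1], mt_end = numt_span[2],
                            divergence = divergence),
    seed = seed, target_fraction = target_fraction, mito_length = mito_len
  )
}

# Pileup with the given base counts at a single position, zero elsewhere.
pileup_at <- function(mito_ref, pos, A = 0, C = 0, G = 0, T = 0) {
  pileup_from_counts(data.frame(pos = pos, A = A, C = C, G = G, T = T),
                     mito_ref)
}

# Exhaustive ungapped alignment of one read over every offset and strand of
# a contig; returns the maximum score. Independent of the seeded aligner.
brute_best_score <- function(read, contig_seq, circular,
                             match = 1, mismatch = -4) {
  L <- nchar(contig_seq)
  m <- nchar(read)
  ext <- if (circular) paste0(contig_seq, contig_seq) else contig_seq
  eraw <- charToRaw(ext)
  starts <- if (circular) 0:(L - 1) else 0:(L - m)
  if (length(starts) == 0 || m > L) return(-Inf)
  best <- -Inf
  for (q in c(read, revcomp(read))) {
    qraw <- charToRaw(q)
    idx <- outer(starts, seq_len(m), `+`)  # 1-based into eraw
    cmp <- matrix(eraw[idx], nrow = length(starts)) !=
      matrix(qraw, nrow = length(starts), ncol = m, byrow = TRUE)
    mm <- rowSums(cmp)
    best <- max(best, max(match * (m - mm) + mismatch * mm))
  }
  best
}

# Oracle for the two-step decision: retained as mitochondrial iff the
# exhaustive best mito score strictly beats the exhaustive best nuclear
# score and is positive (ties to nuclear).
brute_force_retained <- function(seqs, mito_ref, decoys,
                                 match = 1, mismatch = -4) {
  vapply(seqs, function(s) {
    ms <- brute_best_score(s, mito_ref$sequence, TRUE, match, mismatch)
    ns <- max(vapply(decoys, function(d) {
      brute_best_score(s, d$sequence, FALSE, match, mismatch)
    }, numeric(1)))
    ms > ns && ms > 0
  }, logical(1), USE.NAMES = FALSE)
}

# Genotype table assembled directly from per-sample (ref, alt) counts at a
# single position.
genotype_table_from_counts <- function(ref_reads, alt_reads, pos = 1555,
                                       ref = "A", alt = "G",
                                       mode = "clinical",
                                       params = classify_params()) {
  call <- classify_site(ref_reads, alt_reads, mode, params)
  structure(
    data.frame(
      sample = sprintf("S%04d", seq_along(call$ref_reads)),
      pos = pos, ref = ref,
      alt = ifelse(call$alt_reads > 0, alt, NA_character_),
      ref_reads = call$ref_reads, alt_reads = call$alt_reads,
      vaf = call$vaf, genotype_class = call$genotype_class,
      flags = call$flags, stringsAsFactors = FALSE
    ),
    class = c("genotype_table", "data.frame")
  )
}
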