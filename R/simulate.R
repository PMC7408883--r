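# Synthetic capture experiments: a mitochondrial-like reference, nuclear
# decoys carrying diverged NUMT inserts, capture targets, and paired-end
# reads drawn from four provenance classes (on-target nuclear, off-target
# nuclear, true mitochondrial, NUMT) with heteroplasmic variant mixing,
# per-base substitution error and PCR duplicates. Every sample carries a
# ground-truth record so recovery can be tested without external data.

# Reference bases pinned so the bundled knowledge base validates against the
# synthetic sequence; 1095 is pinned too since per-position depth is reported
# there.
KB_PINNED_BASES <- c(
  `669` = "T", `827` = "A", `896` = "A", `930` = "G", `961` = "T",
  `988` = "G", `1005` = "T", `1048` = "C", `1095` = "T", `1189` = "T",
  `1243` = "T", `1438` = "G", `1462` = "G", `1494` = "C", `1537` = "C",
  `1555` = "A"
)

#' Synthetic mitochondrial reference sequence
#'
#' A deterministic 16,569-base synthetic stand-in for an rCRS-style
#' mitochondrial genome (the real reference is not bundled). Bases at the
#' bundled knowledge-base positions are pinned to their reference alleles,
#' and the m.961 context reproduces the homopolymer neighbourhood (four
#' cytosines upstream, five downstream of the T at 961). Neighbours of other
#' pinned positions are set so no homopolymer run of length >= 4 touches
#' them, keeping the homopolymer flag specific to the m.961 region.
#'
#' @param length sequence length (default 16569).
#' @return uppercase base string.
#' @export
synthetic_mito_sequence <- function(length = 16569) {
  bases <- with_seed(823542L, sample(DNA_BASES, length, replace = TRUE))
  # m.961 homopolymer context: CCCC T CCCCC
  if (length >= 966) {
    bases[957:960] <- "C"
    bases[961] <- "T"
    bases[962:966] <- "C"
  }
  for (p in as.integer(names(KB_PINNED_BASES))) {
    if (p > length) next
    b <- KB_PINNED_BASES[[as.character(p)]]
    bases[p] <- b
    if (p >= 957 && p <= 966) next  # keep the homopolymer context intact
    nxt <- function(x) DNA_BASES[(match(x, DNA_BASES)) %% 4 + 1]
    # break any run through the pinned base: neighbours differ from the pin
    # and from their outer neighbours
    if (p - 2 >= 1) {
      bases[p - 1] <- nxt(b)
      bases[p - 2] <- nxt(bases[p - 1])
    }
    if (p + 2 <= length) {
      bases[p + 1] <- nxt(b)
      bases[p + 2] <- nxt(bases[p + 1])
    }
  }
  paste(bases, collapse = "")
}

#' Build a synthetic genome: mitochondrial contig, decoys, capture targets
#'
#' Decoys are random nuclear-like contigs; each `numt_specs` row inserts a
#' copy of the mitochondrial segment `mt_start..mt_end` mutated at the given
#' substitution fraction (per-base Bernoulli, so a 1,000-base insert at
#' divergence 0.02 differs at ~20 sites). Capture targets tile a fraction of
#' each decoy, avoid NUMT inserts, and never touch the mitochondrial contig.
#'
#' @param n_decoys number of nuclear decoy contigs.
#' @param decoy_length length of each decoy in bases.
#' @param numt_specs data.frame with columns `mt_start`, `mt_end` (1-based
#'   inclusive mitochondrial span) and `divergence`; rows are assigned to
#'   decoys round-robin. NULL for no NUMTs.
#' @param seed integer seed; output is deterministic given the seed.
#' @param target_fraction approximate fraction of each decoy under targets.
#' @param mito_length length of the synthetic mitochondrial contig.
#' @return list with elements `mito` ([mito_reference()]), `decoys` (list of
#'   [nuclear_decoy()]), `targets` ([target_regions()]).
#' @export
build_synthetic_genome <- function(n_decoys = 2, decoy_length = 20000,
                                   numt_specs = NULL, seed = 1,
                                   target_fraction = 0.25,
                                   mito_length = 16569) {
  mito <- mito_reference(synthetic_mito_sequence(mito_length))
  if (!is.null(numt_specs) && nrow(numt_specs) > 0) {
    if (any(numt_specs$mt_start > numt_specs$mt_end)) {
      stop("NUMT spec with mt_start > mt_end")
    }
    if (any(numt_specs$mt_start < 1 | numt_specs$mt_end > mito$length)) {
      stop("NUMT spec outside the mitochondrial contig")
    }
    if (any(numt_specs$mt_end - numt_specs$mt_start + 1 > decoy_length)) {
      stop("NUMT segment longer than the decoy contig")
    }
  }
  with_seed(seed, {
    decoys <- vector("list", n_decoys)
    for (i in seq_len(n_decoys)) {
      seq_i <- random_dna(decoy_length)
      ann <- NULL
      if (!is.null(numt_specs) && nrow(numt_specs) > 0) {
        rows <- which(seq_len(nrow(numt_specs)) %% n_decoys == i %% n_decoys)
        if (length(rows)) {
          ann_list <- list()
          # stack inserts left-to-right with spacing so they never overlap
          cursor <- 1L
          gap <- max(1L, decoy_length %/% (2L * length(rows) + 1L))
          for (r in rows) {
            s <- numt_specs$mt_start[r]; e <- numt_specs$mt_end[r]
            seg <- substr(mito$sequence, s, e)
            seg_len <- nchar(seg)
            mut <- mutate_segment(seg, numt_specs$divergence[r])
            ins <- cursor + gap %/% 2L
            if (ins + seg_len - 1 > decoy_length) {
              stop("NUMT inserts do not fit in decoy ", i)
            }
            substr(seq_i, ins, ins + seg_len - 1) <- mut$sequence
            cursor <- ins + seg_len
            ann_list[[length(ann_list) + 1]] <- data.frame(
              mt_start = s, mt_end = e,
              divergence = numt_specs$divergence[r], insert_pos = ins
            )
            ann_list[[length(ann_list)]]$diverged_offsets <- I(list(mut$offsets))
          }
          ann <- do.call(rbind, ann_list)
        }
      }
      decoys[[i]] <- nuclear_decoy(seq_i, sprintf("decoy%d", i), ann)
    }
    targets <- tile_targets(decoys, target_fraction)
    list(mito = mito, decoys = decoys, targets = targets)
  })
}

# Mutate a segment at a per-base substitution fraction; returns the mutated
# sequence and the 1-based offsets substituted.
mutate_segment <- function(seg, divergence) {
  chars <- strsplit(seg, "")[[1]]
  hit <- which(stats::runif(length(chars)) < divergence)
  for (j in hit) {
    chars[j] <- sample(setdiff(DNA_BASES, chars[j]), 1)
  }
  list(sequence = paste(chars, collapse = ""), offsets = hit)
}

# Tile fixed-width target windows over decoys, skipping NUMT inserts.
tile_targets <- function(decoys, target_fraction, width = 500L) {
  rows <- list()
  for (d in decoys) {
    n_win <- max(1L, floor(d$length * target_fraction / width))
    starts <- floor(seq(0, d$length - width, length.out = n_win * 2))
    keep <- rep(TRUE, length(starts))
    if (!is.null(d$numt_annotations)) {
      for (r in seq_len(nrow(d$numt_annotations))) {
        ins0 <- d$numt_annotations$insert_pos[r] - 1L
        len <- d$numt_annotations$mt_end[r] - d$numt_annotations$mt_start[r] + 1L
        keep <- keep & (starts + width <= ins0 | starts >= ins0 + len)
      }
    }
    starts <- utils::head(starts[keep], n_win)
    if (length(starts)) {
      rows[[length(rows) + 1]] <- data.frame(
        contig = d$name, start = as.integer(starts),
        end = as.integer(starts + width)
      )
    }
  }
  target_regions(do.call(rbind, rows))
}

PROFILE_PRESETS <- list(
  # off-target fractions and mito shares follow the sample-type regimes of
  # capture experiments: small custom panels push ~50% of reads off-target
  # with ~0.03% of those from true mtDNA; exomes ~15% off-target with ~0.02%
  # mito; FFPE material raises both; saliva roughly doubles the mito share
  # relative to blood.
  blood_panel  = list(total_read_pairs = 2e6,  off_target_fraction = 0.50,
                      mito_weight = 3.0e-4),
  saliva_panel = list(total_read_pairs = 2e6,  off_target_fraction = 0.50,
                      mito_weight = 9.0e-4),
  ffpe_panel   = list(total_read_pairs = 2e6,  off_target_fraction = 0.73,
                      mito_weight = 5.3e-3),
  blood_wes    = list(total_read_pairs = 44e6, off_target_fraction = 0.15,
                      mito_weight = 2.0e-4),
  frozen_wes   = list(total_read_pairs = 44e6, off_target_fraction = 0.05,
                      mito_weight = 2.0e-4),
  clinical_wes = list(total_read_pairs = 75e6, off_target_fraction = 0.15,
                      mito_weight = 4.3e-4)
)

#' Sequencing-sample profile
#'
#' Generative parameters of one capture experiment. `off_target_fraction` is
#' the expected share of read pairs not drawn from capture targets;
#' `mito_weight` and `numt_weight` are the expected shares of the off-target
#' mass originating from true mtDNA and from NUMT loci respectively.
#'
#' @param name sample/profile label.
#' @param total_read_pairs number of primary read pairs to draw.
#' @param off_target_fraction expected off-target share in \[0,1\].
#' @param mito_weight expected mtDNA share of off-target mass.
#' @param numt_weight expected NUMT share of off-target mass.
#' @param read_length read length in bases.
#' @param error_rate per-base substitution probability.
#' @param duplicate_rate expected PCR-duplicate fraction.
#' @param preset preset label, if built through [profile_preset()].
#' @return object of class `sample_profile`.
#' @export
sample_profile <- function(name, total_read_pairs, off_target_fraction,
                           mito_weight, numt_weight = mito_weight / 2,
                           read_length = 100, error_rate = 0.001,
                           duplicate_rate = 0.05, preset = NA_character_) {
  fr <- c(off_target_fraction, mito_weight, numt_weight,
          error_rate, duplicate_rate)
  if (any(fr < 0 | fr > 1)) stop("profile fractions must lie in [0,1]")
  if (mito_weight + numt_weight > 1) {
    stop("mito_weight + numt_weight exceeds the off-target mass")
  }
  structure(
    list(name = name, total_read_pairs = as.integer(total_read_pairs),
         off_target_fraction = off_target_fraction,
         mito_weight = mito_weight, numt_weight = numt_weight,
         read_length = as.integer(read_length), error_rate = error_rate,
         duplicate_rate = duplicate_rate, preset = preset),
    class = "sample_profile"
  )
}

#' Preset sample profiles
#'
#' Presets emulate the sample-type regimes of targeted capture: custom-panel
#' blood/saliva/FFPE and exome blood/frozen/clinical. Preset read totals are
#' cohort-typical; pass `total_read_pairs` to scale an experiment down.
#'
#' @param preset one of `blood_panel`, `saliva_panel`, `ffpe_panel`,
#'   `blood_wes`, `frozen_wes`, `clinical_wes`.
#' @param total_read_pairs optional override of the preset read total.
#' @param name sample label (defaults to the preset name).
#' @param ... further overrides passed to [sample_profile()].
#' @return a `sample_profile`.
#' @export
profile_preset <- function(preset, total_read_pairs = NULL, name = preset,
                           ...) {
  preset <- match.arg(preset, names(PROFILE_PRESETS))
  p <- PROFILE_PRESETS[[preset]]
  if (!is.null(total_read_pairs)) p$total_read_pairs <- total_read_pairs
  args <- utils::modifyList(
    c(list(name = name, preset = preset), p), list(...)
  )
  do.call(sample_profile, args)
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf(
    "<sample_profile> %s (%s): %s pairs, off-target %.3g, mito %.3g, numt %.3g\n",
    x$name, x$preset, format(x$total_read_pairs, big.mark = ","),
    x$off_target_fraction, x$mito_weight, x$numt_weight))
  invisible(x)
}

#' Genotype specification for the simulator
#'
#' @param position 1-based mitochondrial position(s).
#' @param alt alternative base(s).
#' @param h heteroplasmy level(s) in \[0,1\]; 1 = homoplasmic alternative.
#' @return data.frame of class `genotype_spec`.
#' @export
genotype_spec <- function(position, alt, h) {
  if (any(h < 0 | h > 1)) stop("heteroplasmy h must lie in [0,1]")
  if (anyDuplicated(position)) stop("genotype positions must be unique")
  structure(
    data.frame(position = as.integer(position), alt = toupper(alt), h = h),
    class = c("genotype_spec", "data.frame")
  )
}

#' Simulate one capture sample
#'
#' Draws `total_read_pairs` fragments from the four provenance classes with
#' the profile's expected proportions, applies the genotype (each
#' mitochondrial fragment carries the alternative base with probability `h`,
#' independently per variant), then per-base sequencing error, then appends
#' PCR duplicates as exact copies of existing fragments. Fragment lengths are
#' normal(300, 50) truncated at the read length; base qualities are constant
#' Q30.
#'
#' @param genome output of [build_synthetic_genome()].
#' @param profile a [sample_profile()].
#' @param genotype a [genotype_spec()] or NULL for wild type.
#' @param seed integer seed; output is deterministic given the seed.
#' @param sample_id sample identifier (defaults to the profile name).
#' @return list of class `sim_sample` with `reads` (data.frame: id, class,
#'   contig, start0, frag_len, seq1, qual1, seq2, qual2) and `truth`
#'   (class `truth_record`).
#' @export
simulate_sample <- function(genome, profile, genotype = NULL, seed = 1,
                            sample_id = profile$name) {
  stopifnot(inherits(profile, "sample_profile"))
  mito <- genome$mito
  if (!is.null(genotype)) {
    if (any(genotype$position < 1 | genotype$position > mito$length)) {
      stop("genotype position outside the mitochondrial contig")
    }
    if (any(genotype$h < 0 | genotype$h > 1)) stop("h outside [0,1]")
  }
  rl <- profile$read_length
  n <- profile$total_read_pairs
  with_seed(seed, {
    off <- profile$off_target_fraction
    probs <- c(on_target = 1 - off,
               off_nuclear = off * (1 - profile$mito_weight - profile$numt_weight),
               mito = off * profile$mito_weight,
               numt = off * profile$numt_weight)
    cls <- if (n > 0) sample(names(probs), n, replace = TRUE, prob = probs)
           else character(0)
    flen <- pmax(rl, as.integer(round(stats::rnorm(n, 300, 50))))

    contig <- character(n); start0 <- integer(n); frag <- character(n)
    mito2 <- paste0(mito$sequence, mito$sequence)  # circular wrap

    i_mito <- which(cls == "mito")
    if (length(i_mito)) {
      s <- sample.int(mito$length, length(i_mito), replace = TRUE) - 1L
      contig[i_mito] <- mito$name; start0[i_mito] <- s
      frag[i_mito] <- substring(mito2, s + 1L, s + flen[i_mito])
    }

    dec_names <- vapply(genome$decoys, function(d) d$name, character(1))
    dec_len <- stats::setNames(
      vapply(genome$decoys, function(d) d$length, integer(1)), dec_names)
    # uniform integer draws on [lo, hi] (vectorised)
    runif_int <- function(lo, hi) {
      lo + pmin(hi - lo, floor(stats::runif(length(lo)) * (hi - lo + 1L)))
    }
    fill_frags <- function(i, ctg, s) {
      contig[i] <<- ctg
      start0[i] <<- s
      for (dn in unique(ctg)) {
        sel <- ctg == dn
        d <- genome$decoys[[match(dn, dec_names)]]
        frag[i[sel]] <<- substring(d$sequence, s[sel] + 1L,
                                   s[sel] + flen[i[sel]])
      }
    }

    i_numt <- which(cls == "numt")
    if (length(i_numt)) {
      ann <- numt_annotation_table(genome$decoys)
      if (nrow(ann) == 0) {
        # no NUMT loci in the genome: fold into off-target nuclear
        cls[i_numt] <- "off_nuclear"
        i_numt <- integer(0)
      } else {
        pick <- sample.int(nrow(ann), length(i_numt), replace = TRUE)
        dl <- dec_len[ann$decoy_idx[pick]]
        seg_len <- ann$mt_end[pick] - ann$mt_start[pick] + 1L
        ins0 <- ann$insert_pos[pick] - 1L
        fl <- pmin(flen[i_numt], dl)
        flen[i_numt] <- fl
        # fragment inside the insert when it fits, else covering it
        lo <- pmax(0L, ins0 + pmin(0L, seg_len - fl))
        hi <- pmin(dl - fl, ins0 + pmax(0L, seg_len - fl))
        hi <- pmax(hi, lo)
        s <- runif_int(lo, hi)
        fill_frags(i_numt, dec_names[ann$decoy_idx[pick]], s)
      }
    }

    i_on <- which(cls == "on_target")
    if (length(i_on)) {
      t <- genome$targets[!genome$targets$mito, , drop = FALSE]
      if (nrow(t) == 0) stop("profile requests on-target reads but the genome has no nuclear targets")
      pick <- sample.int(nrow(t), length(i_on), replace = TRUE,
                         prob = t$end - t$start)
      fl <- flen[i_on]
      lo <- pmax(0L, t$start[pick] - fl + 1L)
      hi <- pmax(lo, pmin(dec_len[t$contig[pick]] - fl, t$end[pick] - 1L))
      fill_frags(i_on, t$contig[pick], runif_int(lo, hi))
    }

    i_offn <- which(cls == "off_nuclear")
    if (length(i_offn)) {
      pick <- sample.int(length(genome$decoys), length(i_offn),
                         replace = TRUE, prob = dec_len)
      fl <- pmin(flen[i_offn], dec_len[pick])
      flen[i_offn] <- fl
      s <- runif_int(rep(0L, length(i_offn)), dec_len[pick] - fl)
      # rejection-resample draws that land on a target
      for (round in 1:50) {
        bad <- overlaps_targets(dec_names[pick], s, s + fl, genome$targets)
        if (!any(bad)) break
        s[bad] <- runif_int(rep(0L, sum(bad)), dec_len[pick[bad]] - fl[bad])
      }
      fill_frags(i_offn, dec_names[pick], s)
    }

    # heteroplasmic variant mixing, applied before sequencing error
    if (!is.null(genotype) && length(i_mito)) {
      for (v in seq_len(nrow(genotype))) {
        p0 <- genotype$position[v] - 1L
        offset <- (p0 - start0[i_mito]) %% mito$length
        covered <- offset < flen[i_mito]
        carries <- stats::runif(length(i_mito)) < genotype$h[v]
        sel <- i_mito[covered & carries]
        offs <- offset[covered & carries]
        for (j in seq_along(sel)) {
          substr(frag[sel[j]], offs[j] + 1L, offs[j] + 1L) <- genotype$alt[v]
        }
      }
    }

    seq1 <- substr(frag, 1L, rl)
    seq2 <- revcomp(substring(frag, flen - rl + 1L, flen))
    seq1 <- add_read_errors(seq1, profile$error_rate)
    seq2 <- add_read_errors(seq2, profile$error_rate)

    ids <- sprintf("%s:%06d:%s", sample_id, seq_len(n), cls)
    reads <- data.frame(
      id = ids, class = cls, contig = contig, start0 = start0,
      frag_len = flen, seq1 = seq1, qual1 = rep(strrep("?", rl), n),
      seq2 = seq2, qual2 = rep(strrep("?", rl), n), stringsAsFactors = FALSE
    )

    n_dup <- if (n > 0) stats::rbinom(1, n, profile$duplicate_rate) else 0L
    if (n_dup > 0) {
      src <- sample.int(n, n_dup, replace = TRUE)
      dups <- reads[src, , drop = FALSE]
      dups$id <- sprintf("%s:dup%03d", dups$id, seq_len(n_dup))
      dups$class <- "duplicate"
      reads <- rbind(reads, dups)
      rownames(reads) <- NULL
    }

    counts <- c(
      on_target = sum(cls == "on_target"),
      off_target_nuclear = sum(cls == "off_nuclear"),
      mito = sum(cls == "mito"),
      numt = sum(cls == "numt"),
      duplicates = as.integer(n_dup)
    )
    truth <- structure(
      list(sample = sample_id, genotype = genotype, counts = counts,
           total_fragments = nrow(reads), seed = seed),
      class = "truth_record"
    )
    structure(list(reads = reads, truth = truth, profile = profile,
                   genotype = genotype, seed = seed),
              class = "sim_sample")
  })
}

#' @export
print.truth_record <- function(x, ...) {
  cat("<truth_record> ", x$sample, ": ", x$total_fragments,
      " fragments (", paste(names(x$counts), x$counts, sep = "=",
                            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# Per-base substitution errors on a vector of read strings.
add_read_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  rl <- nchar(reads[1])
  k <- stats::rbinom(length(reads), rl, rate)
  for (i in which(k > 0)) {
    pos <- sample.int(rl, k[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(DNA_BASES, old), 1)
    }
  }
  reads
}

numt_annotation_table <- function(decoys) {
  rows <- list()
  for (i in seq_along(decoys)) {
    a <- decoys[[i]]$numt_annotations
    if (!is.null(a) && nrow(a) > 0) {
      a2 <- a[, c("mt_start", "mt_end", "divergence", "insert_pos")]
      a2$decoy_idx <- i
      rows[[length(rows) + 1]] <- a2
    }
  }
  if (length(rows) == 0) {
    return(data.frame(mt_start = integer(0), mt_end = integer(0),
                      divergence = numeric(0), insert_pos = integer(0),
                      decoy_idx = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a simulated sample as paired FASTQ
#'
#' @param sim a `sim_sample`.
#' @param prefix output prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq`.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq <- function(sim, prefix) {
  r <- sim$reads
  f1 <- paste0(prefix, "_R1.fastq"); f2 <- paste0(prefix, "_R2.fastq")
  write_fastq_records(r$id, r$seq1, r$qual1, f1)
  write_fastq_records(r$id, r$seq2, r$qual2, f2)
  invisible(c(f1, f2))
}

write_fastq_records <- function(id, seq, qual, file) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  Biostrings::writeXStringSet(x, file, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
}

#' Read paired FASTQ into the simulator's read-table shape
#'
#' @param r1,r2 FASTQ paths for the two mates.
#' @return data.frame with columns id, seq1, qual1, seq2, qual2.
#' @export
read_fastq_pair <- function(r1, r2) {
  # Biostrings warns about dropping FASTQ metadata columns; not relevant here
  a <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1))
  b <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2))
  if (length(a) != length(b)) stop("mate files differ in record count")
  data.frame(
    id = sub("\\s.*$", "", names(a)),
    seq1 = as.character(a), qual1 = as.character(Biostrings::quality(a)),
    seq2 = as.character(b), qual2 = as.character(Biostrings::quality(b)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a cohort of samples
#'
#' Per-sample seeds are derived from the master seed and the sample id, so a
#' cohort reproduces per-sample output regardless of row order.
#'
#' @param genome output of [build_synthetic_genome()].
#' @param cohort data.frame with columns `sample`, `preset`, optionally
#'   `total_read_pairs`, and optionally `pos`, `alt`, `h` (NA `pos` = wild
#'   type; one variant per sample row).
#' @param seed master integer seed.
#' @param dir optional directory; when given, paired FASTQs and a
#'   `truth.tsv` are written there.
#' @return list with `samples` (named list of `sim_sample`) and `truth`
#'   (data.frame: sample pos ref alt h n_mito n_numt n_ontarget n_offtarget
#'   n_dup seed).
#' @export
simulate_cohort <- function(genome, cohort, seed = 1, dir = NULL) {
  if (nrow(cohort) > 0 && anyDuplicated(cohort$sample)) {
    stop("duplicate sample ids in cohort spec")
  }
  samples <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    prof <- profile_preset(
      row$preset,
      total_read_pairs = if (!is.null(row$total_read_pairs) &&
                             !is.na(row$total_read_pairs))
        row$total_read_pairs else NULL,
      name = row$sample
    )
    gt <- NULL
    has_var <- !is.null(row$pos) && !is.na(row$pos)
    if (has_var) gt <- genotype_spec(row$pos, row$alt, row$h)
    seed_i <- derive_seed(seed, row$sample)
    sim <- simulate_sample(genome, prof, gt, seed = seed_i,
                           sample_id = row$sample)
    samples[[row$sample]] <- sim
    cn <- sim$truth$counts
    truth_rows[[i]] <- data.frame(
      sample = row$sample,
      pos = if (has_var) as.integer(row$pos) else NA_integer_,
      ref = if (has_var) mito_base(genome$mito, row$pos) else NA_character_,
      alt = if (has_var) row$alt else NA_character_,
      h = if (has_var) row$h else NA_real_,
      n_mito = cn[["mito"]], n_numt = cn[["numt"]],
      n_ontarget = cn[["on_target"]],
      n_offtarget = cn[["off_target_nuclear"]],
      n_dup = cn[["duplicates"]], seed = seed_i,
      stringsAsFactors = FALSE
    )
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(sample = character(0), pos = integer(0), ref = character(0),
               alt = character(0), h = numeric(0), n_mito = integer(0),
               n_numt = integer(0), n_ontarget = integer(0),
               n_offtarget = integer(0), n_dup = integer(0),
               seed = integer(0))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(samples)) {
      write_fastq(samples[[nm]], file.path(dir, nm))
    }
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(samples = samples, truth = truth)
}
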