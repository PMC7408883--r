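# Lightweight ungapped read alignment: exact k-mer seeding over forward and
# reverse-complement strands, diagonal collection, and full-length
# mismatch-counted extension. Substitution-focused by design (no indels):
# the downstream classifier is substitution-based, and indel calling in the
# m.961 homopolymer region is flagged rather than attempted.

CONTIG_SHIFT <- 16777216  # 2^24; positions are packed as contig_id*2^24 + pos0

#' Alignment scoring scheme
#'
#' Ungapped scoring: `score = match * (len - mm) + mismatch * mm` for a read
#' of length `len` with `mm` mismatches. Defaults +1/-4.
#'
#' @param match per-base match reward (> 0).
#' @param mismatch per-base mismatch penalty (negative).
#' @return list of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 1, mismatch = -4) {
  if (match <= 0) stop("match reward must be positive")
  structure(list(match = match, mismatch = mismatch),
            class = "alignment_scoring")
}

#' Build an exact k-mer seed index
#'
#' Indexes every k-mer of each contig on the forward strand (queries search
#' both the read and its reverse complement). Circular contigs are indexed
#' across the origin junction, so an origin-spanning k-mer is findable.
#'
#' @param seqs named character vector of contig sequences, or a list of
#'   `mito_reference` / `nuclear_decoy` objects.
#' @param k k-mer size (>= 11).
#' @param circular character vector of circular contig names.
#' @return object of class `seed_index`.
#' @export
seed_index <- function(seqs, k = 15, circular = character(0)) {
  seqs <- normalize_seqs(seqs, circular)
  circular <- attr(seqs, "circular")
  if (length(seqs) == 0) stop("no sequences to index")
  if (k < 11) stop("k must be >= 11")
  lens <- nchar(seqs)
  if (k > min(lens)) {
    stop("k (", k, ") exceeds the shortest contig length (", min(lens), ")")
  }
  all_kmers <- vector("list", length(seqs))
  all_codes <- vector("list", length(seqs))
  raws <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    L <- lens[i]
    ext <- if (circular[i]) paste0(s, s) else s
    raws[[i]] <- charToRaw(ext)
    n_kmer <- if (circular[i]) L else L - k + 1L
    starts <- seq_len(n_kmer)
    all_kmers[[i]] <- substring(ext, starts, starts + k - 1L)
    all_codes[[i]] <- i * CONTIG_SHIFT + (starts - 1L)
  }
  env <- list2env(split(unlist(all_codes), unlist(all_kmers)), hash = TRUE)
  structure(
    list(env = env, contigs = names(seqs), lengths = lens,
         circular = circular, raw = raws, k = as.integer(k)),
    class = "seed_index"
  )
}

#' @export
print.seed_index <- function(x, ...) {
  cat("<seed_index> k=", x$k, ", ", length(x$contigs), " contig(s): ",
      paste(x$contigs, x$lengths, sep = ":", collapse = ", "), "\n", sep = "")
  invisible(x)
}

normalize_seqs <- function(seqs, circular = character(0)) {
  if (inherits(seqs, "mito_reference")) seqs <- list(seqs)
  if (is.list(seqs)) {
    circ <- vapply(seqs, function(x) {
      isTRUE(x$circular)
    }, logical(1))
    nm <- vapply(seqs, function(x) x$name, character(1))
    seqs <- stats::setNames(vapply(seqs, function(x) x$sequence,
                                   character(1)), nm)
    circular <- union(circular, nm[circ])
  }
  attr(seqs, "circular") <- names(seqs) %in% circular
  seqs
}

# Evaluate all seeded candidate placements for a vector of reads.
# Returns a data.frame: rid (read index), contig_id, start0, strand
# ("+"/"-"), mismatches, score. Processed in chunks to bound memory.
seed_candidates <- function(reads, index, scoring, chunk_size = 2000L) {
  k <- index$k
  out <- vector("list", 0)
  n_reads <- length(reads)
  short_warned <- FALSE
  for (lo in seq(1L, max(n_reads, 1L), by = chunk_size)) {
    if (n_reads == 0) break
    hi <- min(lo + chunk_size - 1L, n_reads)
    idx <- lo:hi
    chunk <- reads[idx]
    if (any(nchar(chunk) < k) && !short_warned) {
      warning("reads shorter than k=", k, " are unmappable", call. = FALSE)
      short_warned <- TRUE
    }
    for (strand in c("+", "-")) {
      q <- if (strand == "+") chunk else revcomp(chunk)
      nlen <- nchar(q)
      keep <- which(nlen >= k)
      if (!length(keep)) next
      km_list <- lapply(keep, function(j) {
        st <- seq_len(nlen[j] - k + 1L)
        substring(q[j], st, st + k - 1L)
      })
      kms <- unlist(km_list, use.names = FALSE)
      rid_km <- rep(idx[keep], vapply(km_list, length, integer(1)))
      off_km <- unlist(lapply(km_list, function(x) seq_along(x) - 1L),
                       use.names = FALSE)
      hits <- mget(kms, envir = index$env, ifnotfound = list(NULL))
      hl <- lengths(hits)
      if (!sum(hl)) next
      codes <- unlist(hits, use.names = FALSE)
      rid <- rep(rid_km, hl)
      off <- rep(off_km, hl)
      cid <- codes %/% CONTIG_SHIFT
      pos0 <- codes %% CONTIG_SHIFT
      start0 <- pos0 - off
      L <- index$lengths[cid]
      circ <- index$circular[cid]
      rlen <- nchar(reads)[rid]
      ok <- (circ & TRUE) | (start0 >= 0 & start0 + rlen <= L)
      start0 <- ifelse(circ, start0 %% L, start0)
      ok <- ok & start0 >= 0
      rid <- rid[ok]; cid <- cid[ok]; start0 <- start0[ok]; rlen <- rlen[ok]
      if (!length(rid)) next
      key <- (rid * 2 + (strand == "-")) * 16 * CONTIG_SHIFT +
        cid * CONTIG_SHIFT + start0
      dup <- duplicated(key)
      rid <- rid[!dup]; cid <- cid[!dup]; start0 <- start0[!dup]
      rlen <- rlen[!dup]
      mm <- integer(length(rid))
      qraw_cache <- vector("list", length(chunk))
      for (j in seq_along(rid)) {
        li <- rid[j] - lo + 1L
        qraw <- qraw_cache[[li]]
        if (is.null(qraw)) {
          qraw <- charToRaw(q[li])
          qraw_cache[[li]] <- qraw
        }
        ref <- index$raw[[cid[j]]]
        seg <- ref[(start0[j] + 1L):(start0[j] + rlen[j])]
        mm[j] <- sum(seg != qraw)
      }
      score <- scoring$match * (rlen - mm) + scoring$mismatch * mm
      out[[length(out) + 1]] <- data.frame(
        rid = rid, contig_id = cid, start0 = start0, strand = strand,
        mismatches = mm, score = score
      )
    }
  }
  if (!length(out)) {
    return(data.frame(rid = integer(0), contig_id = integer(0),
                      start0 = integer(0), strand = character(0),
                      mismatches = integer(0), score = numeric(0)))
  }
  do.call(rbind, out)
}

#' Align reads against a seed index
#'
#' Seed-extend-score: every exact k-mer hit proposes a diagonal; each
#' distinct placement is scored over the full read length (ungapped). The
#' best-scoring placement is returned per read with
#' `mapq_proxy = best - second-best` score (the best score itself when only
#' one placement exists). Reads with no seed hit, or whose best score is not
#' positive, are unmapped. Deterministic: ties resolve by contig order,
#' then start, then strand.
#'
#' @param reads character vector of read sequences.
#' @param index a [seed_index()].
#' @param scoring an [alignment_scoring()].
#' @param ids optional read identifiers.
#' @return data.frame with one row per read: id, mapped, contig, start0
#'   (0-based), strand, score, mismatches, mapq_proxy.
#' @export
align_reads <- function(reads, index, scoring = alignment_scoring(),
                        ids = NULL) {
  n <- length(reads)
  ids <- ids %||% as.character(seq_len(n))
  cand <- seed_candidates(reads, index, scoring)
  res <- data.frame(
    id = ids, mapped = rep(FALSE, n), contig = NA_character_,
    start0 = NA_integer_, strand = NA_character_, score = NA_real_,
    mismatches = NA_integer_, mapq_proxy = NA_real_,
    stringsAsFactors = FALSE
  )
  if (nrow(cand) == 0) return(res)
  ord <- order(cand$rid, -cand$score, cand$contig_id, cand$start0,
               cand$strand)
  cand <- cand[ord, ]
  first <- !duplicated(cand$rid)
  best <- cand[first, ]
  rest <- cand[!first, ]
  second <- rest[!duplicated(rest$rid), ]
  sec_score <- stats::setNames(second$score, second$rid)
  pos_best <- best[best$score > 0, ]
  if (nrow(pos_best)) {
    r <- pos_best$rid
    res$mapped[r] <- TRUE
    res$contig[r] <- index$contigs[pos_best$contig_id]
    res$start0[r] <- pos_best$start0
    res$strand[r] <- pos_best$strand
    res$score[r] <- pos_best$score
    res$mismatches[r] <- pos_best$mismatches
    s2 <- sec_score[as.character(r)]
    res$mapq_proxy[r] <- ifelse(is.na(s2), pos_best$score,
                                pos_best$score - s2)
  }
  res
}

# Competitive best scores per read, split into the mitochondrial contig vs
# all other contigs. Used by the two-step extraction.
align_competitive <- function(reads, index, scoring, mito_name) {
  cand <- seed_candidates(reads, index, scoring)
  n <- length(reads)
  out <- data.frame(
    mito_score = rep(-Inf, n), mito_start0 = rep(NA_integer_, n),
    mito_strand = rep(NA_character_, n), mito_mm = rep(NA_integer_, n),
    nuc_score = rep(-Inf, n), nuc_contig = rep(NA_character_, n),
    nuc_start0 = rep(NA_integer_, n), nuc_strand = rep(NA_character_, n)
  )
  if (nrow(cand) == 0) return(out)
  mito_id <- match(mito_name, index$contigs)
  is_mito <- cand$contig_id == mito_id
  for (part in c("mito", "nuc")) {
    cc <- cand[if (part == "mito") is_mito else !is_mito, ]
    if (!nrow(cc)) next
    ord <- order(cc$rid, -cc$score, cc$contig_id, cc$start0, cc$strand)
    cc <- cc[ord, ]
    b <- cc[!duplicated(cc$rid), ]
    if (part == "mito") {
      out$mito_score[b$rid] <- b$score
      out$mito_start0[b$rid] <- b$start0
      out$mito_strand[b$rid] <- b$strand
      out$mito_mm[b$rid] <- b$mismatches
    } else {
      out$nuc_score[b$rid] <- b$score
      out$nuc_contig[b$rid] <- index$contigs[b$contig_id]
      out$nuc_start0[b$rid] <- b$start0
      out$nuc_strand[b$rid] <- b$strand
    }
  }
  out
}
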