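# Seeded ungapped read placement on contigs, the reference-mismatch baseline,
# and rewriting of read records from a contig's genomic CIGAR.

#' Build a k-mer seed index over a sequence
#'
#' Every position `0 ... nchar(sequence) - k` is indexed; k-mers containing
#' an ambiguous base are skipped.
#'
#' @param sequence Target sequence.
#' @param k Seed length (default 10).
#' @return An object of class `seed_index`: list with `k`, `n` (sequence
#'   length) and `table` (environment mapping k-mer to 0-based offsets).
#' @export
build_seed_index <- function(sequence, k = 10L) {
  n <- nchar(sequence)
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (n >= k) {
    starts <- seq_len(n - k + 1L)
    kms <- substring(sequence, starts, starts + k - 1L)
    ok <- !grepl("[^ACGT]", kms)
    offs <- split(starts[ok] - 1L, kms[ok])
    for (nm in names(offs)) assign(nm, offs[[nm]], envir = env)
  } else {
    warning("sequence shorter than seed length; empty index")
  }
  structure(list(k = as.integer(k), n = n, table = env),
            class = "seed_index")
}

seed_lookup <- function(index, kmer) {
  v <- index$table[[kmer]]
  if (is.null(v)) integer(0) else v
}

#' Place a read on a target by seeded ungapped extension
#'
#' Every k-mer of the read is probed against the index; each hit proposes the
#' offset `hit - seed position in read`. All proposed offsets keeping the
#' read fully inside the target are scored by Hamming distance, and the
#' minimum wins. All offsets tying at the minimum are returned; the caller
#' decides whether a tie is ambiguous (distinct genomic projections).
#'
#' @param read_seq Read sequence (length >= k).
#' @param target Target sequence the index was built over.
#' @param index A `seed_index` for `target`.
#' @return NULL when no seed hits an in-bounds offset; otherwise a list
#'   `offsets` (0-based, ascending, all tied at the minimum) and
#'   `mismatches`.
#' @export
place_read <- function(read_seq, target, index) {
  L <- nchar(read_seq)
  k <- index$k
  if (L < k) return(NULL)
  starts <- seq_len(L - k + 1L)
  kms <- substring(read_seq, starts, starts + k - 1L)
  cand <- unique(unlist(lapply(seq_along(kms), function(i)
    seed_lookup(index, kms[i]) - (starts[i] - 1L))))
  cand <- cand[cand >= 0L & cand + L <= index$n]
  if (!length(cand)) return(NULL)
  cand <- sort(cand)
  mm <- count_mismatches_cpp(read_seq, target, as.integer(cand))
  best <- min(mm)
  list(offsets = cand[mm == best], mismatches = best)
}

# mismatch baseline of a read against the reference at its current alignment:
# mismatching M bases + soft-clipped bases + inserted bases. D/N consume
# reference only. Counting clips as mismatches is what makes clipped reads
# updatable.
reference_mismatches <- function(read, chrom_seq) {
  if (read$cigar == "*" || bitwAnd(read$flag, 4L) > 0L) return(NA_integer_)
  r <- cigar_runs(read$cigar)
  g <- read$pos; q <- 0L; mm <- 0L
  for (i in seq_len(nrow(r))) {
    op <- r$op[i]; L <- r$len[i]
    if (op %in% c("M", "=", "X")) {
      a <- substr(read$seq, q + 1L, q + L)
      b <- substr(chrom_seq, g + 1L, g + L)
      if (nchar(b) < L) b <- paste0(b, strrep("N", L - nchar(b)))  # off-end
      mm <- mm + sum(utf8ToInt(a) != utf8ToInt(b))
      g <- g + L; q <- q + L
    } else if (op == "S") { mm <- mm + L; q <- q + L
    } else if (op == "I") { mm <- mm + L; q <- q + L
    } else if (op %in% c("D", "N")) { g <- g + L }
  }
  mm
}

#' Rewrite a read record from its placement on an aligned contig
#'
#' The contig's genomic CIGAR is sliced at the read's offset for the read's
#' length: the read adopts the genomic position of its first aligned base and
#' the operations (M/I/D/N) covered by its span, with flanking D/N trimmed.
#' Soft clips disappear where bases now align. The original position and
#' CIGAR are recorded in the `OP` (1-based) and `OC` tags, the contig
#' identity in `XC`.
#'
#' @param read One-row alignment list/data.frame.
#' @param offset 0-based offset of the read within the contig sequence.
#' @param contig A `contig` object with `gpos` and `gcigar`.
#' @return List `pos`, `cigar`, `OP`, `OC`, `XC`, or NULL when the slice is
#'   degenerate (e.g. no aligned base).
#' @export
rewrite_read <- function(read, offset, contig) {
  sl <- slice_genomic_cigar(contig$gpos, contig$gcigar, offset,
                            nchar(read$seq))
  if (is.null(sl)) return(NULL)
  list(pos = sl$pos, cigar = sl$cigar,
       OP = read$pos + 1L, OC = read$cigar, XC = contig$id)
}

# slice a genomic (M/I/D/N) cigar at query offset `off`, query length `L`
slice_genomic_cigar <- function(gpos, gcigar, off, L) {
  r <- cigar_runs(gcigar)
  g <- gpos; q <- 0L
  ops <- character(0); lens <- integer(0); pos <- NA_integer_
  need <- L
  for (i in seq_len(nrow(r))) {
    op <- r$op[i]; rl <- r$len[i]
    qw <- if (op %in% c("M", "I")) rl else 0L
    gw <- if (op %in% c("M", "D", "N")) rl else 0L
    if (q + qw <= off && qw > 0L) { q <- q + qw; g <- g + gw; next }
    if (qw == 0L) {
      # D/N: interior only (skip while nothing consumed yet)
      if (q >= off && need < L && need > 0L) {
        ops <- c(ops, op); lens <- c(lens, rl)
      }
      g <- g + gw
      next
    }
    # consuming run overlapping the slice
    skip <- max(0L, off - q)
    take <- min(qw - skip, need)
    if (take > 0L) {
      if (is.na(pos) && op == "M") pos <- g + skip
      ops <- c(ops, op); lens <- c(lens, take)
      need <- need - take
    }
    q <- q + qw; g <- g + gw
    if (need == 0L) break
  }
  if (need > 0L || is.na(pos)) return(NULL)
  # trim trailing D/N
  while (length(ops) && ops[length(ops)] %in% c("D", "N")) {
    ops <- ops[-length(ops)]; lens <- lens[-length(lens)]
  }
  # trim leading I is kept (legal); leading D/N cannot occur (pos from first M)
  while (length(ops) && ops[1L] %in% c("D", "N")) {
    ops <- ops[-1L]; lens <- lens[-1L]
  }
  list(pos = pos, cigar = cigar_string(ops, lens))
}

#' Decide whether a read should adopt a contig placement
#'
#' The update is accepted only when the best contig placement has strictly
#' fewer mismatches than the reference baseline, is unambiguous (all tied
#' placements project to one genomic alignment), stays within
#' `max_move_distance` of the current position, and does not exceed the
#' mismatch cap `ceiling(max_mismatch_fraction * read length)`.
#'
#' @param read One-row alignment list/data.frame.
#' @param ref_mm Reference mismatch baseline for the read.
#' @param placements List of candidate placements, each a list `contig`,
#'   `offset`, `mismatches`, `pos`, `cigar` (genomic projection of the read).
#' @param cfg A [realign_config()].
#' @return NULL to keep the read, else the winning placement.
#' @export
decide_update <- function(read, ref_mm, placements, cfg = realign_config()) {
  if (!length(placements) || is.na(ref_mm)) return(NULL)
  mms <- vapply(placements, `[[`, numeric(1), "mismatches")
  best <- min(mms)
  cap <- ceiling(cfg$max_mismatch_fraction * nchar(read$seq))
  if (best >= ref_mm || best > cap) return(NULL)
  tied <- placements[mms == best]
  proj <- paste0(vapply(tied, `[[`, numeric(1), "pos"), ":",
                 vapply(tied, `[[`, character(1), "cigar"))
  if (length(unique(proj)) > 1L) return(NULL)     # ambiguous
  win <- tied[[1L]]
  if (abs(win$pos - read$pos) > cfg$max_move_distance) return(NULL)
  win
}
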