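# Somatic indel calling on realigned tumor/normal pairs: allele counting from
# realignment tags and CIGAR evidence, one-sided Fisher's exact test for
# tumor enrichment, orientation-bias / positional-complexity / MQ0 filters,
# and tandem-repeat quality penalties.

#' One-sided Fisher's exact probability of tumor alt enrichment
#'
#' The hypergeometric tail probability that, given the table margins, the
#' tumor sample holds at least the observed number of alt reads. Degenerate
#' tables (an empty row or column) return 1.
#'
#' @param normal_ref,normal_alt,tumor_ref,tumor_alt Non-negative counts.
#' @return The p-value.
#' @export
fisher_somatic_p <- function(normal_ref, normal_alt, tumor_ref, tumor_alt) {
  stopifnot(normal_ref >= 0, normal_alt >= 0, tumor_ref >= 0, tumor_alt >= 0)
  m <- normal_alt + tumor_alt          # alt reads overall
  n <- normal_ref + tumor_ref          # ref reads overall
  k <- tumor_ref + tumor_alt           # tumor depth drawn
  if (m == 0 || n == 0 || k == 0 || normal_ref + normal_alt == 0) return(1)
  phyper(tumor_alt - 1, m = m, n = n, k = k, lower.tail = FALSE)
}

#' Read-orientation bias filter
#'
#' Fails when alt support is significantly one-stranded relative to the
#' reference strand balance (Fisher's test on the 2x2 strand table when ref
#' reads exist, else an exact binomial test against 0.5), at level `alpha`.
#' Variants with fewer than `min_alt` alt reads pass (insufficient evidence).
#'
#' @param counts List with `alt_fwd`, `alt_rev`, `ref_fwd`, `ref_rev`.
#' @param alpha Significance level.
#' @param min_alt Minimum alt depth to evaluate.
#' @return TRUE for pass, FALSE for fail.
#' @export
orientation_bias_filter <- function(counts, alpha = 0.01, min_alt = 4L) {
  alt <- counts$alt_fwd + counts$alt_rev
  if (alt < min_alt) return(TRUE)
  refn <- counts$ref_fwd + counts$ref_rev
  p <- if (refn > 0) {
    fisher.test(matrix(c(counts$ref_fwd, counts$ref_rev,
                         counts$alt_fwd, counts$alt_rev), nrow = 2L,
                       byrow = TRUE))$p.value
  } else {
    binom.test(counts$alt_fwd, alt, 0.5)$p.value
  }
  p >= alpha
}

#' Positional read-complexity filter
#'
#' Fails when the difference between the maximum and minimum start position
#' of the alt-supporting reads is strictly below `threshold` and at least two
#' alt reads exist; a span equal to the threshold passes.
#'
#' @param starts Integer vector of alt-read start positions.
#' @param threshold Minimum acceptable span in bp.
#' @return TRUE for pass, FALSE for fail.
#' @export
positional_complexity_filter <- function(starts, threshold = 10L) {
  if (length(starts) < 2L) return(TRUE)
  (max(starts) - min(starts)) >= threshold
}

#' Mapping-quality-zero filter
#'
#' Fails when a strict majority of reads spanning the locus have MAPQ 0.
#'
#' @param spanning_mq0,spanning_total Counts of spanning reads.
#' @return TRUE for pass, FALSE for fail.
#' @export
mq0_filter <- function(spanning_mq0, spanning_total) {
  if (spanning_total == 0L) return(TRUE)
  spanning_mq0 <= spanning_total / 2
}

#' Detect the tandem-repeat / homopolymer context of a locus
#'
#' Greedy scan of unit lengths 1-6 within +/- `window` bp of the locus; the
#' unit whose run (anchored at the locus) covers the most bases, with at
#' least two copies, wins.
#'
#' @param chrom_seq Chromosome sequence.
#' @param pos 0-based locus (first deleted base / insertion point).
#' @param window Scan half-width in bp.
#' @return NULL when no repeat (>= 2 copies) is present, else a list `unit`,
#'   `unit_len`, `copies`, `span` (0-based half-open genomic interval),
#'   `homopolymer` (longest single-base run at the locus).
#' @export
repeat_context <- function(chrom_seq, pos, window = 50L) {
  n <- nchar(chrom_seq)
  base_at <- function(p) substr(chrom_seq, p + 1L, p + 1L)
  best <- NULL
  for (u in 1:6) {
    if (pos + u > n) break
    unit <- substr(chrom_seq, pos + 1L, pos + u)
    if (grepl("[^ACGT]", unit)) next
    # extend forward in whole units
    re <- pos + u
    while (re + u <= min(n, pos + window) &&
           substr(chrom_seq, re + 1L, re + u) == unit) re <- re + u
    # extend backward in whole units
    rs <- pos
    while (rs - u >= max(0L, pos - window) &&
           substr(chrom_seq, rs - u + 1L, rs) == unit) rs <- rs - u
    copies <- (re - rs) %/% u
    if (copies >= 2L && (is.null(best) || (re - rs) > diff(best$span))) {
      best <- list(unit = unit, unit_len = u, copies = copies,
                   span = c(rs, re))
    }
  }
  if (is.null(best)) return(NULL)
  # homopolymer run through the locus
  b <- base_at(pos)
  hs <- pos; while (hs > 0L && base_at(hs - 1L) == b) hs <- hs - 1L
  he <- pos + 1L; while (he < n && base_at(he) == b) he <- he + 1L
  best$homopolymer <- he - hs
  best
}

#' Tandem-repeat / homopolymer quality penalty
#'
#' When the indel length is a multiple of the detected repeat unit, the
#' Phred-scaled variant quality is reduced by `2 * (copies - t)` capped at
#' 30, where `t` is 5 for homopolymers (unit length 1) and 3 for longer
#' units. The penalty is monotone in the run length and zero outside repeat
#' context or when disabled (`cfg$str_penalty = FALSE`).
#'
#' @param indel List/row with `pos`, `type`, `len`.
#' @param chrom_seq Chromosome sequence.
#' @param cfg A [realign_config()].
#' @return Non-negative quality delta to subtract.
#' @export
repeat_penalty <- function(indel, chrom_seq, cfg = realign_config()) {
  if (!isTRUE(cfg$str_penalty)) return(0)
  rc <- repeat_context(chrom_seq, indel$pos)
  if (is.null(rc)) return(0)
  if (indel$len %% rc$unit_len != 0L) return(0)
  t0 <- if (rc$unit_len == 1L) 5L else 3L
  min(30, 2 * max(0L, rc$copies - t0))
}

# genomic intervals a read's alignment truly samples (M/D, N excluded), as a
# matrix of 0-based half-open rows
read_coverage_blocks <- function(cigar, pos0) {
  r <- cigar_runs(cigar)
  g <- pos0
  lo <- integer(0); hi <- integer(0)
  cur_lo <- NA_integer_
  for (i in seq_len(nrow(r))) {
    op <- r$op[i]; L <- r$len[i]
    if (op %in% c("M", "D", "=", "X")) {
      if (is.na(cur_lo)) cur_lo <- g
      g <- g + L
    } else if (op == "N") {
      if (!is.na(cur_lo)) { lo <- c(lo, cur_lo); hi <- c(hi, g); cur_lo <- NA_integer_ }
      g <- g + L
    }
  }
  if (!is.na(cur_lo)) { lo <- c(lo, cur_lo); hi <- c(hi, g) }
  cbind(lo, hi)
}

# does the alignment contiguously sample [lo, hi)?
read_spans_interval <- function(cigar, pos0, lo, hi) {
  blk <- read_coverage_blocks(cigar, pos0)
  any(blk[, 1L] <= lo & blk[, 2L] >= hi)
}

parse_contig_id <- function(ids) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  rbindlist(lapply(parts, function(p) {
    if (length(p) < 4L) return(NULL)
    data.table(chrom = p[1L], pos = as.integer(p[2L]), type = p[3L],
               len = as.integer(p[4L]),
               seq = if (length(p) >= 5L) p[5L] else "")
  }))
}

#' Gather per-sample allele counts at an indel locus
#'
#' Alt support comes from reads whose realignment tag (`XC`) names a contig
#' carrying this indel, or whose own CIGAR shows the indel at the locus; in
#' both cases the read must span the evaluated interval. In repeat context
#' only reads spanning the full repeat run (plus one anchor base each side)
#' are evaluated, for both alleles.
#'
#' @param reads Alignment data.table of one sample.
#' @param indel List/row `chrom`, `pos`, `type`, `len`, `seq`
#'   (left-normalized, 0-based).
#' @param chrom_seq Chromosome sequence (for repeat detection).
#' @return List of counts: `ref_count`, `alt_count`, `alt_fwd`, `alt_rev`,
#'   `ref_fwd`, `ref_rev`, `alt_starts`, `spanning_mq0`, `spanning_total`.
#' @export
gather_counts <- function(reads, indel, chrom_seq) {
  rc <- repeat_context(chrom_seq, indel$pos)
  locus_hi <- indel$pos + if (indel$type == "del") indel$len else 0L
  lo <- indel$pos; hi <- locus_hi
  if (!is.null(rc)) { lo <- min(lo, rc$span[1L]); hi <- max(hi, rc$span[2L]) }
  lo <- lo - 1L; hi <- hi + 1L              # one anchor base each side

  sub <- reads[rname == indel$chrom & bitwAnd(flag, 4L) == 0L & cigar != "*" &
                 pos <= lo & ref_end >= hi]
  if (!nrow(sub))
    return(list(ref_count = 0L, alt_count = 0L, alt_fwd = 0L, alt_rev = 0L,
                ref_fwd = 0L, ref_rev = 0L, alt_starts = integer(0),
                spanning_mq0 = 0L, spanning_total = 0L))

  spans <- vapply(seq_len(nrow(sub)), function(i)
    read_spans_interval(sub$cigar[i], sub$pos[i], lo, hi), logical(1))
  sub <- sub[spans]

  is_alt <- logical(nrow(sub))
  if (nrow(sub)) {
    # CIGAR evidence
    for (i in which(grepl("[ID]", sub$cigar))) {
      for (z in cigar_indels(sub$cigar[i], sub$pos[i], sub$seq[i])) {
        nz <- left_normalize_indel(chrom_seq, z$pos, z$type, z$len, z$seq)
        if (nz$pos == indel$pos && z$type == indel$type && z$len == indel$len &&
            (indel$type == "del" || nz$seq == indel$seq)) {
          is_alt[i] <- TRUE
          break
        }
      }
    }
    # tag evidence
    tagged <- which(!is.na(sub$XC))
    if (length(tagged)) {
      tid <- parse_contig_id(sub$XC[tagged])
      if (!is.null(tid) && nrow(tid) == length(tagged)) {
        for (j in seq_along(tagged)) {
          nz <- left_normalize_indel(chrom_seq, tid$pos[j], tid$type[j],
                                     tid$len[j], tid$seq[j])
          if (nz$pos == indel$pos && tid$type[j] == indel$type &&
              tid$len[j] == indel$len &&
              (indel$type == "del" || nz$seq == indel$seq))
            is_alt[tagged[j]] <- TRUE
        }
      }
    }
  }

  fwd <- bitwAnd(sub$flag, 16L) == 0L
  list(ref_count = sum(!is_alt),
       alt_count = sum(is_alt),
       alt_fwd = sum(is_alt & fwd), alt_rev = sum(is_alt & !fwd),
       ref_fwd = sum(!is_alt & fwd), ref_rev = sum(!is_alt & !fwd),
       alt_starts = sub$pos[is_alt],
       spanning_mq0 = sum(sub$mapq == 0L, na.rm = TRUE),
       spanning_total = nrow(sub))
}

#' Call somatic indels from a realigned tumor/normal pair
#'
#' Candidate indels are collected from the tumor sample's realignment tags
#' and CIGARs, left-normalized, counted in both samples, scored with the
#' one-sided Fisher test and annotated with filter outcomes. Quality is
#' `-10*log10(p)` minus repeat penalties, floored at 0; records below
#' `cfg$min_qual` or with fewer than `cfg$min_alt_count` tumor alt reads are
#' dropped.
#'
#' @param tumor,normal Alignment data.tables or SAM/BAM paths (realigned).
#' @param reference Named character vector of sequences or FASTA path.
#' @param cfg A [realign_config()].
#' @param vcf_path Optional path; when given the calls are also written as
#'   VCF v4.2.
#' @return data.table of calls: `chrom`, `pos` (1-based VCF), `ref`, `alt`,
#'   `p_value`, `qual`, `filters` (comma string, `"PASS"` when clean), plus
#'   per-sample count columns.
#' @export
call_variants <- function(tumor, normal, reference, cfg = realign_config(),
                          vcf_path = NULL) {
  if (is.character(tumor) && length(tumor) == 1L) tumor <- read_alignments(tumor)
  if (is.character(normal) && length(normal) == 1L) normal <- read_alignments(normal)
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) reference <- read_reference(reference)

  cand <- harvest_observed_indels(tumor)
  tag_ids <- unique(tumor$XC[!is.na(tumor$XC)])
  if (length(tag_ids)) {
    tg <- parse_contig_id(tag_ids)
    if (!is.null(tg) && nrow(tg)) {
      tg[, support := cfg$min_alt_count]
      cand <- rbindlist(list(cand, tg), use.names = TRUE)
    }
  }
  if (!nrow(cand)) return(empty_calls(vcf_path, reference, cfg))

  # left-normalize and dedup
  for (i in seq_len(nrow(cand))) {
    nz <- left_normalize_indel(reference[[cand$chrom[i]]], cand$pos[i],
                               cand$type[i], cand$len[i], cand$seq[i])
    cand$pos[i] <- nz$pos; cand$seq[i] <- nz$seq
  }
  cand <- cand[, .(support = sum(support)), by = .(chrom, pos, type, len, seq)]
  setorder(cand, chrom, pos, type, len)

  rows <- lapply(seq_len(nrow(cand)), function(i) {
    v <- as.list(cand[i])
    cs <- reference[[v$chrom]]
    tc <- gather_counts(tumor, v, cs)
    if (tc$alt_count < cfg$min_alt_count) return(NULL)
    nc <- gather_counts(normal, v, cs)
    p <- fisher_somatic_p(nc$ref_count, nc$alt_count, tc$ref_count,
                          tc$alt_count)
    pen <- repeat_penalty(v, cs, cfg)
    qual <- max(0, -10 * log10(max(p, 1e-300)) - pen)
    filt <- character(0)
    if (!orientation_bias_filter(tc, cfg$strand_bias_alpha, cfg$strand_min_alt))
      filt <- c(filt, "orientation_bias")
    if (!positional_complexity_filter(tc$alt_starts,
                                      cfg$pos_complexity_threshold))
      filt <- c(filt, "low_positional_complexity")
    if (!mq0_filter(tc$spanning_mq0 + nc$spanning_mq0,
                    tc$spanning_total + nc$spanning_total))
      filt <- c(filt, "mq0_majority")
    if (qual < cfg$min_qual) return(NULL)
    anchor <- substr(cs, v$pos, v$pos)   # base at 0-based pos-1
    if (v$type == "del") {
      refa <- paste0(anchor, substr(cs, v$pos + 1L, v$pos + v$len))
      alta <- anchor
    } else {
      refa <- anchor
      alta <- paste0(anchor, v$seq)
    }
    data.table(chrom = v$chrom, pos = v$pos, ref = refa, alt = alta,
               p_value = p, qual = qual,
               filters = if (length(filt)) paste(filt, collapse = ",") else "PASS",
               normal_ref = nc$ref_count, normal_alt = nc$alt_count,
               tumor_ref = tc$ref_count, tumor_alt = tc$alt_count)
  })
  calls <- rbindlist(rows)
  if (!nrow(calls)) return(empty_calls(vcf_path, reference, cfg))
  setorder(calls, chrom, pos)
  calls <- resolve_overlapping_calls(calls)
  if (!is.null(vcf_path)) write_vcf(calls, vcf_path, reference)
  calls[]
}

# Per-locus allele resolution: sequencing errors inside a real indel spawn
# weakly supported shifted/mutated echoes of it at the same locus. When
# candidate records overlap (affected reference intervals within 5 bp), only
# the best-supported allele is reported: highest quality, ties broken by
# tumor alt depth, then leftmost position.
resolve_overlapping_calls <- function(calls, pad = 5L) {
  keep <- logical(nrow(calls))
  i <- 1L
  while (i <= nrow(calls)) {
    j <- i
    hi <- calls$pos[i] + nchar(calls$ref[i]) - 1L + pad
    while (j < nrow(calls) && calls$chrom[j + 1L] == calls$chrom[i] &&
           calls$pos[j + 1L] <= hi) {
      j <- j + 1L
      hi <- max(hi, calls$pos[j] + nchar(calls$ref[j]) - 1L + pad)
    }
    grp <- i:j
    best <- grp[order(-calls$qual[grp], -calls$tumor_alt[grp],
                      calls$pos[grp])][1L]
    keep[best] <- TRUE
    i <- j + 1L
  }
  calls[keep]
}

empty_calls <- function(vcf_path, reference, cfg) {
  calls <- data.table(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), p_value = numeric(), qual = numeric(),
                      filters = character(), normal_ref = integer(),
                      normal_alt = integer(), tumor_ref = integer(),
                      tumor_alt = integer())
  if (!is.null(vcf_path)) write_vcf(calls, vcf_path, reference)
  calls
}
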