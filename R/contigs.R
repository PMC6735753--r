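# Candidate contig sources: observed indels, soft-clip reads, localized
# assembly (assembly.R) and known indels. Observed/known indels are applied
# directly to transcript representations to form region-wide haplotype
# contigs; soft-clip and assembly contigs are aligned first and their
# discovered indels routed through the same builder.

#' Harvest distinct indels observed in read CIGARs
#'
#' One entry per distinct (position, type, length, inserted sequence) seen in
#' at least one read's I or D operations; duplicates collapsed, support
#' counted. Records with `"*"` CIGARs are ignored.
#'
#' @param reads Alignment data.table.
#' @return data.table `chrom`, `pos` (0-based leftmost), `type` (`"ins"` or
#'   `"del"`), `len`, `seq` (inserted sequence, `""` for deletions),
#'   `support` (number of reads showing it).
#' @export
harvest_observed_indels <- function(reads) {
  hit <- which(grepl("[ID]", reads$cigar) & reads$cigar != "*")
  if (!length(hit)) return(empty_indels())
  out <- rbindlist(lapply(hit, function(i) {
    lst <- cigar_indels(reads$cigar[i], reads$pos[i], reads$seq[i])
    if (!length(lst)) return(NULL)
    data.table(chrom = reads$rname[i],
               pos = vapply(lst, function(z) as.integer(z$pos), integer(1)),
               type = vapply(lst, `[[`, character(1), "type"),
               len = vapply(lst, function(z) as.integer(z$len), integer(1)),
               seq = vapply(lst, `[[`, character(1), "seq"))
  }))
  if (is.null(out) || !nrow(out)) return(empty_indels())
  out[, .(support = .N), by = .(chrom, pos, type, len, seq)]
}

empty_indels <- function() {
  data.table(chrom = character(), pos = integer(), type = character(),
             len = integer(), seq = character(), support = integer())
}

#' Build a haplotype contig by applying one indel to a local reference
#'
#' The deletion is excised from (or the insertion spliced into) the given
#' transcript representation, producing a contig whose genomic CIGAR is known
#' by construction. Inverse-consistent: undoing the edit recovers the
#' representation sequence exactly.
#'
#' @param indel One-row list/data.frame: `chrom`, `pos`, `type`, `len`, `seq`.
#' @param rep A `transcript_rep` covering the indel locus (exonic).
#' @param source Provenance label recorded on the contig.
#' @param read_length Required exonic flank on both sides of the indel; the
#'   contig is dropped (NULL) if the representation cannot provide it.
#' @return A `contig` object (list: `id`, `seq`, `chrom`, `gpos`, `gcigar`,
#'   `source`, `indel`) or NULL.
#' @export
build_indel_contig <- function(indel, rep, source = "observed_indel",
                               read_length = 100L) {
  l <- map_genome_to_local(rep, indel$pos)
  if (is.na(l)) return(NULL)
  rep_len <- nchar(rep$seq)
  if (indel$type == "del") {
    lend <- map_genome_to_local(rep, indel$pos + indel$len - 1L)
    # deletion must stay within exonic sequence and not swallow a junction
    if (is.na(lend) || lend - l != indel$len - 1L) return(NULL)
    if (l < read_length || rep_len - (l + indel$len) < read_length) return(NULL)
    seq <- paste0(substr(rep$seq, 1L, l), substr(rep$seq, l + indel$len + 1L,
                                                 rep_len))
    local_cigar <- paste0(l, "M", indel$len, "D", rep_len - l - indel$len, "M")
  } else {
    if (l < read_length || rep_len - l < read_length) return(NULL)
    if (grepl("[^ACGT]", indel$seq)) return(NULL)
    seq <- paste0(substr(rep$seq, 1L, l), indel$seq,
                  substr(rep$seq, l + 1L, rep_len))
    local_cigar <- paste0(l, "M", indel$len, "I", rep_len - l, "M")
  }
  proj <- project_to_genome(list(start = 0L, cigar = local_cigar), rep)
  id <- paste0(indel$chrom, ":", indel$pos, ":", indel$type, ":", indel$len,
               if (nzchar(indel$seq)) paste0(":", indel$seq))
  structure(list(id = id, seq = seq, chrom = rep$chrom, gpos = proj$pos,
                 gcigar = proj$cigar, source = source,
                 indel = list(chrom = indel$chrom, pos = as.integer(indel$pos),
                              type = indel$type, len = as.integer(indel$len),
                              seq = indel$seq)),
            class = "contig")
}

# vectorised high-quality clipped-base counts per read at a quality threshold;
# returns list(total_hq, longest_run_hq)
softclip_hq_counts <- function(reads, min_quality) {
  n <- nrow(reads)
  total <- integer(n); longest <- integer(n)
  idx <- which(grepl("S", reads$cigar, fixed = TRUE) & reads$cigar != "*")
  for (i in idx) {
    r <- cigar_runs(reads$cigar[i])
    phred <- utf8ToInt(reads$qual[i]) - 33L
    q <- 0L
    for (k in seq_len(nrow(r))) {
      op <- r$op[k]; L <- r$len[k]
      if (op == "S") {
        nhq <- sum(phred[(q + 1L):(q + L)] >= min_quality)
        total[i] <- total[i] + nhq
        longest[i] <- max(longest[i], nhq)
        q <- q + L
      } else if (op %in% c("M", "I", "=", "X")) q <- q + L
    }
  }
  list(total = total, longest = longest)
}

#' Harvest soft-clip candidate contigs
#'
#' Emits one contig per read whose clipped segment holds at least
#' `cfg$softclip_min_bases` bases at or above `cfg$softclip_min_quality`
#' (default: 15 bases at Phred >= 20). The contig is the whole read sequence.
#' With `cfg$amplicon_consensus`, reads clipped at the same locus are merged
#' into a single majority-vote consensus contig (ties keep the first-read
#' base). Sequences containing N and duplicate sequences are dropped.
#'
#' @param reads Alignment data.table.
#' @param cfg A [realign_config()].
#' @return Character vector of candidate contig sequences (possibly empty).
#' @export
harvest_softclip_contigs <- function(reads, cfg = realign_config()) {
  if (!nrow(reads)) return(character())
  st <- softclip_hq_counts(reads, cfg$softclip_min_quality)
  qual_rows <- which(st$longest >= cfg$softclip_min_bases)
  if (!length(qual_rows)) return(character())
  seqs <- reads$seq[qual_rows]
  if (cfg$amplicon_consensus) {
    locus <- paste0(reads$rname[qual_rows], ":", reads$pos[qual_rows])
    seqs <- vapply(split(seqs, locus), consensus_sequence, character(1))
  }
  seqs <- unique(seqs[!grepl("[^ACGT]", seqs)])
  seqs
}

# majority base per column; ties keep the earliest read's base
consensus_sequence <- function(seqs) {
  if (length(seqs) == 1L) return(seqs)
  L <- max(nchar(seqs))
  mat <- vapply(seqs, function(s)
    c(strsplit(s, "")[[1L]], rep(NA_character_, L - nchar(s))),
    character(L))
  paste0(apply(mat, 1L, function(col) {
    col <- col[!is.na(col)]
    tb <- table(factor(col, levels = unique(col)))  # first occurrence breaks ties
    names(tb)[which.max(tb)]
  }), collapse = "")
}

#' Decide whether localized assembly should run for a window
#'
#' A read is an assembly trigger when its mate is unmapped, when it carries an
#' insertion longer than `insertion_trigger_fraction` of its length, or when
#' it has a high-quality soft-clip run longer than `softclip_trigger_fraction`
#' of its length. Assembly runs when triggering reads exceed
#' `assembly_trigger_fraction` of all reads.
#'
#' @param reads Alignment data.table (non-empty batch).
#' @param cfg A [realign_config()].
#' @return Logical scalar.
#' @export
should_assemble <- function(reads, cfg = realign_config()) {
  if (!nrow(reads)) return(FALSE)
  rl <- nchar(reads$seq)
  mate_unmapped <- bitwAnd(reads$flag, 8L) > 0L
  ins_max <- integer(nrow(reads))
  idx <- which(grepl("I", reads$cigar, fixed = TRUE) & reads$cigar != "*")
  for (i in idx) {
    r <- cigar_runs(reads$cigar[i])
    ins_max[i] <- max(c(0L, r$len[r$op == "I"]))
  }
  st <- softclip_hq_counts(reads, cfg$softclip_min_quality)
  trig <- mate_unmapped |
    (ins_max > cfg$insertion_trigger_fraction * rl) |
    (st$longest > cfg$softclip_trigger_fraction * rl)
  mean(trig) > cfg$assembly_trigger_fraction
}
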