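# VCF text emission, indel left-normalization and known-indel input.

#' Left-normalize an indel against the reference
#'
#' Shifts the indel left while the base preceding it equals the last base of
#' the deleted/inserted block (the standard VCF normalization rotation).
#'
#' @param chrom_seq Chromosome sequence.
#' @param pos 0-based position (first deleted base, or insertion point).
#' @param type `"ins"` or `"del"`.
#' @param len Indel length.
#' @param seq Inserted sequence (`""` for deletions).
#' @return List `pos`, `seq` (rotated inserted sequence for insertions; the
#'   deleted block is implied by the reference for deletions).
#' @export
left_normalize_indel <- function(chrom_seq, pos, type, len, seq = "") {
  base_at <- function(p) substr(chrom_seq, p + 1L, p + 1L)
  if (type == "del") {
    while (pos > 0L && base_at(pos - 1L) == base_at(pos + len - 1L))
      pos <- pos - 1L
    list(pos = as.integer(pos), seq = "")
  } else {
    s <- seq
    while (pos > 0L && base_at(pos - 1L) == substr(s, len, len)) {
      s <- paste0(base_at(pos - 1L), substr(s, 1L, len - 1L))
      pos <- pos - 1L
    }
    list(pos = as.integer(pos), seq = s)
  }
}

#' Write somatic indel calls as VCF v4.2
#'
#' @param calls data.table as returned by [call_variants()] (`pos` 1-based).
#' @param path Output path.
#' @param reference Named character vector of reference sequences (for the
#'   contig header lines).
#' @param sample_names Column names for the two genotype columns.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, reference,
                      sample_names = c("NORMAL", "TUMOR")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=splicealign",
    paste0("##contig=<ID=", names(reference), ",length=",
           nchar(reference), ">"),
    "##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description=\"Somatic event\">",
    "##INFO=<ID=PVAL,Number=1,Type=Float,Description=\"One-sided Fisher exact p-value for tumor alt enrichment\">",
    "##FILTER=<ID=orientation_bias,Description=\"Alt support significantly one-stranded\">",
    "##FILTER=<ID=low_positional_complexity,Description=\"Alt start-position span below threshold\">",
    "##FILTER=<ID=mq0_majority,Description=\"Majority of spanning reads have MAPQ 0\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Evaluated spanning depth\">",
    "##FORMAT=<ID=AD,Number=2,Type=Integer,Description=\"Ref,alt read counts\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_names[1L], "\t", sample_names[2L]))
  body <- if (nrow(calls)) {
    filt <- ifelse(calls$filters == "PASS", "PASS",
                   gsub(",", ";", calls$filters))
    paste0(calls$chrom, "\t", calls$pos, "\t.\t", calls$ref, "\t", calls$alt,
           "\t", sprintf("%.2f", calls$qual), "\t", filt,
           "\tSOMATIC;PVAL=", signif(calls$p_value, 4L),
           "\tGT:DP:AD\t",
           "0/0:", calls$normal_ref + calls$normal_alt, ":",
           calls$normal_ref, ",", calls$normal_alt, "\t",
           "0/1:", calls$tumor_ref + calls$tumor_alt, ":",
           calls$tumor_ref, ",", calls$tumor_alt)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read indels from a VCF file into the internal indel table
#'
#' SNVs and symbolic/multi-allelic records are skipped. Positions follow the
#' internal 0-based convention (`pos` = first deleted base or insertion
#' point), which for anchored VCF indels equals the numeric POS field.
#'
#' @param path VCF path.
#' @return data.table `chrom`, `pos`, `type`, `len`, `seq`, `support`.
#' @export
read_known_indels <- function(path) {
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  out <- list()
  for (i in seq_along(rr)) {
    alts <- as.character(altl[[i]])
    for (a in alts) {
      if (!nzchar(a) || grepl("[^ACGTN]", a)) next
      if (nchar(ref[i]) > 1L && nchar(a) == 1L) {
        out[[length(out) + 1L]] <- data.table(
          chrom = as.character(GenomicRanges::seqnames(rr)[i]),
          pos = as.integer(GenomicRanges::start(rr)[i]),
          type = "del", len = nchar(ref[i]) - 1L, seq = "")
      } else if (nchar(ref[i]) == 1L && nchar(a) > 1L) {
        out[[length(out) + 1L]] <- data.table(
          chrom = as.character(GenomicRanges::seqnames(rr)[i]),
          pos = as.integer(GenomicRanges::start(rr)[i]),
          type = "ins", len = nchar(a) - 1L, seq = substr(a, 2L, nchar(a)))
      }
    }
  }
  res <- rbindlist(out)
  if (is.null(res) || !nrow(res)) return(empty_indels())
  res[, support := 1L]
  unique(res)
}
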