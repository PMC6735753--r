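# Alignment I/O. BAM decoding goes through Rsamtools; SAM text input is
# converted with asBam first. Internally reads live in a data.table with
# 0-based positions; SAM text is emitted 1-based per the SAM spec.

ALN_TAGS <- c("OP", "OC", "XC")

#' Read a SAM or BAM file into an alignment table
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return A data.table with one row per alignment record: `qname`, `flag`,
#'   `rname`, `pos` (0-based), `mapq`, `cigar`, `rnext`, `pnext` (0-based),
#'   `tlen`, `seq`, `qual`, the tags `OP`/`OC`/`XC` (NA when absent),
#'   `ref_end` (0-based exclusive end on the reference), and `uid` (unique
#'   record key: name plus first/second-of-pair flag). The attribute
#'   `"header"` holds the named vector of reference sequence lengths.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  bf <- Rsamtools::BamFile(path)
  hdr <- Rsamtools::scanBamHeader(bf)$targets
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
             "mrnm", "mpos", "isize", "seq", "qual"),
    tag = ALN_TAGS)
  x <- Rsamtools::scanBam(bf, param = p)[[1L]]
  n <- length(x$qname)
  tg <- x$tag
  grab <- function(nm, default) {
    v <- tg[[nm]]
    if (is.null(v)) rep(default, n) else v
  }
  dt <- data.table(
    qname = x$qname,
    flag  = as.integer(x$flag),
    rname = as.character(x$rname),
    pos   = as.integer(x$pos) - 1L,
    mapq  = as.integer(x$mapq),
    cigar = ifelse(is.na(x$cigar), "*", x$cigar),
    rnext = as.character(x$mrnm),
    pnext = as.integer(x$mpos) - 1L,
    tlen  = as.integer(x$isize),
    seq   = as.character(x$seq),
    qual  = as.character(x$qual),
    OP    = as.integer(grab("OP", NA_integer_)),
    OC    = as.character(grab("OC", NA_character_)),
    XC    = as.character(grab("XC", NA_character_))
  )
  # unmapped reads keep the (mate's) stored position; NA -> -1 sentinel
  dt[is.na(pos), pos := -1L]
  dt[, ref_end := pos + cigar_ref_width(cigar)]
  dt[, uid := paste0(qname, "/", ifelse(bitwAnd(flag, 64L) > 0L, 1L,
                                        ifelse(bitwAnd(flag, 128L) > 0L, 2L, 0L)))]
  setattr(dt, "header", hdr)
  dt[]
}

format_sam_records <- function(reads) {
  tags <- character(nrow(reads))
  has_op <- !is.na(reads$OP)
  has_oc <- !is.na(reads$OC)
  has_xc <- !is.na(reads$XC)
  tags <- paste0(
    ifelse(has_op, paste0("\tOP:i:", reads$OP), ""),
    ifelse(has_oc, paste0("\tOC:Z:", reads$OC), ""),
    ifelse(has_xc, paste0("\tXC:Z:", reads$XC), ""))
  paste0(reads$qname, "\t", reads$flag, "\t", reads$rname, "\t",
         reads$pos + 1L, "\t", reads$mapq, "\t", reads$cigar, "\t",
         ifelse(is.na(reads$rnext), "*", reads$rnext), "\t",
         ifelse(is.na(reads$pnext), 0L, reads$pnext + 1L), "\t",
         ifelse(is.na(reads$tlen), 0L, reads$tlen), "\t",
         reads$seq, "\t", reads$qual, tags)
}

#' Write an alignment table to SAM or BAM, coordinate-sorted
#'
#' @param reads An alignment data.table (see [read_alignments()]).
#' @param path Output path ending in `.sam` or `.bam`.
#' @param chrom_lengths Named vector of reference lengths for the `@SQ` lines;
#'   defaults to the table's `"header"` attribute.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(reads, path, chrom_lengths = attr(reads, "header")) {
  stopifnot(!is.null(chrom_lengths))
  ord <- order(match(reads$rname, names(chrom_lengths)), reads$pos)
  reads <- reads[ord]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(chrom_lengths), "\tLN:",
                  as.integer(chrom_lengths)))
  lines <- c(hdr, if (nrow(reads)) format_sam_records(reads))
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = ".sam")
    writeLines(lines, tmp)
    Rsamtools::asBam(tmp, destination = sub("\\.bam$", "", path),
                     overwrite = TRUE, indexDestination = TRUE)
    unlink(tmp)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

#' Load a reference FASTA as plain character sequences
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}
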