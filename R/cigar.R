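# CIGAR helpers. Parsing/width arithmetic delegates to GenomicAlignments;
# these wrappers return plain vectors/run tables convenient for data.table work.
# All positions handled here are 0-based half-open.

#' Decompose a CIGAR string into operation/length runs
#'
#' @param cigar A single CIGAR string (not `"*"`).
#' @return A data.frame with columns `op` (character) and `len` (integer).
#' @export
cigar_runs <- function(cigar) {
  data.frame(
    op  = GenomicAlignments::explodeCigarOps(cigar)[[1L]],
    len = GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]],
    stringsAsFactors = FALSE
  )
}

#' Assemble a CIGAR string from runs, merging adjacent equal operations
#'
#' Zero-length runs are dropped.
#' @param op Character vector of CIGAR operations.
#' @param len Integer vector of run lengths.
#' @return A CIGAR string.
#' @export
cigar_string <- function(op, len) {
  keep <- len > 0L
  op <- op[keep]; len <- len[keep]
  if (!length(op)) return("")
  brk <- c(TRUE, op[-1L] != op[-length(op)])
  grp <- cumsum(brk)
  op2 <- op[brk]
  len2 <- as.integer(tapply(len, grp, sum))
  paste0(len2, op2, collapse = "")
}

# reference bases consumed by each cigar (M/D/N/=/X); vectorised
cigar_ref_width <- function(cigars) {
  out <- integer(length(cigars))
  ok <- !is.na(cigars) & cigars != "*"
  if (any(ok))
    out[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigars[ok])
  out
}

# query bases consumed (M/I/S/=/X)
cigar_query_width <- function(cigars) {
  out <- integer(length(cigars))
  ok <- !is.na(cigars) & cigars != "*"
  if (any(ok))
    out[ok] <- GenomicAlignments::cigarWidthAlongQuerySpace(
      cigars[ok], after.soft.clipping = FALSE)
  out
}

# indels (I/D) of one cigar with genomic positions; pos0 = 0-based read start.
# For D, pos is the first deleted base; for I, the base *before* which the
# insertion sits. seq supplied for I from the read sequence.
cigar_indels <- function(cigar, pos0, read_seq = NULL) {
  r <- cigar_runs(cigar)
  g <- pos0; q <- 0L
  out <- list()
  for (i in seq_len(nrow(r))) {
    op <- r$op[i]; L <- r$len[i]
    if (op == "I") {
      s <- if (!is.null(read_seq)) substr(read_seq, q + 1L, q + L) else
        strrep("N", L)
      out[[length(out) + 1L]] <- list(pos = g, type = "ins", len = L, seq = s)
      q <- q + L
    } else if (op == "D") {
      out[[length(out) + 1L]] <- list(pos = g, type = "del", len = L, seq = "")
      g <- g + L
    } else if (op %in% c("M", "=", "X")) { g <- g + L; q <- q + L
    } else if (op == "N") { g <- g + L
    } else if (op == "S") { q <- q + L }
  }
  out
}

# N operations of one cigar as 0-based half-open intron intervals
cigar_introns <- function(cigar, pos0) {
  r <- cigar_runs(cigar)
  g <- pos0
  out <- list()
  for (i in seq_len(nrow(r))) {
    op <- r$op[i]; L <- r$len[i]
    if (op == "N") {
      out[[length(out) + 1L]] <- c(g, g + L)
      g <- g + L
    } else if (op %in% c("M", "D", "=", "X")) g <- g + L
  }
  out
}
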