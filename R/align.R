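# Contig-vs-representation alignment: semi-global affine-gap DP (compiled),
# selection of the single best alignment across all transcript
# representations, and projection of local alignments to genomic coordinates
# with N operations for traversed junctions.

#' Semi-global affine-gap alignment of a contig against a reference
#'
#' The contig is consumed end-to-end; unaligned reference prefix/suffix are
#' free. A gap of length L costs `gap_open + L * gap_extend`. Tie-breaking is
#' deterministic: the alignment ends at the leftmost maximal cell, and
#' traceback prefers match/mismatch, then deletion (D), then insertion (I).
#'
#' @param contig Contig sequence (query; must not exceed the reference).
#' @param reference Reference sequence.
#' @param scoring Named list `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @return List `score`, `start` (0-based reference offset), `cigar`
#'   (M/I/D runs over the reference given), or NULL when the contig is longer
#'   than the reference or either sequence is empty.
#' @export
semiglobal_align <- function(contig, reference,
                             scoring = realign_config()$scoring) {
  if (!nchar(contig) || !nchar(reference) || nchar(contig) > nchar(reference))
    return(NULL)
  r <- semiglobal_align_cpp(contig, reference,
                            as.integer(scoring$match),
                            as.integer(scoring$mismatch),
                            as.integer(scoring$gap_open),
                            as.integer(scoring$gap_extend))
  if (is.null(r$score) || is.na(r$score)) return(NULL)
  list(score = r$score, start = r$start, cigar = r$cigar)
}

#' Project a local alignment on a transcript representation to the genome
#'
#' Every junction crossed by the alignment becomes an N operation of exactly
#' the intron length; M and D runs are split at exon boundaries. Insertions
#' sit on the exon side preceding the junction.
#'
#' @param alignment List with `start` (0-based local offset) and `cigar`
#'   (M/I/D) as returned by [semiglobal_align()].
#' @param rep A `transcript_rep`.
#' @return List `pos` (0-based genomic), `cigar` (M/I/D/N).
#' @export
project_to_genome <- function(alignment, rep) {
  runs <- cigar_runs(alignment$cigar)
  ex <- rep$exons
  loc <- alignment$start            # current local offset (ref axis)
  gpos <- map_local_to_genome(rep, loc)
  if (is.na(gpos)) stop("alignment start outside representation")
  ops <- character(0); lens <- integer(0)
  emit <- function(op, L) { ops <<- c(ops, op); lens <<- c(lens, as.integer(L)) }

  for (i in seq_len(nrow(runs))) {
    op <- runs$op[i]; L <- runs$len[i]
    if (op == "I") { emit("I", L); next }
    # M or D consume local reference; split at exon boundaries
    while (L > 0L) {
      ei <- findInterval(loc, ex$local_start)
      room <- ex$local_start[ei] + ex$len[ei] - loc
      take <- min(L, room)
      emit(op, take)
      loc <- loc + take; L <- L - take
      if (L > 0L) {
        # crossed into the next exon: emit the intervening intron
        g_here <- ex$g_start[ei] + ex$len[ei]
        g_next <- ex$g_start[ei + 1L]
        emit("N", g_next - g_here)
      }
    }
  }
  list(pos = gpos, cigar = cigar_string(ops, lens))
}

#' Align a contig to every transcript representation and keep the single best
#'
#' The highest-scoring alignment across representations wins. The result is
#' dropped (NULL) when the best score falls below
#' `match * nchar(contig) - contig_score_slack`, or when two representations
#' tie at the best score with *different* genomic projections (ambiguous).
#' Ties with identical genomic projections are kept.
#'
#' @param contig Contig sequence.
#' @param reps List of `transcript_rep` objects.
#' @param cfg A [realign_config()].
#' @return List `score`, `pos`, `cigar` (genomic, may contain N), `rep_index`,
#'   or NULL.
#' @export
best_alignment <- function(contig, reps, cfg = realign_config()) {
  best <- NULL
  ties <- list()
  for (ri in seq_along(reps)) {
    al <- semiglobal_align(contig, reps[[ri]]$seq, cfg$scoring)
    if (is.null(al)) next
    if (is.null(best) || al$score > best$score) {
      best <- list(score = al$score, local = al, rep_index = ri)
      ties <- list()
    } else if (al$score == best$score) {
      ties[[length(ties) + 1L]] <- list(local = al, rep_index = ri)
    }
  }
  if (is.null(best)) return(NULL)
  if (best$score < cfg$scoring$match * nchar(contig) - cfg$contig_score_slack)
    return(NULL)
  proj <- project_to_genome(best$local, reps[[best$rep_index]])
  for (t in ties) {
    p2 <- project_to_genome(t$local, reps[[t$rep_index]])
    if (p2$pos != proj$pos || p2$cigar != proj$cigar) return(NULL)  # ambiguous
  }
  list(score = best$score, pos = proj$pos, cigar = proj$cigar,
       rep_index = best$rep_index)
}
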