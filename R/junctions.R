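# Splice model: the local junction set J, enumeration of valid junction
# combinations (putative transcripts), and spliced reference representations
# with bidirectional local<->genomic coordinate maps.
# Junctions are 0-based half-open intron intervals.

#' Read a tab-delimited junction file
#'
#' Three columns: chrom, intron start (0-based), intron end (exclusive).
#' @param path File path.
#' @param origin Label stored with each junction (`"annotated"` or
#'   `"observed"`).
#' @return A data.table `chrom`, `start`, `end`, `origin`.
#' @export
read_junctions <- function(path, origin = "annotated") {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end"),
                         colClasses = c("character", "integer", "integer"))
  data.table(chrom = x$chrom, start = x$start, end = x$end, origin = origin)
}

# junctions observed as N operations in a batch of reads
harvest_observed_junctions <- function(reads, min_intron_length = 20L) {
  hit <- grepl("N", reads$cigar, fixed = TRUE)
  if (!any(hit)) return(empty_junctions())
  rows <- which(hit)
  out <- rbindlist(lapply(rows, function(i) {
    ji <- cigar_introns(reads$cigar[i], reads$pos[i])
    if (!length(ji)) return(NULL)
    data.table(chrom = reads$rname[i],
               start = vapply(ji, `[`, integer(1), 1L),
               end = vapply(ji, `[`, integer(1), 2L))
  }))
  if (is.null(out) || !nrow(out)) return(empty_junctions())
  out <- unique(out)[end - start >= min_intron_length]
  out[, origin := "observed"]
  out[]
}

empty_junctions <- function() {
  data.table(chrom = character(), start = integer(), end = integer(),
             origin = character())
}

#' Collect the local junction set J for a window
#'
#' Seeds J with every junction having a start or end point within the window
#' padded by two read lengths on either side, then twice adds junctions with
#' an endpoint within one read length of any endpoint of a member of J. The
#' double expansion lets reads partially overlapping the window span two
#' junctions beyond it and still map.
#'
#' @param window One-row list/data.frame `chrom`, `start`, `end` (0-based).
#' @param observed,annotated Junction data.tables (`chrom`,`start`,`end`,
#'   `origin`); either may be empty.
#' @param read_length Read length in bp used for the padding and closure
#'   distances.
#' @param max_junctions Cap on |J|; nearest-to-window junctions win beyond it.
#' @return A junction data.table, sorted, unique by interval. Origin of a
#'   junction seen in both inputs is `"annotated"`.
#' @export
collect_junctions <- function(window, observed = NULL, annotated = NULL,
                              read_length = 100L, max_junctions = 20L) {
  all <- rbindlist(list(
    if (!is.null(annotated) && nrow(annotated)) annotated,
    if (!is.null(observed) && nrow(observed)) observed))
  if (is.null(all) || !nrow(all)) return(empty_junctions())
  all <- all[chrom == window$chrom]
  if (!nrow(all)) return(empty_junctions())
  # annotated wins when the same interval occurs with both origins
  all <- all[order(start, end, origin)]
  all <- unique(all, by = c("start", "end"))

  lo <- window$start - 2L * read_length
  hi <- window$end + 2L * read_length
  inJ <- (all$start >= lo & all$start < hi) | (all$end > lo & all$end <= hi)
  for (pass in 1:2) {
    if (!any(inJ)) break
    ep <- c(all$start[inJ], all$end[inJ])
    cand <- which(!inJ)
    if (!length(cand)) break
    near <- vapply(cand, function(i) {
      min(abs(ep - all$start[i]), abs(ep - all$end[i])) <= read_length
    }, logical(1))
    inJ[cand[near]] <- TRUE
  }
  J <- all[inJ]
  if (nrow(J) > max_junctions) {
    ctr <- (window$start + window$end) / 2
    d <- pmin(abs(J$start - ctr), abs(J$end - ctr))
    J <- J[order(d)][seq_len(max_junctions)]
    warning("junction set capped at ", max_junctions, " for window ",
            window$chrom, ":", window$start, "-", window$end)
  }
  J[order(start, end)]
}

#' Enumerate valid junction combinations (putative transcripts)
#'
#' Recursively forms every subset of J whose members are pairwise
#' non-overlapping (intron intervals do not intersect); each such subset is a
#' putative transcript. The empty combination (the unspliced reference) is
#' always included. If more than `max_combinations` valid combinations exist,
#' enumeration falls back to the empty set plus one singleton per junction,
#' with a warning.
#'
#' @param J A junction data.table (same chromosome), any order.
#' @param max_combinations Cap on the number of combinations.
#' @return A list of integer vectors indexing rows of `sorted(J)`; the
#'   attribute `"junctions"` carries the sorted junction table the indices
#'   refer to. Deterministic order: combinations discovered by
#'   include-first recursion over junctions sorted by (start, end).
#' @export
enumerate_transcripts <- function(J, max_combinations = 1024L) {
  if (is.null(J) || !nrow(J)) {
    out <- list(integer(0))
    attr(out, "junctions") <- empty_junctions()
    return(out)
  }
  J <- as.data.table(J)[order(start, end)]
  n <- nrow(J)
  res <- vector("list", max_combinations)
  cnt <- 0L
  overflow <- FALSE
  recurse <- function(i, chosen) {
    if (overflow) return()
    if (i > n) {
      if (cnt >= max_combinations) { overflow <<- TRUE; return() }
      cnt <<- cnt + 1L
      res[[cnt]] <<- chosen
      return()
    }
    # include J[i] if compatible with everything chosen so far
    ok <- !length(chosen) ||
      all(J$start[i] >= J$end[chosen] | J$end[i] <= J$start[chosen])
    if (ok) recurse(i + 1L, c(chosen, i))
    recurse(i + 1L, chosen)
  }
  recurse(1L, integer(0))
  if (overflow) {
    warning("combination cap exceeded; falling back to singleton transcripts")
    res <- c(lapply(seq_len(n), identity), list(integer(0)))
    cnt <- length(res)
  }
  out <- res[seq_len(cnt)]
  attr(out, "junctions") <- J
  out
}

#' Build a spliced reference representation for one junction combination
#'
#' Excises each intron of the combination from the local reference span and
#' records the exon block structure, giving a monotone bidirectional map
#' between local offsets (into the spliced sequence) and genomic positions.
#'
#' @param span_seq Local reference sequence (character scalar).
#' @param span_start Genomic position (0-based) of `span_seq`'s first base.
#' @param junctions Data.table of the combination's junctions (`start` <
#'   `end`, pairwise disjoint, each inside the span), possibly empty.
#' @param chrom Chromosome name carried along for bookkeeping.
#' @return An object of class `transcript_rep`: list with `seq`, `chrom`,
#'   `exons` (data.table `local_start`, `g_start`, `len`), `junctions`.
#' @export
build_representation <- function(span_seq, span_start, junctions = NULL,
                                 chrom = "") {
  span_len <- nchar(span_seq)
  if (is.null(junctions) || !nrow(junctions)) {
    exons <- data.table(local_start = 0L, g_start = as.integer(span_start),
                        len = as.integer(span_len))
    seq <- span_seq
    junctions <- empty_junctions()
  } else {
    junctions <- as.data.table(junctions)[order(start)]
    if (any(junctions$start < span_start) ||
        any(junctions$end > span_start + span_len))
      stop("junction outside local span: ",
           paste0(junctions$start, "-", junctions$end, collapse = ","))
    bounds <- c(span_start, as.vector(rbind(junctions$start, junctions$end)),
                span_start + span_len)
    g_start <- bounds[seq(1L, length(bounds) - 1L, by = 2L)]
    g_end   <- bounds[seq(2L, length(bounds), by = 2L)]
    len <- as.integer(g_end - g_start)
    keep <- len > 0L
    g_start <- as.integer(g_start[keep]); len <- len[keep]
    exons <- data.table(local_start = cumsum(c(0L, head(len, -1L))),
                        g_start = g_start, len = len)
    seq <- paste0(substring(span_seq,
                            g_start - span_start + 1L,
                            g_start - span_start + len), collapse = "")
  }
  structure(list(seq = seq, chrom = chrom, exons = exons,
                 junctions = junctions),
            class = "transcript_rep")
}

#' Map a local offset in a representation to its genomic position
#' @param rep A `transcript_rep`.
#' @param off Integer vector of 0-based local offsets (must be exonic,
#'   i.e. `0 <= off < nchar(rep$seq)`).
#' @return Integer vector of 0-based genomic positions.
#' @export
map_local_to_genome <- function(rep, off) {
  ex <- rep$exons
  i <- findInterval(off, ex$local_start)
  bad <- i < 1L | off >= ex$local_start[i] + ex$len[i] | off < 0L
  out <- ex$g_start[i] + (off - ex$local_start[i])
  out[bad] <- NA_integer_
  as.integer(out)
}

#' Map a genomic position to its local offset in a representation
#' @param rep A `transcript_rep`.
#' @param gpos Integer vector of 0-based genomic positions; intronic or
#'   out-of-span positions map to NA.
#' @return Integer vector of 0-based local offsets.
#' @export
map_genome_to_local <- function(rep, gpos) {
  ex <- rep$exons
  i <- findInterval(gpos, ex$g_start)
  bad <- i < 1L | gpos >= ex$g_start[pmax(i, 1L)] + ex$len[pmax(i, 1L)]
  i <- pmax(i, 1L)
  out <- ex$local_start[i] + (gpos - ex$g_start[i])
  out[bad] <- NA_integer_
  as.integer(out)
}
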