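#' Tile chromosomes or target regions into overlapping realignment windows
#'
#' Windows are `window_size` bp wide and consecutive windows on a chromosome
#' (or within a target interval) start `window_size - window_overlap` bp
#' apart, so neighbours overlap by `window_overlap` bp. The final window is
#' clipped at the chromosome (or target) end rather than shifted; a sequence
#' no longer than `window_size` yields a single window. Every targeted base
#' is covered by at least one and at most two windows.
#'
#' @param chrom_lengths Named integer vector of reference sequence lengths.
#' @param targets Optional data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open); overlapping targets are merged per chromosome.
#' @param cfg A [realign_config()].
#' @return A data.table with columns `chrom`, `start`, `end`
#'   (0-based half-open), ordered by chromosome (input order) then start.
#' @export
make_windows <- function(chrom_lengths, targets = NULL, cfg = realign_config()) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  step <- cfg$window_size - cfg$window_overlap

  tile <- function(chrom, lo, hi) {
    len <- hi - lo
    starts <- if (len <= cfg$window_size) lo else
      seq.int(lo, hi - 1L, by = step)
    data.table(chrom = chrom, start = as.integer(starts),
               end = as.integer(pmin(starts + cfg$window_size, hi)))
  }

  if (is.null(targets)) {
    out <- rbindlist(lapply(names(chrom_lengths), function(ch)
      tile(ch, 0L, as.integer(chrom_lengths[[ch]]))))
  } else {
    bad <- setdiff(unique(targets$chrom), names(chrom_lengths))
    if (length(bad))
      stop("target chromosome not in reference: ", paste(bad, collapse = ", "))
    tg <- as.data.table(targets)[, .(chrom, start = as.integer(start),
                                     end = as.integer(end))]
    if (any(tg$start < 0) ||
        any(tg$end > chrom_lengths[tg$chrom]))
      stop("target interval outside chromosome bounds")
    # merge overlapping/adjacent targets per chromosome
    pieces <- lapply(names(chrom_lengths), function(ch) {
      sub <- tg[chrom == ch][order(start)]
      if (!nrow(sub)) return(NULL)
      ir <- IRanges::reduce(IRanges::IRanges(sub$start + 1L, sub$end))
      rbindlist(lapply(seq_along(ir), function(i)
        tile(ch, IRanges::start(ir)[i] - 1L, IRanges::end(ir)[i])))
    })
    out <- rbindlist(pieces)
  }
  out[]
}

#' Extract the reads overlapping a window
#'
#' Returns the rows of `reads` whose reference span intersects the window,
#' plus unmapped reads whose mapped mate is placed inside the window (these
#' feed assembly). Reads overlapping two adjacent windows are returned by
#' both; deduplication happens at update time.
#'
#' @param reads An alignment data.table as returned by [read_alignments()].
#' @param window A one-row data.frame/list with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return The overlapping subset (a data.table, possibly empty).
#' @export
stream_window_reads <- function(reads, window) {
  reads[rname == window$chrom &
          ((!bitwAnd(flag, 4L) & pos < window$end & ref_end > window$start) |
             (bitwAnd(flag, 4L) > 0L & pos < window$end & pos >= window$start))]
}
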