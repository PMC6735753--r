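# Orchestration: window the genome, build the per-window contig pool, and
# update reads that unambiguously fit a contig better than the reference.

# assemble the per-window haplotype contig pool
window_contigs <- function(wreads, window, chrom_seq, observed_junc,
                           annotated_junc, known_indels, cfg, read_length) {
  chrom_len <- nchar(chrom_seq)
  J <- collect_junctions(window, observed_junc, annotated_junc,
                         read_length, cfg$max_junctions)
  lo <- max(0L, window$start - 2L * read_length)
  hi <- min(chrom_len, window$end + 2L * read_length)
  if (nrow(J)) {
    lo <- max(0L, min(lo, min(J$start) - read_length))
    hi <- min(chrom_len, max(hi, max(J$end) + read_length))
  }
  span_seq <- substr(chrom_seq, lo + 1L, hi)
  combos <- enumerate_transcripts(J, cfg$max_combinations)
  Jsorted <- attr(combos, "junctions")
  reps <- lapply(combos, function(ix)
    build_representation(span_seq, lo, Jsorted[ix], chrom = window$chrom))

  mapped <- wreads[bitwAnd(flag, 4L) == 0L & cigar != "*"]

  # source 1: indels observed in the original alignments
  indels <- harvest_observed_indels(mapped)
  if (nrow(indels)) indels <- indels[, src := "observed_indel"]

  # source 4: known indels supplied as VCF
  if (!is.null(known_indels) && nrow(known_indels)) {
    kn <- known_indels[chrom == window$chrom & pos >= lo & pos < hi]
    if (nrow(kn)) {
      kn <- kn[, src := "known_indel"]
      indels <- rbindlist(list(indels, kn), use.names = TRUE, fill = TRUE)
    }
  }

  # sources 2 + 3: soft-clip and assembly contigs, aligned to discover indels
  cand_seqs <- character(0)
  cand_src <- character(0)
  sc <- harvest_softclip_contigs(wreads, cfg)
  if (length(sc)) { cand_seqs <- c(cand_seqs, sc)
                    cand_src <- c(cand_src, rep("soft_clip", length(sc))) }
  if (cfg$use_assembly && nrow(wreads) && should_assemble(wreads, cfg)) {
    asm <- assemble_region(wreads, cfg)
    if (length(asm)) { cand_seqs <- c(cand_seqs, asm)
                       cand_src <- c(cand_src, rep("assembly", length(asm))) }
  }
  for (ci in seq_along(cand_seqs)) {
    ba <- best_alignment(cand_seqs[ci], reps, cfg)
    if (is.null(ba)) next
    # an indel is only trusted when anchored by at least a seed length of
    # aligned bases on both flanks of the contig alignment
    runs <- cigar_runs(ba$cigar)
    mcum <- cumsum(ifelse(runs$op == "M", runs$len, 0L))
    mtot <- mcum[length(mcum)]
    anchored <- vapply(which(runs$op %in% c("I", "D")), function(i)
      mcum[i] >= cfg$seed_length && mtot - mcum[i] >= cfg$seed_length,
      logical(1))
    if (!any(anchored)) next
    found <- cigar_indels(ba$cigar, ba$pos, cand_seqs[ci])
    found <- found[anchored]
    for (z in found) {
      indels <- rbindlist(list(indels, data.table(
        chrom = window$chrom, pos = as.integer(z$pos), type = z$type,
        len = as.integer(z$len), seq = z$seq, support = 1L,
        src = cand_src[ci])), use.names = TRUE, fill = TRUE)
    }
  }
  if (is.null(indels) || !nrow(indels)) return(list())

  indels <- indels[!grepl("[^ACGT]", seq) | type == "del"]
  indels <- indels[, .(support = sum(support), src = src[1L]),
                   by = .(chrom, pos, type, len, seq)]
  setorder(indels, -support, pos)

  # materialise each indel on each transcript representation
  contigs <- list()
  seen <- character(0)
  for (i in seq_len(nrow(indels))) {
    for (ri in seq_along(reps)) {
      ctg <- build_indel_contig(as.list(indels[i]), reps[[ri]],
                                source = indels$src[i],
                                read_length = read_length)
      if (is.null(ctg)) next
      key <- ctg$seq
      if (key %in% seen) next
      seen <- c(seen, key)
      contigs[[length(contigs) + 1L]] <- ctg
      if (length(contigs) >= cfg$max_contigs) break
    }
    if (length(contigs) >= cfg$max_contigs) break
  }
  contigs
}

# realign the reads of one window in place inside `all`; returns updated rows
realign_window <- function(all, wrows, contigs, chrom_seq, cfg) {
  if (!length(contigs)) return(integer(0))
  idx <- lapply(contigs, function(ctg) build_seed_index(ctg$seq, cfg$seed_length))
  changed <- integer(0)
  for (r in wrows) {
    read <- all[r]
    if (read$modified || bitwAnd(read$flag, 4L) > 0L || read$cigar == "*") next
    ref_mm <- reference_mismatches(read, chrom_seq)
    if (is.na(ref_mm) || ref_mm == 0L) next
    placements <- list()
    for (ci in seq_along(contigs)) {
      pl <- place_read(read$seq, contigs[[ci]]$seq, idx[[ci]])
      if (is.null(pl)) next
      for (off in pl$offsets) {
        rw <- rewrite_read(read, off, contigs[[ci]])
        if (is.null(rw)) next
        placements[[length(placements) + 1L]] <-
          list(contig = contigs[[ci]]$id, offset = off,
               mismatches = pl$mismatches, pos = rw$pos, cigar = rw$cigar,
               rw = rw)
      }
    }
    win <- decide_update(read, ref_mm, placements, cfg)
    if (is.null(win)) next
    if (win$pos == read$pos && win$cigar == read$cigar) next  # no-op
    data.table::set(all, r, "OP", win$rw$OP)
    data.table::set(all, r, "OC", win$rw$OC)
    data.table::set(all, r, "XC", win$rw$XC)
    data.table::set(all, r, "pos", win$pos)
    data.table::set(all, r, "cigar", win$cigar)
    data.table::set(all, r, "ref_end", win$pos + cigar_ref_width(win$cigar))
    data.table::set(all, r, "modified", TRUE)
    changed <- c(changed, r)
  }
  changed
}

# revert realigned reads whose final CIGAR has an I/D run abutting an N run
revert_junction_abutting <- function(all) {
  rows <- which(all$modified & grepl("N", all$cigar, fixed = TRUE) &
                  grepl("[ID]", all$cigar))
  reverted <- 0L
  for (r in rows) {
    runs <- cigar_runs(all$cigar[r])
    ops <- runs$op
    ind <- which(ops %in% c("I", "D"))
    abut <- any(vapply(ind, function(i)
      (i > 1L && ops[i - 1L] == "N") ||
        (i < length(ops) && ops[i + 1L] == "N"), logical(1)))
    if (!abut) next
    data.table::set(all, r, "pos", all$OP[r] - 1L)
    data.table::set(all, r, "cigar", all$OC[r])
    data.table::set(all, r, "ref_end",
                    all$OP[r] - 1L + cigar_ref_width(all$OC[r]))
    data.table::set(all, r, "OP", NA_integer_)
    data.table::set(all, r, "OC", NA_character_)
    data.table::set(all, r, "XC", NA_character_)
    data.table::set(all, r, "modified", FALSE)
    reverted <- reverted + 1L
  }
  reverted
}

#' Run splice-aware local realignment
#'
#' Tiles the reference (or the target regions) into overlapping windows,
#' builds the candidate contig pool of each window from observed indels,
#' soft-clip sequence, optional localized assembly and optional known indels,
#' aligns contigs onto enumerated transcript representations, and updates
#' every read that unambiguously fits a contig strictly better than the
#' reference. Samples are processed jointly against a shared contig pool.
#' The output read multiset is identical to the input; modified reads carry
#' `OP`/`OC` (original position/CIGAR) and `XC` (supporting contig) tags.
#' Windows holding more than `cfg$max_depth` reads are passed through
#' unchanged. A read overlapping two windows is updated by the first window
#' that strictly improves it and left untouched afterwards.
#'
#' @param reference FASTA path or named character vector of sequences.
#' @param inputs Character vector of SAM/BAM paths (or list of alignment
#'   data.tables), one per sample; tumor/normal pairs are realigned jointly.
#' @param outputs Optional character vector of output SAM/BAM paths, parallel
#'   to `inputs`.
#' @param cfg A [realign_config()].
#' @param targets Optional BED path or data.frame (`chrom`,`start`,`end`,
#'   0-based half-open) restricting realignment.
#' @param known_indels Optional VCF path or indel data.table fed to the
#'   known-indel contig source.
#' @param junctions Optional observed-junction file path or data.table.
#' @param annotated_junctions Optional annotated-junction file path or
#'   data.table.
#' @return List: `reads` (list of per-sample data.tables), `summary`
#'   (windows processed/skipped, reads modified/reverted).
#' @export
run_realignment <- function(reference, inputs, outputs = NULL,
                            cfg = realign_config(), targets = NULL,
                            known_indels = NULL, junctions = NULL,
                            annotated_junctions = NULL) {
  ref <- if (is.character(reference) && length(reference) == 1L &&
             file.exists(reference)) read_reference(reference) else reference
  if (is.character(inputs)) inputs <- lapply(inputs, read_alignments)
  samples <- lapply(inputs, as.data.table)

  hdr <- attr(inputs[[1L]], "header")
  if (is.null(hdr)) hdr <- setNames(nchar(ref), names(ref))
  bad <- setdiff(unique(unlist(lapply(samples, function(s)
    unique(s$rname[bitwAnd(s$flag, 4L) == 0L])))), names(ref))
  if (length(bad))
    stop("alignment reference sequence missing from FASTA: ",
         paste(bad, collapse = ", "))

  all <- rbindlist(lapply(seq_along(samples), function(i)
    samples[[i]][, c(.SD, list(sample = i))]), use.names = TRUE)
  all[, modified := FALSE]
  read_length <- max(nchar(all$seq), 1L)

  if (is.character(targets) && length(targets) == 1L && file.exists(targets)) {
    bed <- rtracklayer::import(targets, format = "BED")
    targets <- data.frame(chrom = as.character(GenomicRanges::seqnames(bed)),
                          start = GenomicRanges::start(bed) - 1L,
                          end = GenomicRanges::end(bed))
  }
  if (is.character(known_indels) && length(known_indels) == 1L &&
      file.exists(known_indels)) known_indels <- read_known_indels(known_indels)
  if (!is.null(known_indels)) known_indels <- as.data.table(known_indels)
  load_junc <- function(x, origin) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L && file.exists(x))
      return(read_junctions(x, origin))
    as.data.table(x)
  }
  ann_junc <- load_junc(annotated_junctions, "annotated")
  obs_junc_in <- load_junc(junctions, "observed")
  obs_junc <- rbindlist(list(
    obs_junc_in,
    harvest_observed_junctions(all, cfg$min_intron_length)),
    use.names = TRUE)

  windows <- make_windows(setNames(nchar(ref), names(ref)), targets, cfg)
  n_skipped <- 0L; n_processed <- 0L
  for (wi in seq_len(nrow(windows))) {
    window <- windows[wi]
    wreads <- stream_window_reads(all, window)
    if (!nrow(wreads)) next
    if (nrow(wreads) > cfg$max_depth) { n_skipped <- n_skipped + 1L; next }
    n_processed <- n_processed + 1L
    contigs <- suppressWarnings(window_contigs(
      wreads, window, ref[[window$chrom]], obs_junc, ann_junc,
      known_indels, cfg, read_length))
    if (!length(contigs)) next
    wrows <- which(all$rname == window$chrom & bitwAnd(all$flag, 4L) == 0L &
                     all$pos < window$end & all$ref_end > window$start)
    realign_window(all, wrows, contigs, ref[[window$chrom]], cfg)
  }

  n_reverted <- if (cfg$filter_junction_abutting)
    revert_junction_abutting(all) else 0L

  # keep mate pointers consistent for moved reads
  moved <- all[modified == TRUE, .(uid, pos)]
  if (nrow(moved)) {
    mate_uid <- paste0(all$qname, "/",
                       ifelse(bitwAnd(all$flag, 64L) > 0L, 2L,
                              ifelse(bitwAnd(all$flag, 128L) > 0L, 1L, 0L)))
    mpos <- moved$pos[match(mate_uid, moved$uid)]
    upd <- which(!is.na(mpos))
    if (length(upd)) data.table::set(all, upd, "pnext", mpos[upd])
  }

  out_samples <- lapply(seq_along(samples), function(i) {
    s <- all[sample == i]
    s[, sample := NULL]
    setorderv(s, c("rname", "pos"))
    setattr(s, "header", hdr)
    s[]
  })
  if (!is.null(outputs)) {
    stopifnot(length(outputs) == length(out_samples))
    for (i in seq_along(outputs))
      write_alignments(out_samples[[i]], outputs[i], hdr)
  }
  list(reads = out_samples,
       summary = list(windows = nrow(windows), processed = n_processed,
                      skipped_depth = n_skipped,
                      reads_modified = sum(all$modified),
                      reads_reverted = n_reverted))
}
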