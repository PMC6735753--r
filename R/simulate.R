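# Deterministic truth-annotated fixture simulator: reference with gene
# structures, junction annotation, and tumor/normal paired-end read sets in
# which indel-spanning reads are deliberately soft-clipped at the variant
# boundary (the naive-aligner behaviour the realigner is built to repair).
# Reads are drawn from spliced transcripts; a purely genomic (DNA) fixture is
# one single-exon gene covering the chromosome.

#' Specify a simulation
#'
#' @param seed RNG seed; all outputs are deterministic functions of the spec.
#' @param genome_length Chromosome length in bp.
#' @param genes List of gene layouts, each `list(exons = c(...), introns =
#'   c(...))` with `length(introns) == length(exons) - 1`; NULL gives one
#'   single-exon gene spanning the chromosome minus 100 bp margins (a DNA
#'   fixture).
#' @param read_length Read length in bp.
#' @param frag_mean,frag_sd Fragment length distribution (bp).
#' @param depth Haploid fold-coverage per sample.
#' @param error_rate Per-base substitution error probability.
#' @param base_quality Constant Phred base quality written for every base.
#' @param variants List of somatic variants, each `list(type = "ins"|"del",
#'   len, vaf, locus = "unique"|"tandem-repeat"|"homopolymer"|
#'   "junction-proximal")`. Variants are placed in exons, well separated.
#' @param unmapped_mate_fraction Fraction of variant-carrying reads emitted
#'   as unmapped (placed at the mate), exercising the assembly trigger.
#' @param mapq Mapping quality written on mapped records.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(seed = 1L, genome_length = 10000L, genes = NULL,
                     read_length = 100L, frag_mean = 250, frag_sd = 30,
                     depth = 60, error_rate = 0.001, base_quality = 35L,
                     variants = list(), unmapped_mate_fraction = 0,
                     mapq = 60L) {
  stopifnot(genome_length > 0, read_length > 0, depth > 0,
            error_rate >= 0, error_rate < 1)
  for (v in variants)
    stopifnot(v$type %in% c("ins", "del"), v$len >= 1,
              v$vaf > 0, v$vaf <= 1)
  spec <- as.list(environment())
  class(spec) <- "sim_spec"
  spec
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Simulate a reference genome with gene structures and spiked variant loci
#'
#' Builds the chromosome sequence, places the genes disjointly, chooses each
#' variant's locus inside an exon according to its locus class (embedding a
#' homopolymer or tandem repeat where requested), and returns the truth set.
#' Deterministic for a given spec.
#'
#' @param spec A [sim_spec()].
#' @return List: `ref` (named character vector, one chromosome `"chr_sim"`),
#'   `genes` (per gene: `span`, `junctions` data.table, `rep` transcript
#'   representation), `junction_file` (data.table), `truth` (data.table
#'   `chrom`, `pos` 0-based, `type`, `len`, `seq`, `vaf`, `locus`).
#' @export
simulate_reference <- function(spec) {
  set.seed(spec$seed)
  chrom <- "chr_sim"
  g <- random_dna(spec$genome_length)

  genes_in <- spec$genes
  if (is.null(genes_in))
    genes_in <- list(list(exons = spec$genome_length - 200L, introns = integer(0)))
  total <- vapply(genes_in, function(x) sum(x$exons) + sum(x$introns), numeric(1))
  gap <- 100L
  if (sum(total) + gap * (length(genes_in) + 1L) > spec$genome_length)
    stop("gene layout exceeds genome length")
  slack <- spec$genome_length - sum(total) - gap * (length(genes_in) + 1L)
  extras <- if (slack > 0) {
    w <- runif(length(genes_in) + 1L)
    floor(slack * w / sum(w))
  } else rep(0L, length(genes_in) + 1L)

  genes <- list()
  cursor <- gap + extras[1L]
  for (i in seq_along(genes_in)) {
    start <- as.integer(cursor)
    ex <- as.integer(genes_in[[i]]$exons)
    intr <- as.integer(genes_in[[i]]$introns)
    bounds <- start
    jst <- integer(0); jen <- integer(0)
    p <- start
    for (e in seq_along(ex)) {
      p <- p + ex[e]
      if (e <= length(intr)) { jst <- c(jst, p); p <- p + intr[e]; jen <- c(jen, p) }
    }
    junc <- data.table(chrom = chrom, start = jst, end = jen,
                       origin = "annotated")
    genes[[i]] <- list(span = c(start, p), junctions = junc)
    cursor <- p + gap + extras[i + 1L]
  }

  # variant placement inside exons, separated from gene edges and each other
  truth <- empty_truth()
  placed <- integer(0)   # genomic positions already used
  margin <- spec$read_length + 50L
  for (vi in seq_along(spec$variants)) {
    v <- spec$variants[[vi]]
    locus <- if (is.null(v$locus)) "unique" else v$locus
    ok <- FALSE
    for (try in 1:200) {
      gi <- sample.int(length(genes), 1L)
      gene <- genes[[gi]]
      ex_bounds <- exon_intervals(gene)
      if (locus == "junction-proximal" && nrow(gene$junctions)) {
        j <- gene$junctions[sample.int(nrow(gene$junctions), 1L)]
        side <- sample(c("before", "after"), 1L)
        pos <- if (side == "before") j$start - v$len - sample(5:25, 1L)
               else j$end + sample(5:25, 1L)
      } else {
        ei <- sample.int(nrow(ex_bounds), 1L)
        lo <- ex_bounds$lo[ei] + margin
        hi <- ex_bounds$hi[ei] - margin - v$len
        if (hi <= lo) next
        pos <- lo + sample.int(hi - lo, 1L)
      }
      in_exon <- any(ex_bounds$lo + margin %/% 2L <= pos &
                       pos + v$len <= ex_bounds$hi - margin %/% 2L)
      if (locus == "junction-proximal")
        in_exon <- any(ex_bounds$lo + 1L <= pos & pos + v$len <= ex_bounds$hi - 1L)
      if (!in_exon) next
      if (length(placed) && min(abs(placed - pos)) < 3L * spec$read_length) next
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place variant ", vi, " (layout too tight)")

    ins_seq <- ""
    if (locus == "homopolymer") {
      run <- strrep(substr(g, pos + 1L, pos + 1L), 12L)
      g <- paste0(substr(g, 1L, pos), run,
                  substr(g, pos + 13L, spec$genome_length))
      if (v$type == "ins") ins_seq <- strrep(substr(run, 1L, 1L), v$len)
    } else if (locus == "tandem-repeat") {
      unit <- random_dna(2L)
      g <- paste0(substr(g, 1L, pos), strrep(unit, 8L),
                  substr(g, pos + 17L, spec$genome_length))
      if (v$type == "ins") ins_seq <- strrep(unit, max(1L, v$len %/% 2L))
    } else if (v$type == "ins") {
      ins_seq <- random_dna(v$len)
      # keep the locus left-normalization-stable
      while (substr(ins_seq, v$len, v$len) == substr(g, pos, pos))
        ins_seq <- random_dna(v$len)
    }
    if (v$type == "del" && locus %in% c("unique", "junction-proximal")) {
      # ensure the base before the run differs from the deletion's last base
      if (substr(g, pos, pos) == substr(g, pos + v$len, pos + v$len)) {
        alt <- setdiff(c("A", "C", "G", "T"),
                       c(substr(g, pos + v$len, pos + v$len),
                         substr(g, pos + 1L, pos + 1L)))[1L]
        substr(g, pos, pos) <- alt
      }
    }
    if (v$type == "ins" && locus %in% c("tandem-repeat", "homopolymer"))
      v$len <- nchar(ins_seq)
    nz <- left_normalize_indel(g, pos, v$type, v$len, ins_seq)
    truth <- rbindlist(list(truth, data.table(
      chrom = chrom, pos = nz$pos, type = v$type, len = as.integer(v$len),
      seq = nz$seq, vaf = v$vaf, locus = locus)))
    placed <- c(placed, pos)
  }

  ref <- setNames(g, chrom)
  for (i in seq_along(genes)) {
    gene <- genes[[i]]
    span_seq <- substr(g, gene$span[1L] + 1L, gene$span[2L])
    genes[[i]]$rep <- build_representation(span_seq, gene$span[1L],
                                           gene$junctions, chrom)
  }
  junction_file <- rbindlist(c(list(empty_junctions()),
                               lapply(genes, `[[`, "junctions")))
  list(ref = ref, genes = genes, junction_file = junction_file, truth = truth)
}

empty_truth <- function() {
  data.table(chrom = character(), pos = integer(), type = character(),
             len = integer(), seq = character(), vaf = numeric(),
             locus = character())
}

exon_intervals <- function(gene) {
  j <- gene$junctions
  lo <- c(gene$span[1L], j$end)
  hi <- c(j$start, gene$span[2L])
  data.table(lo = lo, hi = hi)
}

#' Simulate tumor/normal paired-end reads with naive initial alignments
#'
#' Fragments are drawn from each gene's spliced transcript; tumor fragments
#' overlapping a variant carry it with probability VAF. Variant-spanning
#' reads are emitted soft-clipped at the variant boundary (the longer flank
#' is anchored), junction-spanning reads carry correct N CIGARs, and the
#' normal sample carries no somatic variant. Deterministic for a given spec.
#'
#' @param spec A [sim_spec()].
#' @param refobj Result of [simulate_reference()].
#' @return List `tumor`, `normal` (alignment data.tables with a `"header"`
#'   attribute) and `provenance` (data.table `sample`, `uid`, `hap`,
#'   `variant` index of the overlapped truth row or NA).
#' @export
simulate_reads <- function(spec, refobj) {
  set.seed(spec$seed + 7919L)
  chrom <- names(refobj$ref)
  hdr <- setNames(nchar(refobj$ref), chrom)
  rl <- spec$read_length
  qual <- strrep(intToUtf8(33L + spec$base_quality), rl)

  out <- list()
  prov <- list()
  for (sample in c("tumor", "normal")) {
    recs <- list()
    for (gi in seq_along(refobj$genes)) {
      gene <- refobj$genes[[gi]]
      rep <- gene$rep
      tlen <- nchar(rep$seq)
      # variants of this gene in transcript-local coordinates
      vt <- refobj$truth
      vloc <- list()
      if (sample == "tumor" && nrow(vt)) {
        for (ti in seq_len(nrow(vt))) {
          l <- map_genome_to_local(rep, vt$pos[ti])
          if (!is.na(l)) vloc[[length(vloc) + 1L]] <-
              list(ti = ti, lpos = l, type = vt$type[ti], len = vt$len[ti],
                   seq = vt$seq[ti], vaf = vt$vaf[ti])
        }
      }
      nfrag <- max(1L, round(spec$depth * tlen / (2 * rl)))
      for (fi in seq_len(nfrag)) {
        flen <- max(2L * rl, round(rnorm(1, spec$frag_mean, spec$frag_sd)))
        flen <- min(flen, tlen)
        s <- sample.int(tlen - flen + 1L, 1L) - 1L    # 0-based on ref transcript
        ov <- NULL
        for (vv in vloc) {
          zone_hi <- vv$lpos + if (vv$type == "del") vv$len else 0L
          if (s < zone_hi + 1L && s + flen > vv$lpos - 1L) { ov <- vv; break }
        }
        is_alt <- !is.null(ov) && runif(1) < ov$vaf
        qn <- paste0(sample, ".g", gi, ".f", fi)
        rec <- make_fragment_records(qn, s, flen, rep, ov, is_alt, spec, qual)
        if (is.null(rec)) next
        recs[[length(recs) + 1L]] <- rec$dt
        prov[[length(prov) + 1L]] <- data.table(
          sample = sample, qname = qn, hap = if (is_alt) "alt" else "ref",
          overlapped = !is.null(ov),
          variant = if (is_alt) ov$ti else NA_integer_,
          r1_covers = rec$covers[1L], r2_covers = rec$covers[2L])
      }
    }
    dt <- rbindlist(recs, use.names = TRUE)
    dt[, rname := chrom]
    dt[, rnext := "="]
    dt[, ref_end := pos + cigar_ref_width(cigar)]
    dt[, uid := paste0(qname, "/", ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L))]
    dt[, OP := NA_integer_]; dt[, OC := NA_character_]; dt[, XC := NA_character_]
    setorderv(dt, "pos")
    setattr(dt, "header", hdr)
    out[[sample]] <- dt
  }
  out$provenance <- rbindlist(prov)
  out
}

# build the two mate records of one fragment; returns NULL if degenerate
make_fragment_records <- function(qn, s, flen, rep, ov, is_alt, spec, qual) {
  rl <- spec$read_length
  if (!is_alt || is.null(ov)) {
    r1 <- naive_record(s, rl, rep, NULL, spec)
    r2 <- naive_record(s + flen - rl, rl, rep, NULL, spec)
    covers <- c(FALSE, FALSE)
  } else {
    # alt transcript coordinates: prefix identical below ov$lpos
    alt_shift <- if (ov$type == "ins") ov$len else -ov$len
    alt_len <- nchar(rep$seq) + alt_shift
    flen2 <- min(flen, alt_len - s)
    a1 <- s; a2 <- s + flen2 - rl
    if (a2 < 0L) return(NULL)
    r1 <- naive_record(a1, rl, rep, ov, spec)
    r2 <- naive_record(a2, rl, rep, ov, spec)
    zhi <- ov$lpos + if (ov$type == "ins") ov$len else 0L
    covers <- c(a1 < ov$lpos && a1 + rl > zhi, a2 < ov$lpos && a2 + rl > zhi)
  }
  if (is.null(r1) || is.null(r2)) return(NULL)
  seq1 <- inject_errors(r1$seq, spec$error_rate)
  seq2 <- inject_errors(r2$seq, spec$error_rate)
  f1 <- 99L; f2 <- 147L
  unmap2 <- FALSE; unmap1 <- FALSE
  if (is_alt && spec$unmapped_mate_fraction > 0) {
    if (covers[2L] && runif(1) < spec$unmapped_mate_fraction) unmap2 <- TRUE
    else if (covers[1L] && runif(1) < spec$unmapped_mate_fraction) unmap1 <- TRUE
  }
  if (unmap1) { f1 <- bitwOr(bitwAnd(f1, bitwNot(2L)), 4L); f2 <- bitwOr(f2, 8L) }
  if (unmap2) { f2 <- bitwOr(bitwAnd(f2, bitwNot(2L)), 4L); f1 <- bitwOr(f1, 8L) }
  dt <- data.table(
    qname = qn,
    flag = c(f1, f2),   # 99/147: paired+proper, mate strands, first/second
    pos = c(if (unmap1) r2$pos else r1$pos, if (unmap2) r1$pos else r2$pos),
    mapq = c(if (unmap1) 0L else spec$mapq, if (unmap2) 0L else spec$mapq),
    cigar = c(if (unmap1) "*" else r1$cigar, if (unmap2) "*" else r2$cigar),
    pnext = c(if (unmap2) r1$pos else r2$pos, if (unmap1) r2$pos else r1$pos),
    tlen = c(flen, -flen),
    seq = c(seq1, seq2),
    qual = c(qual, qual))
  list(dt = dt, covers = covers)
}

# one read of rl bases at alt/ref transcript offset `a`; returns pos/cigar/seq
naive_record <- function(a, rl, rep, ov, spec) {
  tlen_ref <- nchar(rep$seq)
  if (is.null(ov)) {
    if (a < 0L || a + rl > tlen_ref) return(NULL)
    pr <- project_to_genome(list(start = a, cigar = paste0(rl, "M")), rep)
    return(list(pos = pr$pos, cigar = pr$cigar,
                seq = substr(rep$seq, a + 1L, a + rl)))
  }
  v <- ov$lpos
  alt_seq <- if (ov$type == "ins")
    paste0(substr(rep$seq, 1L, v), ov$seq, substr(rep$seq, v + 1L, tlen_ref))
  else
    paste0(substr(rep$seq, 1L, v), substr(rep$seq, v + ov$len + 1L, tlen_ref))
  alt_len <- nchar(alt_seq)
  if (a < 0L || a + rl > alt_len) return(NULL)
  sq <- substr(alt_seq, a + 1L, a + rl)
  zone_hi <- v + if (ov$type == "ins") ov$len else 0L
  to_ref <- function(x) x - (if (ov$type == "ins") ov$len else -ov$len)
  if (a + rl <= v) {                 # entirely before the variant
    pr <- project_to_genome(list(start = a, cigar = paste0(rl, "M")), rep)
    return(list(pos = pr$pos, cigar = pr$cigar, seq = sq))
  }
  if (a >= zone_hi) {                # entirely after the variant
    pr <- project_to_genome(list(start = to_ref(a), cigar = paste0(rl, "M")), rep)
    return(list(pos = pr$pos, cigar = pr$cigar, seq = sq))
  }
  # spans the variant: soft-clip at the variant boundary, anchor longer flank
  left <- max(0L, v - a)
  right <- max(0L, a + rl - zone_hi)
  if (left >= right) {
    if (left == 0L) return(NULL)
    pr <- project_to_genome(list(start = a, cigar = paste0(left, "M")), rep)
    cg <- paste0(pr$cigar, rl - left, "S")
    list(pos = pr$pos, cigar = cg, seq = sq)
  } else {
    pr <- project_to_genome(list(start = to_ref(a + rl) - right,
                                 cigar = paste0(right, "M")), rep)
    cg <- paste0(rl - right, "S", pr$cigar)
    list(pos = pr$pos, cigar = cg, seq = sq)
  }
}

inject_errors <- function(s, rate) {
  if (rate <= 0) return(s)
  L <- nchar(s)
  hit <- which(runif(L) < rate)
  if (!length(hit)) return(s)
  v <- strsplit(s, "")[[1L]]
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste(v, collapse = "")
}

#' Simulate a complete fixture on disk
#'
#' Writes `ref.fa`, `junctions.tab`, `tumor.sam`, `normal.sam`, `truth.vcf`
#' and FASTQ files into a directory.
#'
#' @param spec A [sim_spec()].
#' @param dir Output directory (created if needed).
#' @param fastq Also write per-sample FASTQ files.
#' @return List of file paths plus the in-memory objects (`refobj`, `reads`).
#' @export
simulate_dataset <- function(spec, dir, fastq = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refobj <- simulate_reference(spec)
  reads <- simulate_reads(spec, refobj)
  paths <- list(ref = file.path(dir, "ref.fa"),
                junctions = file.path(dir, "junctions.tab"),
                tumor = file.path(dir, "tumor.sam"),
                normal = file.path(dir, "normal.sam"),
                truth = file.path(dir, "truth.vcf"))
  dna <- Biostrings::DNAStringSet(refobj$ref)
  Biostrings::writeXStringSet(dna, paths$ref)
  Rsamtools::indexFa(paths$ref)
  jf <- refobj$junction_file
  utils::write.table(jf[, .(chrom, start, end)], paths$junctions,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_alignments(reads$tumor, paths$tumor)
  write_alignments(reads$normal, paths$normal)
  write_truth_vcf(refobj, paths$truth)
  if (fastq) {
    for (sm in c("tumor", "normal")) {
      fq <- file.path(dir, paste0(sm, ".fq"))
      dtt <- reads[[sm]]
      writeLines(paste0("@", dtt$uid, "\n", dtt$seq, "\n+\n", dtt$qual), fq)
      paths[[paste0(sm, "_fastq")]] <- fq
    }
  }
  c(paths, list(refobj = refobj, reads = reads))
}

write_truth_vcf <- function(refobj, path) {
  g <- refobj$ref[[1L]]
  chrom <- names(refobj$ref)
  tr <- refobj$truth
  lines <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", chrom, ",length=", nchar(g), ">"),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(tr)) {
    body <- vapply(seq_len(nrow(tr)), function(i) {
      p <- tr$pos[i]
      anchor <- substr(g, p, p)
      if (tr$type[i] == "del") {
        refa <- paste0(anchor, substr(g, p + 1L, p + tr$len[i]))
        alta <- anchor
      } else {
        refa <- anchor
        alta <- paste0(anchor, tr$seq[i])
      }
      paste0(chrom, "\t", p, "\t.\t", refa, "\t", alta, "\t.\tPASS\tVAF=",
             tr$vaf[i])
    }, character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
}
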