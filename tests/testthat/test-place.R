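cfg <- realign_config()

test_that("the seed index enumerates every k-mer offset", {
  idx <- build_seed_index("ACGTACGTACGT", k = 10L)
  expect_equal(splicealign:::seed_lookup(idx, "ACGTACGTAC"), 0L)
  expect_equal(splicealign:::seed_lookup(idx, "CGTACGTACG"), 1L)
  expect_equal(splicealign:::seed_lookup(idx, "GTACGTACGT"), 2L)
  expect_length(splicealign:::seed_lookup(idx, "TTTTTTTTTT"), 0L)
  homo <- build_seed_index(strrep("A", 20), k = 10L)
  expect_equal(splicealign:::seed_lookup(homo, strrep("A", 10)), 0:10)
  expect_warning(build_seed_index("ACGT", k = 10L), "shorter")
})

test_that("read placement agrees with a brute-force Hamming scan", {
  set.seed(77)
  for (i in 1:300) {
    tlen <- sample(60:400, 1)
    target <- random_seq(tlen)
    L <- sample(20:min(60, tlen), 1)
    off <- sample(0:(tlen - L), 1)
    read <- substr(target, off + 1, off + L)
    # sprinkle up to 3 mismatches outside the first seed so a hit survives
    nmm <- sample(0:3, 1)
    if (nmm > 0) {
      v <- strsplit(read, "")[[1]]
      for (p in sample(11:L, nmm))
        v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
      read <- paste(v, collapse = "")
    }
    idx <- build_seed_index(target, k = 10L)
    got <- place_read(read, target, idx)
    want <- oracle_hamming_best(read, target)
    # the intact leading 10-mer guarantees the true offset is proposed
    expect_false(is.null(got), info = paste("case", i))
    expect_equal(got$mismatches, want$mismatches, info = paste("case", i))
    expect_true(all(got$offsets %in% want$offsets), info = paste("case", i))
  }
})

test_that("tandem-repeat placements tie and are reported as multiple offsets", {
  unit <- "ACGTTGCAGT"
  target <- paste0(strrep(unit, 6), "CCATGGAT")
  idx <- build_seed_index(target, k = 10L)
  read <- strrep(unit, 2)
  got <- place_read(read, target, idx)
  expect_gt(length(got$offsets), 1L)
  expect_equal(got$mismatches, 0L)
})

test_that("rewriting slices the contig's genomic CIGAR at the read offset", {
  ctg <- list(id = "c:100:del:20", seq = strrep("A", 200), chrom = "c",
              gpos = 1000L, gcigar = "100M20D100M")
  read <- list(pos = 1040L, cigar = "60M", seq = strrep("A", 100),
               flag = 0L)
  rw <- rewrite_read(read, 60L, ctg)
  expect_equal(rw$pos, 1060L)
  expect_equal(rw$cigar, "40M20D60M")
  expect_equal(rw$OP, 1041L)
  expect_equal(rw$OC, "60M")

  # slice entirely within the first M block: no D appears
  rw2 <- rewrite_read(list(pos = 1000L, cigar = "50M", seq = strrep("A", 50),
                           flag = 0L), 10L, ctg)
  expect_equal(rw2$cigar, "50M")
  expect_equal(rw2$pos, 1010L)

  # spliced contig: a read across the junction inherits the N
  ctg2 <- list(id = "c:x", seq = strrep("A", 300), chrom = "c",
               gpos = 500L, gcigar = "150M75N150M")
  rw3 <- rewrite_read(list(pos = 0L, cigar = "100M", seq = strrep("A", 100),
                           flag = 0L), 100L, ctg2)
  expect_equal(rw3$pos, 600L)
  expect_equal(rw3$cigar, "50M75N50M")
  # exon-interior slice has no N
  rw4 <- rewrite_read(list(pos = 0L, cigar = "100M", seq = strrep("A", 100),
                           flag = 0L), 10L, ctg2)
  expect_equal(rw4$cigar, "100M")

  # query-length conservation on insertions
  ctg3 <- list(id = "c:y", seq = strrep("A", 210), chrom = "c",
               gpos = 0L, gcigar = "100M10I100M")
  rw5 <- rewrite_read(list(pos = 0L, cigar = "100M", seq = strrep("A", 100),
                           flag = 0L), 95L, ctg3)
  runs <- cigar_runs(rw5$cigar)
  expect_equal(sum(runs$len[runs$op %in% c("M", "I")]), 100L)
  expect_equal(rw5$cigar, "5M10I85M")
})

test_that("updates require strict improvement, bounded shift and unambiguity", {
  read <- list(pos = 1000L, cigar = "100M", seq = strrep("A", 100), flag = 0L)
  pl <- function(pos, mm, cigar = "100M")
    list(contig = "c", offset = 0L, mismatches = mm, pos = pos, cigar = cigar,
         rw = list(pos = pos, cigar = cigar, OP = 1001L, OC = "100M", XC = "c"))
  # strict improvement required
  expect_null(decide_update(read, 0L, list(pl(1000L, 0L)), cfg))
  expect_null(decide_update(read, 3L, list(pl(1000L, 3L)), cfg))
  expect_false(is.null(decide_update(read, 3L, list(pl(1000L, 2L)), cfg)))
  # mismatch cap: ceiling(0.05 * 100) = 5
  expect_null(decide_update(read, 20L, list(pl(1000L, 6L)), cfg))
  # move distance cap
  expect_null(decide_update(read, 5L, list(pl(2200L, 0L)), cfg))
  # ambiguous tie with different projections
  expect_null(decide_update(read, 5L,
                            list(pl(1000L, 1L), pl(1010L, 1L)), cfg))
  # tie with identical projection is fine
  expect_false(is.null(decide_update(read, 5L,
                                     list(pl(1000L, 1L), pl(1000L, 1L)), cfg)))
})

test_that("the reference baseline counts clipped and inserted bases as cost", {
  chrom_seq <- strrep("ACGT", 100)
  read <- list(pos = 0L, cigar = "8M", seq = "ACGTACGT", flag = 0L)
  expect_equal(splicealign:::reference_mismatches(read, chrom_seq), 0L)
  read2 <- list(pos = 0L, cigar = "4M4S", seq = "ACGTACGT", flag = 0L)
  expect_equal(splicealign:::reference_mismatches(read2, chrom_seq), 4L)
  read3 <- list(pos = 0L, cigar = "4M2I2M", seq = "ACGTTTAC", flag = 0L)
  expect_equal(splicealign:::reference_mismatches(read3, chrom_seq), 2L)
  read4 <- list(pos = 0L, cigar = "8M", seq = "ACGAACGA", flag = 0L)
  expect_equal(splicealign:::reference_mismatches(read4, chrom_seq), 2L)
})
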