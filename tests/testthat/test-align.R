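cfg <- realign_config()

test_that("exact substring contigs align all-M with full match score", {
  ref <- "CGTTAGGCATTACGGATCCGATCGATTACGGATGCCAT"
  ctg <- substr(ref, 8, 27)
  al <- semiglobal_align(ctg, ref)
  expect_equal(al$score, 8L * nchar(ctg))
  expect_equal(al$cigar, "20M")
  expect_equal(al$start, 7L)
})

test_that("an excised block is recovered as a deletion with affine gap cost", {
  set.seed(5)
  ref <- random_seq(60)
  ctg <- paste0(substr(ref, 1, 25), substr(ref, 29, 60))  # 3 bp excised
  al <- semiglobal_align(ctg, ref)
  expect_equal(al$score, 8L * nchar(ctg) - 48L - 3L * 1L)
  expect_match(al$cigar, "^[0-9]+M3D[0-9]+M$")
  chk <- score_of_alignment(ctg, ref, al$start, al$cigar)
  expect_equal(chk$score, al$score)
  expect_equal(chk$query_used, nchar(ctg))
})

test_that("DP score equals the brute-force affine oracle on random pairs", {
  set.seed(42)
  n_cases <- 400
  for (i in seq_len(n_cases)) {
    m <- sample(5:40, 1)
    n <- m + sample.int(41L - m, 1) - 1L
    q <- random_seq(m); r <- random_seq(n)
    # mix in related pairs so gaps actually occur
    if (i %% 3 == 0 && n > m + 4) {
      cut <- sample(2:(m - 2), 1)
      q <- paste0(substr(r, 1, cut), substr(r, cut + 3, m + 2))
    }
    al <- semiglobal_align(q, r)
    expect_equal(al$score, oracle_semiglobal_score(q, r),
                 info = paste("case", i, q, r))
    chk <- score_of_alignment(q, r, al$start, al$cigar)
    expect_equal(chk$score, al$score, info = paste("cigar", i))
    expect_equal(chk$query_used, nchar(q))
  }
})

test_that("extending matched sequence or free reference never lowers the score", {
  set.seed(7)
  for (i in 1:25) {
    q <- random_seq(sample(8:20, 1))
    r <- paste0(random_seq(5), q)          # contig aligns to the reference end
    s1 <- semiglobal_align(q, r)$score
    b <- sample(c("A", "C", "G", "T"), 1)
    # appending a matching base to both extends the optimal alignment
    s2 <- semiglobal_align(paste0(q, b), paste0(r, b))$score
    expect_gte(s2, s1)
    # growing the free reference overhang can never hurt
    s3 <- semiglobal_align(q, paste0(r, random_seq(6)))$score
    expect_gte(s3, s1)
    s4 <- semiglobal_align(q, paste0(random_seq(6), r))$score
    expect_gte(s4, s1)
  }
})

test_that("contigs longer than the reference are rejected", {
  expect_null(semiglobal_align(strrep("A", 30), strrep("A", 10)))
})

test_that("projection inserts N operations of exactly the intron length", {
  set.seed(13)
  span <- random_seq(400)
  J <- data.table::data.table(chrom = "c", start = 130L, end = 180L,
                              origin = "annotated")
  rep1 <- build_representation(span, 100L, J, "c")
  expect_equal(nchar(rep1$seq), 350L)
  pr <- project_to_genome(list(start = 0L, cigar = "100M"), rep1)
  expect_equal(pr$pos, 100L)
  expect_equal(pr$cigar, "30M50N70M")

  # no junction crossed: cigar passes through
  pr2 <- project_to_genome(list(start = 80L, cigar = "40M5D60M"), rep1)
  expect_equal(pr2$cigar, "40M5D60M")
  expect_equal(pr2$pos, 230L)

  # two introns shift offsets cumulatively
  J2 <- data.table::data.table(chrom = "c", start = c(130L, 250L),
                               end = c(180L, 260L), origin = "annotated")
  rep2 <- build_representation(span, 100L, J2, "c")
  pr3 <- project_to_genome(list(start = 0L, cigar = "200M"), rep2)
  expect_equal(pr3$cigar, "30M50N70M10N100M")
  # genomic query width must equal local query width
  runs <- cigar_runs(pr3$cigar)
  expect_equal(sum(runs$len[runs$op %in% c("M", "I")]), 200L)
})

test_that("a spliced representation outscores the unspliced one for a junction contig", {
  set.seed(21)
  span <- random_seq(500)
  J <- data.table::data.table(chrom = "c", start = 200L, end = 320L,
                              origin = "annotated")
  spliced <- build_representation(span, 0L, J, "c")
  flat <- build_representation(span, 0L, NULL, "c")
  ctg <- substr(spliced$seq, 150, 260)   # crosses the junction
  s_spl <- semiglobal_align(ctg, spliced$seq)$score
  s_flat <- semiglobal_align(ctg, flat$seq)$score
  expect_gt(s_spl, s_flat)
  ba <- best_alignment(ctg, list(flat, spliced), cfg)
  expect_match(ba$cigar, "120N")
})

test_that("equal-score alignments with the same genomic projection are kept", {
  set.seed(22)
  span <- random_seq(600)
  far <- data.table::data.table(chrom = "c", start = 480L, end = 560L,
                                origin = "annotated")
  flat <- build_representation(span, 0L, NULL, "c")
  withfar <- build_representation(span, 0L, far, "c")
  ctg <- substr(span, 50, 200)   # nowhere near the far junction
  ba <- best_alignment(ctg, list(flat, withfar), cfg)
  expect_false(is.null(ba))
  expect_equal(ba$pos, 49L)
  expect_equal(ba$cigar, paste0(nchar(ctg), "M"))
})

test_that("projection round-trips through the coordinate map", {
  set.seed(31)
  span <- random_seq(400)
  J <- data.table::data.table(chrom = "c", start = c(1120L, 1240L),
                              end = c(1170L, 1300L), origin = "annotated")
  rep1 <- build_representation(span, 1000L, J, "c")
  for (st in c(0L, 35L, 90L)) {
    pr <- project_to_genome(list(start = st, cigar = "150M"), rep1)
    # walk the genomic cigar back through the map: M bases must map to
    # consecutive local offsets starting at st
    runs <- cigar_runs(pr$cigar)
    g <- pr$pos; locs <- integer(0)
    for (k in seq_len(nrow(runs))) {
      if (runs$op[k] == "M")
        locs <- c(locs, map_genome_to_local(rep1, g:(g + runs$len[k] - 1L)))
      if (runs$op[k] %in% c("M", "D", "N")) g <- g + runs$len[k]
    }
    expect_equal(locs, st:(st + 149L))
  }
})
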