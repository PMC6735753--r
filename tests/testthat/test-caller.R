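cfg <- realign_config()

test_that("the somatic Fisher test matches the factorial tail oracle", {
  # identical proportions
  expect_equal(fisher_somatic_p(10, 0, 10, 0), 1)
  # tumor-enriched table against the oracle
  expect_equal(fisher_somatic_p(20, 0, 10, 10),
               oracle_fisher_tail(20, 0, 10, 10))
  # one-sidedness: depleted tumor alt is not significant
  expect_gt(fisher_somatic_p(10, 10, 20, 0), 0.99)
  # random sweep against the oracle and stats::fisher.test
  set.seed(12)
  for (i in 1:200) {
    x <- sample(0:25, 4, replace = TRUE)
    p <- fisher_somatic_p(x[1], x[2], x[3], x[4])
    expect_equal(p, oracle_fisher_tail(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-12, info = paste(x, collapse = ","))
    if (sum(x[1:2]) > 0 && sum(x[3:4]) > 0 && x[2] + x[4] > 0 &&
        x[1] + x[3] > 0) {
      ft <- stats::fisher.test(matrix(c(x[1], x[2], x[3], x[4]), nrow = 2,
                                      byrow = TRUE),
                               alternative = "greater")$p.value
      expect_equal(p, ft, tolerance = 1e-9)
    }
  }
})

test_that("increasing tumor alt support never increases the p-value", {
  p <- vapply(0:15, function(a) fisher_somatic_p(30, 0, 30, a), numeric(1))
  expect_true(all(diff(p) <= 1e-12))
})

test_that("orientation-bias filter flags one-stranded alt support", {
  expect_true(orientation_bias_filter(list(alt_fwd = 15, alt_rev = 15,
                                           ref_fwd = 50, ref_rev = 50)))
  expect_false(orientation_bias_filter(list(alt_fwd = 20, alt_rev = 0,
                                            ref_fwd = 50, ref_rev = 50)))
  # binomial tail oracle for the no-ref case
  cnt <- list(alt_fwd = 12, alt_rev = 0, ref_fwd = 0, ref_rev = 0)
  expect_equal(orientation_bias_filter(cnt),
               stats::binom.test(12, 12, 0.5)$p.value >= 0.01)
  # insufficient evidence passes
  expect_true(orientation_bias_filter(list(alt_fwd = 3, alt_rev = 0,
                                           ref_fwd = 50, ref_rev = 50)))
})

test_that("positional complexity uses a strict threshold on start span", {
  expect_true(positional_complexity_filter(c(100L, 101L, 130L)))
  expect_false(positional_complexity_filter(c(157L, 157L, 157L)))
  expect_true(positional_complexity_filter(c(100L, 110L)))   # span == 10 passes
  expect_false(positional_complexity_filter(c(100L, 109L)))
  expect_true(positional_complexity_filter(c(42L)))          # single read
})

test_that("MQ0 filter fails only on a strict majority", {
  expect_false(mq0_filter(6L, 10L))
  expect_true(mq0_filter(5L, 10L))
  expect_true(mq0_filter(0L, 0L))
})

test_that("repeat detection and penalties are monotone in run length", {
  set.seed(31)
  flank <- random_seq(60)
  flank2 <- random_seq(60)
  mk <- function(run) paste0(flank, run, flank2)
  # non-repetitive context: no penalty
  plain <- gsub("(.)\\1", "\\1A", mk("G"))   # crude de-repeat of the junction
  ctx0 <- repeat_context(mk("GTCAGTGCCA"), 60L)
  del1 <- list(pos = 60L, type = "del", len = 1L)
  if (is.null(ctx0)) expect_equal(repeat_penalty(del1, mk("GTCAGTGCCA"), cfg), 0)

  # homopolymer: penalty grows with the run
  pen <- vapply(c(6L, 9L, 12L, 15L), function(n)
    repeat_penalty(del1, mk(strrep("A", n)), cfg), numeric(1))
  expect_gt(pen[3], 0)
  expect_true(all(diff(pen) >= 0))
  # 12xA homopolymer 1 bp deletion: documented formula 2 * (12 - 5)
  expect_equal(repeat_penalty(del1, mk(strrep("A", 12)), cfg), 14)

  # dinucleotide repeat: multiple-of-unit indels are penalised
  seq_at <- mk(strrep("AT", 8))
  rc <- repeat_context(seq_at, 60L)
  expect_equal(rc$unit_len, 2L)
  expect_equal(rc$copies, 8L)
  del2 <- list(pos = 60L, type = "del", len = 2L)
  expect_equal(repeat_penalty(del2, seq_at, cfg), 2 * (8 - 3))
  # indel length not a multiple of the unit: no penalty
  del3 <- list(pos = 60L, type = "del", len = 3L)
  expect_equal(repeat_penalty(del3, seq_at, cfg), 0)
  # disabled by configuration
  off <- realign_config(str_penalty = FALSE)
  expect_equal(repeat_penalty(del2, seq_at, off), 0)
})

test_that("repeat loci only count reads spanning the full repeat run", {
  set.seed(41)
  left <- random_seq(200)
  right <- random_seq(200)
  g <- paste0(left, strrep("AT", 8), right)   # repeat at [200, 216)
  indel <- list(chrom = "chr1", pos = 200L, type = "del", len = 2L, seq = "")
  reads <- make_reads(
    list(pos = 150L, seq = substr(g, 151, 250)),   # spans the whole repeat
    list(pos = 190L, seq = substr(g, 191, 290)),   # spans
    list(pos = 205L, seq = substr(g, 206, 305)),   # starts inside: no
    list(pos = 120L, seq = substr(g, 121, 212)))   # ends inside: no
  cnt <- gather_counts(reads, indel, g)
  expect_equal(cnt$spanning_total, 2L)
  expect_equal(cnt$ref_count, 2L)
  expect_equal(cnt$alt_count, 0L)
})

test_that("allele counting separates tagged alt reads from spanning ref reads", {
  set.seed(43)
  g <- random_seq(600)
  # the candidate handed to the counter is left-normalized, as in call_variants
  nzpos <- left_normalize_indel(g, 300L, "del", 20L)$pos
  indel <- list(chrom = "chr1", pos = nzpos, type = "del", len = 20L, seq = "")
  gdel <- paste0(substr(g, 1, 300), substr(g, 321, 600))
  alt_rows <- lapply(1:10, function(i) {
    st <- 230L + 6L * i
    list(pos = st, seq = substr(gdel, st + 1, st + 100),
         cigar = paste0(300L - st, "M20D", 100L - (300L - st), "M"),
         flag = if (i %% 2 == 0) 16L else 0L)
  })
  ref_rows <- lapply(1:10, function(i) {
    st <- 230L + 6L * i
    list(pos = st, seq = substr(g, st + 1, st + 100),
         flag = if (i %% 2 == 0) 16L else 0L)
  })
  mq0_row <- list(list(pos = 260L, seq = substr(g, 261, 360), mapq = 0L))
  reads <- do.call(make_reads, c(alt_rows, ref_rows, mq0_row))
  cnt <- gather_counts(reads, indel, g)
  expect_equal(cnt$alt_count, 10L)
  expect_equal(cnt$ref_count, 11L)
  expect_equal(cnt$alt_fwd, 5L)
  expect_equal(cnt$alt_rev, 5L)
  expect_equal(cnt$spanning_mq0, 1L)
  expect_equal(cnt$spanning_total, 21L)
  expect_equal(sort(cnt$alt_starts),
               sort(vapply(alt_rows, function(r) r$pos, integer(1))))
})

test_that("indel left-normalization shifts through repeats", {
  g <- paste0("GGGG", strrep("AT", 5), "CCCC")  # ATATATATAT at [4, 14)
  nz <- left_normalize_indel(g, 10L, "del", 2L)
  expect_equal(nz$pos, 4L)
  nz2 <- left_normalize_indel(g, 10L, "ins", 2L, "AT")
  expect_equal(nz2$pos, 4L)
  expect_equal(nz2$seq, "AT")
  # non-repetitive locus does not move
  g2 <- "GACTGACA"
  nz3 <- left_normalize_indel(g2, 2L, "del", 1L)   # deletes the C
  expect_equal(nz3$pos, 2L)
})
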