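uid_multiset <- function(dt) sort(dt$uid)

test_that("variant-free data pass through untouched and reads are conserved", {
  spec <- sim_spec(seed = 21)
  refobj <- simulate_reference(spec)
  reads <- simulate_reads(spec, refobj)
  res <- run_realignment(refobj$ref, list(reads$tumor, reads$normal))
  expect_equal(res$summary$reads_modified, 0L)
  out <- res$reads[[1]]
  expect_equal(uid_multiset(out), uid_multiset(reads$tumor))
  expect_equal(sort(paste0(out$pos, out$cigar)),
               sort(paste0(reads$tumor$pos, reads$tumor$cigar)))
})

test_that("a soft-clipped 20 bp deletion is recovered in >= 90% of spanning reads", {
  spec <- sim_spec(seed = 22, variants = list(
    list(type = "del", len = 20L, vaf = 0.5, locus = "unique")))
  refobj <- simulate_reference(spec)
  reads <- simulate_reads(spec, refobj)
  res <- run_realignment(refobj$ref, list(reads$tumor, reads$normal))
  tm <- res$reads[[1]]
  pr <- reads$provenance[sample == "tumor" & hap == "alt"]
  vuids <- c(paste0(pr[r1_covers == TRUE]$qname, "/1"),
             paste0(pr[r2_covers == TRUE]$qname, "/2"))
  sub <- tm[uid %in% vuids & cigar != "*"]
  hasD <- grepl("20D", sub$cigar)
  expect_gte(mean(hasD), 0.9)
  # the deletion sits at the truth locus
  locus <- refobj$truth$pos
  one <- sub[hasD][1]
  z <- splicealign:::cigar_indels(one$cigar, one$pos)
  expect_equal(z[[which(vapply(z, `[[`, character(1), "type") == "del")]]$pos,
               locus)
  # read conservation under modification
  expect_equal(uid_multiset(tm), uid_multiset(reads$tumor))
  # modified reads carry provenance tags
  mod <- tm[!is.na(XC)]
  expect_gt(nrow(mod), 0L)
  expect_true(all(!is.na(mod$OC)))
  expect_true(all(!is.na(mod$OP)))
})

test_that("realignment is idempotent", {
  spec <- sim_spec(seed = 23, variants = list(
    list(type = "ins", len = 12L, vaf = 0.5, locus = "unique")))
  refobj <- simulate_reference(spec)
  reads <- simulate_reads(spec, refobj)
  first <- run_realignment(refobj$ref, list(reads$tumor, reads$normal))
  second <- run_realignment(refobj$ref, first$reads)
  expect_equal(second$summary$reads_modified, 0L)
  for (i in 1:2) {
    a <- first$reads[[i]][order(uid)]
    b <- second$reads[[i]][order(uid)]
    expect_equal(b$pos, a$pos)
    expect_equal(b$cigar, a$cigar)
  }
})

test_that("windows over the depth cap are skipped untouched", {
  spec <- sim_spec(seed = 24, variants = list(
    list(type = "del", len = 20L, vaf = 0.5, locus = "unique")))
  refobj <- simulate_reference(spec)
  reads <- simulate_reads(spec, refobj)
  cfg <- realign_config(max_depth = 10L)   # every window exceeds this
  res <- run_realignment(refobj$ref, list(reads$tumor, reads$normal),
                         cfg = cfg)
  expect_equal(res$summary$reads_modified, 0L)
  expect_gt(res$summary$skipped_depth, 0L)
})

test_that("realignment round-trips through SAM files on disk", {
  dir <- tempfile("rt")
  spec <- sim_spec(seed = 25, variants = list(
    list(type = "del", len = 10L, vaf = 0.5, locus = "unique")))
  out <- simulate_dataset(spec, dir)
  t_out <- file.path(dir, "tumor.realigned.sam")
  n_out <- file.path(dir, "normal.realigned.sam")
  res <- run_realignment(out$ref, c(out$tumor, out$normal),
                         outputs = c(t_out, n_out))
  expect_true(file.exists(t_out))
  back <- read_alignments(t_out)
  expect_setequal(back$uid, out$reads$tumor$uid)
  # output is coordinate-sorted
  expect_true(all(diff(back$pos) >= 0L))
  # tags survive the round trip
  expect_gt(nrow(back[!is.na(XC)]), 0L)
  unlink(dir, recursive = TRUE)
})

test_that("known indels from a VCF seed contigs without read evidence triggers", {
  spec <- sim_spec(seed = 26, variants = list(
    list(type = "del", len = 25L, vaf = 0.5, locus = "unique")))
  refobj <- simulate_reference(spec)
  reads <- simulate_reads(spec, refobj)
  kn <- data.table::data.table(chrom = "chr_sim", pos = refobj$truth$pos,
                               type = "del", len = 25L, seq = "",
                               support = 1L)
  # disable the discovery paths: no soft-clip contigs, no assembly
  cfg <- realign_config(softclip_min_bases = 1000L, use_assembly = FALSE)
  res <- run_realignment(refobj$ref, list(reads$tumor, reads$normal),
                         cfg = cfg, known_indels = kn)
  tm <- res$reads[[1]]
  expect_gt(sum(grepl("25D", tm$cigar)), 0L)
})

test_that("indels abutting junctions are reverted when the filter is enabled", {
  all <- make_reads(list(pos = 100L, seq = strrep("A", 100),
                         cigar = "40M200N10D60M"))
  all[, modified := TRUE]
  all[, OP := 51L]; all[, OC := "40M60S"]; all[, XC := "x"]
  n <- splicealign:::revert_junction_abutting(all)
  expect_equal(n, 1L)
  expect_equal(all$cigar[1], "40M60S")
  expect_equal(all$pos[1], 50L)
  expect_true(is.na(all$XC[1]))
  # non-abutting indel is left alone
  all2 <- make_reads(list(pos = 100L, seq = strrep("A", 100),
                          cigar = "20M200N20M10D60M"))
  all2[, modified := TRUE]
  all2[, OP := 101L]; all2[, OC := "100M"]; all2[, XC := "x"]
  expect_equal(splicealign:::revert_junction_abutting(all2), 0L)
})
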