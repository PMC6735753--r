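# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately plain re-derivation, separate from the
# package's implementation path.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# --- brute-force semi-global affine DP (plain R, score only) ----------------
# Same conventions as the package states: query consumed end-to-end, free
# reference overhangs, gap of length L costs open + L*ext.
oracle_semiglobal_score <- function(query, ref, match = 8, mismatch = 32,
                                    open = 48, ext = 1) {
  m <- nchar(query); n <- nchar(ref)
  qv <- strsplit(query, "")[[1]]; rv <- strsplit(ref, "")[[1]]
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1); D <- M; I <- M
  M[1, ] <- 0
  for (i in 1:m) {
    for (j in 0:n) {
      if (j > 0) {
        s <- if (qv[i] == rv[j]) match else -mismatch
        M[i + 1, j + 1] <- max(M[i, j], D[i, j], I[i, j]) + s
        D[i + 1, j + 1] <- max(max(M[i + 1, j], I[i + 1, j]) - open - ext,
                               D[i + 1, j] - ext)
      }
      I[i + 1, j + 1] <- max(max(M[i, j + 1], D[i, j + 1]) - open - ext,
                             I[i, j + 1] - ext)
    }
  }
  max(M[m + 1, ], D[m + 1, ], I[m + 1, ])
}

# score implied by a CIGAR alignment at a given reference start; used to
# verify that a reported (start, cigar) is consistent with its score
score_of_alignment <- function(query, ref, start, cigar, match = 8,
                               mismatch = 32, open = 48, ext = 1) {
  runs <- cigar_runs(cigar)
  q <- 0L; r <- start; sc <- 0
  for (k in seq_len(nrow(runs))) {
    op <- runs$op[k]; L <- runs$len[k]
    if (op == "M") {
      a <- substr(query, q + 1L, q + L); b <- substr(ref, r + 1L, r + L)
      eq <- sum(utf8ToInt(a) == utf8ToInt(b))
      sc <- sc + eq * match - (L - eq) * mismatch
      q <- q + L; r <- r + L
    } else if (op == "I") { sc <- sc - open - L * ext; q <- q + L
    } else if (op == "D") { sc <- sc - open - L * ext; r <- r + L }
  }
  list(score = sc, query_used = q, ref_end = r)
}

# --- powerset filter oracle for transcript enumeration ----------------------
oracle_transcripts <- function(J) {
  J <- J[order(J$start, J$end), ]
  n <- nrow(J)
  if (n == 0) return(list(integer(0)))
  combos <- list()
  for (mask in 0:(2^n - 1)) {
    ix <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    ok <- TRUE
    if (length(ix) > 1) {
      for (a in seq_along(ix)) for (b in seq_along(ix)) {
        if (a >= b) next
        i <- ix[a]; j <- ix[b]
        if (J$start[i] < J$end[j] && J$start[j] < J$end[i]) ok <- FALSE
      }
    }
    if (ok) combos[[length(combos) + 1]] <- ix
  }
  combos
}

canon_combos <- function(lst) {
  keys <- vapply(lst, function(x) paste(sort(x), collapse = ","), character(1))
  sort(keys)
}

# --- factorial hypergeometric tail oracle for the somatic Fisher test -------
oracle_fisher_tail <- function(n_ref, n_alt, t_ref, t_alt) {
  m <- n_alt + t_alt; n <- n_ref + t_ref; k <- t_ref + t_alt
  if (m == 0 || n == 0 || k == 0 || n_ref + n_alt == 0) return(1)
  tot <- m + n
  p <- 0
  for (x in t_alt:min(k, m)) {
    if (k - x > n) next
    p <- p + choose(m, x) * choose(n, k - x) / choose(tot, k)
  }
  min(1, p)
}

# --- brute-force Hamming placement scan -------------------------------------
oracle_hamming_best <- function(read, target) {
  L <- nchar(read); n <- nchar(target)
  if (n < L) return(NULL)
  offs <- 0:(n - L)
  rv <- utf8ToInt(read)
  mm <- vapply(offs, function(o)
    sum(utf8ToInt(substr(target, o + 1, o + L)) != rv), integer(1))
  list(offsets = offs[mm == min(mm)], mismatches = min(mm))
}

# --- tiny alignment-table builder -------------------------------------------
make_reads <- function(..., chrom = "chr1") {
  rows <- list(...)
  dt <- data.table::rbindlist(lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    L <- nchar(r$seq)
    data.table::data.table(
      qname = if (!is.null(r$qname)) r$qname else paste0("r", i),
      flag = if (!is.null(r$flag)) as.integer(r$flag) else 0L,
      rname = chrom,
      pos = as.integer(r$pos),
      mapq = if (!is.null(r$mapq)) as.integer(r$mapq) else 60L,
      cigar = if (!is.null(r$cigar)) r$cigar else paste0(L, "M"),
      rnext = "=", pnext = 0L, tlen = 0L,
      seq = r$seq,
      qual = if (!is.null(r$qual)) r$qual else strrep("I", L),
      OP = NA_integer_, OC = NA_character_, XC = NA_character_)
  }))
  dt[, ref_end := pos + vapply(cigar, function(cg)
    if (cg == "*") 0L else
      sum(with(splicealign::cigar_runs(cg), len[op %in% c("M","D","N","=","X")])),
    integer(1))]
  dt[, uid := paste0(qname, "/", ifelse(bitwAnd(flag, 64L) > 0L, 1L,
                                        ifelse(bitwAnd(flag, 128L) > 0L, 2L, 0L)))]
  dt[]
}
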