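# Localized de Bruijn assembly. Reads of all samples in a window are pooled,
# k-merised and assembled jointly. k is taken from an ascending ladder; the
# first k (bounded by the read length) whose pruned graph is cycle-free is
# used, since larger k resolves more repeat structure. k-mers seen fewer than
# `min_kmer_count` times, or containing a base below the quality floor or an
# ambiguous base, are pruned.

#' Assemble candidate contigs from the reads of a window
#'
#' Builds a pruned de Bruijn graph jointly over all supplied reads (including
#' unmapped mates) and returns every maximal simple path as a candidate
#' contig sequence. Paths are bounded in number (`cfg$max_paths`) and length;
#' a path revisiting a node is truncated at the first repeat. If no k in the
#' ladder yields a cycle-free graph, or the node budget is exceeded, assembly
#' is abandoned for the window and an empty result returned (other contig
#' sources still apply).
#'
#' @param reads Alignment data.table (all samples pooled).
#' @param cfg A [realign_config()].
#' @return Character vector of contig sequences (possibly empty), with the
#'   chosen k as attribute `"k"`.
#' @export
assemble_region <- function(reads, cfg = realign_config()) {
  if (!nrow(reads)) return(character())
  seqs <- reads$seq
  quals <- reads$qual
  read_len <- max(nchar(seqs))
  ladder <- cfg$kmer_ladder[cfg$kmer_ladder < read_len]
  max_len <- 2L * cfg$window_size + 2L * read_len

  for (k in ladder) {
    km <- kmer_counts(seqs, quals, k, cfg$assembly_quality_floor)
    km <- km[km >= cfg$min_kmer_count]
    if (!length(km)) next
    if (length(km) > cfg$node_budget) return(character())
    g <- debruijn_edges(names(km))
    if (has_cycle(g)) next
    paths <- enumerate_paths(g, k, cfg$max_paths, max_len)
    if (length(paths)) {
      attr(paths, "k") <- k
      return(paths)
    }
  }
  character()
}

# count k-mers across reads, skipping k-mers with ambiguous or low-quality bases
kmer_counts <- function(seqs, quals, k, qual_floor) {
  all <- unlist(lapply(seq_along(seqs), function(i) {
    s <- seqs[i]
    L <- nchar(s)
    if (is.na(s) || L < k) return(character())
    starts <- seq_len(L - k + 1L)
    kms <- substring(s, starts, starts + k - 1L)
    if (!is.na(quals[i]) && nzchar(quals[i]) && quals[i] != "*") {
      ph <- utf8ToInt(quals[i]) - 33L
      lowpos <- which(ph < qual_floor)
      if (length(lowpos)) {
        bad <- unique(unlist(lapply(lowpos, function(p)
          max(1L, p - k + 1L):min(L - k + 1L, p))))
        kms <- kms[-bad[bad >= 1L & bad <= length(kms)]]
      }
    }
    kms
  }))
  all <- all[!grepl("[^ACGT]", all)]
  if (!length(all)) return(integer())
  tb <- table(all)
  setNames(as.integer(tb), names(tb))
}

# adjacency over (k-1)-mer overlaps within the kept k-mer set
debruijn_edges <- function(kmers) {
  k <- nchar(kmers[1L])
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (km in kmers) assign(km, TRUE, envir = env)
  succ <- lapply(kmers, function(km) {
    suf <- substr(km, 2L, k)
    nx <- paste0(suf, c("A", "C", "G", "T"))
    nx[vapply(nx, exists, logical(1), envir = env, inherits = FALSE)]
  })
  names(succ) <- kmers
  succ
}

# cycle detection by iterative colouring DFS
has_cycle <- function(succ) {
  color <- new.env(hash = TRUE, parent = emptyenv())  # 1 grey, 2 black
  for (start in names(succ)) {
    if (!is.null(color[[start]])) next
    stack <- list(list(node = start, i = 0L))
    color[[start]] <- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      nbrs <- succ[[top$node]]
      if (top$i < length(nbrs)) {
        stack[[length(stack)]]$i <- top$i + 1L
        nb <- nbrs[top$i + 1L]
        cl <- color[[nb]]
        if (is.null(cl)) {
          color[[nb]] <- 1L
          stack[[length(stack) + 1L]] <- list(node = nb, i = 0L)
        } else if (cl == 1L) return(TRUE)
      } else {
        color[[top$node]] <- 2L
        stack[[length(stack)]] <- NULL
      }
    }
  }
  FALSE
}

# enumerate root-to-leaf paths (roots = nodes with no predecessor), spelling
# out sequences; branch points enumerate all continuations up to the caps
enumerate_paths <- function(succ, k, max_paths, max_len) {
  nodes <- names(succ)
  indeg <- new.env(hash = TRUE, parent = emptyenv())
  for (nm in nodes) for (nb in succ[[nm]])
    assign(nb, (if (is.null(indeg[[nb]])) 0L else indeg[[nb]]) + 1L, envir = indeg)
  roots <- nodes[vapply(nodes, function(nm) is.null(indeg[[nm]]), logical(1))]
  if (!length(roots)) return(character())
  out <- character(0)
  for (root in roots) {
    # DFS over (node, spelled suffix) with per-path visited set
    stack <- list(list(node = root, seq = root))
    while (length(stack) && length(out) < max_paths) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      nbrs <- succ[[cur$node]]
      extended <- FALSE
      if (nchar(cur$seq) < max_len) {
        for (nb in rev(nbrs)) {
          stack[[length(stack) + 1L]] <-
            list(node = nb, seq = paste0(cur$seq, substr(nb, k, k)))
          extended <- TRUE
        }
      }
      if (!extended) out <- c(out, cur$seq)
    }
    if (length(out) >= max_paths) break
  }
  unique(out[nchar(out) >= 2L * k])
}
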