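#' Realignment configuration
#'
#' Bundles every tunable parameter of the realigner and caller. Defaults are
#' the tool's operating point: 400 bp windows overlapping by 200 bp, windows
#' holding more than 2000 reads skipped, soft-clip contig harvesting at 15 or
#' more high-quality clipped bases, assembly triggered by insertions longer
#' than 15% or high-quality clips longer than 25% of the read length, and
#' 10-mer seeds for read placement.
#'
#' @param window_size Window width in bp.
#' @param window_overlap Overlap between consecutive windows in bp; must be
#'   positive and smaller than `window_size`.
#' @param max_depth Reads per window above which the window is skipped
#'   untouched (guards against pathological pileups).
#' @param max_move_distance Maximum bp a read's start may shift during an
#'   update. The whole-genome preset in practice raises this to 500000; the
#'   default here is 1000.
#' @param softclip_min_bases Minimum number of high-quality clipped bases for
#'   a read to seed a soft-clip contig.
#' @param softclip_min_quality Phred score at or above which a clipped base
#'   counts as high quality.
#' @param assembly_trigger_fraction Fraction of reads in a window that must be
#'   assembly triggers before the de Bruijn assembler runs.
#' @param insertion_trigger_fraction An insertion longer than this fraction of
#'   the read length is an assembly trigger.
#' @param softclip_trigger_fraction A high-quality clip run longer than this
#'   fraction of the read length is an assembly trigger.
#' @param seed_length k-mer length for seeded read placement.
#' @param scoring Named list `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (all positive; penalties are subtracted, a gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @param contig_score_slack A contig whose best alignment scores below
#'   `match * nchar(contig) - contig_score_slack` is dropped. The default is
#'   sized so that an otherwise exact contig carrying one indel event of up
#'   to 75 bp (inserted bases earn no match score) plus two substitution
#'   errors is retained: `gap_open + 75 * (match + gap_extend) +
#'   2 * (match + mismatch)`.
#' @param max_mismatch_fraction Cap on accepted placement mismatches as a
#'   fraction of read length.
#' @param min_intron_length Minimum N-operation length harvested as a splice
#'   junction from input CIGARs.
#' @param max_junctions Cap on the local junction set size per window.
#' @param max_combinations Cap on enumerated junction combinations per window;
#'   beyond it enumeration falls back to singletons plus the empty set.
#' @param kmer_ladder Ascending candidate k-mer sizes for assembly; the first
#'   k giving a cycle-free pruned graph is used.
#' @param min_kmer_count k-mers observed fewer times are pruned.
#' @param assembly_quality_floor k-mers containing a base below this Phred
#'   score are not counted.
#' @param node_budget Abandon assembly for the window above this node count.
#' @param max_paths Cap on enumerated assembly paths per window.
#' @param max_contigs Cap on haplotype contigs per window.
#' @param use_assembly Logical; disable to reproduce the assembly-off mode.
#' @param amplicon_consensus Logical; merge reads clipped at a shared locus
#'   into a majority-vote consensus contig (amplicon mode).
#' @param filter_junction_abutting Logical; revert realigned reads whose final
#'   CIGAR has an indel directly abutting an N operation.
#' @param min_alt_count Minimum tumor alt reads for a variant to be reported.
#' @param pos_complexity_threshold Fail the positional-complexity filter when
#'   the span of alt start positions is strictly below this (and alt >= 2).
#' @param strand_bias_alpha Significance level of the orientation-bias filter.
#' @param strand_min_alt Minimum alt depth before the orientation-bias filter
#'   is evaluated.
#' @param str_penalty Logical; apply tandem-repeat/homopolymer quality
#'   penalties.
#' @param min_qual Variant emission floor on the Phred-scaled quality.
#'
#' @return A list of class `realign_config`.
#' @export
realign_config <- function(window_size = 400L,
                           window_overlap = 200L,
                           max_depth = 2000L,
                           max_move_distance = 1000L,
                           softclip_min_bases = 15L,
                           softclip_min_quality = 20L,
                           assembly_trigger_fraction = 0.10,
                           insertion_trigger_fraction = 0.15,
                           softclip_trigger_fraction = 0.25,
                           seed_length = 10L,
                           scoring = list(match = 8L, mismatch = 32L,
                                          gap_open = 48L, gap_extend = 1L),
                           contig_score_slack = 803L,
                           max_mismatch_fraction = 0.05,
                           min_intron_length = 20L,
                           max_junctions = 20L,
                           max_combinations = 1024L,
                           kmer_ladder = c(23L, 33L, 43L, 53L, 63L),
                           min_kmer_count = 2L,
                           assembly_quality_floor = 5L,
                           node_budget = 50000L,
                           max_paths = 512L,
                           max_contigs = 256L,
                           use_assembly = TRUE,
                           amplicon_consensus = FALSE,
                           filter_junction_abutting = FALSE,
                           min_alt_count = 2L,
                           pos_complexity_threshold = 10L,
                           strand_bias_alpha = 0.01,
                           strand_min_alt = 4L,
                           str_penalty = TRUE,
                           min_qual = 1) {
  stopifnot(window_overlap > 0L, window_overlap < window_size,
            assembly_trigger_fraction > 0, assembly_trigger_fraction <= 1,
            insertion_trigger_fraction > 0, insertion_trigger_fraction <= 1,
            softclip_trigger_fraction > 0, softclip_trigger_fraction <= 1,
            seed_length >= 1L,
            scoring$match > 0, scoring$mismatch > 0,
            scoring$gap_open >= scoring$gap_extend, scoring$gap_extend > 0)
  cfg <- as.list(environment())
  class(cfg) <- "realign_config"
  cfg
}
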