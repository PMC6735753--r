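---
title: "Splice-aware local realignment and somatic indel calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splice-aware local realignment and somatic indel calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicealign)
library(data.table)
```

## The problem

Short-read aligners place each read independently against the reference.
Around insertions and deletions this routinely fails: reads that span an
indel are emitted soft-clipped at the variant boundary, or scattered with
inconsistent gap placements, and downstream variant callers under-count or
miss the event entirely. In RNA-seq the problem compounds, because a read may
span both a splice junction (an N operation hundreds or thousands of bases
wide) and an indel, a configuration that most DNA realigners cannot
represent at all.

`splicealign` re-examines reads locally: candidate haplotypes (contigs) are
constructed per region from the evidence in the reads themselves, mapped onto
*transcript representations* of the local reference, and reads are moved onto
a contig only when they fit it strictly better than the reference and the
placement is unambiguous. A companion caller then counts realigned allele
support in tumor/normal pairs and tests tumor enrichment with a one-sided
Fisher's exact test.

## The procedure

### Windows

All work is local to 400 bp windows that overlap by 200 bp
(`realign_config(window_size, window_overlap)`); a whole chromosome, or only
the intervals of a BED file, is tiled this way. The overlap guarantees every
locus is interior to at least one window, so a variant clipped at one
window's edge is centered in the neighbouring one. Each base falls in at most
two windows; a read overlapping two windows is updated by the first window
that strictly improves it and is left untouched afterwards, which makes the
procedure deterministic and free of oscillation. Windows holding more than
`max_depth` (default 2000) reads are passed through unchanged — abnormally
deep pileups are almost always collapsed repeats where local realignment is
both slow and unsafe.

### Contig generation

Four evidence sources feed the per-window candidate pool:

1. **Observed indels** — I/D operations already present in input CIGARs.
2. **Soft-clip sequence** — the full sequence of any read whose clipped
   segment holds at least 15 bases at or above Phred 20. This is the main
   discovery channel for the clipped misalignments described above.
3. **Localized de Bruijn assembly** — run only when the fraction of
   "triggering" reads (mate unmapped, insertion longer than 15% of the read
   length, or a high-quality clip run longer than 25% of it) exceeds
   `assembly_trigger_fraction` (default 0.10). All samples are assembled
   jointly.
4. **Known indels** — records of an optional input VCF.

Soft-clip and assembly sequences are first aligned to the transcript
representations (below); each indel discovered this way — and every observed
or known indel — is then materialised as a *haplotype contig*: the whole
local representation with that indel applied, built by `build_indel_contig()`.
This region-wide carrier is what reads are placed against; a raw read-length
contig could only host reads at nearly identical offsets.

An indel discovered from a contig alignment is only trusted when it is
anchored by at least a seed length (10 bp) of aligned bases on both flanks;
unanchored trailing gaps are partial evidence (a read that ends inside an
insertion) and are discarded. Without this rule, reads ending inside a long
insertion spawn spurious shorter candidates.

### Transcript representations

For each window the local junction set J collects every splice junction
(annotated, or observed as an N operation in the input) with an endpoint
within the window padded by two read lengths, then twice adds junctions
within one read length of any member's endpoint. The two expansion passes
let a read that barely enters the window still span two junctions beyond it.
Every subset of J whose introns are pairwise disjoint is a putative
transcript; each is rendered as a spliced reference sequence with a monotone
bidirectional local/genomic coordinate map. Enumeration is recursive and
capped (`max_junctions` 20, `max_combinations` 1024, falling back to
singleton junction sets with a warning) because J of size n with disjoint
members yields 2^n combinations.

### Contig alignment

Each contig is aligned end-to-end to every representation by semi-global
dynamic programming with affine gap penalties: reference overhangs are free,
a gap of length L costs `gap_open + L * gap_extend`. The single
highest-scoring alignment wins and is projected to genomic coordinates, with
every crossed junction rendered as an N operation of exactly the intron
length. Ties across representations are kept when their genomic projections
are identical and discarded as ambiguous otherwise.

Default scoring is match 8, mismatch 32, gap open 48, gap extend 1. The gap
extension is deliberately cheap relative to opening: a contig is a candidate
haplotype, and a single long indel should cost little more than a short one.
Mismatch is set high (4 matches' worth) because a contig that needs several
substitutions to fit is more likely noise than haplotype. A contig whose best
score falls below `match * length - contig_score_slack` is dropped; the
default slack (803) is sized so an otherwise exact contig carrying one indel
of up to 75 bp — remembering that inserted bases earn no match score — plus
two sequencing errors survives, while grossly divergent sequence does not.

### Read placement

Reads that do not perfectly match the reference are compared to each
haplotype contig with seeded ungapped extension: the contig is hashed into
10-mers, every read 10-mer probes the table, and each hit proposes one
placement, scored by Hamming distance with the minimum winning. A read is
updated only when (i) its best contig placement has strictly fewer
mismatches than its reference baseline, (ii) the placement is unambiguous —
all tied placements project to one genomic alignment, (iii) the implied move
is at most `max_move_distance`, and (iv) mismatches stay within
`ceiling(0.05 * read length)`. The reference baseline counts soft-clipped
and inserted bases as mismatches: that is precisely what makes an initially
clipped read updatable, and it also makes the procedure idempotent, since a
correctly realigned read has a baseline of zero and can never be moved
again. Updated reads take their position and CIGAR from slicing the contig's
genomic CIGAR at the placement offset — inheriting D, I and N operations as
needed — and carry tags `OP`/`OC` (original position and CIGAR) and `XC`
(supporting contig identity). MAPQ and base qualities are never modified;
the realigner has no mapping-uncertainty model, so preserving is the
conservative choice.

### Somatic calling

Candidate indels are read off the realigned tumor sample (tags and CIGARs),
left-normalized per VCF convention, and counted in both samples: alt support
requires a spanning read whose `XC` tag names a contig carrying the indel or
whose own CIGAR shows it; spanning reads without the indel count as
reference. In repeat context only reads spanning the entire repeat run (plus
one anchor base each side) are evaluated, since a read that ends inside a
repeat cannot distinguish alleles. Somatic status is the one-sided Fisher's
exact probability (hypergeometric tail, computed with `phyper`) that the
tumor holds at least the observed alt count given the margins. Quality is
`-10 log10 p` minus repeat penalties, floored at zero.

Soft filters annotate rather than remove: `orientation_bias` (alt support
significantly one-stranded versus the reference strand balance, Fisher/binomial
at alpha 0.01, evaluated only at alt depth >= 4), `low_positional_complexity`
(span of alt start positions strictly below 10 bp with >= 2 alt reads) and
`mq0_majority` (strict majority of spanning reads at MAPQ 0). The
tandem-repeat penalty detects the maximal repeat unit of length 1-6 anchored
at the locus within +/- 50 bp; when the indel length is a multiple of the
unit, quality drops by `2 * (copies - t)` capped at 30, with `t = 5` for
homopolymers and `t = 3` for longer units — monotone in run length, zero
outside repeats, and disabled wholesale by `str_penalty = FALSE` for
libraries where PCR slippage is not a concern. Records need at least 2 tumor
alt reads and quality >= 1 to be emitted, and overlapping candidate records
(affected intervals within 5 bp) are resolved to the single best-supported
allele — sequencing errors inside a real indel otherwise spawn weakly
supported shifted echoes of it at the same locus. The filter alpha of 0.01 implies
roughly a 1% false-annotation rate on true variants; consumers who need
every record treat filters as annotations, which is how the package's own
recovery statistics count them.

## The fixture simulator

`sim_spec()`/`simulate_reference()`/`simulate_reads()` generate the data the
whole test suite runs on: a random chromosome with gene structures, a
junction annotation file, and tumor/normal paired-end reads drawn from
spliced transcripts. Its defaults are the package's reference study
conditions: a 10 kb chromosome, 100 bp pairs at 60-fold coverage per sample,
fragment length 250 +/- 30, uniform substitution errors at 0.1%, constant
Phred-35 base qualities, and somatic variants at the requested VAF (the
recovery experiments use deletions of 1-50 bp and insertions of 1-30 bp at
VAF 0.25-0.6, the regime a 60x tumor/normal design can resolve). The
simulator's defining feature is its *naive aligner emulation*: every
variant-spanning read is emitted soft-clipped at the variant boundary with
the longer flank anchored — the exact failure mode the realigner exists to
repair — while junction-spanning reads carry correct N CIGARs and the normal
sample carries no somatic variant. Initial alignments are produced by the
generator itself rather than an external aligner so tests are deterministic
and download-free.

What the simulator does *not* emulate: indel-bearing aligner output (some
real aligners place small indels correctly some of the time), quality-score
degradation along the read, PCR duplicates, multi-mapping in genomic
repeats, and strand-biased artefacts. Passing recovery tests therefore
demonstrates the realignment and calling machinery, not robustness to every
artefact of production sequencing.

## Numerical and design choices

* **Coordinates** are 0-based half-open internally; SAM/VCF text is emitted
  1-based. The final window at a sequence end is clipped, not shifted, and a
  sequence no longer than one window gets exactly one.
* **DP tie-breaking** is frozen: leftmost maximal cell of the final row,
  traceback preferring match, then deletion, then insertion. Gap opening is
  preferred over extension at equal score. This makes output deterministic
  across platforms.
* **Assembly k** walks the ladder 23, 33, 43, 53, 63 (bounded by read
  length) until the pruned graph is cycle-free; k-mers seen fewer than twice
  or containing a base below Phred 5 are pruned. Budgets: 50000 nodes, 512
  paths, path length two windows plus two read lengths. If no k is
  cycle-free the window's assembly is abandoned and the other three contig
  sources still apply (tandem duplications shorter than k can defeat
  assembly; the known-indel channel covers them).
* **Ambiguity** is defined as distinct genomic projections tying at the
  minimum mismatch count — two representations or offsets that disagree only
  in bookkeeping but project identically are not ambiguous.
* **Degenerate Fisher tables** (an empty row or column) are defined as
  p = 1: no evidence, not significance.
* **The junction-abutting filter** (`filter_junction_abutting`) reverts
  realigned reads whose final CIGAR has an I/D run adjacent to an N run;
  some downstream callers reject such records. It is off by default.
* **Problem sizes** in the recovery experiments (10 kb genome, 20 DNA
  fixtures, 5 RNA fixtures, 60x coverage) are chosen so the full suite
  exercises every code path — spliced and unspliced, all four contig
  sources, both variant types across the supported length ranges — at
  desk scale.

## Limitations

* Single-chromosome windows only: no inter-chromosomal or inversion contigs,
  and no chimeric contig stitching.
* Read-vs-contig placement is ungapped by design; a read whose true
  alignment needs a second, undiscovered indel will not move.
* The caller is strictly tumor/normal somatic: no single-sample mode and no
  SNVs.
* Insertions longer than a read minus two anchor flanks cannot be fully
  spanned and are not recoverable from read evidence alone (the known-indel
  channel can still carry them).
* Duplicate marking is out of scope; inputs should be duplicate-marked
  upstream if required, and re-marked afterwards if mates are rescued.
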