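---
title: "Methods: split-read and bridge-pair fusion calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: split-read and bridge-pair fusion calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(splitbridge)
```

# The detection model

A chimeric transcript joins two genomic loci at a breakpoint pair. Two read
configurations reveal it in RNA-seq data:

* a **SPLIT read** spans the junction, so its two local alignments flank the
  breakpoint and imply an exact position;
* a **BRIDGE pair** has its two mates on opposite sides of the junction,
  inside the unsequenced part of the fragment, and implies an approximate
  position within the insert-size range.

The pipeline proceeds in stages. Reads are first aligned end-to-end to the
transcriptome and, for reads that fail, to the genome. Reads that remain
unmapped are aligned **locally** to the genome, and pairs of local
alignments of one read become SPLIT candidates when two conditions hold:

1. the pair cannot be a normal spliced alignment — different chromosomes, a
   same-chromosome separation beyond the maximum intron size `I_max`
   (default 20,000 bp, a human-genome scale), or a strand/order arrangement
   incompatible with splicing (this admits inversion-type events); and
2. the pair is near-contiguous in read coordinates: with
   `g = q_second - (q_first + l_first)`, we require
   `-T_inner <= g <= T_outer` (defaults 10 and 2 bp), allowing up to
   `T_inner` bases of microhomology overlap and up to `T_outer` unaligned
   bases at the junction.

At most `max_configs = 20` SPLIT configurations are kept per read, ranked
by combined alignment score, then fewest mismatches, then locus order.

Properly paired reads (same chromosome, within `I_max`) calibrate the
insert-size model (sample mean and standard deviation of outer distances,
measured in transcript coordinates so splicing does not inflate them) and
per-gene expression (mean exonic depth). Pairs with no proper combination
of their mates' placements become BRIDGE candidates.

## Directionality

Every BPC alignment points at its breakpoint from one side. The direction
follows from the alignment strand and the alignment's role in the BPC
(read-coordinate order for SPLIT segments, mate identity for BRIDGE
mates):

| role                 | strand | breakpoint side |
|----------------------|--------|-----------------|
| SPLIT first segment  | `+`    | right           |
| SPLIT first segment  | `-`    | left            |
| SPLIT second segment | `+`    | left            |
| SPLIT second segment | `-`    | right           |
| BRIDGE mate          | `+`    | right           |
| BRIDGE mate          | `-`    | left            |

"Right" means the breakpoint sits at the high-coordinate end of the
supporting alignments on the forward genomic axis. The 5'/3' roles of the
two partners are assigned later, from library strand-specificity when
available, else from the annotated gene strand (a partner whose
transcription flows into the junction is 5'-like), with genomic order as
the deterministic fallback.

## Clustering

BPC alignments are clustered per chromosome by iterative insertion: an
alignment that intersects no cluster starts one; one intersection joins;
several intersections first merge the clusters. The result equals the
connected components of the interval-overlap graph and is therefore
independent of insertion order (a property the test suite verifies by
exhaustive permutation on small sets). Clusters are then separated by
directionality, and by breakpoint position: SPLIT-implied positions are
sorted and chain-broken wherever the gap to the previous position exceeds
the tolerance (10 bp by default) — a single-linkage rule, so a chain of
positions each within tolerance of the next stays together. BRIDGE-only
members attach to the nearest compatible breakpoint group; those
compatible with none remain as bridge-only clusters whose breakpoint is
the junction-side span edge, flagged approximate.

## Overlap trimming

A local alignment can over-extend past the true junction whenever a
mismatch is recouped by downstream chance matches; the amount of
over-extension is a property of the junction's flanking sequence, so all
reads of one fusion inherit it and can even settle on two self-consistent
breakpoint conventions (reads in the two orientations assign the
homologous block to opposite sides). Three measures keep breakpoints
consistent:

* local alignments are trimmed so that their terminal six columns are
  exact matches;
* any read-coordinate overlap between the two segments of a candidate is
  trimmed back to a contiguous configuration (`g = 0`), removing the
  overlap from the side whose trimmed alignment retains the higher exact
  score (ties keep the donor extended, i.e. the overlap is assigned to the
  donor side); pairs whose overlap exceeds `T_inner` are kept only in
  trimmed form, and only when the trimmed alignment still clears the
  local-score threshold;
* fusions whose two breakpoint pairs lie within twice the clustering
  tolerance of each other (same directionality) are merged, the
  SPLIT-richer pair of coordinates winning.

## Rescue

Local alignments that formed no SPLIT (typically because the second read
part was too short to clear the local-score threshold,
`score > Score_max/3`) are revisited. An alignment with score above half
the read's maximum and edit distance below 2 that lies concordantly on a
cluster has the remaining part of its read realigned against each partner
cluster's breakpoint region with the built-in Smith-Waterman; the same
score and edit-distance bounds apply to the rescued part. Two window
frames are tried: the genomic breakpoint region, and — because a partner
half may itself span a splice junction — the spliced transcript frame of
any annotated transcript containing the breakpoint. For bridge-only
partners the search window is extended by `mu + 3 sigma` of the insert
model and the junction position is inferred from the realignment; the
cluster's breakpoint is then set to the position with the most rescued
evidence. Breakpoints that already have SPLIT evidence are never moved by
rescue.

# Filter features and defaults

After discarding SPLIT support whose mate pair maps farther than `I_max`
from both partners, absorbing bridge-only events into nearby
SPLIT-supported ones, and resolving multimapped reads (iterative
assignment of each shared read to its highest-scoring fusion; fusion
score = 3 per unique mated SPLIT, 2 per unique SPLIT without mate
information, 1 per multimapped SPLIT, 1 per BRIDGE), seven features are
computed:

| feature | default threshold | rationale |
|---|---|---|
| metacluster homogeneity | >= 0.25 | homology artifacts split support across competing clusters in one region; genuine events dominate their metacluster. A fusion's own opposite side is not counted as competition. |
| unique SPLIT footprint fraction | >= 0.05 | PCR/optical duplicates collapse to one footprint |
| breakpoint offset deviation | <= 0.25 of read length | genuine junction positions inside reads are uniform around the middle |
| unique SPLIT requirement | at least one non-multimapped SPLIT when no BRIDGE support exists | guards against pure repeat artifacts |
| junction homology | normalized best contiguous reference alignment <= 0.8 | a "junction" found contiguously in the reference (score near 1) is a retro-copy/homology artifact; a genuine junction of unrelated loci scores near 0.5 |
| BRIDGE insert validity | >= 0.5 within `mu +/- 3 sigma` | inserts are measured across the reconstructed (spliced) fusion: mate-to-breakpoint distances are projected through an annotated transcript when one contains both mate and breakpoint, so introns do not inflate them |
| strand consistency (stranded protocols) | dominant orientation fraction >= 0.8 | consistency, not concordance, is thresholded — a uniformly antisense partner is biology and gets flagged, not filtered |

Support of at least `min_support = 2` reads is required. Biotype control
discards fusions whose partner is annotated only with pseudogene or
processed-transcript biotypes (substring match, overridable), and
intergenic partners are reported by default. All thresholds live in
`filter_thresholds()`; the feature table is checkpointed so
`refilter_fusions()` can re-apply different thresholds without
re-alignment. Relaxing any single threshold can only grow the pass set.

The flanking-expression feature (mean proper-read depth in 100 bp windows
next to each breakpoint) is reported but not thresholded.

# The built-in aligner

All alignment is done by an internal seeded mapper: a sorted k-mer index
(k = 13 by default) over the reference, an end-to-end verifier that allows
mismatches only (up to 6 per read), and a seeded local Smith-Waterman with
the scoring scheme +2 match, -2 mismatch, -6 gap open, -3 gap extension.
`Score_max` is read length times the match score, and local alignments
must exceed `Score_max/3`. The mapper runs in process, needs no external
binary, and any pre-computed alignments in the same tabular form can be
substituted (bypass mode). Reads whose only placements are mitochondrial
(`chrM`/`MT`) are discarded by default.

The end-to-end verifier does not handle indels; a read carrying an indel
error simply falls through to local alignment. At the simulated indel
rates (about 0.03 % of bases) this costs a negligible amount of coverage.

# The simulator

`simulate_toy_reference()` builds a uniform-random multi-chromosome genome
with non-overlapping multi-exon genes (4-8 exons of 80-400 bp, introns of
200-1500 bp). Uniform random sequence is effectively repeat-free at any
realistic seed length, which is precisely what the negative-control
property exploits. `generate_fusion_annotations()` plants five classes of
events — both breakpoints at exon boundaries; inside an exon; inside an
intron (the transcript retains intron sequence up to the junction); one
intergenic partner; and multi-isoform events with several exon-boundary
junctions — 20 events per class by default, with coverage drawn uniformly
from 1-60X per transcript. Each partner's transcribed portion is required
to be at least 150 bp: a chimera whose flank is shorter than a read cannot
anchor either SPLIT or BRIDGE evidence and is not a meaningful target for
short-read detection.

`simulate_reads()` draws fragments from Normal(300, 80) truncated to the
transcript, 75 bp mates, with an Illumina-like error model: substitution
rate ramping linearly 0.1 % to 1 % along the read, insertions at 0.01 %
and deletions at 0.02 % per base. Strandedness modes `forward`, `reverse`
and `none` fix or randomize which mate is transcript-sense.
`add_background_reads()` adds reads from the annotated transcriptome with
per-gene log-normal(1, 1) abundance. All generators are deterministic
under a seed.

What the simulator does **not** emulate: repeat and low-complexity
sequence, paralogy between genes, expression-linked fragment biases,
quality-score-dependent errors, or multi-isoform reference genes. Passing
the bundled study therefore demonstrates correctness of the calling logic
under clean mappability, not performance on a real genome, where homology
filters do the heavy lifting.

# Study configuration used by the bundled checks

The packaged acceptance study uses a 5 Mb reference (4 chromosomes, 240
multi-exon genes), three datasets of 100 fusions each (20 per class,
coverage 1-60X, 75 bp pairs, fragment Normal(300, 80), Illumina-like
errors) plus 25,000 background pairs per dataset — the background budget
scales the reference study's read mass to the toy genome's size. Scoring
counts a prediction as true when both breakpoints fall within 20 bp of a
planted junction (multi-isoform junctions count separately; each truth
entry matches at most once). `scripts/acceptance.R` re-runs exactly this
design from scratch.

# Numerical choices and degenerate inputs

* Coordinates are 1-based and closed everywhere, the native convention of
  the R genomic-ranges stack; reports are likewise 1-based.
* Splice compatibility in SPLIT condition 1 uses a fixed 5 bp genomic
  slack, deliberately independent of `T_inner`, so enlarging the
  read-coordinate thresholds can only add candidates.
* Cluster breakpoint consensus is the most-supported position, ties to
  the lowest coordinate. Multimap resolution breaks score ties toward the
  lexicographically smallest fusion id and caps at 50 iterations.
* `estimate_insert_model()` refuses fewer than 2 pairs; the pipeline
  falls back to a 1000 bp bridge tolerance when no model can be built.
  Single-end input skips pairing, bridge detection and the insert-based
  features entirely.
* Bridge-only events keep their approximate breakpoint (the junction-side
  span edge) when rescue finds nothing; they are reported with an
  `approx_breakpoint` flag rather than suppressed.
* An empty candidate set propagates cleanly: the report is a header-only
  table.

# Known limitations

* SPLIT candidates join exactly two local alignments; junctions whose
  reads would need three segments (two junctions within one read) are out
  of scope.
* Local alignment is genome-frame only, so a junction half that itself
  spans a splice junction is recovered only through the transcript-frame
  rescue path, which requires an annotated transcript at the partner
  breakpoint.
* Bridge-only events carry breakpoint uncertainty on the order of the
  insert size; at 20 bp scoring tolerance they are usually counted as
  misses even when the event is real.
* The insert-size model assumes a unimodal library; mixed-insert
  protocols would need per-library models.
* Fusion expression quantification is deliberately not provided; the
  report is designed to feed dedicated quantifiers downstream.
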