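---
title: "Detecting and characterising somatic L1 insertions with retrocall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterising somatic L1 insertions with retrocall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrocall)
```

## The problem

LINE-1 (L1) is the only autonomous active human retrotransposon: a ~6 kb
element with a CpG-island promoter in its 5'UTR and two open reading frames,
the second encoding the endonuclease (EN) and reverse transcriptase that
drive target-primed reverse transcription (TPRT). New somatic insertions are
detected from capture-enriched short-read sequencing (RC-seq style): probes
targeting the L1 termini enrich fragments that span an L1-genome junction,
and the junction itself appears in reads as a soft-clipped alignment — part
of the read maps to the reference genome, the rest to the L1 consensus.

Beyond detection, the *mechanism* of each event is read from its junction
anatomy. Canonical TPRT leaves three hallmarks: an EN recognition motif
(written TT/AAAA across the bottom-strand cleavage point), a short
target-site duplication (TSD), and a 3' poly-A tail. Endonuclease-
independent (ENi) integration into pre-existing double-strand breaks lacks
all three and typically deletes reference sequence at the site.
Recombination-class events involve older, retrotransposition-incompetent
subfamilies (L1PA2) and/or homology between a co-mobilised 3' flank and the
integration target (e.g. Alu-Alu recombination). `retrocall` implements the
whole chain — simulation, alignment, junction calling, somatic filtering,
hallmark classification — plus bisulfite quantification of L1 promoter
methylation, and validates every step on synthetic data with known truth.

## Coordinates

All internal coordinates are 1-based closed intervals, the native convention
of R, `IRanges` and `substr()`; a single convention throughout removes the
usual source of junction off-by-one errors. BED files are written 0-based
half-open and VCF 1-based, as those formats require. Junctions are described
by two reference positions: `bp_right`, the last aligned base before
non-reference sequence (where right-clipped reads end), and `bp_left`, the
first aligned base after it (where left-clipped reads start). Their offset
encodes the site anatomy exactly:

* `bp_right - bp_left + 1 > 0` — a TSD of that length,
* `bp_left - bp_right - 1 > 0` — a site deletion of that length,
* `bp_left = bp_right + 1` — a blunt junction.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions used by the validation suite.

**Consensus sequences.** The bundled L1, L1PA2 and Alu consensi are
synthetic stand-ins built deterministically in code (fixed internal seeds):
a 6018 nt L1 with 5'UTR / ORF1 / ORF2 / 3'UTR landmarks, an L1PA2 derived
from it at 4 % fixed divergence, and a 300 nt Alu. The L1 5'UTR carries a
C-dense promoter CpG island with exactly 19 CpG dinucleotides, so that a
paired per-CpG comparison has 18 degrees of freedom; the high density of
non-CpG cytosines (~210 in the 480 nt amplicon) is a deliberate design
choice that gives the 95 % bisulfite-conversion filter enough informative
positions to resolve a 0.90-conversion library. The element's final 12 nt
are fixed and A-free so a simulated poly-A tail never blends into the
element end during alignment. Homopolymers are capped at 6 nt so that exact
21-mer seeds remain informative.

**Reference genomes** are random contigs at a chosen GC content into which
"decoy" L1 copies are written: possibly 5'-truncated, 2-10 % substituted
copies of the consensus, recorded as a BED-style annotation. Decoys play the
role of the reference TE complement: the caller must exclude clusters at
these loci, and full-length decoys double as the reference cohort for
sensitivity metrics.

**Implantation** writes each insertion as: left flank (ending with the TSD
copy when `tsd_len > 0`), the strand-adjusted consensus segment
(`cons_start > 1` encodes 5' truncation), a pure poly-A run, an optional
transduced 3' flank, then the right flank with `deletion_len` bases removed.
TSDs and deletions are mutually exclusive by construction. EN sites are a
property of the *reference* (the endonuclease selects them), so canonical
and degenerate motifs are written into the reference before insertion and
are therefore shared by tumour and matched normal genomes; "absent" sites
are verified (and if necessary edited) to lie at Hamming distance of at
least 3 from TTAAAA, so that a random A-rich site is never scored as a
motif. Degenerate motifs receive 1-2 substitutions drawn from C/G only —
writing an A next to the insertion point would make the tail boundary
ambiguous.

**Crisp junctions.** A maximal-extension local aligner slides a breakpoint
across any chance identity between the insert end and the reference
continuation, which would make truth breakpoints (and TSD lengths)
ill-defined. The implanter therefore "prepares" each site: the ten
reference bases continuing past each junction are forced to differ from the
corresponding insert bases (motif-forced positions are exempt, and the
randomized truth generator additionally picks truncation points whose first
donor bases avoid the residual collisions on the minus strand). This is a
property of the simulation design, not of the caller: it makes every truth
value uniquely defined so that recovery can be asserted exactly.

**Read simulation** draws sonication fragments uniformly (length uniform in
230-260 bp by default) and sequences each as an inward 2x150 nt pair;
fragments overlapping a probe interval are sampled `enrichment_factor`
times more densely, emulating hybridisation capture as a sampling-density
multiplier (no thermodynamic model — capture efficiencies are not published
for these designs, so the factor is a free parameter). Base errors are
i.i.d. substitutions; no indel errors or quality model, and PCR duplicates
arise only as identical resampled fragments. Fragment coordinates are
encoded in read names, which the test suite uses as alignment truth. With
this model the expected number of reads spanning a junction is
`coverage x enrichment_factor`, which is what "junction depth" means
throughout.

**Bisulfite amplicons** follow the stated chemistry model literally: an
island CpG cytosine is read as C with its per-CpG methylation probability
and as T otherwise, while every other cytosine converts to T with
probability `conversion_efficiency`. Per-CpG estimates are therefore
unbiased, and all deviation in the validation comes from binomial sampling.

What the simulator does *not* emulate: mappability structure of a real
genome, indel sequencing errors, chimeric library artefacts, capture GC
bias, variable insert quality, or polymorphic TE loci segregating in a
population. Passing tests demonstrate the pipeline's junction arithmetic,
filtering logic and statistical behaviour, not its performance on real
libraries.

## Alignment

`alignReads()` is a seed-and-extend soft-clipping aligner: error-free
full-length reads resolve by exact whole-read dictionary matching; remaining
reads take exact 21-mer seeds (read start, middle, end, both orientations),
and each candidate diagonal is extended by the maximal-scoring ungapped
local segment (match +1, mismatch -1), computed with a vectorised
prefix-scan. Among equal-scoring segments the *tightest* is taken, so a
mismatch/match pair straddling a junction cannot drag the breakpoint
across it. An affine-gap Smith-Waterman rescue (open 2, extend 1, via
`Biostrings::pairwiseAlignment`) handles the rare candidate whose ungapped
identity falls below 0.9. Reads with several equally-best placements get a
mapping-quality proxy of 0 and are excluded from clustering (`minq = 1`).
Clips are stored in genome-forward orientation, as in SAM. Externally
aligned reads enter through `ingestSam()`, which converts soft-clipped
primary alignments and skips secondary/supplementary records and
hard-clipped records (their clipped sequence is unavailable).

Clip realignment against the consensus set (`realignClipBatch()`) seeds
with exact 12-mers at 10 nt stride and runs Smith-Waterman in a window
around the seeded region; on a long consensus a clip with no exact seed
anywhere is treated as having no credible hit (score floor 20), while
short targets (<= 1500 nt, e.g. the Alu) are always fully scanned. Ties
prefer the earlier entry of the consensus set, which lists the young
subfamily first — so a clip equally consistent with L1-Ta and L1PA2 is
attributed to the active subfamily.

## Junction calling

Clips of at least 30 nt from non-duplicate, uniquely placed reads are
clustered per contig and clip side with single-linkage within a 10 nt
window; clusters need at least 2 distinct supporting reads. The cluster
breakpoint is the modal member breakpoint (ties leftmost), and the strand /
family / position confidences are the fractions of members agreeing with
the modal element strand, family and breakpoint. The cluster's consensus
clip is a junction-anchored per-position majority vote.

Filters re-express the published post-processing in a self-contained way:
`te_overlap` (breakpoint inside an annotated reference TE interval),
`low_te_identity` (consensus clip under 90 % identity to the TE consensus
or matched span under 30 nt — for 3' junctions the poly-A run is counted
toward the span, since the tail is element-derived but the consensus
carries none), `low_genome_identity` (genomic side under 95 %), and
`inconsistent_breakpoint`, which reinterprets the published two-aligner
concordance check as an independent realignment of the cluster consensus
sequence (a 200 nt reference anchor plus the consensus clip) with a
different seed length (k = 11), requiring the breakpoint to reproduce
within 5 nt.

Right-clip and left-clip clusters on the same contig and element strand
pair within 700 nt. The published deletion anatomies reach 550 nt and the
validation suite simulates deletions up to 600 nt, so the pairing window
must exceed those; 700 nt separates neighbouring events while covering
every plausible TSD or deletion. Unpaired clusters become single-ended
calls labelled `single_end` — they are retained rather than dropped because
a junction-targeted capture design legitimately sees only one junction for
some element anatomies.

## Somatic filtering

`isTumourSpecific()` applies five criteria: (i) exactly one tumour sample
with at least 8 supporting reads and more than 10 times the summed support
of all other libraries (duplicate-removed counts); (ii) no overlap with a
user-supplied database of known polymorphic insertions, with 100 nt slop to
absorb breakpoint imprecision between catalogues; (iii) junction-side
consistency with the capture design — a 5'-junction-only call is accepted
only for elements longer than 6000 nt or shorter than 1000 nt, otherwise a
3' junction is required; (iv) strand, family and position confidences
strictly above 0.9, 0.9 and 0.3; (v) junction microhomology against the
reference strictly below 10 nt (longer identity suggests a molecular
chimera). Call-level confidences are taken from the better-supported
junction; microhomology is the maximum over the junctions present.

## Hallmarks and classification

The EN site is read from the reference around the inferred cleavage point
(the genome-resumption junction, corrected for any site deletion): the
6-mer with TT ending at the cleavage point and AAAA after it, on the
element's strand. Exactly TTAAAA is canonical; Hamming distance up to 2 is
degenerate (the published description says only "degenerate", so the
distance-2 rule is this package's explicit operationalisation); anything
further is absent. TSDs are re-detected from the reference flanks as the
longest duplication consistent with the junction offset, with duplications
under 4 nt reported as 0 to suppress chance micro-duplications. Poly-A
tails are measured on the element-oriented 3' clip from the end of its
consensus match: at least 90 % A, no interruption over 2 nt, minimum
reportable length 10 nt — thresholds chosen to match the anatomies the
method must distinguish (pure tails of 15-102 nt versus no tail). Any
segment beyond the tail is searched against the registered donor-flank
database (20 nt at 90 % identity).

Classification applies, in order: RECOMBINATION_CANDIDATE (no EN motif,
and an L1PA2 donor or a transduced flank matching the repeat family
annotated at the target); TPRT (tail present, motif present, no deletion);
ENi (no motif, no TSD, no tail, with a deletion); AMBIGUOUS otherwise.
Recombination precedes ENi because an older-subfamily donor with target
homology is better explained by rearrangement than by trans-mobilisation;
transduction-type events classify as TPRT with their flank reported, since
3' transduction is TPRT of a read-through transcript.

## Promoter methylation

Overlapping bisulfite pairs merge at the overlap length minimising the
mismatch ratio within [15, 150] nt (ties prefer the longest overlap;
disagreements resolve toward R1; pairs above a 0.3 mismatch ratio are
dropped). Contigs align to the mock-converted consensus (every non-CpG C
pre-converted to T), both strands tried, with C/T tolerated at reference
cytosine positions when computing the identity floor (0.8). Covered island
CpGs read C (methylated) or T (unmethylated); the per-contig conversion
rate is the fraction of covered non-CpG reference cytosines reading T, and
contigs under 0.95 are discarded. A CpG position showing a non-C/T base in
more than half of the retained contigs is flagged as a mutated CpG and
excluded profile-wide. Group profiles are compared with a paired t-test
across CpG positions (pairing by sample is not possible from these inputs),
giving df = 18 for the 19-CpG island; when all per-position differences are
zero the t statistic is reported as 0.

## Validation scale and determinism

All simulators are bit-reproducible for a fixed seed (RNG state is saved
and restored around every simulation). The validation suite runs, among
others: a 500 kb single-contig genome with 12 implants (4 TPRT, 4 ENi with
50-600 nt deletions, 2 transductions, 2 recombination-class) at 50x
junction depth and 0.1 % error, requiring at least 11/12 events recovered
with breakpoints within 2 nt and exact TSD/deletion lengths, and fewer
than 2 false-positive calls passing filters; a 20-element reference cohort
at 60x junction depth over 5 seeds (sensitivity at least 0.95, junction
coverage within 15 % of nominal); tumour/normal/blood trios over 5 seeds
(every private implant tumour-specific, no shared implant, no false
positives); over 1000 randomized oracle-equivalence instances against
brute-force string scans and an exhaustive affine Smith-Waterman; and
per-CpG methylation recovery at 5000 pairs for methylation levels 0, 0.3,
0.8 and 1. These problem sizes were chosen so each property is measured
with comfortable statistical margin while the whole suite stays quick on a
single CPU.

## Known limitations

* The aligner is a purpose-built seed-and-extend tool for 150 nt
  substitution-dominated reads; it generates no split or supplementary
  alignments and is not a general-purpose mapper.
* Family attribution of short clips between closely related subfamilies is
  probabilistic: a 30-40 nt clip may carry no diagnostic position at 4 %
  divergence, which is why family confidence is a per-cluster fraction
  rather than a hard assignment.
* A 3' junction whose poly-A plus transduced flank approaches the read
  length is intrinsically hard to anchor (too little element sequence in
  the clip); such events surface as single-ended 5' calls, which is what
  the capture-design rule (criterion iii) anticipates.
* The mechanism classifier is rule-based, not probabilistic; it reports
  AMBIGUOUS rather than guessing when hallmarks conflict.
* Methylation is quantified against the consensus promoter only; per-locus
  methylation of individual genomic L1 copies is out of scope.
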