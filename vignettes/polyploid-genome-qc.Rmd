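---
title: "Assembly and annotation QC for a synthetic allohexaploid genome"
author: "polyqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly and annotation QC for a synthetic allohexaploid genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyqc)
```

# Scope

`polyqc` re-implements, as a tested pipeline, the bespoke computational
procedures used to quality-control and analyse a large allohexaploid
(bread-wheat-like) genome assembly and its annotation:

1. **k-mer spectra copy-number QC** — decompose the k-mer spectrum of a
   read set by each k-mer's copy number in the assembly, to diagnose
   missing content, artefactual (chimeric) content and spurious
   duplication.
2. **Redundancy filtering** — a two-tiered post-scaffolding filter that
   drops short scaffolds whose k-mer content is already represented in
   longer retained scaffolds.
3. **Genetic-map anchoring** — assign scaffolds to genetic bins from
   exact marker matches and classify each scaffold into a seven-class
   scheme.
4. **Gene confidence ranking** — HC/LC tiers with protein (P1) and
   transcript (T1/T2) evidence ranks; annotation-transfer filtering;
   structural comparison of two annotations.
5. **Alternative splicing and NMD** — event typing (IR, ES, A3SS, A5SS,
   MXE) between isoforms, and candidate nonsense-mediated-decay flagging
   by the 50-nt rule.
6. **Homoeolog triad expression** — balance and stress-response
   classification of A/B/D triads, expression hotspots, and translocation
   detection from outlier triads.

Everything runs offline against a synthetic allohexaploid genome whose
ground truth is known, so each stage can be tested end to end.

# The synthetic genome

`genome_config()` / `generate_genome()` build a miniature genome with the
structural features the pipeline cares about:

* three subgenomes (A, B, D) of seven chromosomes each, named `1A` … `7D`;
* every gene present as a **homoeologous triad** — one copy per subgenome,
  sampled from a common ancestral sequence and mutated independently at
  the configured divergence rate (substitutions only, so copies stay
  colinear and coordinates can be compared directly);
* intergenic spacers carrying insertions from a randomly generated repeat
  library, each flanked by an identical **target-site duplication** of
  `tsd_length` bp — the genomic signature used to argue that a scaffold
  correctly spans a transposable element;
* optional planted homoeolog deletions.

Default dimensions are 140 triads, four exons per gene (enough for every
splicing event type), 2.5-kb spacers and a 15% repeat fraction, giving
about 2 Mb of sequence in total. That size keeps every stage interactive
(seconds) while still producing non-trivial k-mer multiplicity structure:
single-copy gene space, three-copy homoeologous near-duplicates and
higher-copy repeats. All outputs are byte-identical for a fixed seed.

The generator intentionally does **not** emulate several features of real
data: indel divergence between homoeologs, sequencing quality scores,
mate-pair libraries, realistic repeat phylogenies, GC bias, or expression
differences driven by promoter divergence. Passing tests therefore
demonstrate correctness of the *procedures* under controlled conditions,
not robustness to every artefact of real sequencing.

## Read simulation

`generate_reads()` draws fixed-length single-end reads uniformly from both
strands, with substitution-only errors (the k-mer stage is
substitution-sensitive; indels would add no test power). Read names embed
the source coordinates so error rates and coverage can be audited without
alignment.

One numerical subtlety: with purely random fixed-length reads, the k-mers
at the very ends of a chromosome are covered only by reads starting in a
handful of positions, so at desk scale some end k-mers are *never*
sampled. In a spectra analysis those look identical to missing content.
The `tile = TRUE` option therefore spends part of the read budget on a
deterministic tiling (step of half a read length, plus a read flush with
each end) so that every k-mer up to half the read length is guaranteed
covered; the rest of the budget is sampled randomly as usual. The
perfect-assembly identity check uses tiled reads; all statistical tests
use the random path.

# k-mer spectra copy number

`count_kmers()` counts canonical k-mers (lexicographic minimum of a word
and its reverse complement; odd k only, so no word is its own reverse
complement; windows containing non-ACGT symbols are skipped). Counting is
exact, via a 2-bit-encoded hash table in C++ — exactness is what lets a
naive dictionary oracle verify every output in the tests. The default
k = 31 matches common practice for assembly QC.

`spectra_cn()` produces the joint matrix `entry[m][c]`: the number of
distinct k-mers with read multiplicity `m` (rows) and assembly copy
number `c` (columns 0, 1, 2, …, with one open-ended final column above
`c_max`). Row `m = 0` is the *artifact row*: assembly k-mers never seen
in a read. Two conservation laws hold by construction and are asserted in
tests: row sums above row 0 reproduce the read spectrum, and entries at
`c ≥ 1` total the distinct assembly k-mers.

`error_threshold()` separates the sequencing-error peak from real
content: the histogram is smoothed with a centred 3-point moving average
(the minimal smoothing that kills single-bin noise) and must *descend*
from multiplicity 1 — evidence an error peak exists — after which the
first upturn marks the valley. If the spectrum starts by rising (no error
peak, e.g. error-free reads) or never turns upward, a configurable
default floor (2) is returned with a warning. The threshold is detected
per data set rather than hard-coded because any fixed value is specific
to one sequencing depth.

`qc_summary()` reports missing k-mers (read content at or above the
threshold, absent from the assembly), artifact k-mers, duplicated k-mers
and completeness = 1 − missing / (distinct read k-mers ≥ threshold).
"Duplicated" needs a single-copy multiplicity band; by default it spans
from the threshold to 1.5× the main-peak multiplicity, which cleanly
separates one-copy from two-copy content when coverage peaks are
Poisson-like. Both bounds are arguments.

# Redundancy filter

`filter_scaffolds()` processes scaffolds in decreasing length order (ties
broken by id, for determinism). Scaffolds at or above the length gate
(default 500 bp, the conventional contig cutoff) are always kept — the
filter removes *short, redundant* sequence only. A shorter scaffold is
dropped iff at least `redundancy_threshold` (default 0.95) of its
distinct k-mers already occur in the retained cumulative set. The report
quantifies unique content lost (k-mers found only in removed scaffolds),
which is zero whenever the threshold is 1. Scaffolds too short to contain
a single k-mer are removed as pure length casualties, with a message.
Filtering is idempotent: a second pass removes nothing.

# Map anchoring

A `genetic_map()` is a set of markers with categorical cM bin labels on
chromosomes named `{group}{subgenome}`. Bin equality is exact label
equality, not a numeric tolerance — bins are categorical in
population-sequencing maps. `match_markers()` reports exact, full-length,
strand-aware substring matches; markers hitting more than `max_hits`
(default 2) scaffolds are treated as repeats and excluded.

`classify_scaffold()` applies the decision order: one bin of one
chromosome → class 1; several bins of one chromosome → class 2; several
chromosomes of one homoeologous group → class 3 (taking precedence over
class 4 when both readings apply); non-homoeologous conflict → class 4.
Class-1 scaffolds lacking a prior chromosome-arm assignment are re-tagged
class 5; class-1/2 scaffolds whose prior arm disagrees with the map
chromosome become class 6/7. Because 5–7 are override tags, the base
class is kept in a second column so counts can be aggregated either way.
`anchor_assembly()` adds per-class percentages (denominator: all
scaffolds), anchored bp, and HC-gene coverage of the binned scaffold set.

The synthetic map generator plants one genome-unique marker inside every
gene copy in addition to the per-bin window markers; this is what lets a
triad *member* be anchored to a bin on its own. At zero divergence the
three copies of a gene are identical and no unique genic marker exists;
those are skipped with a message.

## Translocations

A planted translocation picks a contiguous block of gene copies on a
source chromosome (all inside one bin window) and reassigns the map
entries of the markers within the block to the destination chromosome,
keeping the cM label — emulating a mapping population in which that block
segregates elsewhere. `detect_translocations()` then looks for **outlier
triads**: exactly one member's chromosome outside the homoeologous group
shared by the other two. Outliers are grouped by (bin of the outlier
member, expected chromosome = majority group + the member's subgenome)
and groups with at least `min_support` (default 3) triads are reported.
Triads whose three members disagree entirely, or that are incompletely
anchored, carry no evidence and are skipped.

# Triad expression

`tpm_normalize()` is standard transcripts-per-million. A triad is
**expressed** in a condition if any member's mean TPM reaches the 2-TPM
background floor; it is **unbalanced** if the highest member mean exceeds
twice the lowest (`ratio_threshold = 2` on replicate means — a simple
ratio rule; no test statistic is implied by the thresholds, so no
dispersion machinery is used). A triad unbalanced in at least one
condition is summarised as unbalanced, so stress-induced imbalance counts
alongside constitutive imbalance.

`classify_stress()` computes the per-member stress/control fold change on
replicate means with a 0.5 pseudocount (protecting against zero means at
negligible bias for expressed genes). Calls are strict: fold > 2 is UP,
fold < 0.5 is DOWN, *exactly* 2 or 0.5 is FLAT. The triad pattern is a
pure function of the three calls — not-DE, 1-DE, 2-DE-same, 3-DE-same, or
opposite — and the taxonomy is proved exhaustive over all 27 call triples
in the tests. `find_hotspots()` reports bins whose median gene TPM
strictly exceeds 20 in a tissue.

The expression simulator draws NB counts with
`mu = level × fold × length/1e3`; planted folds default to 2.5× (UP) and
0.4× (DOWN), deliberately beyond the call thresholds so that zero-noise
recovery is exact, and `dispersion = 0` yields deterministic rounded
means. Directions of same-direction DE patterns are drawn from a balanced
UP/DOWN pool per condition: with i.i.d. directions an extreme mix (every
triad 1-DE) can shift the TPM denominator enough to drag a planted 2.5×
fold below the 2× threshold, which would make exact recovery impossible
for reasons that have nothing to do with the classifier. The default
pattern mix (80% flat, 16% 1-DE, 2% 2-DE-same, 1% 3-DE-same, 1%
opposite) mirrors a stress experiment in which most triads do not respond
and single-homoeolog responses dominate.

# Gene confidence, annotation overlap, splicing, NMD

`assign_confidence()`: a gene is LC iff best-homolog coverage < 60%, or
it lacks wheat transcript support, or it is repeat-associated (an input
flag — repeat annotation is out of scope); every applicable LC reason is
reported in that order. Within HC, coverage ≥ 80% earns P1; a full-length
PacBio transcript earns T1, otherwise full RNA-seq support earns T2.
`transfer_filter()` keeps alignments with coverage ≥ 0.90 **and**
identity ≥ 0.95, both inclusive ("at least").

`compare_annotations()` is strand-aware (antisense overlap counts as
missing, since antisense loci are annotated separately): *identical*
means every intron boundary equal; *contained* means the reference intron
chain occurs as a contiguous sub-chain of a query transcript with the
reference span inside the query gene span (a monoexonic reference inside
a query span is trivially contained); same-strand overlap otherwise is
*structurally different*. Query genes overlapped by two or more reference
genes are flagged as candidate fusions of fragmented reference models.

`classify_as_events()` types isoform differences from intron chains. IR,
ES and MXE structures are recognised first and their introns marked as
explained, so a boundary shift that is really part of a skipped or
mutually exclusive exon is not double-reported as A5SS/A3SS. Donor and
acceptor are assigned in mRNA orientation: on the minus strand the
genomic-left intron boundary is the acceptor. A transcript compared with
itself yields no events, and calls are invariant under coordinate
translation and strand mirroring (both tested).

`flag_nmd()` applies the classical 50-nt rule: a transcript is a
candidate NMD substrate iff its stop codon lies strictly more than 50 nt
(configurable) upstream of the final exon–exon junction in mRNA
coordinates. Monoexonic transcripts are never flagged; transcripts
without a CDS are not evaluable and return `FALSE` with a message.

# Numerical and testing choices

* Exact hash-table k-mer counting (no sketches): desk-scale genomes do
  not need probabilistic counting, and exactness enables
  entry-for-entry oracle tests against a naive dictionary implementation.
* Canonicalisation is `min(kmer, revcomp)`, the standard convention.
* All generators are deterministic per seed; determinism is asserted
  byte-for-byte on FASTA/GFF3 output.
* GFF3 is emitted by a small deterministic writer (gene/mRNA/exon/CDS,
  1-based inclusive, CDS phases accumulated in mRNA order and total CDS
  length trimmed to a multiple of three); `rtracklayer` parses it back in
  the test suite as an independent format check.
* Problem sizes in the test-suite and acceptance script: oracle
  equivalence on 10–50-kb genomes, full-pipeline runs on a ~170-kb
  28-triad genome, translocation recovery on a 70-triad genome, pattern
  recovery on 200–500 simulated triads, and the acceptance script on the
  full ~2-Mb default genome. These sizes make every stage run in seconds
  while leaving all the structure the methods rely on.

# Known limitations

* The redundancy criterion (fraction of distinct k-mers already
  represented) and the balance criterion (max/min ratio of 2) are
  plausible parameterisations of procedures whose exact published
  definitions live in supplementary material not reproduced here; both
  are configurable.
* Balance and stress classification run on replicate means; no
  significance testing is performed, by design.
* `compare_annotations()` counts reference *genes* (not transcripts) in
  its category fractions; mixed cases resolve to the best category
  (identical > contained > structurally different).
* Outlier-triad detection requires exactly one discordant member; triads
  with two or more discordant members are treated as uninformative rather
  than guessed at.
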