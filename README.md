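# polyqc

Quality control and downstream analysis for large polyploid genome
assemblies and their annotations, built around the workflows used for
allohexaploid bread wheat (subgenomes A, B and D; genes in homoeologous
*triads*, one copy per subgenome).

Assembling and annotating a 17-Gb hexaploid genome forces a series of
bespoke computational decisions that are rarely shipped as reusable,
tested code: how to prove the assembly contains what the reads contain,
how to discard redundant scaffolds without losing unique sequence, how to
place scaffolds on a genetic map and notice when the map disagrees with
prior chromosome assignments, how to rank gene models by evidence, and
how to read homoeolog expression and chromosomal translocations out of
triads. `polyqc` implements those procedures as an R package and ships a
synthetic allohexaploid genome generator with complete ground truth, so
every stage is testable offline on a desk-scale (~2 Mb) genome.

## What it computes

* **Spectra-cn QC** — the joint decomposition *N(m, c)*: the number of
  distinct canonical k-mers (k = 31 by default, canonical =
  min(kmer, revcomp)) with multiplicity *m* in the reads and copy number
  *c* in the assembly. Column *c* = 0 above the error threshold is
  missing content; row *m* = 0 is artefactual assembly content;
  completeness = 1 − missing / Σ<sub>m≥t</sub> hist(m). The error
  threshold *t* is auto-detected at the first valley of the smoothed
  read spectrum.
* **Redundancy filter** — scaffolds in decreasing length order; a
  scaffold below the length gate is dropped iff ≥ 95% (configurable) of
  its distinct k-mers already occur in retained scaffolds; unique k-mers
  lost are reported, along with N50 before/after.
* **Map anchoring** — exact strand-aware marker matching, then the
  seven-class verdict per scaffold: (1) unique bin, (2) several bins of
  one chromosome, (3) homoeologous-chromosome conflict, (4)
  non-homoeologous conflict, (5) unique bin without a prior arm
  assignment, (6/7) class 1/2 contradicting the prior arm.
* **Gene confidence** — LC iff homolog coverage < 60% or no wheat
  transcript support or repeat-associated; within HC, P1 at ≥ 80%
  coverage, T1 (PacBio) / T2 (RNA-seq) full-length transcript ranks;
  annotation transfer kept at ≥ 90% coverage and ≥ 95% identity;
  structural annotation overlap in four categories plus fusion flags.
* **Splicing / NMD** — event typing (IR, ES, A3SS, A5SS, MXE) from
  intron chains in mRNA orientation; NMD candidates by the strict 50-nt
  rule.
* **Triad expression** — 2-TPM expression floor; balance by a max/min
  ratio rule; per-homoeolog stress calls (fold > 2 UP, < 0.5 DOWN, else
  FLAT) and the five-pattern triad taxonomy; expression hotspots
  (bin median TPM > 20); translocation candidates from ≥ 3 outlier
  triads per genetic bin.

## Worked example

```r
library(polyqc)

sim   <- generate_genome(genome_config(n_triads = 70, intergenic_length = 600,
                                       repeat_fraction = 0.10, seed = 1))
sim
#> synthetic genome: 21 chromosomes, 431050 bp, 210 genes (70 triads)

reads <- generate_reads(sim, coverage = 30, read_len = 150, tile = TRUE, seed = 2)
sc    <- spectra_cn(reads, sim$genome, k = 31)
qc_summary(sc, threshold = 3)
#> k-mer QC summary
#>   error threshold      : 3
#>   missing k-mers       : 0
#>   artifact k-mers      : 0
#>   duplicated k-mers    : 901
#>   completeness         : 1.0000

mp <- generate_map(sim, bins_per_chromosome = 2,
                   translocations = data.frame(from_chr = "2D", to_chr = "6A",
                                               n_triads = 5), seed = 3)
detect_translocations(triad_member_bins(sim, mp))
#> translocation detection: 5 outlier triads, 1 candidate(s)
#>   source_chromosome source_cM_bin target_chromosome n_support
#> 1                6A            10                2D         5
```

Reading the output: the assembly is the read source, so nothing is
missing and nothing is artefactual — completeness 1. The 901 "duplicated"
k-mers are single-copy-multiplicity words found at copy ≥ 2, here the
near-identical homoeologous gene copies of a deliberately low-divergence
genome. The planted five-triad translocation from chromosome 2D into a
bin of 6A is recovered as exactly one candidate: five triads whose third
member maps to bin (6A, 10 cM) while its homoeologs sit on 2A/2B,
pointing back at the expected chromosome 2D.

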