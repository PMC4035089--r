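---
title: "Methods: comparative analysis of reduced nucleomorph genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of reduced nucleomorph genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleomorphr)
library(dplyr)
```

## The biological problem

Nucleomorphs are the residual nuclei of algal endosymbionts retained inside
chlorarachniophyte and cryptophyte cells. Their genomes are among the
smallest known for a eukaryotic nucleus: three linear chromosomes, extreme
gene density, tiny (18--23 nt) "pigmy" spliceosomal introns, and — in some
lineages — long, nearly identical sub-telomeric repeat blocks that are
homogenized by recombination at the chromosome ends and can secondarily
*expand* an otherwise shrinking genome. Comparing two such genomes asks a
recurring set of structural questions: where do the terminal repeats end and
single-copy sequence begin; what tandem repeat punctuates that boundary; how
much gene order (synteny) survives; which intron positions are conserved
between orthologues; which genes are shared, lineage-specific, or part of a
conserved core; and how expression differs between sub-telomeric and
internal genes.

`nucleomorphr` implements that comparison as a set of tibble-first verbs
plus a seeded synthetic-data generator whose ground truth can score every
detector exactly.

## Containers and coordinates

An annotated genome (`nm_genome`) is a list of two tibbles — chromosomes
(name, sequence, topology) and genes (id, strand, kind, category, family,
and an exon list-column) — so every analysis step is ordinary dplyr work.
All internal coordinates are 1-based inclusive, the GFF3 and Bioconductor
convention; this keeps the package aligned with Biostrings/IRanges, on which
it leans for sequence arithmetic, and confines coordinate conversion to the
BED/bedGraph writers, which emit 0-based half-open intervals as those
formats require. Functional categories travel in a GFF3 `category`
attribute and are never inferred from sequence similarity: homology and
categorization depend on external databases and are treated as inputs.

## Detectors

**Sub-telomeric repeats.** All chromosome ends are read telomere-inward
(right ends reverse-complemented) and compared jointly: the reported repeat
length is the largest terminal prefix over which every pair of ends keeps
identity at or above `min_identity` (default 0.995, chosen to tolerate a
handful of substitutions over tens of kbp while rejecting unrelated
sequence) and which reaches `min_length` (default 1,000 bp). Because
sequence beyond the true boundary diverges at a per-base rate far above
1 − 0.995, the cumulative criterion overshoots the boundary by only a few
tens of bases; the package's own acceptance convention for boundary accuracy
is ±50 bp. The detector assumes the six ends share one repeat of common
length, which is what recombination-driven homogenization produces and what
the generator plants; ends of grossly unequal repeat length would be
reported at the shared (shorter) length.

**Boundary tandem arrays.** Candidate unit lengths are scored by
periodicity — the fraction of positions matching the base one unit
downstream — and the best-scoring length wins, ties broken toward the
smallest unit so the primitive period is canonical. The consensus folds
every base at ≥ 20% column frequency into the smallest covering IUPAC code;
20% reproduces two-state degenerate letters (R, Y) without promoting
sequencing-noise-level variants. An array is only reported when the match
fraction reaches 0.8 and at least `min_copies` fit, which rejects aperiodic
sequence.

**GC profiling.** Windows tile the sequence (window = step by default); the
final short window is included and flagged, so the length-weighted mean of
window GC equals whole-sequence GC exactly — a property the tests assert.
Ambiguity codes are excluded from both numerator and denominator of every GC
computation so degenerate positions cannot bias the estimate.

**Synteny.** Gene order is taken over an ortholog family table (multicopy
families keep every placement); blocks are maximal runs of shared families
consecutive and order-conserved in both genomes, with `max_gap` unshared
genes tolerated (default 0: the strict "same order" criterion) and inverted
runs reported. "More than three homologous genes" is ambiguous between ≥ 3
and ≥ 4, so `min_genes` is an explicit parameter (default 3) and the
generator plants blocks of ≥ 4 so either reading finds them. Each gene
placement may join one block; overlapping candidates are resolved greedily
by length, then leftmost.

**Introns.** The catalogue derives every record from exon structure: length,
phase (upstream spliced-CDS length mod 3), and boundary dinucleotides read
in transcript orientation. Junction calling from spliced alignments (SAM `N`
operations, read via Rsamtools/GenomicAlignments) collapses equivalent gap
placements — a gap flanked by identical bases can slide — to the placement
whose boundaries are canonical on either strand, else leftmost, the standard
splice-caller convention.

**Cross-species intron comparison.** Orthologue pairs are globally aligned
(BLOSUM62, affine gap open 10 / extend 0.5, terminal gaps penalized — a
deterministic internal aligner rather than an external multiple-alignment
binary). Each intron maps to the alignment column of its host residue; a
phase-0 intron sits between codons and is assigned to the preceding residue.
An intron is *comparable* when 15 alignment columns on each side are
gap-free in both sequences and each window exceeds 50% identity,
window-local — the literal reading of the comparability filter used for
intron-position studies; *shared* means same column and same phase in both
genomes. Pairs aligning below 20% overall identity are skipped as
unalignable. Outgroup polarization calls an unshared intron a loss in the
lacking genome only when at least one outgroup carries the position.

**Expression and copy number.** Per-gene depth is coverage summed over gene
positions divided by gene length. Copy number of a collapsed repeat is mean
region depth over a baseline; the baseline is the *median* per-base depth of
single-copy regions, which is robust to other repeat peaks in a way the
mean is not.

**Statistics.** Group contrasts (spacer lengths, protein lengths) use
Welch's unequal-variance t test via `stats::t.test`; the test suite checks
it against the closed form. Redundancy collapse uses single-linkage
clustering at ≥ 98% identity over ≥ 95% of the longer protein — tight
enough to collapse recombination-homogenized sub-telomeric copies (a few
substitutions across 35 kbp) without merging diverged paralogs; the
thresholds are package defaults, since the original analyses do not state
theirs.

## The synthetic-data generator

`simulate_genome_pair()` is first-class, tested code: it emulates the
structure the detectors assume and returns a truth record sufficient to
score each one exactly.

Per genome it plants: three linear chromosomes; one sub-telomeric master
sequence per genome copied to all six ends with exactly `subtel_mismatches`
(default 3) substitutions distributed over the copies; high-GC repeats
(49.4%) against low-GC internal sequence (24%); a degenerate 36-nt boundary
unit (`RTAYCTRGTTRCCTTATCGTATGCCATGGCTTTATC`) tandem-repeated 5--29 times at
each repeat/internal boundary, degenerate positions resolved independently
per copy while the truth retains the degenerate consensus; intronless
sub-telomeric ORF families in six identical copies (eight per repeat,
matching ~45--48 such genes per genome); internal protein genes with
geometric intergenic spacers (means 147.4 and 82.1 bp for the two genomes);
introns of 18--23 nt with 19 nt modal — per-length probabilities derived
from the published proportions (49.1% of introns are 19 nt; 56.7% are under
20 nt) — 58.3% phase 0, GT-AG boundaries with exactly two GC-AG and one
GA-AG planted, one 32-nt longest intron, and an A bias at exonic position
−2; ortholog families shared at 90% with intron positions conserved at 90%;
synteny blocks of sizes 4--7 planted as consecutive runs and verified to be
the *maximal* common runs (the partner arrangement is re-drawn until no
out-of-block adjacency of the two orders coincides); and a 2,500-fold
internal : sub-telomeric expression contrast at internal depth 100.

Numerical choices worth noting:

* **Exact-composition repeat master.** The non-genic part of the
  sub-telomeric master is drawn with a fixed base composition compensating
  the embedded ORFs, so repeat GC hits 49.4% to rounding precision rather
  than carrying ~1 percentage point of sampling noise over 3.5 kbp.
  Codon sampling for coding sequence is calibrated so that excluding stop
  codons does not shift the marginal GC off its target.
* **Per-base Poisson coverage.** Depth is drawn independently per base, not
  by placing reads; this is sufficient for the mean-depth statistics the
  analyses compute, but real read placement is clumpier, so zero-coverage
  gene counts at a given mean depth are conservative relative to real data.
* **Geometric spacers.** Spacer means are published but not variances; the
  geometric distribution is the maximum-entropy choice on non-negative
  integers with a given mean, and is tunable.
* **Desk scale.** Defaults are a tenfold linear scale-down (20 kbp
  chromosomes, 3.5 kbp repeats, 13 internal genes per chromosome) so the
  whole pipeline runs in seconds; `generator_config("full")` restores
  genome-scale lengths (~200 kbp / ~35 kbp). Statistical recovery
  tolerances in the tests (sub-telomeric GC ± 1 percentage point,
  expression ratio within 10%, copy number within Poisson error) reflect
  desk-scale sample sizes.
* **The multicopy gene.** One internal gene is marked as a collapsed
  5-copy repeat; its coverage mean is multiplied accordingly and its truth
  class is `multicopy`, not `internal`, because a collapsed repeat is not a
  single-copy gene and would bias the single-copy group mean upward by its
  copy number.

What passing recovery tests shows — and does not. The generator produces
clean, assembly-free, error-free data under the package's own model, so
perfect recovery demonstrates the detectors' correctness and calibration,
not their robustness to misassembly, mapping artifacts, fragmented
annotation, or repeat variation between ends. Genome-scale headline numbers
(total sizes, ~1,000-intron catalogues, non-redundant counts, 14 synteny
blocks) are properties of the deposited genome sequences and are reproduced
only when those are supplied; shared-intron counts on real data additionally
depend on the alignment engine and are approximate.

## A worked run

```{r run, eval = FALSE}
cfg <- generator_config()
sim <- simulate_genome_pair(cfg, seed = 1)
cov <- simulate_coverage(sim$genome_a, sim$truth, cfg, seed = 2)
report <- run_comparison(sim$genome_a, sim$genome_b, sim$families,
                         coverage_a = cov)
report
tidy(report)
```

Every number in the report equals the output of the corresponding single
verb on the same inputs (the test suite asserts this), and two runs with the
same inputs write byte-identical TSV bundles.

## Known limitations

* Repeat detection reports one common terminal length for all ends; ends
  with genuinely different repeat extents are summarized at the shared
  length.
* Homology (the family table) is an input; gene-content and synteny results
  on real data inherit whatever the user's orthology method decided.
* The aligner is pairwise-global only; orthologue pairs below 20% identity
  are skipped rather than re-aligned with a more sensitive engine.
* No read-level simulation, no assembly, no functional annotation, no
  tRNA/rRNA prediction, and no phylogenetics: those stages sit outside the
  package's scope and their outputs enter, where needed, as inputs.
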