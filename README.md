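# nucleomorphr

Comparative structural analysis of pairs of small, gene-dense genomes —
written for nucleomorphs, the vestigial endosymbiont nuclei of
chlorarachniophyte and cryptophyte algae, and usable for any compact
annotated genome pair.

Nucleomorph genomes are extreme: three linear chromosomes of a few hundred
kbp, tiny 18–23 nt "pigmy" spliceosomal introns, intergenic spacers around a
hundred bp, and — in some lineages — long, nearly identical sub-telomeric
repeats, homogenized by recombination, that secondarily expand an otherwise
shrinking genome. Comparing two of them means answering a fixed set of
structural questions, and this package implements each one as a
tibble-returning verb:

| question | verb |
|---|---|
| where do the terminal repeats end? | `detect_subtelomeric_repeats()` |
| what tandem unit marks the repeat boundary? | `detect_tandem_array()` (degenerate IUPAC consensus) |
| how is GC distributed? | `gc_profile()`, `region_gc()` |
| how big are spacers and proteins, and do they differ? | `intergenic_spacers()`, `protein_length_stats()`, `welch_t_test()` |
| how many genes are there after collapsing multicopies? | `collapse_redundant()` |
| where are the introns and what do they look like? | `catalog_introns()`, `intron_size_distribution()`, `classify_boundaries()`, `splice_signal_matrix()`, `call_junctions()` |
| which intron positions are conserved between orthologues? | `align_proteins()`, `compare_intron_positions()`, `polarize_introns()` |
| how much gene order survives? | `gene_order()`, `detect_synteny_blocks()`, `synteny_stats()` |
| which genes are shared / core? | `set_overlap()`, `core_set()`, `core_overlap()` |
| how do sub-telomeric and internal genes differ in expression? | `gene_depth()`, `expression_contrast()`, `estimate_copy_number()` |

`run_comparison()` chains all stages into one report object with `tidy()`,
`glance()` and `autoplot()` methods. A seeded synthetic generator
(`simulate_genome_pair()`, `simulate_coverage()`,
`simulate_junction_reads()`) produces genome pairs with the full statistical
structure above *plus a ground-truth record*, so every detector can be
scored exactly; it is first-class, tested code, and its defaults encode the
published study conditions (49.4% repeat GC over 24% internal, a 36-nt
`RTAYCTRGTTRCCTTATCGTATGCCATGGCTTTATC` boundary repeat at 5–29 copies, 19-nt
modal introns at 58.3% phase 0, spacer means 147.4 vs 82.1 bp, a 2,500-fold
sub-telomeric expression deficit, a collapsed 5-copy internal repeat).

Formats: FASTA + GFF3 in and out (`read_genome()` / `write_genome()`),
coverage as bedGraph, junction evidence as SAM, family tables and all
reports as TSV.

## Worked example

```r
library(nucleomorphr)

cfg    <- generator_config()                       # desk-scale defaults
sim    <- simulate_genome_pair(cfg, seed = 1)
cov    <- simulate_coverage(sim$genome_a, sim$truth, cfg, seed = 2)
report <- run_comparison(sim$genome_a, sim$genome_b, sim$families,
                         coverage_a = cov)
report
#> <nm_report> genomeA vs genomeB
#>   genomeA: 60,000 bp, GC 34.4%, 99 genes, 61 introns, mean spacer 321.1 bp
#>   genomeB: 60,000 bp, GC 34.5%, 99 genes, 71 introns, mean spacer 317.4 bp
#>   repeats: 6 + 6 regions
#>   introns shared/comparable: 51 of 55/66
#>   synteny blocks: 6 (mean 5.17 genes)
```

Reading the output: all six planted terminal repeats were detected in each
genome; 55 and 66 introns passed the Roy–Penny comparability filter (15
gap-free flanking residues at > 50% identity on both sides of the host
codon) and 51 positions are shared — identical alignment column and phase in
both genomes; the planted synteny blocks were recovered. GC, gene, intron
and spacer figures are genome-wide summaries; the high overall mean spacer
reflects repeat-boundary gaps, while spacers between internal single-copy
genes average the configured 147.4 bp (genome A) and 82.1 bp (genome B).

```r
tidy(report)
#> # A tibble: 8 × 4   (first rows)
#>   stage   metric               genome      value
#> 1 summary total_size           genomeA 60000
#> 2 summary gc_overall           genomeA     0.344
#> 3 summary gc_excluding_repeats genomeA     0.263
#> 6 summary n_nonredundant_genes genomeA    47

report$expression$contrast
#> # A tibble: 1 × 6
#>   mean_a mean_b ratio ratio_infinite n_zero_a n_zero_b
#> 1   110. 0.0400 2758. FALSE                 0        0
```

The detected internal : sub-telomeric depth ratio (2,758 here; the report's
internal group also contains the planted 5-copy repeat gene) recovers the
configured 2,500-fold contrast; restricting to truth-labelled single-copy
genes lands within 10% of 2,500 (the tests do exactly that).

The 36-nt boundary repeat, straight from its printed consensus:

```r
unit <- chartr("RY", "AC", "RTAYCTRGTTRCCTTATCGTATGCCATGGCTTTATC")
detect_tandem_array(strrep(unit, 10), unit_range = c(2, 60), min_copies = 3)
#> # A tibble: 1 × 6
#>   unit_length consensus        copy_number match_fraction start   end
#> 1          36 ATACCTAGTTACC...        10              1       1   360
```

Real genome pairs enter the same way: `read_genome()` on FASTA + GFF3 (gene
categories in a `category=` attribute, families via a four-column TSV
family table), `read_bedgraph()` for coverage, and a SAM of spliced
alignments for `call_junctions()`. Genome-scale headline numbers (total
sizes, intron totals, non-redundant counts, block counts) are properties of
the deposited sequences and are reproduced only when those are supplied.

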