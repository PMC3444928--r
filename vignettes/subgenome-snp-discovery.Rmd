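---
title: "Sub-genome-aware SNP discovery in allopolyploid amplicon panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-genome-aware SNP discovery in allopolyploid amplicon panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In an allopolyploid such as hexaploid tall fescue (2n = 6x = 42; one
meadow-fescue-derived sub-genome P and two *glaucescens*-derived sub-genomes
G1 and G2), any locus amplified by a single primer pair yields a mixture of
six haplotypes: two allelic copies of each of three homoeologous
sub-genomes. Fixed differences between sub-genomes — homoeologous sequence
variants (HSVs) — are typically an order of magnitude more frequent than
allelic SNPs segregating *within* a sub-genome, and if reads from all
sub-genomes are pooled they masquerade as SNPs. Because HSVs date to the
polyploidisation events they are invariant across germplasm, so markers
designed on them are useless for breeding. `polysnp` implements a rule-based
pipeline that decomposes haplotype complexity *before* calling variants:

1. demultiplex barcode-tagged amplicon reads and assign them to amplicon
   templates (approximate e-value ≤ 0.001);
2. assemble one **reference genotype per morphotype panel** into putative
   sub-genome consensus contigs by stringent overlap clustering
   (97% identity over ≥ 100 bp, ≥ 5 reads per contig, singletons saved);
3. attribute contigs to amplicons via progenitor ortholog sequences
   (80% / 10 bp), falling back to the amplicon templates;
4. detect HSVs by pairwise comparison of co-attributed contigs (80% /
   ≥ 10 bp), within and between the morphotype reference assemblies;
5. map every panel genotype's reads to the reference contigs (> 50 bp
   overlap at 80% identity), tabulate nucleotide variants per genotype
   (support ≥ 2 reads and ≥ 20% of site depth);
6. qualify SNPs: substitutions present in more than one but not all panel
   genotypes, not co-located with HSVs, outside the terminal 10 bp of a
   contig; indels are never SNPs;
7. classify variants fixed within each morphotype but differing between
   morphotype reference assemblies as diagnostic;
8. attribute SNP-bearing contigs to progenitor sub-genomes with
   neighbour-joining trees of the contig plus progenitor orthologs.

Dosage-based co-dominant genotype calling from two-channel intensity ratios
and Dice/UPGMA diversity analysis complete the toolkit.

## The stringent assembler

Greedy overlap clustering with the stated stringency cannot by itself
separate sub-genomes at the observed HSV density: one HSV per 109 bp is
~0.9% divergence, i.e. ~99.1% identity, far above the 97% identity
threshold. Production assemblers resolve such co-assembled repeats through
*column conflicts*, and `cluster_reads()` does the same:

* reads join the first existing cluster whose running consensus they match
  at ≥ 97% identity over ≥ 100 columns (identity = matches / aligned
  columns, gaps counted); the running consensus is extended by read
  overhangs and recomputed at every 25% membership growth;
* finished clusters are re-examined for **confirmed conflict columns** —
  two bases each carried by ≥ 3 members. A split at such a column is
  accepted only when the two vote-assigned sides are phase-separated at
  ≥ 2 candidate columns (or at one column with ≥ 5 reads on both sides) and
  the larger side can still form a contig. The multi-column requirement
  stops an isolated heterozygous substitution from shattering a sub-genome
  group, while co-assembled sub-genomes, which disagree at several
  correlated columns, are separated;
* split subgroups that resolve to the same consensus (a haplotype divided
  by read span) are reunited; thin subgroup termini are filled from the
  parent cluster pileup so homoeologous contigs keep equal length — a
  truncated contig would otherwise lose its reads to full-length siblings
  at the mapping stage, distorting every allele fraction downstream;
* clusters below 5 members dissolve into the singleton set, mirroring the
  minimum-reads rule of the emulated assembly protocol.

Consensus calling is column-majority over the member pileup; ties become
IUPAC codes in `consensus()`, but the pipeline's reference contigs use the
lexicographically smallest base instead, so that mapping has an unambiguous
A/C/G/T reference and the alternative allele surfaces as a variant.

Two consensus-level artefacts matter enough to correct explicitly. First, a
reference genotype heterozygous at an allelic site gives a ~50/50 column
whose majority is a coin flip; if the consensus lands on the variant
allele, the contig then differs from its homoeologous siblings at that
column and the site would be discarded as an HSV. `polish_het_columns()`
therefore sets confirmed heterozygous columns (both alleles ≥ 2 member
reads) to the allele shared with the sibling contigs — the ancestral,
reference state of the sub-genome. Second, a column flagged by contig
comparison is only a *fixed* homoeologous difference if the alternative
allele is present in essentially every genotype; `qualify_snps()` overrides
the HSV rejection when at least one genotype with site depth ≥ 3 carries
not a single read of the allele (segregation confirmed). Cross-reference
flags corroborated by the partner assembly's own within-genotype comparison
are exempt from the override: those columns are homoeologous with
independent evidence, and typically arise where one reference co-assembled
a sub-genome pair that the other decomposed.

## The synthetic data generator

`simulate_population()` emulates the study design end to end and returns the
full ground truth, so every stage is testable without external data. Per
amplicon, one ancestral sequence (uniform base composition) gives rise to
the three sub-genome references by independently placed substitutions; the
per-lineage rate is calibrated so the expected pairwise differing-column
density equals `hsv_rate` (default 1/109 per bp). Key parameters:

| parameter | default | meaning |
|---|---|---|
| `amplicon_length` | 500 bp | target PCR product size |
| `hsv_rate` | 1/109 per bp | pairwise sub-genome difference density |
| `snp_rate` | 10 per amplicon per panel | Poisson mean of planted qualifying SNPs |
| `diagnostic_rate` | 1 per amplicon | Poisson mean of morphotype-fixed variants |
| `n_genotypes_per_morphotype` | 6 | panel size |
| `depth` | 25 reads/genotype/amplicon | exact-count or Poisson |
| `read_length` | 400 bp | Titanium-era pyrosequencing read |
| `sub_error` | 0.005 per bp | uniform substitution errors |
| `homopolymer_indel_rate` | 0.005 per bp | indels inside/adjacent to runs ≥ 3 |
| `primer_length` | 20 bp | variation-free primer landing sites |
| `carrier_freq` | 0.5 | per-allele-copy carrier probability |
| `progenitor_divergence` | 0.003 per bp | drift between sub-genome and its contemporary progenitor |

Design choices worth spelling out:

* **Read starts are anchored at the amplicon ends** (`read_start = "ends"`):
  an amplicon library is sequenced from its ligated adapters, so reads
  cover `[1, read_length]` or `[L - read_length + 1, L]`. A uniform-offset
  mode is retained, but it leaves the outer 20% of each amplicon under a
  thin coverage ramp that no amplicon protocol actually produces.
* **Primer landing sites are variation-free**: one primer pair only
  amplifies all three sub-genomes because it sits on conserved sequence,
  and the primer overwrites the template there during PCR. No HSVs, SNPs
  or diagnostics are planted within the terminal `primer_length`.
* **SNP carriers** are drawn by giving each of a genotype's two allele
  copies the alternative base with probability `carrier_freq`, resampling
  until the carrier count lies in `[2, n − 1]` — the truncated-binomial
  count distribution is the test oracle. This is a stand-in, not an
  inference about any real panel's allele-frequency spectrum.
* Barcodes are generated at pairwise Hamming distance ≥ 3 and never
  error-perturbed, keeping exact-match demultiplexing a clean oracle;
  qualities are constant because the pipeline does not use them.
* Reads are emitted forward-strand by default (`strand = "both"` flips a
  fair coin; the pipeline orients reads from the template-assignment
  strand).

What passing tests on this generator do **not** show about real data:
PCR chimeras, paralogous gene families, copy-number differences between
sub-genomes, flowgram-specific error structure, and barcode synthesis
errors are all absent. The generator's coverage is also far more uniform
than the 9–146 reads per amplicon spread seen in practice.

## Distances, trees and attribution

`distance_matrix()` offers p, JC69 (−3/4·ln(1 − 4p/3)) and K2P distances
over pairwise-comparable sites (gap/ambiguity columns excluded per pair);
the composite-likelihood distance of the emulated workflow is a
tool-specific estimator whose replication adds nothing here, because
attribution depends on *relative*, not absolute, distances.
`nj_tree()` is a plain Saitou–Nei implementation (Q-criterion, lowest-index
tie-break, negative branch estimates clamped to zero with a flag);
it is cross-checked in the tests against an independent exhaustive
minimum-evolution search and against `ape::nj()`. `assign_subgenome()`
operationalises "relationships within the tree" as a nearest-progenitor
patristic rule: assign the closer progenitor class when it undercuts the
other by a 10% relative margin *and* the two distances differ by more than
`abs_margin = 0.005` substitutions/site (≈ 2 substitutions over an
amplicon) — below that resolution no attribution is attempted. With only
one progenitor class in the tree, it is assigned only to its direct sister
leaf.

`upgma()` is the classical size-weighted agglomeration with merge height
d/2 and lexicographic tie-breaks (cross-checked against average-linkage
`hclust`); `dice_matrix()` uses pairwise deletion for missing scores, and
the binary encoding is per-allele (one 0/1 column per observed allele).

## Dosage calling

Theta — the B-allele fraction of the amplified copies — replaces raw
two-channel ratios; its expected value under dosage *d* of *2k* amplified
copies is d/2k. Cluster centres are therefore fixed a priori
({0, 1/2, 1} when a single sub-genome amplifies; {0, 1/6, 2/6} with all
three amplified and one polymorphic; {0, …, 4/6} with two polymorphic) and
samples are assigned to the nearest centre, optionally after one round of
per-cluster mean refitting to absorb channel bias. Free clustering is
deliberately avoided: the centres carry the dosage meaning. Locus
clustering behaviour is categorised by occupied-centre count and a
silhouette-like separation score (dispersed below 0.70 — a declared
parameter, not an inferred value); loci with > 50% missing intensities are
failed. Cross-assay concordance collapses co-dominant calls to the allele
set each detects and excludes missing data from numerator and denominator.

## Numerical and procedural conventions

* Internal coordinates are 0-based half-open; every emitted report is
  1-based inclusive. Report rows are sorted lexicographically so identical
  tables are byte-identical files.
* Alignment scoring defaults to match +2 / mismatch −3 / gap open 5 /
  extend 2; the template-assignment e-value uses configurable
  Karlin–Altschul-style constants (λ = 0.5, K = 0.3) calibrated only to
  separate clear accepts from clear rejects at the 0.001 threshold.
* Threshold comparisons are inclusive (≥) by default; `strict_gt`
  switches the "greater than 50 bp overlap" reading to strict.
* Diagnostic classification pairs contigs across the two reference
  assemblies by greedy descending-score one-to-one matching, so each
  contig is compared with its same-sub-genome counterpart; unmatched cross
  pairs feed the HSV mask instead.
* All randomness is seeded; an identical run configuration reproduces a
  byte-identical output inventory (checked by manifest hash).

## Problem sizes

The bundled end-to-end benchmark uses 20 amplicons × 500 bp, two panels of
six genotypes, depth 25, 0.5% substitution and 0.5% homopolymer-indel
error — about 6,000 reads — and completes in a few minutes on one core.
Degenerate checks use 3 amplicons at depth 36 so that every sub-genome is
represented by ≥ 5 reads with near certainty; the assembler decomposition
property uses 100 seeded amplicons of error-free reads.

## Known limitations

* With ~8 reads per sub-genome per amplicon, a sub-genome occasionally
  falls below the 5-read contig minimum; its reads then map onto the
  sibling contigs, where fixed differences are mostly absorbed by the
  ubiquity and HSV rules but the sub-genome's own SNPs are diluted and
  can be missed. This is the dominant sensitivity loss of the default
  benchmark (~8% of planted SNPs).
* Diagnostic classification inherits every pairing mistake between
  reference assemblies; when a sub-genome is missing on one side, its
  contig pairs across sub-genomes and fixed homoeologous differences leak
  into the diagnostic class. A low validation rate for diagnostic
  candidates is consistent with what dedicated assays show for this class.
* The greedy assembler is order-dependent in principle; the tests bound
  this by shuffling reads under fixed seeds rather than assuming it away.
* `G1` cannot be reliably distinguished from `G2`; attribution reports
  only P versus G.
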