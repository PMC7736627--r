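# mitocomp

Comparative mitogenomics of the three *Sebastiscus* rockfishes —
*S. tertius* (MT117231, 16,910 bp), *S. albofasciatus* (MT117230,
17,056 bp) and *S. marmoratus* (MT789709, 17,580 bp) — as a tested,
reusable R pipeline. It is written for molecular ecologists and
phylogeneticists who work with circular vertebrate mitochondrial
genomes and want every step of a standard comparative-mitogenome paper
to be reproducible library code rather than a chain of GUI tools.

## What it computes

Each stage corresponds to one analysis of the study system:

* **Gene-table accounting** — feature sizes (`end − start + 1`), signed
  intergenic spacers (`start₂ − end₁ − 1`, negative = overlap), and the
  canonical 37-gene complement audit (13 PCGs, 22 tRNAs, 2 rRNAs, plus
  O<sub>L</sub> and D-loop). The published annotation tables for all
  three species ship with the package (`rockfish_annotation()`).
* **Composition** — A+T%, AT-skew `(A−T)/(A+T)` and GC-skew
  `(G−C)/(G+C)` over genomes, regions and codon-position partitions;
  IUPAC motif scanning (e.g. the conserved `GCCGG` of the replication
  origin).
* **Codon usage** — coding records under the vertebrate mitochondrial
  code (transl_table 2) with incomplete-stop handling (trailing T/TA),
  RSCU `n_i·X_ij / Σ_j X_ij`, and amino-acid usage.
* **Divergence** — p-distances partitioned into codon positions 1+2 vs
  3, and Nei–Gojobori (1986) Ka/Ks with Jukes–Cantor correction
  (`d = −¾·ln(1 − 4p/3)`) and purifying/neutral/positive
  classification.
* **Control-region repeats** — a deterministic lag-seeded tandem-repeat
  detector reporting unit length, fractional copy number, consensus and
  identity.
* **Phylogenetics** — concatenated 13-PCG supermatrix, closed-form TN93
  distances, Saitou–Nei neighbor joining with seeded bootstrap, Newick
  I/O, and clade-constraint checks (sister pair, genus monophyly).
* **Synthetic data** — a seeded generator that emits full mitogenomes
  with the *S. tertius* layout, stop-free ORFs, planted control-region
  repeats and codon-level evolution under per-gene dN/dS, plus a
  ground-truth ledger, so the whole pipeline is testable offline.

## Worked example

```r
library(mitocomp)

tab <- rockfish_gene_table("ST")          # S. tertius, MT117231
tab
#> gene_table: 39 features, genome length 16910 bp
#> complement: PCG=13 tRNA=22 rRNA=2 origin=1 control=1

f <- tab$features
intervening_spacer(f[f$name == "ATP8", ], f[f$name == "ATP6", ])
#> [1] -10        # the published 10-bp ATP8/ATP6 overlap

ds <- simulate_dataset(simulation_config(seed = 1))
aud <- start_stop_audit(ds$genomes$tertius)
head(aud[, c("gene", "start_codon", "stop_codon", "aa_length")], 4)
#>      gene start_codon stop_codon aa_length
#> ND1   ND1         ATG        TAG       324
#> ND2   ND2         ATG         TA       348
#> COI   COI         GTG        TAA       516
#> COII COII         ATG          T       230
sum(aud$aa_length)
#> [1] 3800        # sense codons over the 13 PCGs, starts in, stops out

round(sort(kaks_table(ds$genomes)$gene_means, decreasing = TRUE)[1:4], 3)
#>  ND4L  ATP8   ND2   ND1
#> 0.142 0.122 0.090 0.046   # all < 1: purifying selection throughout

repeat_report(ds$root)[, c("region", "period", "copies", "identity")]
#>   region period   copies identity
#> 1 D-loop     22 6.090909 0.987013   # planted 22 bp x 6 unit recovered
```

The numbers mean: the bundled *S. tertius* table reproduces the
published genome length and gene complement; the simulated congeners
keep the published start/stop conventions (GTG only for COI, incomplete
stops as trailing T/TA) and the 3,800-residue total; NG86 sees strong
purifying selection on every gene (ratios well below 1); and the
detector recovers the control-region repeat the generator planted.

## The analysis workflow

Numbered drivers under `analysis/` rerun the full study on synthetic
data and write tables to `results/`:

```sh
Rscript analysis/01_feature_accounting.R   # sizes, spacers, complement
Rscript analysis/02_simulate.R             # synthetic congeners + outgroup
Rscript analysis/03_composition_codon.R    # skews, RSCU, start/stop audit
Rscript analysis/04_divergence.R           # p12/p3 distances, Ka/Ks
Rscript analysis/05_repeats.R              # control-region repeat survey
Rscript analysis/06_phylogeny.R            # supermatrix, TN93 + NJ + bootstrap
```

`analysis/01` runs on the bundled real coordinate tables; the others
consume the synthetic dataset from `analysis/02`, so everything works
without network access. The methods vignette
(`vignettes/comparative-mitogenomics.Rmd`) documents the models,
parameter choices, and known limitations.

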