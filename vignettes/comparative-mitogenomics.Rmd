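---
title: "Comparative mitogenomics of Sebastiscus rockfishes: models and methods"
author: "mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics: models and methods}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The study system and what this package computes

The three rockfishes *Sebastiscus tertius* (accession MT117231),
*S. albofasciatus* (MT117230) and *S. marmoratus* (MT789709) carry
circular mitochondrial genomes of 16,910, 17,056 and 17,580 bp with the
canonical vertebrate complement: 13 protein-coding genes (PCGs), 22
tRNAs, 2 rRNAs, one light-strand replication origin (O~L~) and one
control region (D-loop), in the standard order from tRNA-Phe to the
D-loop. `mitocomp` re-implements, as tested library code, the complete
comparative analysis of such genomes:

* gene-table accounting (sizes, intergenic spacers and overlaps,
  complement audit);
* base composition, A+T content and AT/GC skew over genomes, regions and
  codon-position partitions, plus IUPAC motif scanning;
* codon extraction under the vertebrate mitochondrial code
  (transl_table 2), start/stop identification including incomplete
  stops, RSCU and amino-acid usage;
* codon-position-partitioned p-distances and Nei–Gojobori (1986) Ka/Ks
  with Jukes–Cantor correction and selection classification;
* tandem-repeat detection in the control region;
* a concatenated-PCG supermatrix, TN93 distances, neighbor joining with
  bootstrap, and topology-constraint checks;
* a seeded synthetic-mitogenome generator with a ground-truth ledger, so
  every stage is testable without downloading accessions.

The bundled annotation tables (`rockfish_annotation()`) reproduce the
published feature summary verbatim, including its printed Size,
Intervening-spacer, amino-acid and start/stop-codon columns.

# The coordinate model

Coordinates are 1-based inclusive throughout, matching the published
tables; feature size is `end - start + 1` and the signed spacer between
adjacent features is `start2 - end1 - 1` (negative values are overlaps,
e.g. ATP8/ATP6 overlap by 10 bp and ND5/ND6 by 4 bp). No feature wraps
the circular origin in this genus — the D-loop is last and ends at the
genome length — so wrap-around features are rejected with a clear error
rather than modelled. Strands are labelled H (heavy) and L (light),
mapped to `+`/`complement(...)` in the GenBank dialect. Element names
are resolved against a frozen registry with aliases (`ATPase6` ≡
`ATP6`, `Cyt b` ≡ `CYTB`, `COX1` ≡ `COI`, ...) because annotation
sources mix these conventions.

**A note on the published size column.** The three coordinate columns,
the spacer column and the size column of the published table are
mutually redundant, and in six cells (one in *S. tertius*, five in
*S. albofasciatus*, all tRNAs) the printed size disagrees with its own
coordinates. In every such cell the independently printed spacer column
confirms the coordinates, so the package treats coordinates as
authoritative and `analysis/01_feature_accounting.R` lists the
discrepant cells explicitly (111 of 117 size cells agree; all 114
spacer cells agree). The printed tRNA size range 65–74 bp includes one
of the misprinted cells; coordinate-derived tRNA sizes span 67–74 bp.

# Composition and skew

AT-skew is `(A − T)/(A + T)` and GC-skew `(G − C)/(G + C)`; A+T content
is a percentage of unambiguous bases. Ambiguity codes are excluded from
all counts and skew denominators and reported separately: a skew whose
denominator is zero is *undefined* (`NA`), never 0. Codon-position
partitions concatenate the 13 PCGs in table order on their coding
strands (ND6 reverse-complemented), drop incomplete terminal stop bases
— because a partial codon has no defined third position — and keep
complete stop codons. Region and whole-genome summaries are computed on
the H strand.

# Codon usage

Under transl_table 2, TGA encodes Trp, ATA encodes Met, and AGA/AGG are
stops; GTG and ATA at gene position 1 are initiators read as Met. Seven
genes (ND2, COII, ATP6, COIII, ND3, ND4, CYTB) end in incomplete stops
(a trailing T or TA completed to TAA by polyadenylation): a PCG whose
length mod 3 is 1 or 2 contributes that trailing fragment as its stop.
Sense-codon counts therefore satisfy, per gene,
`3 * aa_length + nchar(stop) = size`; summed over the 13 PCGs this
yields exactly 3,800 amino acids for each of the three species, start
codons included and stops excluded (the reading under which the
published per-gene amino-acid column sums to its printed total).

RSCU for codon *j* in family *i* of size *n~i~* is
`n_i * X_ij / sum_j X_ij`; family sums equal *n~i~* whenever the family
is observed, and unobserved families are flagged rather than divided by
zero. Six-fold Leu and Ser are split 2+4 by tRNA family
(Leu(UUR)/Leu(CUN), Ser(UCN)/Ser(AGY)) by default — the convention in
which RSCU is usually plotted — with `split_families = FALSE` to pool.
Stop codons are excluded from RSCU and amino-acid usage.

# Divergence: p-distances and Ka/Ks

p-distances use pairwise deletion (sites where both sequences carry
unambiguous bases). The codon-position partition pools positions
{1, 2} (`p12`) against position 3 (`p3`); because the congeners' genes
are length-identical, a frame-checked concatenator stands in for an
aligner, and any length mismatch is an error instructing external
alignment.

Ka/Ks uses Nei–Gojobori (1986) counting. Per codon, each position
contributes the fraction of its three possible single-base changes that
are synonymous; changes creating a stop count as nonsynonymous, which
makes `S + N = 3 × codons` an exact identity (sites are averaged over
the two sequences). Codons differing at 2–3 positions are resolved by
averaging over all minimal substitution pathways with equal weights,
excluding pathways through stop codons (if every pathway is blocked,
the exclusion is dropped for that pair — a rare degenerate case).
Proportions are Jukes–Cantor corrected, `d = −(3/4)·ln(1 − 4p/3)`,
undefined at `p ≥ 3/4` and flagged. The ratio is undefined when
`Ks = 0` (flagged); otherwise selection is classified purifying/neutral/
positive by comparison with 1 (neutrality band 1e−9). The original
study does not name its Ka/Ks estimator, so its printed means are
treated as soft reference points, not exact targets; NG86+JC is the
canonical counting choice.

A validation note: NG86 assumes an unbiased mutation process. The
parameter-recovery tests therefore run the codon evolver at κ = 1
(matched model), where the estimator's mean over replicates falls
within 25% of the simulated ω; under strong transition bias (κ ≈ 4,
the generator's default for realistic data) NG86 systematically
underestimates ω, a known property of the counting method, not a
defect of this implementation.

# Tandem repeats

The published analysis used Tandem Repeats Finder only for unit length
and copy number, so `mitocomp` specifies a simpler, fully deterministic
detector instead of reproducing TRF's scoring. Candidates are seeded by
self-match runs at lag *p*; runs tolerate mismatch gaps up to
`max(3, p/10)`, are trimmed to their maximum-scoring subsegment
(match = +1, mismatch = −min_identity/(1−min_identity), so a segment at
exactly the identity threshold scores zero — this stops chance matches
in the flanks from inflating the array), and span `[i1, i2 + p]` with
copy number `(span + p)/p`. A majority-rule consensus (ties towards the
alphabetically first base) gives the unit; if the consensus is itself
periodic with a divisor *d* at the identity threshold, the call is
collapsed to the fundamental period *d*. Chance hits are controlled by
a binomial E-value on the number of lag matches (null self-match
probability from base frequencies, clamped to [0.25, 0.6], Bonferroni
scaled over all start × period candidates; default cutoff 0.01 — set
`max_evalue = Inf` for toy sequences shorter than the detection limit).
Overlapping calls are resolved by highest copies × identity, then
smaller period, then smaller start. Defaults: `min_period 10`,
`max_period 600`, `min_copies 1.8`, `min_identity 0.8`.

The detector models substitution noise only. Indel handling by banded
alignment was considered and omitted: slipped-strand repeat copies are
near-perfect, the generator plants substitution noise only, and the
downstream consumers use only unit length and copy number. Copy numbers
are reported fractional (whether the published copy counts include
partial terminal copies is unstated).

# Phylogenetics

The supermatrix concatenates the 13 PCGs in canonical order, coding
strands, incomplete stops trimmed (11,418 columns for this genus'
profile). TN93 distances are computed from the closed form with
empirical base frequencies and the two transition classes separated;
saturation (non-positive logarithm argument) is flagged rather than
silently truncated. Gamma and invariant-site corrections are omitted:
the published model selection chose TN93+G+I, but the shape parameter
is unpublished, and topology — not branch lengths — is the claim this
package reproduces. Neighbor joining implements the Saitou–Nei Q
criterion with a deterministic lexicographic tie-break and clamps
negative branch lengths to zero (deficit recorded). On additive
matrices NJ provably recovers the generating topology; the test suite
exercises this on seeded random trees of up to 8 taxa. Bootstrap
resamples columns with replacement under a fixed seed; support is the
percentage of replicate trees containing each internal bipartition of
the full-data tree, and trees are stored unrooted (rooting is a display
operation). The published ML/BI machinery (MEGA, MrBayes) is
deliberately not reimplemented; the in-repo surrogate's acceptance
surface is the pair of topology constraints — *S. tertius* +
*S. albofasciatus* sister, the three congeners monophyletic against an
outgroup — checked as bipartitions of the unrooted tree.

# The synthetic-mitogenome generator

`simulation_config()` fixes the study conditions; its defaults are the
package's reference scenario and are not tuned per analysis:

* **Layout**: the 39-element *S. tertius* size profile. Published
  *overlaps* are replaced by zero spacers (root genome 16,938 bp):
  overlapping stop-free ORFs in two reading frames would require a
  constraint solver and buy no additional testing power, and all
  size-arithmetic tests run identically on the synthetic layout.
  Spacer-arithmetic tests run against the bundled real tables instead.
* **Composition**: A+T 55%, AT-skew +0.1, GC-skew −0.25, the rockfish
  whole-genome regime. Sense codons are drawn from an
  independent-position distribution with stops removed; because the
  four A/G-rich stop codons carry probability mass, the per-position
  base probabilities are calibrated iteratively so the realized codon
  marginal matches the targets. Composition bias is modelled as a
  genome-strand property: L-strand genes draw codons whose reverse
  complement matches the target, so their coding strands show inverted
  skew — as real L-strand genes do. One simplification relative to real
  data: the same composition target applies to all regions, whereas
  real PCG, rRNA and control regions differ in content and the real
  coding strands of H-genes are T-skewed. Passing tests therefore
  validate the statistics' arithmetic, not the biological heterogeneity
  of real genomes.
* **ORFs and conventions**: every PCG is a stop-free ORF; COI starts
  GTG, everything else ATG; the seven incomplete-stop genes end T/TA;
  the O~L~ contains exactly one GCCGG block; the D-loop carries a
  planted tandem repeat (default 22 bp × 6 copies at 2% per-base noise,
  the *S. tertius* pattern; 275 × 2 and 269 × 4 mirror the congeners).
* **Evolution**: single-base HKY proposals (default κ = 4) arrive as a
  Poisson process at `branch length × genome length` per branch.
  Proposals in PCGs are rejection-sampled: synonymous accepted,
  nonsynonymous accepted with the gene's ω (defaults span 0.013–0.188,
  strongest purifying on ND3/ATP6/CYTB, weakest on ND2/ATP8), stop
  creation rejected; start and stop codons are frozen so leaf genomes
  keep the published conventions. Branch lengths are therefore proposal
  rates: realized substitution rates are lower in coding regions, which
  is immaterial because every test compares against the ledger's
  realized counts, not the nominal branch length. RNA and non-coding
  sites accept all proposals. Indels, rate heterogeneity (+G+I) and
  recombination are not modelled.
* **Determinism**: one root seed; each branch derives a substream seed
  `(seed × 1009 + 97 × edge) mod (2^31 − 1)`. Same seed and config give
  byte-identical output.

The ledger records the planted repeat coordinates, composition targets
and per-branch, per-gene accepted synonymous/nonsynonymous counts —
sufficient to recheck every downstream property without re-simulation.

# Problem sizes and numerical choices

The shipped analyses and tests use: full-length (~17 kb) genomes for
all whole-genome statistics; 500-codon genes, two branches of 0.2 and
20 replicates for dN/dS recovery; 20 seeded control regions for repeat
recovery; 100 random additive matrices of 4–8 taxa for NJ consistency;
and 100–1000 bootstrap replicates (1000 in the analysis scripts,
matching the published setting; fewer in unit tests). Floating-point
policy: exact integer arithmetic wherever the quantity is a count
(sites, sizes, spacers); NG86 site sums are exact fractions of thirds;
JSON reports serialize at 6 significant digits; NJ tie-breaks and
repeat-consensus ties are resolved lexicographically so all outputs are
deterministic.

# Limitations

* No de novo annotation: gene tables are validated, not inferred from
  raw sequence (the original genomes were annotated by homology).
* tRNA secondary structure, O~L~ hairpins and repeat-unit folding are
  out of scope, as are Bayesian inference, model selection by BIC and
  divergence-time estimation.
* Cross-family supermatrices (unequal gene lengths) require externally
  aligned input; the package checks frames and lengths but does not
  align.
* Accession-dependent quantities (e.g. the published whole-genome A+T
  of 55.15/55.04/55.30%) require the NCBI records; the package computes
  them from any supplied FASTA/GenBank input but does not download.

# Reproducing the analyses

```{r}
# from the repository root
# Rscript analysis/01_feature_accounting.R
# Rscript analysis/02_simulate.R
# Rscript analysis/03_composition_codon.R
# Rscript analysis/04_divergence.R
# Rscript analysis/05_repeats.R
# Rscript analysis/06_phylogeny.R
# Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
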