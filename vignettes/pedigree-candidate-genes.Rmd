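---
title: "Tracing trait genes through a breeding pedigree: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing trait genes through a breeding pedigree: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedscan)
```

`pedscan` reconstructs how elite alleles moved through a crop breeding
pedigree and which genes they implicate. This vignette is the package's own
account of the underlying models, the assumptions each stage makes, the
tunable parameters and their defaults, and the places where the design was
genuinely open and a choice had to be made. The running system is an elite
Sea Island cotton fiber-strength pedigree: near-inbred accessions, an
allotetraploid genome split into At and Dt subgenomes, fiber quality
measured in cN·tex⁻¹ across replicated field environments, and fiber
transcriptomes sampled across developmental stages (days post anthesis,
DPA).

## Genotype model and variant filtering

All analyses start from a `GenotypeMatrix`: biallelic SNPs (sites ×
accessions) with calls in {hom ref, het, hom alt, missing}. Indels and
multiallelic records are excluded at parse time; the material is
near-inbred, so heterozygous calls are rare and mostly reflect residual
heterozygosity or artefacts. The filter defaults are the standard
resequencing thresholds for this kind of panel: site quality ≥ 20 (phred),
per-genotype depth ≥ 4 where depth is available, per-site missingness ≤
20%, and MAF > 0.05 computed from called alleles (a heterozygote
contributes one allele of each class). Depth masking applies only when the
VCF carries DP — the thresholds originate in variant calling and cannot be
re-derived from a genotype-only file. Missingness caps of 10% are sometimes
used for population-structure work; structure analyses are out of scope
here, so 20% is the default and the knob is exposed.

## Windowed diversity and sweep blocks

Per-site diversity is the average pairwise difference among sampled
alleles: with reference and alternate allele counts $c_R$ and $c_A$ and
$n = c_R + c_A$,
$$\pi_{site} = \frac{2\,c_R\,c_A}{n(n-1)},$$
zero when fewer than two alleles are called. Windowed θπ divides the sum of
site diversities by the full window span in bp, monomorphic positions
contributing zero — the convention of the standard VCF windowed-π tools, so
values are comparable to published per-bp estimates. Windows tile the
chromosome in non-overlapping 1 Mb steps by default; an explicit step was
only ever specified for the IBD scan, so tiling is the default and the
window size is a parameter. Low-diversity blocks are windows at or below
the empirical 5% quantile (type-7 linear interpolation), adjacent flagged
windows merged. Flagging on ≤ is conservative under ties: a degenerate
all-equal distribution flags everything, which the tests document
explicitly rather than hide.

## The IBD transmission scan

The scan asks, for each candidate ancestor, where a descendant's genome is
locally near-identical to that ancestor. Windows of 200 consecutive SNPs
advance by 20 SNPs (SNP-index space, not bp — density fluctuations should
not change the test's resolution); a window qualifies when the genotype
identity ratio is ≥ 0.99. Identity is *class* identity (hom ref / het /
hom alt), not allele sharing: for near-inbred lines the two notions almost
coincide, but class identity is the stricter reading of "same genotype" and
is fixed throughout. Sites with a missing call in either accession leave
both numerator and denominator, so low-coverage windows are not penalized;
windows with no jointly called site are skipped and logged.

Qualifying windows sharing a SNP index merge into fragments (step < window
guarantees consecutive qualifying windows overlap). A fragment's
`mean_identity` is the mean ratio of its qualifying windows — by
construction ≥ the threshold, which keeps the reported field meaningful
after merging. Fragment endpoints are resolved to one step (20 SNPs) when
the background is clearly below threshold and to one window in the worst
case; a boundary window tolerates $\lfloor(1-r)w\rfloor$ foreign SNPs, so
fragments can overhang true segment ends by a couple of SNPs — the test
suite asserts exactly these bounds. One consequence worth recording: total
fragment length is *not* monotone in the window size, because larger
windows tolerate proportionally more foreign SNPs at segment boundaries;
coverage is monotone in the identity threshold, and that is the invariant
the tests assert.

Attribution is deliberately naive-transparent: the genome is partitioned at
fragment boundaries, a region attributed to an ancestor only when that
ancestor's scan alone covers it; multiply-covered regions are labelled
`shared` and excluded from unique totals. When intermediates and their own
parents are both candidates, truly inherited material is shared along the
chain — the per-ancestor unique totals then measure *private* contributions,
which is what the pedigree summary reports. Summaries total bp per
ancestor, chromosome and subgenome (chromosome-name prefix A/D), report
each ancestor's share of the assembled genome, and both the genes
overlapped by fragments (any bp overlap with the transcript span — the
simplest defensible rule, since no stricter containment rule is canonical)
and the fraction of attributed sequence lying within genes.

## Variant effects

Effect classification is codon-level and strand-aware: the codon is
reconstructed across exon junctions in coding order, reverse-complemented
for minus-strand genes, translated with the standard nuclear code, and
compared. Categories follow the usual annotator vocabulary with precedence
CDS > splicing > UTR > intronic > upstream/downstream > intergenic, one
record per (SNP, gene) so a SNP inside two genes is never collapsed
arbitrarily. Splice sites are the first/last two intron bases. The
upstream/downstream flank is 2,000 bp — deliberately aligned with the
haplotype module's promoter definition rather than the 1 kb default of
common annotators, because internal consistency between the two modules
matters more than tool mimicry; it is configurable. Genes whose CDS length
is not a multiple of three are flagged and their coding variants labelled
`unknown`, never guessed. The classifier is validated against a
brute-force translate-and-compare oracle over all 64 codons × 3 positions ×
3 alternates × 2 strands (3,456 cases).

The *large-effect* predicate is exactly {nonsynonymous, stop-gain,
stop-loss}. Splicing variants are plausibly impactful but are not part of
the screen's definition, so the predicate excludes them.

## Haplotypes, effects, and the synergy ledger

A gene's haplotype concatenates the homozygous alleles at its large-effect
gene-body SNPs plus *all* SNPs in the 2 kb promoter (upstream of the
transcription start on the coding strand), ordered by position. Accessions
with any heterozygous or missing call at those SNPs are `unassigned`:
the lines are near-inbred and the analysis groups accessions discretely;
splitting heterozygotes would manufacture phantom groups. The two most
frequent strings form the main pair, the more frequent being the reference;
effects are elite-minus-reference, and the percent effect uses the
reference-group mean as denominator.

Phenotypes are averaged within accession across environments and replicates
before testing — the accession is the experimental unit, environment shifts
are common to all accessions in a trial, and mixed-model G×E is out of
scope. Group comparisons use Welch's unequal-variance two-tailed t-test
with no multiple-testing correction (single pre-specified contrasts).

For two loci, the `InteractionDecomposition` holds the 2×2 combination-mean
table and everything derivable from it: conditional effects (switching one
locus at a fixed level of the other), the total transition
$m(\text{elite},\text{elite}) - m(\text{ref},\text{ref})$, and two synergy
readings — against externally supplied or data-derived marginals, and
against the reference-context conditionals. The path-additivity identity
$\text{cond}_{A|refB} + \text{cond}_{B|eliteA} = \text{total}$ is exact
algebra on means and is asserted on random tables. Under the generative
model $y = \mu + \beta_A x_A + \beta_B x_B + \gamma x_A x_B$, the
combo-based synergy equals γ exactly at zero noise, which is the package's
recovery test. Missing combinations (real panels often populate only three)
make the conditionals that need them `NA`; nothing is imputed. Because the
minor locus's marginal effect can be small, its context dependence is also
reported as a percent reduction (reference context) and as both a fold and
a fold-excess (elite context) — "k times greater" claims are ambiguous
between the two, so both are emitted.

## Expression screen

Differential expression is a deliberate surrogate: the reusable content of
the published screen is its compound criterion — P < 0.05 and |log2 fold
change| > 1 — not the count model behind it, and the input here is an FPKM
matrix, not read counts. So the fold change is
$\log_2((\bar{F}_{high}+1)/(\bar{F}_{low}+1))$ on raw FPKM means and the
p-value a Welch t-test on log2(FPKM+1) replicates; the +1 pseudocount is
the fixed zero-handling convention. With fewer than two replicates per
group the fold change is still reported and the p-value (hence DEG status)
is undefined.

The co-expression network is the Pearson correlation of log2(FPKM+1) over
*all* samples, with an undirected edge when |r| meets the threshold.
No canonical threshold exists for this step, so `minAbsR` is a required
argument with no asserted default (examples and tests use 0.8). Hub ranking
implements ten of the twelve cytoHubba-family centralities — MCC, DMNC
(ε = 1.7), MNC, Degree, EcCentricity (reciprocal eccentricity), Closeness,
Radiality, Betweenness, Stress, and the local clustering coefficient — with
distance-based scores computed within connected components, and all of them
on the unweighted topology (signed correlation weights are kept as edge
metadata only). EPC and BottleNeck are excluded by default: their published
definitions are Monte-Carlo/underspecified, and a consensus over
deterministic methods is reproducible; the consensus is simply the mean of
dense ranks over whatever methods are enabled, ties broken by Degree then
gene id. Stress centrality enumerates shortest paths and is intended for
the panel-sized networks this screen works on (tens to hundreds of genes),
not for genome-scale graphs. Candidates are consensus hubs that are DEGs at
20 and/or 25 DPA — the secondary-wall-thickening window — with the
one-stage/two-stage distinction carried through.

## Gene sets

Trait gene lists from GWAS are consumed, not computed (the mixed-model
GWAS itself is out of scope); intersections are exact set operations with
id-space mismatches flagged rather than dropped. Pleiotropy is membership
in ≥ 2 trait sets, with a named fiber-quality × yield cross filter. The
final dossier collates every stage per gene and serializes
deterministically (sorted genes and fields), so reports are byte-identical
for identical inputs.

## The synthetic study

The generator produces data with the statistical structure the analyses
assume, plus exact truth, and is itself first-class, tested code. What it
emulates, and what it does not, bounds what green tests mean for real data.

**Pedigree and genomes.** Twelve founder varieties and seven serial
selections (19 accessions; the derived chain D1…D7 with the last as
target) over two chromosomes named A01/D01 to exercise the subgenome split.
Chromosomes default to 10 Mb — desk scale rather than the ~100 Mb of real
cotton chromosomes, chosen so a full scan-and-recover cycle runs in about a
second while windows, steps and densities keep their real-data values — at
0.6 SNPs/kb, the density of the emulated panel. Founders are fully
homozygous with alternate-allele frequencies uniform on [0.05, 0.5]
(monomorphic draws get one founder flipped, keeping every site polymorphic
by construction); background identity between founders is then ≈ 0.64 per
site, far below the 0.99 window threshold, so false IBD windows are
essentially impossible.

**Descent.** Each meiosis draws a Poisson number of crossovers (mean 1 per
chromosome) with uniform breakpoints and no interference — the simplest
model that produces detectable 200-SNP segments — and children are fixed by
selfing (a mosaic of parental haplotypes, doubled). Selection is modelled
as forced carriage: from breeding stage 3 onward the segment spanning the
target gene plus 500 kb of flanking sequence per side is taken from a
parent carrying the elite haplotype. The flank is linkage drag, which real
directed selection also produces; it matters here because the focal-gene
neighbourhood carries only the three planted haplotype SNPs (background
SNPs are excluded there to keep codon contexts controlled), and a 200-SNP
window could never attribute a 3-SNP region on its own. Truth records every
segment's immediate donor and founder origin exactly.

**Focal genes.** The target gene is a three-exon model whose elite
haplotype AGT carries a promoter SNP, an Arg→Gly nonsynonymous SNP
(AGA→GGA) and a Glu→stop stop-gain (GAA→TAA); the partner gene carries a
single Ala→Thr SNP (GCC→ACC). These mirror the codon changes of the
emulated system and give the annotator non-trivial cases by construction.

**Phenotypes.** $y = \text{baseline} + \beta_A + \beta_B + \gamma + $
environment shift $+ \mathcal{N}(0, \sigma^2)$ per accession × trait ×
environment, over 3 locations × 2 years. Defaults are the emulated
fiber-strength ledger: baseline 38.05, βA 4.56, βB 0.15, γ 2.30 cN·tex⁻¹,
residual SD 2.0 (a realistic trial-level SD for FS), environment-shift SD
1.0; boll number gets a main effect (1.34 on baseline 7.0, ≈ 19%) to plant
pleiotropy; the other ten traits are baseline-only. Environment shifts are
common to all accessions, so group contrasts are exactly noise-free at
σ = 0 — the basis of the exact-recovery tests. The population generator
mirrors the emulated panel: 336 accessions with 193 GAG / 60 AGT, minor
variants, and a heterozygous (hence unassigned) remainder.

**Expression.** Two accessions × six stages (0–25 DPA) × three replicates
on the log2(FPKM+1) scale; FPKM is $2^y - 1$, so the screen's pseudocount
inverts the transform exactly. The planted module is built with *exact*
sample correlations: the hub profile carries the late-stage up-shift
(default 3.0 log2 units at 20/25 DPA in the high-FS accession) plus noise;
each of 11 members is 0.85 × the standardized hub profile plus an
orthonormalized residual supported on early-stage samples only. Hub–member
correlations are therefore exactly 0.85 (edges at the usual 0.8 threshold)
and member–member correlations exactly 0.7225 (no edges): the hub has
maximal degree by construction, not by sampling luck, and member fold
changes at the late stages carry the planted shift undiluted. Two further
genes are stage-specific DEGs (one up at 20, one down at 25, |log2FC| from
[1.5, 3]) and the rest of the 69-gene panel is null noise.

**What the generator does not emulate.** Coalescent founder diversity,
linkage disequilibrium within founders, sequencing error and genotype
uncertainty, crossover interference, paralogy/homoeology between
subgenomes, count-level expression noise, and batch structure. Passing
recovery tests therefore demonstrates that the estimators invert the
package's own generative assumptions at realistic parameter values — not
that they are robust to every artefact of real resequencing data.

## Validation at a glance

The suite checks, at fixed seeds: exhaustive oracle equivalence (site
diversity vs pair enumeration up to n = 12; the codon classifier over all
3,456 cases; the network vs a naive double loop; MCC/DMNC/MNC vs subset
enumeration on all 208 graphs with ≤ 6 nodes); recovery on simulations
(pooled bp Jaccard of detected vs true founder fragments averaged over 20
seeded pedigrees, observed ≈ 0.98 against a 0.90 requirement; exact β and γ
at σ = 0; 2·SE coverage of β and γ across 100 seeded panels — note that
±2·SE coverage of a normal mean is nominally ≈ 95.4%, so the ≥ 95%
requirement over 100 seeds sits close to its own expectation and is the
strictest check in the suite); and the algebraic invariants (path
additivity, baseline invariance, locus symmetry, filter idempotency,
threshold monotonicities, round trips). The worked-example arithmetic of
the two-locus ledger and the transmission summary is asserted exactly.

## Known limitations

* Attribution is deterministic interval logic, not probabilistic IBD; no
  phasing, no HMM smoothing, no recombination-rate model.
* The DEG stage is a filter on FPKM summaries, not an inference model;
  genes near the compound cutoff will flicker under resampling.
* Stress/betweenness enumeration and MCC's clique enumeration are for
  panel-sized networks, not genome-scale graphs.
* Haplotype grouping discards heterozygous accessions by design; in
  outcrossing material this would discard most of the panel.
* The percent effect is undefined for traits whose reference mean is zero,
  and fold-based context statements are unstable when the marginal effect
  is near zero — both are reported as computed, with `NA` where undefined.
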