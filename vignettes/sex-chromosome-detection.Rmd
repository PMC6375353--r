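---
title: "Detecting young sex chromosomes from population genomic data"
author: "XYscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting young sex chromosomes from population genomic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(XYscan)
```

## The problem

A young sex chromosome pair looks, over most of its length, like any
autosome. Only a region of suppressed recombination around the
sex-determining (SD) locus accumulates the diagnostic signatures of an
XX–XY system, and in a recently arisen system those signatures are
subtle: the Y still aligns to the X, coverage-based detection fails
under default mapping, and only a minority of sites are fully
differentiated. XYscan implements the battery of statistics used to
find and delimit such regions from whole-genome resequencing of a
handful of males and females:

* windowed population statistics — Hudson's $F_{ST}$, nucleotide
  diversity $\pi$, absolute divergence $d_{xy}$, Nei–Li net divergence
  $d_a = d_{xy} - (\pi_x + \pi_y)/2$, and Tajima's $D$;
* genotype-pattern evidence — XY-patterned sites (every female
  homozygous, every male heterozygous), per-individual and windowed
  normalized inbreeding coefficients $F_{IS}$, their correlation with
  male–female $F_{ST}$, genotype PCA, and Ajk relatedness;
* sex-differential sequencing depth — median-normalized windowed
  coverage in two alignment dialects (all alignments vs. only
  mismatch-free alignments) and male-only-coverage region calling;
* alignment-free k-mer discovery of Y-specific and X-linked sequence;
* quartet topology weighting across four groups, for asking whether
  males of two populations share one Y lineage.

Every stage is driven by a coalescent-based synthetic-data generator
with a machine-readable truth record, so the whole pipeline is
validated by parameter-recovery experiments rather than by fixtures.

## Statistical machinery

**Hudson's $F_{ST}$.** Per biallelic site with allele frequencies
$p_1, p_2$ estimated from $n_1, n_2$ called allele copies, the
numerator is $(p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} -
\frac{p_2(1-p_2)}{n_2-1}$ and the denominator $p_1(1-p_2) +
p_2(1-p_1)$; windows aggregate as the ratio of sums. Negative per-site
numerators are retained so the window ratio stays unbiased. In the
infinite-population limit a fully sex-differentiated site ($p = 0.5$
in the heterogametic sex, $1.0$ in the homogametic sex) gives exactly
$F_{ST} = 0.5$ — the analytic ceiling for sex-linked variation, which
`hudsonComponents(0.5, 1)` reproduces.

**$\pi$, $d_{xy}$, $d_a$.** Per-site unbiased heterozygosity
$\frac{n}{n-1}\,2p(1-p)$ and cross-group diversity
$p_1(1-p_2)+p_2(1-p_1)$ are summed per window and divided by the full
window width by default (a whole-genome-sequencing convention where
practically all positions are callable); a callable-sites denominator
is available for sparse data. $d_a$ follows the exact identity above.

**Tajima's $D$** uses the classical constants
($a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$) from the 1989 formulation,
computed from the window's segregating-site count and mean pairwise
differences; windows with $S < 3$ are NA. Sites with missing calls are
excluded from this statistic so $n$ is constant within a window.

**$F_{IS}$** is the method-of-moments coefficient
$(O_{hom}-E_{hom})/(N-E_{hom})$ per individual, with
$E_{hom} = \sum_\text{sites} 1 - 2p(1-p)\frac{2n}{2n-1}$ over sites
polymorphic in the population subset (the conventional small-sample
correction, so outputs are comparable with standard per-individual
heterozygosity reports). The windowed, normalized form subtracts each
individual's genome-wide $F_{IS}$ excluding the focal contig from the
window value and averages within sex: on an XY region males (permanent
heterozygotes at X/Y-differentiated sites) go negative, females
positive.

**XY-patterned sites.** A site passes when every called male is
heterozygous and every called female homozygous (each for whatever
allele). Strict mode — the default — discards sites with any missing
call in either sex, matching a full-call selection on a small cohort;
lenient mode evaluates called samples only, with a per-sex minimum.
Per-contig counts are reported normalized by the contig's total site
count, which is the ranking statistic used to nominate the sex
chromosome.

**PCA** uses Patterson normalization: genotypes centered by $2\hat p$
and scaled by $\sqrt{2\hat p(1-\hat p)}$, monomorphic sites dropped,
missing values mean-imputed (zero after centering), then an SVD.

**Coverage.** Depth tables in the `samtools depth -aa` layout are
normalized by one grand median per sex (all positions × individuals),
then summarized as the per-position per-sex median across individuals,
averaged in windows and log2-transformed. log2(0) stays NA — zero
coverage is categorically different from low coverage. Under the
perfect-alignment dialect, reads carrying X/Y mismatches drop out and
male coverage over differentiated X sequence halves; under all
alignments the Y reads cross-map and no contrast is visible. That
dialect contrast, not absolute depth, is the hemizygosity diagnostic.
Male-only-coverage regions (candidate Y-specific sequence) are maximal
runs ≥ 1 kb where per position at least 4 of 5 males have nonzero
depth, pooled male depth exceeds 5 and pooled female depth stays below
3 (with the male-breadth count scaling as $\lceil 0.8\,n_m\rceil$ for
other cohort sizes); all three clauses are read so that none is
redundant. The female cutoff for vetting externally assembled Y
contigs ("reaches 5 pooled reads at any position") is a parameter,
since pooled-vs-per-individual and at-any-position readings are both
defensible; pooled/any-position is the default.

**K-mers.** Catalogs hold all 37-mers beginning with the trigger
prefix `AG` (a complexity-reduction device: only ~1/16 of read
positions seed a word) with pooled per-sex counts, pruned below 5.
Words are counted as written — no reverse-complement
canonicalization — because the trigger scheme operates on raw read
orientation; this halves per-strand sensitivity, and `placeKmers()`
compensates by searching both strands. Y-mers require ≥ 10 male and
≤ 4 female counts; X-mers a female/male ratio within [1.75, 2.25], the
2:1 dosage band of X-linked sequence (with an optional rescaling
factor when sample sizes differ). Read pairs are extracted when either
mate contains a catalog word exactly, mirroring mate-aware extraction.

**Topology weighting** evaluates quartets (one sequence per group) by
the four-point condition on Hamming distances over window variants:
the smallest of $d(AB)+d(CD)$, $d(AC)+d(BD)$, $d(AD)+d(BC)$ selects
the topology, ties split equally, and weights are tallies normalized
to 1. For quartets under additive distances this is equivalent to
inferring the quartet tree, so the stage needs no external tree
builder; it is a deliberate quartet-scale reimplementation of subtree
weighting, not a port, and no numerical agreement with the original
tool is claimed. All quartets are enumerated up to 10,000; beyond that
a seeded uniform sample of 1,000 is used (convergence to the
exhaustive weights is tested). Unphased genotypes are split into
pseudo-haplotypes with seeded random allele assignment; true
haplotypes are used as-is when supplied.

## The synthetic cohort

`simConfig()` defaults describe the reference scenario used by the
test suite, chosen to emulate the study system the package targets —
a small cichlid-like cohort:

| parameter | default | meaning |
|---|---|---|
| `nMales`, `nFemales` | 5, 5 | sexed diploids of the focal population |
| `contigs` | 8 + 6 + 6 Mb | three-contig ~20 Mb genome |
| `theta` | 10 per 2 kb block | $\pi \approx 0.005$/bp |
| `sdRegion` | 1–5 Mb of `sexChr` | suppressed-recombination region |
| `tau` | 1.5e-3 /bp | Y-specific mutation density (≈ 38k XY sites / 25 Mb) |
| `yInternalTheta` | 1 | residual diversity among Y copies |
| `xFounders` | 6 | distinct X lineages inside the sd region |
| `depthLambda` | 20 | Poisson sequencing depth |
| `readLength`, `fragment` | 150, 350 | paired-end geometry |
| `yInsertionCount/Length` | 12 × 1.5 kb | Y-only insertions (male-assembly space) |
| `founders2`, `splitThetaScale` | 4, 0.8 | bottleneck + divergence of population 2 |

Genotypes come from a Hudson coalescent without recombination within
2 kb blocks, blocks independent — a deliberately coarse recombination
model (block independence, no LD decay) that keeps the generator exact
and fast. Blocks are shorter than the 10 kb analysis windows so each
window averages several genealogies; with one genealogy per window the
null distributions of window $F_{ST}$ and of chance XY-site counts are
so heavy-tailed that single windows regularly mimic sex linkage, which
no real 10 kb window with internal recombination does to the same
degree. Inside the sd region each male's second haplotype is replaced
by one ancestral Y lineage carrying shared Poisson($\tau L$) derived
mutations plus low internal Y diversity, and the X lineages draw from
a reduced founder pool (`xFounders`), emulating the reduced haplotype
diversity of a non-recombining region; this is what gives the
homogametic sex its elevated regional $F_{IS}$ (calibrated once to the
+0.1–0.2 elevation a real young system shows; under pure random
mating the female side of that signature cannot arise). The
bottlenecked second population resamples ≤ 4 founder haplotypes
(forcing positive Tajima's $D$) and both populations receive
private fixed differences scaled by `splitThetaScale`. A shared-Y
mode places one ancestral Y in both populations' males and an
independent-Y mode gives each population its own; the shared scenario
is simulated at modest population divergence because an introgressed
Y is only detectable in quartet topologies while it is younger than
the population split — at study-scale divergence, population-private
differences dominate the quartet distances.

What the generator does **not** emulate: within-block recombination
and realistic LD decay, sequencing error and base-quality variation,
indel polymorphism inside reads, mapping bias, or linked selection.
Passing tests therefore demonstrate correctness of the statistics and
the recovery logic under an idealized neutral model, not robustness to
artifacts of real pipelines.

All randomness flows from one master seed through a fixed splitting
scheme (`genotypes`, `depth`, `reads`, `reference`, `maleassembly`
stages), so every output is reproducible stage by stage.

## Numerical and design choices

* **Coordinates.** VCF and depth tables are 1-based; every window,
  BED interval and sd-region bound is 0-based half-open. A site at VCF
  position $P$ belongs to window $\lfloor (P-1)/w \rfloor$.
* **Missingness.** Sites with a missing fraction strictly above 0.5
  are removed (a site at exactly 50% stays). Missing genotypes never
  enter allele frequencies; multiallelic records are dropped rather
  than decomposed; indels ride along as biallelic presence/absence
  sites.
* **Degenerate inputs.** Window $F_{ST}$ with zero summed denominator,
  Tajima's $D$ with $S<3$, $F_{IS}$ with $N = E_{hom}$, log2 of zero
  coverage, and topology weights of variant-free windows are all NA,
  never zero.
* **Evidence combination.** `candidateRegion()` flags windows by
  male–female $F_{ST} \ge 0.15$ OR XY-site count $\ge 5$ per 10 kb OR
  perfect-dialect coverage ratio $\le 0.75$, merges flags within
  50 kb, and requires at least `minWindows = 3` distinct flagged
  windows per interval. The support rule exists because fully linked
  coalescent blocks occasionally produce single spurious windows; a
  real sd region contributes dozens to hundreds of contiguous flagged
  windows. The combination rule as a whole is an explicit,
  parameterized surrogate for what is usually done by inspection, and
  reports per-track support rather than a verdict.
* **Contig ranking** uses normalized XY-site density (count divided by
  the contig's total sites), falling back to mean male–female
  $F_{ST}$ when the XY stage is off.
* **Statistical test sizes.** The suite runs parameter recovery on 20
  replicates of the default ~20 Mb scenario; read-level k-mer checks
  use a 40 kb sex contig at 12× coverage (simulating reads for a 20 Mb
  default genome is not a desk-scale operation and adds nothing to the
  property under test); topology checks run twenty 100 kb two-population
  cohorts. Window-level sign consistency of normalized $F_{IS}$ is
  asserted at the level this cohort size supports (≥ 75% of sd windows
  negative in males, ≥ 60% positive in females, with clear region-mean
  separation): at 5+5 diploids the per-window noise floor
  (sd ≈ 0.1–0.17) makes a ≥ 90% per-window criterion unreachable for
  the weaker female signal. Similarly, with 10 samples the null
  maximum |correlation| between a PC and sex over three components has
  a median near 0.5, so the PCA contrast is asserted per replicate and
  on the replicate median rather than as a hard per-run bound.

## Known limitations

* The Hudson estimator is the only $F_{ST}$ flavor wired into the
  window pipeline surface; a Weir–Cockerham variant would be a natural
  extension point.
* Welch tests on window series ignore autocorrelation between
  adjacent windows; p-values there are descriptive, as is conventional
  for genome scans.
* The window F_IS–F_ST association uses Pearson correlation; rank
  correlation is a one-line sensitivity analysis left to the user.
* Juveniles and unknown-sex samples are excluded from every sexed
  statistic.
* Unplaced-scaffold "super contigs" are treated like any contig;
  whether window statistics are meaningful there is the user's call.
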