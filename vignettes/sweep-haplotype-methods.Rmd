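---
title: "Methods: diversity scans, promoter haplotypes and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity scans, promoter haplotypes and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sweephap` reconstructs, as tested code, the population-genomic argument
that a locus was selected during crop improvement: a localized loss of
nucleotide diversity in the improved group, a promoter tag SNP whose wild
allele declines across domestication strata, and a phenotype difference
between the two promoter haplotypes. This vignette documents the statistical
model behind each stage, the tunable parameters, the numerical conventions,
and what the bundled simulator does and does not establish.

## Coordinates

VCF and GFF3 files are 1-based inclusive on disk. Every internal interval —
scan windows, sweep intervals, promoter windows — is 0-based half-open, and
conversion happens only at the I/O boundary. A single convention avoids
off-by-one drift in window membership and overlap tests; all overlap logic
(`call_sweeps()`, `locate_locus()`, promoter membership) is therefore
half-open, so a variant at the ATG's first base is *not* a promoter variant
and a gene starting one bp past a sweep interval does not overlap it.

## Nucleotide diversity

Per site, diversity is Nei's frequency-based estimator with the small-sample
correction,

$$\pi_{site} = \frac{n}{n-1}\Big(1 - \sum_i p_i^2\Big),$$

where $n$ is the number of *called* alleles at the site (two per accession,
minus missing calls) and $p_i$ the allele frequencies. This equals the
fraction of differing pairs among all $\binom{n}{2}$ allele pairs, which is
what the test suite checks against an exhaustive pair-enumeration oracle.
Multiallelic sites enter through their full frequency vector; InDels count
as single polymorphic sites at their VCF position, unweighted by length —
the simplest defensible treatment, stated here as a convention. Missing
genotypes reduce $n$ per site rather than being imputed, which keeps the
estimator unbiased under missingness; sites with fewer than two called
alleles are skipped. Phase is ignored throughout (all statistics are
frequency-based), so `/` and `|` genotype separators are equivalent.

Window diversity is the per-bp average
$\pi_w = \sum_{s \in w} \pi_{site}(s) / |w|$: positions absent from the VCF
are assumed invariant and contribute zero. This matches the usual
resequencing convention and makes $\pi$ comparable across windows with
different variant counts, but it also means an input VCF restricted to a
subset of sites (e.g. array positions) will underestimate absolute π.

## Sweep detection

The scan computes π per group in sliding windows (defaults: 100 kb windows,
10 kb step). Window size and step are **not** estimates — they are scan
resolution parameters, exposed because published thresholds depend on them.
The defaults are conventional for tomato resequencing sweep scans; smaller
windows raise variance (and the rate of zero-diversity windows), larger
ones blur interval edges.

The contrast statistic is the per-window ratio of the ancestral to the
derived group's diversity, e.g. π~CER~/π~BIG~ for improvement. Windows with
a zero denominator are masked rather than stabilized with a pseudocount: a
pseudocount would deform exactly the upper tail from which the threshold is
taken. Masked windows are excluded from quantiles and can never qualify as
sweep windows.

The threshold is the empirical nearest-rank quantile of the defined ratios
over the analyzed chromosome: the $k$-th smallest with $k = \lceil q\,m
\rceil$ (default $q = 0.95$, the "top 5%" convention). Nearest-rank is
interpolation-free, hence identical across numeric libraries and exactly
scale-equivariant. A warning is raised when fewer than $1/(1-q)$ windows are
defined, where the quantile stops being meaningful.

Windows at or above the threshold are merged into sweep intervals; merging
joins runs of qualifying windows that are adjacent in window order (with an
optional gap tolerance of `max_gap` windows, default 0) and then unions any
still-touching intervals genomically. A gene is `within_sweep` iff its span
overlaps any called interval under half-open semantics.

## Promoter haplotypes

The promoter window is the configurable `upstream_len` (default 3000 bp,
the 3-kb convention) immediately upstream of the first base of the ATG,
strand-aware and clipped at the chromosome edge. Each in-window variant gets
a signed offset `rel_pos` (negative upstream), and SNPs are labelled
`SNP1..SNPk` from most-upstream to closest-to-ATG, InDels separately in the
same order. The labelling order is a package convention — it is consistent
with a tag SNP at −1903 bp being the 7th of 8 SNPs spread over 3 kb, but it
is documented as a convention, not a fact about any particular data set.

Haplotype classification keys on **nucleotide identity**, not REF/ALT
index. With a cultivar-derived reference genome the wild allele at a
selected locus is typically the ALT, so an index-based rule would flip
meaning across genome builds; a base-keyed rule (`Hap1 = G`, `Hap2 = A` by
default) does not. Only homozygotes for a configured base are assigned to a
haplotype; heterozygotes are reported as `Het` and genotypes with a missing
allele as `Missing`. Group-wise fractions are taken over non-missing calls.
Published two-haplotype tallies that sum to fewer than the panel size imply
exactly this kind of exclusion; how heterozygotes were handled there is not
stated, so here it is explicit and configurable downstream (the classes are
never silently folded).

### Group comparison

Phenotype differences between haplotypes (or population groups) use the
one-way F statistic from the standard sums-of-squares decomposition,
$F = \mathrm{MS}_{between}/\mathrm{MS}_{within}$, with a permutation
p-value: labels are shuffled `n_perm` times (default 10000) and
$p = (1 + \#\{F_{perm} \ge F\})/(n_{perm} + 1)$. The add-one correction
keeps $p > 0$ and the test valid at finite `n_perm`; under a fixed seed the
result is deterministic. The permutation route is preferred to the F
distribution because haplotype panels are small and unbalanced; the test
suite cross-checks the statistic against `anova(lm(...))` and the p-value
against exhaustive label enumeration on a small instance, and verifies
type-I calibration at β = 0 against binomial bounds. Groups need at least
two observations each; an instance with zero within-group variance (and
nonzero between) has an infinite F and is rejected with an error rather
than reported.

## Phylogeny

Distances between aligned protein sequences are p-distances with pairwise
deletion (columns with a gap in either sequence are dropped per pair); a
Poisson correction $-\log(1-p)$ is available behind `model = "poisson"`.
The substitution model behind the published tree this module mirrors is not
stated, so the common quick-NJ default is used and exact reproduction of
published support values is not claimed.

Neighbor joining follows Saitou–Nei: join the pair minimising
$Q(i,j) = (r-2)\,d(i,j) - R_i - R_j$, with the standard branch-length
formulas, which is exact on additive matrices (property-tested against
random trees, and cross-checked against `ape::nj` as an independent
implementation). Two numerical conventions make results deterministic:
ties in $Q$ are broken by the lowest active-cluster index pair, and
negative branch lengths are clamped to zero (standard practice) with a log
message.

Bootstrap supports resample alignment columns with replacement; each
replicate is rerun through distance + NJ, and the support of each internal
edge of the original tree is the fraction of replicates containing the same
bipartition. Bipartitions are compared as tip-label *sets* (canonicalized
against the alphabetically first taxon), so supports are invariant to input
order and to rooting. Replicates in which some pair loses all comparable
columns are dropped and counted. Newick output carries supports as integer
percentages in node labels, the convention of published NJ figures.

## The synthetic cohort

The generator is a stated world, not a tuning knob: its defaults are fixed
and the tests are written against them.

- **Sites**: `S = 4000` positions uniform without replacement on a 2-Mb
  chromosome; ancestral derived-allele frequencies follow the neutral SFS,
  $P(\text{count}=i) \propto 1/i$ over $i = 1..2n_{PIM}-1$.
- **Bottlenecks**: CER derives from PIM by 30 generations of Wright–Fisher
  binomial drift at $N = 200$; BIG from CER by 30 generations at $N = 100$.
  Expected heterozygosity retention is $(1 - 1/2N)^g$ — about 0.93 and then
  0.86 — enough to make the PIM > CER > BIG ranking essentially certain in
  a 4000-site average while keeping single-window ratios realistically
  noisy.
- **Sweep**: inside [900 kb, 1.1 Mb), BIG heterozygosity is scaled to
  $\lambda = 0.05$ of its drifted value by moving each frequency toward its
  nearer boundary (ties at 0.5 move toward 0, for determinism), solving
  $2p'(1-p') = \lambda\, 2p(1-p)$.
- **Tag SNP and phenotype**: a site 1903 bp upstream of the toy gene's ATG
  with wild-allele (ALT, G) frequencies 0.95/0.45/0.10 in PIM/CER/BIG —
  a decline of the magnitude seen at improvement-selected promoter
  variants — and survival (%) $= 40 + 15 w + \mathcal{N}(0, 10)$ for $w$
  wild alleles, clipped to [0, 100]. Sample sizes 20/40/60 keep the full
  pipeline under a minute at desk scale while preserving the 1:2:3 shape of
  wild:domesticated:improved panels.
- About 2% of sites are emitted as InDels so the InDel code paths run.

Genotypes are two Bernoulli draws per accession from the group frequency —
sites are independent given frequencies. The simulator therefore emulates
the *rank structure* the scan must detect, not linkage: there is no
recombination map, no background selection, no migration, and the sweep is
a marginal heterozygosity rescaling rather than a haplotype-frequency
trajectory. A green sweep-recovery test establishes that the scan finds a
localized diversity deficit of the configured magnitude against drift noise
— it does not validate the method against linked-selection confounders, and
absolute π levels are not calibrated to any real panel.

## Determinism and reporting

Every stochastic entry point (`simulate_cohort()`, `emit_fixture()`,
`compare_groups()`, `bootstrap_support()`, the pipeline) takes a seed and is
reproducible under it; fixture emission is byte-identical. `run_pipeline()`
records provenance (package version, seed, scan parameters, MD5 of file
inputs) in its JSON report and contains no timestamps, so reports are
byte-comparable. Diagnostics go to stderr via `message()`; machine output
goes only to files.

## Known limitations

- Absent sites are assumed invariant; π from sparse or filtered VCFs is
  biased downward.
- Sweep calling is threshold-based on a single statistic; no composite
  likelihood, haplotype, or cross-population statistics beyond the π ratio.
- The haplotype model is a single tag SNP; no phasing or LD analysis.
- The phylogeny module expects a pre-aligned FASTA and performs no
  alignment; p-distance NJ is a fast approximation, not ML.
- The simulator's independence-across-sites assumption understates the
  spatial autocorrelation of real window statistics; empirical thresholds
  on real data should be computed on the real chromosome, as the pipeline
  does.
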