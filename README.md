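# sweephap

Selective-sweep scans and promoter tag-SNP haplotype analysis for crop
resequencing panels.

## What it is for

Crop domestication proceeds through population bottlenecks: in tomato, the
wild *Solanum pimpinellifolium* (PIM) was domesticated into
*S. lycopersicum* var. *cerasiforme* (CER) and then improved into the
large-fruited *S. lycopersicum* (BIG). Loci selected during these
transitions show a sharp, localized loss of nucleotide diversity in the
derived group — a selective sweep — and often carry promoter variants whose
wild allele declines in frequency from wild to improved material.

`sweephap` implements the analysis chain a population geneticist runs to
make that case from a multi-sample VCF:

1. **Diversity scan** — sliding-window nucleotide diversity per group and
   the π-ratio tracks π<sub>PIM</sub>/π<sub>CER</sub> (domestication) and
   π<sub>CER</sub>/π<sub>BIG</sub> (improvement), with an empirical
   top-quantile threshold and merged sweep intervals.
2. **Promoter haplotypes** — variants in the strand-aware window upstream of
   a gene's ATG, classification of accessions at a tag SNP into two
   haplotypes by nucleotide identity, group-wise haplotype frequencies, and
   a permutation one-way ANOVA of an associated phenotype.
3. **Phylogeny** — p-distances from an aligned protein FASTA,
   a Saitou–Nei neighbor-joining tree, and bootstrap bipartition supports.
4. **Synthetic data** — a Wright–Fisher drift simulator that emits a
   VCF/GFF3/TSV/FASTA fixture with the full expected structure (declining
   diversity PIM > CER > BIG, an injected improvement sweep, a tag SNP with
   declining wild-allele frequency, a linked phenotype), so the whole
   pipeline is testable offline.

Per-site diversity uses Nei's unbiased estimator
π = n/(n−1) · (1 − Σᵢ pᵢ²) over the n called alleles at the site; window
values are per-bp sums over the window. Sweep thresholds are nearest-rank
empirical quantiles (k = ⌈q·m⌉), so results are reproducible bit-for-bit.

## Worked example

Everything below runs offline on the bundled generator (seed 7); the output
shown is what the code prints.

```r
library(sweephap)
fix   <- emit_fixture(sim_config(), dir = "fixtures", seed = 7)
tab   <- read_vcf(fix[["vcf"]])
panel <- read_panel(fix[["panel"]])
tab
#> variant_table: 4001 records (3924 SNP, 77 InDel), 120 accessions
#>   chr8: 4001 records, pos 712..1999541

track <- window_pi(tab, panel)          # 100-kb windows, 10-kb step
colMeans(track[, c("pi_PIM", "pi_CER", "pi_BIG")])
#>       pi_PIM       pi_CER       pi_BIG
#> 0.0004599754 0.0004293218 0.0003332494
```

Mean diversity declines PIM > CER > BIG, as the two bottlenecks dictate.
The improvement contrast then localizes the sweep:

```r
imp <- pi_ratio(track, "CER", "BIG")
thr <- empirical_threshold(imp, 0.95)   # top-5% of chromosome 8: 18.77
calls <- call_sweeps(imp, thr)
calls
#>   chrom start     end n_windows max_ratio
#> 1  chr8 9e+05 1100000        10  25.10004

genes <- read_gene_models(fix[["gff3"]])
locate_locus(calls, genes[1, ])
#> [1] "within_sweep"
```

The called interval is exactly the simulated sweep [900 kb, 1.1 Mb) and the
toy gene inside it classifies as `within_sweep`. The promoter tag SNP sits
1903 bp upstream of the ATG, and its wild (G) haplotype collapses from the
wild to the improved group, carrying a higher survival rate:

```r
pv <- extract_promoter_variants(tab, genes[1, ])
pv[pv$pos == 998097, ]
#>   label chrom    pos rel_pos ref alt vtype
#> 3  SNP3  chr8 998097   -1903   A   G   SNP

asg <- classify_haplotypes(tab, "chr8", 998097)   # Hap1 = G, Hap2 = A
haplotype_distribution(asg, panel)[, c("group", "n", "Hap1", "Hap2", "Het", "frac_Hap1")]
#>   group  n Hap1 Hap2 Het frac_Hap1
#> 1   PIM 20   19    0   1      0.95
#> 2   CER 40    6   11  23      0.15
#> 3   BIG 60    0   48  12      0.00

ph  <- read_phenotypes(fix[["pheno"]])
grp <- setNames(asg$haplotype, asg$accession)
compare_groups(ph, grp[grp %in% c("Hap1", "Hap2")],
               measure = "survival_rate", n_perm = 10000, seed = 7)
#> One-way comparison: F(1, 82) = 96.2, permutation p = 9.999e-05 (10000 perms)
#>  group  n     mean       sd
#>   Hap1 25 66.73003 12.48406
#>   Hap2 59 41.25940 10.14506
```

`run_pipeline()` chains all stages and writes TSV/BED/JSON/Markdown reports;
`exec/sweephap.R` exposes the same stages as `simulate`, `scan`,
`haplotype`, `phylo` and `report` subcommands.

## Acceptance script

`scripts/acceptance.R` re-runs the whole analysis from scratch at a given
seed — it simulates the default cohort, writes the fixture files, executes
the scan/haplotype/phenotype pipeline and the bootstrap NJ tree, prints the
report summary, and writes its JSON output:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope notes

Window size and step (defaults 100 kb / 10 kb) are configurable scan
parameters, not estimates; sites absent from the VCF are treated as
invariant; structural variants are excluded; the haplotype is defined by a
single tag SNP (no LD phasing); multiple sequence alignment is out of scope
for the phylogeny module (input must be pre-aligned). See the methods
vignette (`vignettes/sweep-haplotype-methods.Rmd`) for the statistical
details and the simulator's assumptions.
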