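# mullerf

Comparative genomic characterization of heterochromatic chromosome domains,
packaged as a tested, reusable pipeline.

## The problem

The Muller F element — the *Drosophila* "dot" chromosome — is mostly
heterochromatic (H3K9me2/3, HP1a, low recombination) yet carries ~80 active
protein-coding genes. Characterizing how such a domain differs from
euchromatic reference regions requires a battery of sequence-level analyses
run side by side on each region:

* **Repeat landscape** — k-mer occurrence spectra (default k = 13),
  dinucleotide-repeat run tabulation (2–100 units, overlapping matches),
  sliding-window transposon density (1-kb windows, 500-bp step, with
  same-class fragment merging), and masked-fraction summaries per repeat
  class.
* **Gene architecture** — eight characteristics of the most comprehensive
  isoform per gene: coding span, intron repeat size, coding-region size,
  number of coding exons, median coding-exon size, median intron size, and
  the two codon-bias statistics below; compared across regions by
  Kruskal–Wallis with Siegel–Castellan post-hoc tests.
* **Codon bias** — Wright's effective number of codons
  `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` (61 = no bias, 20 = maximal bias)
  and the codon adaptation index (CAI), the geometric mean of relative
  adaptiveness `w` over a gene's codons, with a self-consistent
  dominant-bias reference gene set. The sign of the local LOESS slope of
  CAI on Nc classifies the bias regime: negative ⇒ selection for preferred
  codons, positive ⇒ mutational bias.
* **Melting-temperature metagene** — nearest-neighbor 9-bp duplex Tm
  (Breslauer stack parameters; Tm = 1000·ΔH/(ΔS + R·ln(C/4)) − 273.15 +
  16.6·log₁₀[Na⁺]), per-gene tracks over the coding span ± 2-kb flanks,
  bodies normalized to 3000 bins, aggregated by the per-position median.
* **Multivariate outliers** — Distance–Distance analysis of the eight
  standardized gene characteristics: classical Mahalanobis distance (MD)
  vs. the Stahel–Donoho robust distance (RD, projection-pursuit
  outlyingness weights); outliers exceed √χ²₀.₉₇₅,₈ = 4.19.
* **Synteny and rearrangement** — wanderer-gene detection between species,
  syntenic-block statistics, and the exact Hannenhalli–Pevzner minimum
  signed reversal distance (`d = (n+1) − c + h + f` on the framed
  breakpoint graph) with scenario reconstruction and a breadth-first-search
  oracle for small n.

A first-class synthetic-data module (`synth_config()`, `generate_genome()`,
`generate_gene_models()`, `generate_ortholog_table()`,
`generate_codon_cohort()`, `write_fixtures()`) emits seeded genomes with
planted transposon fragments, microsatellite runs, gene models, codon-usage
regimes and reversal histories, so every analysis stage has an exactly
recoverable ground truth.

## Worked example

```r
library(mullerf)

cfg <- synth_config(seed = 42, profile = "F", region_length = 120000,
                    n_genes = 24, n_reversals = 4)
gen <- generate_genome(cfg)          # planted repeats + runs
gm  <- generate_gene_models(cfg, gen)

region <- genomic_intervals(cfg$chrom, 0, cfg$region_length)
round(masked_fraction(gm$fragments, region), 3)
#> DINE-1    DNA   LINE    LTR  total
#>  0.030  0.063  0.074  0.137  0.305

ft <- gene_feature_table(gm$models, gm$genome, gm$fragments)
summary(ft[, c("coding_span", "nc", "cai")])
#>   coding_span           nc             cai
#>  Min.   :  69.0   Min.   :31.58   Min.   :0.3994
#>  Median : 562.5   Median :40.16   Median :0.5655
#>  Max.   :4120.0   Max.   :51.85   Max.   :0.7684

ot  <- generate_ortholog_table(cfg)
rep <- synteny_report(ot$table, "spA", "spB")
sprintf("shared: %d, blocks: %d (mean %.1f genes/block), reversal distance: %d",
        rep$n_shared, rep$n_blocks, rep$mean_genes_per_block,
        rep$reversal_distance)
#> "shared: 24, blocks: 8 (mean 3.0 genes/block), reversal distance: 4"

attr(dd_classify(numeric(0), numeric(0)), "cutoff")   # DD outlier cutoff
#> 4.194593   (prints as 4.19)
```

The F-profile region carries ~30% planted transposon coverage (the
heterochromatic regime; a D-profile region defaults to 7%), the reversal
distance recovers the 4 planted inversions exactly, and the Distance–
Distance cutoff is the analytic χ² constant.

The orchestrated form of the same run:

```r
paths <- write_fixtures(cfg, "fixtures/")
run_pipeline(list(regions = list(list(label = "synthF",
                                      fasta = paths[["fasta"]],
                                      genes = paths[["genes"]],
                                      repeats = paths[["repeats"]],
                                      orthologs = paths[["orthologs"]]))),
             outdir = "out/")
```

writes one TSV/JSON per stage plus `summary.json` and a parameter log;
re-running with the same config and seed is byte-identical. A command-line
wrapper lives at `inst/cli/mullerf-cli.R`
(`fixtures | repeats | genes | codon | melt | outliers | synteny | all`).

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the models, the
synthetic-data design, numerical choices and known limitations; roxygen
comments on every exported function are the reference documentation.
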