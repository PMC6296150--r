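# mitomethr

Genotype-specific analysis of mitochondrial DNA methylation from
whole-genome bisulfite sequencing and qPCR, as an R package.

The mitochondrial genome is a ~16.5 kb circular, multi-copy molecule whose
CpG methylation is low (~10%) and sits near the resolution limit of
bisulfite assays, so honest analysis requires deep coverage, genotype-aware
mapping, and per-site calibration. mitomethr implements that workflow for
analysts working with purified mtDNA libraries:

* **CpG enumeration and genotype comparison.** Both-strand CpG sites on a
  circular genome in 1-based plus-strand coordinates (the junction
  dinucleotide counts), and positional diffs between equal-length genotypes
  — point substitutions that create a CG show up as a gained (+,−) site
  pair.
* **Bisulfite pipeline.** A non-directional, conversion-aware aligner
  (reads and reference collapsed C→T / G→A; unique-best seed-and-extend on
  the doubled circular sequence; strand classes OT/OB/CTOT/CTOB recovered
  from the conversion-mode combination), coordinate-based PCR
  deduplication, and per-cytosine methylation extraction with mate overlaps
  counted once. Third-party cytosine reports can be ingested directly.
* **Full-potential normalisation.** Untreated long-PCR amplicons (PCR
  erases methylation) give each site's background `b`; M.SssI-treated
  amplicons give its ceiling `c`; a sample's raw percentage `r` is
  normalised as `clamp((r − b)/(c − b) × 100, 0, 100)` at sites covered by
  ≥ 10 reads in every control.
* **Per-site statistics.** One-way ANOVA across groups, pairwise Welch
  contrasts with the joint rule (p < 0.05 **and** |difference| > 5 points),
  star annotation, and gene labelling from an interval map (a standard
  human mitochondrial gene map ships in `inst/extdata/`).
* **qPCR quantification.** MeDIP 5mC/5hmC ratios
  (`efficiency^(Ct_5hmC − Ct_5mC)`), ΔΔCt expression against the averaged
  reference genes *18SrRNA*/*OAZ1*/*HPRT1* (`fold = 2^(−ΔΔCt)`), and
  Pearson correlation of site methylation with expression folds.
* **A truth-tracked simulator** for bisulfite libraries (conversion
  efficiency, methylation protection, sequencing error, PCR duplicates,
  strand classes, circular vs linear molecules) and qPCR Ct tables, so the
  whole chain is testable without external data.

## Worked example

```r
library(mitomethr)

# a 4 kb circular genome with 100 CpG dinucleotides (200 dual-strand sites)
genome <- synthetic_reference_genome(length = 4000, n_cpg = 100, seed = 42,
                                     cpg_free = c(1000, 1001))
cpg_sites(genome)
#> # A tibble: 200 × 3
#>    position strand context
#>       <int> <chr>  <chr>
#>  1       26 +      CpG
#>  2       27 -      CpG
#>  3       46 +      CpG
#> # ...

# a genotype variant that creates a CpG at positions 1000-1001
subs <- data.frame(position = c(1000, 1001), base = c("C", "G"))
subs <- subs[subs$base != substring(genome$sequence, subs$position,
                                    subs$position), ]
variant <- simulate_genotype(genome, subs, name = "variant")
cpg_diff(variant, genome)
#> # A tibble: 2 × 3
#>   position strand change
#> 1     1000 +      gained
#> 2     1001 -      gained

# simulate long-PCR controls and one tumor-like sample at 60x, then run
# align -> dedup -> extract -> validate -> normalize
cfg <- read_sim_config(mean_coverage = 60)
ctrl <- simulate_controls(
  genome, control_spec(amplicons = list(c(1, 2200), c(2000, 4000))),
  cfg, seed = 1
)
calls_of <- function(sim) {
  aln <- align_bisulfite(sim$reads, genome)
  extract_methylation(deduplicate(aln), sim$reads, genome)
}
neg <- calls_of(ctrl$negative)
pos <- calls_of(ctrl$positive)
valid <- validate_sites(list(neg, pos), min_reads = 10)
potentials <- compute_full_potential(neg, pos, valid)

methylome <- draw_methylome(genome, methylome_spec(), seed = 2)   # ~10% CpG
sample_sim <- simulate_bisulfite_reads(genome, methylome, cfg, seed = 3)
calls <- coverage_filter(calls_of(sample_sim), min_reads = 10)
profile <- normalize_profile(calls, potentials, sample_id = "tumor_1")
profile
#> # A tibble: 190 × 5
#>    sample  position strand raw_pct normalized_pct
#>  1 tumor_1      132 +        14.3           17.5
#>  2 tumor_1      133 -        20             24
#>  3 tumor_1      266 +        25             26.9
#> # ...
mean(profile$normalized_pct)
#> [1] 10.60963
```

190 of the 200 CpG sites validate (the amplicon edges taper below 10 reads
at this depth), and the genome-wide mean normalised methylation recovers
the simulated ~10% regime. `pairwise_contrasts()` then takes several such
profiles plus a sample→group design and returns the per-site contrast table
(difference in points, Welch p, stars, joint-rule pass flag);
`autoplot()` methods draw the profile, potential, and volcano views.

On the qPCR side:

```r
ct <- simulate_qpcr_ct(
  c(`18SrRNA` = 1000, OAZ1 = 30, HPRT1 = 8, ND5 = 4),
  qpcr_sim_config(noise_sd = 0, replicates = 1), seed = 4
)
ct
#> # A tibble: 4 × 3
#>   sample  replicate    ct
#> 1 18SrRNA         1  15.0
#> 2 OAZ1            1  20.1
#> 3 HPRT1           1  22
#> 4 ND5             1  23
```

Feeding such tables for replicated control and treatment groups into
`ddct_fold_change(table, control_group = "ctrl")` returns per-sample and
per-group fold changes with SEM; a doubled template yields fold 2 exactly
when noise-free. `medip_ratio()` and
`correlate_methylation_expression()` (with broom-style `tidy()`/`glance()`
methods) complete the quantification layer.

`run_pipeline(pipeline_config(...))` orchestrates the whole chain from a
single seed (or a YAML file via `read_pipeline_config()`), writes the TSV
artifacts and a JSON run manifest, and is wrapped by the thin CLI at
`inst/scripts/mitomethr-cli.R` (`cpg-sites`, `cpg-diff`, `run-all`).

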