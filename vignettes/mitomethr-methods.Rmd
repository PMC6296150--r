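---
title: "Methods: genotype-specific mitochondrial methylome analysis with mitomethr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-specific mitochondrial methylome analysis with mitomethr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomethr)
```

# Scope and model

mitomethr analyses cytosine methylation of small circular genomes — in
practice the ~16.5 kb, multi-copy mitochondrial genome — from whole-genome
bisulfite sequencing, with companion qPCR-based quantification. The package
covers the full chain:

1. **CpG enumeration** on circular genotype sequences, on both strands, in
   1-based plus-strand coordinates, and positional comparison of genotypes
   (gained/lost CpG sites after point substitutions).
2. **Non-directional bisulfite alignment** of 150 bp paired-end reads to the
   circular genome, coordinate-based PCR deduplication, and per-cytosine
   methylation extraction into a cytosine report.
3. **Control-anchored normalisation**: untreated long-PCR amplicons of the
   genome are necessarily unmethylated and estimate the per-site background
   (bisulfite conversion failure); the same amplicons treated with the
   M.SssI CpG methyltransferase estimate the per-site ceiling. Their
   difference is the site's *full potential*, taken as 100%.
4. **Per-site statistics**: one-way ANOVA across groups and pairwise Welch
   contrasts with a joint significance rule (p below alpha *and* an absolute
   methylation difference above a minimum number of percentage points), with
   star annotation and gene-feature labelling.
5. **qPCR quantification**: MeDIP 5mC/5hmC ratios, relative expression by
   the delta-delta-Ct method against the averaged internal controls
   *18SrRNA*, *OAZ1* and *HPRT1*, and Pearson correlation of site
   methylation with expression fold changes.
6. A **synthetic-data generator** that emulates the bisulfite libraries and
   qPCR experiments with known truth, so every stage is testable offline.

## Coordinate and site conventions

A CpG site is a cytosine in CG dinucleotide context. The plus-strand site is
the C of a CG; the minus-strand site is the cytosine of the complementary
strand, which sits opposite the plus-strand G and is reported at the G's
plus-strand coordinate. A CG dinucleotide therefore contributes two sites at
adjacent coordinates, and strand counts are always balanced (CG is its own
reverse complement). On circular genomes the junction dinucleotide (last
base, first base) counts. N bases never form sites. Genotype comparison
requires equal-length sequences; indel-bearing genotypes are out of scope.

# The bisulfite aligner

The genome is small enough for an exact in-memory approach. Both the reads
and the genome are conversion-collapsed — C-to-T for the original-strand
hypothesis, G-to-A for the complementary-strand hypothesis — so alignment is
blind to methylation state. Each mate is matched in the four conversion
modes against a k-mer index (k = 20 by default, three seed offsets per
read) of the doubled reference, extended without gaps, and accepted only if
its best hit beats the runner-up strictly (ties are "ambiguous" and
dropped; the ambiguity rate is recorded as an attribute). Mates must align
in complementary modes within the configured insert range; the mode
combination identifies the molecule's strand class (OT, OB, CTOT, CTOB).

Consequences worth knowing:

* A fully unmethylated *or* fully methylated read still aligns (conversion
  state carries no mismatch cost), but a completely *unconverted* read is
  genuinely mode-ambiguous — it matches both collapsed references equally at
  its locus — and is rejected. Real libraries are converted, so this only
  matters for pathological inputs.
* Alignment is ungapped: the simulator emits no indels and desk-scale
  verification (origin recovery against the simulator's hidden sidecar) is
  the design goal. Indel-bearing real data should be aligned externally and
  ingested as a cytosine report via `read_cytosine_report()`, which accepts
  the 7-column Bismark cytosine-report dialect and a minimal 5-column
  variant.
* Deduplication is coordinate-based: one representative per (leftmost
  position, fragment length, strand class). At deep coverage of a tiny
  genome, distinct molecules occasionally collide on this key, so the
  deduplicated count is the number of distinct keys, not the number of
  distinct molecules — an intrinsic property of coordinate deduplication,
  which the simulator's truth tables mirror.
* Overlapping mates of a fragment are counted once per site (the first
  mate's call wins). Both mates carry the same molecule's methylation state,
  so double-counting would manufacture pseudo-replication; this choice
  trades a few percent of nominal depth for honest counts.

# Normalisation algebra

For a validated site with negative-control methylation $b$ (percent),
positive-control methylation $c$, and sample methylation $r$, the default
normalisation is

$$\mathrm{norm} = \mathrm{clamp}\left(\frac{r - b}{c - b} \times 100,\ 0,\ 100\right).$$

The subtraction treats the negative control as the site's conversion-failure
background and the positive control as its achievable ceiling. A plain-ratio
mode (`mode = "ratio"`, $r / (c - b) \times 100$) is provided for
sensitivity analysis, since the published description of the scheme fixes
only that the control difference defines 100%. Two anchoring identities hold
exactly and are tested: the positive control normalised against its own
potential table is 100 everywhere, the negative control 0.

Validation requires at least `min_reads = 10` calls (inclusive) in *every*
control; sites whose potential falls below `min_potential = 10` percentage
points are excluded rather than divided by a near-zero denominator. The
10-point floor is a package default, not an empirical constant.

Because the methyltransferase is imperfect (per-site efficiency ~Beta with
mean 0.90 in the simulator), the potential is ~89% of the raw scale and
normalised values run ~1.11x the true methylation — about +1.1 points at the
10% regime. This inflation is intrinsic to control-anchored normalisation
with an enzyme-limited ceiling; the package reports it rather than hiding
it, and accuracy statements about the *estimator* are made on the raw
extraction scale.

# Statistics

* Per-site one-way ANOVA uses the classical equal-variance F from group
  sums of squares; sites with zero total variance return p = 1 and a
  degeneracy flag.
* Pairwise contrasts use Welch's t by default (`var_equal = FALSE`): with
  n = 3 per group, variance homogeneity is untestable and Welch is the
  robust default. The joint pass rule is `p < alpha` **and**
  `|difference| > min_difference` (defaults 0.05 and 5 points); the
  difference rule is configurable per contrast family because stage-type
  contrasts are conventionally reported without it.
* No multiple-testing correction is applied by default across the ~800
  sites, matching the per-site reporting convention of this assay class;
  Benjamini–Hochberg is available (`p_adjust = "BH"`) and its use is
  announced loudly.
* Star annotation uses strict thresholds: `*` below 0.05, `**` below 0.01,
  `***` below 0.001.
* Gene annotation labels a site by the first feature interval containing its
  position (intervals may wrap the origin; matching ignores the site's
  strand, as mitochondrial gene labels conventionally apply to sites on
  either strand); unmatched sites are `Non-coding`. When reproducing
  published per-site tables, note that running text and tables occasionally
  disagree on a coordinate (transposed digits); treat the table as
  canonical.
* The methylation–expression correlation pairs each expression replicate
  with its group's mean methylation at the site, reports $R^2$, the
  two-sided correlation-test p (numerically identical to the regression F
  for a simple linear fit) and the slope sign.

qPCR quantification fixes the amplification efficiency at 2.0 (perfect
doubling) unless overridden — no standard curves are modelled, by design.
The MeDIP ratio is formed directly from antibody Cts
($E^{\Delta Ct}$) with an optional input-Ct subtraction mode; reference
genes are aggregated as the arithmetic mean of their Cts (a geometric mean
of quantities at equal efficiencies).

# The synthetic-data generator

The generator's defaults encode the study regime the package targets:
16,569 bp circular genome; 150 bp paired-end fragments with ~300 bp inserts
(SD 50); 500x mean read coverage; bisulfite conversion efficiency 0.995 and
methylation protection 0.995; per-base sequencing error 0.001; 5% PCR
duplicates; non-directional libraries with the four strand classes drawn
uniformly; CpG methylation ~Beta(mean 0.10, concentration 20) and non-CpG
methylation at 0.002; two overlapping long-PCR control amplicons
([1, 9000] and [8500, 16569] — the published amplicon size reads "~8500 kb",
which can only mean ~8,500 bp at this genome size); M.SssI efficiency
~Beta(mean 0.90, concentration 50) per site. The qPCR model is
$Ct = \mathrm{intercept} - \log(q)/\log(E) + \mathcal{N}(0, 0.15)$ with an
intercept default of 25 cycles, a typical mid-dynamic-range value.

Key emulation choices:

* **Methylation states are drawn per molecule**, so overlapping mates agree
  at shared sites and mate-overlap double counting is observable downstream.
* **Replicates of a group share the group's methylome.** The per-site Beta
  draw happens once per group (base methylome plus the group's injected
  effect); replicates then differ only through library sampling. Redrawing
  site levels per replicate would add ~6.5 points of between-replicate
  standard deviation at concentration 20 and does not correspond to
  replicate tumors of one genotype.
* **Fragments never cross amplicon ends in control samples** (linear
  molecules) but may span the origin in genomic samples (circular). Edge
  taper leaves the few positions within a read length of the genome origin
  under-covered in controls, which is why a handful of the 870 sites
  typically fail 10-read validation — the same mechanism that loses sites in
  real control libraries.
* **Every fragment's origin lives in a sidecar table**, not in the FASTQ
  headers, so the aligner cannot cheat; origin-recovery tests compare
  against the sidecar.
* The same seed reproduces a simulation byte for byte, FASTQ included.

What the generator does *not* emulate: indels, base-quality variation,
adapter contamination (trimming is out of scope), nuclear mitochondrial
pseudogene (NUMT) contamination, strand-biased library chemistry, and
copy-number structure. Passing tests on synthetic data therefore
demonstrate the correctness of the computational chain under the stated
noise model, not robustness to every artefact of real libraries.

# Numerical choices and degenerate inputs

* Beta draws with a degenerate mean (0 or 1) are constants; group-effect
  shifts are applied additively then clamped to [0, 1].
* Normalised percentages are clamped to [0, 100], since they are reported as
  percentages throughout.
* Zero-variance sites: ANOVA and t statistics return p = 1 with a flag
  rather than NaN.
* The aligner requires reads at least as long as the seed (20 bp); an N-run
  longer than the reads triggers an unmappable-region warning.
* Ties in deduplication keep the first-encountered fragment; ties in
  annotation keep the first feature, with a warning.
* All randomness flows through explicit integer seeds; `run_pipeline()`
  derives fixed per-stage substreams from the single configuration seed, so
  a configuration reproduces every artifact byte for byte.

# Problem sizes used by the test suite

The packaged checks run the complete chain at the study scale: a 16,569 bp
genome with 435 CpG dinucleotides (870 dual-strand sites), controls and a
tumor-like sample at 500x, an origin-recovery run of 100,000 error-free
fragments, 2,000-replicate null simulations for the ANOVA size, and a
3-group x 3-replicate differential design with +15-point effects at 10
sites at 500x coverage. The 500x depth matters for the differential check:
with n = 3 a Welch test has ~3 degrees of freedom (critical t about 3.2),
and the noncentrality at 500x (~7) is what makes a 15-point effect reliably
detectable, whereas shallower libraries (say 150x, noncentrality ~3.4)
leave per-site power near 50%. Unit tests use a 4 kb miniature genome with
100 planted CpGs at 30–60x so the suite stays fast.

Because the reference sequence itself is not bundled, the genome-derived
checks run on a synthetic stand-in generated by
`synthetic_reference_genome()`: random sequence at mitochondrial base
composition, stripped of CG dinucleotides and re-planted with exactly 435 of
them (junction included), giving the documented census (16,569 bp, 870
dual-strand sites) by construction. Users with the real reference FASTA get
the genuine census through `read_genome_fasta()` + `cpg_sites()` — the
enumeration path is identical.

# Known limitations

* Ungapped, unique-best alignment only; repeat-region reads are dropped as
  ambiguous rather than rescued.
* Base qualities are ignored in methylation calling.
* The control scheme corrects conversion failure only through the
  subtraction anchor; no binomial-mixture model of non-conversion is
  fitted.
* Normalised levels inherit the enzyme-ceiling inflation described above;
  cross-study comparisons should use the same control preparation.
* `simulate_bisulfite_reads()` emits paired-end reads only (the aligner
  itself also accepts single-end reads, classifying strand from the
  conversion mode alone).
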