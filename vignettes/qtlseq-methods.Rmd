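---
title: "QTL-seq by bulked segregant analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QTL-seq by bulked segregant analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaqtl)
```

## The statistical model

QTL-seq detects a quantitative trait locus from two pooled DNA samples
drawn from the phenotypic extremes of a segregating F2 population. Three
sampling layers stack on top of each other, and the package models all
three explicitly:

1. **Segregation.** Each F2 individual carries 0, 1 or 2 copies of the
   donor allele at any site, with probabilities ¼/½/¼. A bulk of $k$
   individuals therefore contributes $2k$ chromosomes whose donor-allele
   count is Binomial($2k$, ½) under the null of no linkage to the trait.
2. **Selection.** Bulking the $k$ lowest and $k$ highest phenotypes skews
   the allele frequency at (and, through linkage, around) a QTL. For a
   single additive QTL with effect $a$ per donor copy and environmental
   noise $\sigma_e$, the skew grows with the selection intensity and with
   $a^2/(a^2/2 + \sigma_e^2)$, the fraction of phenotypic variance the
   locus explains.
3. **Sequencing.** At a site covered by $d$ reads in a pool with true
   donor frequency $p$, the observed donor-read count is
   Binomial($d$, $p'$) with $p' = p(1-e) + (1-p)e$ for per-read error
   rate $e$; $d$ itself is Poisson around the mean pool depth.

The per-site, per-pool **SNP-index** is the observed donor-read fraction;
$\Delta$(SNP-index) is the high-pool minus low-pool difference of windowed
means. Under the null it is symmetric around 0; near a QTL whose donor
allele lowers the trait it goes strongly negative (low pool
donor-enriched), and mirrored otherwise.

The Monte-Carlo confidence band reproduces layers 1 and 3 per replicate —
resample a bulk, then binomial reads at the observed depth — and takes
empirical two-sided quantiles over 1000 replicates. The 1:2:1 dosage
sampling is implemented as a single Binomial($2k$, ½) draw per bulk, which
is exactly equal in distribution because an F2 individual's two gamete
alleles are independent Bernoulli(½).

Two deliberate properties of this band are worth knowing. First, it models
a *single site*, while the scan statistic averages ~25 sites per 50-kb
window; window averaging shrinks the read-sampling variance but not the
bulk-sampling variance, so the band is conservative for windows (the null
calibration test measures a significant-window fraction far below the
nominal 5%). Second, the band depends on depth, so it is computed per
window at that window's rounded mean depth and cached per distinct depth,
rather than once genome-wide.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `pop_size` | 280 | individuals | F2 design size of the emulated study |
| `bulk_size` | 30 | individuals | extreme bulks of 30 low / 30 high |
| `mean_depth` | 50 | reads/site/pool | pooled sequencing at ~50× |
| `window_bp` / `step_bp` | 50,000 / 5,000 | bp | the standard QTL-seq window geometry |
| `filter_threshold` | 0.3 | index | drop sites < 0.3 in *both* pools (strict `<`) |
| `n_reps` / `confidence` | 1000 / 0.95 | — | replicates and level of the null band |
| `qtl_additive_effect` | −5 | % NUE per donor copy | donor allele lowers NUE; magnitude 5 |
| `qtl_dominance` | 0 | % NUE | additive by default |
| `phenotype_mean` | 18.05 | % NUE | population mean of the emulated trait |
| `phenotype_sd_env` | 7 | % NUE | environmental noise SD of the study conditions |
| `cm_per_kb` | 0.004 | cM/kb | ≈ 1 cM per 250 kb, a typical rice map density |
| `seq_error_rate` | 0.001 | /read | post-filter short-read error scale |
| `promoter_bp` | 1000 | bp | promoter window upstream of the ATG, inclusive |
| `min_size_diff` | 4 | bp | smallest gel-resolvable InDel length difference |

With effect −5 and `sd_env` 7 the locus explains
$12.5/(12.5+49) \approx 20\%$ of the phenotypic variance and the
population SD is $\sqrt{61.5} \approx 7.8$. We kept `sd_env` at the stated
study condition of 7 rather than back-solving it to force a particular
population SD; the two conventions differ by less than one percentage
point of SD and do not change any qualitative behaviour.

## What the generator emulates — and what it does not

The generator produces, from one master seed: a random reference genome;
parental variant sites (Poisson count at `variant_density`, positions
uniform, SNP/InDel split by `indel_fraction`); an F2 population via a
Haldane crossover process (Poisson crossover count over the chromosome's
genetic length, uniform positions, no interference); single-QTL phenotypes
with Gaussian noise; extreme bulks with stable id tie-breaking; and
Poisson-Binomial pooled depths. Each stage draws from its own seed stream
(fixed offsets from the master seed) so stages are independently
reproducible, and the whole study is byte-identical under one seed.

The default in-silico genome is two 10-Mb chromosomes at
`variant_density` 5e-4 (~10,000 sites, ~25 per window, 4,000 windows).
This is a deliberate desk-scale reduction of a rice genome: 10 Mb at
0.004 cM/kb gives a 40-cM chromosome, long enough that selection-induced
allele-frequency skew decays visibly along the chromosome and the
candidate interval is a proper sub-region, yet small enough that a fifty-
study calibration experiment runs in about a minute.

Simulations use one QTL with additive(+dominance) architecture, uniform
recombination, no crossover interference, unlinked error-free phenotyping
of recombinant panels, and depth-independent error. Real data add
alignment artefacts, repeat-region miscalls, segregation distortion,
multi-QTL architectures and phenotyping error; passing tests here
demonstrates the statistic and its implementation are correct under the
stated model, not that the model captures every property of field data.

## Numerical and coordinate conventions

* Internal coordinates are 1-based inclusive (VCF/GFF convention); BED
  exports are 0-based half-open, with the conversion round-trip tested.
* Window $j$ on a chromosome covers 1-based positions
  $j\cdot\text{step}+1$ … $j\cdot\text{step}+\text{window}$; means are
  unweighted over member sites; windows with no sites carry `NA` and are
  excluded from interval calling, never imputed. Sites with zero depth in
  either pool are dropped before the index filter.
* Null-band quantiles use empirical order statistics with linear
  interpolation (R type 7).
* Candidate intervals are maximal runs of *consecutive* significant
  windows; a single intervening non-significant window splits a run even
  though 50-kb windows 5 kb apart overlap genomically.
* Report rates round half-up (half away from zero) to 2 decimals, the
  convention of sequencing summary tables, with a small epsilon guard
  against binary representation of `x.xx5`.
* Shapiro–Wilk is the normality statistic; it is undefined (reported `NA`
  with a warning) for constant data or n < 3. Sample SD uses the n−1
  denominator. Negative NUE values are kept, flagged, and allowed to rank.
* Codon translation uses the standard nuclear code; minus-strand genes are
  handled by reverse-complementing both the coding sequence and the
  alternate allele. "Splicing" means the two intronic bases flanking any
  exon–intron junction; exonic junction bases take their coding effect.
  The promoter window is measured from the translation start (ATG), not
  the transcription start, with an inclusive boundary.
* In-frame InDels fully contained in the CDS are re-translated to detect
  created or removed stop codons; InDels straddling a CDS boundary are
  reported as plain in-frame without re-translation. InDel inputs are
  assumed VCF left-anchored.

## Open design choices

Several points were genuinely open; the package's choices and reasons:

* **Null model: simulation, not permutation.** "Replacement tests" for
  pooled allele frequencies can mean permuting pool labels or simulating
  segregation; the package simulates segregation (the Takagi-style null),
  which captures depth dependence and requires no per-site data reuse.
  Pool-label permutation is not implemented.
* **Δ orientation.** Δ = high-pool − low-pool, configurable and logged.
  With the donor allele lowering the trait, Δ is negative at the QTL.
* **Depth-specific thresholds.** Bands are per-window at the window's
  mean depth, because depth varies along the genome and the null width
  depends on it; a single genome-wide depth would mis-calibrate tails of
  the depth distribution.
* **Substitution-mapping endpoints.** The mapped interval extends from
  the concordant-marker run outward to the nearest flanking *discordant*
  markers. These carry the recombination breakpoints that exclude the
  QTL, so the returned interval is conservative and provably contains the
  QTL on error-free panels (verified over 50 seeded panels); reporting
  only the concordant markers' span can miss a QTL sitting between a
  concordant and a discordant marker.
* **Heterozygotes in concordance.** Default `recessive_donor` (H
  phenotypically like the recipient homozygote), matching a recessive
  low-trait donor allele; an `exclude` mode drops H calls from
  concordance for additive interpretations.
* **Stop changes are their own classes.** `stop_gain`/`stop_loss` are
  reported separately from `nonsynonymous`; all three, plus `splicing`
  and `frameshift`, count as large-effect.
* **Family means.** F2 individuals phenotyped via F2:3 families use the
  arithmetic family mean; the max/min range ratio is reported as computed
  from the data, whatever the inputs imply.
* **Tie-breaks.** Bulk selection orders by (phenotype, id) so equal
  phenotypes resolve deterministically and the two bulks are always
  disjoint.

## Problem sizes and runtime

The shipped test and acceptance experiments use the default two-
chromosome 20-Mb genome: 50 no-QTL studies for null calibration, 20
planted-QTL studies for recovery and the pool signature, 50 recombinant
panels for substitution-mapping coverage, and 20 seeds per effect level
for the power-monotonicity property. On one CPU the full test suite runs
in ~3–4 minutes and the acceptance script in ~2.

## Known limitations

Single-QTL phenotypes only (no epistasis, no multi-QTL); no read-level
FASTQ/BAM simulation or alignment; no G′ or other BSA statistics beyond
the SNP-index family; no multiple-testing correction beyond the
simulation band (deliberately, to match standard QTL-seq practice); GO
enrichment and primer thermodynamics are out of scope. The recombinant
panel generator produces homozygous single-breakpoint recombinants with
error-free phenotype classes — the idealized fixture substitution mapping
assumes — so it exercises the mapping logic, not phenotyping robustness.
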