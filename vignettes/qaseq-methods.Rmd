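---
title: "qaseq: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qaseq: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qaseq)
```

This vignette is the package's own account of the statistics it
implements: the counting model, the stochastic layers of the simulator,
the CNV and mutation calling procedures, and the places where the design
was genuinely open and a choice had to be made. Nothing here states an
empirical result that the test suite does not itself compute.

## 1. Absolute quantitation by UMI family counting

Each quantitation module is one amplicon. Before exponential
amplification every input molecule is tagged with a unique molecular
identifier (UMI); all reads sharing a `(module, UMI)` key form a family
descended from one molecule. The molecule count of a module is the number
of families passing two filters:

* an absolute floor: families with fewer than `min_reads = 3` reads are
  discarded as polymerase/sequencing error products;
* a relative cutoff: 5% of the mean of the three largest family sizes in
  the module (`family_size_cutoff()`).

The two published rules are composed as
`max(min_reads, fraction * mean(top 3))` — the conservative reading, since
either rule alone admits families the other would reject. Families exactly
at a non-integer cutoff pass (`>=` comparison), stated explicitly for
bit-exact reproducibility. The cutoff is computed **per module**, not per
run, because amplification efficiency — and therefore the family-size
scale — varies between amplicons.

The *conversion yield* is the fraction of input molecules recovered as
counted families. It is the assay's efficiency metric: with `10 ng`
genomic DNA (`mass_to_copies(10)` = 2,790 haploid copies) a yield of 0.86
means roughly 2,400 counted families per module.

## 2. The simulator: a stated world

`sim_config()` + `simulate_run()` generate FASTQ reads plus full ground
truth. The layers, in order, with defaults and their rationale:

| layer | parameter (default) | what it models |
|---|---|---|
| input sampling | `input_mass_ng` / `input_copies`; `haploid_genome_mass_pg = 3.584` | Poisson draw per module with mean `copies x ploidy/2`; the mass constant is chosen so 10 ng is exactly 2,790 haploid copies |
| barcoding | `conversion_yield = 0.86` | each duplex independently recovered as one countable family; UMIs uniform over `4^12` |
| amplification | `pcr_cycles = 12`, `high_eff_cycles = 5`, `per_cycle_efficiency = 0.80`, `efficiency_sd = 0.05` | branching process; see below |
| depth | `mean_depth_per_module = 90000` | multinomial read sampling over family sizes |
| errors | `per_base_error_rate = 0.002` | i.i.d. substitutions over the whole read |
| off-target | `off_target_fraction = 0.4` | primer-dimer/non-specific reads with random primer regions (about 60% on-target is typical for large multiplex panels) |
| variants | `spiked_variants` | a binomial share of barcoded molecules carries the alt base on every read, pre-error |

**Amplification model.** Family sizes are generated by a Galton–Watson
branching process, so the observed log-normal family-size distribution is
*emergent*, not assumed. Two refinements matter:

1. The first `high_eff_cycles = 5` cycles run at efficiency
   `max(e, 0.995)`. These represent the long-annealing barcoding/nested
   steps of the wet protocol, which are engineered for near-complete
   extension. Without them, Bernoulli duplication failures at copy number
   1–2 put heavy discrete atoms at half/quarter size and the log-size
   distribution is strongly left-skewed — qualitatively wrong for this
   assay class.
2. Each family draws its own per-cycle efficiency once, from
   TruncNormal(0.80, 0.05) on [0, 1]. Random per-molecule yield
   differences amplified exponentially over the remaining cycles are
   exactly what makes family sizes log-normal; a single shared efficiency
   cannot produce that shape. The truncated normal is used rather than a
   Beta because the log-growth-rate spread should be symmetric — a Beta
   pinned near its upper bound is itself left-skewed and re-introduces the
   artifact. A mean efficiency of 0.8 with 5% per-molecule spread is a
   realistic operating point for highly multiplexed PCR.

Setting `efficiency_sd = 0` and `high_eff_cycles = 0` recovers the
classical fixed-efficiency process (mean family size `(1+e)^C`), which the
unit tests exercise separately.

**What the simulator does not emulate.** Paired-end reads, indels, PCR
chimeras and recombination, quality-score error profiles, UMI-length
variation, GC-dependent efficiency, and library-to-library technical
variation beyond molecule sampling. A green test therefore establishes
correctness of the *counting and calling machinery* under the stated
noise model — not performance on any particular instrument or chemistry.
In particular, replicate-level CV in real data includes technical
components the simulator deliberately omits, so simulated CVs sit at the
Poisson floor.

## 3. Read assignment

Reads are laid out `[UMI][forward primer][insert]`; the simulator fixes
this convention (UMI 5' of the gene-specific primer) and the assigner
relies on it. Assignment is alignment-free: Hamming distance between the
post-UMI window and every panel primer, accepting the unique module within
`max_mismatches = 2`. Ties and no-hits stay unassigned — an ambiguous read
must never inflate an absolute count — and ambiguous reads are not rescued
by insert comparison for the same reason. Exact matches are resolved by
hashing, so only error-carrying reads take the scan. Reverse-complement
search is not performed (the simulator emits one orientation); the flag
space is reserved for real-data dialects.

## 4. CNV calling

Per-module ploidy is `2 x count / mean(reference counts)`; a gene's
ploidy is `2 x mean(gene module counts) / mean(reference counts)`. The
mean (not median) matches the module-ensemble definition of the gene
estimate; `estimator = "median"` is available for outlier-heavy data.

`call_cnvs()` proceeds sequentially: testable genes (at least
`min_modules_per_gene_for_test = 3` non-excluded modules — below that a
rank test is meaningless and the gene is reported untestable) are ordered
by `|estimate - 2|` descending and each is tested against the panel-fixed
reference module ploidies with a two-sided Mann–Whitney U test, followed
by Benjamini–Hochberg correction across tested genes. Significant genes
report their point estimate and direction; everything else is reported at
exactly 2.00. The exact sequential scheme of the original pipeline is not
published in detail; ordered testing with a fixed reference and BH
correction is this package's documented stand-in, and both the ordering
and the correction are arguments.

**Mann–Whitney conventions.** With both samples of size at most 8 and no
ties, the exact Wilcoxon rank-sum null distribution is used with the
symmetric two-sided rule `min(1, 2 min(P(U <= u), P(U >= u)))`; the test
suite verifies this against brute-force enumeration of all rank
assignments. Otherwise the normal approximation with tie correction and a
0.5 continuity correction is used. Identical constant samples have zero
rank variance and return p = 1.

**Precision diagnostics.** `cv_vs_modules()` subsamples `m` modules
(averaging over `n_random = 30` selections, since many down-selections
exist), computes the replicate CV of the gene ploidy, and compares with
the Poisson prediction `sqrt(1/(mN) + 1/(m_ref N))`. A single 5-replicate
CV estimate carries ~36% relative noise (chi distribution with 4 df), so
scaling-law tests average the curve over independent replicate sets.
`lod_from_replicates()` brackets detectable ploidy at
`mean ± k_sigma x sd` with `k_sigma = 3` by default; `k_sigma` is exposed
because the multiplier used for any particular published bracket is not
derivable from first principles.

**Companion tests.** The 2x2 chi-square test of independence
(`chi_square_independence()`) defaults to *no* Yates continuity
correction — with small clinical tables the corrected and uncorrected
tests disagree substantially, and the uncorrected Pearson statistic is the
convention this package follows. `two_sample_t()` is Welch's test:
replicate groups of different sizes have no reason to share a variance.

## 5. Mutation calling

Families passing the size cutoff are collapsed to a per-position consensus
(`consensus_families()`): modal base if its fraction reaches
`min_concordance = 0.8`, else `N`. Calls are made at molecule level:
`VAF = alt families / non-N families` at the position, requiring
`min_alt_families = 3` supporting molecules. The family-level denominator
(rather than read-level) is precisely what UMI error correction buys: a
sequencing error must dominate an entire family to survive, which at
family size >= 3 and per-base error ~0.002 is vanishingly rare — hence
molecule-level VAFs are quantitative down to 0.1%. The threshold of 3 alt
families suppresses residual consensus/chimera artifacts; it is a
configurable stand-in, as the originating pipelines do not publish their
exact error model. Substitutions only; indels are out of scope end to end.

## 6. Tumor fraction and tumor ploidy from plasma

The cfDNA mixture model:

* forward: `Ploidy(cfDNA) = sum_i p_i f_i + 2 (1 - sum_i f_i)` and
  `VAF(cfDNA) = sum_i v_i f_i` over tumor subclones (multi-clone supported
  forward-only, for simulation);
* inversion (single clone, monoallelic `v = 0.5`):
  `f = 2 x VAF(cfDNA)`, then
  `Ploidy(tumor) = (Ploidy(cfDNA) - 2 (1 - f)) / f`.

The inversion is only offered under those two stated assumptions; if the
mutation is biallelic the fraction is exactly 2-fold overestimated (an
assertable property, and the reason results carry a note attribute). VAFs
in [1%, 30%] are the trusted inversion window — above that germline SNPs
intrude, below it quantitation noise dominates; outside the window the
result is annotated, not refused. Negative inferred ploidy (plasma ploidy
below the normal-DNA floor `2(1-f)`) flags inconsistent inputs and is
returned with `valid = FALSE` rather than clamped, because clamping would
silently hide a contradiction the user needs to see.

## 7. RNA expression

Gene counts are the mean of yield-adjusted amplicon counts
(`count / yield`); per-amplicon yields default to 1 unless a calibration
is supplied. Expression is `log2(count) - mean(log2(reference counts))`,
i.e. normalization to the geometric mean of the reference genes — the
arithmetic-mean-of-logs convention is this package's documented dialect.
Two invariants pin the normalization: global rescaling of all counts
leaves every value unchanged, and the reference genes' own values average
to zero exactly. `replicate_sd_vs_amplicons()` recomputes expression from
the first `m` amplicons per gene (5'-most first, matching how fragmented
RNA is assayed) to quantify the variance reduction from multi-amplicon
ensembles; reverse-transcription efficiency is not modeled separately but
absorbed into the conversion yield, matching cDNA-as-input designs.

## 8. Numerical and degenerate-input policy

* Cutoffs: `>=` comparisons throughout; per-module cutoffs; with fewer
  than 3 families the top-size mean runs over what exists.
* Zero reference mean, empty size lists, zero-margin tables, sub-minimum
  replicate counts: domain errors, not NA propagation.
* UMI collisions are accepted, not corrected: with `4^12 ~ 1.7e7` UMIs
  and thousands of molecules per module the per-module collision
  probability is ~1e-4 and biases counts down negligibly.
* Optional UMI error collapse (Hamming-1 neighbour at >= 10x size) exists
  but is off by default — the size cutoff already absorbs error families,
  and silent merging would change counts in well-behaved runs.
* All simulator randomness flows from one integer seed; identical
  configuration and seed give byte-identical FASTQ and tables.

## 9. Known limitations

* Primer-based assignment presumes panel primers are mutually distant;
  `random_panel()` guarantees this, real panels should be checked.
* The sequential-test order and reference-refinement rule of the original
  multiplexed CNV pipeline are stand-ins (Section 4).
* Counting is duplex-level: one family per barcoded molecule. Strand-level
  (duplex-consensus) chemistry is out of scope.
* The simulator's off-target reads are unassignable by construction;
  structured artifacts (primer cross-hybridization producing assignable
  chimeras) are not modeled, so specificity against such artifacts is
  untested here.
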