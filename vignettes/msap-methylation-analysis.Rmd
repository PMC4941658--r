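---
title: "Scoring and analysing MSAP cytosine methylation profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and analysing MSAP cytosine methylation profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msapr)
```

## The assay and its scoring model

Methylation-sensitive amplified polymorphism (MSAP) is an AFLP variant
that probes cytosine methylation at 5'-CCGG sites without prior sequence
knowledge. Genomic DNA is digested in two parallel reactions with the
isoschizomers HpaII and MspI (each paired with EcoRI), amplified with
selective primers, and each amplified fragment (a *locus*) is scored
present (1) or absent (0) in each lane. The two enzymes recognise the
same site but differ in methylation sensitivity:

* both cut unmethylated CCGG;
* HpaII is blocked when either cytosine is methylated on both strands;
* MspI is blocked when the external cytosine is hemi-methylated.

For the (HpaII, MspI) lane pair this yields a bijective scoring rule on
the three informative patterns, plus one uninformative class:

| pattern (H, M) | called state | biochemistry |
|---|---|---|
| (1, 1) | `NON`   | unmethylated CCGG |
| (0, 1) | `FULL`  | internal cytosine methylated on both strands |
| (1, 0) | `HEMI`  | external cytosine methylated on one strand |
| (0, 0) | `UNINF` | site absent *or* methylation blocking both enzymes |

`classify_band_pair()` implements exactly this map and `call_states()`
applies it element-wise to a `band_matrix`. Two conventions follow from
the biochemistry and are applied consistently downstream:

* `UNINF` is never imputed. Band absence in both lanes cannot distinguish
  a missing restriction site from doubly-blocked methylation, so these
  loci are excluded from every class-specific statement (they match no
  transition symbol except the explicit `U`, they count as unmethylated
  in the breadth indicator, and they are dropped from expression
  associations).
* Relative levels use the **total-marker denominator**: each class
  percentage divides by all loci of the analysed set, not by informative
  loci only. The methylation levels are therefore *relative* — the four
  class percentages sum to 100 and `UNINF` depresses the others — which
  mirrors how such surveys report their levels. Subset analyses (e.g. a
  candidate-gene panel) use the subset size as denominator.

## Polymorphism, breadth and sharing

A locus is *polymorphic* when its called state differs between at least
two samples (`find_polymorphic()`); since the pattern-to-state map is a
bijection, defining polymorphism on raw lanes would give the same set.
Methylation breadth is summarised by the tau specificity score over
$n$ samples,

$$\tau_i = \frac{\left(\sum_{j=1}^{n} M_{ij}\right) - 1}{n - 1},$$

where $M_{ij} = 1$ if locus/gene $i$ is methylated (`HEMI` or `FULL`) in
sample $j$ and 0 otherwise (`NON` and `UNINF` both map to 0). Thus
$\tau = 1$ means methylated everywhere (no specificity) and $\tau = 0$
methylated in exactly one sample. For breadth 0 the formula would give a
meaningless negative "specificity", so `tau_score()` returns `NA` there:
the score is defined on methylated genes only.

Sharing statements follow set algebra on the class indicator:
`shared_sites()` counts loci carrying a class in *every* member of a
subset, where for the `METHYLATED` class each member may be `HEMI` or
`FULL` independently — which is why a shared-methylated total can exceed
the sum of shared-full and shared-hemi counts. `specific_sites()` counts
loci carrying a class in exactly one sample; summed over samples, the
`METHYLATED`-specific counts equal the number of breadth-1 loci. Because
a published tissue-specific total could have been computed either on the
pooled methylated class or per class and then unioned, both readings are
available by calling `specific_sites()` with each `class` argument.
`venn_regions()` emits exhaustive region counts for subsets up to five
samples; beyond five the output would explode combinatorially, so larger
subsets are served by `shared_sites()` on demand.

## Stage-path dynamics

`count_transitions()` matches loci position-wise against a pattern over
an ordered stage path, with alphabet `N`, `H`, `F` (exact states), `M`
(methylated: `H` or `F`) and `U` (`UNINF`). `UNINF` matching nothing but
`U` is a deliberate reading: transition rows describe determinate state
changes, and a locus that drops out of a stage should not be counted as
"non-methylated" there. With `U` in the alphabet, the fully-specified
patterns over a path partition the locus set — a property the tests
exercise. The built-in `default_transition_queries()` encodes the ten
classical patterns: three over leaf maturation and seven over the
vascular path, listed in phloem–cambium–mature-xylem column order (the
vascular rows condition on cambium as the developmental reference but
are printed in that column order, and the queries follow the printed
form).

## Methylation and expression

`group_expression()` partitions genes by their called state in one
tissue and compares mean expression pairwise with two-sided t-tests.
Expression is `log2(x + 1)`-transformed by default because qRT-PCR and
FPKM scales are multiplicative; raw-scale analysis is a flag away.
`pattern_correlation()` pools gene-by-tissue pairs — by default over the
four vascular tissues, where transcriptome data are typically available —
and correlates an ordinal state encoding with expression.

The encoding `NON = 0 < FULL = 1 < HEMI = 2` orders states by expected
transcriptional suppression, reflecting the observation that
hemi-methylation silences more strongly than full internal-cytosine
methylation in this system. No standard numeric encoding exists for
MSAP states; this choice is an interpretation, is configurable, and is
recorded in every result object that uses it. Under it, stronger
suppression produces a *negative* correlation with expression.

Statistical conventions: the default two-sample test is the classical
equal-variance Student t (the procedure such surveys report), with Welch
available via `var_equal = FALSE`. Degenerate inputs are given defined
results rather than errors where a definition is natural: two identical
constant groups give $t = 0$, $p = 1$; a comparison group with fewer
than two genes yields `NA` with a warning; zero variance in either
correlation vector yields `NA` with a warning. Raw p-values are reported
for the (three) level metrics without multiplicity correction, matching
the analysis this package reproduces; users testing many metrics should
adjust externally.

## The synthetic-data generator

Real MSAP gel data for the reference survey are not available, so the
package ships a generator whose defaults *are* the study conditions and
whose truth is returned alongside the data:

* **Biochemical states first.** Each locus × sample draws one of
  `UNMETH`, `INTERNAL_FULL`, `EXTERNAL_HEMI`, `BLOCKED_BOTH`; bands
  follow deterministically via the enzyme-sensitivity map
  (`simulate_band_pattern()`). Calling the simulated bands must return
  the truth except on `BLOCKED_BOTH`, which is called `UNINF` — the
  assay's documented information loss. The generator exposes blocked
  methylation and site absence as a single knob because the data cannot
  distinguish them.
* **Per-tissue class frequencies** (`default_class_probs()`) are
  calibrated to the observed ranges: hemi-methylation ~7.9–11.9% with
  the shoot apex highest, full methylation ~9.4–14.2% with the phloem
  highest, non-methylation ~33–39%, the female catkin poorest in both
  methylated classes, and the remainder (~40%) uninformative.
* **Ten samples, 10³–10⁴ loci** grouped into primer pairs of 11–204
  loci with fragment lengths 55–550 bp, matching the survey's scale
  (the analysis scripts use 10,000 loci; unit tests use 50–500 for
  speed, and the law-of-large-numbers check uses 10⁵).
* **A monomorphic block** (default 18% of loci, drawn once from the
  across-tissue mean frequencies and copied to every sample) calibrates
  marker polymorphism to the observed ~82%.
* **Stage series** evolve called states along an ordered path under a
  row-stochastic transition matrix, returning the exact count of every
  fully-specified pattern; specific patterns can be forced onto leading
  loci to build constructed ground truth.
* **Expression** is log-normal with additive log-scale suppression:
  $x = \exp\!\big(\mathcal{N}(\mu - \delta(\text{state}),\ \sigma)\big)$
  with $\delta(\text{NON}) = 0$, defaults
  $\delta_{\text{full}} = 0.5 < \delta_{\text{hemi}} = 1.0$ and
  $\sigma = 0.5$ — the simplest multiplicative-noise model that
  reproduces the hemi > full suppression ordering. `UNINF` genes get the
  unsuppressed baseline.
* **Replicates** (three biological replicates per tissue in the source
  design) can be emitted with per-cell band-flip noise; how replicates
  were reconciled is not documented for the source survey, so the
  package provides a transparent convention: majority vote per cell with
  ties called `UNINF` (`consensus_states()`).

All generators are bit-reproducible given a seed.

### What the generator does and does not emulate

It reproduces the marginal class frequencies, the polymorphic fraction,
the stage-transition structure and the suppression ordering — enough to
verify that every pipeline operation recovers what was put in. It does
**not** emulate fragment co-migration, primer-pair-specific banding
biases, spatial correlation of methylation along chromosomes, or
tissue-correlated methylation profiles beyond the monomorphic block.
One visible consequence: uniformly methylated monomorphic loci make the
"common pattern in every tissue" fraction of synthetic data (a few
percent) larger than the very rare common patterns of the real survey,
where tissue profiles diverge more richly than an i.i.d. model allows.
Passing tests therefore demonstrate the *correctness of the
computations*, not that real gels are this well behaved — scoring errors,
co-migrating fragments and replicate disagreement in real data enter
upstream of this pipeline.

## Worked example

```{r pipeline}
cfg <- simulation_config(n_loci = 2000, seed = 7)
gen <- generate_band_matrix(cfg)
states <- call_states(gen$bands)
identical(states, gen$truth_states)

find_polymorphic(states)$summary

profs <- relative_levels(states)
summarize_levels(profs)

compare_groups(profs, default_groups(), "methylated_pct")
```

```{r tau}
head(tau_table(states))
tau_score(rep(1, 10))          # methylated in all ten samples
tau_score(c(1, rep(0, 9)))     # methylated in exactly one
```

```{r dynamics}
transition_table(states, default_transition_queries())
```

```{r association}
expr <- generate_expression(gen$truth_states, cfg, seed = 8)
group_expression(states, expr, "cambium")
pattern_correlation(states, expr)[c("r", "p_value", "n_pairs")]
```

## Numerical choices and limitations

* Percentages are stored at full precision and rounded only for display,
  to avoid cascading rounding error.
* Missing band cells are rejected, not imputed: the scoring scheme
  presumes every locus was scored in every lane, and an explicit `NA`
  token in a band file is an error with coordinates.
* Sample order in input files is authoritative for default stage paths.
* The TSV dialect is fixed (tab, UTF-8, `.` decimal, no quoting) so that
  fixtures roundtrip bit-exactly; `read_*` functions never silently
  coerce and always report the offending cell.
* The pipeline treats any binary presence matrix identically, whatever
  electrophoresis platform produced it (denaturing polyacrylamide gels
  and capillary traces are not distinguished).
* The package analyses called states only; it does not resolve
  co-migrating fragments, process gel images, or map methylation within
  gene bodies (bisulfite-level analysis is out of scope).
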