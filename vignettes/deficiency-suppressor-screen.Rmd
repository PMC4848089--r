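---
title: "Models and methods behind defsup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind defsup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

defsup implements the quantitative machinery of a dominant deficiency
suppressor screen in a *Drosophila* nonsense-mediated decay (NMD) mutant,
together with the downstream genomic and molecular statistics such a screen
relies on. This vignette documents the models, the parameters that matter,
the numerical choices, and what the bundled simulator does and does not
emulate.

```{r setup}
library(defsup)
```

## The screen and its score

An X-linked, partially viable NMD mutation is crossed to a collection of
autosomal deficiencies, each carried over a balancer chromosome. Scoring all
F1 males in a cross yields a 2×2 table: mutant vs non-mutant X chromosome
crossed with deficiency vs balancer autosome. The Deficiency Suppression
Score is

$$\mathrm{DSS} \;=\; \frac{\texttt{mut\_df}}{\texttt{mut\_df}+\texttt{bal\_df}}
 \;-\; \frac{\texttt{mut\_bal}}{\texttt{mut\_bal}+\texttt{bal\_bal}},$$

the proportion of Df/+ males that are mutant minus the same proportion among
Balancer/+ males. The balancer arm controls for the deficiency's general
viability cost, so DSS isolates the deficiency's specific effect on mutant
survival. A score **strictly greater than 0.1** calls the deficiency a
suppressor; the cutoff is a fixed-effect threshold, not a hypothesis test,
and its false-positive rate therefore falls as progeny counts grow (the test
suite reports this operating characteristic). DSS is kept on the fraction
scale in $[-1, 1]$. Replicate rows sharing a deficiency are pooled (counts
summed) before scoring, the convention used throughout.

`compute_dss()` requires both arms non-empty and names the empty arm
otherwise. Two exact invariances pin the arithmetic down: swapping the Df
and Bal columns negates the score, and scaling all four counts by a common
positive integer leaves it unchanged.

## Viability statistics

Mutant viability from a balancer cross is the mutant:balancer ratio
normalized to the same ratio from a parallel control cross
(`normalized_viability()`). Its confidence interval is computed on the
test-cross mutant *proportion* — the ratio-of-ratios has no standard
interval, and the proportion is what the error bars describe. Binomial
intervals use the **Wilson score** form (`binomial_ci()`): it is standard
for proportions, behaves well at small n and at the 0/1 boundaries, always
lies inside $[0, 1]$ and always contains the point estimate. Differences in
proportions use the chi-square test of equal or given proportions
(`test_equal_proportions()`, `stats::prop.test()` under the hood) with the
Yates continuity correction on by default and toggleable — the correction
choice is a convention, so it is exposed. Replicate means are compared with
Student's t-tests (`two_sample_t()`), with a zero-variance guard that
reports p = 1 rather than failing on degenerate data, and summarised with
±2 SEM half-widths (`sem2()`), a close approximation of the 95% interval.

## Candidate-region refinement

Each deficiency is an interval on a chromosome (0-based, half-open — the BED
convention — throughout). Candidate suppressor regions are

$$\bigcup_{\text{suppressors}} \text{span} \;\setminus\;
  \bigcup_{\text{non-suppressors}} \text{span},$$

computed per chromosome and emitted as maximal disjoint intervals labeled in
coordinate order (`refine_candidate_regions()`). Every base deleted by any
non-suppressing deficiency is eliminated: a gene whose removal suppresses
cannot lie where removal failed to suppress. Uncertain breakpoints are
handled conservatively: elimination and support both use the certainly
deleted (inner) span, while maximal (outer) spans enter only coverage
summaries — an uncertainly deleted base neither supports nor eliminates.
Abutting intervals merge; zero-length remnants are dropped. `min_support`
optionally drops whole regions overlapped by fewer than k suppressing
deficiencies; support is counted per maximal region, the natural unit of the
candidate list. The interval algebra is delegated to IRanges; the test suite
checks it against an independent per-base membership oracle on hundreds of
randomized toy genomes.

## Genomic load

Loss of NMD stabilizes many transcripts, so a deficiency might suppress
simply by removing a large amount of over-expressed mRNA. The regional load
statistic quantifies that possibility in a fixed order:

1. **RPM**: each library is scaled to one million reads
   (`rpm_normalize()`).
2. **Ribosomal rescale**: mutant samples are divided by the ratio of mean
   ribosomal-protein RPM in mutant vs control samples
   (`ribosomal_rescale()`). Equal sequencing depth does not mean equal
   cellular mRNA when a degradation pathway is lost; ribosomal-protein
   genes, assumed unchanged, anchor the scale. The reference set is supplied
   explicitly (one gene id per line); the simulator flags 74 by default.
3. **Regional sums**: rescaled RPM summed over the genes each deficiency
   removes, per sample (`regional_load()`). A gene counts when its span
   overlaps the deficiency span at all (`contained = TRUE` demands full
   containment).
4. **Replicate means within condition**, then
   `percent_increase = (load_mutant − load_control) / 10^6` — the mutant
   excess as a fraction of a one-million-read library, taken literally;
   `as_fold = TRUE` offers the conventional relative view
   `(mutant − control)/control`.

The order matters: rescaling raw counts before RPM would be undone by the
per-library renormalization whenever the rescale factor differs from 1 (a
regression test pins this down). `correlate_dss_load()` then reports the
Pearson correlation between DSS and percent increase with the usual
$t = r\sqrt{(n-2)/(1-r^2)}$ significance test; a weak correlation argues
that suppression is locus-specific rather than a bulk-load effect.

## Molecular assays

**Half-life** (`fit_halflife()`): after transcription shutoff, expression is
modelled as first-order decay $E(t) = E_0 e^{-kt}$, $t_{1/2} = \ln 2 / k$.
Replicates are averaged per time point first and the fit is ordinary least
squares of log mean expression on time — the appropriate estimator for the
two-to-three-point actinomycin time courses these assays produce, and exact
to machine precision on noise-free exponentials. A non-positive fitted rate
is reported as "stable" with infinite half-life rather than a negative one.

**Relative expression** (`relative_expression()`): qPCR folds use
$2^{-\Delta\Delta C_t}$ with $\Delta C_t = C_t^{target} - C_t^{reference}$
referenced to the control-condition mean, assuming perfect amplification
efficiency (no efficiency correction; the assays this emulates normalize to
a ribosomal reference transcript). Inputs already on the linear scale take
the direct ratio path. The reference subtraction makes the fold invariant to
sample-wide Ct shifts, which the tests assert.

**Allele stabilization** (`allele_ratio_gel()`, `allele_ratio_sanger()`):
for a restriction site destroyed by a premature-termination-codon allele,
ethidium stain intensity is proportional to mass, so molar abundance is
intensity/length, with the two cut fragments' intensities and lengths
summed; the ratio is uncut (PTC) over cut (wild type), normalized to a
designated control condition. Sanger chromatogram peak heights at the
distinguishing base are used directly. A zero wild-type signal yields an
infinite-ratio flag rather than an error.

## The synthetic screen generator

`simulate_screen()` produces every input the pipeline consumes, under one
seed, with deterministic per-unit substreams (hash-derived seeds per cross,
gene and curve) so that extending a simulation never perturbs earlier draws.

* **Genome**: one toy chromosome (default 1 Mb) with 400 non-overlapping
  gene spans; 100 deficiencies tile it gap-free with 15% pairwise overlap —
  a desk-scale analogue of a few hundred molecularly defined deficiencies
  covering a genome. One gene is the *driver*, the true suppressor locus; a
  deficiency "deletes" a gene when their spans overlap.
* **Crosses**: N zygotes (default 200 scored males, a realistic fly-cross
  yield; several checks use 4000 to study the large-N regime) are allocated
  multinomially with probability 1/4 per genotype class — the simplest
  exchangeable model consistent with Mendelian segregation, since brood
  structure is not part of the model — then survival-thinned: the mutant
  class survives with probability `v0 = 0.10` (the partially viable NMD
  mutant's 10% baseline) or `v1 = 0.30` when the deficiency deletes the
  driver; balancer classes survive unconditionally. Only males are
  generated, matching a screen that scores F1 males. Under this model the
  expected DSS of a driver-deleting cross is
  $v_1/(1+v_1) - v_0/(1+v_0) \approx 0.140$, the closed form the tests
  recover.
* **Expression**: negative-binomial counts, lognormal baseline means
  (median 100, sdlog 1), shared dispersion 0.1
  (variance $\mu + 0.1\mu^2$), two conditions × two replicates (matching
  the two-plus-two library design such screens draw on); the driver's mean
  is multiplied by 16.7 in the mutant — the fold by which the causal
  stress-response transcript rises when NMD is lost — and 74 flagged
  ribosomal genes are unchanged.
* **Decay**: for each half-life (defaults 0.5, 1, 2, 4 h) and replicate,
  relative expression $2^{-t/h}$ at t = 0, 1, 2 h with multiplicative
  lognormal noise (CV 0.05, mean 1), then renormalized to the t = 0 value so
  every curve starts at exactly 1 — noise must be multiplicative for
  relative expression to stay positive.

What the generator does **not** emulate: read-level sequences (counts are
drawn directly), female progeny and maternal effects, brood structure or
cross-to-cross viability heterogeneity, breakpoint uncertainty (simulated
deficiencies have exact breakpoints; the refinement machinery still accepts
inner/outer spans), genuine biological covariance between neighbouring
genes, and genome-wide NMD-target sets beyond the single driver. Passing
tests therefore demonstrate correctness of the arithmetic and the
recoverability of a planted signal under idealized noise — not performance
on real screens, where viability effects are heterogeneous and expression
changes are polygenic.

## Numerical conventions and edge cases

* Coordinates are 0-based half-open everywhere; BED files read/written
  natively, with `one_based = TRUE` converting 1-based inclusive input by
  `start − 1`. BED scores hold `round(1000·DSS)` clamped to [0, 1000];
  exact scores travel in a sidecar TSV because the BED score column cannot
  represent them.
* Strict inequality at the suppressor threshold: DSS exactly 0.1 is not a
  suppressor.
* Zero denominators (empty cross arms, zero-total libraries, zero ribosomal
  signal, missing reference genes) raise typed errors naming the offender;
  degenerate statistics (zero-variance t-tests, flat decay curves, zero
  wild-type allele signal) return flagged results instead of errors when a
  principled value exists.
* Wilson bounds are clamped against floating-point noise so the interval
  always contains the point estimate.
* Ties and abutting intervals: unions merge `[a,b) [b,c)` into `[a,c)`;
  subtraction drops empty remnants.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run entirely on simulated data:
10^4 random cross tables against the direct-arithmetic oracle; 500
randomized toy genomes (up to 10^5 bases, up to 50 deficiencies) against the
per-base oracle; 1000 replicate crosses at N = 4000 for the closed-form DSS
expectation; 100 replicate screens (100 deficiencies each) for driver
recovery and call operating characteristics; 500 noisy decay curves for
half-life recovery; and 40 replicate expression screens for the load-ranking
property. These sizes give Monte-Carlo standard errors comfortably inside
the tolerances asserted.

## Known limitations

The viability CI describes the test-cross proportion, not the normalized
ratio-of-ratios. The qPCR model assumes perfect efficiency. Half-life fits
weight time points equally on the log scale, which is optimal only under
roughly constant log-scale noise. Region support is counted per maximal
candidate region, so `min_support` filters regions, not bases. No
multiple-testing correction is applied across deficiencies — the screen's
cutoff is a fixed threshold by design, and its calls should be read as a
ranked shortlist, not as hypothesis tests.
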