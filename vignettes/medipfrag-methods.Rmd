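---
title: "Methods: DMR-dependent cfDNA fragmentation analysis"
author: "medipfrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DMR-dependent cfDNA fragmentation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Plasma cell-free DNA (cfDNA) is released when nucleases digest chromatin
during cell death, so its fragment-size distribution carries an imprint of
chromatin structure. DNA methylation compacts nucleosomes; hypomethylated
chromatin is more accessible and is cut more often *within* the nucleosome,
releasing sub-mononucleosomal ("short", 100–150 bp) fragments in addition
to the canonical mononucleosomal ("long", 151–220 bp) ones peaking near
167 bp. In cancer, global hypomethylation plus the shorter fragmentation of
tumor-derived cfDNA should therefore concentrate short fragments in
regionally hypomethylated DNA.

cfMeDIP-seq gives paired libraries per plasma sample: an **Input** library
(the cfDNA pool before enrichment) and an **IP** library (after
immunoprecipitation with a 5-methylcytosine antibody, which retains
methylated molecules). This package implements the complete analysis that
connects the two: fragment-level statistics, windowed differential
methylation between cancer and healthy cohorts, input-adjusted
fragmentation profiles over differentially methylated regions (DMRs), and
a correlation-based classifier — together with a generative simulator that
encodes the mechanism so every stage can be tested against ground truth.

## Statistics computed

* **Short fragments ratio** `R = n_short / n_long`, with the boundary fixed
  at 150 bp (a 150 bp fragment is short, 151 bp is long) and the analysis
  restricted to 100–220 bp. Undefined ratios (no long fragments) propagate
  as missing rather than zero, because a zero would bias window selection
  downstream.
* **Window counts.** Deduplicated IP fragments are counted per 10-kb
  nonoverlapping window; a fragment belongs to the single window containing
  its midpoint `floor((start+end)/2)` (0-based, half-open coordinates
  throughout). Midpoint assignment keeps the count and ratio computations
  consistent and has no boundary ties under integer floor.
* **Differential methylation.** Windows with pooled mean count below 10 are
  removed; per-sample median-of-ratios size factors normalize sequencing
  depth; each window is tested with a negative-binomial Wald test
  (below); Benjamini–Hochberg adjustment; classes are `HYPER` when
  `padj < 0.05` and `log2FC > 1`, `HYPO` when `padj < 0.05` and
  `log2FC < -1`. A raw-p mode (`use_padj = FALSE`) reproduces the
  convention sometimes used for secondary cohorts.
* **Input-adjusted short fragments ratio** of a window:
  `R_IP(window) / R_Input(genome-wide)`, the window's IP ratio scaled by
  the sample's genome-wide Input ratio. This removes sample-level
  differences in short-fragment abundance present before capture. A
  per-window Input denominator is available (`denominator =
  "window_input"`) for sensitivity analysis; the genome-wide form is the
  default because the per-window Input counts (Input is sequenced an order
  of magnitude shallower than IP) are too sparse to be a stable
  denominator, and the genome-wide definition is the operationally complete
  one.
* **Window selection.** Profiles are built over hypomethylated windows
  where *every* sample has at least 20 deduplicated IP fragments and an
  adjusted ratio below 10. Selection is monotone in both criteria.
* **Classification.** The baseline profile is the per-window median
  adjusted ratio of healthy samples; each sample is scored by the Pearson
  correlation `r` of its profile to the baseline; low `r` is cancer-like.
  The operating cutoff maximizes sensitivity + specificity (ties resolved
  toward specificity, then the lower cutoff); prediction is strict
  (`r < cutoff` is cancer). The ROC sweeps all thresholds and the AUC is
  the Mann–Whitney probability with half-credit for ties, which equals the
  trapezoidal integral of the curve.

## The negative-binomial window test

The external count-model packages commonly used for this step bundle many
estimation refinements; this package deliberately implements a minimal,
fully documented pipeline whose correctness is established by null
calibration and planted-effect recovery rather than by numeric parity with
any particular package:

1. normalized counts `y_ij / s_j` with median-of-ratios `s_j` (geometric
   mean reference over windows with all-positive counts; a pseudo-reference
   fallback over positive counts is available for sparse matrices);
2. per-window method-of-moments dispersion
   `alpha = (v - mu * mean(1/s)) / mu^2` from the pooled within-group
   variance `v`;
3. a mean–dispersion trend `a0 + a1/mu` fitted by least squares across all
   windows on the *unfloored* moment estimates — including negative ones,
   so that pure sampling noise averages out instead of biasing the trend
   upward — with coefficients floored at zero;
4. the working dispersion `max(1e-8, 0.5 * max(alpha, 0) + 0.5 * trend)`,
   a 50/50 shrink that stabilizes the 3-vs-3 design;
5. a Wald z-test of the group coefficient in an NB log-link GLM with
   `log(s_j)` offsets and the dispersion held fixed;
6. the reported effect `log2((mu_cancer + 0.5)/(mu_healthy + 0.5))` on
   normalized group means, with the 0.5 pseudocount bounding zero-count
   windows without shrinkage machinery.

On simulated null cohorts (exchangeable groups, ~2000 windows, 3 vs 3)
the raw p-value fraction below 0.05 sits near 0.04 — slightly conservative
because the moment estimate is floored at zero before shrinkage — and no
window reaches `padj < 0.05` with `|log2FC| > 1`. In the large-count,
small-dispersion limit the Wald p agrees with a pooled-Poisson normal
approximation within a factor of two on the `-log10` scale.

## The generative model

Each simulated sample draws `N_in` Input fragments (default 200,000):

* the source window is uniform; the window's methylation `m` is drawn once
  per cohort from Beta(8, 2) (mean 0.8, the genome-wide methylation level
  typical of plasma DNA);
* in cancer samples a fragment is tumor-derived with probability `f_t`
  (default 0.2); tumor fragments see the tumor landscape `m'`, which is
  lowered to `m(1 - delta_hypo)` on planted hypomethylated windows
  (default `delta_hypo` 0.5, 200 windows) and raised to
  `m + delta_hyper (1 - m)` on planted hypermethylated windows (default
  0.4, 200 windows);
* the fragment is short with probability
  `pi_base + kappa (1 - m_source) + gamma * tumor` (defaults 0.145, 0.15,
  0.02), clipped to [0, 1]: accessibility rises as methylation falls, and
  tumor fragments carry a small global excess of short fragments;
* lengths are integer truncated normals — short: mean 135, sd 10 on
  [100, 150]; long: mean 167, sd 12 on [151, 220] (the mononucleosomal
  peak);
* starts are uniform within the source window subject to the fragment
  lying inside the chromosome; barcodes are unique serial strings, so the
  simulator emits PCR-duplicate-free libraries;
* the fragment carries a methylated flag: probability `m_source` for long
  fragments and `lambda_short * m_source` for short ones (below);
* the IP library is a per-molecule Bernoulli thinning of the same pool:
  methylated fragments are retained with `p_cap = 0.8`, unmethylated with
  `p_bg = 0.05`. Sharing molecules between Input and IP is what makes
  "input adjustment" meaningful.

One base seed drives everything; sample `i` uses the stream `seed + i`, so
cohorts are byte-reproducible and samples independent under parallel
generation.

### Why short fragments are hypomethylated at the fragment level

A model in which the methylated flag is independent of fragment length
within a window cannot reproduce the defining observation of paired
Input/IP fragmentomics: the IP library's short fragments ratio falls some
30% below the Input ratio in healthy plasma. With within-window
independence the only coupling between capture and length is the
between-window covariance of methylation and short-fraction, and a direct
expectation computation shows that effect is ~2%, an order of magnitude
too small. Mechanistically the coupling *is* fragment-level: short
fragments are the product of intra-nucleosomal digestion of accessible,
hypomethylated chromatin, so the short molecules themselves are depleted
of 5mC. The simulator therefore discounts the methylation probability of
short fragments by `lambda_short` (default 0.7, set so the healthy
IP/Input ratio retention is ~0.72, i.e. a ~28% drop — the magnitude seen
in real paired libraries).

A consequence worth stating plainly: under this mechanism the IP reaction
depletes cancer-derived short fragments (which originate from
*hypomethylated* windows) at least as strongly as healthy ones, so the
simulated cancer cohort's IP-vs-Input change is, in expectation, slightly
*larger* in magnitude than the healthy cohort's (−29.0% vs −28.8% at
defaults), not smaller as reported for patient plasma. Within this model
class — per-molecule capture by fragment methylation — no parameter choice
reverses that ordering; reproducing the observed attenuation in patients
would require cancer short fragments that retain enough 5mC to be
captured, i.e. a second, methylation-preserving source of short fragments
that the simulator deliberately does not include. Group contrasts of the
IP−Input change on simulated data should therefore not be read as
reproducing the patient-plasma contrast.

### What the defaults can and cannot show

The default tumor fraction of 0.2 dilutes planted count effects heavily:
the expected IP-count fold change of a hypomethylated window is
`log2((1-f_t) + f_t * c(m')/c(m))` where `c(m) = p_bg + (p_cap-p_bg) m` is
the mean capture rate, which at `f_t = 0.2` is bounded near −0.3 even for
complete demethylation and is about −0.14 at the default `delta_hypo`.
Windows at this tumor burden therefore never cross the 2-fold calling
threshold — the default cohort is a *null-like, realistic-burden* setting
that exercises calibration (type-I control) and the direction of the
fragmentation contrasts (planted hypo windows show higher adjusted ratios
in cancer), not DMR recovery at `|log2FC| > 1`.

For end-to-end recovery and classification the package ships a
**strong-effect preset** (`strong_effect_config()`), fixed a priori by the
power analysis above: tumor fraction 0.7 and `delta_hypo = 0.9` (expected
hypo-window log2FC ≈ −1.27, comfortably callable), `kappa = 0.25`, a
compact 2 × 2.5 Mb genome (500 windows, 60 + 60 planted) sequenced to
500,000 Input fragments per sample so that per-window ratio estimates are
precise enough (~650 IP fragments per window) for correlation-based
scoring. This emulates a newly diagnosed, untreated, high-burden cohort
profiled at depth. Note the asymmetry inherited from the Beta(8, 2)
landscape: with mean methylation 0.8, capture is near its ceiling, so
planted *hyper*methylated windows can gain at most ~0.3 log2 units and are
essentially never callable at the 2-fold threshold; the classifier — like
the diagnostic approach it implements — uses hypomethylated windows only.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere; fragment length is
  `end − start`; strand is ignored (all statistics are strand-agnostic).
* "Uniquely mapped" is operationalized as mapping quality ≥ 30 on both
  mates plus no secondary/supplementary flags; proper-pair flag required;
  inserts under 20 bp eliminated. Dropped-pair counts are reported per
  reason.
* Deduplication keys on (chromosome, start, end, barcode) and keeps the
  first record — deterministic, idempotent. Barcodes are taken verbatim;
  barcode error correction against a whitelist is out of scope.
* The dedup/size-filter order, the 100–220 bp restriction of DMR counts,
  the 50/50 dispersion shrink, the 0.5 pseudocount, and the strict `<`
  at the classification cutoff are all fixed conventions chosen for
  determinism and boundedness; each is exercised by a dedicated test.
* Degenerate inputs: empty fragment sets are legal everywhere except
  `mean_size()`; ratios with empty denominators are missing; a cohort
  with a missing group fails fast with the group named.
* The healthy median baseline includes all healthy samples by default
  (every published healthy sample contributes); a leave-one-out mode
  exists for the stricter prospective reading. Bootstrap AUC confidence
  intervals use 2000 stratified percentile replicates.

## Problem sizes used by the test-suite

The suite simulates cohorts at the study conditions (2000 windows, 3 vs 3
samples, 200,000 Input fragments) for calibration and conservation checks,
ten seeded replicates for the null-calibration property, and the
strong-effect preset (500 windows, 500,000 fragments, 3 vs 3 discovery and
8 vs 11 validation) for the end-to-end classifier check; unit tests run on
toy fixtures of a few hundred fragments. These sizes were chosen so the
full suite exercises every stage at realistic per-window depths.

## Limitations

The simulator draws fragments independently and uniformly across windows:
it does not model GC bias (the analysis deliberately applies no GC
adjustment), copy-number alterations, nucleosome positioning, sequencing
error, CpG-level methylation structure, or biological between-sample
variability in the methylation landscape. Passing tests therefore
demonstrate the correctness and calibration of the *analysis* under the
stated mechanism, not performance on real plasma; in particular the
classifier's perfect separation on the strong-effect fixture reflects the
absence of inter-individual baseline variation, and real-cohort accuracy
will be lower. The NB test is a minimal Wald pipeline; it does not
implement independent filtering, outlier handling, or fold-change
shrinkage.
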