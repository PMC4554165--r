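---
title: "Screening differentially expressed miRNAs in paired scar/normal skin arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening differentially expressed miRNAs in paired scar/normal skin arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirscar)
```

## The design and the statistical model

`mirscar` analyses paired miRNA microarray experiments in which each patient
contributes one hypertrophic-scar and one normal-skin array. The working
model for the log2 expression of miRNA $g$ on the array of patient $i$ in
condition $c$ is additive:

$$
x_{gic} = \mu_g + b_i + \delta_g \,\mathbf{1}[c = \text{scar}] + \varepsilon_{gic},
\qquad b_i \sim N(0, \sigma_b^2),\ \varepsilon \sim N(0, \sigma^2).
$$

The patient effect $b_i$ is shared by both arrays of a patient, so it
cancels exactly in the paired differences $d_{gi} = x_{gi,\text{scar}} -
x_{gi,\text{normal}}$; under this model the paired t-test on $d_{gi}$ is
exact. Three selection criteria are computed:

* **t-test** (criterion 1): $t_g = \bar d_g / (s_g/\sqrt n)$, two-sided p on
  $n-1$ degrees of freedom, selected if $p \le \alpha$ (default 0.05).
* **FDR** (criterion 2): Benjamini–Hochberg step-up q-values over all miRNAs
  jointly, selected if $q \le \alpha$. Because BH never decreases a p-value,
  the FDR set is always nested in the t-test set; `intersect_criteria()`
  asserts this on every dataset.
* **DC-SIS** (criterion 3): each miRNA is ranked by
  $\omega_g = \mathrm{dCor}^2(x_g, y)$, the squared distance correlation
  between its expression vector over all arrays and the binary tissue label,
  and the top $d$ are retained.

DC-SIS is model-free — it assumes no functional form linking expression to
the label and detects arbitrary dependence — which is why it is used
alongside the t-test rather than instead of it. The pairing is ignored by
the screen: distance correlation is defined for i.i.d. samples, so the
screen treats the $n = 2 \times$ patients arrays as the sample. A paired
variant (screening the differences) is deliberately out of scope.

## Distance correlation and the model size

The squared distance covariance is the V-statistic
$\mathrm{dCov}^2(x,y) = m^{-2} \sum_{k,l} A_{kl} B_{kl}$ with $A$ and $B$ the
double-centered pairwise distance matrices of $x$ and $y$. The V-statistic
(rather than the unbiased U-statistic) matches the original screening
formulation; it carries a positive $O(1/m)$ bias, which is irrelevant for
ranking because the bias is shared across miRNAs screened against the same
response. Tiny negative values from floating-point cancellation are clamped
to zero, and $\mathrm{dCor}^2$ is defined as 0 when either input is constant.
Ties in $\omega$ are broken lexicographically by miRNA id so output is
deterministic across platforms.

The retained model size is $d = 6\lfloor n/\log n \rfloor$ with the natural
logarithm, the screening-literature convention; at $n = 18$ arrays this
gives $d = 36$, at $n = 9$ it would give 24. Both the multiplier and the
log base are exposed (`model_size()`, `dcsis_screen()`) because the rule is
a convention, not a law: published studies are not always explicit about
the base or about whether $n$ counts arrays or patients, and small-$n$
results are sensitive to both. We count arrays, since that is the sample
the screen actually sees.

## Preprocessing

Raw intensities are prepared in four steps, each exposed individually and
composed by `preprocess_expression()`:

1. **Background subtraction** with a floor: values become
   $\max(x - B, \text{floor})$ with floor 1.0 on the raw scale, so the log2
   transform is always finite. The floor makes the function total at the
   cost of compressing the lowest intensities; those rows are exactly the
   ones the detection filter then removes.
2. **log2 transform.**
3. **MA-lowess normalization.** For each array $x$ against the reference
   $r$ = per-miRNA median across arrays, a robust lowess fit of
   $M = x - r$ on $A = (x + r)/2$ (span 0.3, 3 robustness iterations) is
   subtracted. The median pseudo-array reference is deterministic,
   order-independent and needs one fit per array, unlike cyclic pairwise
   schemes. Span and iteration count are conventional defaults and are
   configurable, since source studies rarely state them.
4. **Detection filter**: keep rows exceeding `min_signal` (default
   log2(2 × floor)) in at least half the arrays. Published analyses often
   report a post-filter count without stating the rule; here the rule is
   explicit and logged.

Two numerical properties of the lowess step deserve mention. First, the
per-array median of $M$ after normalization is close to 0 (the acceptance
checks use ±0.05 at bias amplitude 0.5), and the intensity-dependent trend
is reduced several-fold. Second, the operation is *not* exactly idempotent:
a locally weighted fit through $n$ noisy points re-fits a noise wiggle of
order $\sigma/\sqrt{\text{span} \cdot n}$ (about 0.05 log2 units at the
default 513 miRNAs and $\sigma = 0.5$) on every application, and with the
$(x+r)/2$ abscissa a small regression-to-the-mean slope adds to this. A
second application therefore perturbs values by a small fraction of the
first pass and keeps arrays centred — the tests assert exactly that — and
idempotence holds in the low-noise limit. Users should apply the
normalization once, as is standard.

## Multiple testing

q-values are BH-adjusted p-values by default: parameter-free and
reproducible. A Storey-style option (`fdr_adjust(method = "storey")`)
rescales BH by $\hat\pi_0 = \min(1, \overline{\mathbf 1[p > 0.5]}/0.5)$ for
users who want the less conservative estimate; it never drops below the raw
p-value. Zero-variance rows are retained with degenerate results
($t = 0, p = 1$ or $t = \pm\infty, p = 0$, logged) rather than dropped, so
the multiple-testing denominator $m$ is always the number of miRNAs tested.

## Over-representation analysis

`hypergeom_enrich()` tests a query gene list (e.g. predicted miRNA targets)
against any GMT collection: $p = P(X \ge k)$ for
$X \sim \mathrm{Hypergeometric}(N, K, n)$, the upper tail *including* the
observed overlap — the standard over-representation convention. The universe
defaults to the genes annotated in the collection and can be overridden,
because the appropriate reference set (annotated genes vs. all genes on the
array) is a genuine analysis choice. Query genes outside the universe are
dropped with a logged count, never silently. miRNA-to-target mapping is out
of scope: the function consumes gene lists from whatever predictor the user
trusts.

## The synthetic-data generator

`simulate_mirna_dataset()` emulates the features of real paired arrays that
this pipeline claims to handle, with known ground truth:

* the paired design (one scar and one normal array per patient);
* per-miRNA baselines $\mu_g \sim N(9, 2^2)$ on the log2 scale and patient
  effects with SD 0.5 — values typical of single-channel miRNA arrays;
* planted differential miRNAs (default 20 of 513 at $|\delta| = 1.5$ log2
  units, 75% lowered in scar, mirroring the predominance of down-regulation
  reported in scar tissue);
* additive background (default 50 raw units) and a smooth per-array
  intensity-dependent bias, injected multiplicatively on the raw scale
  (additively in log2) with amplitude ≤ `bias_amplitude`, so MA-lowess is
  the correct remedy.

Planted effects use a constant magnitude rather than a distribution: the
configuration names the mean absolute log2 fold change, and a constant
satisfies that while making power checks deterministic. The generator does
*not* simulate probe-level replicates, spot-quality artifacts, dye swaps,
non-Gaussian heavy-tailed noise, or covariates such as age and sex. Passing
tests on these data therefore demonstrate that the pipeline's statistics
behave as designed under their own assumptions — exact type-I error,
FDR control, sure-screening recovery — not that any particular biological
dataset satisfies those assumptions.

Determinism is a contract: the same configuration (including seed) yields
bit-identical data, and `run_pipeline()` manifests record MD5 hashes of
every output so reruns can be verified byte-for-byte.

## Validation problem sizes

The test suite validates the estimator against an independently coded
brute-force distance-covariance oracle (100 random pairs, $m \le 50$,
agreement to 1e-12) and the hypergeometric tail against exhaustive
enumeration of all draws for universes up to $N = 12$. Behavioural checks
use: 10⁵ null miRNAs for the paired-t type-I error (target interval
[0.04, 0.06] at nominal 0.05); 50 replicates of 500 miRNAs with 10% planted
effects for empirical FDR (≤ 0.075 at $q \le 0.05$); 100 replicates of 500
miRNAs, 9 patients, 10 planted effects at 1.5 log2 units and noise 0.5 for
sure-screening recovery (≥ 9/10 planted miRNAs selected in ≥ 90% of
replicates); and bias-amplitude-0.5 simulations for normalization quality.
These sizes give stable Monte-Carlo estimates while keeping the whole suite
under a minute.

## Known limitations

* The t-test is the traditional one, not a moderated (shrunken-variance)
  test; with 9 pairs a limma-style test would be more powerful, but the
  three-criteria screen is defined around the traditional test.
* DC-SIS selects a fixed count $d$, not a significance-calibrated set; on a
  null dataset it still returns $d$ miRNAs (with a warning when all scores
  are zero and the selection falls back to id order).
* Lowess normalization assumes the majority of miRNAs are unchanged between
  arrays; designs where most features shift in one direction violate the
  median-reference assumption.
* Reported fold changes are anti-logged mean paired differences,
  $2^{\bar d_g}$; columns are labelled explicitly since conventions differ.
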