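---
title: "Reference-free assembly evaluation with Feature-Response Curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free assembly evaluation with Feature-Response Curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frcurve)
library(ggplot2)
```

## The problem

De novo genome assemblies are still mostly judged by contiguity — N50, the
smallest contig length such that contigs at least that long cover half the
assembly. Contiguity says nothing about correctness: an assembler that
aggressively merges sequences produces long, wrong contigs and a flattering
N50. Validation pipelines in the amosvalidate tradition instead scan the
read layout for localized signals that the shotgun process has been
violated — mate pairs at the wrong distance or orientation, coverage
anomalies, k-mer frequency anomalies, clustered SNPs, breakpoints where
leftover reads half-align. `frcurve` consumes those per-contig diagnostic
features, turns them into Feature-Response Curves for ranking assemblies,
and provides the multivariate machinery (PCA with random-matrix
calibration, ICA-based feature selection) to ask which of the many
correlated features actually carry information.

## The feature taxonomy and counting rules

Twelve raw feature types are recognized (`feature_types()`). Two are point
signals (`BREAKPOINT`, `HIGH_SNP`); the other ten mark extended intervals.
For cohort analysis the two flavors of mates-elsewhere coverage
(`HIGH_LINKING_CVG`, `HIGH_SPANNING_CVG`) are collapsed into one column,
leaving the 11 analysis features (`analysis_features()`).

Counting follows the point/extent distinction: a point feature counts once
no matter how it is reported, while an extent feature of length $\ell$
counts $\max(1, \lceil \ell / T \rceil)$ for a tally window $T$
(`counting_config()`, default $T = 10$ kbp). The window value is
configurable because it is a convention, not an estimate; any fixed
kbp-scale choice preserves the ordering of assemblies, and counts are
monotone in $T$ by construction. Coordinates are 0-based half-open
throughout (BED-compatible), points stored as width-1 intervals, which
makes overlap arithmetic unambiguous: touching intervals do not overlap.

## The Feature-Response Curve

For a feature threshold $\varphi$, sort contigs by length (longest first,
ties broken by id for determinism) and take the longest prefix of that
order whose cumulative feature count stays $\le \varphi$; the response is
the fraction of the genome covered by that prefix. Sweeping $\varphi$ from
0 to the total feature count traces the curve: a good assembly climbs to
high coverage at small $\varphi$. The prefix is cumulative — this is the
published construction — but a per-contig-threshold variant (each contig
admitted on its own count) is available behind `cumulative = FALSE` for
comparison. The genome size is the natural denominator when an estimate
exists; otherwise the assembly total is used, which rescales but does not
reorder curves. `frc_auc()` summarizes a curve by its normalized
trapezoidal area on $[0, \varphi_{\max}]$, carrying the last coverage
value forward where a curve has saturated, so curves with different
supports are comparable.

```{r frc-demo}
sim <- simulate_assembly(toy_assembly_spec(error_rate = 0.4, seed = 1))
curve <- compute_frc(sim$assembly)
frc_auc(curve)
autoplot(curve)
```

## PCA of the cohort matrix and Marčenko–Pastur calibration

A cohort of assemblies becomes a matrix (`build_feature_matrix()`): one
row per assembly, the 11 feature totals as columns, optionally N50 and the
number of contigs. Columns live on wildly different scales (counts vs bp),
so the PCA (`assembly_pca()`) is of the correlation matrix — columns
z-scored, zero-variance columns dropped with a warning. Eigenvalue-based
retention rules only make sense on this scale.

Two retention rules are provided. The 80%-cumulative-variance heuristic
(`retain_by_variance()`) is the common default. The sharper rule fits the
Marčenko–Pastur law — the limiting eigenvalue distribution of pure-noise
data with aspect ratio $\gamma = p/n$ — and keeps only eigenvalues above
the upper bulk edge $\lambda_+ = \sigma^2 (1 + \sqrt{\gamma})^2$
(`fit_mp()`, `retain_by_mp()`). $\gamma$ is fixed by the matrix shape,
never fitted; $\sigma^2$ is chosen by grid search (0.05–3.0, step 0.01)
minimizing the Cramér–von Mises distance between the MP CDF and the
empirical eigenvalue CDF. The MP CDF itself is evaluated by trapezoidal
quadrature of the density on a 2048-point grid, using the scale relation
$F_{\sigma^2}(x) = F_1(x/\sigma^2)$ so one quadrature serves the whole
grid search. A Kaiser-style count of eigenvalues above 1 is exposed
separately (`retain_by_kaiser()`).

Numerical caveats we settled deliberately:

* the whole-spectrum fit is the default. An iterated trim-and-refit
  (exclude above-edge eigenvalues, refit, repeat) was evaluated and
  rejected: on small matrices whose columns are standardized, strong
  factors compress the noise bulk below MP shape and the iteration
  contracts $\sigma^2$ toward the grid floor. A single robustness pass is
  available via `trim_spikes = TRUE`;
* a degenerate (all-equal) spectrum is an error, not a fit;
* loadings are sign-fixed (largest-magnitude coefficient positive) so
  loading tables are reproducible across platforms.

## ICA and feature selection

Independent component analysis models the standardized matrix as
$X = A S$ with statistically independent, non-Gaussian sources: each
feature column is a linear mixture of latent error processes observed
across the cohort. `run_ica()` implements symmetric fixed-point FastICA
with the tanh contrast after PCA whitening (tolerance $10^{-6}$, at most
1000 iterations, 5 restarts from seeded random rotations). The whitening
basis and IC signs are canonicalized (largest loading positive, sources
skewed positive) so a seed fully determines the result, including under
column permutations of the input.

On finite cohorts the iteration frequently settles into a small limit
cycle: directions that are nearly Gaussian have no stable contrast optimum,
and the reference implementations behave identically. We therefore return
the tightest iterate with a warning rather than failing — the informative,
non-Gaussian components have long converged by then, and the downstream
kurtosis ranking is unaffected.

ICs are ranked by the magnitude of the excess kurtosis of their sources
(`excess_kurtosis()`, population-moment form; magnitude because
sub-Gaussian sources are exactly as non-Gaussian as super-Gaussian ones).
`retain_ics()` keeps the shortest prefix carrying 80% of the total
|kurtosis| mass by default, with the percentile reading available as an
option. `select_features()` then takes, per retained IC, the feature with
the largest-magnitude mixing coefficient, deduplicated in order.
`ica_select_features()` wires the pipeline together, always excluding the
N50/NUM_CONTIG extras — selection is over the diagnostic features only.

A limitation worth stating precisely: at cohort scale ($n \approx 80$),
the sample excess kurtosis of a genuinely Laplace source has a coefficient
of variation near 0.6, and near-Gaussian directions fluctuate around
$\pm\sqrt{24/n} \approx 0.55$. Consequently the 80%-mass prefix cannot
reliably stop at the true number of structured components: with three
equally non-Gaussian sources the smallest carries over 20% of the mass —
the condition for retaining all three — only about a quarter of the time,
and noise directions contribute enough mass that the prefix usually
crosses into them. Exact recovery of a planted feature subset is therefore
demonstrated with the component count matched to the planted rank (three),
where it is a property of the unmixing itself; the kurtosis-mass retention
remains the pipeline default for exploratory use, where over-retention is
the safer failure mode.

## Validating features against true mis-assemblies

When contigs can be aligned to a trusted reference, the alignment
differences (dnadiff-style) give true mis-assembly intervals.
`filter_misassemblies()` applies the usual hygiene first: SNPs and indels
shorter than 10 bp are sequence-level noise, not structural errors, and
breakpoint calls within 1000 bp of a contig end sit where partial
alignments are expected; both margins are configurable conventions.
`score_features()` then counts a feature as correct iff its interval
intersects (≥ 1 bp, half-open) a surviving true interval on the same
contig; every record contributes its counting-rule count to both totals,
so the bookkeeping is consistent with the FRC. Overlaps are computed with
IRanges; the test suite checks the result against a brute-force all-pairs
intersection.

## What the synthetic generators emulate

`simulate_feature_matrix()` builds the statistical object the multivariate
analyses assume: a cohort matrix $X = SA + \varepsilon$ with $k$
non-Gaussian latent factors mapped to counts. Defaults are the package's
study conditions, chosen once: 80 assemblies (the scale at which such
cohorts are realistically assembled), 11 features, 3 factors with
unit-variance Laplace sources (excess kurtosis 3, comfortably detectable
at this $n$); each factor loads at 6.0 on one distinct feature and at
fixed magnitude 0.5 with random signs elsewhere, with residual noise sd
0.35. The dense cross-loadings mirror how mis-assembly signals co-occur
(a collapsed repeat perturbs mates, coverage and k-mers at once) and are
what makes the factors visible as correlation-matrix spikes far above the
MP edge; the fixed magnitude guarantees the designated feature stays
dominant after standardization. Counts arise by rounding a softplus at
baseline 20 — near-linear there, and large enough that integer rounding
(variance 1/12) is negligible against the signal. Both properties failed
under an earlier, smaller-scale parameterization, which is why they are
stated here as explicit design constraints rather than incidental
defaults. A Poisson link is available for over-dispersion experiments.

`simulate_assembly()` builds a toy assembly: log-normal contig lengths
(median 20 kb, sdlog 0.7, 50 contigs, genome 2 Mb), a per-contig planted
mis-assembly probability, one truth interval plus a Poisson number of
co-occurring feature records per error, and a uniform background of
0.05 features/kb. It emulates the *local* structure validation needs —
features clustering at true error loci over a background — and the
negative relationship between planted error rate and FRC area that the
end-to-end tests exercise.

Neither generator imitates real read layouts: there are no repeat
families, no coverage autocorrelation along contigs, no assembler-specific
error profiles, and feature types at an error locus are drawn from a fixed
pool rather than an error-type-specific signature. Passing tests therefore
certify the statistical machinery — counting, curve construction,
spectral calibration, unmixing, overlap scoring — on data whose generative
truth is known, not the biological fidelity of any particular feature
caller.

## Problem sizes and determinism

The shipped test and acceptance workloads use: 200 random toy assemblies
(≤ 20 contigs) for exact FRC-vs-enumeration agreement; 100 instances for
monotonicity properties; 50 null and 20 spiked 500×50 matrices for MP
calibration (σ² within 10%, ≤ 2 null components, exactly 3 spikes); 20
cohort seeds for planted ICA recovery; 200 random instances for overlap
scoring; and 20 seed pairs for low- vs high-error FRC discrimination.
Every stochastic step is seed-driven, and each seed fully determines every
output, including file exports (which carry the seed in their headers).
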