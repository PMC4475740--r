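---
title: "Edge-wise functional connectivity analysis: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-wise functional connectivity analysis: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectograph)
```

# The problem

Resting-state fMRI measures slow spontaneous fluctuations of the BOLD
signal; the Pearson correlation between two brain regions' fluctuations is
taken as their *functional connectivity*. In neurodegenerative disease,
whole-brain studies repeatedly find weakened long-distance connectivity —
particularly between default-mode-network nodes (posterior cingulate,
precuneus, medial superior frontal, parahippocampal cortex) and between the
temporal lobe and frontal/parietal cortex — with mild cognitive impairment
sitting between healthy aging and dementia, and with connection strength
tracking cognitive screening scores such as the MMSE. `connectograph`
implements the full edge-wise analysis such studies use, plus a synthetic
cohort generator with recorded ground truth so every stage can be validated
quantitatively.

# Signal conditioning

Per subject the input is a T×N matrix of regional series (or a labeled 4D
image from which `extract_regional_series()` computes unweighted voxel
means per region, in atlas order).

**Nuisance regression** (`regress_nuisance`) residualizes each region on a
design with an intercept, a linear drift term, and — when available — six
rigid-body motion parameters and the mean white-matter and CSF series
(10 columns). The intercept is included even though drift alone is often
quoted, because a projection without it is ill-posed; residuals are then
mean-zero and orthogonal to every regressor, making the operation
idempotent. The global (whole-brain) mean signal is deliberately *not*
regressed. With no nuisance inputs (the synthetic route) the stage
degrades to intercept+drift removal and logs that fact.

**Band-pass** (`bandpass`) retains 0.01–0.08 Hz, the canonical
resting-state band. The realization is a 2nd-order Butterworth applied
forward–backward (zero phase) — the de facto standard of that era's
pipelines; the band, not the filter family, is what such studies specify,
so the family/order are package conventions exposed as arguments. The slow
low-edge transient (a 0.01 Hz pole rings for minutes) is handled by
odd-reflection padding of about three periods of the low cutoff,
`min(T-1, ceil(3/(low·dt)))` samples, after which a 512-sample 0.04 Hz
sinusoid passes within 5% of unit gain, 0.2 Hz is attenuated below 10%,
and a constant is removed to numerical noise.

**Order.** Regression first, filtering second (`preprocess_series`); a
regression test pins this order, since swapping it changes the output
(the nuisance fit would then see out-of-band energy it cannot represent).

# The connectome

Pearson correlation per region pair, then Fisher's z = atanh(r) for
variance stabilization. Degenerate |r| = 1 entries (duplicate signals) are
clipped to 1−1e−7 before atanh so z stays finite, with a logged note. The
diagonal is stored as 0 and excluded everywhere: all edge statistics run
over the N(N−1)/2 upper-triangle entries (4005 at N = 90), in the fixed
column-major upper-triangle order shared by every edge-wise vector in the
package.

Mean-strength summaries default to |z| (matching the usual "mean absolute
z-score" display); whether group-level strength ANOVAs should use signed
or absolute z is genuinely ambiguous in the literature this emulates, so
both are exposed (`absolute` flag) with absolute as the documented default.

# Dual-criterion altered-edge selection

Edge (i,j) is *altered* between control and patient groups iff

- **(a)** one-sample two-tailed t on z differs from zero in at least one
  of the two groups, Bonferroni-corrected within each group over all m
  edges (reject at p < α/m, α = 0.05, m = 4005); and
- **(b)** two-sample two-tailed t differs between groups,
  Benjamini–Hochberg FDR-corrected at q = 0.05.

Criterion (a)'s "at least one group" is interpreted as the union over the
two groups being compared. The two-sample test is classical
pooled-variance Student's t (df = nA+nB−2; 27 and 35 subjects give
df = 60) — the convention of the era's neuroimaging toolchains — with
Welch's form available via `var_equal = FALSE`. Direction labels come from
signed group means: *decreased* when the control mean exceeds the patient
mean. Zero-variance edges never crash the pipeline; they receive limit
p-values (0 for a nonzero mean, 1 otherwise) with a logged note.

The BH mask is computed through `stats::p.adjust(method = "BH")`; the test
suite verifies it against a brute-force step-up enumeration (every rank k
checked explicitly) on 1000 random p-vectors, and verifies that Bonferroni
rejections are always a subset of BH rejections at the same level.

Any group pair can be contrasted with the same machinery (NC–MCI, MCI–AD,
NC–AD). `summarize_altered()` partitions the result by node degree, lobe,
and interlobe/intralobe × inter/intrahemispheric class.

One caveat of reported post hoc F statistics in the emulated literature:
a two-group post hoc on 35+27 subjects has 60 error df; a printed
subscript of 52 is inconsistent with that arithmetic and is not
reproduced here.

# Cognition correlations

For each altered edge, Pearson r (via `stats::cor.test`) between subject
z at that edge and MMSE over the *pooled* subjects of the requested group
set — pooling is explicit, never an average of per-group r, because the
between-group spread is part of the severity signal. These correlations
are exploratory, so p-values are deliberately uncorrected at α = 0.05 and
the report says so. MMSE enters as the raw 0–30 integer; z (not raw r) is
the correlated quantity, since z is what the selection pipeline carries.

# The synthetic cohort generator

The generator defines the study conditions the package validates against:

| parameter | default | rationale |
|---|---|---|
| group sizes | 27 NC / 27 MCI / 35 AD | the emulated cohort design |
| T, interval | 200 volumes, 2 s | 6 min 40 s at TR = 2 s |
| AR(1) coefficient | 0.3 | BOLD-like smoothness at TR 2 s |
| base / intralobe / homologue r | 0.1 / 0.3 / 0.6 | strongest edges between interhemispheric homologues, then within lobes |
| affected edges | 20 curated long-distance interlobe pairs (DMN + temporal anchors) | the disconnection pattern being emulated |
| affected baseline r | 0.5 | strong enough to pass criterion (a) in every group |
| effect sizes Δr | 0 / 0.15 / 0.30 (NC/MCI/AD) | **package conventions** — the emulated studies report no effect sizes |
| MMSE model | intercepts 23 / 22.5 / 18.5 + 10·(mean affected-edge z) + N(0, 1.5²), rounded, clamped to [0, 30] | yields means ≈ 28.5 / 26 / 20.5 and a strength–MMSE coupling of roughly r ≈ 0.4–0.7 in pooled patients |

**Temporal model.** `x_t = φ x_{t−1} + √(1−φ²) L ε_t`, with L the Cholesky
factor of the target correlation matrix. Because φ is shared across
regions, the stationary lag-0 cross-correlation equals the target exactly,
so sample correlations converge to the planted values as T grows — the
property the recovery tests rely on.

**Positive-definite repair.** The rule-built target matrix (background,
intralobe, homologue, affected-edge values) need not be PD; `nearest_pd()`
clips eigenvalues at ε = 1e−6 and renormalizes the diagonal, iterating
until the floor holds. The projection perturbs non-affected entries by a
small amount that differs between group targets, so a handful of edges
adjacent to the planted ones can carry real (tiny but detectable) group
differences; recovery tests therefore score the planted set, not the
total selection count.

**Seeding.** One master seed; each subject's stream is derived from
(seed, group, within-group index), so resizing one group leaves every
other subject's data bit-identical. MMSE is drawn inside the same
per-subject stream from the subject's realized mean affected-edge z, so
the cognition coupling emerges through the same sampling noise the
analysis sees.

**What it does not emulate:** hemodynamic response convolution,
physiological noise spectra, head motion, scanner drift artifacts, spatial
smoothness, or registration error. Passing tests therefore demonstrate
statistical correctness of the pipeline under a faithful covariance/AR
model — not robustness to acquisition artifacts.

# Validation design and problem sizes

The suite validates, among others: planted-edge recovery (≥ 80% at
Δr = 0.3, 27/35 subjects, T = 200 — in practice 100%, all labeled
decreased); the NC > MCI > AD ordering of mean planted-edge z at > 2
standard errors (the *global* 4005-edge mean shifts by only ~0.001 when 20
edges are attenuated, so at these sample sizes its ANOVA is
directional-but-weak — mirroring the non-significant global group effects
such cohorts report; the package checks ordering on the planted edges and
reports the global direction); false-discovery control of the full dual
criterion on 100 null cohorts (20 regions, 15/15 subjects, T = 150 — sizes
chosen to make a 100-replicate simulation comfortable on a laptop); and a
type-I rate of 0.05 ± 0.02 for the two-sample edge test over 1035 null
edges. `scripts/acceptance.R` recomputes all of these from a single
command-line seed.

# Known limitations

- Pooled-variance t assumes equal group variances; switch to Welch when
  group variances plausibly differ.
- The bundled lobe grouping is one of several conventional AAL groupings
  (insula is filed under limbic); classification results depend on it,
  which is why the atlas table is user-replaceable and the lobe vocabulary
  open.
- No cluster-level or network-based inference, no permutation tests, no
  graph metrics, no partial correlation or dynamic connectivity — the
  edge-wise mass-univariate design is the scope.
- Criterion (a) with Bonferroni at m = 4005 is very strict for weakly
  nonzero edges; edges with genuine group differences but near-zero mean
  in both groups are excluded by design.
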