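---
title: "Methods: surrogate-thresholded connectomes and longitudinal network segregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surrogate-thresholded connectomes and longitudinal network segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connseg)
```

## The problem

Subthreshold depressive symptoms — totals below the clinical cut-off on the
Beck Depression Inventory II (BDI-II < 20) — are common in older adults and
may precede late-life depression. A candidate neural marker is resting-state
functional connectivity (FC) within and between the seven canonical cortical
networks (visual VN, somatomotor SMN, dorsal and ventral attention DAN/VAN,
limbic LN, control CN, default mode DMN). `connseg` implements the full
analysis chain from parcellated BOLD time series to the statistical designs
that relate FC to symptom trajectories across two visits, together with a
synthetic cohort generator that makes every stage testable without access to
restricted cohort data.

## Connectome construction

Each subject-visit contributes a node × time matrix of mean BOLD series
(default: 400 Schaefer-style parcels, 296 volumes after discarding the first
four of 300). Edges are Pearson correlations between node series, giving a
symmetric N × N matrix with an undefined diagonal.

Raw correlation matrices are dense and noisy. To keep only edges unlikely
under temporally autocorrelated noise, every row is phase-randomized: Fourier
transform, replacement of the positive-frequency phases by independent
uniform draws (DC and Nyquist bins fixed, conjugate-symmetric assignment so
the inverse transform is real), inverse transform. A surrogate preserves each
row's amplitude spectrum — hence mean, variance and autocorrelation function
— while destroying cross-row dependence. All rows are re-scrambled jointly
and the full correlation matrix recomputed once per iteration (default 1000
iterations). The two-sided add-one permutation p-value of edge (i, j) is

p_ij = (1 + #{surrogates with |r_surr| ≥ |r_obs|}) / (1 + n_surrogates),

so p is never zero and the smallest achievable value with 1000 surrogates is
1/1001. Edges with p ≥ 0.05 (boundary excluded) are set to zero; survivors
are Fisher-transformed (z = atanh r) and split by sign into FC_pos and
FC_neg matrices with disjoint support, because mixing positive and negative
weights in one strength sum would let them cancel.

Numerical choices: correlations of |r| = 1 are clipped to 1 − 1e−7 before
atanh (logged); zero-variance rows produce NA edges and a warning, never a
silent zero; the per-surrogate correlation matrices are evaluated in the
frequency domain (phase surrogates have constant row means and variances, so
the centering terms are precomputed), which is algebraically identical to
materializing each surrogate — the test suite asserts exact agreement with
the naive path under a shared RNG stream.

Two-sidedness is a deliberate choice: both FC_pos and FC_neg are analyzed
downstream, so the null must be rejected for strong dependence of either
sign. Surrogate draws are independent per subject (seeds derived from the
run seed); nothing in the method requires sharing draws across subjects.

## Strengths and segregation

For node i in network k (n_k nodes, N total), with W the sign-restricted
z matrix (negative weights as magnitudes, so larger always means stronger):

* intra_i = Σ_{j∈k, j≠i} W_ij / (n_k (n_k − 1) / 2)
* inter_i = Σ_{j∉k} W_ij / (n_k (N − n_k))
* between_i[B] = Σ_{j∈B} W_ij / (n_k n_B)

The denominators are network-wide possible-edge counts, parallel across the
three definitions; a per-node alternative (e.g. N − n_k for inter) differs
only by a constant factor per network and cannot change any standardized
statistic downstream. Each node carries six strength values (intra, inter,
between × two signs), the per-node between value being the mean of
between_i[B] over the six other networks — the only reading that yields
exactly two between estimates per node while the network-pair analysis keeps
the full 7 × 7 between matrix. A 400-node scheme therefore emits 2400
node-level values per subject-visit.

Network-level intra and inter are arithmetic means over member nodes (sums
would only rescale; means keep values comparable across networks of
different sizes, and the choice is flagged to users). The network-pair
between value is the exact cross-edge mean Σ_{i∈A, j∈B} W_ij / (n_A n_B).

Per-network segregation is

Q = (intra − inter) / (intra + inter),

1 for a fully segregated network (all weight inside), −1 for full
integration, 0 for balance; undefined (NA, logged) when intra + inter = 0.
Q is computed from FC_pos strengths by default — the segregation results it
accompanies are positive-weight results — with an FC_neg variant behind the
`q_sign` flag. A singleton network has no within edges; its intra strength
is defined as 0.

## Statistical designs

All models use listwise deletion and report `n_used`; residual dfs vary
with per-analysis missingness.

**Cross-sectional:** OLS with the baseline FC measure as outcome and
baseline BDI-II, age, sex and education (ISCED 97) as predictors. FC is the
outcome because a model fit (R²) is reported per FC measure; the
standardized BDI-II coefficient is the headline quantity and is identical
in magnitude either way round.

**Longitudinal interactions:** repeated-measures ANCOVA with a two-level
within factor (time), sex between subjects, and age, ISCED and inter-scan
interval as covariates. With exactly two levels, the time × moderator
interaction F is identical to the squared t of the moderator in a
regression of the difference score on the same terms — `connseg` computes
it that way, and the suite verifies exact agreement with an independently
specified long-format `aov()` oracle on arbitrary data. Design A uses FC at
both visits as the within pair and ΔBDI-II (= BDI-II_t1 − BDI-II_t0) as
moderator; design B uses the BDI-II pair and baseline FC as moderator.
Partial η² is F/(F + df2) for df1 = 1, identical to the
sums-of-squares form.

**Baseline-adjusted regression:** ΔBDI-II on baseline FC plus age, sex,
ISCED, interval and baseline BDI-II, testing whether FC carries predictive
information beyond baseline severity (and guarding against pure
regression-to-the-mean).

**Corrections:** the network-level family threshold is 0.05/7 ≈ 0.007
(strictly below; a p exactly at the threshold is not flagged), applied to
every result table as the study's convention even for the 21 network-pair
tests (configurable). ROI-level post-hoc tests within a significant network
use Benjamini–Hochberg across the network's ROIs, plus separate left- and
right-hemisphere aggregates.

**Symptom domains:** BDI-II totals decompose into cognitive, affective and
somatic sub-scores. The instrument does not fix a unique three-factor
assignment, so the mapping ships as an editable YAML config (default:
affective {1, 4, 10, 11, 12, 17}, cognitive {2, 3, 5, 6, 7, 8, 9, 13, 14},
somatic {15, 16, 18, 19, 20, 21}); any partition of 1..21 is accepted and
sub-scores always sum to the total.

**Robustness:** re-analyses after excluding subjects with mild baseline
symptoms (BDI-II 14–19, the standard banding) or without baseline symptoms
(BDI-II = 0), or under a custom predicate, reported side by side with the
primary fit.

## The synthetic cohort generator

The generator emulates the study conditions the analysis assumes, and its
defaults are fixed at those conditions: 243 subjects, two visits
3.7 ± 0.7 years apart, age 67 ± 6.5 (55–84), ISCED 6.8 ± 1.9, DemTect
14.8 ± 2.4, BDI-II totals with mean 4.05, SD 3.58, truncated below 20 and
correlated ≈ 0.57 across visits; 300 BOLD volumes with 4 discarded.

BOLD matrices are stationary Gaussian AR(1) processes (lag-1 coefficient
0.3 — temporal autocorrelation is what makes the surrogate test
non-trivial; white noise would understate it) whose spatial covariance has
within-network correlation 0.30 and between-network correlation 0.05. The
cohort level of the within-coupling and its between-subject SD (0.08) are
free parameters — no per-network FC distributions are published for the
emulated cohort — chosen once as typical resting-state block-correlation
levels. Each subject's per-network coupling is re-drawn at follow-up with
correlation 0.7 to baseline, emulating stable individual differences.

The plantable effect makes ΔBDI-II a linear function of the *latent*
baseline coupling of a target network (default VAN, negative sign: lower
coupling, worsening symptoms) with a standardized magnitude (default 0.20,
the scale of a partial η² ≈ 0.035 effect), a small age effect (0.05), and
Gaussian noise scaled so the visit-to-visit total correlation lands near
its target. Totals are drawn from a truncated negative binomial and
decomposed into 21 items (0–3) so the domain machinery is exercisable;
items never drive the planted effect. Because the effect is planted on the
latent coupling and the pipeline measures FC through finite, thresholded
data, recovered standardized effects are attenuated relative to the
planted magnitude (by roughly a third in the suite's reduced profile) —
this is measurement attenuation, not bias in the estimator.

What the generator does *not* emulate: hemodynamic response shapes,
head-motion artifacts, spatially heterogeneous parcel sizes' signal
quality, non-Gaussian BOLD marginals, or item-level symptom dynamics.
Passing tests therefore demonstrate the correctness and calibration of the
pipeline's computations on data with the assumed covariance and effect
structure, not robustness to acquisition artifacts.

## Problem sizes and determinism

The package's own verification suite uses deliberately small profiles,
chosen as a package design decision so the whole suite runs comfortably on
one CPU: the surrogate-calibration study uses an 8-seed grid of 50
independent AR(1) series (T = 296) with 1000 surrogates; the
parameter-recovery study runs the full chain (simulate, threshold with 20
surrogates, metrics, design B) on 100 planted and 100 null replicates at
n = 243 with a 14-node (2 per network) scheme; the documented recovery
pair is planted magnitude 0.3 at n = 243, chosen a priori to sit well
above the 80% power floor. The bundled pipeline profile is 12–20 subjects,
2–4 nodes per network and a few dozen surrogates; the full-scale profile
(400 nodes, 296 volumes, 243 subjects, 1000 surrogates) is a documented
offline run of the same code paths.

Everything is deterministic given the run seed: identical seeds give
identical cohorts, surrogate draws and tables. One caveat: with a
multi-threaded BLAS, matrix-product reduction order can vary between
processes, so repeated runs agree to ~1e−15 rather than bit-for-bit;
single-threaded BLAS reproduces outputs exactly.

## Known limitations

* The inter-network denominator and the node-level between summary are
  reasoned reconstructions of ambiguous verbal definitions; both are
  documented above and differ from alternatives only by per-network
  constants.
* Whether network-level strengths are node means or sums is a scale
  convention; means are used and flagged.
* The two-level repeated-measures equivalence does not extend to more than
  two visits; no mixed-effects machinery is provided.
* No preprocessing (motion correction, filtering, global-signal handling)
  is included — the artifact starts at parcellated time series.

## A worked example

```{r example, eval = FALSE}
library(connseg)
scheme <- make_parcel_scheme(setNames(rep(4, 7), NETWORKS_7))
sim <- simulate_cohort(scheme, n_subjects = 40,
                       effect = effect_spec("VAN", 0.3, -1), seed = 1)
fc0 <- vapply(sim$bold, function(b) {
  z <- build_connectome(b$t0, n_surrogates = 100, alpha = 0.05)
  network_metrics(z, scheme)$net$pos$intra[["VAN"]]
}, numeric(1))
rm_time_by_fc0(fc0, sim$cohort)
```
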