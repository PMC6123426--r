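---
title: "Detecting left-right transcriptomic laterality and developmental asynchrony"
author: "lateralyzer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting left-right transcriptomic laterality and developmental asynchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Many paired anatomical structures — embryonic brain hemispheres above all —
are suspected of developing slightly asymmetrically: not with different
developmental programs on the two sides, but with one side running a little
ahead of the other along a *shared* trajectory. Direct left-right
differential expression in such tissue is subtle: few individual genes pass
genome-wide significance with the 5–13 pairs typically available. The
strategy implemented here is therefore indirect:

1. estimate a per-gene **side effect** (right minus left, paired within
   individual) and a per-gene **age effect** (expression change per
   post-conception week, pcw) with moderated t-statistics;
2. aggregate weak per-gene side effects into **gene-set enrichment** on the
   side-ranked list, with permutation-based error control;
3. correlate the side and age t-values across genes: if genes that rise
   with age are systematically higher on the right, the right side is
   transcriptionally "older" — it **leads** the left along the shared
   trajectory. The sign of this correlation is the direction call, and its
   significance is assessed by an exhaustive left/right **sign-flip
   permutation** test;
4. compare the sets lateralized in different structures by **Jaccard
   overlap**, per side.

Because real data of this design are access-controlled, the package ships a
negative-binomial simulator with *known injected laterality*, so every stage
is verifiable end to end.

## Models

### Paired side contrast

For gene $g$, let $y_{gis}$ be the log2-CPM of individual $i$, side
$s \in \{L, R\}$:
$$y_{gis} = \alpha_{gi} + \beta_g \,[s = R] + \varepsilon_{gis}.$$
The individual intercepts $\alpha_{gi}$ make this a paired analysis; no
other covariates enter the side model (age and sex are absorbed by the
individual factor). $\beta_g > 0$ means higher expression on the right.
The model is fitted by weighted least squares with precision weights (below).
For this design the weighted fit has a closed form — with per-pair
difference $d_i$ and pairwise harmonic weight
$h_i = (1/w_{iL} + 1/w_{iR})^{-1}$,
$\hat\beta = \sum h_i d_i / \sum h_i$ — which the package uses both for
speed (the flip permutations re-fit the model $2^{n-1}$ times) and because
it makes a global L/R relabel negate every statistic *bit-exactly*. A
property test asserts its equality with the generic least-squares path at
$10^{-10}$.

### Age contrast

$y_{gj} = \mu_g + a_g\,\mathrm{age}_j + \gamma_g\,[\mathrm{sex}_j = M] +
\varepsilon_{gj}$, unpaired, with structure added as a categorical factor
only when samples from several structures are pooled. $a_g$ is in log2
units per week; $t > 0$ means expression increases with age. The side and
age t-vectors may legitimately come from different sample sets.

### Precision weights

Log-transformed counts are heteroscedastic: low-count genes are noisy.
Per-gene OLS residual standard deviations (square-rooted) are
lowess-smoothed (span 0.5) against mean log2 count, the trend is evaluated
at each observation's fitted log2 count — clamped to the observed
mean-count range, so extrapolation is bounded — and the observation weight
is trend$^{-4}$. Observation-level weights were chosen (the alternative,
sample-level weights, is not implemented; the per-observation variant is
the standard one).

### Moderated t

Per-gene residual variances $s_g^2$ (residual df $d_g$) are assumed to
follow $s_0^2 F(d_g, d_0)$ across genes. $(d_0, s_0^2)$ are estimated by
closed-form moment matching of the mean and variance of $\log s_g^2$
against the known digamma/trigamma moments of the log-F distribution; when
the excess-variance estimate is non-positive the prior is infinitely
informative ($d_0 = \infty$, full shrinkage). The posterior variance is
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, the moderated
statistic $\tilde t_g = \hat\beta_g / (\tilde s_g u_g)$ with $u_g$ the
unscaled standard-error factor, and p-values use $d_0 + d_g$ degrees of
freedom. Genes with zero residual variance are excluded from
hyperparameter estimation and assigned $\tilde s^2 = s_0^2$. Two limits
are property-tested: $d_0 = 0$ reproduces the classical weighted paired t
exactly, and $d_0 \to \infty$ gives a constant posterior variance. The full
pipeline agrees with the reference voom/eBayes implementation to
$r > 0.999$ on simulated data (unit test); small residual differences come
from lowess details.

Multiplicity is controlled per structure by Benjamini-Hochberg step-up
q-values, implemented literally as
$q_{(i)} = \min_{j \ge i} (m/j)\,p_{(j)}$ and tested against a brute-force
oracle.

### Preranked weighted GSEA

Genes are ranked by the side t-value (descending; ties broken
lexicographically by gene ID so ranking is bit-reproducible). Walking the
list, a member of set $S$ ("hit") adds $|s_i|^p / \sum_{hits} |s|^p$
(default $p = 1$, i.e. t-weighted; $p = 0$ gives the rank-only KS-style
statistic), a miss subtracts $1/(N - N_H)$. The enrichment score is the
signed maximal absolute deviation of this running sum; a tie between the
positive and negative extremum — judged with a $10^{-9}$ tolerance so that
algebraically equivalent implementations agree despite rounding — resolves
to the positive value. A set containing the whole list has no misses and
ES $= 1$.

The null is gene-set randomization (random same-size draws of positions
from the ranked list; the only null available for preranked input),
default 1000 draws. NES divides ES by the mean |null ES| of matching sign;
the nominal p is the same-sign tail fraction; FWER compares the observed
NES against each permutation's most extreme same-sign normalized null ES
across all sets; and FDR is the pooled-tail-ratio estimator — the fraction
of all pooled same-sign null NES values at least as extreme, divided by the
fraction of observed same-sign NES values at least as extreme, clipped to
$[0, 1]$ and computed within sign class. (The historical reference tool's
FDR has undocumented details; this estimator is the package's pinned,
documented choice and is not claimed to match the tool bit-for-bit.) Sets
are tested only when 15–500 of their members are detected in the ranked
list. Transcription-factor-target collections go through the identical
engine; only the GMT content differs.

### The asynchrony statistic and its permutation null

The headline statistic is the Pearson correlation $r$ across genes between
side t-values and age t-values. $r > 0$: the right side leads. Genes are
not independent observations, so the nominal p-value of $r$ is biased; the
report carries an explicit caveat flag, and the *direction call* instead
requires the sign-flip permutation p-value. Left/right labels are flipped
per individual in all $2^{n-1}$ distinct ways (the all-flipped complement
of an assignment merely negates side statistics, so the first individual is
fixed unflipped); for each assignment the side DE, optionally the GSEA
FDR < 0.25 set count, and $r$ are recomputed exactly as for the true
labels. The empirical p uses the add-one estimator
$p = (1 + \#\{|r_{perm}| \ge |r_{obs}|\})/(1 + \#perm)$, so it is never 0.
Assignments are summarized by their similarity to the truth,
$\max(k, n-k)/n$ with $k$ the number of unflipped individuals — a declared
definition (the mirror symmetry of the statistic motivates counting a
near-globally-flipped assignment as similar). Exhaustive enumeration is
capped at $n = 20$; beyond that a seeded Monte-Carlo subsample must be
requested explicitly.

A second null randomizes the assignment of t-values to genes (10 times by
default) and counts gene sets at GSEA FDR < 0.25: if functional programs,
not scattered genes, are lateralized, the observed count dwarfs the
randomized counts. The ratio is reported raw and with add-one smoothing
$(obs+1)/(\overline{null}+1)$, the latter defined even when no null set
passes.

### Cross-structure overlap

Per structure, sets with GSEA FDR < 0.05 and positive NES are
right-lateralized (negative, left). Pairwise Jaccard indices
$|A \cap B| / |A \cup B|$ are assembled per side; the Jaccard of two empty
sets is declared 0 (avoiding spurious perfect overlap between structures
with no enrichments). In the pipeline summary the *leading side* column is
descriptive (the sign of $r$), while the *direction call* column
additionally requires the permutation p — the descriptive column mirrors
how leading sides are tabulated across structures, the call column is the
inferential statement.

## The synthetic world

`sim_config()` fixes the stated world; its defaults were chosen once, to
echo the scale of a paired embryonic brain study, and are not tuned to test
outcomes:

| parameter | default | meaning / rationale |
|---|---|---|
| `n_individuals` | 6 | mid-range of the 5–13 pairs per structure in such studies |
| `n_genes` | 2000 | down from the ~10^4 expressed genes for test speed; structurally faithful |
| `age_range` | 7.5–13 pcw | the foetal age window of the emulated design |
| `frac_age_genes` | 0.3 | a large minority of genes carry developmental programs |
| `slope_sd` | 0.2 log2/week | ~2-fold change over the 5.5-week window for a 1-sd gene; typical of developing neural tissue |
| `asynchrony_delta` | 0.25 weeks | free choice, not an estimate — the emulated analysis explicitly declined to quantify the lag; 0.25 weeks produces the "subtle, detectable in aggregate" regime |
| `side_noise_sd` | 0.05 log2 | small age-independent consistent laterality |
| `dispersion` | 0.1 | biological CV ≈ 0.3, usual for human tissue |
| `lib_size_mean`, `cv` | 2e6, 0.2 | log-normal, heavy-tailed like real libraries; desk-scale depth |
| `sex_ratio` | 0.5 | mixed sexes |

Counts for gene $g$, individual $i$ (nominal age $T_i$), side
$s \in \{-1,+1\}$ are NB with mean proportional to
$2^{\mu_g + a_g (T_i + s\Delta/2) + \epsilon_{gs}}$ scaled to the sample's
library size, variance $m + \phi m^2$ ($\phi = 0$ is the testable Poisson
limit). The asynchrony is injected symmetrically ($\pm\Delta/2$) so the
nominal age stays the midpoint and age-slope estimation is unbiased. The
side noise $\epsilon_{gs}$ is shared across individuals — consistent
laterality, which is what the paired design detects. Three reserved marker
genes (XIST, EIF1AY, KDM5D) get sex-determined expression for the QC stage.

Coherent gene sets are drawn with probability proportional to the positive
part of $a_g$. The generator's contract (a worked example frozen in the
tests) is that a coherent set's mean signed age slope exceeds the
collection-wide mean; single-signed membership also makes coherent sets
right-enriched under $\Delta > 0$, which the enrichment, randomization and
overlap stages are tested against. Drawing sign-balanced "large $|a_g|$"
sets would dilute set-level laterality and break that contract, so the
positive-part rule was adopted deliberately.

**What a green test does not establish.** The simulator draws independent
genes (no co-expression beyond the injected programs), one expression
program shared across structures, no cell-type mixtures, splicing, spatial
gradients or read-level artefacts, and its sex markers are caricatures.
Green tests establish that the *statistical machinery* is correct and
calibrated in this stated world — not that any particular biological system
is lateralized.

## Numerical choices and edge cases

- log2-CPM uses `log2((count + 0.5) / (libsize + 1) * 1e6)`; the 0.5 prior
  avoids log 0 and is configurable.
- The expression filter (≥ 5 reads in ≥ 3 libraries, per structure) is
  idempotent; `min_reads = 0` keeps everything.
- MDS QC quantifies the traditional visual outlier judgment as distance to
  the structure centroid exceeding median + 5·MAD in MDS space, on the top
  500 most-variable genes; per-dimension sex/side/age tests are
  Bonferroni-corrected over the `k_dims = 8` dimensions examined (both
  defaults configurable; the emulated analyses do not state either value).
- Sex inference thresholds: XIST > 2 log2-CPM and both Y markers < 1 for
  female, the reverse for male, otherwise "indeterminate" (never a crash
  when markers are missing). The direction of the rule is standard; the
  thresholds are this package's defaults.
- GSEA with every member score zero (weight p > 0) is an error — the hit
  normalization is undefined.
- Empirical permutation p-values use add-one estimators; GSEA nominal
  p/FWER/FDR are plain tail fractions (0 is possible and meaningful there).
- All randomized stages take explicit seeds and restore the caller's RNG
  state; identical config + seed gives bit-identical output, including
  written files.

## Known limitations

- The FDR estimator follows the classic pooled-tail-ratio construction but
  is not bit-compatible with any particular GSEA release.
- The sign-flip p-value has granularity $1/2^{n-1}$; with 5 pairs the
  smallest achievable p is 1/16, so "significance at 0.05" is impossible
  below n = 6 — a property of the design, not the implementation.
- `asynchrony_delta` is expressed in weeks but the package deliberately
  does not estimate the lag in weeks from data (the age effect is
  confounded with sex and structure availability in realistic designs);
  only the direction and its permutation significance are reported.
- The age model treats age strictly linearly; curvature over wide windows
  is not modelled.
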