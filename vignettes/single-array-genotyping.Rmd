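---
title: "Single-array SNP genotyping with log-concave mixtures: model and methods"
author: "arraycall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-array SNP genotyping: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arraycall)
```

## The problem

A SNP microarray measures, for every biallelic marker, two fluorescence
intensities — one per allele.  The common calling strategy clusters each
SNP across many arrays; it needs large sample collections and breaks down
when a SNP's minor allele frequency (MAF) is low and one or two of its
genotype clusters are empty or nearly so.  This package instead genotypes
all SNPs of a *single* array simultaneously: on one array the three
genotype clouds each contain tens of thousands of points, so cluster
estimation is easy regardless of any individual marker's MAF, and an array
can be processed the moment it comes off the scanner.

## Signal transform and seed partition

With `A` and `B` the linear-scale channel intensities, the working
coordinates are `strength = (log10 A + log10 B)/2` and `contrast = log10 B
− log10 A`.  Equal channels give contrast 0 (heterozygotes); homozygotes
sit at symmetric positive/negative contrast, so the genotypes form three
horizontal bands.  The orientation (BB on top) is a convention;
`flip_contrast` reverses it for platforms with swapped channel labels.
Non-positive or missing intensities are raised to `clip_floor` (default 1
on the raw scale) rather than dropped, so every SNP gets a call; clipped
SNPs carry a flag.

EM needs a starting partition: two horizontal lines at contrast −0.2 and
0.2 split the plane into AA / AB / BB sectors (boundary values go to the
closed middle sector).  These defaults suit typical arrays whose
heterozygote band is centred near zero; they are deliberately crude — the
EM refines the partition, and perturbing the lines by ±0.1 leaves the final
calls unchanged on well-separated data (this is a test in the suite).

## The histogram

All SNPs are binned on an `nx × ny` grid (default 100 × 100, the advised
size; finer grids cost time without changing calls).  Bins are half-open
`[lo, hi)` with the last bin closed, a convention stated explicitly because
an off-by-one at a bin edge can move a SNP across a call boundary.  The
domain is the data range padded by 1% per side, so boundary B-splines are
not dominated by edge bins; points outside an explicitly supplied domain
are clamped into the boundary bins and flagged, never discarded.  The
histogram is the whole interface to the fitting stage: runtime from here on
depends on the grid, not on the number of SNPs.

## Penalized Poisson density smoothing

Counts `y` in the bins are treated as Poisson with log expectation
expanded in B-splines, `η = Bα` in one dimension.  The penalized
log-likelihood

$$\ell(\alpha) = \sum_i \left( y_i \eta_i - e^{\eta_i} \right)
  - \tfrac{\lambda}{2}\,\lVert D_3 \alpha \rVert^2$$

is maximized by IRLS; `D₃` forms third differences of adjacent
coefficients.  The basis covers the domain with `nseg = 10` equal segments
of cubic splines plus three boundary splines, 13 bases per direction.  Two
properties of the third-order penalty carry the whole design:

* **Moment conservation.**  At the optimum, `Σμ = Σy` and the mean and
  variance computed from the fit equal those of the data, for *every* λ.
  The smooth component can never drift away from its data — essential when
  the fits are mixture components.
* **Log-concave limit.**  The null space of `D₃` is the quadratic
  sequences, so as λ grows the log-density tends to a parabola, i.e. a
  Gaussian.  Components stay unimodal without a parametric assumption.

In two dimensions `η = B_r A B_cᵀ` with a coefficient matrix `A` penalized
along rows and columns (Frobenius norms, one λ per direction).  The IRLS
normal equations are assembled with the generalized linear array model
(GLAM) row-tensor identities, never forming the `(nx·ny) × (n_r·n_c)`
Kronecker design.  A deliberately naive Kronecker implementation
(`naive_fit_2d_kron()`, refused above 400 total bases) exists purely as the
correctness oracle; the suite asserts agreement to 1e-8 on twenty random
instances.

### Numerical choices

* IRLS starts from a ridged least-squares fit of `log(y + 1)` on the basis.
* The linear predictor is capped at 300 inside the objective so `exp`
  cannot overflow; a candidate step that would materially decrease the
  penalized likelihood is step-halved (up to 20 times, relative slack
  1e-9).  Both guards exist because the bare linearization can diverge
  transiently when a component's density extrapolates upward into an empty
  corner of the grid.
* A scaled ridge (1e-9 of the largest normal-equation diagonal) is added to
  each solve: the penalty's null space — quadratic surfaces, 9 dimensions
  in 2-D — is unidentified wherever a component carries almost no mass.
  The ridge and the step-halving are identical in the GLAM and Kronecker
  paths, so they share a fixed point.
* `μ` is floored at 1e-10 inside the working weights to avoid division
  blow-ups in empty regions.
* Convergence: max abs coefficient change below 1e-6, at most 50
  iterations; non-convergence is flagged in the result, not fatal.
* Fractional counts (the EM pseudo-counts) are accepted by reading the
  Poisson log-likelihood as a quasi-likelihood in `y`.

## The EM mixture

The three-component mixture is fitted by alternating (1) an E-step that
splits each bin's observed count into three pseudo-counts proportional to
the current component densities `μ_k`, and (2) an M-step that re-smooths
each component's pseudo-counts with the 2-D fitter, warm-started from the
previous coefficients.  The pseudo-counts sum to the observed histogram
exactly at every iteration, and there are no explicit mixing-proportion
parameters — the proportions are implicit in the pseudo-count totals.
The observed-data penalized log-likelihood is recorded each iteration and
is non-decreasing up to the inner-solver tolerance (the suite checks this
with relative slack 1e-8·(1+|L|); an absolute slack would be meaningless
against a log-likelihood of order 1e5).

**Convergence metric.**  EM stops when the *count-weighted mean* absolute
membership change per iteration falls below 1e-6 — the average amount by
which an individual SNP's probabilities still move.  A max-over-bins metric
was rejected after inspection: on low-MAF arrays a single outlier SNP in a
far tail bin drifts between the two remote components for ~80 iterations
without any call changing, holding the whole fit hostage.  The weighted
metric is equally tied to calls but robust to lone outliers.  On typical
arrays EM converges in 11–25 iterations; the deliberately pathological
low-MAF stress preset can need 40–120, with the log-likelihood monotone
throughout — the slow part is the far-field membership of a handful of
points, not the cluster densities.

**Extinction.**  A component whose pseudo-count total falls below 1 (possible
at extreme MAF on a small array) is frozen at a flat density carrying 1e-6
of the data mass and flagged; EM continues with the rest.  Likewise an
empty seed sector receives a uniform floor so its component is fittable at
all.  No catch-all outlier component is included; the three log-concave
components have proven flexible enough, and the hook is left to a future
configuration option.

**Determinism.**  Nothing in the fit is random: the same input and
configuration reproduce the same calls byte for byte.

## Calling, confidence and evaluation

Each SNP inherits the membership triple of its bin; the argmax is the
call and the maximum `P*` the confidence.  With three components `P*`
cannot fall below 1/3, attained exactly at the uniform triple.  Exact ties
are resolved deterministically preferring AB, then AA (ties are measure
zero and flagged).  By default no NoCall threshold is applied — there is no
principled way to pick one, and since all three probabilities are stored a
threshold can be applied, changed or removed at any later time
(`apply_nocall_threshold()`, idempotent and monotone).

Evaluation machinery: `crosstab()` builds the 4×4 concordance table
(rows = this method, columns = reference, order AA/AB/BB/NN) with a
column-normalized percentage view summing to 100% per reference class;
`compute_maf()` pools calls across arrays and computes the B-allele
frequency `f = (2·n_BB + n_AB) / (2·(n_AA + n_AB + n_BB))` and
`MAF = min(f, 1−f)`, excluding NN calls (a SNP with no called genotype gets
`NA`); `quality_summaries()` reports the per-array `P*` distribution, the
per-SNP mean `P*` across arrays (a useful per-marker quality indicator)
and how many distinct genotypes each SNP shows.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `nx`, `ny` | 100 × 100 | histogram bins; finer only costs time |
| `nseg`, `degree` | 10, 3 | 10+3 cubic B-splines per direction |
| `lambda` | 300 | smoothness of each component's log-density |
| `split_lo`, `split_hi` | −0.2, 0.2 | seed split lines on contrast |
| `nocall_threshold` | none | `P*` below it → NN, in `[1/3, 1]` |
| `clip_floor` | 1 | raw-intensity floor before logs |
| `em_tol`, `em_maxit` | 1e-6, 50 | EM stopping rule |
| `irls_tol`, `irls_maxit` | 1e-6, 50 | inner solver stopping rule |

**On λ.**  Calls are insensitive to λ over a very wide plateau: on a fixed
synthetic array, λ = 100, 300 and 1000 give bit-identical calls (asserted
as a test), at both 1e5 and 1e6 SNPs.  Within that plateau the default 300
is the value at which each component stays close to its unimodal
log-concave limit on full-size histograms and EM iteration counts stop
growing with array size; with much weaker smoothing (λ = 10) the penalty is
negligible against a million-count histogram, mis-seeded mass from the
crude initial split lingers as secondary bumps in the component densities,
and EM spends dozens of extra iterations transporting it — without changing
the final calls.  The stand-alone smoothing functions
(`fit_pspline_poisson_1d/2d`) default to λ = 10, a neutral value for
generic density smoothing at ordinary histogram scales.

## The synthetic-data generator

`simulate_array()` draws, per SNP, a MAF from a configurable sampler
(fixed value, finite set, uniform, or beta rescaled to `[0, 0.5]`), a
genotype from Hardy–Weinberg proportions `((1−p)², 2p(1−p), p²)` with B the
minor allele, and `(strength, contrast)` from the genotype's Gaussian
cluster, optionally bent by a quadratic shear; the transform is then
inverted to produce linear-scale intensities, so the pipeline's transform
recovers the sampled coordinates exactly.  Presets:

* `affymetrix_like` — clusters mirror-symmetric about contrast 0 (one-dye
  chemistry) with touching Gaussian tails; `separation` (default 7) is the
  center spacing in units of the contrast spread (default 0.2), MAF uniform
  on `[0.05, 0.5]`.
* `illumina_like` — tighter, asymmetric, bent clusters with near-empty
  valleys (two-dye chemistry), which yields visibly higher `P*`.
* `low_maf_stress` — affymetrix geometry with MAF drawn from
  `{0, 0.01, 0.05}`, exercising nearly-empty clusters and the
  extinct-component path.

Hardy–Weinberg sampling is the population-genetics default truth model;
the generator emulates the cluster *geometry* of real arrays but not probe
effects, spatial artifacts, batch effects, copy-number changes or null
alleles (the three-component model implicitly assumes normal diploid DNA).
Passing tests on these simulations therefore demonstrate correct recovery
of the model's own data-generating process, not robustness to every
artifact of real chips — concordance against an external reference remains
the only real-data validation.

## Problem sizes and known limitations

The test suite runs synthetic arrays of 1e3–1e5 SNPs (one runtime check
uses 1e6) with 40–100 bins per side; the acceptance script uses 2e4–1e6
SNPs.  These sizes keep the full suite around a minute on one core while
exercising every code path; results do not change with more data because
the fit sees only the histogram.  The three per-SNP stages — transform,
binning, per-SNP argmax — are compiled (Rcpp) so that a million-SNP array
costs little more than the fit itself; the fit is pure R, and on a fixed
histogram domain its EM iteration count is identical at 1e5 and 1e6 SNPs.

Known limitations: no data-driven λ selection (deliberate; calls sit on a
wide plateau); no catch-all outlier component; no copy-number-aware extra
components; no multi-array refinement; bin-level probabilities mean all
SNPs in one bin share a probability triple — at a 100 × 100 grid that
granularity is far below the cluster scale.  EM on extreme low-MAF arrays
can exceed the default 50-iteration cap while a few far-field outlier
memberships settle; the fit is flagged unconverged, the log-likelihood
remains monotone, and raising `em_maxit` resolves it without changing
in-cluster calls.
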