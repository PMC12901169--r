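---
title: "Worst-case SAR measurement error from directional coupler directivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Worst-case SAR measurement error from directional coupler directivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptxsar)
```

## The measurement problem

Online SAR supervision in a parallel-transmit (pTx) MRI system reconstructs
local SAR from the complex forward signals of every transmit channel,
measured with directional couplers between the amplifiers and the RF array.
A real coupler has finite directivity $D$: a fraction $1/D$ of the reflected
wave leaks into the forward port, so each channel measures
$a_\mathrm{meas} = a_\mathrm{act} + b / D$ instead of $a_\mathrm{act}$.  In
a coupled array the reflected signal $b$ on one channel is dominated by
power coupled in from the *other* channels, so the measurement error is a
property of the whole array, not of one channel, and it can make the
supervision *underestimate* SAR — the unsafe direction.

With the array's scattering matrix $S$, the vector of reflected signals is
$y = \tfrac{1}{\mu} e^{i\phi} S x_\mathrm{act}$, where $\phi$ is the phase
offset between the reference planes of the S-parameter data and of the
coupler measurement, and $1/\mu$ the cable attenuation between those planes.
The measured excitation vector is therefore a linear image of the actual
one,

$$x_\mathrm{meas} = M\, x_\mathrm{act}, \qquad
  M = \tfrac{1}{\mu} e^{i\phi} D^{-1} S + I .$$

Supervision evaluates SAR with virtual observation points (VOPs): Hermitian
PSD matrices $Q_j$ with $\mathrm{SAR}_j = x^H Q_j x$.  Plugging
$x_\mathrm{meas}$ into the quadratic form shows that measuring through $M$
is the same as supervising with the congruence-transformed set
$\tilde Q_j = M^H Q_j M$.  The worst-case relative error at a given $\phi$
is then a comparison of two matrix sets over all excitations,

$$r(\phi) \;=\; \max_{Q_j} \; \max_{x \in \mathbb{C}^{N}}
  \frac{x^H Q_j x}{\max_k\, x^H \tilde Q_k x},$$

and the headline safety number is the peak of $r$ over $\phi$.  A ratio
$r$ corresponds to an underestimation of $(1 - 1/r)\cdot 100$ percent of
the actual SAR.  The same machinery with a single identity VOP gives the
worst-case error of the *total forward power* measurement, which equals
$1/\lambda_\mathrm{min}(M^H M)$.

## How the solver works

For each actual VOP the inner problem is: maximize the convex quadratic
$x^T Q_{j,\mathbb{R}} x$ over the real embedding
$Q_\mathbb{R} = \left(\begin{smallmatrix}\Re Q & -\Im Q\\ \Im Q & \Re
Q\end{smallmatrix}\right)$, subject to $x^T \tilde Q_{k,\mathbb{R}} x \le 1$
for every measured VOP (`real_embed()` is exposed and property-tested:
quadratic forms are preserved exactly).  `worst_case_ratio()` solves the
semidefinite relaxation of this program through its dual,

$$\min_{\lambda \ge 0} \textstyle\sum_k \lambda_k
  \quad \text{s.t.} \quad \sum_k \lambda_k \tilde Q_k \succeq Q_j,$$

by a log-determinant barrier (damped Newton in the $K$ dual variables,
path parameter multiplied by 20 per stage, target relative gap
`ptxsar_tol("solver")` = 1e-8).  Two sound upper bounds come out of the
dual: $\sum_k \lambda_k$ at any strictly feasible point, and the largest
generalized eigenvalue of $(Q_j, \sum_k w_k \tilde Q_k)$ at the normalized
weights $w = \lambda / \sum \lambda$ — the reported bound is their minimum.
Because the generalized-eigenvalue refinement is exact in $w$ and flat to
first order around the optimum, the reported value is far more accurate
than the raw barrier objective; with a single measured VOP the simplex is a
point and the bound is the generalized eigenvalue itself, computed by
Cholesky whitening with no iteration at all.

The relaxation is complemented by a rank-one extraction: the generalized
eigenvector, rescaled onto the active constraint and refined by
deterministic local ascent, is a *feasible* excitation.  Its achieved ratio
is a lower bound, and the relative distance to the upper bound is reported
as `certificate_gap` rather than hidden.  In every instance family we test
(including the acceptance suite's 50 random arrays) the gap closes to
$\sim 10^{-10}$; an instance where the relaxation were loose would be
flagged by its own certificate.

Remaining choices, stated once:

* **Outer loop.** The maximum over actual VOPs is an exhaustive loop; ties
  are broken by the lowest index.
* **Phase grid.** $r(\phi)$ is not concave or convex in $\phi$ (sweeps
  routinely show several local maxima), so $\phi$ is grid-searched on a
  uniform grid over $[0, 2\pi)$ with the endpoint excluded; the default is
  360 steps (one per degree).
* **Degenerate directions.** Before solving, directions in the common null
  space of all measured VOPs are detected from the eigenvalues of
  $\sum_k \tilde Q_k$.  If actual SAR is positive along such a direction
  the problem is genuinely unbounded (a drive the supervision cannot see)
  and the solver signals an `unbounded` error; if actual SAR also vanishes
  there, the direction is harmless and is deflated away by projecting onto
  the orthogonal complement.
* **Scaling.** VOP sets are normalized by the largest spectral norm in the
  actual set before solving; the ratio is scale-free, so W/kg magnitudes
  never reach the barrier.
* **Verification.** `oracle_max_ratio()` is an independent instrument —
  isotropic complex Gaussian sampling normalized onto the feasible
  boundary, plus deterministic projected ascent on the best 32 candidates
  (200 iterations, step halved on non-improvement).  It shares no code path
  with the relaxation and provides the certified lower bounds used in the
  tests.  Sampling is exponentially inefficient in channel count; the
  oracle is meaningful up to roughly 8 channels.

## Parameters that matter

| Parameter | Units / default | Meaning |
|---|---|---|
| `directivity_db` | dB, no default | Coupler directivity on the **voltage** convention, $D = 10^{\mathrm{dB}/20}$. The leaked reflected wave adds to a voltage phasor, so a power convention would halve the modelled effect. A per-channel vector is accepted (hardware varies); a scalar is the common case. |
| `phase_rad` | rad, 0 | Reference-plane offset $\phi$, one global value for all channels (cable lengths are near-identical in practice). |
| `attenuation_linear` | —, 1 | $\mu \ge 1$; 1 means the coupler sits at the S-parameter reference plane. Kept explicit because moving the coupler toward the amplifier scales the effective $S$ by the attenuation squared and *reduces* the SAR error. |
| `n_steps` | —, 360 | Phase grid size per sweep. |
| `ptxsar_tol()` | — | Validation and solver tolerances (passivity 1e-6, Hermiticity 1e-9, PSD 1e-10, solver gap 1e-8), all package options. |

Percentages are reported in both conventions — $(1-1/r)\cdot 100$ ("percent
of the actual SAR", the headline and default) and $(r-1)\cdot 100$ (excess
over the measured value) — because published numbers do not always state
which is meant; the CSV output always carries both columns.

## What the synthetic generator emulates — and what it does not

`synth_smatrix()` draws reciprocal matrices with a prescribed diagonal
reflection magnitude and circulant, distance-decaying off-diagonal coupling
(decay 0.5 per ring step), mirroring nearest-neighbour-dominated transmit
arrays; a dense mode removes the decay for stress tests.  Passivity is
enforced by global rescaling (not spectral clipping) so the coupling
*structure* is preserved, and `target_max_reflected_power` pins the largest
eigenvalue of $S^H S$ exactly.  `synth_vops()` builds Hermitian PSD
matrices as sums of random outer products with unit peak spectral norm.

`make_benchmark_suite()` fixes three regimes chosen to span the practical
range: a well-decoupled 8-channel array (worst-case reflected power 8%,
like intrinsically decoupled, heavily loaded microstrip elements), a
strongly coupled 8-channel array (84%, the worst coupling reported for
large-diameter arrays without effective decoupling networks), and a
strongly coupled 32-channel array (60%).

None of this is electromagnetically real: synthetic VOPs are not
compressed from simulated E-fields, carry no compression overestimation
term, and the S-matrices reproduce no specific hardware.  Passing tests
therefore demonstrate the correctness of the *error calculus* (congruence
transform, worst-case optimization, passivity analysis) on matrices with
realistic structure — they do not validate any particular array's safety
factor.  VOP sets for real arrays are inputs, produced upstream by field
simulation and compression.

## Numerical choices and problem sizes

The test and acceptance workloads are sized for a single CPU: random
solver-vs-oracle instances use 2–4 channels and up to 5 VOPs (50 instances,
3000 oracle samples each); benchmark-suite sweeps use 72 phase steps; the
single-channel closed-form check uses 3600 steps to resolve the peak to
well under 0.05 percentage points; the coupling-vs-error association uses
20 generator draws at 4 channels and 24 phase steps.  A 32-channel,
12-VOP phase point solves in a few seconds.

Degenerate inputs are handled explicitly: zero actual VOPs give ratio 0
contributions; an all-zero measured set, or any unseen drive direction with
positive actual SAR, raises `ptxsar_unbounded`; singular error matrices are
accepted by `custom_error_matrix()` and diagnosed downstream, matching how
a sniffer-coil correlation matrix with a blind channel would behave.

## Known limitations

* The worst case is certified per phase grid point; a peak falling between
  grid points is resolved only to the grid resolution (use more steps for
  narrow resonant features).
* The sampling oracle does not scale past ~8 channels; at 32 channels the
  certificate gap is the only per-instance optimality evidence (it is
  reported, and has been at the 1e-10 level throughout).
* Only finite directivity is modelled.  Digitization error, receiver
  noise, coupler insertion loss and frequency response are other real
  error sources and are out of scope.
* File formats: Touchstone v1.1 (not v2.0) for S-parameters, and a
  documented plain-text JSON container for VOP sets, chosen so fixtures
  are diffable, portable and exactly round-trippable.
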