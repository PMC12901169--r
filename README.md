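# ptxsar

Worst-case SAR measurement error from directional coupler directivity in
parallel-transmit MRI.

## The problem

Multi-channel (pTx) MRI systems supervise local SAR online by measuring the
complex forward signal of every transmit channel with directional couplers
and evaluating virtual observation points (VOPs): Hermitian PSD matrices
Q_j with SAR_j = xᴴ Q_j x for the excitation vector x.  A real coupler has
finite directivity D, so a fraction 1/D of the reflected wave leaks into
the forward measurement.  In a coupled array the reflected signal on a
channel is dominated by power coupled in from the *other* channels, and the
leak can make the supervision **underestimate** SAR — the safety-relevant
direction.  Safety factors must therefore be derived from the worst case
over all excitations, not from a single-channel estimate.

`ptxsar` computes that worst case exactly.  With the array S-matrix, the
measured excitation vector is x_meas = M x_act where

    M = (1/μ) e^{iφ} D⁻¹ S + I

(φ the reference-plane phase offset, 1/μ the cable attenuation).
Measuring through M is equivalent to supervising with the transformed VOP
set Q̃_j = Mᴴ Q_j M, and the worst-case relative error at a given φ is

    r(φ) = max_j max_x  xᴴ Q_j x / max_k xᴴ Q̃_k x ,

solved per VOP as a quadratically constrained program via its semidefinite
relaxation, with a certified feasible excitation extracted and the
relaxation gap reported.  Because r is not a convex function of φ, the
phase is swept on a uniform grid (default 360 steps over [0, 2π)).  The
underestimation of the *total forward power* measurement is the same
computation with a single identity VOP and equals 1/λ_min(MᴴM).  The
package is aimed at RF safety engineers and coil developers who need the
safety factor for a given array/coupler combination, and it generalizes to
any linear measurement model (e.g. sniffer-coil correlation matrices) via
`custom_error_matrix()`.

It also includes the standard array-quality diagnostic: the eigenvalues of
SᴴS, whose largest value is the worst-case total reflected power fraction.

## Worked example

```r
library(ptxsar)

suite <- make_benchmark_suite(seed = 42)     # three synthetic fixtures
f <- suite$high_coupling_8ch                 # strongly coupled 8-channel array

reflected_power_spectrum(f$smatrix)
#> <passivity_spectrum> 8 modes 'synth-8ch'; worst-case reflected power 0.84

sw <- phase_sweep(f$vops, f$smatrix, directivity_db = 25, n_steps = 72)
sw
#> <phase_sweep_result:sar> 72 phases, directivity 25 dB; peak ratio 1.12156
#>   (10.8% of actual) at phase 1.658 rad

power_error_sweep(f$smatrix, 25, n_steps = 72)
#> <phase_sweep_result:power> 72 phases, directivity 25 dB; peak ratio 1.08252
#>   (7.62% of actual) at phase 3.665 rad
```

Reading: at the worst reference-plane phase, a 25 dB coupler on this array
can under-report local SAR by 10.8% of its true value (ratio r = 1.122 of
actual to measured-inferred SAR), while the total-forward-power error peaks
lower, at 7.6% — supervising power alone understates the SAR risk.  The
safety factor to apply is the peak ratio.  `tidy(sw)` returns the per-phase
tibble (both percent conventions included), `glance(sw)` the peak row, and
`autoplot(sw)` the error-vs-phase curve.  Worst-case results carry a
`certificate_gap`: the reported excitation provably achieves the bound up
to that (tiny) gap.

File-based pipelines use `read_touchstone()` (Touchstone v1.1 .sNp),
`read_vops()`/`write_vops()` (documented JSON container), and
`run_analysis()` / `inst/cli/ptxsar.R` for end-to-end CSV/JSON report
bundles from a YAML config.  An independent brute-force verifier,
`oracle_max_ratio()`, certifies lower bounds on small instances.

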