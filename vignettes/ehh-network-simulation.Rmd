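---
title: "Extended Hodgkin-Huxley network simulation: models, partitioning and the hardware performance model"
author: "ehhsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended Hodgkin-Huxley network simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehhsim)
```

## The model family

`ehhsim` simulates conductance-based neural networks in the extended
Hodgkin-Huxley (eHH) formalism.  Each cell is a serial chain of
electrically lumped compartments; each compartment's membrane voltage obeys

$$C \frac{dV_i}{dt} = I_{app,i} - I_{channels,i} - I_{leak,i} - I_{mc,i} - I_{gap,i}$$

with ionic currents $I_{channel} = g_c\,(V - V_c)\,\prod_k y_k^{p_k}$ over
gate activation variables $y_k \in [0,1]$, an ohmic leak
$g_l\,(V - V_l)$, an inter-compartment current
$I_{mc,i} = g_{int} \sum_j (V_i - V_j)/p_{ij}$ over the chain neighbours,
and a gap-junction current between the *gap compartments* (dendrites) of
different cells,

$$I_{gap,i} = \sum_j w_{ij}\,\bigl(c_0\,e^{c_1 V_{ij}^2} + c_2\bigr)\,V_{ij},
\qquad V_{ij} = V_i - V_j .$$

The gap conductance falls off with the squared voltage difference — the
defining property of the electrical coupling between olivary dendrites —
and $w_{ij}$ weights the junction into cell $i$ from cell $j$; diagonal
entries are ignored.

Gate dynamics use either transition rates,
$dy/dt = (1-y)\alpha - y\beta$, or the relaxation form
$dy/dt = (y_\infty - y)/\tau$.  Every rate, steady-state and time-constant
curve is one member of a three-branch generalized family
(`rate_function()`): with $x = (k_1 - v)k_2$,

| branch | form |
|---|---|
| $f_t = 0$ | $k_0 (k_1 - v)\,/\,(e^{x} - 1)$ |
| $f_t = 1$ | $k_0\, e^{x}$ |
| $f_t = 2$ | $k_0\,/\,(e^{x} + 1)$ |

wrapped affinely as $a f(v) + b$.  The affine wrap is this library's
extension of the bare family: it admits constant rates ($f_t = 1$,
$k_2 = 0$), offset time constants ($b > 0$) and saturating curves, which
the inferior-olive preset needs.  Richer generalizations exist in the
hardware-library lineage this package follows, but anything beyond the
affine wrap is deliberately out of scope here.

Branch 0 has a removable singularity at $x = 0$; the evaluator returns the
analytic limit $k_0/k_2$ whenever $|x| < 10^{-7}$.  The guard width is far
below any physiological grid spacing and the branch is first-order
continuous across it, which the test suite checks numerically.

Auxiliary (calcium-like) states extend the gate vector: each is first-order
linear in one channel current of its compartment,
$ds/dt = c_I\,I + c_S\,s$ with $c_S < 0$, and may drive gates in place of
the voltage.  This is exactly the shape of the olivary dendritic calcium
pool, kept generic.

## Presets

`build_original_hh()` is the classic squid-axon cell in its 1952
conventions: voltage is the displacement from rest with depolarization
*negative*, $g_{Na} = 120$, $g_K = 36$, $g_l = 0.3$ mS/cm²,
$V_{Na} = -115$, $V_K = +12$, $V_l = -10.613$ mV, $C = 1$ µF/cm².  The six
rate curves are stored as generalized records, e.g.
$\alpha_n \leftrightarrow (f_t = 0, k_0 = -0.01, k_1 = -10, k_2 = -0.1)$;
the suite verifies all six against direct transcriptions on a dense grid
at $10^{-12}$ relative tolerance.

`build_io_cell()` is a three-compartment inferior-olive (IO) cell —
dendrite, soma, axon — transcribed from the published olivary model
lineage (De Gruijl et al. / Schweighofer et al.): dendritic high-threshold
calcium ($r^2$), calcium-gated potassium ($s$, driven by the calcium
concentration), h-current ($q$); somatic low-threshold calcium ($k^3 l$),
sodium ($m^3 h$), delayed rectifier ($n^4$) and fast potassium ($x_s^4$);
axonal sodium ($m_a^3 h_a$) and potassium ($x_a^4$).  Compartments share
$g_{int} = 0.13$ with surface ratios $0.25$ (soma : dendrite) and $0.15$
(axon : soma); the current into the later compartment of a link divides by
$p$, the earlier by $1 - p$.  Counting the calcium concentration — which
occupies a slot of the same per-gate state pipeline — the cell carries 13
gate variables, split 4 / 6 / 3 over dendrite / soma / axon, so every
compartment holds between 3 and 6.

Three transcription choices deserve mention, all documented here because
the exact source curves fall outside the affine-wrapped family:

* $\tau_q$ (h-current) and $\tau_l$ (calcium inactivation) are published as
  products/sums of exponentials.  They are represented by least-squares
  sigmoid fits over the voltage range the model actually visits
  (about $-100$ to $-30$ mV), accurate to roughly 10% at the range edges
  and much better in the subthreshold band.  Both are slow gates; the fit
  error perturbs time constants, not fixed points.
* the calcium-dependent activation rate of the KCa gate is published as
  $\min(2\cdot10^{-5}\,[Ca], 0.01)$; it is represented by the smooth
  saturating curve $0.01(1 - e^{-0.002 [Ca]})$, which matches the linear
  regime exactly and the cap asymptotically.
* the sodium activation gates $m$ and $m_a$ are instantaneous in the
  source model.  They are stored as relaxation gates with a constant
  $\tau = 0.05$ ms — the preset's default time step — so a forward-Euler
  step lands exactly on $m_\infty(V)$ of the pre-step voltage,
  reproducing the instantaneous update at the default step while keeping
  the gates inside the generalized framework.

`build_io_network(n)` replicates the cell all-to-all with gap constants
$c_0 = 0.8$, $c_1 = -0.01$, $c_2 = 0.2$; generated weights in $[0,1]$ are
scaled by a global gap conductance (default $0.04$ mS/cm²) so that the
stored weights keep the documented 0-to-1 range.

Default time steps are 0.01 ms for the squid-axon preset and 0.05 ms for
the IO preset — forward-Euler stability margins chosen as library
conventions and exposed in `sim_config()`.

## The solver

The integrator is forward Euler, $u^{n+1} = u^n + \Delta t\, f(u^n)$,
applied synchronously to the whole state vector: every term is assembled
from the pre-step snapshot.  (The hardware implementation this library
emulates splits the update between a cell kernel and gap kernels, but that
split is mathematically the same synchronous step, so it is not emulated
separately.)  Properties the suite verifies:

* first-order convergence: the global trace error against a $\Delta t/64$
  reference scales with slope $1.0 \pm 0.15$ in log-log over
  $\Delta t \in \{0.04, 0.02, 0.01\}$;
* gate boundedness: transition-rate gates remain in $[0,1]$ whenever
  $\Delta t(\alpha + \beta) \le 1$ along the trajectory;
* a cell initialized at the fixed point (gates at steady state, voltage at
  the root of the total current — `resting_voltage()`) stays at rest to
  within $10^{-3}$ mV over 50 ms;
* determinism: identical inputs give byte-identical traces.

Steady-state initialization orders its computation: voltage-driven gates
first, then auxiliary fixed points $s^\ast = -c_I I / c_S$ from the
resulting channel currents, then auxiliary-driven gates.  Stimuli are
constant, pulse (half-open $[on, off)$, so step counts are unambiguous) or
zero-order-hold series.  Non-finite derivatives abort the run with an
error naming the offending state variable and step.

## Ring-partitioned gap computation

The all-to-all gap sum is the only term coupling cells, and the library
mirrors the multi-accelerator systolic schedule used in hardware: cells are
split into $K$ equal contiguous blocks (phantom zero-weight cells pad the
last block when $K$ does not divide $N$; their output is discarded), each
block lives on one emulated gap kernel, and blocks of voltages circulate
around a ring in $K$ stages — *start* (each kernel consumes its own block
and forwards it), *middle* stages (consume the received block, forward
it), *end* (consume the final block, update).  At stage $s$, kernel $k$
consumes block $(k - s - 1 \bmod K) + 1$; after $K$ stages every kernel
has seen every block exactly once, transmitting exactly one block per
non-final stage — the transfer volume behind the ring-throughput model.

One design decision is worth spelling out.  Floating-point addition is not
associative, so the *accumulation order* decides whether different $K$
give bit-identical currents.  The emulator therefore normalizes the
default accumulation to ascending global cell index — a flat running sum
that is independent of the block structure — making the partitioned result
bit-identical to the dense evaluation for **every** kernel count, and
whole-network traces invariant in `n_gap_kernels`.  The hardware's actual
arrival-order accumulation is available as `order = "schedule"`; it
differs from the dense sum only by reassociation, bounded in the suite at
$10^{-10}$ relative and observed near $10^{-16}$.  Conservation
($\sum_i I_{gap,i} = 0$ for symmetric weights, by pairwise antisymmetry)
is checked through both paths.

The emulation is sequential; concurrency is represented by the contract
that a stage consumes only data produced before it (double-buffered block
exchange), which the schedule's structure enforces.

## Connectivity generation

Weight matrices need not be stored: entry $(i,j)$ is regenerated on demand
from the stateless counter-based Squares generator — four middle-square
rounds over a 64-bit counter and key.  The counter layout is row-major,
$(i-1)n + (j-1)$, with the upper-triangle counter shared between $(i,j)$
and $(j,i)$ in symmetric mode, so `weight_entry()` reproduces any stored
entry exactly without materializing the matrix.  Keys are built from user
seeds by the published digit rules (non-zero, pairwise-distinct low and
high hex digits, odd lowest digit).  Uniform weights are the 32-bit output
over $2^{32}$; Gaussian weights apply $\mu + \sigma\,\Phi^{-1}(u)$
(`stats::qnorm`) and clip to $[0,1]$ — with the defaults
$\mu = 0.5, \sigma = 0.15$ the clipped tail mass is $8.6\cdot10^{-4}$,
kept deliberately below the 0.1% the weight range allows.  The suite
checks chi-square uniformity (256 bins, $n = 10^5$, $p > 0.001$), the KS
statistic against $U(0,1)$, probit accuracy against a root-finding oracle
($10^{-9}$), and the mean and clipping of generated matrices.

## The hardware performance model

The analytical model predicts when the dataflow implementation is bound by
compute or by memory:

* cell kernel DRAM: $(96+4)\,uf\,f + 44 f/\lceil N_g/uf\rceil +
  4 f/(\lceil N_g/uf\rceil N_c)$ bytes/s.  (The printed one-line
  simplification of this expression in the source material is inconsistent
  with its own expanded form; the expanded form is implemented.)
* gap kernel DRAM: $4\,uf_{gap}\,f$ — one 4-byte weight per lane per tick.
  Against a 15 GB/s DIMM this crosses at 118 MHz for $uf_{gap} = 32$
  (and at 235 MHz for 16: $15\cdot10^9/64\cdot10^6 = 234.375$).
* on-chip memory blocks: $\lceil w/w_{hw}\rceil \lceil d/d_{hw}\rceil
  \lceil p/p_{hw}\rceil$ over a 36-bit x 1024 x 1-port block geometry;
  vectorizing 8 values never costs blocks when the depth stays a multiple
  of eight block depths.
* ticks per ring stage: $N \cdot \max(d_{gap}, \lceil N/uf_{gap}\rceil)$
  — each cell's accumulation occupies the pipeline for the larger of the
  pipeline depth and its unrolled iteration count.  The two printed
  branch conditions in the source material place the unroll factor on
  opposite sides; the unified max form reproduces both printed branches
  and the linear-then-quadratic scaling narrative, and it is validated
  against a tick-by-tick pipeline emulation for small $(N, uf, d)$.
* multi-kernel ticks: $N_{steps}\,K\,\cdot$ stage ticks over blocks of
  $N/K$ — per-kernel wall ticks fall as $1/K$ once saturated, so the
  aggregate over kernels is constant: the perfect-scaling property.
* execution time: $\max(ticks/f,\; bytes\cdot ticks/bw_{DRAM})$ with the
  bottleneck labelled; the ring interconnect is omitted because its
  required throughput sits orders of magnitude under its bandwidth
  (5 MB/s versus 5 GB/s in the saturated example).  A printed version of
  the transfer-time formula carries an extra frequency factor that is
  dimensionally inconsistent; the implementation uses
  $D = bytes_{tick} \cdot ticks$.

The pipeline depth `d_gap = 90` and inner-loop buffer `size_buffer = 16`
are placeholders: they depend on the synthesized design and are exposed in
`perf_config()` rather than asserted.

## What the synthetic networks do and do not show

Test networks are built in code: preset cells, explicit or generated
weight matrices, fixed keys.  They exercise exactly the mathematics above
— equation fidelity, partitioning, conservation, convergence, generator
statistics.  They do **not** emulate biological heterogeneity (identical
preset cells unless the user varies parameters), sparse or
distance-dependent connectivity (the gap computation is all-to-all by
design, a known cost for sparser networks), chemical synapses, branching
dendritic trees, or stochastic channel gating — all outside this library's
scope.  Passing tests therefore certify the numerics and the emulated
schedule, not biological realism of any particular network.

Problem sizes in the default suite are desk-scale by choice: gap networks
of 12-48 cells, simulations of a few hundred steps, a convergence
reference at $\Delta t = 1.5625\cdot10^{-4}$ ms over 4 ms, $10^5$-draw
generator checks, and tick-model sweeps over $N \le 64$,
$uf \in \{1,2,4,8\}$, $d \le 16$.

## Known limitations

* Double precision only: base R has no 32-bit float type, so the
  single-float arithmetic of the hardware lineage is not reproduced;
  the performance model's 4-byte data sizes are parameters, not the
  arithmetic width.
* Compartment chains are strictly serial; no branching.
* The gap computation always evaluates all $N^2$ pair terms.
* The NeuroML import covers the HH gate subset only (sigmoid, exponential
  and exp-linear rates, `gateHHrates`/`gateHHtauInf`, plus fixed time
  courses); everything else errors loudly rather than being silently
  ignored.  Attribute values are taken in the file's declared units.
* R-side indices are 1-based throughout the API; the generator's counter
  layout is 0-based as documented above.
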