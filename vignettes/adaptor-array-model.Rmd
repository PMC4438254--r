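---
title: "Modeling a time-multiplexed synaptic-plasticity adaptor array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling a time-multiplexed synaptic-plasticity adaptor array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastadapt)
```

`plastadapt` is a behavioral simulator of a synaptic-plasticity adaptor
array that is *separate from the neurons* of a spiking network: each adaptor
receives the pre- and post-synaptic spikes of one connection, adapts a 4-bit
weight (STDP) or a 4-bit axonal delay (STDDP), and emits a weighted or
delayed pre-synaptic spike toward the post-synaptic neuron. The architecture
multiplexes one physical circuit over 8192 time-multiplexed (TM) slots, and
maps up to 8192 dynamically-assigned (DA) synapses onto each slot through a
direct-mapped cache, for $2^{26}$ addressable plastic synapses. This
vignette explains the model the package implements, the choices that were
genuinely open, and what the simulations do and do not show.

## The discrete-time model

Time advances in integer ticks of 1 ms — the update period of every TM slot.
Sub-tick pipeline cycles are not simulated; the two functional consequences
of the pipeline are preserved explicitly instead:

* **last-wins collisions**: when several same-kind spikes target the same
  slot within one tick, only the last one in input order survives
  (`align_tick_events()`), mirroring the order-preserving input FIFO;
* **write ordering within a tick and slot**: prefix assignment, then window
  observation, then modification/emission, then window start or restart.

Within a tick, slots are processed in ascending slot index. Since at most
one pre and one post spike survive per slot per tick and slots do not
interact, this order only fixes the consumption order of the two
pseudo-random streams (LFSR, threshold), making whole runs bit-reproducible
from their seeds.

### Time windows

Each slot owns a time-window generator, canonically a *remaining-time
down-counter*: `start_window(slot, d, polarity)` loads `d`, every tick
decrements all active counters, and the transition 1 → 0 raises a falling
edge readable for exactly that tick. The equivalent up-counter view used to
measure spike-time differences is `elapsed = duration − remaining`. A window
started at tick $t$ with duration $d$ is therefore active at observation
times $t+1, \dots, t+d-1$ and fires its falling edge at $t+d$.

The **analog variant** models an aVLSI window generator as the same
down-counter whose *loaded duration* is distorted by a per-slot
multiplicative mismatch factor, `round(d * f_slot)` clipped to `[1, 16]`,
with `f_slot = exp(sigma * z_slot)` frozen at construction (device mismatch,
not per-event noise). `sigma = 0` reproduces the digital model bit-exactly,
which the tests verify over random operation sequences. The log-normal form
is the standard first-order model for multiplicative transistor mismatch; no
mismatch statistics are available for the original circuit, so `sigma` is a
free parameter and results under `analog` backends are qualitative. R's
round-half-to-even is used as the (deterministic) tie-break for `d * f`.

### Plasticity rules

With $\Delta t < 0$ meaning pre-before-post, the package provides:

* `stdp_delta_proportional()`: $\Delta w = A^+ + \Delta t$ (potentiation,
  $\Delta t < 0$) or $-A^- + \Delta t$ (depression, $\Delta t > 0$) while
  the window is active, which with
  $A^\pm = 16$ equal to the 16-tick window is just the counter value at
  observation, signed by the window's polarity;
* `stdp_delta_fixed()`: $\pm$ `step` (default 1) while active;
* `stdp_delta_exponential()`: the classical $A^\pm e^{\mp\Delta t/\tau^\pm}$
  curve, kept as a *reference oracle* for sign/shape tests only — the engine
  never evaluates it;
* `stddp_delta()`: $-$`step` while the window is active, $+$`step` after it
  expired, and 0 on the falling-edge tick (delay perfectly tuned).

Simultaneous pre/post arrivals never modify anything. All stored values are
clamped to `[0, 15]` by `saturating_add()`.

**Either start or modify.** A spike arriving at an *inactive* window, or at
an active window of its *own* polarity, (re)starts the window; a spike of
the *opposite* polarity performs a modification and leaves the window
running. The alternative — the modifying spike also restarts the window with
its own polarity — is available as `stdp_restart_on_mod = TRUE`. The
either/or semantics is the default for two reasons. First, it is the direct
reading of the hardware's event handling. Second, it matters dynamically:
under restart-on-mod every consecutive pre/post event pair contributes one
modification whose expected value cancels exactly against its mirrored pair
for *any* stationary post process, so the weight distribution cannot depend
on the input rate; under either/or one post-started window can depress
several following pre spikes, which makes the net drift neutral at low rates
but depressive when the post rate is high — the regime in which competitive
STDP pushes weights toward zero.

### Memory fabric

The **Master RAM** is a sparse map keyed by the full 26-bit address;
unwritten addresses read 0 (weak bistable weight, zero delay), matching the
experiments' zero-delay initialization. The per-slot **Local cache** holds
the working 4-bit value of the resident DA synapse; the **DA-address RAM**
holds its 13-bit prefix. Assignment is direct-mapped: a pre spike whose
prefix mismatches the stored one evicts the resident synapse without
write-back — write-through at every modification makes write-back redundant
and keeps the Master RAM permanently coherent. Post-synaptic spikes never
assign; a post with a mismatching prefix therefore modifies the *resident*
synapse, a documented hazard of the architecture that the engine reproduces
(and the tests pin down).

For STDP the Master RAM stores one **bistable bit** per synapse. On
assignment the bit is expanded to `bit * 8 + r3`, `r3` being 3 bits from a
16-bit maximal-length Fibonacci LFSR (taps 16, 15, 13, 4 — verified maximal
by enumeration in the tests); on every commit the new 4-bit weight is
re-binarized with `weight > threshold`, where the threshold is a fresh
uniform draw from `{4, ..., 11}` (inclusive bounds; strict `>`). Thresholds
come from a seeded MINSTD stream rather than a second LFSR; one draw is made
per committing slot visit, which is statistically identical on the commit
path to refreshing every time slot and keeps runs deterministic. All three
stochastic elements (LFSR, thresholds, mismatch factors) are seeded
explicitly, so identical seeds give identical complete simulations.

## Synthetic inputs and the neuron stub

The package generates every experimental input itself:

* `poisson_train()`: independent Bernoulli trials per 1 ms tick with
  $p = \text{rate}/1000$ — at most one spike per tick, the discrete-time
  Poisson process the balanced-excitation protocol assumes;
* `paired_pulse_protocol()`: per adaptor one pre spike at a frozen random
  tick in `[1, 15]` and one post spike at tick 16 of every 32-tick period —
  the polychronization drill;
* `lif_neuron()`: a discrete-time leaky integrate-and-fire stub with
  instantaneous PSC pulses; post-synaptic currents sum linearly (the summed
  weights of the tick's weighted spikes are added to the membrane), and the
  fired flag feeds back as the shared post-synaptic spike *within the same
  tick*.

The stub's defaults (`tau_ms = 60`, threshold `2.8 ×` fan-in, reset 0) were
set once by solving the LIF charging equation so that 1024 inputs at 10 Hz
with mid-range weights produce a post rate in the tens of Hz, roughly
doubling-plus at 20 Hz, and — importantly — keeping the post-spike interval
longer than the 16 ms plasticity window in both regimes. The stub has no
refractory period, no conductances and no ion channels; the
balanced-excitation results are therefore *property-level* (bimodality, the
direction of the rate effect), not histogram-exact reproductions, and say
nothing about networks whose neurons integrate on very different
timescales.

What the generators deliberately do **not** emulate: correlated or bursty
input statistics, axonal routing latencies (order hundreds of µs, which the
architecture tolerates but the experiments do not exercise), electrical
pulse-width encoding of weights (emitted spikes carry the weight as an
integer field), and real device-mismatch distributions.

## Experiments

* `run_balanced_excitation()` wires n Poisson sources → n STDP adaptors →
  one LIF stub, initial weights uniform on `{0..15}` ("uniform positive"
  read as including 0; `[1, 15]` would only shift the first histogram bin).
  The same-tick feedback is implemented by peeking the tick's emission drive
  (the cached weights of the spiking slots) before stepping the engine —
  identical to the engine's own emissions while all slots stay assigned,
  which holds in this protocol. Runs include the from-zero transient; no
  warm-up is discarded.
* `run_da_validation()` reuses 128 slots for 16 sequential runs with DA
  prefixes 0x0000, 0x0200, …, 0x1E00, reading weights back after each run;
  Master-RAM snapshots after each run let the tests verify that later runs
  leave earlier prefixes untouched.
* `run_polychronization()` runs the paired-pulse protocol through an STDDP
  array (delays start at 0) and reports per-period coincidence counts and
  final delay errors. Because each period applies at most one ±1 step, an
  adaptor whose desired delay is D reaches coincidence in exactly
  |D − d₀| periods — the tests check this exhaustively over all 256
  (initial, desired) pairs.
* `capacity_report()` is the architecture's scaling arithmetic (TM count =
  update period / clock period, etc.), kept as a tiny calculator.

```{r example}
p <- run_polychronization(n_adaptors = 32, seed = 1)
p$coincident
```

## Numerical and corner-case decisions

* **Simultaneous pre+post on one slot**: no modification (specified); the
  window is restarted with pre polarity — the restart choice is this
  package's, as only the no-adaptation part is fixed by the architecture.
* **STDDP pre during an active window**: restarts it with the current delay
  (`stddp_pre_restart = TRUE`, configurable); the hardware behavior is not
  documented for this corner.
* **STDDP same-tick pre+post**: the post observes the window as it was
  before the pre's restart (observation precedes starts), while the
  restarted window uses the post-modified delay (modifications precede
  starts). The paired-pulse protocol never exercises this corner.
* **Emitted weight**: a pre spike emits the post-assignment,
  pre-modification cached weight, matching a read-then-modify pipeline.
* **Posts on never-assigned slots** can start windows but commit nothing
  (there is no resident synapse to write through for).
* **Degenerate inputs**: zero-rate Poisson input leaves weights bit-for-bit
  untouched; empty traces produce empty emission tables; unsorted traces and
  out-of-range addresses/weights are rejected with errors.

## Verification strategy and problem sizes

The unit suite checks every operation against hand-derived values, and the
engine against an *independent straight-line oracle*: a per-adaptor replay
of the event sequence with no multiplexing, cache, or LFSR, compared
bit-for-bit on collision-free traces (110 random traces across both modes
and both STDP rules). Property tests cover the split/compose address
bijection, alignment conservation and idempotence, LFSR maximality by full
enumeration, threshold uniformity, window falling-edge timing by induction,
and determinism of complete runs.

The experiment-level checks run at the published desk scale — 1024 adaptors
for 1.25 s (balanced excitation, ten matched seed pairs), 128 slots × 16
runs (dynamic assignment), 128 adaptors × 16 periods (polychronization) —
sizes chosen because they are the protocols' own operating points and
complete in about a minute in total.

## Limitations

* Clock-cycle-accurate pipeline behavior (stall-free scheduling, FIFO depth,
  DDR3 flow control) is out of scope; only its functional consequences are
  modeled.
* The analog backend is a *parameterized* mismatch model, not a circuit
  simulation; its accuracy numbers depend entirely on `mismatch_sigma`, so
  only the limits (σ = 0 equals digital; coincidence degrades as σ grows)
  are meaningful.
* The neuron stub is intentionally minimal; absolute post rates and
  histogram shapes in the balanced-excitation experiment depend on it.
* One mode per array instance: mixing STDP and STDDP synapses requires two
  arrays, as in the hardware.
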