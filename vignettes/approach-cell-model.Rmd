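---
title: "The approach sensitivity cell model: methods and design notes"
author: "acsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The approach sensitivity cell model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acsim)
```

## The cell and the problem it solves

The retina detects approaching objects before the visual cortex ever sees
them: a dedicated retinal ganglion cell type, the approach sensitivity cell
(AC), fires when the image of an object expands (looms) and stays silent
when it contracts or translates. `acsim` simulates this cell directly on
the event stream of a Dynamic Vision Sensor (DVS), a camera whose pixels
independently emit an OFF event when their log intensity falls by more than
a comparator threshold since the last memorized value, and an ON event when
it rises. Because an expanding dark object darkens pixels all along its
growing contour, looming shows up as an excess of OFF events that no other
motion type produces.

The model is a two-layer nonlinear pooling circuit:

1. The sensor plane is partitioned into an $n \times n$ grid of
   **subunits**, each owning an $m \times m$ block of pixels
   ($n \cdot m = 128$ for the DVS128 profile; 8 subunits of 16 px by
   default). Each subunit keeps two potentials, $V_{on}$ and $V_{off}$,
   incremented by `synaptic_weight` for each ON/OFF event landing in its
   receptive field.
2. Subunit potentials are **half rectified** ($\max(0, v)$) before
   pooling. This is the crucial nonlinearity: a few strongly driven OFF
   subunits on the looming contour cannot be cancelled by weak inhibition
   spread over the rest of the field.
3. The net synaptic current is the weighted difference of total OFF
   (excitatory) and ON (inhibitory) drive,
   $I_{net} = G_{off}\sum V_{off}^{\mathrm{eff}} - G_{on}\sum V_{on}$.
4. The membrane integrates $\Delta V_{mem} = I_{net}\,\Delta T$, clamped at
   zero from below, and fires either when it strictly exceeds a fixed
   threshold (IF mode) or when it exceeds a uniform random draw on
   $[0, \theta]$ (Poisson mode).

### Center–surround suppression

Uniform global dimming (a light switched off) raises *every* OFF potential
and would make a naive pooling cell fire. The surround scheme subtracts
from each subunit's rectified OFF potential the mean of its existing
von Neumann neighbors' rectified potentials, and rectifies again:

$$V_{\mathrm{center\to AC}} = \max\!\Big(0,\; V_{center} -
  \tfrac{1}{n_{nb}}\sum V_{surround}\Big),$$

with $n_{nb} \in \{0, 2, 3, 4\}$ for a singleton grid, corner, edge and
interior subunit respectively. A spatially uniform field therefore
contributes exactly zero, while a looming annulus — which concentrates OFF
drive in a ring of subunits — survives subtraction.

### Why lateral motion is silent

A rigid translating object darkens pixels on its leading edge and
brightens the same number on its trailing edge, so OFF and ON inflow are
equal at every frame. With `g_on = g_off` the totals track each other
exactly (both decay by the same shared factor), so $I_{net} \le 0$ at all
times and the membrane never leaves zero. The package asserts this both as
an algebraic cancellation property and end-to-end on synthetic streams.

## Event-driven processing order

Events are processed one at a time in the order of the hardware state
machine: subunit decay (timestamp-driven), subunit update, per-subunit
input computation, net current, membrane update, threshold comparison.
Two engines implement these semantics — a compiled loop (default) and a
pure-R composition of the exported per-operation functions — and the test
suite keeps them in lock-step, additionally checking both against a
closed-form dense recomputation of the entire subunit state at every event.

## Parameters, units, defaults

| parameter | default | meaning |
|---|---|---|
| `n_side`, `rf_side` | 8, 16 | subunit grid and receptive-field side (product = sensor side) |
| `g_off`, `g_on` | 1, 1 | excitatory/inhibitory pooling weights |
| `synaptic_weight` | 1 | potential increment per event |
| `if_threshold` | 1500 | firing threshold (potential units) |
| `firing_mode` | `"IF"` | deterministic threshold vs. Poisson draw |
| `max_firing_rate` | 60 Hz | absolute refractory interval 1/rate ≈ 16.7 ms |
| `decay_period_us` | 20 000 | period of the shared multiplicative decay |
| `decay_factor` | 0.6 | per-period decay multiplier |
| `dt_max_us` | = decay period | saturation of the inter-event interval |

Three numerical choices deserve comment.

**Time unit.** $\Delta T$ in the membrane update is the interval since the
previously processed *input* event (the cell updates once per incoming
event, as the hardware does), expressed in milliseconds so that O(1)
weights and thresholds in the low thousands are natural scales. The first
event of a stream integrates over $\Delta T = 0$, and the decay clock
starts at the first event's timestamp.

**Interval saturation.** A free-running inter-event counter in hardware has
finite width; we model this by saturating $\Delta T$ at `dt_max_us`
(default: one decay period). Without saturation the first event after a
long silent gap would integrate an arbitrarily large interval against
whatever stale current the previous phase left behind, producing spikes
that reflect the gap length rather than the stimulus.

**Refractory behavior.** `max_firing_rate` is an absolute refractory
interval during which the membrane is *held at its reset value*, the usual
integrate-and-fire convention. The alternative — suppressing the spike
while integration continues — lets the membrane run far past threshold
during strong looming drive, and the stale residue then fires on the first
event of the next phase, destroying the approach/recede selectivity the
cell exists to produce. At the default 60 Hz bound the refractory interval
is 16.7 ms, which also sets the minimum possible inter-spike interval of
the simulated cell.

Like the registers of the hardware implementation they mirror, all of
these are runtime parameters, and the defaults were calibrated once for
the canonical synthetic looming scene described next; a different scene
(different event rates, speeds, contrasts) will generally need a different
threshold/decay pair. The firing rate rises with `g_off` and falls with
`if_threshold`, monotonically over the tested ranges, which is the
practical tuning recipe.

## The synthetic stimulus generator

Real recordings of looming objects are not shipped with the package;
instead the generator renders hard-edged two-level scenes (disc or square,
dark-on-light by default) along piecewise-linear center/radius
trajectories, and converts them to events with an explicit DVS pixel
model: each pixel memorizes a log intensity and emits
$\lfloor |\Delta \log I| / \theta \rfloor$ events per frame step, moving
its memory by that integer number of threshold steps (large changes burst,
as in the sensor). Events within a frame share the frame timestamp and are
ordered by $(y, x, \text{polarity})$; optional seeded uniform jitter can
break the frame alignment when order sensitivity is being probed.

The canonical conditions are: a dark disc (50 % of background intensity,
i.e. a log contrast of 0.69 against a comparator threshold of 0.35)
centered on a 128 × 128 sensor, expanding from 6 px to 48 px radius over
400 ms in 10 ms frame steps — roughly a hand-held object brought toward
the camera at arm speed — and the mirrored contraction for recession. The
lateral archetype translates a 12 px disc at 2 px/frame; integer
displacement per frame keeps the ON/OFF symmetry exact, which the tests
exploit. The approach/recede compound inserts a 100 ms silent gap after
each phase (real recordings pause between passes) giving a 1 s iteration
period; the determinism analysis tiles it 20 times.

What the generator deliberately does **not** emulate: optics blur,
per-pixel threshold mismatch, background leak/shot noise (the background
filter is instead tested against explicitly injected noise), and the
hardware arbiter's event ordering. Passing tests on these streams
therefore demonstrate the circuit's selectivity mechanism, not robustness
to every artifact of a physical sensor.

## Denoising filters

Two standard pre-filters precede the cell when configured. The
background-activity filter keeps an event only if its pixel or one of its
8 neighbors was active within the preceding `dt_us` (causal,
polarity-agnostic; dropped events still refresh the timestamp map — the
common hardware variant, and the one the brute-force oracle implements).
The hot-pixel filter drops a pixel's events while its raw count in the
trailing window exceeds a limit. Both produce subsequences of their input:
no reordering, no retiming.

## The determinism (entropy) analysis

For a stimulus that repeats every `iteration_period_us`, output spikes are
classified per iteration $i$ into approach-window and recede-window counts
($AC_e = AC_{e,ap} + AC_{e,re}$), normalized to
$p_i = AC_{e,ap}(i) / \sum_i AC_{e,ap}(i)$, and summarized by the Shannon
entropy $H = -\sum p_i \log p_i$ in nats. A perfectly repeatable cell
yields the uniform distribution and $H = \log n$ (2.9957 for $n = 20$,
conventionally printed as 2.99); initial-state carryover between
iterations and decay-phase interactions push $H$ below that bound. Window
boundaries are supplied explicitly (the package sets the approach window
to the phase boundary recorded by the stimulus metadata) rather than
inferred from the spike train. Entropy values measured on a particular
physical recording depend on that recording and the chosen registers, so
the package reproduces the *procedure* and the bound, not any specific
published value; the same holds for inter-spike-interval statistics, whose
lower end is pinned by the refractory interval.

## Degenerate inputs and tie-breaks

Empty streams are legal everywhere (a run returns zero spikes and
untouched state; plots render blank axes). Events sharing a timestamp
integrate over $\Delta T = 0$, so only the first event of a burst moves
the membrane; threshold crossing is strict, so a membrane exactly at
threshold does not fire; a 1 × 1 subunit grid has no surround and passes
its center through. Streams with decreasing timestamps are rejected, never
reordered.

## Problem sizes used by the test suite

The shipped tests run the full acceptance battery in well under a minute:
exhaustive address-space checks (32 768 combinations), dense-oracle
equivalence on 5 000-event random streams, filter oracles at a few
thousand events, and the 20-repetition looming protocol (≈ 285 000
events) through the compiled engine. These sizes were chosen as the
smallest that exercise every code path and boundary; the engine itself
processes millions of events per second, so larger recordings are limited
by memory, not time.

## Known limitations

* One cell per run: multiple ACs tiling different visual fields (the
  hardware's "mother cell" container) are out of scope, though nothing in
  the stream model prevents running several `ac_run()` calls over cropped
  streams.
* The simulator is floating-point; it does not reproduce the fixed-point
  rounding of an FPGA implementation bit for bit.
* AEDAT support covers the 2.0 text-header dialect with 32-bit big-endian
  words only, which is sufficient for DVS128 interchange.
* The membrane has no leak between events; with extremely sparse input the
  interval saturation bound (`dt_max_us`) is what keeps stale currents
  from dominating, and very low-rate scenes may warrant a smaller bound.
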