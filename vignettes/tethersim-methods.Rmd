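---
title: "tethersim: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tethersim: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tethersim)
```

# What this package models

Modern freely-moving neuroscience rigs aggregate very different devices —
multichannel amplifiers, absolute-orientation sensors, optical tracking
receivers, stimulators — onto a single thin serialized tether, commutated
by a motor so the animal can turn indefinitely. `tethersim` is a software
model of that architecture plus the behavioral statistics used to evaluate
it. Everything runs in simulated time with seeded generators, so every
claim the package makes is checkable against ground truth without
hardware.

The package has six functional layers:

1. **Frame protocol** (`device_map()`, `encode_frame()`, `multiplex()`):
   heterogeneous sources share one ordered channel of timestamped frames.
2. **Block-transfer link** (`link_config()`, `block_latency_samples()`,
   `effective_bandwidth()`, `transfer_schedule()`): the host reads the
   byte stream in fixed-size blocks, trading latency for throughput.
3. **Device simulators** (`generate_ephys_frames()`,
   `generate_orientation_frames()`, `generate_lighthouse_events()`).
4. **Pose tracking** (`triangulate()`, `fuse_pose()`): sweep-timing
   triangulation fused with inertial orientation.
5. **Commutation** (`run_commutator()`): torque-free twist cancellation
   from absolute heading.
6. **Behavior analysis** (`occupancy_histogram()`,
   `shannon_entropy_bits()`, `bootstrap_entropy()`,
   `synthetic_trajectory()`).

# The wire format and clock

A frame is `(device_id, timestamp_ticks, payload)`. The wire layout — a
14-byte little-endian header (4 B id, 8 B timestamp, 2 B payload length)
followed by the payload — is this package's own concrete choice; it was
picked for fixed-offset parsing and easy independent verification, and no
byte-compatibility with any external acquisition standard is claimed. The
2-byte length field caps payloads at 65,535 bytes; larger payloads must be
chunked by their producer.

All devices timestamp against one shared tick counter. Its frequency is
configurable with a default of 30,000 Hz, so that one tick equals one
spike-band sample period; timestamps are carried as doubles, exact below
2^53 ticks (thousands of years at this rate).

`multiplex()` merges per-device streams ordered by timestamp, with ties
broken by ascending device id and then per-device arrival order. The
tie-break is arbitrary but fixed, which makes merged streams byte-stable
across runs.

# The block-transfer latency model

The host does not read continuously: it reads blocks of `B` bytes, each
transfer paying a fixed overhead. Two closed forms capture the trade-off:

* latency in sample periods: `B / aggregate_bytes_per_sample` — the wait
  for the **oldest** sample in a block. An 8,192-byte block over an
  8-byte-per-sample device waits 1,024 periods; over 1,920 bytes per
  sample it waits under five. We document the worst-case (oldest sample)
  reading; the newest sample in a block waits essentially one period.
* effective bandwidth: `B / (B / bandwidth + overhead)`, monotone in `B`
  and asymptoting to the link ceiling.

`transfer_schedule()` realizes the same model in simulated time as a byte
FIFO: block *b* spans stream bytes `((b-1)B, bB]` and fills when
cumulative production reaches `bB`; a frame is delivered when the block
holding its **last** byte is delivered, at fill time plus
`B / bandwidth + overhead`. The byte-FIFO formulation was chosen over
whole-frame packing deliberately: under whole-frame packing, halving the
block size can *increase* a frame's delivery latency for unlucky frame
size sequences (block boundaries shift across a frame), while in the FIFO
model `ceiling(x / B) * B` is monotone under halving, so smaller blocks
are never slower at zero overhead — the behavior the latency/throughput
trade-off story requires. A frame larger than one block is rejected, which
keeps the whole-frame delivery semantics well defined.

One convention matters for latency accounting: a sample timestamped at
tick `k` covers the conversion interval `[k, k+1)` and its frame is
produced at `(k+1)/clock_hz`. The event the loop reacts to happens at
`k/clock_hz`, so even a one-frame block contributes exactly one sample
period of irreducible latency — the limiting case the closed-loop tests
pin.

Partial trailing blocks are undelivered by default (`NA` delivery); a
flush timeout can be enabled explicitly. Flushing policies are not part of
the modeled contract, so the default leaves them out of every latency
statistic rather than inventing numbers.

# Closed-loop harness

`run_loop()` chains: threshold detection on one channel of a simulated
ephys stream → block delivery through `transfer_schedule()` → a
configurable host processing delay → an upstream command frame through its
own link leg (block = one command frame, mirroring a low-bandwidth control
back-channel). Per-event latency is the sum of these nonnegative terms,
and the summary reports the median and the 99.9th percentile by
**nearest rank**, i.e. the smallest sample at rank `ceiling(0.999 n)` —
the natural reading of a "99.9% worst case". No wall-clock hardware
latency figure is claimed or reproduced; the harness reproduces the
*accounting*, and its testable content is structural: additivity of the
decomposition and monotonicity of worst-case latency in block size at zero
overhead.

The spike detector is deliberately minimal (threshold crossing with
refractory suppression). It stands in for "acting on a neural voltage
reading"; it is not a spike sorter and the simulator's template shape is
not part of its contract.

# Pose tracking

Tracking stations are ideal spinning-plane emitters: a sweep angle is
`2 * pi * offset / period` from the pulse offset within a rotation, one
azimuth and one elevation plane per station, one sync reference per
rotation. Station orientation maps angles to world rays (boresight = local
+y, azimuth about local vertical, elevation about local horizontal).

`triangulate()` intersects rays by least squares: for two stations this is
the midpoint of the common perpendicular segment, with the miss distance
as the residual; for more stations the least-squares point with the RMS
ray distance. The closed-form two-ray midpoint was chosen over nonlinear
refinement because at the jitter levels of interest the problem is locally
linear; the function is a documented extension point. Rays within 0.5° of
parallel are rejected as ill-conditioned rather than returning a huge
unstable estimate.

`fuse_pose()` resamples optical position (linear) and inertial orientation
(spherical interpolation) onto a uniform grid covering the overlap of the
two input ranges, default 100 Hz. Grid points farther than `max_gap_s`
(default 0.2 s) from every optical sample are flagged `imu_only` and hold
the last optical fix — a deliberate, conservative dropout policy: it never
invents positions, and downstream consumers can filter on the flag. Yaw,
pitch and roll always come from the inertial stream, because the absolute
orientation sensor is the instrument that drives the commutator.

Euler convention, fixed throughout: intrinsic yaw–pitch–roll (Z–Y′–X″),
yaw in [−180°, 180°) for control, pitch in [−90°, 90°]; world frame
right-handed, z up, origin at the arena center. Heading *histograms* use
yaw in [0°, 360°); `yaw_to_360()` / `yaw_to_180()` convert explicitly.

# Torque-free commutation

The commutator never sees torque. It integrates the wrapped absolute
heading by shortest-path unwrapping (valid whenever the animal turns less
than half a revolution between samples; deltas near ±180° log a warning as
a violated-assumption detector), tracks
`residual_twist_turns = (unwrapped_heading − motor_angle) / 360` as an
exact bookkeeping identity, and commands the motor when |residual| reaches
a threshold. Commands are quantized to the stepper step and subject to a
slew limit; after a command the policy disarms until the residual falls
below threshold again (hysteresis), which prevents chatter at the
threshold boundary.

Defaults — 0.25-turn threshold, 1.8° step — are engineering choices for a
typical stepper, not published constants. The property that matters, and
that the acceptance suite verifies over 10^5-step random rotation scripts,
is boundedness: residual twist never exceeds threshold + one step, for
arbitrarily long recordings. That is the software analogue of a tether
that never tangles regardless of session length.

# Behavior analysis

The pipeline quantifies how freely an animal explores:

* `compute_speed()`: centered-difference 3D speed, boxcar-smoothed over
  0.25 s (edges truncate the window rather than shrinking the series).
* `occupancy_histogram()`: 20 × 20 bins over the arena bounding box
  ([−0.8, 0.8] m² for the 1.6 m hexagon). Samples slower than the
  stationary threshold are excluded *first*; then the histogram is built;
  then, optionally, the single highest-count bin is excluded as the home
  position; normalization happens last. This order is fixed and
  test-pinned because the home bin is defined by the argmax *after* the
  stationary filter.
* `heading_histogram()`: 40 × 40 bins over yaw 0–360° × pitch ±45°,
  linear binning (the two yaw end bins are distinct, not circularly
  merged); out-of-range pitch is clipped into the end bins and counted.
* `shannon_entropy_bits()`: `−Σ p log₂ p` over included bins; the
  normalized variant divides by `log₂(included bin count)`. **Both are
  always available** because the two scales are easy to conflate when
  comparing conditions; reporting both removes the ambiguity.
* `bootstrap_entropy()`: block bootstrap over contiguous 60-s time bins
  (truncated final bin dropped), resampling bins with replacement and
  rebuilding the histogram — including re-applying the exclusions — per
  replicate; 1,000 replicates by default, 2.5/97.5 percentile bounds.
  Time-bin resampling respects the strong autocorrelation of position
  data, which an i.i.d. sample bootstrap would ignore (and thereby
  understate the CI width).

Choices the underlying literature leaves open, fixed here: the stationary
threshold is 2 cm/s on the 0.25-s-smoothed speed; "~1 min" bins are
exactly 60 s; the home position is identified by argmax rather than by
coordinates. Long-recording auxiliaries: `band_power()` computes zero-phase
band power (6–10 and 30–50 Hz defaults) via an FFT brick-wall mask —
chosen because no IIR filter-design dependency is required and zero-phase
behavior is exact — and `activity_level()` is the 1-Hz block-mean of the
acceleration-vector norm.

# The synthetic trajectory generator

`synthetic_trajectory()` is the test fixture for the whole behavioral
pipeline. It emulates the *structure* of real head-tracking data — 100 Hz
3D position plus yaw/pitch, a 1.6 m hexagonal arena with a variable-height
tiled floor, a home position with elevated dwell, stationary periods, and
mobility differences between tether conditions — via alternating episodes:

* **dwell**: exactly stationary at home (exponential durations, mean
  20 s), entered by walking home at twice the median speed (never by
  teleporting);
* **explore**: a correlated random walk — log-AR(1) speed around the
  preset median with a 2-s decorrelation time, clipped at the preset
  maximum; heading diffusing at the preset rate; a 30-s mean reversion
  keeping the path in the arena, with hexagon clamping as a hard
  constraint. z follows the tile height field smoothed over 0.5 s (a
  mouse climbs a tile edge in about that time); pitch follows the slope,
  clipped to ±45°.

The two presets state the modeled world: `"free"` (median 0.10 m/s, max
0.8 m/s, 15% home dwell, heading diffusion 1.5 rad/√s) and `"restricted"`
(0.05 m/s, 0.4 m/s, 50% dwell, 4.0 rad/√s) — a ~2× speed contrast with
slower, more tortuous, more home-bound movement under the heavy-tether
condition. These values were chosen once as a plausible rendering of the
reported ~2× median-speed contrast and were not tuned against test
outcomes.

What a green test does and does not establish: the generator produces the
right *kinds* of structure (autocorrelated paths, dwell, bounded arena,
speed-dependent coverage), so it can validate the analysis pipeline's
bookkeeping, exclusion order, and discrimination power. It does not
reproduce real mouse kinematics, thigmotaxis, rearing, or sleep structure,
and the absolute entropy values it yields are properties of the synthetic
world — real-animal entropy values are never asserted anywhere in the
package.

# Numerical and degenerate-input policy

* Entropy of an all-zero (or fully excluded) grid is an error, not 0 —
  silence would hide an upstream filtering bug.
* An all-stationary trajectory yields an occupancy grid flagged `empty`.
* `0 log 0 := 0` in entropy sums; probabilities come from counts, so no
  renormalization drift.
* Triangulation rejects near-parallel rays (< 0.5°) and rank-deficient
  geometry via a reciprocal-condition check.
* Bootstrap and generators consume explicit integer seeds; identical
  inputs and seeds give bit-identical output.
* The coverage acceptance test uses an i.i.d. categorical stationary
  model with a *non-uniform* cell distribution: at the uniform
  distribution the plug-in entropy estimator sits on its upper boundary
  (every estimate is below the true value), where percentile CIs cannot
  cover and no estimator-agnostic test is meaningful.

# Configuration and formats

Run configuration is YAML (`load_config()`), one dialect only; YAML was
chosen over TOML because a maintained YAML parser is available in the
target environment and the config schema needs nothing TOML-specific.
Unknown keys are rejected by name. Formats: device maps as JSON; streams
as a 4-byte `"ONIS"` magic plus flat concatenated frames with a JSON
sidecar map; poses as CSV; ephys exports as flat interleaved little-endian
int16 with a JSON sidecar. Every CLI run writes a manifest (package and R
versions, seed, normalized config and its MD5, input digests).

# Known limitations

* The wire format is self-defined; no interoperability with external
  acquisition software is claimed.
* The lighthouse model is ideal (no base-station data encoding, no
  occlusion geometry beyond configured windows, no photodiode physics);
  jitter enters only as Gaussian pulse-time noise.
* The closed-loop harness models no operating-system scheduling; its
  millisecond-scale outputs are simulated-time accounting, not predictions
  of any hardware's wall-clock latency.
* The trajectory generator is a statistical emulation, not a behavioral
  model; conclusions about real animals require real data through the
  same pipeline (`read_pose_csv()` accepts external pose tables after
  column mapping).
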