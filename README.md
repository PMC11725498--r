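# tethersim

Simulation and analysis toolkit for single-tether neural acquisition and
freely-moving behavior.

Freely-moving electrophysiology pulls in opposite directions: large-scale
recording wants bandwidth and many devices, natural behavior wants a tether
so light and torque-free the animal forgets it is there. Rigs that resolve
this multiplex heterogeneous devices (amplifiers, inertial orientation
sensors, optical tracking receivers, stimulators) over one thin serialized
cable, read it in tunable blocks on the host, rotate the tether with a
motorized commutator driven purely by measured heading, and quantify the
behavioral payoff with occupancy-entropy statistics.

`tethersim` implements that whole architecture as a deterministic,
seed-driven software model, for engineers reasoning about
latency/throughput trade-offs and closed-loop budgets, and for
behavioral analysts who need the entropy/bootstrap pipeline with ground
truth to validate against. No hardware, no external data: every module is
paired with a simulator that knows the right answer.

## The core quantities

* **Block-fill latency** (sample periods) for a read block of `B` bytes
  over devices producing `a` bytes per sample period: `L = B / a`
  (worst case, oldest sample in the block).
* **Effective bandwidth** under per-transfer overhead `t₀` on a link with
  ceiling `W`: `W_eff(B) = B / (B/W + t₀)` — monotone in `B`, asymptote
  `W`.
* **Channel capacity**: `floor(W / (f_s · bytes_per_sample))` — a
  150 MB/s link carries 2,500 channels of 30 kHz × 2-byte spike-band
  data.
* **Closed-loop latency** per detected event, in simulated time:
  `Δ = (t_deliver − t_event) + t_process + t_uplink`, summarized by median
  and nearest-rank 99.9th percentile.
* **Residual tether twist** (turns):
  `r = (unwrapped_heading − motor_angle)/360`, held within
  `threshold + one motor step` by the commutation policy, indefinitely.
* **Occupancy/heading entropy**: `H = −Σ p log₂ p` over a 20 × 20 spatial
  grid (stationary samples excluded, home bin optionally excluded) or a
  40 × 40 yaw × pitch grid; optionally normalized by `log₂(bins)`; CIs by
  block bootstrap over 60-s time bins.

## Worked example

```r
library(tethersim)

## link arithmetic
block_latency_samples(8192, 8)        # 1024 sample periods
block_latency_samples(8192, 1920)     # 4.27 — four large probes: < 5
channel_capacity(150e6, 30000, 2)     # 2500 spike-band channels
effective_bandwidth(link_config(150e6, 8192, 1e-5))  # 126,784,977 B/s

## closed loop on a simulated 16-channel stream, 1 KiB blocks
ecfg <- ephys_sim_config(n_channels = 16, spike_rate_hz = 10, seed = 42)
loop <- run_loop(ecfg, loop_config(threshold_counts = -800,
                                   link = link_config(150e6, 1024, 0)), 2)
loop$summary
#> $n_events  16
#> $median_s  0.00039      # simulated-time accounting, not hardware
#> $p999_s    0.000574

## torque-free commutation through 15 full turns
o <- generate_orientation_frames(orientation_script(
  data.frame(duration_s = 60, yaw_rate_deg_per_s = 90,
             pitch_deg = 0, roll_deg = 0)))
log <- run_commutator(o$yaw_deg, o$time_s)
max(abs(log$residual_turns))          # 0.248 — never exceeds 0.25 + step
tail(log$motor_angle_deg, 1)          # 5310 degrees commanded in total

## behavioral contrast between tether conditions (synthetic, 30 min)
for (m in c("free", "restricted")) {
  tr <- synthetic_trajectory(mobility = mobility_preset(m),
                             duration_s = 1800, seed = 42)
  sp <- compute_speed(tr)
  b  <- bootstrap_entropy(tr, "occupancy", n_boot = 200, seed = 42)
  cat(sprintf("%-10s speed %.3f m/s | entropy %.2f [%.2f, %.2f] bits\n",
              m, median(sp[sp >= 0.02]),
              b$raw$median, b$raw$ci_low, b$raw$ci_high))
}
#> free       speed 0.091 m/s | entropy 7.58 [7.35, 7.75] bits
#> restricted speed 0.058 m/s | entropy 4.51 [4.10, 4.71] bits
```

The free condition moves ~2× faster and covers the arena far more evenly;
the bootstrap CIs do not overlap. These numbers describe the synthetic
world the generator states (see the methods vignette) — they are pipeline
validation, not real-animal results.

## Command line

A thin CLI wraps the same functions
(`inst/cli/tethersim.R`, installed under `system.file("cli", package =
"tethersim")`):

```sh
Rscript inst/cli/tethersim.R simulate       --out-dir session/
Rscript inst/cli/tethersim.R benchmark-link --out sweep.csv
Rscript inst/cli/tethersim.R closed-loop    --out-prefix loop
Rscript inst/cli/tethersim.R track          --pose truth.csv --out fused.csv
Rscript inst/cli/tethersim.R commutate      --pose fused.csv --out cmd.csv
Rscript inst/cli/tethersim.R behavior       --pose fused.csv --out report.json
```

Each subcommand accepts `--config config.yaml` (see `load_config()`) plus
overriding flags, logs to stderr, and writes a reproducibility manifest.

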