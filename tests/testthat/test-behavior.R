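make_traj <- function(x, y, z = 0, dt = 0.01, yaw = 0, pitch = 0) {
  n <- max(length(x), length(y), length(z), length(yaw), length(pitch))
  data.frame(time_s = (seq_len(n) - 1) * dt,
             x_m = rep_len(x, n), y_m = rep_len(y, n), z_m = rep_len(z, n),
             yaw_deg = rep_len(yaw, n), pitch_deg = rep_len(pitch, n))
}

test_that("compute_speed: stationary, straight line, and circle closed form", {
  tr0 <- make_traj(0.1, 0.2, 0.05, yaw = 0)
  tr0 <- tr0[rep(1, 200), ]; tr0$time_s <- (0:199) * 0.01
  expect_true(all(compute_speed(tr0) == 0))
  # 1 m over 10 s: 0.1 m/s in the interior
  n <- 1001
  trl <- make_traj(seq(0, 1, length.out = n), 0, 0)
  sp <- compute_speed(trl)
  expect_near(sp[100:900], rep(0.1, 801), tol = 1e-9)
  # circle radius r, period T: |v| = 2*pi*r/T
  r <- 0.4; T <- 8
  th <- 2 * pi * (0:(8 * 100 - 1)) / (100 * T)
  trc <- make_traj(r * cos(th), r * sin(th), 0)
  spc <- compute_speed(trc)
  expect_lt(max(abs(spc[50:750] - 2 * pi * r / T)), 1e-3)
  expect_error(compute_speed(trl[1:2, ]),
               class = "tethersim_insufficient_data")
})

test_that("occupancy histogram: binning, stationary filter, home exclusion", {
  # fast movement confined to one tile -> a single nonzero bin
  set.seed(3)
  tr <- make_traj(0.41 + cumsum(rnorm(500, 0, 0.004)) * 0 + 0.01 * sin(1:500),
                  0.41 + 0.01 * cos(1:500), 0)
  g <- occupancy_histogram(tr, stationary_speed_threshold = 0.02)
  expect_identical(sum(g$counts > 0), 1L)
  expect_identical(g$excluded_bins, which.max(g$counts))
  # all-stationary trajectory -> empty flag
  g0 <- occupancy_histogram(make_traj(rep(0.1, 300), 0.1, 0))
  expect_true(attr(g0, "empty"))
  expect_error(shannon_entropy_bits(g0),
               class = "tethersim_undefined_entropy")
  # uniform sweep over the full extent: chi-square sanity vs multinomial
  set.seed(8)
  nn <- 40000
  tru <- make_traj(runif(nn, -0.8, 0.8), runif(nn, -0.8, 0.8), 0)
  gu <- occupancy_histogram(tru, stationary_speed_threshold = 0,
                            exclude_home = FALSE)
  expect_equal(sum(gu$counts), nn)
  expected <- nn / 400
  chi2 <- sum((gu$counts - expected)^2 / expected)
  # df = 399; 99.9% quantile as the independent multinomial oracle bound
  expect_lt(chi2, qchisq(0.999, 399))
})

test_that("heading histogram: single bin, end bins distinct, uniform rows, clipping", {
  trc <- make_traj(0, 0, 0, yaw = 123.4, pitch = 10)
  trc <- trc[rep(1, 100), ]; trc$time_s <- (0:99) * 0.01
  g <- heading_histogram(trc)
  expect_identical(sum(g$counts > 0), 1L)
  # yaw 359.9 and 0.1 land in distinct end bins (no circular merge)
  tr2 <- make_traj(0, 0, 0, yaw = c(0.1, 359.9), pitch = 0)
  g2 <- heading_histogram(tr2)
  nz <- which(g2$counts > 0, arr.ind = TRUE)
  expect_identical(sort(unname(nz[, 1])), c(1L, 40L))
  # uniform yaw sweep at fixed pitch: one row, near-uniform
  yy <- seq(0, 360 - 1e-6, length.out = 4000)
  tr3 <- make_traj(0, 0, 0, yaw = yy, pitch = 0)
  g3 <- heading_histogram(tr3)
  row_tot <- rowSums(g3$counts > 0)
  expect_identical(sum(colSums(g3$counts) > 0), 1L)   # one pitch column
  expect_true(all(g3$counts[g3$counts > 0] == 100))
  # pitch outside +/-45 clipped into end bins and logged
  tr4 <- make_traj(0, 0, 0, yaw = 10, pitch = c(60, -80, 0))
  g4 <- heading_histogram(tr4)
  expect_identical(g4$clipped, 2L)
  expect_identical(sum(g4$counts), 3L)
})

test_that("entropy closed forms and bounds", {
  one <- matrix(0L, 20, 20); one[5, 5] <- 100L
  expect_identical(shannon_entropy_bits(one), 0)
  unif <- matrix(7L, 20, 20)
  expect_equal(shannon_entropy_bits(unif), log2(400))
  expect_equal(shannon_entropy_bits(unif, normalized = TRUE), 1)
  # two bins (0.25, 0.75): direct evaluation of -sum p log2 p
  two <- matrix(c(25L, 75L), 1, 2)
  expect_equal(shannon_entropy_bits(two),
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)))
  expect_equal(round(shannon_entropy_bits(two), 4), 0.8113)
  # bounds as a property over random grids
  set.seed(12)
  for (i in 1:20) {
    cc <- matrix(rpois(100, 3), 10, 10)
    if (sum(cc) == 0) next
    h <- shannon_entropy_bits(cc)
    expect_gte(h, 0)
    expect_lte(h, log2(100) + 1e-12)
    hn <- shannon_entropy_bits(cc, normalized = TRUE)
    expect_true(hn >= 0 && hn <= 1 + 1e-12)
  }
  expect_error(shannon_entropy_bits(matrix(0L, 2, 2)),
               class = "tethersim_undefined_entropy")
})

test_that("bootstrap entropy: degenerate CI, median containment, reproducibility", {
  # degenerate single-bin occupancy -> CI exactly [0, 0]
  set.seed(4)
  tr1 <- make_traj(0.41 + 0.01 * sin(1:13000), 0.41 + 0.01 * cos(1:13000), 0)
  b1 <- bootstrap_entropy(tr1, "occupancy", exclude_home = FALSE,
                          n_boot = 50, seed = 2)
  expect_identical(c(b1$raw$ci_low, b1$raw$ci_high), c(0, 0))
  # CI contains the replicate median; identical seeds reproduce exactly
  tr2 <- synthetic_trajectory(duration_s = 300, seed = 5)
  b2 <- bootstrap_entropy(tr2, "occupancy", n_boot = 100, seed = 9)
  expect_gte(b2$raw$median, b2$raw$ci_low)
  expect_lte(b2$raw$median, b2$raw$ci_high)
  b3 <- bootstrap_entropy(tr2, "occupancy", n_boot = 100, seed = 9)
  expect_identical(b2$replicates, b3$replicates)
  b4 <- bootstrap_entropy(tr2, "occupancy", n_boot = 100, seed = 10)
  expect_false(identical(b2$replicates$raw, b4$replicates$raw))
  # heading flavor runs and respects bounds
  b5 <- bootstrap_entropy(tr2, "heading", n_boot = 50, seed = 1)
  expect_true(b5$normalized$median >= 0 && b5$normalized$median <= 1)
  expect_error(bootstrap_entropy(tr2[1:500, ], "occupancy"),
               class = "tethersim_insufficient_data")
})

test_that("band power: tone concentration, flat-spectrum proportionality, zeros", {
  fs <- 500
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  tone <- sin(2 * pi * 8 * t)
  bp <- band_power(tone, fs)
  m <- tapply(bp$power, bp$band, mean)
  expect_gt(m[["6-10 Hz"]] / m[["30-50 Hz"]], 100)
  # white noise: power proportional to bandwidth (20 Hz vs 4 Hz -> ratio 5)
  set.seed(77)
  wn <- rnorm(fs * 240)
  bw <- band_power(wn, fs)
  mw <- tapply(bw$power, bw$band, mean)
  expect_lt(abs(mw[["30-50 Hz"]] / mw[["6-10 Hz"]] - 5), 0.75)
  expect_true(all(band_power(rep(0, fs * 30), fs)$power == 0))
  expect_error(band_power(tone, fs, bands = list(c(6, 300))),
               class = "tethersim_domain")
  expect_error(band_power(tone[1:100], fs),
               class = "tethersim_insufficient_data")
})

test_that("activity level: norms, smoothing to 1 Hz, block boundaries", {
  fs <- 100
  acc <- matrix(rep(c(0, 0, 9.81), each = 10 * fs), ncol = 3)
  a <- activity_level(acc, fs)
  expect_near(a$activity, rep(9.81, 10), tol = 1e-12)
  # alternating +/- a on one axis: mean norm = a
  alt <- cbind(rep(c(2, -2), 5 * fs), 0, 0)
  a2 <- activity_level(alt, fs)
  expect_near(a2$activity, rep(2, 10), tol = 1e-12)
  # rest/active blocks segment at the right boundary
  rest <- matrix(rep(c(0, 0, 9.81), each = 10 * fs), ncol = 3)
  act <- matrix(rep(c(5, 5, 12), each = 10 * fs), ncol = 3)
  a3 <- activity_level(rbind(rest, act), fs)
  thresh <- mean(range(a3$activity))
  expect_identical(which(a3$activity > thresh)[1], 11L)
})

test_that("yaw converters are inverse on their shared domain", {
  y <- c(0, 90, 179.5, 180, 270, 359.9)
  expect_near(yaw_to_360(yaw_to_180(y)), y, tol = 1e-9)
  expect_true(all(yaw_to_180(y) >= -180 & yaw_to_180(y) < 180))
})
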