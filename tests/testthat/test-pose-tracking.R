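test_that("sweep offsets map to angles as stated", {
  p <- 1 / 60
  a <- sweep_to_angles(0, 0, p)
  expect_identical(c(a$azimuth_rad, a$elevation_rad), c(0, 0))
  a4 <- sweep_to_angles(p / 4, p / 8, p)
  expect_equal(a4$azimuth_rad, pi / 2)
  expect_equal(a4$elevation_rad, pi / 4)
  # second half of the period maps to negative angles, range (-pi, pi]
  expect_equal(sweep_to_angles(p * 0.75, 0, p)$azimuth_rad, -pi / 2)
  expect_error(sweep_to_angles(p, 0, p), class = "tethersim_domain")
  expect_error(sweep_to_angles(-1e-9, 0, p), class = "tethersim_domain")
})

test_that("triangulation recovers exact intersections and flags degeneracy", {
  stns <- default_stations()
  target <- c(1, 1, 1)
  # forward model supplies the exact angles; the inverse must recover the
  # point with zero residual
  traj <- data.frame(time_s = 0, x_m = target[1], y_m = target[2],
                     z_m = target[3])
  ev <- generate_lighthouse_events(traj, stns, 0)
  ang <- sweep_to_angles(ev$az_offset_s, ev$el_offset_s,
                         stns[[1]]$sweep_period_s)
  tri <- triangulate(data.frame(station_id = ev$station_id,
                                azimuth_rad = ang$azimuth_rad,
                                elevation_rad = ang$elevation_rad), stns)
  expect_near(tri$position, target, tol = 1e-9)
  expect_lt(tri$residual_m, 1e-9)
  # skew rays with a known common perpendicular: ray 1 along +x through
  # the origin, ray 2 along +y at height h; closest points (0,0,0) and
  # (0,0,h) -> midpoint (0,0,h/2), miss distance h (closed-form oracle)
  h <- 0.01
  q_yaw_m90 <- c(cos(-pi / 4), 0, 0, sin(-pi / 4))  # local +y -> world +x
  s1 <- station_pose(1L, c(-2, 0, 0), q_yaw_m90)
  s2 <- station_pose(2L, c(0, -2, h), c(1, 0, 0, 0))
  tri2 <- triangulate(data.frame(station_id = c(1L, 2L), azimuth_rad = 0,
                                 elevation_rad = 0), list(s1, s2))
  expect_near(tri2$position, c(0, 0, h / 2), tol = 1e-12)
  expect_equal(tri2$residual_m, h, tolerance = 1e-9)
  # degenerate cases
  expect_error(triangulate(data.frame(station_id = 1L, azimuth_rad = 0,
                                      elevation_rad = 0), list(s1)),
               class = "tethersim_insufficient_data")
  sA <- station_pose(1L, c(0, -1, 0), c(1, 0, 0, 0))
  sB <- station_pose(2L, c(0, -2, 0), c(1, 0, 0, 0))
  expect_error(triangulate(data.frame(station_id = c(1L, 2L),
                                      azimuth_rad = c(0, 1e-4),
                                      elevation_rad = 0), list(sA, sB)),
               class = "tethersim_ill_conditioned")
})

test_that("jitter-free track recovery is exact to numerical precision", {
  stns <- default_stations()
  set.seed(14)
  traj <- data.frame(time_s = seq(0, 2, 0.02),
                     x_m = runif(101, -0.6, 0.6),
                     y_m = runif(101, -0.6, 0.6),
                     z_m = runif(101, 0, 0.4))
  ev <- generate_lighthouse_events(traj, stns, 0)
  tp <- track_positions(ev, stns)
  expect_identical(nrow(tp), nrow(traj))
  err <- max(abs(as.matrix(tp[, c("x_m", "y_m", "z_m")]) -
                   as.matrix(traj[, c("x_m", "y_m", "z_m")])))
  expect_lt(err, 1e-9)
  # 90th-percentile planar error decreases as jitter decreases
  p90 <- sapply(c(2e-5, 2e-6, 2e-7), function(j) {
    evj <- generate_lighthouse_events(traj, stns, j, seed = 3)
    tpj <- track_positions(evj, stns)
    truth <- traj[tpj$sample, ]
    unname(quantile(sqrt((tpj$x_m - truth$x_m)^2 +
                           (tpj$y_m - truth$y_m)^2), 0.9))
  })
  expect_true(all(diff(p90) < 0))
})

test_that("fuse_pose resamples, flags dropouts, and tracks yaw across the wrap", {
  # constant inputs -> constant fused pose on a uniform grid
  opt <- data.frame(time_s = seq(0, 1, 0.05), x_m = 0.2, y_m = -0.1,
                    z_m = 0.3)
  q <- quat_from_ypr(30, 10, 0)
  imu <- data.frame(time_s = seq(0, 1, 0.01), qw = q[1], qx = q[2],
                    qy = q[3], qz = q[4])
  fp <- fuse_pose(opt, imu, output_rate_hz = 100)
  expect_equal(diff(fp$time_s), rep(0.01, nrow(fp) - 1))
  expect_true(all(fp$x_m == 0.2 & fp$z_m == 0.3))
  expect_near(fp$yaw_deg, rep(30, nrow(fp)), tol = 1e-6)
  expect_true(all(fp$position_source == "optical"))
  # grid covers only the overlap of the two input ranges
  imu_short <- imu[imu$time_s >= 0.25 & imu$time_s <= 0.8, ]
  fp2 <- fuse_pose(opt, imu_short, output_rate_hz = 100)
  expect_gte(min(fp2$time_s), 0.25)
  expect_lte(max(fp2$time_s), 0.8)
  # a dropout gap flags imu_only exactly for grid points in the gap and
  # holds the last optical position
  # optical samples remain at <= 0.25 and >= 0.70; the dropout region is
  # every grid point farther than 0.2 s from BOTH edges: (0.45, 0.50)
  opt_gap <- opt[opt$time_s < 0.3 | opt$time_s > 0.7, ]
  fp3 <- fuse_pose(opt_gap, imu, output_rate_hz = 100, max_gap_s = 0.2)
  in_gap <- fp3$time_s > 0.455 & fp3$time_s < 0.495
  expect_true(all(fp3$position_source[in_gap] == "imu_only"))
  expect_true(all(fp3$position_source[fp3$time_s > 0.52] == "optical"))
  expect_true(all(fp3$position_source[fp3$time_s <= 0.25] == "optical"))
  expect_true(all(fp3$x_m[in_gap] == 0.2))
  # fused yaw follows a full 360-degree scripted rotation including wrap
  scr <- orientation_script(data.frame(duration_s = 10,
                                       yaw_rate_deg_per_s = 36,
                                       pitch_deg = 0, roll_deg = 0),
                            noise_sd_deg = 0.2, seed = 8)
  o <- generate_orientation_frames(scr)
  imu2 <- data.frame(time_s = o$time_s, qw = o$quat[, 1], qx = o$quat[, 2],
                     qy = o$quat[, 3], qz = o$quat[, 4])
  opt2 <- data.frame(time_s = seq(0, 9.99, 0.05), x_m = 0, y_m = 0, z_m = 0)
  fp4 <- fuse_pose(opt2, imu2, output_rate_hz = 100)
  truth <- approx(o$time_s, o$true_yaw_deg, xout = fp4$time_s, rule = 2)$y
  expect_lt(max(abs(wrap180(fp4$yaw_deg - truth))), 1.5)
  # ordering error and empty input
  expect_error(fuse_pose(opt[c(2, 1, 3:21), ], imu),
               class = "tethersim_ordering")
  expect_identical(nrow(fuse_pose(opt[0, ], imu)), 0L)
})

test_that("pose CSV roundtrips", {
  fp <- data.frame(time_s = c(0, 0.01), x_m = c(0, 0.1), y_m = 0, z_m = 0.2,
                   yaw_deg = c(10, 20), pitch_deg = 0, roll_deg = 0,
                   position_source = "optical", residual_m = 0)
  path <- tempfile(fileext = ".csv")
  write_pose_csv(fp, path)
  rt <- read_pose_csv(path)
  expect_equal(rt, fp)
})
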