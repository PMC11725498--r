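#' Arena specification
#'
#' A hexagonal arena (default 1.6 m across) with a variable-height tiled
#' floor and a home position with elevated dwell — the geometry the
#' synthetic trajectory generator emulates. Tile heights follow a fixed
#' deterministic pattern so the arena itself carries no randomness.
#'
#' @param diameter_m Hexagon diameter (vertex to vertex), default 1.6.
#' @param tile_size_m Floor tile pitch, default 0.2.
#' @param tile_height_max_m Maximum tile height, default 0.05.
#' @param home 2-vector, x-y of the home position (inside the hexagon).
#' @return An `arena_spec` object with a `floor_height(x, y)` function.
#' @export
arena_spec <- function(diameter_m = 1.6, tile_size_m = 0.2,
                       tile_height_max_m = 0.05, home = c(-0.45, -0.35)) {
  stopifnot(diameter_m > 0, tile_size_m > 0, tile_height_max_m >= 0)
  circumradius <- diameter_m / 2
  apothem <- circumradius * sqrt(3) / 2
  floor_height <- function(x, y) {
    ix <- floor(x / tile_size_m)
    iy <- floor(y / tile_size_m)
    ((ix * 7 + iy * 13) %% 5) / 4 * tile_height_max_m
  }
  structure(list(diameter_m = diameter_m, circumradius = circumradius,
                 apothem = apothem, tile_size_m = tile_size_m,
                 tile_height_max_m = tile_height_max_m,
                 home = as.double(home), floor_height = floor_height),
            class = "arena_spec")
}

# signed slab projections of points onto the hexagon's 3 edge normals
hex_projections <- function(x, y) {
  cbind(x,
        x * cos(pi / 3) + y * sin(pi / 3),
        x * cos(2 * pi / 3) + y * sin(2 * pi / 3))
}

#' Hexagon containment and clamping
#'
#' The arena is the intersection of three slabs; a point is inside when
#' all three |projections| are at most the apothem. `hex_clamp()` scales
#' outside points radially back to the boundary.
#'
#' @param x,y Coordinates (vectorized), meters, arena-centered.
#' @param arena An [arena_spec()].
#' @param tol Numerical tolerance in meters for the containment test.
#' @return `hex_contains()`: logical vector. `hex_clamp()`: a list with
#'   clamped `x`, `y`.
#' @export
hex_contains <- function(x, y, arena, tol = 1e-9) {
  pr <- abs(hex_projections(x, y))
  a <- arena$apothem + tol
  pr[, 1] <= a & pr[, 2] <= a & pr[, 3] <= a
}

#' @rdname hex_contains
#' @export
hex_clamp <- function(x, y, arena) {
  pr <- abs(hex_projections(x, y))
  worst <- pmax(pr[, 1], pr[, 2], pr[, 3])
  f <- pmin(1, (1 - 1e-12) * arena$apothem / pmax(worst, 1e-12))
  list(x = x * f, y = y * f)
}

#' Mobility presets
#'
#' Two stated mobility conditions differing ~2x in median running speed,
#' emulating the contrast between a heavy conventional tether
#' (`"restricted"`) and a light micro-coax (`"free"`): the restricted
#' condition moves slower, turns more, and spends more time at home, so it
#' covers far less of the arena.
#'
#' @param name `"free"` or `"restricted"`.
#' @return List with `median_speed` (m/s), `max_speed` (m/s),
#'   `home_dwell_fraction`, `heading_diffusion` (rad/sqrt(s)).
#' @export
mobility_preset <- function(name = c("free", "restricted")) {
  name <- match.arg(name)
  if (name == "free") {
    list(median_speed = 0.10, max_speed = 0.80,
         home_dwell_fraction = 0.15, heading_diffusion = 1.5,
         label = "free")
  } else {
    list(median_speed = 0.05, max_speed = 0.40,
         home_dwell_fraction = 0.50, heading_diffusion = 4.0,
         label = "restricted")
  }
}

#' Synthetic freely-moving trajectory
#'
#' A seeded generator emulating 100 Hz head tracking of a mouse in the
#' hexagonal arena: alternating home-dwell episodes (stationary at the
#' home position) and exploration episodes following a correlated random
#' walk — log-AR(1) speed around the preset median (clipped at the
#' maximum), diffusing heading, and a mean-reverting path kept inside the
#' hexagon. Yaw follows the direction of motion; pitch couples to
#' floor-height transitions and is clipped to +/-45 degrees.
#'
#' @param arena An [arena_spec()].
#' @param mobility A [mobility_preset()] or a compatible list.
#' @param duration_s Duration in seconds.
#' @param seed Integer seed; identical (arguments, seed) give identical
#'   output.
#' @param sample_rate_hz Sampling rate, default 100.
#' @return Data frame `time_s`, `x_m`, `y_m`, `z_m`, `yaw_deg`
#'   (\[0, 360)), `pitch_deg` (\[-45, 45\]), `condition_label`.
#' @export
synthetic_trajectory <- function(arena = arena_spec(),
                                 mobility = mobility_preset("free"),
                                 duration_s = 600, seed = 1L,
                                 sample_rate_hz = 100) {
  stopifnot(duration_s > 0, sample_rate_hz > 0,
            mobility$home_dwell_fraction >= 0,
            mobility$home_dwell_fraction < 1)
  dt <- 1 / sample_rate_hz
  n <- max(2L, round(duration_s * sample_rate_hz))
  set.seed(seed)
  home <- arena$home
  label <- if (!is.null(mobility$label)) mobility$label else "custom"

  if (mobility$median_speed <= 0) {
    x <- rep(home[1], n); y <- rep(home[2], n)
    yaw <- rep(0, n)
  } else {
    # episode plan: explore/dwell alternation with exponential durations
    dwell_mean <- 20
    f <- mobility$home_dwell_fraction
    explore_mean <- if (f > 0) dwell_mean * (1 / f - 1) else Inf
    x <- numeric(n); y <- numeric(n); yaw <- numeric(n)
    pos <- home; th <- runif(1, 0, 2 * pi)
    i <- 1L
    exploring <- TRUE
    phi <- 1 - dt / 30                 # 30-s mean reversion to arena center
    rho <- exp(-dt / 2)                # 2-s speed decorrelation
    sig_ls <- 0.6
    while (i <= n) {
      len <- if (exploring) {
        if (is.finite(explore_mean)) {
          max(1L, round(rexp(1, 1 / explore_mean) * sample_rate_hz))
        } else n
      } else {
        max(1L, round(rexp(1, 1 / dwell_mean) * sample_rate_hz))
      }
      if (!exploring && sqrt(sum((pos - home)^2)) > 1e-9) {
        # walk home before settling: straight segment at the median speed,
        # so dwell episodes never teleport
        v <- min(2 * mobility$median_speed, mobility$max_speed)
        d <- sqrt(sum((pos - home)^2))
        m_full <- max(1L, ceiling(d / (v * dt)))
        m <- min(m_full, n - i + 1L)
        jdx <- i:(i + m - 1L)
        # if the session ends mid-walk, cover only the reachable fraction
        # (never teleport)
        frac <- seq_len(m) / m_full
        x[jdx] <- pos[1] + frac * (home[1] - pos[1])
        y[jdx] <- pos[2] + frac * (home[2] - pos[2])
        th <- atan2(home[2] - pos[2], home[1] - pos[1])
        yaw[jdx] <- th
        pos <- c(x[jdx[m]], y[jdx[m]])
        i <- i + m
        if (i > n) break
      }
      len <- min(len, n - i + 1L)
      idx <- i:(i + len - 1L)
      if (exploring) {
        ls <- stats::filter(rnorm(len, 0, sig_ls * sqrt(1 - rho^2)),
                            rho, method = "recursive")
        s <- pmin(mobility$median_speed * exp(as.numeric(ls)),
                  mobility$max_speed)
        th_seq <- th + cumsum(rnorm(len, 0,
                                    mobility$heading_diffusion * sqrt(dt)))
        sx <- s * dt * cos(th_seq)
        sy <- s * dt * sin(th_seq)
        px <- as.numeric(stats::filter(sx, phi, method = "recursive",
                                       init = pos[1]))
        py <- as.numeric(stats::filter(sy, phi, method = "recursive",
                                       init = pos[2]))
        cl <- hex_clamp(px, py, arena)
        x[idx] <- cl$x; y[idx] <- cl$y
        yaw[idx] <- th_seq
        pos <- c(cl$x[len], cl$y[len])
        th <- th_seq[len]
      } else {
        x[idx] <- home[1]; y[idx] <- home[2]
        yaw[idx] <- th
        pos <- home
      }
      i <- i + len
      exploring <- !exploring
    }
  }
  # tile edges are stepped; the animal climbs them over ~0.5 s, so smooth
  # the height profile along the path before adding head height
  z_floor <- boxcar_smooth(arena$floor_height(x, y),
                           max(1L, round(0.5 * sample_rate_hz)))
  z <- z_floor + 0.04                     # head height above the tile
  # pitch from floor slope along motion, smoothed, clipped to +/-45
  dz <- c(0, diff(z))
  dxy <- c(dt * 0.01, sqrt(diff(x)^2 + diff(y)^2))
  pitch <- atan2(dz, pmax(dxy, 1e-6)) * RAD2DEG
  pitch <- boxcar_smooth(pitch, max(1L, round(0.25 * sample_rate_hz)))
  pitch <- pmin(45, pmax(-45, pitch + rnorm(n, 0, 2)))
  data.frame(time_s = (seq_len(n) - 1) * dt,
             x_m = x, y_m = y, z_m = z,
             yaw_deg = wrap360(yaw * RAD2DEG),
             pitch_deg = pitch,
             condition_label = label)
}
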