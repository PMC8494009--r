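# Shared fixtures and independent oracles. Fixtures are cached per test run
# (the PDE runs are the expensive part of the suite).

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, ...) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, make_fixture(name, ...), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Full analysis of the FK linear-core rotor fixture, reused across files.
fk_rotor_analysis <- function() {
  cached("fk_analysis", {
    m <- cached_fixture("fk_linear_rotor")
    cfg <- default_config("fk")
    res <- analyze_movie(m, cfg, phase_method = "vr")
    res$lat <- NULL  # not needed downstream; keeps the cache lean
    res$movie <- m
    res$cfg <- cfg
    gc()
    res
  })
}

# Short AP plane-wave strip (propagation along x), shared by several tests.
ap_plane_movie <- function() {
  cached("ap_plane", {
    cfg <- default_config("ap")
    grid <- sim_grid(120, 12, cfg$dx, cfg$dt)
    mask <- matrix(FALSE, 12, 120); mask[, 1:3] <- TRUE
    run_simulation(kinetics_ap(), grid, list(stimulus(0, 0.5, mask)),
                   duration = 60, record_every = cfg$dt_lat)
  })
}

# Independent winding-number oracle: sum of unwrapped cyclic differences
# around the 2x2 plaquette with corner (i + 0.5, j + 0.5), divided by 2*pi.
# Uses the same ring orientation as detect_ps.
winding_oracle <- function(phi) {
  ny <- nrow(phi); nx <- ncol(phi)
  out <- matrix(NA_real_, ny - 1L, nx - 1L)
  for (i in seq_len(ny - 1L)) for (j in seq_len(nx - 1L)) {
    ring <- c(phi[i, j], phi[i + 1L, j], phi[i + 1L, j + 1L], phi[i, j + 1L])
    out[i, j] <- round(sum(wrap_phase(diff(c(ring, ring[1])))) / (2 * pi))
  }
  out
}

# Random smooth-plus-vortex phase field: a low-frequency smooth background
# with bounded gradient plus a single vortex at a random subpixel centre.
random_vortex_field <- function(n = 16, amp = 0.5) {
  cy <- stats::runif(1, 4, n - 3) + 0.211
  cx <- stats::runif(1, 4, n - 3) + 0.137
  s <- sample(c(-1, 1), 1)
  k1 <- stats::runif(1, -1, 1) * 2 * pi / n * 0.5
  k2 <- stats::runif(1, -1, 1) * 2 * pi / n * 0.5
  p0 <- stats::runif(1, 0, 2 * pi)
  smooth <- outer(seq_len(n), seq_len(n), function(y, x)
    amp * sin(k1 * y + k2 * x + p0))
  vortex <- outer(seq_len(n), seq_len(n), function(y, x)
    atan2(y - cy, x - cx))
  list(phi = wrap_phase(smooth + s * vortex), centre = c(cy, cx), s = s)
}

# Field with a straight phase-defect line and no winding: a half-plane
# offset whose raw jump exceeds pi on every crossing edge.
straddle_field <- function(n = 12, offset = 3.2) {
  base <- matrix(0.1, n, n)
  base[, (n %/% 2 + 1):n] <- wrap_phase(0.1 + offset)
  base
}

# Independent explicit-Euler 1D cable integrator (the plane-wave speed
# oracle). Deliberately a plain loop sharing nothing with the package's
# field stepper except the reaction definition.
cable_speed <- function(kinetics, dx, dt, n = 500, duration,
                        stim_len = 20L, V_star = 0.5) {
  m <- kinetics$m
  state <- lapply(kinetics$rest_state, rep, n)
  state[[1]][seq_len(stim_len)] <- 1
  nt <- round(duration / dt)
  i1 <- round(0.45 * n); i2 <- round(0.8 * n)
  t1 <- NA_real_; t2 <- NA_real_
  for (s in seq_len(nt)) {
    u <- state[[1]]
    lap <- (c(u[1], u[-n]) + c(u[-1], u[n]) - 2 * u) / dx^2
    dv <- kinetics$reaction(state)
    prev1 <- u[i1]; prev2 <- u[i2]
    state[[1]] <- u + dt * (kinetics$P11 * lap + dv[[1]])
    for (k in seq_len(m)[-1]) state[[k]] <- state[[k]] + dt * dv[[k]]
    tnow <- s * dt
    if (is.na(t1) && prev1 < V_star && state[[1]][i1] >= V_star)
      t1 <- tnow - dt * (state[[1]][i1] - V_star) / (state[[1]][i1] - prev1)
    if (is.na(t2) && prev2 < V_star && state[[1]][i2] >= V_star)
      t2 <- tnow - dt * (state[[1]][i2] - V_star) / (state[[1]][i2] - prev2)
    if (!is.na(t2)) break
  }
  (i2 - i1) * dx / (t2 - t1)
}

# Sub-frame upward crossing time of a single-pixel trace.
crossing_times <- function(tr, t, V_star = 0.5) {
  i <- which(tr[-length(tr)] < V_star & tr[-1] >= V_star)
  t[i] + (V_star - tr[i]) / (tr[i + 1] - tr[i]) * (t[i + 1] - t[i])
}

# Plane-wave front speed measured from a movie along row `row`.
movie_speed <- function(movie, row = NULL, frac = c(0.45, 0.8)) {
  d <- dim(movie$V)
  if (is.null(row)) row <- d[1] %/% 2
  j1 <- round(frac[1] * d[2]); j2 <- round(frac[2] * d[2])
  t1 <- crossing_times(movie$V[row, j1, ], movie$t)[1]
  t2 <- crossing_times(movie$V[row, j2, ], movie$t)[1]
  (j2 - j1) * movie$dx / (t2 - t1)
}
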