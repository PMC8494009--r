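#' Canned simulation scenarios
#'
#' Deterministic movies covering the situations the analysis modules are
#' designed for. All simulated fixtures use the reference model parameters
#' from [default_config()] on reduced-scale domains; domain sizes,
#' initiation protocols and timings are frozen design choices documented in
#' the methods vignette. `seed` is recorded in the metadata and only
#' affects fixtures with a stochastic ingredient (`sinusoid_movie` noise);
#' the PDE fixtures are bit-reproducible by construction.
#'
#' * `ap_circular_rotor`: S1-S2 cross-field initiation of a rotor with
#'   Aliev-Panfilov kinetics (compact meandering core); recorded after the
#'   initiation transient. Times are model units (a.u.).
#' * `s1s2_block`: the same AP scenario recorded from rest, capturing the
#'   conduction block line that precedes rotor formation.
#' * `fk_linear_rotor`: sustained linear-core rotor in the Fenton-Karma MBR
#'   set, initiated from a broken wavefront (a 1D pulse profile embedded in
#'   the top half of the domain; the free end curls up into a spiral).
#' * `bocf_linear_rotor`: S1-S2 conduction block episode in the
#'   Bueno-Orovio-Cherry-Fenton EPI set: the S2 wave is blocked along the
#'   refractory boundary and decays, leaving an extended block line (the
#'   EPI wavelength far exceeds any desk-scale domain, so no sustained
#'   rotor forms; the block line is the object of interest).
#' * `fk_scroll_3d_small`: broken-wavefront scroll wave in a small FK (MBR)
#'   slab, for 3D phase-defect-surface analysis.
#' * `sinusoid_movie`: analytic movie `V = 0.5 + 0.4 sin(2 pi f t)` (plus
#'   optional seeded noise), for frequency and Hilbert-phase tests.
#'
#' @param name Fixture name (see above).
#' @param seed Integer seed recorded in the metadata; used only where a
#'   fixture has random content.
#' @param f,n_frames,fs,noise_sd `sinusoid_movie` controls: frequency (Hz),
#'   frame count, sampling rate (frames/s), and optional Gaussian noise SD.
#' @return A [pd_movie()].
#' @export
make_fixture <- function(name, seed = 1L,
                         f = 20, n_frames = 1000, fs = 1000, noise_sd = 0) {
  switch(name,
    sinusoid_movie = fixture_sinusoid(seed, f, n_frames, fs, noise_sd),
    ap_circular_rotor = fixture_ap(seed, window = "rotor"),
    s1s2_block = fixture_ap(seed, window = "initiation"),
    fk_linear_rotor = fixture_fk(seed),
    bocf_linear_rotor = fixture_bocf(seed),
    fk_scroll_3d_small = fixture_fk3d(seed),
    stop("unknown fixture name: ", name)
  )
}

fixture_sinusoid <- function(seed, f, n_frames, fs, noise_sd) {
  ny <- 16L; nx <- 16L
  dt <- 1 / fs
  t <- (seq_len(n_frames) - 1) * dt
  tr <- 0.5 + 0.4 * sin(2 * pi * f * t)
  V <- array(rep(tr, each = ny * nx), dim = c(ny, nx, n_frames))
  if (noise_sd > 0) {
    set.seed(seed)
    V <- V + array(stats::rnorm(length(V), sd = noise_sd), dim = dim(V))
  }
  m <- pd_movie(V = V, dt_frame = dt, dx = 1, kinetics = "sinusoid", seed = seed)
  m$f <- f
  m
}

# S1 plane wave from the left edge; S2 clamps the upper-left quadrant
# inside the S1 repolarization tail (cross-field protocol).
s1s2_protocol <- function(grid, t_s2, s1_dur, s2_dur, value = 1) {
  m1 <- matrix(FALSE, grid$ny, grid$nx); m1[, 1:3] <- TRUE
  m2 <- matrix(FALSE, grid$ny, grid$nx)
  m2[1:(grid$ny %/% 2), 1:(grid$nx %/% 2)] <- TRUE
  list(stimulus(0, s1_dur, m1, value), stimulus(t_s2, s2_dur, m2, value))
}

# Frozen fixture constants. S2 timings sit inside the vulnerable window of
# the S1 repolarization gradient, found once from the models' measured
# conduction velocity and action potential duration (see methods vignette).
fixture_pars <- list(
  ap = list(nx = 100L, ny = 100L, t_s2 = 45, s1_dur = 0.5, s2_dur = 0.5,
            t_rotor = 70, duration = 170),
  fk = list(n = 320L, strip_len = 700L, profile_t = 280, tail_cols = 30L,
            duration = 900, t_keep = 300),
  bocf = list(nx = 144L, ny = 144L, t_s2 = 300, s1_dur = 2, s2_dur = 2,
              duration = 500),
  fk3d = list(nx = 48L, ny = 48L, nz = 8L, t_s2 = 180, s1_dur = 2,
              s2_dur = 2, duration = 300)
)

slice_movie <- function(movie, keep) {
  nd <- length(dim(movie$V))
  idx <- rep(list(quote(expr = )), nd)
  idx[[nd]] <- keep
  movie$V <- do.call(`[`, c(list(movie$V), idx, drop = FALSE))
  if (!is.null(movie$R))
    movie$R <- do.call(`[`, c(list(movie$R), idx, drop = FALSE))
  movie$t <- movie$t[keep]
  movie$t0 <- movie$t[1]
  movie
}

fixture_ap <- function(seed, window) {
  p <- fixture_pars$ap
  cfg <- default_config("ap")
  kin <- kinetics_ap()
  grid <- sim_grid(p$nx, p$ny, cfg$dx, cfg$dt)
  prot <- s1s2_protocol(grid, p$t_s2, p$s1_dur, p$s2_dur)
  m <- run_simulation(kin, grid, prot, duration = p$duration,
                      record_every = cfg$dt_lat)
  m$seed <- seed
  m$t_s2 <- p$t_s2
  if (window == "initiation") m else
    slice_movie(m, which(m$t >= p$t_rotor))
}

# 1D pulse profile (u, v, w, ... along a cable) used to seed spiral waves.
pulse_profile <- function(kin, n, dx, dt, t_profile) {
  strip <- sim_grid(n, 4, dx, dt)
  mask <- matrix(FALSE, 4, n); mask[, 1:3] <- TRUE
  ms <- run_simulation(kin, strip, list(stimulus(0, 2, mask)),
                       duration = t_profile, record_every = t_profile)
  lapply(ms$final_state, function(A) A[2, ])
}

fixture_fk <- function(seed) {
  p <- fixture_pars$fk
  cfg <- default_config("fk")  # 2D grid constants; MBR reaction set
  kin <- kinetics_fk("MBR")
  prof <- pulse_profile(kin, p$strip_len, cfg$dx, cfg$dt, p$profile_t)
  exc <- which(prof[[1]] > 0.5)
  lo <- min(exc) - p$tail_cols
  n <- p$n
  window <- lo:(lo + n - 1L)
  grid <- sim_grid(n, n, cfg$dx, cfg$dt)
  init <- lapply(seq_along(prof), function(i) {
    A <- matrix(kin$rest_state[i], n, n)
    A[1:(n %/% 2), ] <- matrix(prof[[i]][window], n %/% 2, n, byrow = TRUE)
    A
  })
  m <- run_simulation(kin, grid, list(), duration = p$duration,
                      record_every = cfg$dt_lat, init = init)
  m$seed <- seed
  slice_movie(m, which(m$t >= p$t_keep))
}

fixture_bocf <- function(seed) {
  p <- fixture_pars$bocf
  cfg <- default_config("bocf")
  kin <- kinetics_bocf()
  grid <- sim_grid(p$nx, p$ny, cfg$dx, cfg$dt)
  prot <- s1s2_protocol(grid, p$t_s2, p$s1_dur, p$s2_dur)
  m <- run_simulation(kin, grid, prot, duration = p$duration,
                      record_every = cfg$dt_lat)
  m$seed <- seed
  m$t_s2 <- p$t_s2
  m
}

fixture_fk3d <- function(seed) {
  p <- fixture_pars$fk3d
  cfg <- default_config("fk", dim = 3)
  kin <- kinetics_fk("MBR")
  grid <- sim_grid(p$nx, p$ny, cfg$dx, cfg$dt, nz = p$nz)
  m1 <- array(FALSE, dim = c(p$ny, p$nx, p$nz)); m1[, 1:3, ] <- TRUE
  m2 <- array(FALSE, dim = c(p$ny, p$nx, p$nz))
  m2[1:(p$ny %/% 2), 1:(p$nx %/% 2), ] <- TRUE
  prot <- list(stimulus(0, p$s1_dur, m1), stimulus(p$t_s2, p$s2_dur, m2))
  m <- run_simulation(kin, grid, prot, duration = p$duration,
                      record_every = cfg$dt_lat, init = NULL)
  m$seed <- seed
  m$t_s2 <- p$t_s2
  m
}
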