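#' Simulation grid
#'
#' Defines a regular 2D or 3D grid with no-flux (Neumann) boundaries for the
#' monodomain simulator.
#'
#' @param nx,ny,nz Pixel counts per axis (`nz = NULL` for 2D).
#' @param dx Grid spacing (mm, or dimensionless for AP kinetics).
#' @param dt Explicit-Euler time step. Must satisfy the diffusion stability
#'   bound `dt < dx^2 / (2 * dim * P11)`; this is checked against the kinetics
#'   when a simulation is run.
#' @return A `pd_grid` object.
#' @export
sim_grid <- function(nx, ny, dx, dt, nz = NULL) {
  stopifnot(nx >= 2, ny >= 2, dx > 0, dt > 0)
  if (!is.null(nz)) stopifnot(nz >= 2)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 nz = if (is.null(nz)) NULL else as.integer(nz),
                 dx = dx, dt = dt,
                 dim = if (is.null(nz)) 2L else 3L),
            class = "pd_grid")
}

check_stability <- function(grid, kinetics) {
  bound <- grid$dx^2 / (2 * grid$dim * kinetics$P11)
  if (grid$dt >= bound) {
    stop(sprintf(
      "dt = %g violates the explicit-Euler diffusion stability bound %g (dx = %g, dim = %d, P11 = %g)",
      grid$dt, bound, grid$dx, grid$dim, kinetics$P11))
  }
  invisible(TRUE)
}

#' Stimulation protocol
#'
#' A protocol is a list of stimuli. Each stimulus clamps the first state
#' variable (transmembrane potential) to `value` over a spatial mask for a
#' time window, the standard way of delivering S1/S2 pulses in monodomain
#' simulations.
#'
#' @param onset Stimulus onset time (model time units).
#' @param duration Stimulus duration.
#' @param mask Logical array matching the grid (`ny x nx` or `ny x nx x nz`),
#'   `TRUE` where the stimulus is applied.
#' @param value Clamped value of the first state variable (default 1,
#'   the excited plateau of the normalized models).
#' @return A `pd_stimulus` object.
#' @export
stimulus <- function(onset, duration, mask, value = 1) {
  stopifnot(onset >= 0, duration > 0, is.logical(mask), any(mask))
  structure(list(onset = onset, duration = duration, mask = mask,
                 value = value), class = "pd_stimulus")
}

validate_protocol <- function(protocol, grid) {
  if (length(protocol) == 0) return(invisible(TRUE))
  shp <- if (grid$dim == 2L) c(grid$ny, grid$nx) else c(grid$ny, grid$nx, grid$nz)
  onsets <- vapply(protocol, function(s) s$onset, numeric(1))
  if (is.unsorted(onsets)) stop("stimulus onset times must be non-decreasing")
  for (s in protocol) {
    if (!inherits(s, "pd_stimulus")) stop("protocol entries must be pd_stimulus objects")
    if (!identical(dim(s$mask), as.integer(shp)))
      stop("stimulus mask does not match the grid dimensions")
  }
  invisible(TRUE)
}

# Five-point Neumann Laplacian; the ghost node mirrors the boundary value,
# which makes the operator mass-conserving (all boundary fluxes vanish).
laplace2 <- function(M, dx) {
  ny <- nrow(M); nx <- ncol(M)
  (M[c(1L, seq_len(ny - 1L)), , drop = FALSE] +
   M[c(seq_len(ny - 1L) + 1L, ny), , drop = FALSE] +
   M[, c(1L, seq_len(nx - 1L)), drop = FALSE] +
   M[, c(seq_len(nx - 1L) + 1L, nx), drop = FALSE] - 4 * M) / dx^2
}

# Seven-point Neumann Laplacian for 3D slabs.
laplace3 <- function(A, dx) {
  d <- dim(A)
  i0 <- c(1L, seq_len(d[1] - 1L)); i1 <- c(seq_len(d[1] - 1L) + 1L, d[1])
  j0 <- c(1L, seq_len(d[2] - 1L)); j1 <- c(seq_len(d[2] - 1L) + 1L, d[2])
  k0 <- c(1L, seq_len(d[3] - 1L)); k1 <- c(seq_len(d[3] - 1L) + 1L, d[3])
  (A[i0, , , drop = FALSE] + A[i1, , , drop = FALSE] +
   A[, j0, , drop = FALSE] + A[, j1, , drop = FALSE] +
   A[, , k0, drop = FALSE] + A[, , k1, drop = FALSE] - 6 * A) / dx^2
}

#' One explicit-Euler step of the monodomain equation
#'
#' Advances a state by one time step of
#' \eqn{\partial_t u = \Delta P u + F(u)} with a 5-point (2D) or 7-point (3D)
#' Laplacian applied to the first state variable only and no-flux boundaries
#' implemented by mirrored ghost nodes.
#'
#' @param state List of `m` arrays (one per state variable), each `ny x nx`
#'   (or `ny x nx x nz`).
#' @param kinetics A [pd_kinetics][kinetics] object.
#' @param grid A [sim_grid()] object.
#' @return The state advanced by `grid$dt`.
#' @export
step_euler <- function(state, kinetics, grid) {
  check_stability(grid, kinetics)
  if (!all(vapply(state, function(x) all(is.finite(x)), logical(1))))
    stop("numerical blow-up: non-finite state")
  deriv <- kinetics$reaction(state)
  lap <- if (grid$dim == 2L) laplace2(state[[1]], grid$dx) else laplace3(state[[1]], grid$dx)
  out <- vector("list", kinetics$m)
  out[[1]] <- state[[1]] + grid$dt * (kinetics$P11 * lap + deriv[[1]])
  for (i in seq_len(kinetics$m)[-1]) out[[i]] <- state[[i]] + grid$dt * deriv[[i]]
  out
}

rest_state_field <- function(kinetics, grid) {
  shp <- if (grid$dim == 2L) c(grid$ny, grid$nx) else c(grid$ny, grid$nx, grid$nz)
  lapply(kinetics$rest_state, function(v) array(v, dim = shp))
}

#' Run a monodomain simulation
#'
#' Integrates the monodomain equation with explicit Euler stepping, applies
#' the stimulation protocol, and records the voltage observable `V` (and
#' optionally the recovery observable `R`) every `record_every` time units.
#' The run is fully deterministic given identical inputs.
#'
#' @param kinetics A [pd_kinetics][kinetics] object.
#' @param grid A [sim_grid()] object.
#' @param protocol List of [stimulus()] objects (may be empty).
#' @param duration Total simulated time; the movie holds
#'   `floor(duration / record_every) + 1` frames (the frame at t = 0
#'   included).
#' @param record_every Frame interval of the recorded movie (the LAT frame
#'   interval of the model's reference configuration is the natural choice).
#' @param init Optional initial state (list of `m` arrays); defaults to the
#'   resting state everywhere.
#' @param record_R If `TRUE` (default) also record the `R` observable.
#' @param reaction_on Set to `FALSE` to integrate pure diffusion (used for
#'   conservation checks).
#' @return A [pd_movie()] with metadata (`dt_frame`, `dx`, kinetics tag,
#'   frame times) and the full final state in `$final_state`.
#' @export
run_simulation <- function(kinetics, grid, protocol = list(), duration,
                           record_every, init = NULL, record_R = TRUE,
                           reaction_on = TRUE) {
  check_stability(grid, kinetics)
  validate_protocol(protocol, grid)
  stopifnot(duration >= 0, record_every > 0)

  state <- if (is.null(init)) rest_state_field(kinetics, grid) else init
  dt <- grid$dt
  rec_steps <- max(1L, round(record_every / dt))
  n_frames <- floor(duration / record_every) + 1L
  # integrate exactly to the last recorded frame so recording never
  # underruns when record_every is not an exact multiple of dt
  n_steps <- rec_steps * (n_frames - 1L)

  shp <- dim(state[[1]])
  V <- array(NA_real_, dim = c(shp, n_frames))
  R <- if (record_R) array(NA_real_, dim = c(shp, n_frames)) else NULL
  times <- numeric(n_frames)
  npix <- prod(shp)

  apply_stimuli <- function(state, t) {
    for (s in protocol) {
      if (t >= s$onset && t < s$onset + s$duration) state[[1]][s$mask] <- s$value
    }
    state
  }

  store <- function(frame, state, t) {
    V[(npix * (frame - 1L) + 1L):(npix * frame)] <<- state[[1]]
    if (record_R)
      R[(npix * (frame - 1L) + 1L):(npix * frame)] <<- kinetics$r_obs(state)
    times[frame] <<- t
  }

  state <- apply_stimuli(state, 0)
  store(1L, state, 0)
  frame <- 1L
  for (step in seq_len(n_steps)) {
    deriv <- if (reaction_on) kinetics$reaction(state) else
      lapply(state, function(x) array(0, dim = dim(x)))
    lap <- if (grid$dim == 2L) laplace2(state[[1]], grid$dx) else laplace3(state[[1]], grid$dx)
    state[[1]] <- state[[1]] + dt * (kinetics$P11 * lap + deriv[[1]])
    for (i in seq_len(kinetics$m)[-1]) state[[i]] <- state[[i]] + dt * deriv[[i]]
    t <- step * dt
    state <- apply_stimuli(state, t)
    if (step %% rec_steps == 0L && frame < n_frames) {
      if (!all(is.finite(state[[1]])))
        stop(sprintf("numerical blow-up at step %d (t = %g)", step, t))
      frame <- frame + 1L
      store(frame, state, (frame - 1L) * record_every)
    }
  }
  if (frame < n_frames)
    stop("internal error: fewer frames recorded than expected")
  if (max(V, na.rm = TRUE) < kinetics$v_star)
    warning("dead run: no pixel ever crossed V_star")

  pd_movie(V = V, R = R, dt_frame = record_every, dx = grid$dx,
           t0 = 0, kinetics = paste0(kinetics$name, "/", kinetics$set),
           final_state = state, duration = duration)
}
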