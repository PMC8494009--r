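#' Wrap an angle difference into [-pi, pi)
#'
#' The unwrap operator `U`: adds the integer multiple of `2*pi` that brings
#' its argument closest to zero. All phase comparisons in the package go
#' through this function, so that differences of `2*pi` are disregarded.
#' The boundary maps to the negative representative: `wrap_phase(pi) == -pi`.
#'
#' @param x Numeric vector/array of angle differences (radians).
#' @return Values congruent to `x` modulo `2*pi`, in `[-pi, pi)`.
#' @export
wrap_phase <- function(x) ((x + pi) %% (2 * pi)) - pi

#' Activation phase from two observables
#'
#' The classical phase of cardiac phase mapping: the polar angle of the
#' state `(V, R)` around a reference point `(V_star, R_star)` chosen inside
#' the action-potential cycle,
#' `phi_act = atan2(R - R_star, V - V_star) + b`, wrapped to `[-pi, pi)`.
#' The additive constant `b` fixes the absolute phase (e.g. so that the
#' resting state has phase 0).
#'
#' @param V,R Numeric arrays of the same shape (a single frame or a whole
#'   movie's worth of frames).
#' @param V_star,R_star Reference point in the (V, R) plane.
#' @param b Additive phase offset (radians), default 0.
#' @return Array of phases in `[-pi, pi)`; pixels exactly at
#'   `(V_star, R_star)` (where the angle is undefined) are `NA`.
#' @export
activation_phase <- function(V, R, V_star, R_star, b = 0) {
  if (!identical(dim(V), dim(R)) || length(V) != length(R))
    stop("V and R must have the same shape")
  phi <- wrap_phase(atan2(R - R_star, V - V_star) + b)
  phi[(V == V_star) & (R == R_star)] <- NA_real_
  phi
}

#' Activation phase of a whole movie
#'
#' Convenience wrapper applying [activation_phase()] to a movie's `V` and
#' `R` arrays using thresholds from the movie's kinetics (or given
#' explicitly).
#'
#' @param movie A [pd_movie()] carrying both `V` and `R`.
#' @param V_star,R_star Reference point; defaults 0.5 and the value stored
#'   for the generating kinetics are the conventional choices.
#' @param b Phase offset.
#' @return Array of phases, same shape as `movie$V`.
#' @export
movie_activation_phase <- function(movie, V_star = 0.5, R_star, b = 0) {
  if (is.null(movie$R)) stop("movie has no R observable; use hilbert_phase()")
  activation_phase(movie$V, movie$R, V_star, R_star, b)
}

# Analytic signal of the columns of a matrix (time down the rows), via FFT:
# negative frequencies zeroed, positive doubled.
analytic_signal <- function(M) {
  n <- nrow(M)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(M)
  stats::mvfft(X * h, inverse = TRUE) / n
}

#' Hilbert phase of a movie
#'
#' Phase from a single observable: each pixel's mean-subtracted voltage
#' trace is turned into its analytic signal (Hilbert transform embedding)
#' and the phase is the angle of that complex trace, frame by frame. This is
#' the standard route for optical-mapping recordings where no independent
#' recovery variable is available.
#'
#' The offset `b` fixes the absolute phase; the default `-pi` places the
#' resting (diastolic) state near phase 0, matching the activation-phase
#' convention.
#'
#' @param movie A [pd_movie()]; pixel traces should span at least two
#'   dominant periods for a stable analytic signal.
#' @param b Additive phase offset (radians).
#' @return Array of phases in `[-pi, pi)`, same shape as `movie$V`;
#'   constant (or background `NA`) pixel traces give `NA` phases.
#' @export
hilbert_phase <- function(movie, b = -pi) {
  d <- dim(movie$V)
  nd <- length(d)
  nt <- d[nd]
  npix <- prod(d[-nd])
  flat <- matrix(movie$V, nrow = npix, ncol = nt)
  ok <- apply(flat, 1, function(x) all(is.finite(x))) &
    (apply(flat, 1, max) > apply(flat, 1, min))
  phi <- matrix(NA_real_, npix, nt)
  # chunk over pixels: the complex FFT buffers would otherwise dominate
  # memory on large movies
  todo <- which(ok)
  chunk <- 16384L
  for (lo in seq(1L, length(todo), by = chunk)) {
    rows <- todo[lo:min(lo + chunk - 1L, length(todo))]
    M <- t(flat[rows, , drop = FALSE])
    M <- sweep(M, 2, colMeans(M))
    a <- analytic_signal(M)
    phi[rows, ] <- t(atan2(Im(a), Re(a)))
  }
  array(wrap_phase(phi + b), dim = d)
}

#' Update a local activation time (LAT) field from a new frame
#'
#' A pixel's LAT is the most recent time its voltage rose through `V_star`.
#' Pixels whose voltage crosses upward between the previous and the new
#' frame get their LAT overwritten with the new frame time ("newest LAT");
#' all other pixels keep their previous value. The value 0 is the
#' "never activated" sentinel, so recordings must start at a positive frame
#' time for activated pixels (frame 1 of a movie starting at t = 0 never
#' assigns a LAT, which guarantees this).
#'
#' @param lat Numeric matrix/array of current LATs (0 = never activated).
#' @param prev_frame,new_frame Consecutive voltage frames.
#' @param t_new Time of `new_frame` (must be > 0).
#' @param V_star Activation threshold.
#' @return Updated LAT field.
#' @export
update_lat <- function(lat, prev_frame, new_frame, t_new, V_star) {
  stopifnot(identical(dim(lat), dim(prev_frame)),
            identical(dim(lat), dim(new_frame)))
  cross <- !is.na(prev_frame) & !is.na(new_frame) &
    (prev_frame < V_star) & (new_frame >= V_star)
  lat[cross] <- t_new
  lat
}

#' LAT fields for every frame of a movie
#'
#' Runs [update_lat()] along a movie and returns the running LAT field after
#' each frame. Frame 1 is all zeros (nothing can have activated at or before
#' the first recorded frame).
#'
#' @param movie A [pd_movie()].
#' @param V_star Activation threshold (default 0.5).
#' @return Array of LATs with the same shape as `movie$V`.
#' @export
movie_lat <- function(movie, V_star = 0.5) {
  d <- dim(movie$V)
  nd <- length(d)
  out <- array(0, dim = d)
  lat <- array(0, dim = d[-nd])
  npix <- prod(d[-nd])
  for (k in seq_len(d[nd])[-1]) {
    lat <- update_lat(lat, movie_frame(movie, k - 1L), movie_frame(movie, k),
                      movie$t[k], V_star)
    out[(npix * (k - 1L) + 1L):(npix * k)] <- lat
  }
  out
}

#' Arrival-time phase
#'
#' A phase built from elapsed time since activation:
#' `phi_arr = 2*pi * tanh(3 * t_elapsed / tau)`, wrapped to `[-pi, pi)`.
#' The saturating tanh makes recovered tissue (`t_elapsed >> tau`)
#' equivalent to resting tissue (phase ~ 0 modulo `2*pi`), so the wave front
#' and wave back produce no phase jumps; the only steep spatial transitions
#' of `phi_arr` occur across conduction block lines, where LAT itself is
#' discontinuous.
#'
#' @param t_now Current time.
#' @param lat LAT field (0 = never activated).
#' @param tau Characteristic recovery time of the medium (e.g. the mean
#'   action potential duration, or the inverse dominant frequency).
#' @return Phase array in `[-pi, pi)`; never-activated pixels are `NA`.
#' @export
arrival_phase <- function(t_now, lat, tau) {
  if (tau <= 0) stop("tau must be positive")
  phi <- wrap_phase(2 * pi * tanh(3 * (t_now - lat) / tau))
  phi[lat == 0] <- NA_real_
  phi
}

#' Arrival-time phase of a whole movie
#'
#' @param movie A [pd_movie()].
#' @param tau Characteristic time constant (see [arrival_phase()]).
#' @param V_star Activation threshold used to build the LAT fields.
#' @param lat Optional precomputed LAT array from [movie_lat()].
#' @return Phase array, same shape as `movie$V`.
#' @export
movie_arrival_phase <- function(movie, tau, V_star = 0.5, lat = NULL) {
  if (is.null(lat)) lat <- movie_lat(movie, V_star)
  d <- dim(movie$V)
  nd <- length(d)
  npix <- prod(d[-nd])
  out <- array(NA_real_, dim = d)
  for (k in seq_len(d[nd])) {
    idx <- (npix * (k - 1L) + 1L):(npix * k)
    latk <- array(lat[idx], dim = d[-nd])
    out[idx] <- arrival_phase(movie$t[k], latk, tau)
  }
  out
}

#' Wrapped spatial phase gradient magnitude
#'
#' Forward differences of a phase field along each axis, each passed through
#' [wrap_phase()] (so differences of `2*pi` are disregarded), divided by the
#' pixel spacing; the result is the Euclidean norm over axes. Pixels whose
#' forward neighbour is missing (last row/column, or an undefined
#' neighbour) give `NA`.
#'
#' @param phi Phase matrix (2D) or 3D array.
#' @param dx Pixel spacing.
#' @return Array of gradient magnitudes, same shape as `phi`.
#' @export
phase_gradient <- function(phi, dx = 1) {
  d <- dim(phi)
  shift_fwd <- function(axis) {
    idx <- rep(list(quote(expr = )), length(d))
    idx[[axis]] <- c(seq_len(d[axis])[-1], NA_integer_)
    do.call(`[`, c(list(phi), idx, drop = FALSE))
  }
  total <- array(0, dim = d)
  for (ax in seq_along(d)) {
    g <- wrap_phase(shift_fwd(ax) - phi) / dx
    total <- total + g^2
  }
  sqrt(total)
}

#' Mean upstroke and downstroke phases
#'
#' Finds the circular-mean phase of pixels crossing the activation threshold
#' upward (`phi1`, the middle of the upstroke) and downward (`phi2`, the
#' middle of the downstroke) over the frames of a movie. Crossings are sign
#' changes of `V - V_star` between consecutive frames; the sign of `dV/dt`
#' is taken from that same backward difference.
#'
#' @param movie A [pd_movie()].
#' @param phases Phase array matching `movie$V` (e.g. from
#'   [movie_activation_phase()]).
#' @param V_star Activation threshold.
#' @return List with elements `phi1` and `phi2` (radians in `[-pi, pi)`).
#' @export
phase_levels <- function(movie, phases, V_star = 0.5) {
  stopifnot(identical(dim(phases), dim(movie$V)))
  d <- dim(movie$V)
  nd <- length(d)
  npix <- prod(d[-nd])
  up <- c(); down <- c()
  for (k in seq_len(d[nd])[-1]) {
    prev <- movie$V[(npix * (k - 2L) + 1L):(npix * (k - 1L))]
    cur <- movie$V[(npix * (k - 1L) + 1L):(npix * k)]
    ph <- phases[(npix * (k - 1L) + 1L):(npix * k)]
    u <- which(!is.na(prev) & !is.na(cur) & prev < V_star & cur >= V_star)
    dn <- which(!is.na(prev) & !is.na(cur) & prev >= V_star & cur < V_star)
    up <- c(up, ph[u]); down <- c(down, ph[dn])
  }
  circ_mean <- function(x, which) {
    x <- x[!is.na(x)]
    if (length(x) == 0)
      stop("no ", which, " crossings found; cannot compute ", which, " phase level")
    atan2(mean(sin(x)), mean(cos(x)))
  }
  list(phi1 = circ_mean(up, "upstroke"), phi2 = circ_mean(down, "downstroke"))
}

#' Wave front and wave back pixel sets
#'
#' The wave front (WF) is the set of pixels crossing the activation
#' threshold upward between two consecutive frames; the wave back (WB) the
#' set crossing downward. The two sets are disjoint by construction.
#'
#' @param prev_frame,new_frame Consecutive voltage frames.
#' @param V_star Activation threshold.
#' @return List of two integer matrices `WF` and `WB`, each with columns
#'   `y`, `x` (and `z` for 3D frames).
#' @export
wave_fronts <- function(prev_frame, new_frame, V_star = 0.5) {
  stopifnot(identical(dim(prev_frame), dim(new_frame)))
  ok <- !is.na(prev_frame) & !is.na(new_frame)
  wf <- which(ok & prev_frame < V_star & new_frame >= V_star, arr.ind = TRUE)
  wb <- which(ok & prev_frame >= V_star & new_frame < V_star, arr.ind = TRUE)
  nm <- if (length(dim(prev_frame)) == 3L) c("y", "x", "z") else c("y", "x")
  colnames(wf) <- nm; colnames(wb) <- nm
  list(WF = wf, WB = wb)
}

#' Diffusive thickness of a phase defect line
#'
#' Voltage diffusion smears the jump across a conduction block line into a
#' boundary layer whose thickness is set by the diffusion coefficient `D`
#' and the action potential duration `tau`: `d = sqrt(D * tau)`, scaled by
#' the conduction-velocity anisotropy ratio when the line runs parallel to
#' the myofiber direction.
#'
#' @param D Voltage diffusion coefficient perpendicular to the line
#'   (cm^2/s).
#' @param tau Action potential duration (ms).
#' @param anisotropy_ratio Conduction-velocity anisotropy ratio (>= 1);
#'   1 for a line perpendicular to the fibers.
#' @return Thickness in mm.
#' @examples
#' defect_thickness(1.171, 269)        # ~5.6 mm
#' defect_thickness(1.171, 269, 2.5)   # ~14 mm
#' @export
defect_thickness <- function(D, tau, anisotropy_ratio = 1) {
  if (D < 0 || tau < 0) stop("D and tau must be non-negative")
  if (anisotropy_ratio < 1) stop("anisotropy_ratio must be >= 1")
  # D in cm^2/s, tau in ms: sqrt(cm^2/s * s) = cm -> mm
  10 * sqrt(D * tau / 1000) * anisotropy_ratio
}
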