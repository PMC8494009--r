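#' Spatiotemporal voltage movie
#'
#' The universal input of the package: a dense array of (normalized)
#' transmembrane potential `V(y, x[, z], t)` on a regular grid, with frame
#' interval and pixel spacing metadata, and optionally a second recovery
#' observable `R` of the same shape. Movies come from the built-in simulator
#' ([run_simulation()], [make_fixture()]) or from optical-mapping recordings
#' ([normalize_optical()]).
#'
#' Undefined pixels (background in optical recordings) are `NA` in every
#' frame and propagate as undefined through all phase and detection
#' operations.
#'
#' @param V Numeric array, `ny x nx x nt` (2D) or `ny x nx x nz x nt` (3D).
#' @param dt_frame Frame interval (ms, or model time units for AP kinetics).
#' @param dx Pixel spacing (mm, or dimensionless for AP).
#' @param R Optional recovery-observable array of the same shape as `V`.
#' @param t0 Time of the first frame (default 0).
#' @param kinetics Optional tag naming the generating model.
#' @param final_state,duration,seed Optional simulator provenance.
#' @return An object of class `pd_movie`.
#' @export
pd_movie <- function(V, dt_frame, dx, R = NULL, t0 = 0, kinetics = NA_character_,
                     final_state = NULL, duration = NA_real_, seed = NA_integer_) {
  stopifnot(is.array(V), length(dim(V)) %in% c(3L, 4L), dt_frame > 0, dx > 0)
  if (!is.null(R) && !identical(dim(R), dim(V)))
    stop("R must have the same shape as V")
  nd <- length(dim(V))
  nt <- dim(V)[nd]
  structure(list(
    V = V, R = R, dt_frame = dt_frame, dx = dx, t0 = t0,
    t = t0 + (seq_len(nt) - 1) * dt_frame,
    kinetics = kinetics, final_state = final_state,
    duration = duration, seed = seed,
    spatial_dim = nd - 1L
  ), class = "pd_movie")
}

#' @export
print.pd_movie <- function(x, ...) {
  d <- dim(x$V)
  cat(sprintf("<pd_movie %s: %s px, %d frames, dt_frame = %g, dx = %g%s>\n",
              ifelse(is.na(x$kinetics), "", x$kinetics),
              paste(d[-length(d)], collapse = "x"), d[length(d)],
              x$dt_frame, x$dx,
              if (is.null(x$R)) ", V only" else ", V+R"))
  invisible(x)
}

n_frames <- function(movie) dim(movie$V)[length(dim(movie$V))]

# Extract frame k of V (or R) as a matrix / 3D array.
movie_frame <- function(movie, k, what = c("V", "R")) {
  what <- match.arg(what)
  A <- movie[[what]]
  if (is.null(A)) stop("movie has no ", what, " observable")
  nd <- length(dim(A))
  if (nd == 3L) A[, , k] else A[, , , k]
}

#' Write / read a movie container
#'
#' Persists a movie (and any attached phase or LAT fields) to a single-file
#' container using R's native serialization, with schema validation on read.
#' The round-trip is lossless for both data and metadata.
#'
#' @param movie A `pd_movie`.
#' @param path File path (conventionally `.rds`).
#' @return `read_movie()` returns the `pd_movie`; `write_movie()` returns
#'   `path` invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "pd_movie"))
  saveRDS(unclass(movie), path)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- readRDS(path)
  for (field in c("V", "dt_frame", "dx")) {
    if (is.null(x[[field]]))
      stop("invalid movie container: missing required field '", field, "'")
  }
  m <- pd_movie(V = x$V, dt_frame = x$dt_frame, dx = x$dx, R = x$R,
                t0 = if (is.null(x$t0)) 0 else x$t0,
                kinetics = if (is.null(x$kinetics)) NA_character_ else x$kinetics,
                final_state = x$final_state,
                duration = if (is.null(x$duration)) NA_real_ else x$duration,
                seed = if (is.null(x$seed)) NA_integer_ else x$seed)
  for (extra in setdiff(names(x), names(m))) m[[extra]] <- x[[extra]]
  m
}

#' Normalize a raw optical-mapping movie
#'
#' Converts integer fluorescence intensity frames to a normalized voltage
#' movie: each pixel's trace is mapped to `[0, 1]` by its own minimum and
#' maximum over the full recording. Pixels whose trace range or maximum
#' intensity does not exceed `background_threshold` are flagged as
#' background and set to `NA` in all frames.
#'
#' @param raw Numeric array `ny x nx x nt` of non-negative intensities.
#' @param dt_frame,dx Acquisition metadata (frame interval, pixel spacing).
#' @param background_threshold Pixels with trace range <= this value (or
#'   maximum intensity <= this value) are treated as background. Default 0
#'   flags only strictly constant pixels.
#' @return A `pd_movie` with `V` in `[0, 1]` and background pixels `NA`.
#' @export
normalize_optical <- function(raw, dt_frame, dx = 1, background_threshold = 0) {
  stopifnot(is.array(raw), length(dim(raw)) == 3L, all(raw >= 0, na.rm = TRUE))
  d <- dim(raw)
  if (d[3] < 2) stop("need at least 2 frames to normalize")
  flat <- matrix(raw, nrow = d[1] * d[2], ncol = d[3])
  mins <- apply(flat, 1, min)
  maxs <- apply(flat, 1, max)
  rng <- maxs - mins
  bg <- (rng <= background_threshold) | (maxs <= background_threshold)
  if (all(bg)) stop("all pixels classified as background")
  out <- (flat - mins) / ifelse(rng > 0, rng, 1)
  out[bg, ] <- NA_real_
  pd_movie(V = array(out, dim = d), dt_frame = dt_frame, dx = dx,
           kinetics = "optical")
}
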