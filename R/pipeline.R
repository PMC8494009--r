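#' Full phase-defect analysis of a movie
#'
#' Runs the standard pipeline on a 2D movie: phase computation (activation
#' phase from `(V, R)` when `R` is present, Hilbert phase otherwise, and
#' the LAT-based arrival phase), frame-wise PS / PDL / CBL detection,
#' PS-PDL association, temporal tracking, and the recording-level summary.
#'
#' @param movie A [pd_movie()] (2D).
#' @param config Run configuration, e.g. [default_config()]; must provide
#'   `V_star`, `dt_c`, `dphi_crit`, `dphi_arr_crit`, `tau`, `ps_method`,
#'   and `R_star` when the activation phase is used.
#' @param phase_method `"auto"` (default: activation phase if `R` present,
#'   else Hilbert), `"vr"`, or `"hilbert"`. The arrival phase is always
#'   computed in addition.
#' @return List with elements `phi` (phase array used for PS/PDL),
#'   `phi_arr`, `lat`, `ps` (tracked + associated detections), `ps_tracks`,
#'   `pdl` (tracked defect midpoints), `pdl_families`, `cbl`, and
#'   `summary` (one-row data frame from [rotor_summary()]).
#' @export
analyze_movie <- function(movie, config, phase_method = c("auto", "vr", "hilbert")) {
  phase_method <- match.arg(phase_method)
  if (movie$spatial_dim != 2L) stop("analyze_movie() handles 2D movies")
  if (phase_method == "auto")
    phase_method <- if (!is.null(movie$R)) "vr" else "hilbert"
  phi <- switch(phase_method,
    vr = movie_activation_phase(movie, config$V_star, config$R_star),
    hilbert = hilbert_phase(movie))
  lat <- movie_lat(movie, config$V_star)
  phi_arr <- movie_arrival_phase(movie, config$tau, config$V_star, lat = lat)

  ps <- detect_frames(phi, movie$t, function(f) detect_ps(f, config$ps_method))
  pdl <- detect_frames(phi, movie$t, function(f) detect_pdl(f, config$dphi_crit))
  cbl <- detect_frames(lat, movie$t, function(f) detect_cbl(f, config$dt_c))

  # per-frame association
  ps_list <- lapply(sort(unique(c(ps$frame, pdl$frame))), function(f) {
    associate_ps_pdl(ps[ps$frame == f, , drop = FALSE],
                     pdl[pdl$frame == f, , drop = FALSE])
  })
  ps <- if (length(ps_list)) do.call(rbind, ps_list) else {
    ps$on_pdl <- logical(0); ps$pdl_dist <- numeric(0)
    ps$pdl_component <- integer(0); ps
  }
  ps_tracked <- track_ps(ps, movie$dt_frame)
  pdl_tracked <- track_pdl(pdl, movie$dt_frame)
  list(
    phi = phi, phi_arr = phi_arr, lat = lat,
    ps = ps_tracked, ps_tracks = track_table(ps_tracked),
    pdl = pdl_tracked$defects, pdl_families = pdl_tracked$families,
    cbl = cbl,
    summary = rotor_summary(ps_tracked, pdl_tracked, movie)
  )
}
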