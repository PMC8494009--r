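#' Phase singularity detection by ring methods
#'
#' Classical PS detection on a phase frame: around each interior grid-cell
#' corner, the raw (not unwrapped) phase differences between adjacent pixels
#' on a ring are computed in cyclic order. A PS is assigned iff exactly one
#' of those differences exceeds `pi` in absolute value. The `ring2x2` method
#' uses the 4 pixels of the 2x2 plaquette; the combined `ring2x2_4x4` method
#' additionally requires that the surrounding ring of 8 pixels (the 4x4
#' perimeter without its corners) also has exactly one difference larger
#' than `pi`. The chirality is the sign of the phase winding around the
#' 2x2 ring, i.e. minus the sign of the single large raw difference: the
#' raw differences of wrapped phases telescope to zero around the ring, so
#' unwrapping the one super-`pi` jump leaves a net winding of the opposite
#' sign.
#'
#' Using raw differences is essential: a corner straddling a phase defect
#' line without winding has two large jumps (one in, one out) and is
#' correctly rejected.
#'
#' @param phi Phase matrix in `[-pi, pi)`; `NA` pixels make every ring they
#'   touch ineligible.
#' @param method `"ring2x2"` or `"ring2x2_4x4"`.
#' @return Data frame with one row per PS: corner coordinates `y`, `x`
#'   (half-integer, between pixel centers at integers), `chirality`
#'   (+1/-1) and `method`.
#' @export
detect_ps <- function(phi, method = c("ring2x2", "ring2x2_4x4")) {
  method <- match.arg(method)
  stopifnot(is.matrix(phi))
  ny <- nrow(phi); nx <- ncol(phi)
  if (method == "ring2x2_4x4" && (ny < 4 || nx < 4))
    stop("combined ring method needs at least a 4x4 grid")
  if (ny < 2 || nx < 2) stop("need at least a 2x2 grid")

  # 2x2 plaquette with corner (i + 0.5, j + 0.5); counter-clockwise ring
  # (i,j) -> (i+1,j) -> (i+1,j+1) -> (i,j+1) with y increasing downward.
  ii <- seq_len(ny - 1L); jj <- seq_len(nx - 1L)
  p1 <- phi[ii, jj, drop = FALSE]
  p2 <- phi[ii + 1L, jj, drop = FALSE]
  p3 <- phi[ii + 1L, jj + 1L, drop = FALSE]
  p4 <- phi[ii, jj + 1L, drop = FALSE]
  d1 <- p2 - p1; d2 <- p3 - p2; d3 <- p4 - p3; d4 <- p1 - p4
  big <- (abs(d1) > pi) + (abs(d2) > pi) + (abs(d3) > pi) + (abs(d4) > pi)
  ok <- !is.na(big) & big == 1L
  if (method == "ring2x2_4x4") {
    ok4 <- matrix(FALSE, ny - 1L, nx - 1L)
    ci <- seq(2L, ny - 2L); cj <- seq(2L, nx - 2L)
    if (length(ci) && length(cj)) {
      # ring of 8: perimeter of the 4x4 block, corners excluded, CCW
      offs <- list(c(-1L, 0L), c(0L, -1L), c(1L, -1L), c(2L, 0L),
                   c(2L, 1L), c(1L, 2L), c(0L, 2L), c(-1L, 1L))
      ring <- lapply(offs, function(o)
        phi[ci + o[1], cj + o[2], drop = FALSE])
      cnt <- 0
      for (k in seq_along(ring)) {
        nxt <- ring[[if (k == length(ring)) 1L else k + 1L]]
        cnt <- cnt + (abs(nxt - ring[[k]]) > pi)
      }
      ok4[ci, cj] <- !is.na(cnt) & cnt == 1L
    }
    ok <- ok & ok4
  }
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(y = numeric(0), x = numeric(0),
                      chirality = integer(0), method = character(0)))
  # chirality = winding sign = -sign of the unique super-pi raw difference
  chir <- integer(nrow(idx))
  dlist <- list(d1, d2, d3, d4)
  for (r in seq_len(nrow(idx))) {
    ds <- vapply(dlist, function(D) D[idx[r, 1], idx[r, 2]], numeric(1))
    chir[r] <- -as.integer(sign(ds[which(abs(ds) > pi)[1]]))
  }
  data.frame(y = idx[, 1] + 0.5, x = idx[, 2] + 0.5,
             chirality = chir, method = method, row.names = NULL)
}

# Group defect midpoints into connected components: two midpoints are
# adjacent when their Chebyshev distance is <= 1 (8-connectivity in 2D,
# 26-connectivity in 3D, on the half-integer midpoint lattice).
defect_components <- function(pts) {
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  cheb <- matrix(0, n, n)
  for (cn in seq_len(ncol(pts)))
    cheb <- pmax(cheb, abs(outer(pts[, cn], pts[, cn], `-`)))
  adj <- cheb <= 1 + 1e-9
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

defect_frame <- function(pts, source) {
  pts <- as.data.frame(pts)
  comp <- defect_components(as.matrix(pts))
  pts$component <- comp
  pts$source <- rep(source, nrow(pts))
  pts
}

empty_defects <- function(dim3 = FALSE, source = character(0)) {
  out <- data.frame(y = numeric(0), x = numeric(0))
  if (dim3) out$z <- numeric(0)
  out$component <- integer(0)
  out$source <- character(0)
  out
}

# Edge midpoints of a 2D lattice whose endpoint values satisfy `flag`
# (a function of the two endpoint matrices returning a logical matrix).
flag_edges2 <- function(A, flag) {
  ny <- nrow(A); nx <- ncol(A)
  # horizontal edges: (i, j) -- (i, j+1), midpoint (i, j + 0.5)
  h <- flag(A[, seq_len(nx - 1L), drop = FALSE], A[, seq_len(nx - 1L) + 1L, drop = FALSE])
  hidx <- which(h, arr.ind = TRUE)
  # vertical edges: (i, j) -- (i+1, j), midpoint (i + 0.5, j)
  v <- flag(A[seq_len(ny - 1L), , drop = FALSE], A[seq_len(ny - 1L) + 1L, , drop = FALSE])
  vidx <- which(v, arr.ind = TRUE)
  rbind(
    if (nrow(hidx)) cbind(y = hidx[, 1], x = hidx[, 2] + 0.5) else NULL,
    if (nrow(vidx)) cbind(y = vidx[, 1] + 0.5, x = vidx[, 2]) else NULL
  )
}

flag_edges3 <- function(A, flag) {
  d <- dim(A)
  out <- NULL
  for (ax in 1:3) {
    n <- d[ax]
    idx0 <- rep(list(quote(expr = )), 3); idx1 <- idx0
    idx0[[ax]] <- seq_len(n - 1L); idx1[[ax]] <- seq_len(n - 1L) + 1L
    f <- flag(do.call(`[`, c(list(A), idx0, drop = FALSE)),
              do.call(`[`, c(list(A), idx1, drop = FALSE)))
    w <- which(f, arr.ind = TRUE)
    if (nrow(w)) {
      m <- cbind(y = as.numeric(w[, 1]), x = as.numeric(w[, 2]),
                 z = as.numeric(w[, 3]))
      m[, ax] <- m[, ax] + 0.5
      out <- rbind(out, m)
    }
  }
  out
}

#' Conduction block lines from a LAT field
#'
#' Flags the midpoint of every 4-neighbour edge whose endpoints were both
#' activated (LAT > 0) and whose activation times differ by more than
#' `dt_c`. The positivity conditions exclude the wave front itself (where
#' one side has simply not been reached yet) so that only genuine block
#' remains. Midpoints are grouped into 8-connected components.
#'
#' @param lat LAT matrix (0 = never activated).
#' @param dt_c Critical activation-time difference, of order `dx / c` with
#'   `c` the plane-wave speed (see [default_config()] for per-model values).
#' @return Data frame of edge midpoints with columns `y`, `x` (half-integer
#'   on one axis), `component`, `source = "cbl_lat"`.
#' @export
detect_cbl <- function(lat, dt_c) {
  stopifnot(is.matrix(lat), dt_c > 0)
  pts <- flag_edges2(lat, function(a, b)
    !is.na(a) & !is.na(b) & a > 0 & b > 0 & abs(a - b) > dt_c)
  if (is.null(pts)) return(empty_defects())
  defect_frame(pts, "cbl_lat")
}

#' Phase defect lines from a phase field
#'
#' Flags the midpoint of every 4-neighbour edge across which the wrapped
#' phase difference `|U(phi_1 - phi_2)|` exceeds `dphi_crit` (differences of
#' `2*pi` are disregarded). Edges with an undefined endpoint are skipped.
#' Midpoints are grouped into 8-connected components.
#'
#' @param phi Phase matrix in `[-pi, pi)`.
#' @param dphi_crit Critical phase jump (radians); must lie in `(0, pi)` to
#'   be able to fire on wrapped differences (a warning is issued otherwise).
#' @return Data frame of edge midpoints (`y`, `x`, `component`,
#'   `source = "pdl_phase"`).
#' @export
detect_pdl <- function(phi, dphi_crit) {
  stopifnot(is.matrix(phi), dphi_crit > 0)
  if (dphi_crit >= pi)
    warning("dphi_crit >= pi can never fire on wrapped phase differences")
  pts <- flag_edges2(phi, function(a, b)
    !is.na(a) & !is.na(b) & abs(wrap_phase(a - b)) > dphi_crit)
  if (is.null(pts)) return(empty_defects())
  defect_frame(pts, "pdl_phase")
}

#' Phase defect lines by the cosine criterion
#'
#' Variant PDL detector thresholding the cosine of the phase difference
#' across each edge: an edge is flagged iff `cos(phi_1 - phi_2) < A`. Since
#' the cosine is near +1 in smooth tissue and near -1 across a defect, the
#' `<` comparison flags defects; it is exactly equivalent to
#' [detect_pdl()] with `dphi_crit = acos(A)`. The opposite (`>`) comparison,
#' which flags smooth tissue instead, is available behind
#' `flag_smooth = TRUE` for strict reproduction of the printed rule.
#'
#' @param phi Phase matrix.
#' @param A Cosine threshold in `[-1, 1]`.
#' @param flag_smooth If `TRUE`, use the literal `cos(dphi) > A` comparison.
#' @return Data frame of edge midpoints (`source = "pdl_cos"`).
#' @export
detect_pdl_cos <- function(phi, A, flag_smooth = FALSE) {
  stopifnot(is.matrix(phi), A >= -1, A <= 1)
  cmp <- if (flag_smooth) function(ca) ca > A else function(ca) ca < A
  pts <- flag_edges2(phi, function(a, b)
    !is.na(a) & !is.na(b) & cmp(cos(a - b)))
  if (is.null(pts)) return(empty_defects())
  defect_frame(pts, "pdl_cos")
}

#' Phase defect surfaces in a 3D phase field
#'
#' The 3D generalization of [detect_pdl()]: the wrapped-jump rule is applied
#' to every axis-aligned edge of the voxel lattice, and flagged edge
#' midpoints are grouped into 26-connected components. The resulting point
#' set samples the phase defect surface inside the wall.
#'
#' @param phi 3D phase array.
#' @param dphi_crit Critical phase jump (radians).
#' @return Data frame of edge midpoints with columns `y`, `x`, `z`,
#'   `component`, `source = "pds_phase"`.
#' @export
detect_pds <- function(phi, dphi_crit) {
  stopifnot(is.array(phi), length(dim(phi)) == 3L, dphi_crit > 0)
  pts <- flag_edges3(phi, function(a, b)
    !is.na(a) & !is.na(b) & abs(wrap_phase(a - b)) > dphi_crit)
  if (is.null(pts)) return(empty_defects(dim3 = TRUE))
  defect_frame(pts, "pds_phase")
}

# Point set of a PDL for distance queries: the flagged edge midpoints plus
# both end nodes of each flagged edge (the nodes are "part of the PDL").
pdl_points <- function(defects) {
  if (nrow(defects) == 0L)
    return(cbind(y = numeric(0), x = numeric(0), component = integer(0)))
  y <- defects$y; x <- defects$x
  horiz <- (x %% 1) != 0
  n1 <- cbind(y = ifelse(horiz, y, y - 0.5), x = ifelse(horiz, x - 0.5, x))
  n2 <- cbind(y = ifelse(horiz, y, y + 0.5), x = ifelse(horiz, x + 0.5, x))
  cbind(rbind(cbind(y = y, x = x), n1, n2),
        component = rep(defects$component, 3))
}

#' Associate phase singularities with phase defect lines
#'
#' Labels each PS as lying on / off a PDL by its minimum Euclidean distance
#' to any point of the PDL point set (flagged edge midpoints plus both end
#' nodes of each flagged edge). With PS positions at cell corners, the
#' default `max_dist = 0.75` px counts a PS as on-PDL exactly when its own
#' plaquette touches the defect (corner-to-node distance `sqrt(2)/2`).
#'
#' @param ps Data frame from [detect_ps()] (a single frame).
#' @param pdl Data frame from [detect_pdl()] / [detect_cbl()] (same frame).
#' @param max_dist On-PDL distance threshold in pixels.
#' @return `ps` with added columns `on_pdl` (logical), `pdl_dist` (pixels,
#'   `Inf` when the defect set is empty) and `pdl_component` (component id
#'   of the nearest PDL point, `NA` when off).
#' @export
associate_ps_pdl <- function(ps, pdl, max_dist = 0.75) {
  ps$on_pdl <- logical(nrow(ps))
  ps$pdl_dist <- rep(Inf, nrow(ps))
  ps$pdl_component <- rep(NA_integer_, nrow(ps))
  if (nrow(ps) == 0L || nrow(pdl) == 0L) return(ps)
  pts <- pdl_points(pdl)
  for (r in seq_len(nrow(ps))) {
    d2 <- (pts[, "y"] - ps$y[r])^2 + (pts[, "x"] - ps$x[r])^2
    k <- which.min(d2)
    ps$pdl_dist[r] <- sqrt(d2[k])
    if (ps$pdl_dist[r] <= max_dist) {
      ps$on_pdl[r] <- TRUE
      ps$pdl_component[r] <- as.integer(pts[k, "component"])
    }
  }
  ps
}

#' Frame-wise detections over a whole movie
#'
#' Runs a per-frame detector over every frame of a phase (or LAT) array and
#' binds the results with `frame` and `t` columns.
#'
#' @param x Array whose last dimension is time (phase array for
#'   `detect_ps` / `detect_pdl`, LAT array for `detect_cbl`).
#' @param times Frame times (e.g. `movie$t`).
#' @param detector A function of a single frame returning a data frame
#'   (e.g. `function(f) detect_pdl(f, 2.22)`).
#' @return A single data frame over all frames.
#' @export
detect_frames <- function(x, times, detector) {
  d <- dim(x)
  nd <- length(d)
  stopifnot(d[nd] == length(times))
  npix <- prod(d[-nd])
  out <- vector("list", d[nd])
  for (k in seq_len(d[nd])) {
    f <- array(x[(npix * (k - 1L) + 1L):(npix * k)], dim = d[-nd])
    if (nd - 1L == 2L) f <- as.matrix(f)
    det <- detector(f)
    if (nrow(det)) {
      det$frame <- k
      det$t <- times[k]
    } else {
      det$frame <- integer(0)
      det$t <- numeric(0)
    }
    out[[k]] <- det
  }
  do.call(rbind, out)
}
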