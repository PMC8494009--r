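#' Link phase singularities into tracks
#'
#' Greedy frame-to-frame linking of PS detections: a PS continues an
#' existing track when it lies at most 1 pixel away (Chebyshev distance, so
#' horizontal, vertical or diagonal moves) from that track's detection in
#' the previous frame and keeps its chirality; otherwise it starts a new
#' track. When several pairings compete, the nearest pair wins, with ties
#' broken by lowest (y, x) order of the current detection; each detection
#' joins at most one track.
#'
#' @param ps Data frame of detections over frames (from [detect_frames()]):
#'   columns `frame`, `y`, `x`, `chirality`.
#' @param dt_frame Frame interval, used to convert lifespans to time.
#' @return `ps` with an added `track` column, plus an attribute-free summary
#'   obtainable from [track_table()]. Tracks are numbered in order of birth.
#' @export
track_ps <- function(ps, dt_frame) {
  ps <- ps[order(ps$frame, ps$y, ps$x), , drop = FALSE]
  if (nrow(ps) == 0L) {
    ps$track <- integer(0)
    attr(ps, "dt_frame") <- dt_frame
    return(ps)
  }
  ps$track <- NA_integer_
  next_id <- 1L
  frames <- sort(unique(ps$frame))
  prev_rows <- integer(0)
  for (f in frames) {
    cur_rows <- which(ps$frame == f)
    linked <- rep(FALSE, length(cur_rows))
    if (length(prev_rows) && any(ps$frame[prev_rows] == f - 1L)) {
      cand <- expand.grid(ci = seq_along(cur_rows), pi_ = seq_along(prev_rows))
      cy <- ps$y[cur_rows[cand$ci]]; cx <- ps$x[cur_rows[cand$ci]]
      py <- ps$y[prev_rows[cand$pi_]]; px <- ps$x[prev_rows[cand$pi_]]
      cheb <- pmax(abs(cy - py), abs(cx - px))
      same <- ps$chirality[cur_rows[cand$ci]] == ps$chirality[prev_rows[cand$pi_]]
      cand$dist <- sqrt((cy - py)^2 + (cx - px)^2)
      cand <- cand[cheb <= 1 + 1e-9 & same, , drop = FALSE]
      if (nrow(cand)) {
        cand <- cand[order(cand$dist,
                           ps$y[cur_rows[cand$ci]], ps$x[cur_rows[cand$ci]]), ,
                     drop = FALSE]
        used_prev <- rep(FALSE, length(prev_rows))
        for (r in seq_len(nrow(cand))) {
          ci <- cand$ci[r]; pi_ <- cand$pi_[r]
          if (!linked[ci] && !used_prev[pi_]) {
            ps$track[cur_rows[ci]] <- ps$track[prev_rows[pi_]]
            linked[ci] <- TRUE
            used_prev[pi_] <- TRUE
          }
        }
      }
    }
    for (ci in which(!linked)) {
      ps$track[cur_rows[ci]] <- next_id
      next_id <- next_id + 1L
    }
    prev_rows <- cur_rows
  }
  attr(ps, "dt_frame") <- dt_frame
  ps
}

#' Per-track summary table
#'
#' @param tracked Output of [track_ps()].
#' @return Data frame with one row per track: `track`, `birth`, `death`
#'   (frame indices), `n_frames`, `chirality` and `lifespan`
#'   (`(death - birth + 1) * dt_frame`).
#' @export
track_table <- function(tracked) {
  dt_frame <- attr(tracked, "dt_frame")
  if (nrow(tracked) == 0L)
    return(data.frame(track = integer(0), birth = integer(0),
                      death = integer(0), n_frames = integer(0),
                      chirality = integer(0), lifespan = numeric(0)))
  sp <- split(tracked, tracked$track)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    track = d$track[1],
    birth = min(d$frame), death = max(d$frame),
    n_frames = length(unique(d$frame)),
    chirality = d$chirality[1]
  )))
  out$lifespan <- (out$death - out$birth + 1) * dt_frame
  out[order(out$track), , drop = FALSE]
}

#' Link phase defect components into families over time
#'
#' PDL components in consecutive frames are linked when any pair of their
#' points lies at most 1 pixel apart (Chebyshev distance). Families are the
#' connected components of this link graph over the whole recording, so
#' defect lines are allowed to branch and merge; a family's lifespan runs
#' from its earliest to its latest linked frame.
#'
#' @param defects Data frame of defect midpoints over frames (from
#'   [detect_frames()]): columns `frame`, `y`, `x`, `component`.
#' @param dt_frame Frame interval.
#' @return List with `defects` (input plus a `family` column) and
#'   `families` (one row per family: `family`, `first_frame`, `last_frame`,
#'   `lifespan = (last - first + 1) * dt_frame`).
#' @export
track_pdl <- function(defects, dt_frame) {
  if (nrow(defects) == 0L) {
    defects$family <- integer(0)
    return(list(defects = defects,
                families = data.frame(family = integer(0),
                                      first_frame = integer(0),
                                      last_frame = integer(0),
                                      lifespan = numeric(0))))
  }
  key <- paste(defects$frame, defects$component, sep = ":")
  nodes <- unique(key)
  node_id <- stats::setNames(seq_along(nodes), nodes)
  edges <- integer(0)
  frames <- sort(unique(defects$frame))
  by_frame <- split(seq_len(nrow(defects)), defects$frame)
  for (f in frames) {
    nxt <- as.character(f + 1L)
    if (is.null(by_frame[[nxt]])) next
    a_rows <- by_frame[[as.character(f)]]
    b_rows <- by_frame[[nxt]]
    dy <- abs(outer(defects$y[a_rows], defects$y[b_rows], `-`))
    dxm <- abs(outer(defects$x[a_rows], defects$x[b_rows], `-`))
    close <- pmax(dy, dxm) <= 1 + 1e-9
    if (any(close)) {
      w <- which(close, arr.ind = TRUE)
      pairs <- unique(cbind(key[a_rows[w[, 1]]], key[b_rows[w[, 2]]]))
      edges <- c(edges, rbind(node_id[pairs[, 1]], node_id[pairs[, 2]]))
    }
  }
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  fam <- igraph::components(g)$membership
  defects$family <- as.integer(fam[node_id[key]])
  sp <- split(defects$frame, defects$family)
  families <- data.frame(
    family = as.integer(names(sp)),
    first_frame = vapply(sp, min, numeric(1)),
    last_frame = vapply(sp, max, numeric(1))
  )
  families$lifespan <- (families$last_frame - families$first_frame + 1) * dt_frame
  rownames(families) <- NULL
  list(defects = defects, families = families)
}

#' Dominant frequency of a recording
#'
#' Frequency of the largest spectral peak (zero bin excluded) of the
#' spatially averaged, mean-subtracted voltage trace. The reciprocal is the
#' dominant activation period, the natural choice for the arrival-phase
#' time constant `tau`.
#'
#' @param movie A [pd_movie()] spanning at least two activation periods.
#' @return List with `frequency` and `period` (in the reciprocal/units of
#'   the movie's time base: Hz if `dt_frame` is in seconds, kHz-equivalent
#'   cycles/ms if in ms).
#' @export
dominant_frequency <- function(movie) {
  d <- dim(movie$V)
  nd <- length(d)
  nt <- d[nd]
  flat <- matrix(movie$V, ncol = nt)
  tr <- colMeans(flat, na.rm = TRUE)
  tr <- tr - mean(tr)
  if (max(abs(tr)) == 0) stop("flat signal: no dominant frequency")
  spec <- Mod(stats::fft(tr))[seq_len(floor(nt / 2) + 1L)]
  spec[1] <- 0
  k <- which.max(spec)
  f <- (k - 1) / (nt * movie$dt_frame)
  list(frequency = f, period = 1 / f)
}

#' Recording-level summary statistics
#'
#' Computes the per-recording summary of PS and PDL behaviour: detection
#' densities, co-location of PSs with PDLs, birth rates, lifespans and the
#' dominant frequency of activation.
#'
#' @param ps_tracked Output of [track_ps()] where rows additionally carry
#'   `on_pdl` and `pdl_component` columns from [associate_ps_pdl()].
#' @param pdl_tracked Output of [track_pdl()].
#' @param movie The analysed [pd_movie()].
#' @return One-row data frame with columns `ps_per_frame`,
#'   `pdl_per_frame`, `frac_ps_off_pdl`, `pdl_without_ps_per_frame`,
#'   `new_ps_per_frame`, `new_pdl_per_frame`, `frac_ps_never_on_pdl`,
#'   `frac_pdl_never_hosting_ps`, `dominant_frequency`, `dominant_period`,
#'   `mean_ps_lifespan`, `mean_pdl_lifespan`.
#' @export
rotor_summary <- function(ps_tracked, pdl_tracked, movie) {
  nf <- n_frames(movie)
  dt_frame <- movie$dt_frame
  defects <- pdl_tracked$defects
  families <- pdl_tracked$families
  tt <- track_table(ps_tracked)

  comp_per_frame <- if (nrow(defects)) {
    mean(vapply(split(defects$component, defects$frame),
                function(x) length(unique(x)), numeric(1))) *
      length(unique(defects$frame)) / nf
  } else 0

  # components not hosting any PS, averaged over all frames
  pdl_wo_ps <- if (nrow(defects)) {
    per_frame <- vapply(sort(unique(defects$frame)), function(f) {
      comps <- unique(defects$component[defects$frame == f])
      hosting <- unique(ps_tracked$pdl_component[
        ps_tracked$frame == f & isTRUE_vec(ps_tracked$on_pdl)])
      length(setdiff(comps, hosting))
    }, numeric(1))
    sum(per_frame) / nf
  } else 0

  frac_off <- if (nrow(ps_tracked)) mean(!ps_tracked$on_pdl) else NA_real_

  frac_never_on <- if (nrow(tt)) {
    ever_on <- vapply(split(ps_tracked$on_pdl, ps_tracked$track), any, logical(1))
    mean(!ever_on)
  } else NA_real_

  frac_pdl_never_ps <- if (nrow(families)) {
    on <- ps_tracked[isTRUE_vec(ps_tracked$on_pdl), , drop = FALSE]
    hosting_fams <- unique(defects$family[
      paste(defects$frame, defects$component) %in%
        paste(on$frame, on$pdl_component)])
    mean(!(families$family %in% hosting_fams))
  } else NA_real_

  df <- tryCatch(dominant_frequency(movie),
                 error = function(e) list(frequency = NA_real_, period = NA_real_))

  data.frame(
    ps_per_frame = nrow(ps_tracked) / nf,
    pdl_per_frame = comp_per_frame,
    frac_ps_off_pdl = frac_off,
    pdl_without_ps_per_frame = pdl_wo_ps,
    new_ps_per_frame = nrow(tt) / nf,
    new_pdl_per_frame = nrow(families) / nf,
    frac_ps_never_on_pdl = frac_never_on,
    frac_pdl_never_hosting_ps = frac_pdl_never_ps,
    dominant_frequency = df$frequency,
    dominant_period = df$period,
    mean_ps_lifespan = if (nrow(tt)) mean(tt$lifespan) else NA_real_,
    mean_pdl_lifespan = if (nrow(families)) mean(families$lifespan) else NA_real_
  )
}

isTRUE_vec <- function(x) !is.na(x) & x
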