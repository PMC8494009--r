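test_that("wrap_phase maps differences into [-pi, pi) with the stated tie rule", {
  expect_identical(wrap_phase(0), 0)
  expect_equal(wrap_phase(5.0), 5.0 - 2 * pi)
  expect_equal(wrap_phase(pi), -pi)  # boundary -> negative representative
  expect_equal(wrap_phase(-pi), -pi)
  x <- seq(-20, 20, by = 0.37)
  w <- wrap_phase(x)
  expect_true(all(w >= -pi & w < pi))
  expect_equal(sin(w), sin(x), tolerance = 1e-12)
  expect_equal(cos(w), cos(x), tolerance = 1e-12)
})

test_that("wrapped differences are antisymmetric away from the pi boundary", {
  set.seed(11)
  a <- runif(200, -pi, pi); b <- runif(200, -pi, pi)
  off <- abs(abs(wrap_phase(a - b)) - pi) > 1e-9
  expect_equal(wrap_phase(a - b)[off], -wrap_phase(b - a)[off])
})

test_that("activation phase is the polar angle about (V_star, R_star)", {
  Vs <- 0.5; Rs <- 0.3
  V <- matrix(c(Vs + 1, Vs, Vs - 1, Vs), 2, 2)
  R <- matrix(c(Rs, Rs + 1, Rs, Rs), 2, 2)
  phi <- activation_phase(V, R, Vs, Rs)
  expect_equal(phi[1, 1], 0)
  expect_equal(phi[2, 1], pi / 2)
  expect_equal(phi[1, 2], -pi)   # pi wraps to the storage representative
  expect_true(is.na(phi[2, 2]))  # exactly at the reference point
  # the offset b rotates and re-wraps
  expect_equal(activation_phase(V, R, Vs, Rs, b = pi / 2)[1, 1], pi / 2)
  expect_error(activation_phase(V, R[1, , drop = FALSE], Vs, Rs), "same shape")
})

test_that("hilbert phase winds once per period on the sinusoid movie", {
  m <- cached_fixture("sinusoid_movie")
  phi <- hilbert_phase(m)
  tr <- phi[5, 5, ]
  wraps <- sum(abs(diff(tr)) > pi)
  expect_true(abs(wraps - 20) <= 1)  # f*T = 20 periods recorded
  expect_true(all(phi[!is.na(phi)] >= -pi & phi[!is.na(phi)] < pi))
})

test_that("constant pixel traces give undefined hilbert phase", {
  V <- array(0.5, dim = c(4, 4, 64))
  V[1, 1, ] <- 0.5 + 0.3 * sin(2 * pi * (0:63) / 16)
  m <- pd_movie(V, dt_frame = 1, dx = 1)
  phi <- hilbert_phase(m)
  expect_true(all(is.na(phi[2, 2, ])))
  expect_true(all(!is.na(phi[1, 1, ])))
})

test_that("LAT updates keep the newest upward crossing and the 0 sentinel", {
  lat <- matrix(0, 1, 3)
  # pixel 1: 0.2, 0.4, 0.6 -> crossing between frames 2 and 3
  # pixel 2: never exceeds V_star; pixel 3: two upstrokes, keeps the newest
  f <- function(v1, v2, v3) matrix(c(v1, v2, v3), 1, 3)
  lat <- update_lat(lat, f(0.2, 0.1, 0.2), f(0.4, 0.2, 0.6), 2, 0.5)
  expect_equal(as.numeric(lat), c(0, 0, 2))
  lat <- update_lat(lat, f(0.4, 0.2, 0.6), f(0.6, 0.3, 0.2), 3, 0.5)
  expect_equal(as.numeric(lat), c(3, 0, 2))
  lat <- update_lat(lat, f(0.6, 0.3, 0.2), f(0.7, 0.4, 0.7), 4, 0.5)
  expect_equal(as.numeric(lat), c(3, 0, 4))  # "newest LAT" overwrites
})

test_that("movie LAT is per-pixel non-decreasing and positive once activated", {
  m <- ap_plane_movie()
  lat <- movie_lat(m, 0.5)
  tr <- lat[6, 60, ]
  expect_true(all(diff(tr) >= 0))
  expect_true(all(tr[tr > 0] > 0))
  expect_equal(tr[1], 0)  # nothing can be assigned at the first frame
})

test_that("arrival phase follows the saturating tanh of elapsed time", {
  lat <- matrix(c(10, 0), 1, 2)
  expect_equal(arrival_phase(10, lat, tau = 20)[1, 1], 0)
  expect_true(is.na(arrival_phase(10, lat, tau = 20)[1, 2]))
  # t_elapsed = tau: 2*pi*tanh(3) = 6.2521 -> wraps to about -0.0311
  phi <- arrival_phase(30, lat, tau = 20)[1, 1]
  expect_equal(phi, wrap_phase(2 * pi * tanh(3)), tolerance = 1e-12)
  expect_equal(phi, -0.0311, tolerance = 1e-3)
  # saturation: recovered tissue is phase-equivalent to rest
  expect_equal(abs(arrival_phase(1e6, lat, tau = 20)[1, 1]), 0, tolerance = 1e-9)
  expect_error(arrival_phase(10, lat, tau = 0), "tau")
})

test_that("arrival phase advances monotonically through one cycle between activations", {
  # between LAT updates the phase drifts forward along the tanh (fast when
  # young, saturating to 2*pi total); it can only reset where LAT updates
  m <- ap_plane_movie()
  lat <- movie_lat(m, 0.5)
  pa <- movie_arrival_phase(m, tau = 20, V_star = 0.5, lat = lat)
  tr <- pa[6, 60, ]
  latr <- lat[6, 60, ]
  defined <- which(!is.na(tr))
  incr <- wrap_phase(diff(tr[defined]))
  lat_changed <- diff(latr[defined]) != 0
  expect_true(all(incr[!lat_changed] >= -1e-9))
  expect_lte(sum(incr[!lat_changed]), 2 * pi)
})

test_that("wrapped phase gradients ignore 2*pi jumps", {
  const <- matrix(1.3, 5, 5)
  g <- phase_gradient(const, dx = 1)
  expect_true(all(g[1:4, 1:4] == 0))
  ramp <- wrap_phase(matrix(rep(0.1 * (1:30), each = 5), 5, 30))
  g <- phase_gradient(ramp, dx = 1)
  expect_equal(max(abs(g[1:4, 1:29] - 0.1)), 0, tolerance = 1e-12)
  # a raw step of 3.0 is below pi and survives unwrapping unchanged;
  # a step of 3.5 exceeds pi and unwraps to 3.5 - 2*pi (magnitude 2.7832)
  stepf <- matrix(c(0, 3, 0, 3), 2, 2)
  expect_equal(phase_gradient(stepf, dx = 1)[1, 1], 3, tolerance = 1e-12)
  stepf2 <- wrap_phase(matrix(c(0, 3.5, 0, 3.5), 2, 2))
  expect_equal(phase_gradient(stepf2, dx = 1)[1, 1], abs(3.5 - 2 * pi),
               tolerance = 1e-12)
  # undefined neighbours poison the gradient
  ramp[2, 3] <- NA
  expect_true(is.na(phase_gradient(ramp, 1)[2, 2]))
})

test_that("phase levels are the circular means at threshold crossings", {
  # synthetic cycle V = V* + cos(theta), R = R* + sin(theta), theta rising:
  # upward V crossings at theta = -pi/2 (phase -pi/2), downward at +pi/2
  nt <- 200
  theta <- 2 * pi * (0:(nt - 1)) / 50
  V <- array(rep(0.5 + cos(theta), each = 4), dim = c(2, 2, nt))
  R <- array(rep(0.3 + sin(theta), each = 4), dim = c(2, 2, nt))
  m <- pd_movie(V, dt_frame = 1, dx = 1, R = R)
  phi <- activation_phase(V, R, 0.5, 0.3)
  lev <- phase_levels(m, phi, 0.5)
  expect_equal(lev$phi1, -pi / 2, tolerance = 0.1)
  expect_equal(lev$phi2, pi / 2, tolerance = 0.1)

  quiet <- pd_movie(array(0, c(2, 2, 10)), 1, 1, R = array(0, c(2, 2, 10)))
  expect_error(phase_levels(quiet, array(0, c(2, 2, 10)), 0.5), "upstroke")
})

test_that("phase levels differ between upstroke and downstroke of a plane wave", {
  m <- ap_plane_movie()
  phi <- movie_activation_phase(m, 0.5, 1)
  lev <- phase_levels(m, phi, 0.5)
  expect_gt(abs(wrap_phase(lev$phi1 - lev$phi2)), 0.5)
})

test_that("wave front and wave back are disjoint parallel bands on a plane wave", {
  m <- ap_plane_movie()
  k <- which.min(abs(m$t - 40))
  fr <- wave_fronts(m$V[, , k - 1], m$V[, , k], 0.5)
  expect_gt(nrow(fr$WF), 0)
  expect_gt(nrow(fr$WB), 0)
  expect_equal(nrow(merge(as.data.frame(fr$WF), as.data.frame(fr$WB))), 0)
  # bands: each set spans all rows within a narrow column range
  expect_equal(sort(unique(fr$WF[, "y"])), 1:12)
  expect_lte(diff(range(fr$WF[, "x"])), 3)
  expect_lte(diff(range(fr$WB[, "x"])), 3)
  # the front is ahead of the back, separated by the pulse width
  expect_gt(min(fr$WF[, "x"]), max(fr$WB[, "x"]))

  quiet <- matrix(0, 5, 5)
  fr0 <- wave_fronts(quiet, quiet, 0.5)
  expect_equal(nrow(fr0$WF) + nrow(fr0$WB), 0L)
})

test_that("plane waves are invisible to the arrival phase", {
  # no conduction block: the phi_arr jump across any edge stays far below
  # the activation-phase defect threshold (2.22 rad)
  m <- ap_plane_movie()
  lat <- movie_lat(m, 0.5)
  pa <- movie_arrival_phase(m, tau = 20, V_star = 0.5, lat = lat)
  worst <- 0
  for (k in seq(10, dim(pa)[3], 5)) {
    g <- phase_gradient(pa[, , k], dx = 1)  # per-pixel jump in rad/px
    worst <- max(worst, max(g, na.rm = TRUE))
  }
  expect_lt(worst, 2.22)
})

test_that("defect thickness follows the diffusion boundary-layer estimate", {
  expect_equal(round(defect_thickness(1.171, 269), 1), 5.6)
  expect_equal(round(defect_thickness(1.171, 269, 2.5), 0), 14)
  expect_equal(defect_thickness(0, 100), 0)
  expect_error(defect_thickness(-1, 10), "non-negative")
  expect_error(defect_thickness(1, 10, 0.5), "anisotropy")
})

test_that("arrival phase is a monotone reparameterization of activation phase on a plane wave", {
  m <- ap_plane_movie()
  lat <- movie_lat(m, 0.5)
  pa <- movie_arrival_phase(m, tau = 20, V_star = 0.5, lat = lat)
  phi <- movie_activation_phase(m, 0.5, 1, b = pi / 2)  # rest (0,0) -> 0
  # follow one pixel between its activation and the end of the recording:
  # both phases advance monotonically through one cycle
  tr_a <- phi[6, 30, ]; tr_b <- pa[6, 30, ]
  defined <- which(!is.na(tr_b))
  a <- cumsum(c(tr_a[defined][1], wrap_phase(diff(tr_a[defined]))))
  b <- cumsum(c(tr_b[defined][1], wrap_phase(diff(tr_b[defined]))))
  expect_gt(cor(a, b, method = "spearman"), 0.9)
})

test_that("hilbert and activation phase localize the rotor tip on the same defect", {
  res <- fk_rotor_analysis()
  m <- res$movie
  ph <- hilbert_phase(m)
  phi <- res$phi
  # one defect-layer width sqrt(D*tau)/dx ~ 15 px at this resolution
  layer_px <- sqrt(0.1 * 162) / m$dx
  near <- vapply(seq_along(m$t), function(k) {
    a <- detect_ps(phi[, , k], "ring2x2")
    b <- detect_ps(ph[, , k], "ring2x2")
    if (nrow(a) == 0 || nrow(b) == 0) return(NA)
    d <- min(sqrt(outer(a$y, b$y, "-")^2 + outer(a$x, b$x, "-")^2))
    d <= layer_px
  }, logical(1))
  expect_gt(sum(!is.na(near)), 100)
  expect_gt(mean(near, na.rm = TRUE), 0.8)
})

test_that("arrival and activation phase are rank-associated on the rotor", {
  res <- fk_rotor_analysis()
  b <- -atan2(0 - 0.8, 0 - 0.5)
  phi0 <- activation_phase(res$movie$V[, , 200], res$movie$R[, , 200],
                           0.5, 0.8, b = b)
  pa <- res$phi_arr[, , 200]
  g <- phase_gradient(pa, 1)
  ok <- !is.na(phi0) & !is.na(pa) & !is.na(g) & g < 1  # exclude defect pixels
  expect_gt(cor(phi0[ok] %% (2 * pi), pa[ok] %% (2 * pi),
                method = "spearman"), 0.4)
})
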