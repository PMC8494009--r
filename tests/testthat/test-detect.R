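test_that("the 2x2 ring detects a hand-built vortex plaquette", {
  # ring order (1,1) -> (2,1) -> (2,2) -> (1,2): phases 0, pi/2, pi, 3pi/2
  # (stored wrapped). Raw cyclic diffs: pi/2, pi/2 (to -pi after wrap of pi
  # ... evaluated on stored values), exactly one super-pi jump.
  phi <- matrix(0, 2, 2)
  phi[1, 1] <- 0; phi[2, 1] <- pi / 2
  phi[2, 2] <- wrap_phase(pi); phi[1, 2] <- wrap_phase(3 * pi / 2)
  ps <- detect_ps(phi, "ring2x2")
  expect_equal(nrow(ps), 1L)
  expect_equal(c(ps$y, ps$x), c(1.5, 1.5))
  # winding of this ring is +1; chirality follows the winding
  expect_equal(ps$chirality, winding_oracle(phi)[1, 1])
})

test_that("uniform and defect-straddling fields yield no phase singularity", {
  expect_equal(nrow(detect_ps(matrix(1, 6, 6), "ring2x2")), 0L)
  # two super-pi jumps across a defect line (no winding) must be rejected
  phi <- matrix(c(0, 0, 3.2, 3.2), 2, 2)
  expect_equal(nrow(detect_ps(wrap_phase(phi), "ring2x2")), 0L)
  expect_equal(nrow(detect_ps(straddle_field(8), "ring2x2")), 0L)
})

test_that("ring detections skip plaquettes touching undefined pixels", {
  f <- random_vortex_field(10)
  phi <- f$phi
  ps0 <- detect_ps(phi, "ring2x2")
  expect_equal(nrow(ps0), 1L)
  phi[floor(f$centre[1]), floor(f$centre[2])] <- NA
  expect_equal(nrow(detect_ps(phi, "ring2x2")), 0L)
})

test_that("the combined 2x2+4x4 ring confirms vortices and needs a 4x4 grid", {
  set.seed(21)
  hits <- 0L
  for (i in 1:25) {
    f <- random_vortex_field(14, amp = 0.4)
    ps <- detect_ps(f$phi, "ring2x2_4x4")
    if (nrow(ps) == 1 &&
        max(abs(c(ps$y, ps$x) - (floor(f$centre) + 0.5))) <= 1) hits <- hits + 1L
  }
  expect_gte(hits, 22)  # the outer ring occasionally rejects near-edge cases
  expect_error(detect_ps(matrix(0, 3, 3), "ring2x2_4x4"), "4x4")
})

test_that("ring2x2 equals the winding-number oracle on smooth+vortex fields", {
  set.seed(31)
  for (i in 1:150) {
    f <- random_vortex_field(12)
    ps <- detect_ps(f$phi, "ring2x2")
    w <- winding_oracle(f$phi)
    hit <- which(w != 0, arr.ind = TRUE)
    expect_equal(nrow(ps), nrow(hit))
    if (nrow(ps) == nrow(hit) && nrow(ps) > 0) {
      ord <- order(ps$y, ps$x); ord2 <- order(hit[, 1], hit[, 2])
      expect_equal(ps$y[ord], as.numeric(hit[ord2, 1]) + 0.5)
      expect_equal(ps$x[ord], as.numeric(hit[ord2, 2]) + 0.5)
      expect_equal(ps$chirality[ord],
                   as.integer(w[hit[ord2, , drop = FALSE]]))
    }
  }
})

test_that("conduction block edges require bilateral activation and a large LAT jump", {
  lat <- matrix(c(10, 12, 100, 102), 1, 4)
  cbl <- detect_cbl(lat, dt_c = 16)
  expect_equal(nrow(cbl), 1L)
  expect_equal(c(cbl$y, cbl$x), c(1, 2.5))  # between cells 2 and 3
  expect_equal(nrow(detect_cbl(matrix(c(10, 0), 1, 2), 5)), 0L)
  expect_equal(nrow(detect_cbl(matrix(50, 4, 4), 5)), 0L)
  expect_error(detect_cbl(matrix(1, 2, 2), dt_c = 0))
})

test_that("phase defect edges threshold the wrapped jump and ignore 2*pi", {
  row <- matrix(c(0.1, 0.1, 2.9, 2.9), 1, 4)
  pdl <- detect_pdl(row, 2)
  expect_equal(nrow(pdl), 1L)
  expect_equal(c(pdl$y, pdl$x), c(1, 2.5))
  # a difference of 2*pi - 0.2 unwraps to -0.2: not a defect
  row2 <- wrap_phase(matrix(c(0.1, 0.1 + 2 * pi - 0.2), 1, 2))
  expect_equal(nrow(detect_pdl(row2, 2)), 0L)
  expect_equal(nrow(detect_pdl(matrix(1, 5, 5), 2)), 0L)
  expect_warning(detect_pdl(matrix(c(0, 3), 1, 2), pi), "never fire")
  # undefined endpoints are skipped
  row3 <- matrix(c(0.1, NA, 2.9), 1, 3)
  expect_equal(nrow(detect_pdl(row3, 2)), 0L)
})

test_that("defect monotonicity: lower thresholds flag supersets of edges", {
  set.seed(41)
  for (i in 1:20) {
    f <- random_vortex_field(12)
    a <- detect_pdl(f$phi, 1.2)
    b <- suppressWarnings(detect_pdl(f$phi, 2.5))
    expect_true(all(paste(b$y, b$x) %in% paste(a$y, a$x)))
  }
})

test_that("the cosine-threshold detector is exactly the arccos-equivalent rule", {
  expect_equal(nrow(detect_pdl_cos(matrix(c(0, 3), 1, 2), A = 0)), 1L)
  expect_equal(nrow(detect_pdl_cos(matrix(1, 4, 4), A = 0.9)), 0L)
  set.seed(51)
  for (i in 1:20) {
    f <- random_vortex_field(12)
    a <- detect_pdl(f$phi, 2.22)
    b <- detect_pdl_cos(f$phi, cos(2.22))
    expect_identical(a[c("y", "x", "component")], b[c("y", "x", "component")])
  }
  # the printed comparison direction flags smooth tissue instead
  smooth <- matrix(seq(0, 0.5, length.out = 4), 2, 2)
  expect_gt(nrow(detect_pdl_cos(smooth, A = cos(2.22), flag_smooth = TRUE)), 0)
})

test_that("3D defect surfaces extrude 2D defect lines and group by 26-connectivity", {
  base <- straddle_field(8)
  vol <- array(base, dim = c(8, 8, 5))
  pds <- detect_pds(vol, 2)
  pdl <- detect_pdl(base, 2)
  expect_equal(nrow(pds), nrow(pdl) * 5)  # in-plane edges replicated per layer
  expect_equal(length(unique(pds$component)), 1L)
  expect_equal(nrow(detect_pds(array(1, c(5, 5, 5)), 2)), 0L)
})

test_that("the 3D slab fixture has a block surface meeting the bottom-surface defect line", {
  m <- cached_fixture("fk_scroll_3d_small")
  cfg <- default_config("fk", dim = 3)
  lat <- movie_lat(m, cfg$V_star)
  pa <- movie_arrival_phase(m, cfg$tau, cfg$V_star, lat = lat)
  post <- which(m$t > m$t_s2 + 10 & m$t < m$t_s2 + 60)
  found <- FALSE
  for (k in post) {
    pds <- detect_pds(pa[, , , k], cfg$dphi_arr_crit)
    if (nrow(pds) == 0) next
    bot <- detect_pdl(pa[, , 1, k], cfg$dphi_arr_crit)
    if (nrow(bot) > 0 && sum(pds$z <= 1.5) > 0) {
      found <- TRUE
      # the surface's bottom layer contains the surface-detected line
      expect_true(all(paste(bot$y, bot$x) %in%
                        paste(pds$y[pds$z == 1], pds$x[pds$z == 1])))
      break
    }
  }
  expect_true(found)
})

test_that("PS-PDL association uses plaquette-scale distance", {
  ps <- data.frame(y = 2.5, x = 2.5, chirality = 1L, method = "ring2x2")
  pdl <- data.frame(y = 2, x = 2.5, component = 1L, source = "pdl_phase")
  out <- associate_ps_pdl(ps, pdl)
  expect_true(out$on_pdl)
  expect_equal(out$pdl_dist, 0.5)
  expect_equal(out$pdl_component, 1L)
  far <- data.frame(y = 8, x = 8.5, component = 1L, source = "pdl_phase")
  expect_false(associate_ps_pdl(ps, far)$on_pdl)
  none <- associate_ps_pdl(ps, far[0, ])
  expect_false(none$on_pdl)
  expect_equal(none$pdl_dist, Inf)
})
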