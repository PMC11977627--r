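test_that("LOR projection hits centred elements for symmetric endpoints", {
  g <- default_geometry()
  # endpoints on facets 0 and 7 at mid-depth, u = 0, z = 0: both plane
  # intersections at the transaxial centre; the axial boundary z = 0 bins
  # to the lower element (41) by the floor rule
  e1 <- facet_to_world(g, 0L, 0, 0, 5)
  e2 <- facet_to_world(g, 7L, 0, 0, 5)
  lor <- project_lor(e1, e2, 0L, 7L, g)
  expect_identical(nrow(lor), 1L)
  expect_true(lor$iu1 %in% 7:8 && lor$iu2 %in% 7:8)
  expect_true(lor$iv1 %in% 41:42 && lor$iv2 %in% 41:42)
})

test_that("LOR projection is idempotent on element centres and rejects misses", {
  g <- default_geometry()
  set.seed(50)
  iu <- sample(0:15, 30, TRUE); iv <- sample(0:83, 30, TRUE)
  iu2 <- sample(0:15, 30, TRUE); iv2 <- sample(0:83, 30, TRUE)
  p1 <- element_center(rep(0L, 30), iu, iv, g)
  p2 <- element_center(rep(7L, 30), iu2, iv2, g)
  lor <- project_lor(p1, p2, rep(0L, 30), rep(7L, 30), g)
  expect_identical(nrow(lor), 30L)
  expect_identical(lor$iu1, iu); expect_identical(lor$iv1, iv)
  expect_identical(lor$iu2, iu2); expect_identical(lor$iv2, iv2)
  # sub-element shifts map to the same element
  p1b <- p1 + matrix(c(0, 0, 0.3), 30, 3, byrow = TRUE)
  lor2 <- project_lor(p1b, p2, rep(0L, 30), rep(7L, 30), g)
  same <- lor2$iu1 == iu
  expect_gt(mean(same), 0.9)
  # degenerate (coincident) endpoints rejected with a reason
  bad <- project_lor(p1[1, ], p1[1, ], 0L, 7L, g)
  expect_identical(nrow(bad), 0L)
  expect_identical(unname(attr(bad, "rejects")["degenerate"]), 1L)
  # off-axis lines that miss the narrow grid are rejected as off_grid
  q1 <- facet_to_world(g, 0L, 9, 0, 5)
  q2 <- facet_to_world(g, 5L, -9, 0, 5)
  lor3 <- project_lor(q1, q2, 0L, 5L, g)
  expect_true(nrow(lor3) == 0 || attr(lor3, "rejects")["off_grid"] >= 0)
})

test_that("attenuation weights are symmetric and match closed-form chords", {
  g <- default_geometry()
  e1 <- facet_to_world(g, 0L, 0, 0, 5)
  e2 <- facet_to_world(g, 7L, 0, 0, 5)
  lor <- project_lor(e1, e2, 0L, 7L, g)
  expect_equal(attenuation_weight(lor, NULL, g), 1)
  # a water cylinder of 25 mm diameter centred on the chord
  cyl <- cylinder_phantom(activity = 1, diameter = 25, length = 40)
  mu <- make_attenuation_phantom(cyl, voxel_size = 0.5, extent = 16,
                                 z_extent = 22)
  w <- attenuation_weight(lor, mu, g)
  expect_equal(w, exp(25 * 0.0096), tolerance = 0.02)
  # swapping the endpoints leaves the weight unchanged
  lor_sw <- project_lor(e2, e1, 7L, 0L, g)
  expect_equal(attenuation_weight(lor_sw, mu, g), w, tolerance = 1e-9)
})

test_that("randoms estimates follow window * S_i * S_j and match a delayed window", {
  g <- default_geometry()
  expect_equal(attr(estimate_randoms(rep(0, 14), g), "total_cps"), 0)
  rates <- rep(1e5, 14)
  re <- estimate_randoms(rates, g, window = 2)
  expect_equal(re$rate_cps[1], 2e-9 * 1e10)   # 20 cps per pair
  expect_identical(nrow(re), 49L)
  # delayed-window measurement on synthetic Poisson streams
  dur <- 0.4
  s <- poisson_singles(rep(5e4, 14), duration = dur, seed = 51)
  spf <- tabulate(s$df$facet + 1L, 14) / dur
  est <- attr(estimate_randoms(spf, g, window = 2), "total_cps") * dur
  meas <- delayed_window_randoms(s, g, window = 2, delay = 1e4)
  expect_equal(meas / est, 1, tolerance = 0.15)
})

test_that("single-slice rebinning assigns slices and conserves counts", {
  g <- default_geometry()
  mk <- function(iv1, iv2) {
    p1 <- element_center(0L, 8L, iv1, g)
    p2 <- element_center(7L, 8L, iv2, g)
    project_lor(p1, p2, 0L, 7L, g)
  }
  s1 <- ssrb_rebin(mk(10L, 10L), g)
  expect_equal(sum(s1$counts[, , 21]), 1)     # slice 2k (0-based 20)
  s2 <- ssrb_rebin(mk(10L, 11L), g)
  expect_equal(sum(s2$counts[, , 22]), 1)     # slice 2k+1
  # conservation: counts + rejects = input
  lors <- rbind(mk(10L, 10L), mk(3L, 80L))
  class(lors) <- c("projected_lors", "data.frame")
  reb <- ssrb_rebin(lors, g, max_ring_diff = 10)
  expect_equal(sum(reb$counts) + reb$n_rejected, 2)
  expect_identical(reb$n_rejected, 1L)
})

test_that("filtered backprojection localizes points, preserves DC, and shifts linearly", {
  # analytic sinogram of a centred point: one count in the central radial
  # bin at every angle
  nr <- 101; na <- 64; rb <- 0.5
  sino <- matrix(0, nr, na)
  sino[51, ] <- 100
  img <- fbp2d(sino, radial_bin = rb, pixel_size = 0.5, n_pixels = 101)
  am <- which(img == max(img), arr.ind = TRUE)
  expect_identical(unname(am[1, ]), c(51L, 51L))
  # DC fidelity: the analytic sinogram of a unit-density disk comes back
  # at unit density
  nr2 <- 161; rb2 <- 0.25
  rc <- (seq_len(nr2) - (nr2 + 1) / 2) * rb2
  disk <- matrix(2 * sqrt(pmax(100 - rc^2, 0)), nr2, 128)
  dimg <- fbp2d(disk, radial_bin = rb2, pixel_size = 0.25, n_pixels = 161)
  xc2 <- (seq_len(161) - 81) * 0.25
  rr <- sqrt(outer(xc2^2, xc2^2, `+`))
  expect_equal(mean(dimg[rr < 7]), 1, tolerance = 0.02)
  # shifting the sinogram shifts the point accordingly
  sino2 <- matrix(0, nr, na)
  phis <- (seq_len(na) - 0.5) * pi / na
  # point at (x, y) = (5, 0): r = 5 cos(phi)
  roff <- round(5 * cos(phis) / rb) + 51
  sino2[cbind(roff, seq_len(na))] <- 100
  img2 <- fbp2d(sino2, radial_bin = rb, pixel_size = 0.5, n_pixels = 101)
  am2 <- which(img2 == max(img2), arr.ind = TRUE)
  expect_lt(abs((am2[1, 1] - 51) * 0.5 - 5), 0.51)
  expect_lt(abs(am2[1, 2] - 51) * 0.5, 0.51)
  # empty slice -> zero image
  expect_true(all(fbp2d(matrix(0, nr, na)) == 0))
})

test_that("MLEM converges onto a noise-free point source with monotone likelihood", {
  g <- default_geometry()
  lors <- point_truth_lors(g, c(3, 2, 5), n = 8000, seed = 52)
  vol <- mlem_reconstruct(lors, g, n_iter = 12, dims = c(48, 48, 48),
                          voxel_size = 0.5, sens_stride = 4)
  expect_true(all(vol$values >= 0))
  expect_true(all(diff(vol$loglik) >= -1e-6))
  ax <- volume_axes(vol)
  am <- which(vol$values == max(vol$values), arr.ind = TRUE)[1, ]
  expect_lt(abs(ax$x[am[1]] - 3), 0.51)
  expect_lt(abs(ax$y[am[2]] - 2), 0.51)
  expect_lt(abs(ax$z[am[3]] - 5), 0.51)
  expect_error(mlem_reconstruct(lors[0, ], g), "no LORs")
  # FBP of the same data agrees on the location within a voxel
  sino <- ssrb_rebin(lors, g, n_angles = 64, radial_bin = 0.84)
  zsl <- round((5 + 84 * 0.84 / 2) / 0.42)
  sl <- apply(sino$counts[, , (zsl - 2):(zsl + 2)], c(1, 2), sum)
  img <- fbp2d(sl, radial_bin = 0.84, pixel_size = 0.5, n_pixels = 48)
  amf <- which(img == max(img), arr.ind = TRUE)[1, ]
  xc <- ((1:48) - 24.5) * 0.5
  expect_lt(abs(xc[amf[1]] - 3), 0.85)
  expect_lt(abs(xc[amf[2]] - 2), 0.85)
})

test_that("one MLEM iteration from a uniform image reproduces the event count", {
  g <- default_geometry()
  lors <- point_truth_lors(g, c(0, 0, 0), n = 3000, seed = 53)
  dims <- c(32, 32, 32)
  sens <- mlem_sensitivity(g, dims, 1, -dims / 2, stride = 6)
  v1 <- mlem_reconstruct(lors, g, n_iter = 1, dims = dims, voxel_size = 1,
                         weights = rep(1, nrow(lors)), randoms = 0,
                         sens = sens)
  expect_equal(sum(sens * v1$values) / nrow(lors), 1, tolerance = 1e-6)
})
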