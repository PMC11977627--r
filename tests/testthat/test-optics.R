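test_that("expected light is linear in deposited energy and transaxially symmetric", {
  g <- default_geometry()
  m <- optical_model()
  p <- facet_to_world(g, 0L, 0, 0, 4)
  ints1 <- data.frame(x = p[1], y = p[2], z = p[3], edep = 200)
  ints2 <- ints1; ints2$edep <- 400
  m1 <- expected_light_map(ints1, m, g)
  m2 <- expected_light_map(ints2, m, g)
  expect_equal(unclass(m2), 2 * unclass(m1), tolerance = 1e-12)
  # on the facet axis (u = 0, z = 0) the facet-0 map is symmetric under
  # transaxial and axial mirroring
  f0 <- m1[, , 1]
  expect_equal(f0, f0[rev(seq_len(nrow(f0))), ], tolerance = 1e-6)
  expect_equal(f0, f0[, rev(seq_len(ncol(f0)))], tolerance = 1e-6)
  # neighbouring facet maps mirror each other
  expect_equal(m1[, , 2], m1[rev(seq_len(4)), , 14], tolerance = 1e-6)
})

test_that("interactions outside the scintillator are rejected", {
  g <- default_geometry()
  expect_error(
    expected_light_map(data.frame(x = 0, y = 0, z = 0, edep = 100),
                       optical_model(), g),
    "outside")
})

test_that("three-facet containment exceeds 90% for uniform photoelectric events", {
  g <- default_geometry()
  oc <- optical_containment(g, optical_model(), n = 1500, seed = 5)
  expect_gt(oc$mean_percent, 90)
})

test_that("containment decreases with depth below the sensor plane over the mid-depth range", {
  g <- default_geometry()
  m <- optical_model()
  frac <- vapply(c(2, 4, 6), function(h) {
    p <- facet_to_world(g, 0L, 0, 0,
                        g$spec$facet_apothem - h - 30)
    L <- expected_light_matrix(p, 511, m, g)
    fs <- colSums(matrix(L[1, ], 64, 14))
    (fs[1] + fs[2] + fs[14]) / sum(fs)
  }, numeric(1))
  expect_true(all(diff(frac) <= 1e-6))
})

test_that("total collected signal falls with distance from the sensor plane", {
  g <- default_geometry()
  m <- optical_model()
  # pixel-aligned transaxial position (dead space distorts the on-gap trend)
  u0 <- g$sensors$u_centers[2]
  tot <- vapply(c(2, 4, 6, 8), function(h) {
    p <- facet_to_world(g, 0L, u0, 0, g$spec$facet_apothem - h -
                          sqrt(30^2 - u0^2))
    sum(expected_light_matrix(p, 511, m, g))
  }, numeric(1))
  expect_true(all(diff(tot) < 0))
})

test_that("the mirror term vanishes at zero reflectance and only adds light otherwise", {
  g <- default_geometry()
  p <- facet_to_world(g, 0L, 2, 5, 3)
  L_full <- expected_light_matrix(p, 511, optical_model(), g)
  L_dir <- expected_light_matrix(p, 511,
                                 optical_model(inner_reflectance = 0), g)
  expect_true(all(L_full - L_dir >= -1e-12))
  expect_gt(sum(L_full), sum(L_dir))
  # two-source chains superpose (CS-PE two-peak structure)
  p2 <- facet_to_world(g, 0L, 2, -8, 3)
  ints <- data.frame(x = c(p[1], p2[1]), y = c(p[2], p2[2]),
                     z = c(p[3], p2[3]), edep = c(200, 311))
  both <- expected_light_map(ints, optical_model(), g)
  one <- expected_light_map(ints[1, ], optical_model(), g)
  two <- expected_light_map(ints[2, ], optical_model(), g)
  expect_equal(unclass(both), unclass(one) + unclass(two),
               tolerance = 1e-10)
})

test_that("sampled signals follow Poisson statistics around the expectation", {
  expect_true(all(sample_signals(array(0, c(4, 16, 14)), dark_mean = 0) == 0))
  set.seed(8)
  N <- 400
  draws <- replicate(3000, sample_signals(matrix(N, 1, 1), dark_mean = 0))
  expect_equal(mean(draws), N, tolerance = 0.02)
  expect_equal(stats::var(draws) / mean(draws), 1, tolerance = 0.1)
})

test_that("scanner gains are reproducible per scanner seed", {
  g <- default_geometry()
  g1 <- scanner_gains(g, scanner_seed = 4)
  g2 <- scanner_gains(g, scanner_seed = 4)
  g3 <- scanner_gains(g, scanner_seed = 5)
  expect_identical(g1, g2)
  expect_false(identical(g1, g3))
  expect_length(g1, 4 * 16 * 14)
  # gains do not disturb the ambient RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(scanner_gains(g, scanner_seed = 9)); b <- runif(1)
  expect_identical(a, b)
})
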