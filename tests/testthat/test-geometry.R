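test_that("derived facet width and outer radius reproduce the printed dimensions", {
  s <- annulus_spec()
  expect_lt(abs(s$facet_width - 18.2) / 18.2, 0.005)
  expect_lt(abs(s$max_outer_radius - 41.0) / 41.0, 0.01)
  # closed-form square case
  sq <- annulus_spec(inner_radius = 5, n_facets = 4, facet_apothem = 10)
  expect_equal(sq$facet_width, 20)
})

test_that("invalid annulus configurations raise configuration errors", {
  expect_error(annulus_spec(inner_radius = 45), "inner_radius")
  expect_error(annulus_spec(n_facets = 2), "n_facets")
  expect_error(annulus_spec(length = -1), "length")
})

test_that("locate_point assigns facets, depths, and inside flags", {
  g <- default_geometry()
  loc <- locate_point(g, c(35, 0, 0))
  expect_identical(loc$facet, 0L)
  expect_equal(loc$u, 0)
  expect_equal(loc$depth, 5)
  expect_true(loc$inside)
  expect_false(locate_point(g, c(0, 0, 0))$inside)    # bore
  expect_false(locate_point(g, c(35, 0, 50))$inside)  # beyond the ends
})

test_that("facet assignment agrees with the angular-sector oracle on random interior points", {
  g <- default_geometry()
  set.seed(42)
  n <- 10000
  r <- runif(n, 30.05, 39.6)
  phi <- runif(n, 0, 2 * pi)
  p <- cbind(r * cos(phi), r * sin(phi), runif(n, -35, 35))
  loc <- locate_point(g, p)
  inside <- loc$inside
  expect_gt(mean(inside), 0.9)
  # oracle: the facet whose angular sector [az - pi/14, az + pi/14)
  # contains the point's azimuth
  sector <- (round(phi / (2 * pi / 14)) %% 14)
  expect_true(all(loc$facet[inside] == sector[inside]))
})

test_that("locate_point inverts facet_to_world on facet-flat centres", {
  g <- default_geometry()
  for (f in c(0L, 3L, 9L)) {
    p <- facet_to_world(g, f, 0, 0, g$spec$facet_apothem - 30)
    loc <- locate_point(g, p)
    expect_identical(loc$facet, f)
    expect_equal(loc$u, 0, tolerance = 1e-9)
    expect_equal(loc$depth, g$spec$facet_apothem - 30, tolerance = 1e-9)
  }
})

test_that("coincidence map has seven symmetric partners spanning the bore", {
  g <- default_geometry()
  expect_identical(coincidence_partners(g, 0L), c(4L, 5L, 6L, 7L, 8L, 9L, 10L))
  all_pairs <- 0
  for (i in 0:13) {
    pi_ <- coincidence_partners(g, i)
    expect_length(pi_, 7)
    expect_false(i %in% pi_)
    for (j in pi_) expect_true(i %in% coincidence_partners(g, j))
    all_pairs <- all_pairs + length(pi_)
  }
  expect_identical(all_pairs / 2, 49)   # unique pairs
  expect_error(coincidence_partners(g, 14L), "out of range")
  # every partner-facet chord intersects the open bore cylinder
  for (i in 0:13) {
    for (j in coincidence_partners(g, i)) {
      a <- facet_to_world(g, i, 0, 0, 2)
      b <- facet_to_world(g, j, 0, 0, 2)
      d <- b - a
      tt <- seq(0, 1, length.out = 201)
      rmin <- min(sqrt((a[1] + tt * d[1])^2 + (a[2] + tt * d[2])^2))
      expect_lt(rmin, 30)
    }
  }
})

test_that("clamp_to_annulus moves outside points onto the solid and flags them", {
  g <- default_geometry()
  out <- clamp_to_annulus(g, rbind(c(0, 0, 0), c(35, 0, 0), c(60, 0, 80)))
  expect_identical(out$clamped, c(TRUE, FALSE, TRUE))
  expect_true(all(in_annulus(g, out$p)))
})
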