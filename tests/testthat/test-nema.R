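test_that("FWHM and FWTM of an analytic Gaussian match the closed forms", {
  vol <- gaussian_volume(sigma = 0.6, voxel = 0.25, n = 81)
  rr <- resolution_metrics(vol)
  expect_identical(rr$direction, c("radial", "tangential", "axial"))
  for (k in 1:3) {
    expect_equal(rr$fwhm[k], 2.3548 * 0.6, tolerance = 0.02)
    expect_equal(rr$fwtm[k] / rr$fwhm[k], 1.8226, tolerance = 0.02)
  }
  # intensity scaling leaves widths unchanged
  vol2 <- vol; vol2$values <- vol$values * 37.5
  rr2 <- resolution_metrics(vol2)
  expect_equal(rr2$fwhm, rr$fwhm, tolerance = 1e-9)
  # an off-axis source: radial/tangential labels follow the source azimuth
  vol3 <- gaussian_volume(sigma = 0.6, voxel = 0.25, n = 81,
                          center = c(5, 0, 0))
  rr3 <- resolution_metrics(vol3, source_xy = c(5, 0))
  expect_equal(rr3$fwhm, rr$fwhm, tolerance = 0.02)
})

test_that("FWHM is stable under grid refinement", {
  vol <- gaussian_volume(sigma = 0.6, voxel = 0.25, n = 61)
  fw1 <- resolution_metrics(vol)$fwhm[1]
  vol_up <- gaussian_volume(sigma = 0.6, voxel = 0.125, n = 121)
  fw2 <- resolution_metrics(vol_up)$fwhm[1]
  expect_equal(fw2, fw1, tolerance = 0.01)
})

test_that("sensitivity conversions reproduce the branching arithmetic", {
  # peak: 0.086 cps/Bq with the Na-22 branching fraction prints as 9.5%
  sm <- sensitivity_metrics(rates = 0.086, background = 0, activity = 1,
                            nuclide = "Na22")
  expect_equal(sm$peak_absolute_pct, 9.49, tolerance = 0.001)
  expect_equal(round(sm$peak_absolute_pct, 1), 9.5)
  # integrated: 0.751 cps/Bq over the sweep -> 82.9% absolute
  rates <- rep(0.751 / 15, 15)
  sm2 <- sensitivity_metrics(rates, 0, 1, "Na22",
                             positions = seq(-35, 35, by = 5))
  expect_equal(sm2$integrated_S, 0.751, tolerance = 1e-12)
  expect_equal(round(sm2$integrated_absolute_pct, 1), 82.9)
  # zero counts -> zero sensitivity; invalid activity errors
  expect_equal(sensitivity_metrics(0, 0, 1, "Na22")$peak_S, 0)
  expect_error(sensitivity_metrics(1, 0, 0), "activity")
})

# a sinogram with known trues (centred), scatter (uniform), and zero randoms
constructed_sinogram <- function(g, trues, scatter, n_angles = 32) {
  n_radial <- 2L * ceiling(30 / 0.42)
  counts <- array(0, dim = c(n_radial, n_angles, 167))
  rc <- (seq_len(n_radial) - 0.5) * 0.42 - 30
  ctr <- which.min(abs(rc))
  inside <- abs(rc) <= 20.5           # phantom radius 12.5 + 8 mm margin
  counts[ctr, , 84] <- trues / n_angles
  counts[inside, , 84] <- counts[inside, , 84] +
    scatter / n_angles / sum(inside)
  structure(list(counts = counts, n_radial = n_radial,
                 n_angles = n_angles, n_slices = 167L, radial_bin = 0.42,
                 radial_extent = 30, slice_pitch = 0.42, n_rejected = 0),
            class = "ssrb_sinogram")
}

test_that("count-rate analysis recovers constructed trues, scatter and NECR", {
  g <- default_geometry()
  sino <- constructed_sinogram(g, trues = 9e5, scatter = 1e5)
  cr <- countrate_metrics(list(sino), activities = 1e6, durations = 1,
                          randoms_rates = 0)
  expect_equal(cr$table$total_cps, 1e6, tolerance = 1e-9)
  expect_equal(cr$table$trues_cps, 9e5, tolerance = 0.01)
  expect_equal(cr$table$scatter_cps, 1e5, tolerance = 0.1)
  expect_equal(cr$table$necr_cps, 8.1e5, tolerance = 0.02)
  expect_equal(cr$scatter_fraction_pct, 10, tolerance = 0.1)
  # all-zero sinograms give zero rates
  z <- constructed_sinogram(g, 0, 0)
  crz <- countrate_metrics(list(z, z), c(1e5, 2e5), c(1, 1), 0)
  expect_true(all(crz$table$total_cps == 0))
  expect_true(all(crz$table$necr_cps == 0))
})

test_that("peak NECR is located by parabolic interpolation over the sweep", {
  g <- default_geometry()
  acts <- c(2, 4, 6, 8, 10) * 1e6
  # trues saturating with activity, scatter proportional: NECR peaks inside
  trues <- c(3, 5.5, 7, 7.2, 6.5) * 1e5
  scat <- 0.15 * trues
  sinos <- lapply(seq_along(acts), function(k) {
    constructed_sinogram(g, trues[k], scat[k])
  })
  cr <- countrate_metrics(sinos, acts, rep(1, 5), randoms_rates = 0)
  expect_gt(cr$peak_necr_activity_Bq, 4e6)
  expect_lt(cr$peak_necr_activity_Bq, 10e6)
  expect_gte(cr$peak_necr_cps, max(cr$table$necr_cps))
  # NECR never exceeds the trues rate
  expect_true(all(cr$table$necr_cps <= cr$table$trues_cps + 1e-9))
})

# digital IQ-phantom activity volume with optional Gaussian blur
digital_iq_volume <- function(phantom, voxel = 0.5, blur_sigma = 0,
                              n_xy = 72, nz = 100) {
  xc <- (seq_len(n_xy) - (n_xy + 1) / 2) * voxel
  zc <- (seq_len(nz) - (nz + 1) / 2) * voxel
  X <- matrix(xc, n_xy, n_xy); Y <- matrix(xc, n_xy, n_xy, byrow = TRUE)
  vals <- array(0, dim = c(n_xy, n_xy, nz))
  unif <- X^2 + Y^2 <= (phantom$uniform_diameter / 2)^2
  for (k in seq_len(nz)) {
    if (abs(zc[k]) <= phantom$uniform_length / 2) vals[, , k][unif] <- 1
    if (zc[k] < -phantom$uniform_length / 2 &&
        zc[k] >= -phantom$uniform_length / 2 - phantom$rod_length) {
      for (j in seq_along(phantom$rod_diameters)) {
        cx <- phantom$rod_offset * cos(phantom$rod_angles[j])
        cy <- phantom$rod_offset * sin(phantom$rod_angles[j])
        rod <- (X - cx)^2 + (Y - cy)^2 <= (phantom$rod_diameters[j] / 2)^2
        vals[, , k][rod] <- 1
      }
    }
  }
  if (blur_sigma > 0) {
    w <- dnorm(seq(-3, 3) * voxel, 0, blur_sigma)
    w <- w / sum(w)
    # separable Gaussian blur, one pass per axis
    blur1 <- function(a, axis) {
      d <- dim(a)
      m <- apply(a, setdiff(1:3, axis), function(v) {
        as.numeric(stats::filter(c(rep(0, 3), v, rep(0, 3)), w,
                                 sides = 2))[4:(length(v) + 3)]
      })
      arr <- array(m, dim = c(d[axis], d[setdiff(1:3, axis)]))
      aperm(arr, order(c(axis, setdiff(1:3, axis))))
    }
    for (ax in 1:3) vals <- blur1(vals, ax)
    vals[is.na(vals)] <- 0
  }
  structure(list(values = vals, voxel_size = voxel, slice_pitch = voxel,
                 origin = c(-n_xy / 2 * voxel, -n_xy / 2 * voxel,
                            -nz / 2 * voxel)),
            class = "image_volume")
}

test_that("image-quality metrics are exact on a noise-free digital phantom", {
  ph <- iq_phantom()
  vol <- digital_iq_volume(ph, voxel = 0.5)
  iq <- iq_metrics(vol, ph)
  expect_equal(iq$uniformity$mean, 1, tolerance = 1e-9)
  expect_equal(iq$uniformity$pct_std, 0, tolerance = 1e-9)
  expect_true(all(abs(iq$recovery$RC - 1) < 1e-9))
  expect_true(all(iq$spillover$SOR == 0))
  expect_error(iq_metrics(vol, cylinder_phantom()), "registration")
})

test_that("partial volume makes recovery increase with rod diameter", {
  ph <- iq_phantom()
  vol <- digital_iq_volume(ph, voxel = 0.5, blur_sigma = 0.8)
  iq <- iq_metrics(vol, ph)
  expect_identical(iq$recovery$diameter, c(1, 2, 3, 4, 5))
  expect_true(all(diff(iq$recovery$RC) > 0))
  expect_true(all(iq$recovery$RC <= 1.05))
})

test_that("the NECR identity holds and degrades with background", {
  expect_equal(necr(9e5, 1e5, 0), 8.1e5)
  expect_equal(necr(100, 0, 0), 100)
  expect_true(necr(100, 20, 30) < 100)
  expect_equal(necr(0, 5, 5), 0)
})
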