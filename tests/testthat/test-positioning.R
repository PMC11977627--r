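test_that("harmonization subtracts, clamps, and max-normalizes", {
  u <- matrix(1, 12, 16)
  h <- harmonize(u, 0.0025)
  expect_true(all(h == 1))                       # uniform in, uniform out
  d <- matrix(runif(192), 12, 16)
  h0 <- harmonize(d, 0)
  expect_equal(unclass(h0), unclass(d) / max(d), tolerance = 1e-12,
               ignore_attr = TRUE)
  # maximum is 1 for any non-zero input; values non-negative
  hh <- harmonize(d, 0.0025)
  expect_equal(max(hh), 1)
  expect_true(all(hh >= 0))
  # scale invariance
  expect_equal(unclass(harmonize(5 * d)), unclass(harmonize(d)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # idempotence at f = 0
  expect_equal(unclass(harmonize(h0, 0)), unclass(h0), tolerance = 1e-12,
               ignore_attr = TRUE)
  # all-zero input flagged, not an error
  z <- harmonize(matrix(0, 12, 16))
  expect_true(attr(z, "all_zero"))
  expect_true(all(z == 0))
  # batch form matches the single form row by row
  B <- rbind(as.numeric(d), 2 * as.numeric(d))
  hb <- harmonize(B)
  expect_equal(hb[1, ], as.numeric(harmonize(as.numeric(d))),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(hb[1, ], hb[2, ], tolerance = 1e-12)
  expect_error(harmonize(d, 0.01), "f_factor")
})

test_that("centre of mass lands on symmetric peaks and averages twin peaks", {
  g <- default_geometry()
  lut <- data.frame(moment = c(1, 10), depth = c(3, 6))
  class(lut) <- c("depth_lut", "data.frame")
  # symmetric single peak centred on the primary facet
  d <- matrix(0, 12, 16)
  d[5:8, 8:9] <- c(1, 3, 3, 1)    # symmetric in u around the facet centre
  est <- com_position(d, 0L, g, lut)
  loc <- locate_point(g, cbind(est$x, est$y, est$z))
  expect_identical(loc$facet, 0L)
  expect_lt(abs(loc$u), 1e-6)
  expect_lt(abs(est$z), 1e-6)
  # two equal peaks at symmetric axial offsets average to z = 0
  # (the twin-peak bias of CS-PE chains)
  d2 <- matrix(0, 12, 16)
  d2[6:7, 6] <- 1; d2[6:7, 11] <- 1   # v = -11 and +11 mm
  est2 <- com_position(d2, 0L, g, lut)
  expect_lt(abs(est2$z), 1e-6)
  expect_error(com_position(matrix(0, 12, 16), 0L, g, lut), "all-zero")
})

test_that("the depth lookup is calibrated monotonically where populated", {
  g <- default_geometry()
  lut <- calibrate_depth_lut(g, n = 1200, seed = 6)
  expect_true(all(is.finite(lut$depth)))
  expect_gt(stats::cor(lut$moment, lut$depth), 0.5)
})

test_that("training reduces loss deterministically and memorizes noiseless data", {
  set.seed(30)
  X <- matrix(runif(40 * 192), 40, 192)
  y <- cbind(runif(40, -9, 9), runif(40, -35, 35), runif(40, 0, 11))
  m1 <- train_positioner(X, y, width = 32, n_blocks = 1, epochs = 40,
                         batch_size = 20, seed = 5)
  m2 <- train_positioner(X, y, width = 32, n_blocks = 1, epochs = 40,
                         batch_size = 20, seed = 5)
  expect_identical(m1$loss_history, m2$loss_history)
  # broadly decreasing loss
  expect_lt(tail(m1$loss_history, 1), m1$loss_history[1])
  # a single repeated noiseless example is memorized to < 0.1 mm
  Xr <- X[rep(1, 64), ]
  yr <- y[rep(1, 64), , drop = FALSE]
  yr <- yr + matrix(rnorm(64 * 3, 0, 1e-9), 64, 3)  # avoid zero scale
  mm <- train_positioner(Xr, yr, width = 16, n_blocks = 1, epochs = 60,
                         batch_size = 32, seed = 6)
  g <- default_geometry()
  p <- predict_position(mm, Xr[1:4, ], rep(0L, 4), g)
  loc <- attr(p, "local")
  expect_lt(sqrt(mean((loc - yr[1:4, ])^2)), 0.1)
  expect_error(train_positioner(X[0, , drop = FALSE], y[0, , drop = FALSE]),
               "degenerate")
})

test_that("network predictions stay inside the annulus and are deterministic", {
  g <- default_geometry()
  set.seed(31)
  X <- matrix(runif(30 * 192), 30, 192)
  y <- cbind(runif(30, -9, 9), runif(30, -35, 35), runif(30, 0, 11))
  m <- train_positioner(X, y, width = 16, n_blocks = 1, epochs = 5, seed = 7)
  # wild inputs, every prediction clamped into the solid
  Xw <- matrix(runif(50 * 192, 0, 10), 50, 192)
  pr <- predict_position(m, Xw, sample(0:13, 50, TRUE), g)
  expect_true(all(in_annulus(g, cbind(pr$x, pr$y, pr$z))))
  pr2 <- predict_position(m, Xw, rep(0L, 50), g)
  pr3 <- predict_position(m, Xw, rep(0L, 50), g)
  expect_identical(pr2, pr3)
  expect_error(predict_position(m, Xw[, 1:100], 0L, g), "192")
})

test_that("evaluation reports strata, accounting totals, and the twin-peak penalty", {
  ds <- shared_positioning_dataset()
  n <- nrow(ds$X)
  # a perfect oracle has zero error everywhere
  rep0 <- evaluate_positioner(ds$world, ds$world, ds$label, ds$depth_w)
  expect_true(all(rep0$rmse_3d == 0))
  expect_identical(rep0$n[rep0$stratum == "all"], n)
  # label strata partition the set
  lab_rows <- rep0[grepl("^label:", rep0$stratum), ]
  expect_identical(sum(lab_rows$n), n)
  # the centre of mass pays for the CS-PE two-peak ambiguity
  g <- default_geometry()
  lut <- calibrate_depth_lut(g, n = 1200, seed = 8)
  com <- com_position(ds$X, ds$facet, g, lut)
  repc <- evaluate_positioner(com, ds$world, ds$label)
  r <- function(lb) repc$rmse_3d[repc$stratum == paste0("label:", lb)]
  expect_gt(r("CS-PE"), r("PE"))
})

test_that("positioning error shrinks with light yield", {
  g <- default_geometry()
  lut <- calibrate_depth_lut(g, n = 800, seed = 9)
  rmse <- vapply(c(6, 29, 120), function(ly) {
    m <- optical_model(light_yield = ly)
    set.seed(40)
    n <- 250
    u <- runif(n, -6, 6); v <- runif(n, -20, 20)
    depth <- runif(n, 1, 8)
    p <- facet_to_world(g, rep(0L, n), u, v, depth)
    L <- expected_light_matrix(p, rep(511, n), m, g)
    noisy <- matrix(rpois(length(L), L), nrow(L), ncol(L))
    d <- assemble_distribution(noisy, rep(0L, n), g)
    est <- com_position(harmonize(d), rep(0L, n), g, lut)
    sqrt(mean((est$z - v)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})
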