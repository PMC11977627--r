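test_that("Compton kinematics follow the scattering formula", {
  # forward scatter keeps the energy; backscatter at 511 keV gives 511/3
  compton <- function(E, theta) E / (1 + (E / 511) * (1 - cos(theta)))
  expect_equal(compton(511, 0), 511)
  expect_equal(compton(511, pi), 511 / 3)
  # sampler returns energies consistent with its angles
  set.seed(1)
  kn <- sample_klein_nishina(1000, 511)
  expect_equal(kn$Eprime, compton(511, kn$theta), tolerance = 1e-12)
  expect_true(all(kn$Eprime >= 511 / 3 - 1e-9 & kn$Eprime <= 511))
})

test_that("Klein-Nishina sampler matches the numerically integrated cross-section", {
  set.seed(2)
  n <- 2e5
  kn <- sample_klein_nishina(n, 511)
  br <- seq(-1, 1, length.out = 21)
  obs <- table(cut(cos(kn$theta), br))
  # numerically integrate the (unnormalized) pdf over each bin
  probs <- vapply(seq_len(20), function(k) {
    stats::integrate(klein_nishina_pdf, br[k], br[k + 1], E = 511)$value
  }, numeric(1))
  probs <- probs / sum(probs)
  cs <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = probs))
  expect_gt(cs$p.value, 0.01)
})

test_that("path survival is exponential in the line integral and multiplicative", {
  water <- cylinder_phantom(activity = 1, diameter = 30, length = 30)
  mu <- make_attenuation_phantom(water, voxel_size = 0.5, extent = 16,
                                 z_extent = 16)
  expect_equal(path_survival(c(1, 2, 3), c(1, 2, 3), mu), 1)
  s10 <- path_survival(c(0, 0, -5), c(0, 0, 5), mu)
  expect_equal(s10, exp(-0.096), tolerance = 0.01)
  # multiplicative over concatenated sub-segments
  a <- c(-4, 1, -6); b <- c(5, -2, 3); m <- (a + b) / 2
  expect_equal(path_survival(a, b, mu),
               path_survival(a, m, mu) * path_survival(m, b, mu),
               tolerance = 1e-9)
})

test_that("LYSO cross-sections are consistent and interpolate within range", {
  xs <- lyso_cross_sections()
  E <- c(50, 75, 170, 340, 511)
  expect_equal(xs$mu_total(E), xs$mu_pe(E) + xs$mu_cs(E), tolerance = 1e-12)
  expect_equal(xs$mu_total(511), 0.087, tolerance = 1e-6)
  expect_equal(xs$mu_pe(511) / xs$mu_total(511), 0.33, tolerance = 1e-6)
  expect_true(all(xs$mu_pe(E) > 0 & xs$mu_cs(E) > 0))
})

test_that("geometric pair acceptance from a centred source matches the solid-angle value", {
  g <- default_geometry()
  # opaque crystal: every photon that intercepts the annulus interacts
  phys <- physics_config(xs = lyso_cross_sections(total_511 = 1e3),
                         acollinearity_fwhm_deg = 0,
                         positron_range = FALSE,
                         object_attenuation = FALSE)
  truth <- simulate_events(point_source("Na22", 1e6, c(0, 0, 0)), g, phys,
                           n = 8000, seed = 9)
  hit <- !is.na(truth$photons$fx)
  pair_hit <- tapply(hit, truth$photons$event, all)
  # both photons intercept the 60 mm-ID x 72 mm annulus wall:
  # cos(theta_max) = 3.6 / sqrt(3.6^2 + 3.0^2)
  expect_equal(mean(pair_hit), 3.6 / sqrt(3.6^2 + 3^2), tolerance = 0.02)
  # in the opaque limit interactions sit at the inner surface
  first <- truth$interactions[truth$interactions$order == 1, ]
  r <- sqrt(first$x^2 + first$y^2)
  expect_true(all(r < 30.2))
})

test_that("photoelectric chains conserve energy and labels partition chains", {
  g <- default_geometry()
  phys <- physics_config(object_attenuation = FALSE)
  truth <- simulate_events(point_source("Na22", 1e6), g, phys, n = 4000,
                           seed = 10)
  expect_true(all(truth$photons$label %in%
                    c("PE", "CSE", "CS-PE", "multi", "miss")))
  dep <- tapply(truth$interactions$edep,
                paste(truth$interactions$event, truth$interactions$photon),
                sum)
  lab <- truth$photons$label[match(names(dep),
                                   paste(truth$photons$event,
                                         truth$photons$photon))]
  # PE-terminated chains deposit the full 511 keV
  expect_true(all(abs(dep[lab == "PE"] - 511) < 1e-9))
  expect_true(all(abs(dep[lab == "CS-PE"] - 511) < 1e-9))
  # escape chains deposit strictly less
  expect_true(all(dep[lab == "CSE"] < 511))
  # deposits never exceed the photon energy
  expect_true(all(dep <= 511 + 1e-9))
})

test_that("chain-label frequencies shift toward PE as the photoelectric fraction grows", {
  g <- default_geometry()
  pe_share <- vapply(c(0.2, 0.5, 0.9), function(f) {
    phys <- physics_config(xs = lyso_cross_sections(pe_fraction_511 = f),
                           object_attenuation = FALSE)
    truth <- simulate_events(point_source("Na22", 1e6), g, phys, n = 2500,
                             seed = 11)
    lab <- truth$photons$label
    sum(lab == "PE") / sum(lab != "miss")
  }, numeric(1))
  expect_true(all(diff(pe_share) > 0))
})

test_that("object attenuation lowers coincidence yield relative to air", {
  g <- default_geometry()
  src_air <- cylinder_phantom(activity = 1e6, diameter = 3, length = 3)
  n <- 6000
  phys_on <- physics_config()
  phys_off <- physics_config(object_attenuation = FALSE)
  mp <- mouse_phantom(activity = 1e6)
  t_on <- simulate_events(mp, g, phys_on, n = n, seed = 12)
  t_off <- simulate_events(mp, g, phys_off, n = n, seed = 12)
  yield <- function(tr) {
    ok <- !is.na(tr$photons$fx) & !tr$photons$object_scattered
    sum(tapply(ok, tr$photons$event, all))
  }
  expect_lt(yield(t_on), yield(t_off))
})

test_that("simulation is reproducible at fixed seed", {
  g <- default_geometry()
  t1 <- simulate_events(point_source(), g, n = 500, seed = 33)
  t2 <- simulate_events(point_source(), g, n = 500, seed = 33)
  expect_identical(t1, t2)
})
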