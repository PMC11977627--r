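#' Parametric scintillation-light model
#'
#' Expected sensor signals are computed with a solid-angle model: each
#' energy deposition radiates optical photons isotropically; the photons
#' reaching a sensor pixel are the direct solid-angle fraction of its 4 mm
#' active square plus a single mirror-image term for light reflected off the
#' specular inner (bore) surface; the absorptive end faces contribute
#' nothing. Light is attenuated exponentially with optical path length.
#'
#' @param light_yield Scintillation photons per keV.
#' @param collection_efficiency Fraction of photons at a sensor converted to
#'   photoelectrons (folds optical coupling and PDE).
#' @param attenuation_length Optical attenuation length, mm.
#' @param inner_reflectance Specular reflection coefficient of the bore
#'   surface (0 disables the mirror term).
#' @param mirror_reach_scale Fraction of the grazing-limit angular reach
#'   within which single-reflection light off the convex bore surface is
#'   spread (the specular lobe).
#' @param mirror_falloff_power Exponent of the cosine falloff of the
#'   specular lobe across its reach.
#' @return Object of class `optical_model`.
#' @export
optical_model <- function(light_yield = 29, collection_efficiency = 0.25,
                          attenuation_length = 60, inner_reflectance = 0.95,
                          mirror_reach_scale = 0.7,
                          mirror_falloff_power = 2) {
  stopifnot(light_yield >= 0, collection_efficiency >= 0,
            collection_efficiency <= 1, inner_reflectance >= 0,
            inner_reflectance <= 1, attenuation_length > 0,
            mirror_reach_scale > 0, mirror_falloff_power >= 0)
  structure(list(light_yield = light_yield,
                 collection_efficiency = collection_efficiency,
                 attenuation_length = attenuation_length,
                 inner_reflectance = inner_reflectance,
                 mirror_reach_scale = mirror_reach_scale,
                 mirror_falloff_power = mirror_falloff_power),
            class = "optical_model")
}

# solid angle of a rectangle [x1,x2]x[y1,y2] at perpendicular distance h
# (Gotoh-Yagi corner decomposition)
rect_solid_angle <- function(x1, x2, y1, y2, h) {
  corner <- function(x, y) atan2(x * y, h * sqrt(x^2 + y^2 + h^2))
  corner(x2, y2) - corner(x1, y2) - corner(x2, y1) + corner(x1, y1)
}

#' Expected light on every sensor for a set of energy depositions
#'
#' Vectorized core of the optical model: for `m` deposition points it
#' returns an `m x (n_facets*64)` matrix of expected photoelectron counts,
#' one column per sensor pixel in array order (transaxial index fastest,
#' then axial, then facet).
#'
#' @param points `m x 3` matrix of deposition positions, mm (world frame).
#' @param edep Deposited energies, keV (length m).
#' @param model An [optical_model()].
#' @param g A `scanner_geometry`.
#' @return Numeric matrix `m x (n_facets * n_u * n_v)`.
#' @export
expected_light_matrix <- function(points, edep, model, g) {
  points <- to_matrix3(points)
  m <- nrow(points)
  sg <- g$sensors
  npix <- sg$n_u * sg$n_v
  nf <- g$spec$n_facets
  out <- matrix(0, m, nf * npix)
  scale <- model$light_yield * edep * model$collection_efficiency / (4 * pi)
  half <- sg$pixel_size / 2
  lam <- model$attenuation_length
  rho <- model$inner_reflectance
  R <- g$spec$inner_radius

  # mirror of each point across the bore surface (radial reflection)
  r_xy <- sqrt(points[, 1]^2 + points[, 2]^2)
  mir_scale <- (2 * R - r_xy) / r_xy
  mirror <- cbind(points[, 1] * mir_scale, points[, 2] * mir_scale,
                  points[, 3])

  pix_u <- rep(sg$u_centers, times = sg$n_v)  # length npix, iu fastest
  pix_v <- rep(sg$v_centers, each = sg$n_u)

  # occlude: light travels only through the crystal, so a straight path
  # whose transaxial segment dips inside the bore cylinder is blocked
  # (that light is carried by the mirror term instead); occlude_radius < R
  # lets the mirror paths (which graze the bore by construction) through.
  blocked <- function(ax, ay, bx, by, radius) {
    dx <- outer(-ax, bx, `+`)   # b - a, m x npix
    dy <- outer(-ay, by, `+`)
    l2 <- dx^2 + dy^2
    tt <- -(ax * dx + ay * dy) / pmax(l2, 1e-12)
    tt <- pmin(pmax(tt, 0), 1)
    cx <- ax + tt * dx
    cy <- ay + tt * dy
    cx^2 + cy^2 < radius^2
  }

  # single-reflection reach: light bouncing off the convex bore surface can
  # only span (a fraction of) the sum of the source's and the pixel's
  # tangent angles, with a specular lobe falling off across that reach;
  # a convex mirror also diverges the beam, reducing its intensity
  phi_src <- atan2(points[, 2], points[, 1])
  tang_src <- acos(pmin(R / pmax(r_xy, R), 1))
  div_w <- 1 / (1 + 2 * (r_xy - R) / R)

  add_source <- function(src, weight, occlude_radius, tangent_limit) {
    for (f in seq_len(nf)) {
      nrm <- g$frames$normal[f, 1:2]
      uax <- g$frames$u[f, 1:2]
      s <- src[, 1] * nrm[1] + src[, 2] * nrm[2]
      t <- src[, 1] * uax[1] + src[, 2] * uax[2]
      h <- g$spec$facet_apothem - s
      h <- pmax(h, 1e-6)
      # m x npix relative offsets in the facet frame
      X <- outer(-t, pix_u, `+`)
      Y <- outer(-src[, 3], pix_v, `+`)
      H <- matrix(h, m, npix)
      omega <- rect_solid_angle(X - half, X + half, Y - half, Y + half, H)
      dist <- sqrt(X^2 + Y^2 + H^2)
      # pixel world xy on this facet
      bx <- g$frames$origin[f, 1] + pix_u * uax[1]
      by <- g$frames$origin[f, 2] + pix_u * uax[2]
      if (occlude_radius > 0) {
        omega[blocked(src[, 1], src[, 2], bx, by, occlude_radius)] <- 0
      }
      w <- weight
      if (tangent_limit) {
        phi_pix <- atan2(by, bx)
        r_pix <- sqrt(bx^2 + by^2)
        tang_pix <- acos(pmin(R / r_pix, 1))
        dphi <- abs(outer(phi_src, phi_pix, `-`))
        dphi <- pmin(dphi, 2 * pi - dphi)
        reach <- outer(tang_src, tang_pix, `+`) * model$mirror_reach_scale
        lobe <- cos(pmin(dphi / reach, 1) * (pi / 2))^model$mirror_falloff_power
        omega <- omega * lobe
        omega[dphi > reach] <- 0
        w <- weight * div_w
      }
      cols <- (f - 1) * npix + seq_len(npix)
      out[, cols] <<- out[, cols] +
        (w * scale) * omega * exp(-dist / lam)
    }
  }
  add_source(points, 1, R, FALSE)
  if (rho > 0) add_source(mirror, rho, 0, TRUE)
  out
}

#' Expected (noise-free) sensor signal map for one interaction chain
#'
#' @param interactions data.frame with columns `x, y, z, edep` (one row per
#'   energy deposition of the chain); all depositions must lie inside the
#'   scintillator solid.
#' @param model An [optical_model()].
#' @param g A `scanner_geometry`.
#' @return A `sensor_signal_map`: numeric array `n_u x n_v x n_facets` of
#'   expected photoelectron counts.
#' @export
expected_light_map <- function(interactions, model, g) {
  pts <- cbind(interactions$x, interactions$y, interactions$z)
  if (!all(in_annulus(g, pts))) {
    stop("interaction outside the scintillator solid")
  }
  mat <- expected_light_matrix(pts, interactions$edep, model, g)
  vals <- colSums(mat)
  sg <- g$sensors
  structure(array(vals, dim = c(sg$n_u, sg$n_v, g$spec$n_facets)),
            class = "sensor_signal_map")
}

#' Three-facet containment of the expected light
#'
#' Samples photoelectric-like events at positions uniform over facet area
#' and depth, computes the expected light on every sensor, identifies each
#' event's primary facet (largest facet sum), and returns the fraction of
#' the total expected light collected by the primary facet and its two
#' azimuthal neighbours.
#'
#' @param g A `scanner_geometry`.
#' @param model An [optical_model()].
#' @param n Number of sampled events.
#' @param seed Optional integer seed.
#' @param chunk Events per vectorized block (memory control).
#' @return List with `mean_percent` (mean containment, %) and `fractions`
#'   (per-event containment fractions).
#' @export
optical_containment <- function(g, model = optical_model(), n = 1e4,
                                seed = NULL, chunk = 2000) {
  if (!is.null(seed)) set.seed(seed)
  s <- g$spec
  f <- sample(seq_len(s$n_facets), n, replace = TRUE) - 1L
  u <- stats::runif(n, -s$facet_width / 2 * 0.999, s$facet_width / 2 * 0.999)
  v <- stats::runif(n, -s$length / 2 * 0.997, s$length / 2 * 0.997)
  dmax <- s$facet_apothem -
    sqrt(pmax(s$inner_radius^2 - u^2, 0))
  depth <- stats::runif(n) * (dmax - 0.01)
  p <- facet_to_world(g, f, u, v, depth)
  nf <- s$n_facets
  npix <- g$sensors$n_u * g$sensors$n_v
  fractions <- numeric(n)
  for (lo in seq(1, n, by = chunk)) {
    hi <- min(lo + chunk - 1, n)
    idx <- lo:hi
    L <- expected_light_matrix(p[idx, , drop = FALSE], rep(511, length(idx)),
                               model, g)
    fs <- t(apply(L, 1, function(r) colSums(matrix(r, npix, nf))))
    prim <- max.col(fs)
    tot <- rowSums(fs)
    nb <- fs[cbind(seq_along(idx), prim)] +
      fs[cbind(seq_along(idx), (prim %% nf) + 1)] +
      fs[cbind(seq_along(idx), ((prim - 2) %% nf) + 1)]
    fractions[idx] <- nb / tot
  }
  list(mean_percent = mean(fractions) * 100, fractions = fractions)
}

#' Fixed per-sensor gain factors for a scanner realization
#'
#' @param g A `scanner_geometry`.
#' @param sigma Lognormal sigma of the gain spread.
#' @param scanner_seed Integer seed identifying the scanner realization.
#' @return Numeric vector, one gain per sensor pixel (array order).
#' @export
scanner_gains <- function(g, sigma = 0.02, scanner_seed = 1) {
  nsens <- g$sensors$n_u * g$sensors$n_v * g$spec$n_facets
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(scanner_seed)
  stats::rlnorm(nsens, meanlog = -sigma^2 / 2, sdlog = sigma)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Sample noisy sensor signals around their expectations
#'
#' Per-sensor Poisson draw around the expectation, multiplied by the fixed
#' per-sensor gain, plus an additive Poisson dark-count floor.
#'
#' @param expected A `sensor_signal_map` (or any numeric array/matrix of
#'   expectations in photoelectrons).
#' @param gains Per-sensor gain factors (recycled; default all 1).
#' @param dark_mean Mean dark counts per sensor per event window.
#' @return Sampled signals with the same shape as `expected`.
#' @export
sample_signals <- function(expected, gains = 1, dark_mean = 0.5) {
  stopifnot(all(expected >= 0))
  vals <- stats::rpois(length(expected), as.numeric(expected)) * gains +
    stats::rpois(length(expected), dark_mean)
  out <- expected
  out[] <- vals
  out
}

#' Per-facet and per-array sums of a sensor signal map
#'
#' @param map A `sensor_signal_map` (`n_u x n_v x n_facets`).
#' @param g A `scanner_geometry`.
#' @return List with `facet_sums` (length `n_facets`) and `array_sums`
#'   (`arrays_per_facet x n_facets` matrix; arrays are axial groups of
#'   `array_pixels` sensor rows).
#' @export
signal_sums <- function(map, g) {
  sg <- g$sensors
  nf <- g$spec$n_facets
  arr_of_row <- rep(seq_len(sg$arrays_per_facet), each = sg$array_pixels)
  array_sums <- vapply(seq_len(nf), function(f) {
    slab <- map[, , f]
    as.numeric(rowsum(colSums(slab), arr_of_row))
  }, numeric(sg$arrays_per_facet))
  list(facet_sums = colSums(array_sums), array_sums = array_sums)
}
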