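#' Nuclide decay and positron-branching data
#'
#' Half-lives in seconds and positron branching fractions for the nuclides
#' used in the NU4 protocols.
#'
#' @param nuclide `"F18"` or `"Na22"`.
#' @return List with `half_life` (s) and `positron_branching`.
#' @export
nuclide_data <- function(nuclide = c("F18", "Na22")) {
  nuclide <- match.arg(nuclide)
  switch(nuclide,
    F18  = list(nuclide = "F18",  half_life = 109.77 * 60,
                positron_branching = 0.9686),
    Na22 = list(nuclide = "Na22", half_life = 2.6018 * 365.25 * 86400,
                positron_branching = 0.9060)
  )
}

#' Point-source specification
#'
#' A point source (Na-22 by default) embedded in a small acrylic cube, as
#' used for the NU4 spatial-resolution and sensitivity measurements.
#'
#' @param nuclide `"Na22"` or `"F18"`.
#' @param activity Activity in Bq at the reference time.
#' @param position World position of the source, mm.
#' @param encapsulation_side Side of the acrylic cube, mm.
#' @return Object of class `c("point_source", "phantom")`.
#' @export
point_source <- function(nuclide = "Na22", activity = 1.85e6,
                         position = c(0, 0, 0), encapsulation_side = 10) {
  stopifnot(activity >= 0, length(position) == 3)
  structure(list(kind = "point", nuclide = nuclide_data(nuclide),
                 activity = activity, position = as.numeric(position),
                 encapsulation_side = encapsulation_side),
            class = c("point_source", "phantom"))
}

#' NU4 mouse-like count-rate phantom
#'
#' A polyethylene cylinder (25 mm diameter, 70 mm long) with a 3.2 mm
#' diameter hole drilled parallel to the axis at a 10 mm radial offset,
#' holding the F-18 line source.
#'
#' @param activity Activity in Bq at acquisition start.
#' @param diameter,length Cylinder dimensions, mm.
#' @param hole_diameter,hole_offset Line-source bore, mm.
#' @param center World position of the phantom centre, mm.
#' @return Object of class `c("mouse_phantom", "phantom")`.
#' @export
mouse_phantom <- function(activity = 16e6, diameter = 25, length = 70,
                          hole_diameter = 3.2, hole_offset = 10,
                          center = c(0, 0, 0)) {
  stopifnot(activity >= 0,
            hole_offset + hole_diameter / 2 <= diameter / 2)
  structure(list(kind = "mouse", nuclide = nuclide_data("F18"),
                 activity = activity, diameter = diameter, length = length,
                 hole_diameter = hole_diameter, hole_offset = hole_offset,
                 center = as.numeric(center)),
            class = c("mouse_phantom", "phantom"))
}

#' NU4 image-quality phantom
#'
#' A PMMA cylinder with three regions stacked along the axis: five fillable
#' hot rods (1-5 mm diameter, at a common radial offset), a uniform fillable
#' chamber, and two cold chambers (one water-filled, one air-filled).
#' Dimensions follow the NU4-2008 standard and are overridable.
#'
#' The phantom is oriented along +z with the uniform region centred at
#' `center`; rods extend below it (negative z) and the cold chambers above.
#'
#' @param activity Activity (Bq of F-18) in the fillable volume.
#' @param body_diameter Outer body diameter, mm.
#' @param uniform_diameter,uniform_length Uniform-chamber dimensions, mm.
#' @param rod_diameters Hot-rod diameters, mm.
#' @param rod_offset Radial offset of the rod centres, mm.
#' @param rod_length Rod length, mm.
#' @param cold_diameter,cold_length Cold-chamber interior dimensions, mm.
#' @param cold_offset Radial offset of the cold-chamber centres, mm.
#' @param center World position of the uniform-region centre, mm.
#' @return Object of class `c("iq_phantom", "phantom")`.
#' @export
iq_phantom <- function(activity = 2.96e6, body_diameter = 30,
                       uniform_diameter = 30, uniform_length = 15,
                       rod_diameters = c(1, 2, 3, 4, 5), rod_offset = 7,
                       rod_length = 20, cold_diameter = 8, cold_length = 15,
                       cold_offset = 7.5, center = c(0, 0, 0)) {
  stopifnot(activity >= 0, length(rod_diameters) == 5)
  nrod <- length(rod_diameters)
  rod_angles <- 2 * pi * (seq_len(nrod) - 1) / nrod
  structure(list(kind = "iq", nuclide = nuclide_data("F18"),
                 activity = activity, body_diameter = body_diameter,
                 uniform_diameter = uniform_diameter,
                 uniform_length = uniform_length,
                 rod_diameters = rod_diameters, rod_offset = rod_offset,
                 rod_length = rod_length, rod_angles = rod_angles,
                 cold_diameter = cold_diameter, cold_length = cold_length,
                 cold_offset = cold_offset, center = as.numeric(center)),
            class = c("iq_phantom", "phantom"))
}

#' Uniform activity-filled cylinder
#'
#' @param activity Bq of F-18.
#' @param diameter,length Dimensions, mm. Water-filled.
#' @param center World centre, mm.
#' @return Object of class `c("cylinder_phantom", "phantom")`.
#' @export
cylinder_phantom <- function(activity = 1e6, diameter = 25, length = 40,
                             center = c(0, 0, 0)) {
  structure(list(kind = "cylinder", nuclide = nuclide_data("F18"),
                 activity = activity, diameter = diameter, length = length,
                 center = as.numeric(center)),
            class = c("cylinder_phantom", "phantom"))
}

#' Decay-corrected activity
#'
#' @param spec A phantom object carrying `activity` and `nuclide`.
#' @param t Elapsed time since the reference activity, s.
#' @return Activity in Bq: `A0 * 2^(-t / half_life)`.
#' @export
activity_at <- function(spec, t) {
  if (any(t < 0)) stop("t must be >= 0")
  spec$activity * 2^(-t / spec$nuclide$half_life)
}

#' Sample positron emissions from a phantom
#'
#' Positions are uniform over the active region (the point, line source,
#' cylinder volume, or uniform chamber + hot rods weighted by volume x
#' concentration). Emission times are an inhomogeneous Poisson process at
#' the decay-corrected positron emission rate `activity(t) * branching`,
#' generated by inverting the cumulative intensity.
#'
#' @param spec A phantom object.
#' @param n Number of emissions to draw.
#' @param seed Optional integer seed (set via [set.seed()] when given).
#' @return data.frame with columns `x, y, z` (mm) and `time` (s).
#' @export
sample_emissions <- function(spec, n, seed = NULL) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      time = numeric(0)))
  }
  pos <- sample_positions(spec, n)
  lambda0 <- spec$activity * spec$nuclide$positron_branching  # events/s
  # inhomogeneous Poisson times: Lambda(t) = lambda0*T/ln2*(1 - 2^(-t/T))
  T_half <- spec$nuclide$half_life
  cum <- cumsum(stats::rexp(n))
  scale <- lambda0 * T_half / log(2)
  if (lambda0 <= 0) stop("phantom has zero positron emission rate")
  frac <- cum / scale
  # invert; emissions beyond total decays would need frac >= 1 (astronomically
  # unlikely for requested n) -- clamp defensively
  frac <- pmin(frac, 1 - 1e-12)
  times <- -T_half * log2(1 - frac)
  data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3], time = times)
}

# uniform positions over the active region of each phantom kind
sample_positions <- function(spec, n) {
  if (spec$kind == "point") {
    return(matrix(rep(spec$position, each = n), ncol = 3))
  }
  if (spec$kind == "mouse") {
    r <- spec$hole_diameter / 2 * sqrt(stats::runif(n))
    a <- stats::runif(n, 0, 2 * pi)
    x <- spec$hole_offset + r * cos(a)
    y <- r * sin(a)
    z <- stats::runif(n, -spec$length / 2, spec$length / 2)
    return(cbind(x + spec$center[1], y + spec$center[2], z + spec$center[3]))
  }
  if (spec$kind == "cylinder") {
    r <- spec$diameter / 2 * sqrt(stats::runif(n))
    a <- stats::runif(n, 0, 2 * pi)
    z <- stats::runif(n, -spec$length / 2, spec$length / 2)
    return(cbind(r * cos(a) + spec$center[1], r * sin(a) + spec$center[2],
                 z + spec$center[3]))
  }
  if (spec$kind == "iq") {
    # uniform concentration over uniform chamber + rods: weight by volume
    v_unif <- pi * (spec$uniform_diameter / 2)^2 * spec$uniform_length
    v_rods <- pi * (spec$rod_diameters / 2)^2 * spec$rod_length
    w <- c(v_unif, v_rods)
    comp <- sample.int(length(w), n, replace = TRUE, prob = w)
    r01 <- sqrt(stats::runif(n))
    a <- stats::runif(n, 0, 2 * pi)
    z01 <- stats::runif(n)
    x <- y <- z <- numeric(n)
    is_u <- comp == 1
    x[is_u] <- (spec$uniform_diameter / 2) * r01[is_u] * cos(a[is_u])
    y[is_u] <- (spec$uniform_diameter / 2) * r01[is_u] * sin(a[is_u])
    z[is_u] <- (z01[is_u] - 0.5) * spec$uniform_length
    for (k in seq_along(spec$rod_diameters)) {
      sel <- comp == k + 1
      if (!any(sel)) next
      rad <- spec$rod_diameters[k] / 2
      cx <- spec$rod_offset * cos(spec$rod_angles[k])
      cy <- spec$rod_offset * sin(spec$rod_angles[k])
      x[sel] <- cx + rad * r01[sel] * cos(a[sel])
      y[sel] <- cy + rad * r01[sel] * sin(a[sel])
      # rods sit below the uniform chamber
      z[sel] <- -spec$uniform_length / 2 - z01[sel] * spec$rod_length
    }
    return(cbind(x + spec$center[1], y + spec$center[2], z + spec$center[3]))
  }
  stop("unknown phantom kind: ", spec$kind)
}

#' Linear attenuation coefficients at 511 keV
#'
#' Literature values in 1/mm, overridable per call site.
#' @return Named list: water, polyethylene, acrylic, air.
#' @export
mu_511 <- function() {
  list(water = 0.0096, polyethylene = 0.0093, acrylic = 0.0112, air = 0)
}

#' Voxelized attenuation map for a phantom
#'
#' Builds a voxel grid of linear attenuation coefficients at 511 keV,
#' aligned to the world frame, from the analytic phantom geometry.
#'
#' @param spec A phantom object (or `NULL` for an air-only map).
#' @param voxel_size Isotropic voxel size, mm.
#' @param extent Half-extent of the grid in x and y, mm.
#' @param z_extent Half-extent in z, mm (defaults to `extent`).
#' @param mu Named list of attenuation coefficients (see [mu_511()]).
#' @return Object of class `mu_map`: list with 3-D `values` array (1/mm),
#'   `voxel_size`, and `origin` (world position of the corner of voxel
#'   \[1,1,1\]).
#' @export
make_attenuation_phantom <- function(spec, voxel_size = 1, extent = 20,
                                     z_extent = extent, mu = mu_511()) {
  nx <- ny <- as.integer(ceiling(2 * extent / voxel_size))
  nz <- as.integer(ceiling(2 * z_extent / voxel_size))
  origin <- c(-nx, -ny, -nz) / 2 * voxel_size
  xc <- origin[1] + (seq_len(nx) - 0.5) * voxel_size
  yc <- origin[2] + (seq_len(ny) - 0.5) * voxel_size
  zc <- origin[3] + (seq_len(nz) - 0.5) * voxel_size
  vals <- array(0, dim = c(nx, ny, nz))
  if (!is.null(spec)) {
    gx <- array(xc, dim = c(nx, ny, nz))
    gy <- array(rep(yc, each = nx), dim = c(nx, ny, nz))
    gz <- array(rep(zc, each = nx * ny), dim = c(nx, ny, nz))
    cx <- gx - spec$center[1]; cy <- gy - spec$center[2]
    cz <- gz - spec$center[3]
    r2 <- cx^2 + cy^2
    if (spec$kind == "point") {
      half <- spec$encapsulation_side / 2
      inb <- abs(cx) <= half & abs(cy) <= half & abs(cz) <= half
      vals[inb] <- mu$acrylic
    } else if (spec$kind == "mouse") {
      inb <- r2 <= (spec$diameter / 2)^2 & abs(cz) <= spec$length / 2
      vals[inb] <- mu$polyethylene
      hr2 <- (cx - spec$hole_offset)^2 + cy^2
      hole <- hr2 <= (spec$hole_diameter / 2)^2 & abs(cz) <= spec$length / 2
      vals[hole] <- mu$water
    } else if (spec$kind == "cylinder") {
      inb <- r2 <= (spec$diameter / 2)^2 & abs(cz) <= spec$length / 2
      vals[inb] <- mu$water
    } else if (spec$kind == "iq") {
      z_lo <- -spec$uniform_length / 2 - spec$rod_length
      z_hi <- spec$uniform_length / 2 + spec$cold_length
      inb <- r2 <= (spec$body_diameter / 2)^2 & cz >= z_lo & cz <= z_hi
      vals[inb] <- mu$acrylic
      unif <- r2 <= (spec$uniform_diameter / 2)^2 &
        abs(cz) <= spec$uniform_length / 2
      vals[unif] <- mu$water
      for (k in seq_along(spec$rod_diameters)) {
        rcx <- spec$rod_offset * cos(spec$rod_angles[k])
        rcy <- spec$rod_offset * sin(spec$rod_angles[k])
        rod <- (cx - rcx)^2 + (cy - rcy)^2 <= (spec$rod_diameters[k] / 2)^2 &
          cz <= -spec$uniform_length / 2 &
          cz >= -spec$uniform_length / 2 - spec$rod_length
        vals[rod] <- mu$water
      }
      zc_mid <- spec$uniform_length / 2 + spec$cold_length / 2
      for (off in c(-1, 1)) {
        ch <- (cx - off * spec$cold_offset)^2 + cy^2 <=
          (spec$cold_diameter / 2)^2 &
          abs(cz - zc_mid) <= spec$cold_length / 2
        vals[ch] <- if (off < 0) mu$water else mu$air  # water then air chamber
      }
    } else {
      stop("unknown phantom kind: ", spec$kind)
    }
  }
  structure(list(values = vals, voxel_size = voxel_size, origin = origin),
            class = "mu_map")
}
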