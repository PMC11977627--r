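#' Annulus specification
#'
#' Describes the monolithic scintillator annulus: a cylinder of LYSO with a
#' circular bore and a regular polygonal (tetradecagonal by default) outer
#' surface whose flat faces ("facets") carry the photosensor arrays.
#'
#' Derived quantities: `facet_width = 2 * facet_apothem * tan(pi/n_facets)`
#' (the full width of one flat outer face) and
#' `max_outer_radius = facet_apothem / cos(pi/n_facets)` (radius at the
#' edges between facets).
#'
#' @param inner_radius Bore radius in mm.
#' @param length Axial length of the annulus in mm.
#' @param n_facets Number of flat outer faces.
#' @param facet_apothem Perpendicular distance from the scanner axis to each
#'   flat outer face, mm. With the defaults the minimum scintillator
#'   thickness at a facet centre is `facet_apothem - inner_radius` = 9.7 mm.
#' @return An object of class `annulus_spec`.
#' @export
annulus_spec <- function(inner_radius = 30, length = 72, n_facets = 14,
                         facet_apothem = 39.7) {
  if (n_facets < 3) {
    stop("configuration error: n_facets must be >= 3 (got ", n_facets, ")")
  }
  if (length <= 0) {
    stop("configuration error: annulus length must be > 0 (got ", length, ")")
  }
  if (inner_radius >= facet_apothem) {
    stop("configuration error: inner_radius (", inner_radius,
         ") must be < facet_apothem (", facet_apothem, ")")
  }
  if (inner_radius <= 0) {
    stop("configuration error: inner_radius must be > 0")
  }
  spec <- list(
    inner_radius     = inner_radius,
    length           = length,
    n_facets         = as.integer(n_facets),
    facet_apothem    = facet_apothem,
    facet_width      = 2 * facet_apothem * tan(pi / n_facets),
    max_outer_radius = facet_apothem / cos(pi / n_facets)
  )
  structure(spec, class = "annulus_spec")
}

#' Photosensor grid on one facet
#'
#' Each facet carries `arrays_per_facet` square SiPM arrays stacked axially;
#' every array is `array_pixels x array_pixels` pixels. With the defaults a
#' facet reads out 4 transaxial x 16 axial pixels.
#'
#' @param arrays_per_facet Number of arrays stacked along the axis.
#' @param array_pixels Pixels per side of one array.
#' @param pixel_size Active pixel width, mm.
#' @param pixel_pitch Centre-to-centre pixel spacing, mm.
#' @return An object of class `sensor_grid` with pixel-centre coordinates in
#'   the facet (u = transaxial, v = axial) frame.
#' @export
sensor_grid <- function(arrays_per_facet = 4, array_pixels = 4,
                        pixel_size = 4.0, pixel_pitch = 4.4) {
  nu <- as.integer(array_pixels)                  # transaxial pixels
  nv <- as.integer(arrays_per_facet * array_pixels)  # axial pixels
  u_centers <- (seq_len(nu) - (nu + 1) / 2) * pixel_pitch
  v_centers <- (seq_len(nv) - (nv + 1) / 2) * pixel_pitch
  structure(list(
    arrays_per_facet = as.integer(arrays_per_facet),
    array_pixels     = nu,
    pixel_size       = pixel_size,
    pixel_pitch      = pixel_pitch,
    n_u              = nu,
    n_v              = nv,
    u_centers        = u_centers,
    v_centers        = v_centers
  ), class = "sensor_grid")
}

#' Virtual pseudo-detector specification
#'
#' Infinitely thin planar detectors, one per facet, tangent to a cylinder of
#' `plane_radius`, each gridded into `elements_transaxial x elements_axial`
#' square elements. Estimated LOR endpoints are projected onto these planes
#' for reconstruction.
#'
#' @param plane_radius Distance of each plane from the scanner axis, mm.
#' @param elements_transaxial,elements_axial Element counts per plane.
#' @param element_size Element width, mm.
#' @return An object of class `virtual_detector_spec`.
#' @export
virtual_detector_spec <- function(plane_radius = 30, elements_transaxial = 16,
                                  elements_axial = 84, element_size = 0.84) {
  structure(list(
    plane_radius        = plane_radius,
    elements_transaxial = as.integer(elements_transaxial),
    elements_axial      = as.integer(elements_axial),
    element_size        = element_size
  ), class = "virtual_detector_spec")
}

#' Build the scanner geometry
#'
#' Assembles facet frames, world-frame sensor pixel centres, virtual
#' pseudo-detector planes and the facet coincidence map from the component
#' specifications. The world frame has its origin at the scanner centre,
#' +z along the bore axis, and facet 0's outward normal along +x; facet i's
#' normal is at azimuth `2*pi*i/n_facets`.
#'
#' @param spec An [annulus_spec()].
#' @param sensors A [sensor_grid()].
#' @param virtual A [virtual_detector_spec()].
#' @param partner_offsets Integer offsets (mod `n_facets`) defining which
#'   facets are in coincidence; the default (4:10 for 14 facets) gives each
#'   facet the seven opposing partners whose chords traverse the bore.
#' @return An object of class `scanner_geometry`.
#' @export
build_geometry <- function(spec = annulus_spec(), sensors = sensor_grid(),
                           virtual = virtual_detector_spec(),
                           partner_offsets = NULL) {
  if (!inherits(spec, "annulus_spec")) spec <- do.call(annulus_spec, spec)
  n <- spec$n_facets
  if (is.null(partner_offsets)) {
    # symmetric band of opposing facets; 7 partners for the 14-facet default
    k <- floor((n - 1) / 4)
    partner_offsets <- seq.int(1 + k, n - 1 - k)
  }
  az <- 2 * pi * (seq_len(n) - 1) / n
  normals <- cbind(cos(az), sin(az), 0)
  u_axes  <- cbind(-sin(az), cos(az), 0)
  v_axes  <- cbind(0, 0, 1)[rep(1, n), , drop = FALSE]
  origins <- normals * spec$facet_apothem

  frames <- list(azimuth = az, origin = origins, u = u_axes, v = v_axes,
                 normal = normals)

  # world-frame sensor pixel centres: one row per (facet, u index, v index)
  sg <- expand.grid(iu = seq_len(sensors$n_u), iv = seq_len(sensors$n_v))
  pix <- do.call(rbind, lapply(seq_len(n), function(i) {
    uu <- sensors$u_centers[sg$iu]
    vv <- sensors$v_centers[sg$iv]
    world <- origins[rep(i, nrow(sg)), ] +
      outer(uu, u_axes[i, ]) + outer(vv, c(0, 0, 1))
    data.frame(facet = i - 1L, iu = sg$iu - 1L, iv = sg$iv - 1L,
               u = uu, v = vv, x = world[, 1], y = world[, 2], z = world[, 3])
  }))

  partners <- lapply(seq_len(n) - 1L,
                     function(i) sort((i + partner_offsets) %% n))
  names(partners) <- as.character(seq_len(n) - 1L)

  g <- list(spec = spec, sensors = sensors, virtual = virtual,
            frames = frames, pixels = pix, partners = partners,
            partner_offsets = as.integer(partner_offsets))
  structure(g, class = "scanner_geometry")
}

#' @export
print.scanner_geometry <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "scanner_geometry: %d facets, bore radius %.1f mm, apothem %.2f mm,\n",
    s$n_facets, s$inner_radius, s$facet_apothem))
  cat(sprintf("  facet width %.2f mm, max outer radius %.2f mm, length %.1f mm\n",
              s$facet_width, s$max_outer_radius, s$length))
  cat(sprintf("  sensors: %d x %d pixels/facet at %.1f mm pitch\n",
              x$sensors$n_u, x$sensors$n_v, x$sensors$pixel_pitch))
  cat(sprintf("  virtual planes: %d x %d elements of %.2f mm at radius %.1f mm\n",
              x$virtual$elements_transaxial, x$virtual$elements_axial,
              x$virtual$element_size, x$virtual$plane_radius))
  invisible(x)
}

#' Coincidence partners of a facet
#'
#' @param g A `scanner_geometry`.
#' @param i Facet index, 0-based.
#' @return Integer vector of partner facet indices (0-based).
#' @export
coincidence_partners <- function(g, i) {
  n <- g$spec$n_facets
  if (length(i) != 1 || is.na(i) || i < 0 || i >= n) {
    stop("facet id out of range: ", i)
  }
  g$partners[[as.character(as.integer(i))]]
}

#' Locate points within the annulus
#'
#' Assigns each point to the facet whose angular sector contains it (maximum
#' dot product with the facet normals, ties to the lower index) and returns
#' facet-local coordinates: `u` along the facet width, `v` = z, and `depth`,
#' the distance from the inner cylindrical (bore) surface measured along the
#' facet normal. Points outside the scintillator solid are flagged, not
#' errors.
#'
#' @param g A `scanner_geometry`.
#' @param p Numeric 3-vector or n x 3 matrix of world coordinates, mm.
#' @return A data.frame with columns `facet`, `u`, `v`, `depth`, `inside`.
#' @export
locate_point <- function(g, p) {
  p <- to_matrix3(p)
  s <- g$spec
  nrm <- g$frames$normal[, 1:2, drop = FALSE]
  # dot of each point's xy with each facet normal: n_pts x n_facets
  d <- p[, 1:2, drop = FALSE] %*% t(nrm)
  facet <- max.col(d, ties.method = "first") # lower index on ties
  sdist <- d[cbind(seq_len(nrow(p)), facet)] # along-normal distance
  uax <- g$frames$u[facet, 1:2, drop = FALSE]
  u <- rowSums(p[, 1:2, drop = FALSE] * uax)
  # bore surface along the facet normal at transaxial offset u
  disc <- s$inner_radius^2 - u^2
  s0 <- ifelse(disc > 0, sqrt(pmax(disc, 0)), NA_real_)
  depth <- sdist - s0
  r_xy <- sqrt(p[, 1]^2 + p[, 2]^2)
  # inside the polygon prism means below the apothem on EVERY facet plane,
  # i.e. the maximum along-normal distance is below the apothem
  max_d <- d[cbind(seq_len(nrow(p)), facet)]
  inside <- r_xy >= s$inner_radius - 1e-9 &
    max_d <= s$facet_apothem + 1e-9 &
    abs(p[, 3]) <= s$length / 2 + 1e-9
  data.frame(facet = facet - 1L, u = u, v = p[, 3], depth = depth,
             inside = inside)
}

#' Test whether world points lie inside the scintillator solid
#' @param g A `scanner_geometry`.
#' @param p Numeric 3-vector or n x 3 matrix, mm.
#' @return Logical vector.
#' @export
in_annulus <- function(g, p) locate_point(g, p)$inside

#' Clamp world points to the scintillator solid
#'
#' Points outside the annulus are moved to the (approximately) nearest point
#' of the solid: the axial coordinate is clamped to the annulus length and
#' the radial coordinate, taken along the assigned facet's normal, is clamped
#' between the bore surface and the facet plane.
#'
#' @param g A `scanner_geometry`.
#' @param p Numeric 3-vector or n x 3 matrix, mm.
#' @return List with `p` (clamped n x 3 matrix) and `clamped` logical vector.
#' @export
clamp_to_annulus <- function(g, p) {
  p <- to_matrix3(p)
  s <- g$spec
  loc <- locate_point(g, p)
  out <- p
  out[, 3] <- pmin(pmax(p[, 3], -s$length / 2), s$length / 2)
  f <- loc$facet + 1L
  u <- loc$u
  half_w <- s$facet_width / 2
  u <- pmin(pmax(u, -half_w), half_w)
  # radial clamp along the facet normal
  nrm <- g$frames$normal[f, 1:2, drop = FALSE]
  sdist <- rowSums(p[, 1:2, drop = FALSE] * nrm)
  s_lo <- sqrt(pmax(s$inner_radius^2 - u^2, 0))
  sdist <- pmin(pmax(sdist, s_lo), s$facet_apothem)
  uax <- g$frames$u[f, 1:2, drop = FALSE]
  out[, 1:2] <- nrm * sdist + uax * u
  clamped <- rowSums(abs(out - p)) > 1e-9
  list(p = out, clamped = clamped)
}

#' Facet-local to world coordinates
#'
#' @param g A `scanner_geometry`.
#' @param facet 0-based facet index (vectorized).
#' @param u Transaxial offset in the facet frame, mm.
#' @param v Axial coordinate, mm.
#' @param depth Distance from the bore surface along the facet normal, mm.
#' @return n x 3 matrix of world coordinates.
#' @export
facet_to_world <- function(g, facet, u, v, depth) {
  s <- g$spec
  f <- as.integer(facet) + 1L
  s0 <- sqrt(pmax(s$inner_radius^2 - u^2, 0))
  sdist <- s0 + depth
  nrm <- g$frames$normal[f, 1:2, drop = FALSE]
  uax <- g$frames$u[f, 1:2, drop = FALSE]
  xy <- nrm * sdist + uax * u
  cbind(xy, v)
}

#' Geometry summary as a plain list (for JSON dumps)
#' @param g A `scanner_geometry`.
#' @return A list of plain vectors suitable for `jsonlite::toJSON`.
#' @export
geometry_to_list <- function(g) {
  list(
    annulus = unclass(g$spec),
    sensors = unclass(g$sensors)[c("arrays_per_facet", "array_pixels",
                                   "pixel_size", "pixel_pitch")],
    virtual = unclass(g$virtual),
    partner_offsets = g$partner_offsets,
    facet_azimuth_deg = g$frames$azimuth * 180 / pi
  )
}

# internal: accept a 3-vector or n x 3 matrix
to_matrix3 <- function(p) {
  if (is.null(dim(p))) {
    stopifnot(length(p) == 3)
    p <- matrix(p, nrow = 1)
  }
  storage.mode(p) <- "double"
  stopifnot(ncol(p) == 3)
  p
}
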