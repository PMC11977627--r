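#' Project estimated LOR endpoints onto the virtual pseudo-detectors
#'
#' The infinite line through the two 3-D position estimates is intersected
#' with each endpoint's facet plane (the virtual pseudo-detector tangent to
#' the 30 mm circle, sharing the facet's frame); each intersection is
#' binned into the plane's 16 x 84 element grid (bin index =
#' `floor((coord - grid_min)/element_size)`, boundary points to the lower
#' index). Lines that miss either grid are rejected with a reason.
#'
#' @param e1,e2 `n x 3` matrices (or data.frames with x, y, z) of endpoint
#'   estimates, mm.
#' @param f1,f2 0-based facet ids of the two endpoints.
#' @param g A `scanner_geometry`.
#' @param times Optional per-LOR timestamps (ns).
#' @return Object of class `projected_lors`: data.frame with `plane1, iu1,
#'   iv1, plane2, iu2, iv2, time_ns, weight` (weight initialized to 1) for
#'   accepted LORs, plus attribute `"rejects"` (named counts).
#' @export
project_lor <- function(e1, e2, f1, f2, g, times = NULL) {
  if (is.data.frame(e1)) e1 <- cbind(e1$x, e1$y, e1$z)
  if (is.data.frame(e2)) e2 <- cbind(e2$x, e2$y, e2$z)
  e1 <- to_matrix3(e1); e2 <- to_matrix3(e2)
  n <- nrow(e1)
  if (is.null(times)) times <- rep(0, n)
  f1 <- as.integer(f1); f2 <- as.integer(f2)
  vd <- g$virtual
  dirv <- e2 - e1
  dl <- sqrt(rowSums(dirv^2))
  degenerate <- dl < 1e-9

  intersect_plane <- function(f) {
    nrm <- g$frames$normal[f + 1L, , drop = FALSE]
    denom <- rowSums(dirv * nrm)
    tpar <- abs(denom) < 1e-12
    tt <- (vd$plane_radius - rowSums(e1 * nrm)) / denom
    pt <- e1 + dirv * tt
    u <- rowSums(pt[, 1:2, drop = FALSE] *
                   g$frames$u[f + 1L, 1:2, drop = FALSE])
    list(u = u, z = pt[, 3], parallel = tpar)
  }
  i1 <- intersect_plane(f1)
  i2 <- intersect_plane(f2)
  half_u <- vd$elements_transaxial * vd$element_size / 2
  half_z <- vd$elements_axial * vd$element_size / 2
  bin <- function(coord, half) {
    as.integer(floor((coord + half) / vd$element_size))
  }
  iu1 <- bin(i1$u, half_u); iv1 <- bin(i1$z, half_z)
  iu2 <- bin(i2$u, half_u); iv2 <- bin(i2$z, half_z)
  in1 <- iu1 >= 0 & iu1 < vd$elements_transaxial &
    iv1 >= 0 & iv1 < vd$elements_axial
  in2 <- iu2 >= 0 & iu2 < vd$elements_transaxial &
    iv2 >= 0 & iv2 < vd$elements_axial
  ok <- !degenerate & !i1$parallel & !i2$parallel & in1 & in2
  rejects <- c(degenerate = sum(degenerate),
               parallel = sum((i1$parallel | i2$parallel) & !degenerate),
               off_grid = sum(!ok & !degenerate & !i1$parallel &
                                !i2$parallel))
  out <- data.frame(plane1 = f1[ok], iu1 = iu1[ok], iv1 = iv1[ok],
                    plane2 = f2[ok], iu2 = iu2[ok], iv2 = iv2[ok],
                    time_ns = times[ok], weight = rep(1, sum(ok)))
  attr(out, "rejects") <- rejects
  class(out) <- c("projected_lors", "data.frame")
  out
}

#' World coordinates of virtual-detector element centres
#'
#' @param plane 0-based plane (facet) id, vectorized.
#' @param iu,iv 0-based transaxial/axial element indices.
#' @param g A `scanner_geometry`.
#' @return `n x 3` matrix of world coordinates, mm.
#' @export
element_center <- function(plane, iu, iv, g) {
  vd <- g$virtual
  u <- (iu + 0.5) * vd$element_size -
    vd$elements_transaxial * vd$element_size / 2
  z <- (iv + 0.5) * vd$element_size -
    vd$elements_axial * vd$element_size / 2
  f <- as.integer(plane) + 1L
  nrm <- g$frames$normal[f, 1:2, drop = FALSE]
  uax <- g$frames$u[f, 1:2, drop = FALSE]
  xy <- nrm * vd$plane_radius + uax * u
  cbind(xy, z)
}

#' Attenuation correction weights for projected LORs
#'
#' @param lors A `projected_lors` data.frame.
#' @param mu_map A `mu_map` (or `NULL` for unit weights).
#' @param g A `scanner_geometry`.
#' @return Numeric vector of weights `exp(+integral of mu dl)` along the
#'   chord between the two element centres (1 in air).
#' @export
attenuation_weight <- function(lors, mu_map, g) {
  if (is.null(mu_map)) return(rep(1, nrow(lors)))
  p1 <- element_center(lors$plane1, lors$iu1, lors$iv1, g)
  p2 <- element_center(lors$plane2, lors$iu2, lors$iv2, g)
  tau <- cpp_line_integrals(p1, p2, as.numeric(mu_map$values),
                            dim(mu_map$values), mu_map$voxel_size,
                            mu_map$origin)
  exp(tau)
}

#' Randoms estimate from singles rates
#'
#' For each coincidence-partner facet pair (i, j) the expected random rate
#' is `window * S_i * S_j` with the window expressed as the accepted |dt|
#' range.
#'
#' @param singles_rates Per-facet singles rates, counts/s.
#' @param g A `scanner_geometry`.
#' @param window Coincidence window (max |dt|), ns.
#' @return Object of class `randoms_estimate`: data.frame `facet_i,
#'   facet_j, rate_cps` for all unordered partner pairs, with attribute
#'   `"total_cps"`.
#' @export
estimate_randoms <- function(singles_rates, g, window = 2.0) {
  stopifnot(all(singles_rates >= 0),
            length(singles_rates) == g$spec$n_facets)
  w_s <- window * 1e-9
  rows <- list()
  for (i in seq_len(g$spec$n_facets) - 1L) {
    for (j in coincidence_partners(g, i)) {
      if (j > i) {
        rows[[length(rows) + 1]] <- data.frame(
          facet_i = i, facet_j = j,
          rate_cps = w_s * singles_rates[i + 1] * singles_rates[j + 1])
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "total_cps") <- sum(out$rate_cps)
  class(out) <- c("randoms_estimate", "data.frame")
  out
}

#' Delayed-window randoms measurement (oracle for the singles estimate)
#'
#' Counts partner-facet pairs whose arrival-time difference falls in an
#' acceptance of the same full width as the prompt window but offset by
#' `delay` (far outside it) - an unbiased measurement of the accidental
#' coincidence count. The scan visits each stream ordering once, so the
#' raw pair count is halved to match the folded prompt acceptance.
#'
#' @param singles A `singles` object.
#' @param g A `scanner_geometry`.
#' @param window Full window width, ns (as in [daq_config()]).
#' @param delay Delay offset, ns.
#' @return Delayed-coincidence count (numeric).
#' @export
delayed_window_randoms <- function(singles, g, window = 2.0, delay = 500) {
  df <- singles$df
  t <- df$time_ns
  n <- length(t)
  if (n < 2) return(0)
  h <- window / 2
  lo <- findInterval(t + delay - h, t, left.open = TRUE) + 1L
  hi <- findInterval(t + delay + h, t)
  cnt <- 0
  nf <- g$spec$n_facets
  maxk <- max(hi - lo + 1L, 0L)
  for (k in seq_len(maxk)) {
    j <- lo + k - 1L
    sel <- which(j <= hi & j >= 1L & j <= n)
    if (length(sel) == 0) next
    off <- (df$facet[j[sel]] - df$facet[sel]) %% nf
    cnt <- cnt + sum(off %in% g$partner_offsets)
  }
  cnt / 2
}

#' Single-slice rebinning of projected LORs
#'
#' Each LOR is assigned to the axial slice at the mean of its two axial
#' element indices on the doubled grid (2*n_axial - 1 slices); the
#' transaxial bin is computed from the in-plane chord (signed radial
#' offset from the axis and azimuth over \[0, pi)). LORs with axial element
#' difference above `max_ring_diff` are rejected and counted.
#'
#' @param lors A `projected_lors` data.frame.
#' @param g A `scanner_geometry`.
#' @param n_angles Angular bins over \[0, pi).
#' @param radial_bin Radial bin width, mm.
#' @param radial_extent Half-extent of the radial axis, mm.
#' @param max_ring_diff Maximum axial element difference accepted.
#' @param weights Optional per-LOR weights (e.g. attenuation corrections).
#' @return Object of class `ssrb_sinogram`: list with `counts` (array
#'   `n_radial x n_angles x n_slices`), bin metadata, and `n_rejected`.
#' @export
ssrb_rebin <- function(lors, g, n_angles = 128, radial_bin = 0.42,
                       radial_extent = 30, max_ring_diff = Inf,
                       weights = NULL) {
  vd <- g$virtual
  n_slices <- 2L * vd$elements_axial - 1L
  n_radial <- 2L * ceiling(radial_extent / radial_bin)
  if (is.null(weights)) weights <- lors$weight
  n <- nrow(lors)
  counts <- array(0, dim = c(n_radial, n_angles, n_slices))
  meta <- list(n_radial = n_radial, n_angles = n_angles,
               n_slices = n_slices, radial_bin = radial_bin,
               radial_extent = radial_extent,
               slice_pitch = vd$element_size / 2)
  if (n == 0) {
    return(structure(c(list(counts = counts), meta, n_rejected = 0),
                     class = "ssrb_sinogram"))
  }
  ring_diff <- abs(lors$iv1 - lors$iv2)
  keep <- ring_diff <= max_ring_diff
  slice <- lors$iv1 + lors$iv2          # doubled-grid slice index (0-based)
  p1 <- element_center(lors$plane1, lors$iu1, lors$iv1, g)
  p2 <- element_center(lors$plane2, lors$iu2, lors$iv2, g)
  dx <- p2[, 1] - p1[, 1]; dy <- p2[, 2] - p1[, 2]
  L <- sqrt(dx^2 + dy^2)
  ok <- keep & L > 1e-9
  # signed radial offset of the chord and its angle in [0, pi)
  phi <- atan2(dy, dx) + pi / 2          # normal direction of the chord
  r <- p1[, 1] * cos(phi) + p1[, 2] * sin(phi)
  neg <- phi < 0; phi[neg] <- phi[neg] + pi; r[neg] <- -r[neg]
  wrap <- phi >= pi; phi[wrap] <- phi[wrap] - pi; r[wrap] <- -r[wrap]
  ir <- floor((r + radial_extent) / radial_bin)
  ia <- floor(phi / (pi / n_angles))
  ia[ia >= n_angles] <- n_angles - 1L
  ok <- ok & ir >= 0 & ir < n_radial
  idx <- cbind(ir[ok] + 1L, ia[ok] + 1L, slice[ok] + 1L)
  w <- weights[ok]
  # accumulate (vectorized over unique bins)
  lin <- (idx[, 3] - 1) * (n_radial * n_angles) +
    (idx[, 2] - 1) * n_radial + idx[, 1]
  acc <- rowsum(w, lin)
  counts[as.integer(rownames(acc))] <- acc
  structure(c(list(counts = counts), meta,
              list(n_rejected = sum(!ok))), class = "ssrb_sinogram")
}

#' Filtered backprojection of one sinogram slice
#'
#' Ramp filter (optionally apodized with a Hann window) applied in
#' frequency space along the radial axis, followed by linear-interpolation
#' backprojection onto a square pixel grid.
#'
#' @param slice `n_radial x n_angles` matrix of sinogram counts.
#' @param radial_bin Radial bin width, mm.
#' @param pixel_size Output pixel size, mm.
#' @param n_pixels Output image side, pixels.
#' @param apodize Use a Hann window on top of the ramp.
#' @return `n_pixels x n_pixels` image matrix (x fastest, centred on the
#'   scanner axis).
#' @export
fbp2d <- function(slice, radial_bin = 0.42, pixel_size = 0.25,
                  n_pixels = 256, apodize = FALSE) {
  nr <- nrow(slice); na <- ncol(slice)
  if (all(slice == 0)) return(matrix(0, n_pixels, n_pixels))
  # ramp filter with zero-padding to the next power of two
  npad <- 2^ceiling(log2(2 * nr))
  freq <- c(seq(0, npad / 2), seq(-npad / 2 + 1, -1)) / npad
  ramp <- abs(freq)
  if (apodize) ramp <- ramp * (0.5 + 0.5 * cos(pi * freq / max(freq)))
  filtered <- matrix(0, nr, na)
  for (a in seq_len(na)) {
    pr <- c(slice[, a], rep(0, npad - nr))
    fr <- Re(stats::fft(stats::fft(pr) * ramp, inverse = TRUE)) / npad
    filtered[, a] <- fr[seq_len(nr)]
  }
  filtered <- filtered / radial_bin
  # backproject
  half <- n_pixels * pixel_size / 2
  xc <- (seq_len(n_pixels) - 0.5) * pixel_size - half
  img <- matrix(0, n_pixels, n_pixels)
  X <- matrix(xc, n_pixels, n_pixels)
  Y <- matrix(xc, n_pixels, n_pixels, byrow = TRUE)
  r0 <- -(nr / 2 - 0.5) * radial_bin
  for (a in seq_len(na)) {
    phi <- (a - 0.5) * pi / na
    tpos <- (X * cos(phi) + Y * sin(phi) - r0) / radial_bin + 1
    t0 <- floor(tpos)
    frac <- tpos - t0
    v0 <- ifelse(t0 >= 1 & t0 <= nr, filtered[pmin(pmax(t0, 1), nr), a], 0)
    v1 <- ifelse(t0 + 1 >= 1 & t0 + 1 <= nr,
                 filtered[pmin(pmax(t0 + 1, 1), nr), a], 0)
    img <- img + (1 - frac) * v0 + frac * v1
  }
  img * pi / na
}

#' Reconstruct a volume with SSRB + 2-D FBP
#'
#' @param sino An `ssrb_sinogram`.
#' @param pixel_size In-plane voxel size, mm.
#' @param n_pixels In-plane image side.
#' @param apodize Hann apodization flag passed to [fbp2d()].
#' @return Object of class `image_volume`: list with `values`
#'   (`n_pixels x n_pixels x n_slices`), `voxel_size` (xy), `slice_pitch`
#'   (z), `origin` (world corner of voxel \[1,1,1\]).
#' @export
fbp_reconstruct <- function(sino, pixel_size = 0.25, n_pixels = 256,
                            apodize = FALSE) {
  vals <- array(0, dim = c(n_pixels, n_pixels, sino$n_slices))
  for (s in seq_len(sino$n_slices)) {
    sl <- sino$counts[, , s]
    if (any(sl > 0)) {
      vals[, , s] <- fbp2d(sl, sino$radial_bin, pixel_size, n_pixels,
                           apodize)
    }
  }
  z0 <- -(sino$n_slices / 2) * sino$slice_pitch
  structure(list(values = vals, voxel_size = pixel_size,
                 slice_pitch = sino$slice_pitch,
                 origin = c(-n_pixels / 2 * pixel_size,
                            -n_pixels / 2 * pixel_size, z0)),
            class = "image_volume")
}

#' Geometric detection efficiency of LOR bins
#'
#' Analytic per-LOR normalization factors: obliquity of the line on the
#' two virtual planes (`cos(theta1) * cos(theta2)`), inverse square of the
#' endpoint separation, and the probability that each annihilation photon
#' interacts in the crystal along its outward path
#' (`1 - exp(-mu_total * chord)`). Used consistently in the MLEM forward
#' model and the sensitivity image.
#'
#' @param p1,p2 `n x 3` matrices of element-centre world coordinates.
#' @param plane1,plane2 0-based plane ids.
#' @param g A `scanner_geometry`.
#' @param mu_lyso Total LYSO attenuation at 511 keV, 1/mm.
#' @return Numeric vector of relative efficiencies.
#' @export
lor_efficiency <- function(p1, p2, plane1, plane2, g, mu_lyso = 0.087) {
  d <- p2 - p1
  L <- sqrt(rowSums(d^2))
  dn <- d / L
  n1 <- g$frames$normal[as.integer(plane1) + 1L, , drop = FALSE]
  n2 <- g$frames$normal[as.integer(plane2) + 1L, , drop = FALSE]
  cos1 <- abs(rowSums(dn * n1))
  cos2 <- abs(rowSums(dn * n2))
  # crystal chords outward from each endpoint
  chord <- function(p, dirv) {
    iv <- crystal_intervals(g, p, dirv)
    pmax(iv[, "b1"] - iv[, "a1"], 0) + pmax(iv[, "b2"] - iv[, "a2"], 0)
  }
  c1 <- chord(p1, -dn)
  c2 <- chord(p2, dn)
  pint <- (1 - exp(-mu_lyso * c1)) * (1 - exp(-mu_lyso * c2))
  cos1 * cos2 / L^2 * pint
}

#' Analytic sensitivity image for list-mode MLEM
#'
#' Backprojects the full allowed LOR set (optionally subsampled by
#' `stride` in each element axis, with intersection lengths scaled
#' accordingly) with attenuation weights, giving each voxel's detection
#' sensitivity.
#'
#' @param g A `scanner_geometry`.
#' @param dims Image dimensions (length 3).
#' @param voxel_size Isotropic voxel size, mm.
#' @param origin World corner of voxel \[1,1,1\].
#' @param mu_map Optional `mu_map` for attenuation weighting of the LORs
#'   (sensitivity uses 1/weight = survival probability).
#' @param stride Element subsampling stride (>= 1).
#' @param jitter Sample ray endpoints uniformly within each element
#'   instead of at its centre (unbiased quadrature of the bin acceptance;
#'   deterministic via `jitter_seed`).
#' @param jitter_seed Seed for the jittered quadrature.
#' @return 3-D array of sensitivities.
#' @export
mlem_sensitivity <- function(g, dims, voxel_size, origin, mu_map = NULL,
                             stride = 2, jitter = TRUE, jitter_seed = 7) {
  vd <- g$virtual
  ius <- seq(0, vd$elements_transaxial - 1, by = stride)
  ivs <- seq(0, vd$elements_axial - 1, by = stride)
  grid <- expand.grid(iu = ius, iv = ivs)
  sens <- array(0, dim = dims)
  pairs <- list()
  for (i in seq_len(g$spec$n_facets) - 1L) {
    for (j in coincidence_partners(g, i)) if (j > i) {
      pairs[[length(pairs) + 1]] <- c(i, j)
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(jitter_seed)
  es <- vd$element_size
  for (pr in pairs) {
    c1 <- element_center(rep(pr[1], nrow(grid)), grid$iu, grid$iv, g)
    c2 <- element_center(rep(pr[2], nrow(grid)), grid$iu, grid$iv, g)
    # all element pairs between the two planes (outer product over grids)
    n1 <- nrow(c1)
    ia <- rep(seq_len(n1), each = n1)
    ib <- rep(seq_len(n1), times = n1)
    p1 <- c1[ia, , drop = FALSE]
    p2 <- c2[ib, , drop = FALSE]
    if (jitter) {
      # uniform offsets within the element, in each plane's (u, z) frame;
      # the covered strip widens to stride*element_size in each axis
      ju <- function(n) stats::runif(n, -stride * es / 2, stride * es / 2)
      u1 <- g$frames$u[pr[1] + 1L, 1:2]
      u2 <- g$frames$u[pr[2] + 1L, 1:2]
      n_l <- length(ia)
      o1u <- ju(n_l); o1z <- ju(n_l)
      o2u <- ju(n_l); o2z <- ju(n_l)
      p1 <- p1 + cbind(o1u * u1[1], o1u * u1[2], o1z)
      p2 <- p2 + cbind(o2u * u2[1], o2u * u2[2], o2z)
    }
    w <- lor_efficiency(p1, p2, rep(pr[1], length(ia)),
                        rep(pr[2], length(ia)), g)
    if (!is.null(mu_map)) {
      tau <- cpp_line_integrals(p1, p2, as.numeric(mu_map$values),
                                dim(mu_map$values), mu_map$voxel_size,
                                mu_map$origin)
      w <- w * exp(-tau)
    }
    sens <- sens + cpp_backproject(p1, p2, w, dims, voxel_size, origin)
  }
  sens * stride^4
}

#' Monte-Carlo normalization sensitivity for list-mode MLEM
#'
#' Estimates each voxel's detection sensitivity by simulating a uniform
#' emission density over a cylinder covering the field of view, running
#' the truth-level acceptance chain (first interactions in the crystal,
#' partner-facet test, projection onto the virtual detector grids) and
#' backprojecting the accepted LOR bins. This captures acceptance effects
#' that the analytic solid-angle model misses (facet-sector assignment of
#' oblique chains, grid-edge losses). Attenuation enters analytically as a
#' per-LOR survival weight when `mu_map` is given.
#'
#' @param g A `scanner_geometry`.
#' @param dims,voxel_size,origin Image grid.
#' @param n_events Normalization simulation size.
#' @param seed Integer seed.
#' @param mu_map Optional `mu_map`; accepted LORs are weighted by
#'   `exp(-integral of mu dl)`.
#' @param fov_radius,fov_length Uniform emission region, mm.
#' @return 3-D array of relative sensitivities.
#' @export
mlem_sensitivity_mc <- function(g, dims, voxel_size, origin,
                                n_events = 1e6, seed = 99, mu_map = NULL,
                                fov_radius = 28,
                                fov_length = g$spec$length * 0.97,
                                chunk = 5e5) {
  src <- cylinder_phantom(activity = 1e6, diameter = 2 * fov_radius,
                          length = fov_length)
  phys <- physics_config(object_attenuation = FALSE,
                         acollinearity_fwhm_deg = 0,
                         positron_range = FALSE)
  sens <- array(0, dim = dims)
  done <- 0; blk <- 0; total_lors <- 0
  while (done < n_events) {
    blk <- blk + 1
    nb <- min(chunk, n_events - done)
    truth <- simulate_events(src, g, phys, n = nb, seed = seed + blk)
    lors <- truth_lors(truth, g)
    rm(truth)
    done <- done + nb
    if (nrow(lors) == 0) next
    total_lors <- total_lors + nrow(lors)
    p1 <- element_center(lors$plane1, lors$iu1, lors$iv1, g)
    p2 <- element_center(lors$plane2, lors$iu2, lors$iv2, g)
    # divide out the normalization phantom's line integral: bins crossed
    # by longer emission chords collect proportionally more lines
    emis <- list(shape = "cylinder", radius = fov_radius,
                 half_length = fov_length / 2, center = c(0, 0, 0))
    dseg <- p2 - p1
    L <- sqrt(rowSums(dseg^2))
    dn <- dseg / L
    ivc <- object_interval(emis, p1, dn)
    chord <- pmin(ivc[, 2], L) - pmax(ivc[, 1], 0)
    good <- chord > 1
    lors <- lors[good, , drop = FALSE]
    p1 <- p1[good, , drop = FALSE]
    p2 <- p2[good, , drop = FALSE]
    w <- 1 / chord[good]
    if (!is.null(mu_map)) {
      tau <- cpp_line_integrals(p1, p2, as.numeric(mu_map$values),
                                dim(mu_map$values), mu_map$voxel_size,
                                mu_map$origin)
      w <- w * exp(-tau)
    }
    sens <- sens + cpp_backproject(p1, p2, w, as.integer(dims),
                                   voxel_size, origin)
  }
  if (total_lors == 0) stop("normalization simulation produced no LORs")
  sens
}

#' Truth-level LORs from simulated events
#'
#' Pairs each event's two first interactions, keeps partner-facet pairs,
#' and projects them onto the virtual detectors (oracle positioning: no
#' optics, noise or network involved).
#'
#' @param truth An `event_truth`.
#' @param g A `scanner_geometry`.
#' @param exclude_object_scatter Drop pairs where either photon Compton
#'   scattered in the object before reaching the crystal (useful when
#'   studying corrections other than scatter, which this package does not
#'   correct for).
#' @return A `projected_lors` data.frame.
#' @export
truth_lors <- function(truth, g, exclude_object_scatter = FALSE) {
  ph <- truth$photons
  ok <- !is.na(ph$fx)
  if (exclude_object_scatter) ok <- ok & !ph$object_scattered
  a <- ph[ok & ph$photon == 1L, c("event", "fx", "fy", "fz")]
  b <- ph[ok & ph$photon == 2L, c("event", "fx", "fy", "fz")]
  m <- merge(a, b, by = "event", suffixes = c("1", "2"))
  if (nrow(m) == 0) {
    return(project_lor(matrix(0, 0, 3), matrix(0, 0, 3), integer(0),
                       integer(0), g))
  }
  p1 <- cbind(m$fx1, m$fy1, m$fz1)
  p2 <- cbind(m$fx2, m$fy2, m$fz2)
  f1 <- locate_point(g, p1)$facet
  f2 <- locate_point(g, p2)$facet
  nf <- g$spec$n_facets
  keep <- ((f2 - f1) %% nf) %in% g$partner_offsets |
    ((f1 - f2) %% nf) %in% g$partner_offsets
  ev <- truth$events
  times <- ev$time_ns[match(m$event[keep], ev$event)]
  project_lor(p1[keep, , drop = FALSE], p2[keep, , drop = FALSE],
              f1[keep], f2[keep], g, times)
}

#' List-mode MLEM reconstruction
#'
#' Maximum-likelihood EM for list-mode PET data with on-the-fly exact
#' voxel ray tracing between element centres, multiplicative per-LOR
#' attenuation weights and additive expected randoms in the forward model.
#' Zero-sensitivity voxels are masked. The recorded log-likelihood (up to
#' a data-independent constant) is non-decreasing.
#'
#' @param lors A `projected_lors` data.frame.
#' @param g A `scanner_geometry`.
#' @param n_iter Iterations (>= 1).
#' @param dims Image dimensions (length 3; default 96 x 96 x 288).
#' @param voxel_size Isotropic voxel size, mm.
#' @param origin World corner of voxel \[1,1,1\] (default centres the grid).
#' @param weights Per-LOR multiplicative forward-model factors (survival
#'   probabilities, <= 1). The default converts the stored correction
#'   weights (`lors$weight`, >= 1) to survivals via `1/weight`, so
#'   attenuation enters the system model consistently with the
#'   attenuation-weighted sensitivity image.
#' @param randoms Per-LOR additive expected randoms (scalar or vector).
#' @param sens Sensitivity image (array matching `dims`); computed with
#'   [mlem_sensitivity()] when `NULL`.
#' @param mu_map Passed to [mlem_sensitivity()] when `sens` is `NULL`.
#' @param sens_stride Subsampling stride for the sensitivity image.
#' @return Object of class `image_volume` with extra fields `loglik`
#'   (per-iteration) and `n_lors`.
#' @export
mlem_reconstruct <- function(lors, g, n_iter = 20,
                             dims = c(96, 96, 288), voxel_size = 0.25,
                             origin = NULL, weights = NULL, randoms = 0,
                             sens = NULL, mu_map = NULL, sens_stride = 2) {
  if (nrow(lors) == 0) stop("no LORs to reconstruct")
  stopifnot(n_iter >= 1)
  if (is.null(origin)) origin <- -dims * voxel_size / 2
  p1 <- element_center(lors$plane1, lors$iu1, lors$iv1, g)
  p2 <- element_center(lors$plane2, lors$iu2, lors$iv2, g)
  if (is.null(weights)) {
    # survival (1/correction) x geometric bin efficiency, matching the
    # efficiency model inside the sensitivity image
    weights <- lor_efficiency(p1, p2, lors$plane1, lors$plane2, g) /
      lors$weight
  }
  weights <- rep_len(weights, nrow(lors))
  randoms <- rep_len(randoms, nrow(lors))
  if (is.null(sens)) {
    sens <- mlem_sensitivity(g, dims, voxel_size, origin, mu_map,
                             sens_stride)
  }
  init <- array(1, dim = dims)
  init[sens <= 0] <- 0
  res <- cpp_mlem(p1, p2, weights, randoms, as.numeric(sens),
                  as.integer(dims), voxel_size, origin, as.integer(n_iter),
                  as.numeric(init))
  structure(list(values = res$image, voxel_size = voxel_size,
                 slice_pitch = voxel_size, origin = origin,
                 loglik = res$loglik, sens = sens, n_lors = nrow(lors)),
            class = "image_volume")
}

#' World coordinates of an image volume's voxel centres along each axis
#' @param vol An `image_volume`.
#' @return List with numeric vectors `x`, `y`, `z`.
#' @export
volume_axes <- function(vol) {
  d <- dim(vol$values)
  zstep <- if (!is.null(vol$slice_pitch)) vol$slice_pitch else vol$voxel_size
  list(x = vol$origin[1] + (seq_len(d[1]) - 0.5) * vol$voxel_size,
       y = vol$origin[2] + (seq_len(d[2]) - 0.5) * vol$voxel_size,
       z = vol$origin[3] + (seq_len(d[3]) - 0.5) * zstep)
}
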