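#' Point-source spatial resolution (NU4 style)
#'
#' Forms one-dimensional response functions along the radial, tangential
#' and axial axes by summing the volume over the two orthogonal directions
#' within a window of +/- 2 FWHM (two passes: the first with the full
#' extent to get a provisional FWHM, the second restricted to the window).
#' The peak amplitude is a parabolic fit through the three highest
#' samples; FWHM and FWTM come from linear interpolation between the
#' samples bracketing the half/tenth maximum. No function fitting is used.
#'
#' @param vol An `image_volume` containing a single point-source image.
#' @param source_xy World xy of the source (defines the radial direction;
#'   a source on the axis uses x as radial).
#' @return Object of class `resolution_result`: data.frame with one row
#'   per direction (`direction, fwhm, fwtm, peak`), mm.
#' @export
resolution_metrics <- function(vol, source_xy = c(0, 0)) {
  ax <- volume_axes(vol)
  v <- vol$values
  # rotate x to the radial direction of the source
  theta <- if (sqrt(sum(source_xy^2)) > 1e-6) {
    atan2(source_xy[2], source_xy[1])
  } else 0
  # centre of the response: the global maximum voxel, in rotated coords
  am <- which(v == max(v), arr.ind = TRUE)[1, ]
  ct <- cos(theta); st <- sin(theta)
  cx <- ax$x[am[1]]; cy <- ax$y[am[2]]; cz <- ax$z[am[3]]
  center <- c(r = cx * ct + cy * st, t = -cx * st + cy * ct, z = cz)
  rows <- lapply(c("radial", "tangential", "axial"), function(nm) {
    pr <- profile_1d(v, ax, nm, theta, center = center)
    est <- width_estimates(pr$coord, pr$profile)
    # second pass: restrict the orthogonal sums to +/- 2 FWHM
    pr2 <- profile_1d(v, ax, nm, theta, window = 2 * est$fwhm,
                      center = center)
    est2 <- width_estimates(pr2$coord, pr2$profile)
    data.frame(direction = nm, fwhm = est2$fwhm, fwtm = est2$fwtm,
               peak = est2$peak)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("resolution_result", "data.frame")
  out
}

# 1-D response function along a named direction, summing the two
# orthogonal directions (restricted to +/- window around `center`, given
# in rotated (r, t, z) coordinates)
profile_1d <- function(v, ax, direction, theta = 0, window = Inf,
                       center = c(0, 0, 0)) {
  nx <- dim(v)[1]; ny <- dim(v)[2]; nz <- dim(v)[3]
  ct <- cos(theta); st <- sin(theta)
  X <- matrix(ax$x, nx, ny)
  Y <- matrix(ax$y, nx, ny, byrow = TRUE)
  R <- X * ct + Y * st
  T_ <- -X * st + Y * ct
  if (direction %in% c("radial", "tangential")) {
    main <- if (direction == "radial") R else T_
    orth <- if (direction == "radial") T_ else R
    orth_c <- if (direction == "radial") center[2] else center[1]
    step <- vol_step(ax$x)
    bins <- as.integer(round(main / step))
    omask <- abs(orth - orth_c) <= window
    zmask <- abs(ax$z - center[3]) <= window
    vz <- apply(v[, , zmask, drop = FALSE], c(1, 2), sum)
    vz[!omask] <- 0
    agg <- rowsum(as.numeric(vz), as.numeric(bins))
    list(coord = as.numeric(rownames(agg)) * step,
         profile = as.numeric(agg))
  } else {
    mask <- abs(R - center[1]) <= window & abs(T_ - center[2]) <= window
    prof <- vapply(seq_len(nz), function(k) sum(v[, , k][mask]), numeric(1))
    list(coord = ax$z, profile = prof)
  }
}

vol_step <- function(x) if (length(x) > 1) x[2] - x[1] else 1

# parabolic peak + linear-interpolated FWHM/FWTM of a sampled profile
width_estimates <- function(coord, profile) {
  if (all(profile <= 0)) stop("no peak found in profile")
  i <- which.max(profile)
  if (i == 1 || i == length(profile)) {
    peak <- profile[i]
    ppos <- coord[i]
  } else {
    y1 <- profile[i - 1]; y2 <- profile[i]; y3 <- profile[i + 1]
    denom <- y1 - 2 * y2 + y3
    dx <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
    peak <- y2 - 0.25 * (y1 - y3) * dx
    ppos <- coord[i] + dx * (coord[2] - coord[1])
  }
  width_at <- function(frac) {
    target <- frac * peak
    above <- which(profile >= target)
    if (length(above) == 0) return(NA_real_)
    lo <- min(above); hi <- max(above)
    left <- if (lo > 1) {
      coord[lo - 1] + (target - profile[lo - 1]) /
        (profile[lo] - profile[lo - 1]) * (coord[lo] - coord[lo - 1])
    } else coord[1]
    right <- if (hi < length(profile)) {
      coord[hi] + (profile[hi] - target) /
        (profile[hi] - profile[hi + 1]) * (coord[hi + 1] - coord[hi])
    } else coord[length(profile)]
    right - left
  }
  list(peak = peak, peak_pos = ppos, fwhm = width_at(0.5),
       fwtm = width_at(0.1))
}

#' FWHM/FWTM of a 1-D profile
#'
#' Convenience wrapper around the NU4-style estimator (parabolic peak,
#' linear-interpolated crossings).
#'
#' @param coord Sample positions, mm.
#' @param profile Sample values.
#' @return List with `fwhm`, `fwtm`, `peak`.
#' @export
profile_widths <- function(coord, profile) {
  est <- width_estimates(coord, profile)
  est[c("fwhm", "fwtm", "peak")]
}

#' Detection sensitivity from an axial position sweep
#'
#' `S_i = (R_i - R_B) / A_cal` per position; absolute sensitivity divides
#' by the positron branching fraction. The integrated values sum over the
#' measured positions.
#'
#' @param rates Measured prompt rates per axial position, cps.
#' @param background Background rate (source out), cps.
#' @param activity Calibrated source activity, Bq.
#' @param nuclide `"Na22"` or `"F18"`.
#' @param positions Axial positions, mm (optional, for the profile).
#' @return Object of class `sensitivity_result`: list with `profile`
#'   (data.frame `position, S_cps_per_Bq, S_absolute_pct`), `peak_S`,
#'   `peak_absolute_pct`, `integrated_S`, `integrated_absolute_pct`.
#' @export
sensitivity_metrics <- function(rates, background = 0, activity,
                                nuclide = "Na22", positions = NULL) {
  if (activity <= 0) stop("calibrated activity must be > 0")
  br <- nuclide_data(nuclide)$positron_branching
  S <- (rates - background) / activity
  SA <- S / br * 100
  if (is.null(positions)) positions <- seq_along(rates)
  structure(list(
    profile = data.frame(position = positions, S_cps_per_Bq = S,
                         S_absolute_pct = SA),
    peak_S = max(S), peak_absolute_pct = max(SA),
    integrated_S = sum(S), integrated_absolute_pct = sum(S) / br * 100),
    class = "sensitivity_result")
}

#' NU4 count-rate analysis of an activity sweep
#'
#' Implements the NU4 count-rate procedure on SSRB sinograms: pixels
#' farther than 8 mm outside the phantom radius are zeroed; each angular
#' row is shifted so its maximum is centred; rows are summed over angles
#' into a radial profile; counts outside a centred 14 mm strip, plus the
#' linearly interpolated background under the strip, form
#' scatter + randoms. Randoms come from the supplied estimates; NECR is
#' `T^2 / Total`; the peak is located by a parabolic fit over the activity
#' sweep; the scatter fraction averages acquisitions with randoms below
#' 1% of trues.
#'
#' @param sinos List of `ssrb_sinogram` objects, one per acquisition.
#' @param activities Activity at each acquisition, Bq.
#' @param durations Acquisition durations, s.
#' @param randoms_rates Estimated randoms rate per acquisition, cps.
#' @param phantom_radius Phantom radius, mm (8 mm margin added).
#' @param strip_halfwidth Half-width of the central strip, mm (7 = 14/2).
#' @return Object of class `countrate_result`: list with `table`
#'   (data.frame `activity_Bq, total_cps, trues_cps, scatter_cps,
#'   randoms_cps, necr_cps`), `peak_necr_cps`, `peak_necr_activity_Bq`,
#'   `scatter_fraction_pct`.
#' @export
countrate_metrics <- function(sinos, activities, durations, randoms_rates,
                              phantom_radius = 12.5, strip_halfwidth = 7) {
  stopifnot(length(sinos) == length(activities),
            length(sinos) == length(durations))
  randoms_rates <- rep_len(randoms_rates, length(sinos))
  rows <- lapply(seq_along(sinos), function(k) {
    sp <- sinogram_strip_counts(sinos[[k]], phantom_radius, strip_halfwidth)
    total <- sp$total / durations[k]
    sr <- sp$scatter_plus_randoms / durations[k]
    trues <- total - sr
    randoms <- min(randoms_rates[k], sr)
    scatter <- sr - randoms
    necr <- if (total > 0) trues^2 / total else 0
    data.frame(activity_Bq = activities[k], total_cps = total,
               trues_cps = trues, scatter_cps = scatter,
               randoms_cps = randoms, necr_cps = necr)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$activity_Bq), ]
  # peak NECR by parabolic interpolation over the sweep
  i <- which.max(tab$necr_cps)
  if (i > 1 && i < nrow(tab)) {
    xs <- tab$activity_Bq[(i - 1):(i + 1)]
    ys <- tab$necr_cps[(i - 1):(i + 1)]
    co <- stats::coef(stats::lm(ys ~ xs + I(xs^2)))
    peak_a <- if (is.finite(co[3]) && co[3] < 0) {
      -co[2] / (2 * co[3])
    } else tab$activity_Bq[i]
    peak_n <- co[1] + co[2] * peak_a + co[3] * peak_a^2
    if (!is.finite(peak_n) || peak_n < tab$necr_cps[i]) {
      peak_a <- tab$activity_Bq[i]; peak_n <- tab$necr_cps[i]
    }
  } else {
    peak_a <- tab$activity_Bq[i]; peak_n <- tab$necr_cps[i]
  }
  low <- tab$randoms_cps < 0.01 * tab$trues_cps & tab$trues_cps > 0
  sf <- if (any(low)) {
    mean(tab$scatter_cps[low] / (tab$trues_cps[low] + tab$scatter_cps[low]))
  } else NA_real_
  structure(list(table = tab, peak_necr_cps = peak_n,
                 peak_necr_activity_Bq = peak_a,
                 scatter_fraction_pct = sf * 100),
            class = "countrate_result")
}

# NU4 strip analysis of one sinogram: total counts and scatter+randoms
sinogram_strip_counts <- function(sino, phantom_radius, strip_halfwidth) {
  nr <- sino$n_radial
  rc <- (seq_len(nr) - 0.5) * sino$radial_bin - sino$radial_extent
  lim <- phantom_radius + 8
  total <- 0; sr <- 0
  for (s in seq_len(sino$n_slices)) {
    sl <- sino$counts[, , s]
    if (!any(sl > 0)) next
    sl[abs(rc) > lim, ] <- 0
    # align each angular row's maximum to the centre
    ctr <- floor(nr / 2) + 1L
    for (a in seq_len(ncol(sl))) {
      im <- which.max(sl[, a])
      if (sl[im, a] > 0 && im != ctr) {
        sl[, a] <- shift_vec(sl[, a], ctr - im)
      }
    }
    prof <- rowSums(sl)
    total <- total + sum(prof)
    # edges of the 14 mm strip; linear background underneath
    inside <- abs(rc) <= strip_halfwidth
    li <- min(which(inside)); ri <- max(which(inside))
    cl <- prof[li]; cr <- prof[ri]
    n_in <- ri - li + 1
    bkg <- (cl + cr) / 2 * n_in
    sr <- sr + sum(prof[!inside]) + bkg
  }
  list(total = total, scatter_plus_randoms = min(sr, total))
}

shift_vec <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  src <- seq_len(n) - k
  okk <- src >= 1 & src <= n
  out[okk] <- x[src[okk]]
  out
}

#' NU4 image-quality metrics
#'
#' Uniformity over a 22.5 mm diameter x 10 mm cylindrical VOI centred in
#' the uniform region; recovery coefficients from the 10 mm axial average
#' of the rod region (maximum pixel in a 2x-diameter ROI around each rod,
#' then the axial line profile at that transverse position), with the NU4
#' combined percent standard deviation; spillover ratios as the mean in a
#' 4 mm diameter x 7.5 mm VOI inside each cold chamber divided by the
#' uniform mean.
#'
#' @param vol An `image_volume` of the IQ phantom (registered: phantom
#'   axis = z, geometry as in [iq_phantom()]).
#' @param phantom The [iq_phantom()] that was imaged.
#' @param uniformity_diameter,uniformity_length Uniformity VOI, mm.
#' @param sor_diameter,sor_length Cold-chamber VOI, mm.
#' @return Object of class `iq_result`: list with `uniformity` (mean, max,
#'   min, pct_std), `recovery` (data.frame per rod: `diameter, RC,
#'   pct_std`), `spillover` (data.frame: `chamber, SOR, pct_std`).
#' @export
iq_metrics <- function(vol, phantom,
                       uniformity_diameter = 22.5, uniformity_length = 10,
                       sor_diameter = 4, sor_length = 7.5) {
  if (is.null(phantom$kind) || phantom$kind != "iq") {
    stop("phantom registration missing: supply the imaged iq_phantom()")
  }
  ax <- volume_axes(vol)
  v <- vol$values
  nx <- dim(v)[1]; ny <- dim(v)[2]
  X <- matrix(ax$x, nx, ny)
  Y <- matrix(ax$y, nx, ny, byrow = TRUE)
  ctr <- phantom$center
  R2 <- (X - ctr[1])^2 + (Y - ctr[2])^2

  # uniformity VOI
  zin <- abs(ax$z - ctr[3]) <= uniformity_length / 2
  um <- R2 <= (uniformity_diameter / 2)^2
  uvals <- as.numeric(v[, , zin, drop = FALSE][rep(um, sum(zin))])
  unif <- list(mean = mean(uvals), max = max(uvals), min = min(uvals),
               pct_std = stats::sd(uvals) / mean(uvals) * 100)
  u_cv <- stats::sd(uvals) / mean(uvals)

  # recovery coefficients: average the central 10 mm of the rod region
  rod_z0 <- ctr[3] - phantom$uniform_length / 2 - phantom$rod_length
  rod_z1 <- ctr[3] - phantom$uniform_length / 2
  zmid <- (rod_z0 + rod_z1) / 2
  zrod <- abs(ax$z - zmid) <= 5
  slab <- apply(v[, , zrod, drop = FALSE], c(1, 2), mean)
  rc_rows <- lapply(seq_along(phantom$rod_diameters), function(k) {
    dk <- phantom$rod_diameters[k]
    cx <- ctr[1] + phantom$rod_offset * cos(phantom$rod_angles[k])
    cy <- ctr[2] + phantom$rod_offset * sin(phantom$rod_angles[k])
    roi <- (X - cx)^2 + (Y - cy)^2 <= dk^2  # 2x diameter -> radius = dk
    if (!any(roi)) return(NULL)
    sl <- slab; sl[!roi] <- -Inf
    im <- which(sl == max(sl), arr.ind = TRUE)[1, ]
    prof <- v[im[1], im[2], zrod]
    rc <- mean(prof) / unif$mean
    p_cv <- stats::sd(prof) / mean(prof)
    data.frame(diameter = dk, RC = rc,
               pct_std = 100 * sqrt(p_cv^2 + u_cv^2))
  })
  recovery <- do.call(rbind, rc_rows)

  # spillover: cold chambers sit above the uniform region
  zc_mid <- ctr[3] + phantom$uniform_length / 2 + phantom$cold_length / 2
  zsor <- abs(ax$z - zc_mid) <= sor_length / 2
  sor_rows <- lapply(c(water = -1, air = 1), function(off) {
    cx <- ctr[1] + off * phantom$cold_offset
    roi <- (X - cx)^2 + (Y - ctr[2])^2 <= (sor_diameter / 2)^2
    vals <- as.numeric(v[, , zsor, drop = FALSE][rep(roi, sum(zsor))])
    data.frame(SOR = mean(vals) / unif$mean,
               pct_std = 100 * sqrt((stats::sd(vals) / max(mean(vals),
                                                           1e-12))^2 +
                                      u_cv^2))
  })
  spillover <- cbind(chamber = c("water", "air"),
                     do.call(rbind, sor_rows))
  structure(list(uniformity = unif, recovery = recovery,
                 spillover = spillover), class = "iq_result")
}

#' Noise-equivalent count rate
#'
#' @param trues,scatter,randoms Rates, cps.
#' @return `T^2 / (T + S + R)`.
#' @export
necr <- function(trues, scatter, randoms) {
  tot <- trues + scatter + randoms
  ifelse(tot > 0, trues^2 / tot, 0)
}

#' Serialize a NU4 analysis result as JSON
#'
#' @param report A `sensitivity_result`, `countrate_result`, `iq_result`
#'   or `resolution_result`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
nema_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 8,
                         dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("NU4 detection sensitivity\n")
  cat(sprintf("  peak: %.4f cps/Bq (%.1f%% absolute)\n",
              x$peak_S, x$peak_absolute_pct))
  cat(sprintf("  integrated: %.4f cps/Bq (%.1f%% absolute), %d positions\n",
              x$integrated_S, x$integrated_absolute_pct,
              nrow(x$profile)))
  invisible(x)
}

#' @export
print.countrate_result <- function(x, ...) {
  cat("NU4 count-rate analysis\n")
  print(format(x$table, digits = 4), ...)
  cat(sprintf("  peak NECR %.0f cps at %.2f MBq; scatter fraction %.1f%%\n",
              x$peak_necr_cps, x$peak_necr_activity_Bq / 1e6,
              x$scatter_fraction_pct))
  invisible(x)
}

#' @export
print.iq_result <- function(x, ...) {
  cat("NU4 image quality\n")
  u <- x$uniformity
  cat(sprintf("  uniformity: mean %.4g, max %.4g, min %.4g, %%STD %.2f\n",
              u$mean, u$max, u$min, u$pct_std))
  cat("  recovery coefficients:\n")
  print(format(x$recovery, digits = 3), ...)
  cat("  spillover ratios:\n")
  print(format(x$spillover, digits = 3), ...)
  invisible(x)
}
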