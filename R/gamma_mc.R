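#' LYSO photon cross-sections
#'
#' Tabulated linear attenuation coefficients of LYSO between 50 and 511 keV,
#' split into photoelectric and Compton components and interpolated
#' log-log. The 511 keV total and photoelectric fraction are configurable;
#' the energy dependence follows the tabulated shape (photoelectric roughly
#' as E^-3, Compton following the Klein-Nishina trend).
#'
#' @param total_511 Total linear attenuation at 511 keV, 1/mm.
#' @param pe_fraction_511 Photoelectric fraction of the total at 511 keV.
#' @return Object of class `lyso_xs` with functions `mu_total(E)`,
#'   `mu_pe(E)`, `mu_cs(E)` (E in keV, output 1/mm).
#' @export
lyso_cross_sections <- function(total_511 = 0.087, pe_fraction_511 = 0.33) {
  E <- c(50, 80, 120, 170, 250, 350, 511)
  # shape tables, normalized to 1 at 511 keV
  pe_shape <- (511 / E)^3
  cs_shape <- c(2.05, 1.85, 1.67, 1.51, 1.32, 1.16, 1.00)
  mu_pe_tab <- total_511 * pe_fraction_511 * pe_shape
  mu_cs_tab <- total_511 * (1 - pe_fraction_511) * cs_shape
  logE <- log(E)
  interp <- function(tab) {
    lt <- log(tab)
    function(e) {
      e <- pmin(pmax(e, 50), 511)
      exp(stats::approx(logE, lt, xout = log(e), rule = 2)$y)
    }
  }
  mu_pe <- interp(mu_pe_tab)
  mu_cs <- interp(mu_cs_tab)
  structure(list(
    energies = E, mu_pe_tab = mu_pe_tab, mu_cs_tab = mu_cs_tab,
    mu_pe = mu_pe, mu_cs = mu_cs,
    mu_total = function(e) mu_pe(e) + mu_cs(e)
  ), class = "lyso_xs")
}

#' Klein-Nishina scattering-angle sampler
#'
#' Draws Compton scattering polar angles from the Klein-Nishina differential
#' cross-section at photon energy `E` by rejection sampling in cos(theta),
#' and returns the scattered photon energy from the Compton relation
#' `E' = E / (1 + (E/511)(1 - cos theta))`.
#'
#' @param n Number of samples.
#' @param E Photon energy, keV (scalar or length-n).
#' @return data.frame with columns `theta` (rad) and `Eprime` (keV).
#' @export
sample_klein_nishina <- function(n, E = 511) {
  stopifnot(all(E > 0))
  E <- rep_len(E, n)
  alpha <- E / 511
  # unnormalized pdf in c = cos(theta)
  kn <- function(c, a) {
    r <- 1 / (1 + a * (1 - c))
    r^2 * (r + 1 / r - (1 - c^2))
  }
  # envelope: maximum over c is at c = 1 where f = 2
  fmax <- 2
  theta <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    c_try <- stats::runif(length(todo), -1, 1)
    u <- stats::runif(length(todo), 0, fmax)
    ok <- u <= kn(c_try, alpha[todo])
    theta[todo[ok]] <- acos(c_try[ok])
    todo <- todo[!ok]
  }
  Eprime <- E / (1 + alpha * (1 - cos(theta)))
  data.frame(theta = theta, Eprime = Eprime)
}

#' Klein-Nishina differential cross-section (unnormalized, per cos theta)
#'
#' @param cos_theta Cosine of the polar scattering angle.
#' @param E Photon energy, keV.
#' @return Unnormalized density values; the sampler in
#'   [sample_klein_nishina()] follows this shape.
#' @export
klein_nishina_pdf <- function(cos_theta, E = 511) {
  a <- E / 511
  r <- 1 / (1 + a * (1 - cos_theta))
  r^2 * (r + 1 / r - (1 - cos_theta^2))
}

#' Survival probability along a path through an attenuation map
#'
#' @param p1,p2 Endpoints (3-vectors or n x 3 matrices), mm.
#' @param mu_map A `mu_map` from [make_attenuation_phantom()].
#' @return `exp(-integral of mu dl)` per path.
#' @export
path_survival <- function(p1, p2, mu_map) {
  p1 <- to_matrix3(p1); p2 <- to_matrix3(p2)
  tau <- cpp_line_integrals(p1, p2, as.numeric(mu_map$values),
                            dim(mu_map$values), mu_map$voxel_size,
                            mu_map$origin)
  exp(-tau)
}

#' Physics configuration for the photon Monte Carlo
#'
#' @param xs LYSO cross-sections from [lyso_cross_sections()].
#' @param energy_cutoff Tracking cutoff, keV: a Compton daughter below this
#'   energy is absorbed at its production vertex.
#' @param acollinearity_fwhm_deg FWHM of the Gaussian acollinearity blur of
#'   the photon-pair angle (0 disables).
#' @param positron_range Logical: apply the nuclide-specific Gaussian
#'   positron-range blur to the emission point.
#' @param positron_range_fwhm FWHM (mm) per nuclide for the range blur.
#' @param object_attenuation Logical: transport photons through the object
#'   (attenuation plus single Compton scatter) before the annulus.
#' @param max_interactions Safety cap on crystal-chain length.
#' @return List of class `physics_config`.
#' @export
physics_config <- function(xs = lyso_cross_sections(), energy_cutoff = 50,
                           acollinearity_fwhm_deg = 0.25,
                           positron_range = TRUE,
                           positron_range_fwhm = c(F18 = 0.54, Na22 = 1.0),
                           object_attenuation = TRUE,
                           max_interactions = 6) {
  structure(list(xs = xs, energy_cutoff = energy_cutoff,
                 acollinearity_fwhm_deg = acollinearity_fwhm_deg,
                 positron_range = positron_range,
                 positron_range_fwhm = positron_range_fwhm,
                 object_attenuation = object_attenuation,
                 max_interactions = as.integer(max_interactions)),
            class = "physics_config")
}

# --- ray/solid intersection helpers (vectorized over rays) -----------------

# interval [tlo, thi] of each ray inside the polygon prism + axial slab,
# restricted to t >= 0; rows with thi <= tlo never hit the solid hull
ray_hull_interval <- function(g, p, d) {
  s <- g$spec
  n <- nrow(p)
  tlo <- rep(0, n); thi <- rep(Inf, n)
  nf <- s$n_facets
  for (i in seq_len(nf)) {
    nrm <- g$frames$normal[i, 1:2]
    pn <- p[, 1] * nrm[1] + p[, 2] * nrm[2]
    dn <- d[, 1] * nrm[1] + d[, 2] * nrm[2]
    tcross <- (s$facet_apothem - pn) / dn
    pos <- dn > 1e-12; neg <- dn < -1e-12; par <- !pos & !neg
    thi[pos] <- pmin(thi[pos], tcross[pos])
    tlo[neg] <- pmax(tlo[neg], tcross[neg])
    bad <- par & pn > s$facet_apothem
    thi[bad] <- -Inf
  }
  hl <- s$length / 2
  dz <- d[, 3]; pz <- p[, 3]
  pos <- dz > 1e-12; neg <- dz < -1e-12; par <- !pos & !neg
  t1 <- (-hl - pz) / dz; t2 <- (hl - pz) / dz
  thi[pos] <- pmin(thi[pos], t2[pos]); tlo[pos] <- pmax(tlo[pos], t1[pos])
  thi[neg] <- pmin(thi[neg], t1[neg]); tlo[neg] <- pmax(tlo[neg], t2[neg])
  bad <- par & abs(pz) > hl
  thi[bad] <- -Inf
  cbind(tlo = tlo, thi = thi)
}

# interval of each ray inside the bore cylinder (t unrestricted)
ray_bore_interval <- function(g, p, d) {
  R <- g$spec$inner_radius
  a <- d[, 1]^2 + d[, 2]^2
  b <- 2 * (p[, 1] * d[, 1] + p[, 2] * d[, 2])
  cc <- p[, 1]^2 + p[, 2]^2 - R^2
  disc <- b^2 - 4 * a * cc
  hit <- disc > 0 & a > 1e-12
  sq <- sqrt(pmax(disc, 0))
  c0 <- ifelse(hit, (-b - sq) / (2 * a), Inf)
  c1 <- ifelse(hit, (-b + sq) / (2 * a), -Inf)
  cbind(c0 = c0, c1 = c1)
}

# up to two intervals of each ray inside the scintillator = hull minus bore
crystal_intervals <- function(g, p, d) {
  hull <- ray_hull_interval(g, p, d)
  bore <- ray_bore_interval(g, p, d)
  a1 <- hull[, 1]; b1 <- pmin(hull[, 2], bore[, 1])
  a2 <- pmax(hull[, 1], bore[, 2]); b2 <- hull[, 2]
  none <- bore[, 1] >= hull[, 2] | bore[, 2] <= hull[, 1]
  b1[none] <- hull[none, 2]
  # no second interval: collapse it to zero length at the hull exit
  a2[none] <- hull[none, 2]; b2[none] <- hull[none, 2]
  b1 <- pmax(b1, a1)
  b2 <- pmax(b2, a2)
  empty <- !is.finite(b1 - a1)
  a1[empty] <- 0; b1[empty] <- 0
  empty2 <- !is.finite(b2 - a2)
  a2[empty2] <- 0; b2[empty2] <- 0
  cbind(a1 = a1, b1 = b1, a2 = a2, b2 = b2)
}

# isotropic unit vectors
random_directions <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  cbind(r * cos(phi), r * sin(phi), z)
}

# rotate unit vectors d by polar angle theta (about d) and azimuth phi
rotate_direction <- function(d, theta, phi) {
  # build an orthonormal basis around each d
  ref <- cbind(rep(1, nrow(d)), 0, 0)
  swap <- abs(d[, 1]) > 0.9
  ref[swap, ] <- matrix(rep(c(0, 1, 0), sum(swap)), ncol = 3, byrow = TRUE)
  e1 <- cbind(d[, 2] * ref[, 3] - d[, 3] * ref[, 2],
              d[, 3] * ref[, 1] - d[, 1] * ref[, 3],
              d[, 1] * ref[, 2] - d[, 2] * ref[, 1])
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(d[, 2] * e1[, 3] - d[, 3] * e1[, 2],
              d[, 3] * e1[, 1] - d[, 1] * e1[, 3],
              d[, 1] * e1[, 2] - d[, 2] * e1[, 1])
  st <- sin(theta)
  d * cos(theta) + e1 * (st * cos(phi)) + e2 * (st * sin(phi))
}

# homogeneous convex stand-in for the scanned object, for MC transport
object_model <- function(phantom, mu = mu_511()) {
  if (is.null(phantom)) return(NULL)
  switch(phantom$kind,
    point = list(shape = "box", half = phantom$encapsulation_side / 2,
                 center = phantom$position, mu = mu$acrylic),
    mouse = list(shape = "cylinder", radius = phantom$diameter / 2,
                 half_length = phantom$length / 2, center = phantom$center,
                 mu = mu$polyethylene),
    cylinder = list(shape = "cylinder", radius = phantom$diameter / 2,
                    half_length = phantom$length / 2, center = phantom$center,
                    mu = mu$water),
    iq = list(shape = "cylinder", radius = phantom$body_diameter / 2,
              half_length = (phantom$uniform_length / 2 + phantom$rod_length +
                             phantom$cold_length) / 2 +
                            phantom$uniform_length / 4,
              center = phantom$center, mu = mu$water),
    NULL)
}

# chord [t0, t1] of rays through the object solid, restricted to t >= 0
object_interval <- function(obj, p, d) {
  n <- nrow(p)
  if (is.null(obj)) return(cbind(rep(0, n), rep(0, n)))
  pc <- sweep(p, 2, obj$center)
  if (obj$shape == "cylinder") {
    a <- d[, 1]^2 + d[, 2]^2
    b <- 2 * (pc[, 1] * d[, 1] + pc[, 2] * d[, 2])
    cc <- pc[, 1]^2 + pc[, 2]^2 - obj$radius^2
    disc <- b^2 - 4 * a * cc
    hit <- disc > 0 & a > 1e-12
    sq <- sqrt(pmax(disc, 0))
    t0 <- ifelse(hit, (-b - sq) / (2 * a), 0)
    t1 <- ifelse(hit, (-b + sq) / (2 * a), 0)
    # clip to axial extent
    dz <- d[, 3]; pz <- pc[, 3]; hl <- obj$half_length
    zlo <- ifelse(abs(dz) > 1e-12, pmin((-hl - pz) / dz, (hl - pz) / dz),
                  ifelse(abs(pz) <= hl, -Inf, Inf))
    zhi <- ifelse(abs(dz) > 1e-12, pmax((-hl - pz) / dz, (hl - pz) / dz),
                  ifelse(abs(pz) <= hl, Inf, -Inf))
    t0 <- pmax(t0, zlo, 0); t1 <- pmin(t1, zhi)
    return(cbind(t0, pmax(t1, t0)))
  }
  # axis-aligned box
  t0 <- rep(0, n); t1 <- rep(Inf, n)
  for (k in 1:3) {
    dk <- d[, k]; pk <- pc[, k]; h <- obj$half
    lo <- ifelse(abs(dk) > 1e-12, pmin((-h - pk) / dk, (h - pk) / dk),
                 ifelse(abs(pk) <= h, -Inf, Inf))
    hi <- ifelse(abs(dk) > 1e-12, pmax((-h - pk) / dk, (h - pk) / dk),
                 ifelse(abs(pk) <= h, Inf, -Inf))
    t0 <- pmax(t0, lo); t1 <- pmin(t1, hi)
  }
  cbind(pmax(t0, 0), pmax(pmin(t1, 1e9), pmax(t0, 0)))
}

#' Simulate annihilation events
#'
#' Emits back-to-back 511 keV photon pairs from the phantom (with optional
#' positron-range and acollinearity blur), transports them through a
#' homogeneous convex stand-in for the object (attenuation and single
#' Compton scatter) and then through the LYSO annulus, sampling free paths
#' from the total attenuation and choosing photoelectric absorption vs
#' Compton scatter by their cross-section ratio. Compton daughters are
#' followed until absorption, escape from the crystal, or the energy
#' cutoff (below which the daughter is absorbed at its vertex).
#'
#' @param phantom A phantom object.
#' @param geometry A `scanner_geometry`.
#' @param physics A [physics_config()].
#' @param n Number of annihilation events.
#' @param seed Optional integer seed.
#' @return Object of class `event_truth`: list of data.frames `events`
#'   (`event, x, y, z, time_ns`), `photons` (`event, photon, label,
#'   object_scattered, fx, fy, fz` = first crystal interaction), and
#'   `interactions` (`event, photon, order, kind, x, y, z, edep, facet,
#'   time_ns`).
#' @export
simulate_events <- function(phantom, geometry, physics = physics_config(),
                            n = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  em <- sample_emissions(phantom, n)
  pos0 <- cbind(em$x, em$y, em$z)
  if (physics$positron_range &&
      !is.null(physics$positron_range_fwhm[[phantom$nuclide$nuclide]])) {
    sigma <- physics$positron_range_fwhm[[phantom$nuclide$nuclide]] / 2.3548
    pos0 <- pos0 + matrix(stats::rnorm(3 * n, 0, sigma), ncol = 3)
  }
  d1 <- random_directions(n)
  d2 <- -d1
  if (physics$acollinearity_fwhm_deg > 0) {
    sig <- physics$acollinearity_fwhm_deg * pi / 180 / 2.3548
    dth <- abs(stats::rnorm(n, 0, sig))
    d2 <- rotate_direction(d2, dth, stats::runif(n, 0, 2 * pi))
  }
  time_ns <- em$time * 1e9

  obj <- if (physics$object_attenuation) object_model(phantom) else NULL

  res1 <- transport_photons(pos0, d1, time_ns, geometry, physics, obj, 1L)
  res2 <- transport_photons(pos0, d2, time_ns, geometry, physics, obj, 2L)

  events <- data.frame(event = seq_len(n), x = pos0[, 1], y = pos0[, 2],
                       z = pos0[, 3], time_ns = time_ns)
  photons <- rbind(res1$photons, res2$photons)
  photons <- photons[order(photons$event, photons$photon), ]
  interactions <- rbind(res1$interactions, res2$interactions)
  if (nrow(interactions) > 0) {
    interactions <- interactions[order(interactions$event,
                                       interactions$photon,
                                       interactions$order), ]
  }
  rownames(photons) <- rownames(interactions) <- NULL
  structure(list(events = events, photons = photons,
                 interactions = interactions),
            class = "event_truth")
}

# transport a batch of photons; returns photon summaries + interaction rows
transport_photons <- function(pos, dir, time_ns, g, physics, obj,
                              photon_id) {
  n <- nrow(pos)
  C_MM_NS <- 299.792458
  E <- rep(511, n)
  t_now <- time_ns
  object_scattered <- rep(FALSE, n)
  xs <- physics$xs

  # --- object stage: attenuate / Compton-scatter in the homogeneous
  # object; a photon that traverses without interacting is done with the
  # object, one that scatters gets a fresh ray (up to two scatters)
  if (!is.null(obj) && obj$mu > 0) {
    eligible <- rep(TRUE, n)
    for (pass in 1:2) {
      iv <- object_interval(obj, pos, dir)
      chord <- iv[, 2] - iv[, 1]
      can <- eligible & chord > 1e-9 & E > physics$energy_cutoff
      if (!any(can)) break
      u <- stats::runif(n)
      x_free <- -log(u) / obj$mu
      interact <- can & x_free < chord
      eligible <- interact        # survivors leave the object for good
      if (!any(interact)) break
      tt <- iv[, 1] + x_free
      idx <- which(interact)
      pos[idx, ] <- pos[idx, ] + dir[idx, ] * tt[idx]
      t_now[idx] <- t_now[idx] + tt[idx] / C_MM_NS
      kn <- sample_klein_nishina(length(idx), E[idx])
      dir[idx, ] <- rotate_direction(dir[idx, , drop = FALSE], kn$theta,
                                     stats::runif(length(idx), 0, 2 * pi))
      E[idx] <- kn$Eprime
      object_scattered[idx] <- TRUE
      # photons degraded below cutoff die in the object
    }
  }

  # --- crystal stage
  alive <- E > physics$energy_cutoff
  rec <- vector("list", physics$max_interactions)
  order_idx <- rep(0L, n)
  had_pe_end <- rep(FALSE, n)
  n_cs <- rep(0L, n)
  step <- 0L
  while (any(alive) && step < physics$max_interactions) {
    step <- step + 1L
    idx <- which(alive)
    p <- pos[idx, , drop = FALSE]
    d <- dir[idx, , drop = FALSE]
    iv <- crystal_intervals(g, p, d)
    len1 <- pmax(iv[, "b1"] - iv[, "a1"], 0)
    len2 <- pmax(iv[, "b2"] - iv[, "a2"], 0)
    mu_t <- xs$mu_total(E[idx])
    x_free <- stats::rexp(length(idx)) / mu_t
    t_int <- ifelse(x_free < len1, iv[, "a1"] + x_free,
                    ifelse(x_free - len1 < len2,
                           iv[, "a2"] + (x_free - len1), NA_real_))
    hit <- !is.na(t_int) & is.finite(t_int)
    # escaped photons die
    alive[idx[!hit]] <- FALSE
    if (!any(hit)) next
    hi <- idx[hit]
    tt <- t_int[hit]
    newp <- pos[hi, , drop = FALSE] + dir[hi, , drop = FALSE] * tt
    t_now[hi] <- t_now[hi] + tt / C_MM_NS
    pos[hi, ] <- newp
    # PE vs CS
    p_pe <- xs$mu_pe(E[hi]) / xs$mu_total(E[hi])
    is_pe <- stats::runif(length(hi)) < p_pe
    edep <- numeric(length(hi))
    kind <- character(length(hi))
    # Compton branch
    ci <- which(!is_pe)
    if (length(ci) > 0) {
      kn <- sample_klein_nishina(length(ci), E[hi[ci]])
      below <- kn$Eprime < physics$energy_cutoff
      edep[ci] <- E[hi[ci]] - kn$Eprime
      # daughters below the cutoff are absorbed at the vertex
      edep[ci[below]] <- E[hi[ci[below]]]
      kind[ci] <- "CS"
      live_ci <- ci[!below]
      if (length(live_ci) > 0) {
        dir[hi[live_ci], ] <- rotate_direction(
          dir[hi[live_ci], , drop = FALSE], kn$theta[!below],
          stats::runif(length(live_ci), 0, 2 * pi))
        E[hi[live_ci]] <- kn$Eprime[!below]
      }
      E[hi[ci[below]]] <- 0
      alive[hi[ci[below]]] <- FALSE
      n_cs[hi[ci]] <- n_cs[hi[ci]] + 1L
    }
    # PE branch
    pi_ <- which(is_pe)
    if (length(pi_) > 0) {
      edep[pi_] <- E[hi[pi_]]
      kind[pi_] <- "PE"
      E[hi[pi_]] <- 0
      alive[hi[pi_]] <- FALSE
      had_pe_end[hi[pi_]] <- TRUE
    }
    order_idx[hi] <- order_idx[hi] + 1L
    loc <- locate_point(g, newp)
    rec[[step]] <- data.frame(
      event = hi, photon = photon_id, order = order_idx[hi], kind = kind,
      x = newp[, 1], y = newp[, 2], z = newp[, 3], edep = edep,
      facet = loc$facet, time_ns = t_now[hi])
  }

  interactions <- do.call(rbind, rec[!vapply(rec, is.null, logical(1))])
  if (is.null(interactions)) {
    interactions <- data.frame(event = integer(0), photon = integer(0),
                               order = integer(0), kind = character(0),
                               x = numeric(0), y = numeric(0), z = numeric(0),
                               edep = numeric(0), facet = integer(0),
                               time_ns = numeric(0))
  }
  n_int <- order_idx
  label <- rep("miss", n)
  label[n_int == 1 & had_pe_end] <- "PE"
  label[n_int == 1 & !had_pe_end & n_cs == 1] <- "CSE"
  label[n_int == 2 & had_pe_end & n_cs == 1] <- "CS-PE"
  label[n_int >= 2 & label == "miss"] <- "multi"
  first <- interactions[interactions$order == 1, ]
  fx <- fy <- fz <- rep(NA_real_, n)
  if (nrow(first) > 0) {
    fx[first$event] <- first$x
    fy[first$event] <- first$y
    fz[first$event] <- first$z
  }
  photons <- data.frame(event = seq_len(n), photon = photon_id,
                        label = label, object_scattered = object_scattered,
                        fx = fx, fy = fy, fz = fz)
  list(photons = photons, interactions = interactions)
}
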