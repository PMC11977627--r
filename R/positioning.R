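#' Harmonize photon distributions
#'
#' Subtracts a small fraction (`f_factor`) of each distribution's pixel sum
#' from every pixel (background removal), clamps negatives to zero, then
#' normalizes the maximum to 1. This makes measured distributions
#' comparable to the simulation-scaled data the positioner is trained on.
#' All-zero distributions are returned unchanged (flagged via attribute
#' `all_zero` when a single distribution is given).
#'
#' @param d A distribution: length-192 vector, 12 x 16 matrix, or an
#'   `n x 192` matrix of stacked distributions (rows).
#' @param f_factor Fraction of the pixel sum subtracted from each pixel.
#' @return Harmonized distribution(s), same shape as the input.
#' @export
harmonize <- function(d, f_factor = 0.0025) {
  stopifnot(f_factor >= 0, f_factor < 1 / 192)
  if (is.null(dim(d)) || (nrow(d) == 12 && ncol(d) == 16)) {
    shape <- dim(d)
    v <- as.numeric(d)
    stopifnot(all(v >= 0))
    v <- pmax(0, v - f_factor * sum(v))
    mx <- max(v)
    all_zero <- mx <= 0
    if (!all_zero) v <- v / mx
    out <- if (is.null(shape)) v else matrix(v, shape[1], shape[2])
    attr(out, "all_zero") <- all_zero
    return(out)
  }
  stopifnot(all(d >= 0))
  s <- rowSums(d)
  v <- d - s * f_factor    # s recycles down rows (column-major)
  v[v < 0] <- 0
  mx <- apply(v, 1, max)
  mx[mx <= 0] <- 1
  v / mx
}

# unfolded sensor coordinates of the 192 distribution pixels:
# transaxial index r = 0..11 across (prev, primary, next), axial 0..15
distribution_coords <- function(g) {
  sg <- g$sensors
  k <- rep(rep(0:2, each = sg$n_u), times = sg$n_v)   # facet offset block
  iu <- rep(rep(seq_len(sg$n_u), times = 3), times = sg$n_v)
  iv <- rep(seq_len(sg$n_v), each = 3 * sg$n_u)
  u_unfold <- (k - 1) * g$spec$facet_width + sg$u_centers[iu]
  list(u = u_unfold, v = sg$v_centers[iv])
}

#' Calibrate the centre-of-mass depth lookup
#'
#' The centre-of-mass positioner has no intrinsic depth estimate; depth is
#' read from a lookup calibrated on simulated photoelectric events that
#' maps the distribution's transaxial second moment to the mean distance
#' below the sensor plane.
#'
#' @param g A `scanner_geometry`.
#' @param optics An [optical_model()].
#' @param n Calibration events.
#' @param seed Integer seed.
#' @param nbins Lookup bins over the observed moment range.
#' @return Object of class `depth_lut`: data.frame with `moment` (bin
#'   centre, mm) and `depth` (mean distance below the sensor plane, mm).
#' @export
calibrate_depth_lut <- function(g, optics = optical_model(), n = 3000,
                                seed = 1, nbins = 12) {
  set.seed(seed)
  s <- g$spec
  u <- stats::runif(n, -s$facet_width / 2 * 0.95, s$facet_width / 2 * 0.95)
  v <- stats::runif(n, -s$length / 2 * 0.9, s$length / 2 * 0.9)
  dmax <- s$facet_apothem - sqrt(pmax(s$inner_radius^2 - u^2, 0))
  depth <- stats::runif(n) * (dmax - 0.01)
  f <- sample(seq_len(s$n_facets), n, replace = TRUE) - 1L
  p <- facet_to_world(g, f, u, v, depth)
  w_true <- s$facet_apothem -
    rowSums(p[, 1:2] * g$frames$normal[f + 1L, 1:2, drop = FALSE])
  L <- expected_light_matrix(p, rep(511, n), optics, g)
  dist <- assemble_distribution(L, f, g)
  mom <- distribution_moment(harmonize(dist), g)
  br <- seq(min(mom), max(mom), length.out = nbins + 1)
  bin <- cut(mom, br, include.lowest = TRUE)
  lut <- data.frame(moment = (br[-length(br)] + br[-1]) / 2,
                    depth = as.numeric(tapply(w_true, bin, mean)))
  lut$depth <- stats::approx(lut$moment[!is.na(lut$depth)],
                             lut$depth[!is.na(lut$depth)],
                             xout = lut$moment, rule = 2)$y
  structure(lut, class = c("depth_lut", "data.frame"))
}

# signal-weighted transaxial spread (second central moment, mm)
distribution_moment <- function(dist, g) {
  co <- distribution_coords(g)
  s <- rowSums(dist)
  s[s <= 0] <- 1
  mu <- (dist %*% co$u) / s
  sqrt(pmax((dist %*% co$u^2) / s - mu^2, 0))
}

#' Centre-of-mass position estimate
#'
#' Baseline positioner: the transaxial and axial coordinates are the
#' signal-weighted centroid of the unfolded sensor coordinates across the
#' three-facet span; depth comes from the second-moment lookup. The world
#' position is clamped to the scintillator solid.
#'
#' @param d Harmonized distribution(s): length-192 vector, 12 x 16 matrix,
#'   or `n x 192` matrix.
#' @param primary 0-based primary facet id (vectorized).
#' @param g A `scanner_geometry`.
#' @param depth_lut A [calibrate_depth_lut()] result.
#' @return data.frame with `x, y, z` (mm), `facet`, `clamped`.
#' @export
com_position <- function(d, primary, g, depth_lut) {
  if (is.null(dim(d)) || (nrow(d) == 12 && ncol(d) == 16)) {
    d <- matrix(as.numeric(d), 1)
  }
  s <- rowSums(d)
  if (any(s <= 0)) stop("all-zero distribution has no centroid")
  co <- distribution_coords(g)
  u_bar <- as.numeric((d %*% co$u) / s)
  v_bar <- as.numeric((d %*% co$v) / s)
  mom <- as.numeric(distribution_moment(d, g))
  w_hat <- stats::approx(depth_lut$moment, depth_lut$depth, xout = mom,
                         rule = 2)$y
  # unfolded u -> azimuth around the primary facet, at the estimated depth
  az <- g$frames$azimuth[primary + 1L] + u_bar / g$spec$facet_apothem
  radial <- g$spec$facet_apothem - w_hat
  p <- cbind(radial * cos(az), radial * sin(az), v_bar)
  cl <- clamp_to_annulus(g, p)
  out <- data.frame(x = cl$p[, 1], y = cl$p[, 2], z = cl$p[, 3],
                    facet = locate_point(g, cl$p)$facet,
                    clamped = cl$clamped)
  out
}

# ---------------------------------------------------------------------------
# residual network positioner (dense residual blocks, base-R matrix ops)

relu <- function(x) (x > 0) * x

init_positioner <- function(n_in, width, n_blocks, seed) {
  set.seed(seed)
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0,
                                                sqrt(2 / nin)), nin, nout)
  params <- list(W_in = he(n_in, width), b_in = rep(0, width),
                 blocks = lapply(seq_len(n_blocks), function(i) {
                   list(W1 = he(width, width), b1 = rep(0, width),
                        W2 = he(width, width) * 0.1, b2 = rep(0, width))
                 }),
                 W_out = he(width, 3) * 0.1, b_out = rep(0, 3))
  params
}

positioner_forward <- function(params, X, keep = FALSE) {
  cache <- list()
  H <- relu(sweep(X %*% params$W_in, 2, params$b_in, `+`))
  if (keep) cache$H0 <- H
  for (i in seq_along(params$blocks)) {
    bl <- params$blocks[[i]]
    A <- relu(sweep(H %*% bl$W1, 2, bl$b1, `+`))
    B <- sweep(A %*% bl$W2, 2, bl$b2, `+`)
    if (keep) cache[[paste0("A", i)]] <- A
    H2 <- relu(H + B)
    if (keep) {
      cache[[paste0("Hin", i)]] <- H
      cache[[paste0("Hout", i)]] <- H2
    }
    H <- H2
  }
  Y <- sweep(H %*% params$W_out, 2, params$b_out, `+`)
  if (keep) {
    cache$Hlast <- H
    list(Y = Y, cache = cache)
  } else Y
}

positioner_backward <- function(params, X, cache, dY) {
  grads <- list(blocks = vector("list", length(params$blocks)))
  H <- cache$Hlast
  grads$W_out <- crossprod(H, dY)
  grads$b_out <- colSums(dY)
  dH <- dY %*% t(params$W_out)
  for (i in rev(seq_along(params$blocks))) {
    bl <- params$blocks[[i]]
    Hin <- cache[[paste0("Hin", i)]]
    Hout <- cache[[paste0("Hout", i)]]
    A <- cache[[paste0("A", i)]]
    dH2 <- dH * (Hout > 0)
    dB <- dH2
    grads$blocks[[i]] <- list(
      W2 = crossprod(A, dB), b2 = colSums(dB),
      W1 = NULL, b1 = NULL)
    dA <- dB %*% t(bl$W2)
    dA <- dA * (A > 0)
    grads$blocks[[i]]$W1 <- crossprod(Hin, dA)
    grads$blocks[[i]]$b1 <- colSums(dA)
    dH <- dH2 + dA %*% t(bl$W1)
  }
  dH <- dH * (cache$H0 > 0)
  grads$W_in <- crossprod(X, dH)
  grads$b_in <- colSums(dH)
  grads
}

#' Train the residual network positioner
#'
#' A dense residual network (input 192, configurable width and number of
#' residual blocks, linear 3-output head) trained with Adam on mean squared
#' error to regress the facet-local coordinates of the chain's first
#' interaction (transaxial offset `u`, axial `z`, distance below the sensor
#' plane `w`) from the harmonized 12 x 16 distribution. Targets are
#' standardized internally. Training is deterministic given `seed`.
#'
#' @param X `n x 192` matrix of harmonized distributions.
#' @param y `n x 3` matrix of local targets (`u`, `z`, `w`), mm.
#' @param width Hidden width.
#' @param n_blocks Number of residual blocks (network depth scales with
#'   this; each block holds two dense layers).
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param lr_decay Multiplicative learning-rate decay applied every
#'   `lr_decay_every` epochs.
#' @param lr_decay_every Epoch interval for the decay.
#' @param seed Integer seed (initialization and shuffling).
#' @param verbose Print per-epoch loss.
#' @return Object of class `positioner_model` with fields `params`,
#'   `center`, `scale`, `loss_history`, `config`.
#' @export
train_positioner <- function(X, y, width = 64, n_blocks = 2, epochs = 15,
                             batch_size = 512, lr = 2e-3, lr_decay = 0.5,
                             lr_decay_every = 10, seed = 1,
                             verbose = FALSE) {
  X <- as.matrix(X); y <- as.matrix(y)
  if (nrow(X) < 2 || nrow(X) != nrow(y) || ncol(y) != 3) {
    stop("degenerate training set")
  }
  center <- colMeans(y)
  scale <- apply(y, 2, stats::sd)
  scale[scale < 1e-9] <- 1
  yt <- sweep(sweep(y, 2, center), 2, scale, `/`)
  n <- nrow(X)
  params <- init_positioner(ncol(X), width, n_blocks, seed)
  # Adam state mirrors the parameter tree
  zeros_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  mom1 <- zeros_like(params); mom2 <- zeros_like(params)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  loss_hist <- numeric(epochs)
  update <- function(p, g, m, v) {
    # recursively apply Adam to matching list structures
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- update(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mhat <- m / (1 - b1^step)
      vhat <- v / (1 - b2^step)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  lr0 <- lr
  for (ep in seq_len(epochs)) {
    lr <- lr0 * lr_decay^((ep - 1) %/% lr_decay_every)
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (lo in seq(1, n, by = batch_size)) {
      hi <- min(lo + batch_size - 1, n)
      idx <- ord[lo:hi]
      Xb <- X[idx, , drop = FALSE]; yb <- yt[idx, , drop = FALSE]
      fw <- positioner_forward(params, Xb, keep = TRUE)
      err <- fw$Y - yb
      loss <- mean(err^2)
      dY <- 2 * err / length(err)
      grads <- positioner_backward(params, Xb, fw$cache, dY)
      step <- step + 1
      r <- update(params, grads, mom1, mom2)
      params <- r$p; mom1 <- r$m; mom2 <- r$v
      ep_loss <- ep_loss + loss; nb <- nb + 1
    }
    loss_hist[ep] <- ep_loss / nb
    if (verbose) message(sprintf("epoch %d loss %.5f", ep, loss_hist[ep]))
  }
  structure(list(params = params, center = center, scale = scale,
                 loss_history = loss_hist,
                 config = list(width = width, n_blocks = n_blocks,
                               epochs = epochs, batch_size = batch_size,
                               lr = lr, seed = seed, n_train = n)),
            class = "positioner_model")
}

#' Predict interaction positions with the trained network
#'
#' Network outputs (facet-local `u`, `z`, `w`) are mapped to world
#' coordinates through the primary facet's frame and clamped to the
#' scintillator solid.
#'
#' @param model A `positioner_model`.
#' @param d Harmonized distribution(s) (`n x 192`, vector, or 12 x 16).
#' @param primary 0-based primary facet id(s).
#' @param g A `scanner_geometry`.
#' @return data.frame `x, y, z, facet, clamped` plus attribute `"local"`
#'   (the raw local predictions).
#' @export
predict_position <- function(model, d, primary, g) {
  if (is.null(dim(d)) || (nrow(d) == 12 && ncol(d) == 16)) {
    d <- matrix(as.numeric(d), 1)
  }
  if (ncol(d) != 192) stop("distribution must have 192 elements")
  Y <- positioner_forward(model$params, d)
  Y <- sweep(sweep(Y, 2, model$scale, `*`), 2, model$center, `+`)
  p <- local_to_world(Y, primary, g)
  cl <- clamp_to_annulus(g, p)
  out <- data.frame(x = cl$p[, 1], y = cl$p[, 2], z = cl$p[, 3],
                    facet = locate_point(g, cl$p)$facet,
                    clamped = cl$clamped)
  attr(out, "local") <- Y
  out
}

# facet-local (u, z, w = distance below sensor plane) -> world
local_to_world <- function(Y, facet, g) {
  f <- as.integer(facet) + 1L
  nrm <- g$frames$normal[f, 1:2, drop = FALSE]
  uax <- g$frames$u[f, 1:2, drop = FALSE]
  radial <- g$spec$facet_apothem - Y[, 3]
  xy <- nrm * radial + uax * Y[, 1]
  cbind(xy, Y[, 2])
}

# world -> facet-local (u, z, w) for a given primary facet
world_to_local <- function(p, facet, g) {
  p <- to_matrix3(p)
  f <- as.integer(facet) + 1L
  nrm <- g$frames$normal[f, 1:2, drop = FALSE]
  uax <- g$frames$u[f, 1:2, drop = FALSE]
  u <- rowSums(p[, 1:2, drop = FALSE] * uax)
  s <- rowSums(p[, 1:2, drop = FALSE] * nrm)
  cbind(u = u, z = p[, 3], w = g$spec$facet_apothem - s)
}

#' Build a positioning data set from simulated events
#'
#' Simulates annihilations from an extended source filling the bore,
#' builds per-photon distributions through the optics + DAQ chain, and
#' pairs each harmonized distribution with the facet-local coordinates of
#' the chain's FIRST interaction (the intended LOR endpoint; for chains
#' that begin with a Compton vertex this is the Compton vertex).
#'
#' @param g A `scanner_geometry`.
#' @param n_events Annihilation count (each contributes up to 2 photons).
#' @param optics An [optical_model()].
#' @param daq A [daq_config()].
#' @param f_factor Harmonization f-factor.
#' @param seed Integer seed.
#' @param source Optional phantom; default is an air-filled cylinder
#'   spanning most of the bore (no attenuation object).
#' @return List: `X` (harmonized distributions), `y` (local targets
#'   `u, z, w`), `facet` (primary facet), `label` (chain label), `world`
#'   (true first-interaction positions), `depth_w` (target `w`).
#' @export
make_positioning_dataset <- function(g, n_events = 20000,
                                     optics = optical_model(),
                                     daq = daq_config(), f_factor = 0.0025,
                                     seed = 1, source = NULL) {
  if (is.null(source)) {
    source <- cylinder_phantom(activity = 1e6, diameter = 56,
                               length = g$spec$length * 0.95)
  }
  physics <- physics_config(object_attenuation = FALSE)
  truth <- simulate_events(source, g, physics, n = n_events, seed = seed)
  singles <- build_singles(truth, g, optics, daq)
  df <- singles$df
  ph <- truth$photons
  mi <- match(paste(df$event, df$photon), paste(ph$event, ph$photon))
  world <- cbind(ph$fx[mi], ph$fy[mi], ph$fz[mi])
  keep <- !is.na(world[, 1])
  df <- df[keep, ]; world <- world[keep, , drop = FALSE]
  X <- harmonize(singles$dist[keep, , drop = FALSE], f_factor)
  y <- world_to_local(world, df$facet, g)
  list(X = X, y = y, facet = df$facet, label = df$label, world = world,
       depth_w = y[, 3])
}

#' Evaluate a positioner on a labeled test set
#'
#' @param pred `n x 3` matrix (or data.frame with x, y, z) of predicted
#'   world positions.
#' @param truth `n x 3` matrix of true first-interaction world positions.
#' @param label Chain labels (PE, CSE, CS-PE, multi).
#' @param depth_w True distance below the sensor plane (for stratification).
#' @param depth_breaks Depth bin edges, mm.
#' @return Object of class `positioner_report`: data.frame with one row
#'   per stratum (`stratum, n, bias_x/y/z, rmse_x/y/z, rmse_3d`).
#' @export
evaluate_positioner <- function(pred, truth, label = NULL, depth_w = NULL,
                                depth_breaks = c(0, 4, 8, 12)) {
  if (is.data.frame(pred)) pred <- cbind(pred$x, pred$y, pred$z)
  err <- pred - truth
  strata <- list(all = rep(TRUE, nrow(err)))
  if (!is.null(label)) {
    for (lb in unique(label)) strata[[paste0("label:", lb)]] <- label == lb
  }
  if (!is.null(depth_w)) {
    bins <- cut(depth_w, depth_breaks, include.lowest = TRUE)
    for (lv in levels(bins)) {
      strata[[paste0("depth:", lv)]] <- !is.na(bins) & bins == lv
    }
  }
  rows <- lapply(names(strata), function(nm) {
    sel <- strata[[nm]]
    if (!any(sel)) return(NULL)
    e <- err[sel, , drop = FALSE]
    data.frame(stratum = nm, n = sum(sel),
               bias_x = mean(e[, 1]), bias_y = mean(e[, 2]),
               bias_z = mean(e[, 3]),
               rmse_x = sqrt(mean(e[, 1]^2)),
               rmse_y = sqrt(mean(e[, 2]^2)),
               rmse_z = sqrt(mean(e[, 3]^2)),
               rmse_3d = sqrt(mean(rowSums(e^2))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("positioner_report", "data.frame"))
}
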