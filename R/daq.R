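#' DAQ configuration
#'
#' @param array_threshold Per-array trigger threshold in photoelectron
#'   units; array sums below it are excluded from the facet sums (the
#'   hardware applies an analog threshold to the same sums). Comparison is
#'   inclusive (`>=` keeps the array).
#' @param coincidence_window Full width of the accepted arrival-time
#'   difference, ns: two singles form a prompt when
#'   `|dt| <= coincidence_window / 2`. This convention makes the
#'   singles-product randoms rate exactly `window * S_i * S_j`.
#' @param intrinsic_singles_rate Background singles per facet per second
#'   (crystal intrinsic radioactivity stand-in; 0 disables).
#' @return Object of class `daq_config`.
#' @export
daq_config <- function(array_threshold = 5, coincidence_window = 2.0,
                       intrinsic_singles_rate = 0) {
  stopifnot(coincidence_window > 0, array_threshold >= 0,
            intrinsic_singles_rate >= 0)
  structure(list(array_threshold = array_threshold,
                 coincidence_window = coincidence_window,
                 intrinsic_singles_rate = intrinsic_singles_rate),
            class = "daq_config")
}

#' Apply the per-array trigger threshold
#'
#' Sums each facet's sensor signals into its axial groups of
#' `array_pixels` rows ("arrays"), zeroes arrays whose sum is below the
#' threshold, and returns the surviving array sums plus per-facet sums.
#' No energy threshold is applied at the facet level.
#'
#' @param map A `sensor_signal_map` (`n_u x n_v x n_facets`) or a numeric
#'   vector of the same length in array order.
#' @param g A `scanner_geometry`.
#' @param cfg A [daq_config()].
#' @return List with `array_sums` (`arrays_per_facet x n_facets`, with
#'   sub-threshold arrays zeroed) and `facet_sums` (length `n_facets`).
#' @export
apply_thresholds <- function(map, g, cfg = daq_config()) {
  sums <- signal_sums(as_signal_array(map, g), g)
  a <- sums$array_sums
  a[a < cfg$array_threshold] <- 0
  list(array_sums = a, facet_sums = colSums(a))
}

as_signal_array <- function(map, g) {
  sg <- g$sensors
  dims <- c(sg$n_u, sg$n_v, g$spec$n_facets)
  if (is.null(dim(map))) map <- array(map, dim = dims)
  stopifnot(all(dim(map) == dims))
  map
}

# array sums for a batch of flattened 896-signal rows: n x (4*n_facets)
batch_array_sums <- function(mat, g) {
  sg <- g$sensors
  nf <- g$spec$n_facets
  npa <- sg$n_u * sg$array_pixels      # pixels per array (16)
  narr <- sg$arrays_per_facet * nf
  grp <- rep(seq_len(narr), each = npa)
  t(rowsum(t(mat), grp))               # n x narr
}

#' Build singles from simulated event truth
#'
#' Runs the optical model over every photon's interaction chain, samples
#' sensor noise, applies the array thresholds, and records one single per
#' photon whose facet sums survive: its trigger time (first interaction),
#' triggering facet (maximum facet sum), the four array sums of that facet,
#' and the 12 x 16 photon distribution assembled from the triggering facet
#' and its two neighbours. Truth links are retained for accounting.
#'
#' @param truth An `event_truth` from [simulate_events()].
#' @param g A `scanner_geometry`.
#' @param optics An [optical_model()].
#' @param cfg A [daq_config()].
#' @param gains Per-sensor gains (default from [scanner_gains()]).
#' @param dark_mean Dark-count mean per sensor per event window.
#' @param chunk Photons per vectorized block.
#' @return Object of class `singles`: list with `df` (data.frame: `time_ns,
#'   facet, fsum, a1..a4, event, photon, label, object_scattered`) and
#'   `dist` (matrix, one 192-long distribution per row; see
#'   [assemble_distribution()] for the layout).
#' @export
build_singles <- function(truth, g, optics = optical_model(),
                          cfg = daq_config(), gains = NULL, dark_mean = 0.5,
                          chunk = 4000) {
  if (is.null(gains)) gains <- rep(1, g$sensors$n_u * g$sensors$n_v *
                                     g$spec$n_facets)
  ints <- truth$interactions
  if (nrow(ints) == 0) return(empty_singles())
  key <- paste(ints$event, ints$photon)
  photon_ids <- !duplicated(key)
  first <- ints[photon_ids, c("event", "photon", "time_ns")]
  pid <- match(key, paste(first$event, first$photon))
  np <- nrow(first)

  nf <- g$spec$n_facets
  npix <- g$sensors$n_u * g$sensors$n_v
  # process photons in chunks: expected light, noise, thresholds, trigger
  res_df <- vector("list", 0)
  res_dist <- vector("list", 0)
  pb <- split(seq_len(np), ceiling(seq_len(np) / chunk))
  for (blk in pb) {
    rows <- which(pid %in% blk)
    L <- expected_light_matrix(cbind(ints$x[rows], ints$y[rows],
                                     ints$z[rows]),
                               ints$edep[rows], optics, g)
    M <- rowsum(L, pid[rows])                       # photons x 896
    M <- stats::rpois(length(M), M) * rep(gains, each = nrow(M)) +
      stats::rpois(length(M), dark_mean)
    M <- matrix(M, ncol = nf * npix)
    asums <- batch_array_sums(M, g)
    asums[asums < cfg$array_threshold] <- 0
    fs <- t(rowsum(t(asums), rep(seq_len(nf),
                                 each = g$sensors$arrays_per_facet)))
    trig <- max.col(fs, ties.method = "first")
    fsum <- fs[cbind(seq_len(nrow(fs)), trig)]
    ok <- fsum > 0
    if (!any(ok)) next
    sel <- which(ok)
    arr_cols <- t(vapply(trig[sel], function(f)
      (f - 1) * g$sensors$arrays_per_facet +
        seq_len(g$sensors$arrays_per_facet), numeric(4)))
    a4 <- matrix(asums[cbind(rep(sel, each = 4), as.integer(t(arr_cols)))],
                 ncol = 4, byrow = TRUE)
    dist <- assemble_distribution(M[sel, , drop = FALSE], trig[sel] - 1L, g)
    fi <- first[blk, ][ok, ]
    res_df[[length(res_df) + 1]] <- data.frame(
      time_ns = fi$time_ns, facet = trig[sel] - 1L, fsum = fsum[sel],
      a1 = a4[, 1], a2 = a4[, 2], a3 = a4[, 3], a4 = a4[, 4],
      event = fi$event, photon = fi$photon)
    res_dist[[length(res_dist) + 1]] <- dist
  }
  if (length(res_df) == 0) return(empty_singles())
  df <- do.call(rbind, res_df)
  dist <- do.call(rbind, res_dist)
  # truth labels
  ph <- truth$photons
  mi <- match(paste(df$event, df$photon), paste(ph$event, ph$photon))
  df$label <- ph$label[mi]
  df$object_scattered <- ph$object_scattered[mi]
  ord <- order(df$time_ns)
  structure(list(df = df[ord, ], dist = dist[ord, , drop = FALSE]),
            class = "singles")
}

empty_singles <- function() {
  structure(list(
    df = data.frame(time_ns = numeric(0), facet = integer(0),
                    fsum = numeric(0), a1 = numeric(0), a2 = numeric(0),
                    a3 = numeric(0), a4 = numeric(0), event = integer(0),
                    photon = integer(0), label = character(0),
                    object_scattered = logical(0)),
    dist = matrix(numeric(0), 0, 192)), class = "singles")
}

#' Assemble 12 x 16 photon distributions around triggering facets
#'
#' The distribution concatenates the 4 x 16 sensor blocks of the facets
#' (primary - 1, primary, primary + 1) (mod n_facets) along the transaxial
#' axis, ordered by increasing azimuth then increasing z: row index 0-11 is
#' transaxial, column index 0-15 axial. Rows of the returned matrix are the
#' distributions flattened transaxial-fastest (length 192).
#'
#' @param signals `n x (n_facets*64)` matrix of per-photon sensor signals
#'   in array order.
#' @param primary 0-based triggering facet per row.
#' @param g A `scanner_geometry`.
#' @return `n x 192` matrix.
#' @export
assemble_distribution <- function(signals, primary, g) {
  nf <- g$spec$n_facets
  sg <- g$sensors
  npix <- sg$n_u * sg$n_v
  n <- nrow(signals)
  out <- matrix(0, n, 3 * npix)
  for (k in 0:2) {                      # prev, primary, next
    f <- (primary + k - 1) %% nf
    # columns of facet f in array order (iu fastest, then iv)
    # rows have different primary facets, so gather row-wise
    cols <- outer(f * npix, seq_len(npix), `+`)      # n x npix column ids
    block <- matrix(signals[cbind(rep(seq_len(n), npix),
                                  as.integer(cols))], n, npix)
    # reorder into (transaxial within 12, axial 16): target column index
    # for pixel (iu, iv): (iv-1)*12 + k*4 + iu
    iu <- rep(seq_len(sg$n_u), times = sg$n_v)
    iv <- rep(seq_len(sg$n_v), each = sg$n_u)
    tgt <- (iv - 1) * (3 * sg$n_u) + k * sg$n_u + iu
    out[, tgt] <- block
  }
  out
}

#' Convert a flattened distribution row to a 12 x 16 matrix
#' @param row Numeric vector of length 192 (transaxial-fastest layout).
#' @return 12 x 16 matrix (rows transaxial, columns axial).
#' @export
distribution_matrix <- function(row) matrix(row, nrow = 12)

#' Simulate intrinsic-background singles
#'
#' Stand-in for the crystal's intrinsic radioactivity: singles arrive as a
#' homogeneous Poisson process at `rate` per facet, at positions uniform
#' over the scintillator and with deposited energies uniform between
#' 100 and 400 keV, pushed through the optical model and thresholds like
#' any other deposition.
#'
#' @param g A `scanner_geometry`.
#' @param rate Singles per facet per second.
#' @param duration Acquisition length, s.
#' @param optics An [optical_model()].
#' @param cfg A [daq_config()].
#' @param seed Optional integer seed.
#' @return A `singles` object (labels `"intrinsic"`).
#' @export
simulate_intrinsic_singles <- function(g, rate, duration,
                                       optics = optical_model(),
                                       cfg = daq_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, rate * g$spec$n_facets * duration)
  if (n == 0) return(empty_singles())
  s <- g$spec
  f <- sample(seq_len(s$n_facets), n, replace = TRUE) - 1L
  u <- stats::runif(n, -s$facet_width / 2 * 0.999, s$facet_width / 2 * 0.999)
  v <- stats::runif(n, -s$length / 2 * 0.997, s$length / 2 * 0.997)
  dmax <- s$facet_apothem - sqrt(pmax(s$inner_radius^2 - u^2, 0))
  depth <- stats::runif(n) * (dmax - 0.01)
  p <- facet_to_world(g, f, u, v, depth)
  edep <- stats::runif(n, 100, 400)
  truth <- list(
    events = data.frame(event = seq_len(n), x = p[, 1], y = p[, 2],
                        z = p[, 3],
                        time_ns = sort(stats::runif(n, 0, duration * 1e9))),
    photons = data.frame(event = seq_len(n), photon = 1L,
                         label = "intrinsic", object_scattered = FALSE,
                         fx = p[, 1], fy = p[, 2], fz = p[, 3]),
    interactions = data.frame(event = seq_len(n), photon = 1L, order = 1L,
                              kind = "PE", x = p[, 1], y = p[, 2],
                              z = p[, 3], edep = edep, facet = f,
                              time_ns = NA_real_))
  truth$interactions$time_ns <- truth$events$time_ns
  class(truth) <- "event_truth"
  build_singles(truth, g, optics, cfg)
}

#' Find prompt coincidences on a singles timeline
#'
#' Two singles whose trigger times differ by at most half the coincidence
#' window (the window is the full width of the signed time-difference
#' acceptance) and whose facets are coincidence partners form a prompt. Groups
#' of three or more in-window singles are discarded entirely (multiple
#' coincidence rejection); in-window pairs on non-partner facets are
#' rejected and counted. Singles counts per facet are accumulated for
#' randoms estimation.
#'
#' @param singles A `singles` object (time-sorted; this is checked).
#' @param g A `scanner_geometry`.
#' @param cfg A [daq_config()].
#' @return Object of class `coincidences`: list with `events` (data.frame:
#'   `time_ns, primary, secondary, dt_ns`, truth columns `event_a, event_b,
#'   label_a, label_b, scattered_a, scattered_b`), `dist_primary`,
#'   `dist_secondary` (matrices), `counts` (list: `n_singles,
#'   singles_per_facet, n_prompt, n_multiple_discarded, n_nonpartner,
#'   duration_s`).
#' @export
find_coincidences <- function(singles, g, cfg = daq_config()) {
  df <- singles$df
  n <- nrow(df)
  t <- df$time_ns
  if (is.unsorted(t)) stop("singles timeline must be time-sorted")
  w <- cfg$coincidence_window / 2   # max |dt| = half the full width
  nf <- g$spec$n_facets
  spf <- tabulate(df$facet + 1L, nbins = nf)
  duration_s <- if (n > 1) (t[n] - t[1]) * 1e-9 else 0
  counts <- list(n_singles = n, singles_per_facet = spf, n_prompt = 0L,
                 n_multiple_discarded = 0L, n_nonpartner = 0L,
                 duration_s = duration_s)
  if (n < 2) {
    return(structure(list(events = empty_coinc_df(),
                          dist_primary = matrix(numeric(0), 0, 192),
                          dist_secondary = matrix(numeric(0), 0, 192),
                          counts = counts), class = "coincidences"))
  }
  # neighbours within the window (timeline is sorted)
  lo <- findInterval(t - w, t, left.open = TRUE) + 1L   # first index >= t-w
  hi <- findInterval(t + w, t)                           # last index <= t+w
  nwin <- hi - lo                                        # neighbours excl self
  pair_a <- which(nwin == 1 & c(diff(t) <= w, FALSE))
  pair_b <- pair_a + 1L
  good <- nwin[pair_b] == 1
  pair_a <- pair_a[good]; pair_b <- pair_b[good]
  counts$n_multiple_discarded <- sum(nwin >= 2)
  fa <- df$facet[pair_a]; fb <- df$facet[pair_b]
  # partner test: offset in the allowed set
  off <- (fb - fa) %% nf
  is_partner <- off %in% g$partner_offsets |
    ((fa - fb) %% nf) %in% g$partner_offsets
  counts$n_nonpartner <- sum(!is_partner)
  pair_a <- pair_a[is_partner]; pair_b <- pair_b[is_partner]
  counts$n_prompt <- length(pair_a)
  if (length(pair_a) == 0) {
    return(structure(list(events = empty_coinc_df(),
                          dist_primary = matrix(numeric(0), 0, 192),
                          dist_secondary = matrix(numeric(0), 0, 192),
                          counts = counts), class = "coincidences"))
  }
  # primary = larger facet sum (order-invariant)
  swap <- df$fsum[pair_b] > df$fsum[pair_a]
  ia <- ifelse(swap, pair_b, pair_a)
  ib <- ifelse(swap, pair_a, pair_b)
  events <- data.frame(
    time_ns = pmin(t[pair_a], t[pair_b]),
    primary = df$facet[ia], secondary = df$facet[ib],
    dt_ns = abs(t[pair_b] - t[pair_a]),
    event_a = df$event[ia], event_b = df$event[ib],
    label_a = df$label[ia], label_b = df$label[ib],
    scattered_a = df$object_scattered[ia],
    scattered_b = df$object_scattered[ib])
  structure(list(events = events,
                 dist_primary = singles$dist[ia, , drop = FALSE],
                 dist_secondary = singles$dist[ib, , drop = FALSE],
                 counts = counts), class = "coincidences")
}

empty_coinc_df <- function() {
  data.frame(time_ns = numeric(0), primary = integer(0),
             secondary = integer(0), dt_ns = numeric(0),
             event_a = integer(0), event_b = integer(0),
             label_a = character(0), label_b = character(0),
             scattered_a = logical(0), scattered_b = logical(0))
}

#' Classify prompts into trues, scatters and randoms using truth links
#'
#' A prompt whose two singles stem from the same annihilation is true
#' (neither photon object-scattered) or scattered (at least one was); two
#' different annihilations make a random.
#'
#' @param coinc A `coincidences` object.
#' @return Factor of length `nrow(coinc$events)` with levels
#'   `c("true", "scatter", "random")`.
#' @export
classify_prompts <- function(coinc) {
  ev <- coinc$events
  same <- ev$event_a == ev$event_b
  scat <- ev$scattered_a | ev$scattered_b
  out <- ifelse(!same, "random", ifelse(scat, "scatter", "true"))
  factor(out, levels = c("true", "scatter", "random"))
}
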