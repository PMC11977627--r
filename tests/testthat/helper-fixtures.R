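# shared fixtures, built in code

default_geometry <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- build_geometry()
    g
  }
})

# synthetic singles object with prescribed times/facets (for DAQ logic
# tests that do not need real optics)
synthetic_singles <- function(time_ns, facet, fsum = NULL, dist = NULL) {
  n <- length(time_ns)
  if (is.null(fsum)) fsum <- rep(100, n)
  if (is.null(dist)) dist <- matrix(1, n, 192)
  df <- data.frame(time_ns = time_ns, facet = as.integer(facet),
                   fsum = fsum,
                   a1 = fsum / 4, a2 = fsum / 4, a3 = fsum / 4,
                   a4 = fsum / 4,
                   event = seq_len(n), photon = rep(1L, n),
                   label = rep("PE", n),
                   object_scattered = rep(FALSE, n))
  ord <- order(df$time_ns)
  structure(list(df = df[ord, ], dist = dist[ord, , drop = FALSE]),
            class = "singles")
}

# independent Poisson singles streams on each facet at the given per-facet
# rates (cps), over `duration` seconds
poisson_singles <- function(rates_cps, duration, seed = 1) {
  set.seed(seed)
  times <- list(); facets <- list()
  for (f in seq_along(rates_cps)) {
    n <- stats::rpois(1, rates_cps[f] * duration)
    times[[f]] <- stats::runif(n, 0, duration * 1e9)
    facets[[f]] <- rep(f - 1L, n)
  }
  synthetic_singles(unlist(times), unlist(facets))
}

# isotropic 3-D Gaussian image volume
gaussian_volume <- function(sigma = 0.6, voxel = 0.25, n = 81,
                            center = c(0, 0, 0), amplitude = 1) {
  xc <- (seq_len(n) - (n + 1) / 2) * voxel
  g1 <- function(c0) exp(-(xc - c0)^2 / (2 * sigma^2))
  vals <- amplitude * outer(outer(g1(center[1]), g1(center[2])),
                            g1(center[3]))
  structure(list(values = array(vals, dim = c(n, n, n)),
                 voxel_size = voxel, slice_pitch = voxel,
                 origin = rep(-(n / 2) * voxel, 3)),
            class = "image_volume")
}

# small positioning data set shared by the positioning tests (built once)
shared_positioning_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) {
      ds <<- make_positioning_dataset(default_geometry(), n_events = 6000,
                                      seed = 21)
    }
    ds
  }
})

# truth-level LOR extraction for a quick point-source scan
point_truth_lors <- function(g, position, n = 15000, seed = 5) {
  ps <- point_source("Na22", 2e6, position)
  phys <- physics_config(object_attenuation = FALSE,
                         acollinearity_fwhm_deg = 0,
                         positron_range = FALSE)
  truth <- simulate_events(ps, g, phys, n = n, seed = seed)
  truth_lors(truth, g)
}
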