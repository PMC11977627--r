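#' Run configuration
#'
#' Bundles the per-stage configurations and the master seed. Child seeds
#' for the stochastic stages are derived from the master seed by a fixed
#' counter scheme (`seed + 1000 * stage_index`), so each stage is
#' independently reproducible.
#'
#' @param geometry A `scanner_geometry`.
#' @param phantom A phantom object.
#' @param physics A [physics_config()].
#' @param optics An [optical_model()].
#' @param daq A [daq_config()].
#' @param f_factor Harmonization f-factor.
#' @param n_events Annihilations to simulate.
#' @param seed Master seed (integer).
#' @param recon Reconstruction settings: list with `method` ("mlem" or
#'   "fbp"), `n_iter`, `dims`, `voxel_size`, `sens_stride`,
#'   `attenuation` (logical).
#' @return Object of class `run_config`.
#' @export
run_config <- function(geometry = build_geometry(),
                       phantom = point_source(),
                       physics = physics_config(),
                       optics = optical_model(),
                       daq = daq_config(),
                       f_factor = 0.0025,
                       n_events = 10000, seed = 1,
                       recon = list(method = "mlem", n_iter = 10,
                                    dims = c(64, 64, 64),
                                    voxel_size = 0.5, sens_stride = 3,
                                    attenuation = FALSE)) {
  structure(list(geometry = geometry, phantom = phantom, physics = physics,
                 optics = optics, daq = daq, f_factor = f_factor,
                 n_events = n_events, seed = as.integer(seed),
                 recon = recon),
            class = "run_config")
}

stage_seed <- function(cfg, stage_index) cfg$seed + 1000L * stage_index

#' Run the simulation-to-reconstruction pipeline
#'
#' Executes simulate -> daq -> position -> project -> reconstruct (any
#' contiguous prefix selectable via `stages`) and returns the stage
#' outputs plus a manifest of event counts and (when `out_dir` is given)
#' output file hashes. Deterministic at fixed config: rerunning reproduces
#' identical manifests.
#'
#' @param cfg A [run_config()].
#' @param stages Character vector of stages to run (a contiguous prefix of
#'   `c("simulate", "daq", "position", "project", "reconstruct")`).
#' @param out_dir Optional directory for list-mode/volume/manifest files.
#' @param positioner `"com"` (default) or a trained `positioner_model`.
#' @return Object of class `run_result`: list with the stage outputs
#'   (`truth`, `singles`, `coincidences`, `positions`, `lors`, `volume`)
#'   and `manifest`.
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "daq", "position",
                                         "project", "reconstruct"),
                         out_dir = NULL, positioner = "com") {
  all_stages <- c("simulate", "daq", "position", "project", "reconstruct")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  last <- max(match(stages, all_stages))
  g <- cfg$geometry
  manifest <- list(seed = cfg$seed, n_events = cfg$n_events,
                   counts = list(), files = list())
  res <- list()

  truth <- simulate_events(cfg$phantom, g, cfg$physics, cfg$n_events,
                           seed = stage_seed(cfg, 1L))
  manifest$counts$annihilations <- nrow(truth$events)
  manifest$counts$interactions <- nrow(truth$interactions)
  res$truth <- truth
  if (last >= 2) {
    set.seed(stage_seed(cfg, 2L))
    singles <- build_singles(truth, g, cfg$optics, cfg$daq)
    coinc <- find_coincidences(singles, g, cfg$daq)
    manifest$counts$singles <- nrow(singles$df)
    manifest$counts$prompts <- coinc$counts$n_prompt
    res$singles <- singles
    res$coincidences <- coinc
  }
  if (last >= 3) {
    if (identical(positioner, "com")) {
      lut <- calibrate_depth_lut(g, cfg$optics, seed = stage_seed(cfg, 3L))
      pa <- com_position(harmonize(res$coincidences$dist_primary,
                                   cfg$f_factor),
                         res$coincidences$events$primary, g, lut)
      pb <- com_position(harmonize(res$coincidences$dist_secondary,
                                   cfg$f_factor),
                         res$coincidences$events$secondary, g, lut)
    } else {
      pa <- predict_position(positioner,
                             harmonize(res$coincidences$dist_primary,
                                       cfg$f_factor),
                             res$coincidences$events$primary, g)
      pb <- predict_position(positioner,
                             harmonize(res$coincidences$dist_secondary,
                                       cfg$f_factor),
                             res$coincidences$events$secondary, g)
    }
    res$positions <- list(primary = pa, secondary = pb)
    manifest$counts$positioned <- nrow(pa)
  }
  if (last >= 4) {
    lors <- project_lor(res$positions$primary, res$positions$secondary,
                        res$coincidences$events$primary,
                        res$coincidences$events$secondary, g,
                        res$coincidences$events$time_ns)
    if (isTRUE(cfg$recon$attenuation)) {
      mu <- make_attenuation_phantom(cfg$phantom)
      lors$weight <- attenuation_weight(lors, mu, g)
    }
    res$lors <- lors
    manifest$counts$lors <- nrow(lors)
    manifest$counts$lor_rejects <- as.list(attr(lors, "rejects"))
  }
  if (last >= 5) {
    rc <- cfg$recon
    if (identical(rc$method, "fbp")) {
      sino <- ssrb_rebin(res$lors, g)
      vol <- fbp_reconstruct(sino, pixel_size = rc$voxel_size,
                             n_pixels = rc$dims[1])
      res$sinogram <- sino
    } else {
      mu <- if (isTRUE(rc$attenuation)) {
        make_attenuation_phantom(cfg$phantom)
      } else NULL
      vol <- mlem_reconstruct(res$lors, g, n_iter = rc$n_iter,
                              dims = rc$dims, voxel_size = rc$voxel_size,
                              mu_map = mu,
                              sens_stride = rc$sens_stride)
    }
    res$volume <- vol
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$lors)) {
      f <- file.path(out_dir, "lors.lm")
      write_listmode(res$lors, f, g)
      manifest$files[["lors.lm"]] <- unname(tools::md5sum(f))
    }
    if (!is.null(res$volume)) {
      f <- file.path(out_dir, "volume.raw")
      write_volume(res$volume, f)
      manifest$files[["volume.raw"]] <- unname(tools::md5sum(f))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res$manifest <- manifest
  structure(res, class = "run_result")
}

# ---------------------------------------------------------------------------
# file formats: projected list-mode (binary records + JSON header),
# volumes (raw float32 + JSON sidecar)

LISTMODE_VERSION <- 1L

#' Write projected list-mode data
#'
#' Fixed-length little-endian records (int64-as-double time ns; uint8
#' plane ids; uint8 element indices packed as two bytes each; float32
#' weight) preceded by a length-prefixed JSON header carrying the schema
#' version, geometry hash and record count. Round-trips bit-exactly.
#'
#' @param lors A `projected_lors` data.frame.
#' @param path Output file.
#' @param g The `scanner_geometry` the data belong to.
#' @export
write_listmode <- function(lors, path, g) {
  header <- list(schema = "mapet-listmode", version = LISTMODE_VERSION,
                 n_records = nrow(lors), geometry = geometry_hash(g))
  hj <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(length(hj), con, size = 4, endian = "little")
  writeBin(hj, con)
  writeBin(as.numeric(lors$time_ns), con, size = 8, endian = "little")
  writeBin(as.integer(lors$plane1), con, size = 1)
  writeBin(as.integer(lors$plane2), con, size = 1)
  writeBin(as.integer(lors$iu1), con, size = 1)
  writeBin(as.integer(lors$iu2), con, size = 1)
  writeBin(as.integer(lors$iv1), con, size = 1)
  writeBin(as.integer(lors$iv2), con, size = 1)
  writeBin(as.numeric(lors$weight), con, size = 4, endian = "little")
  invisible(path)
}

#' Read projected list-mode data
#'
#' @param path File written by [write_listmode()].
#' @param g Optional `scanner_geometry`; when given, the stored geometry
#'   hash must match unless `override = TRUE`.
#' @param override Skip the geometry hash check.
#' @return A `projected_lors` data.frame with attribute `"header"`.
#' @export
read_listmode <- function(path, g = NULL, override = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  hlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(hlen) == 0 || hlen <= 0 || hlen > 1e6) {
    stop("truncated or corrupt list-mode header")
  }
  hj <- readBin(con, "raw", hlen)
  header <- jsonlite::fromJSON(rawToChar(hj))
  if (!identical(header$schema, "mapet-listmode") ||
      header$version != LISTMODE_VERSION) {
    stop("unsupported list-mode schema/version")
  }
  if (!is.null(g) && !override && header$geometry != geometry_hash(g)) {
    stop("geometry hash mismatch; pass override = TRUE to force")
  }
  n <- header$n_records
  rd <- function(what, size, count = n, ...) {
    out <- readBin(con, what, count, size = size, ...)
    if (length(out) < count) {
      stop("truncated list-mode file at record ", length(out))
    }
    out
  }
  time_ns <- rd("numeric", 8, endian = "little")
  plane1 <- rd("integer", 1)
  plane2 <- rd("integer", 1)
  iu1 <- rd("integer", 1)
  iu2 <- rd("integer", 1)
  iv1 <- rd("integer", 1)
  iv2 <- rd("integer", 1)
  weight <- rd("numeric", 4, endian = "little")
  out <- data.frame(plane1 = plane1, iu1 = iu1, iv1 = iv1,
                    plane2 = plane2, iu2 = iu2, iv2 = iv2,
                    time_ns = time_ns, weight = weight)
  attr(out, "header") <- header
  class(out) <- c("projected_lors", "data.frame")
  out
}

#' Hash of the geometry configuration (for file headers)
#' @param g A `scanner_geometry`.
#' @return Character md5 hash.
#' @export
geometry_hash <- function(g) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(geometry_to_list(g), auto_unbox = TRUE,
                              digits = 12), tf)
  unname(tools::md5sum(tf))
}

#' Write an image volume as raw float32 + JSON sidecar
#' @param vol An `image_volume`.
#' @param path Output path (sidecar at `paste0(path, ".json")`).
#' @export
write_volume <- function(vol, path) {
  con <- file(path, "wb")
  writeBin(as.numeric(vol$values), con, size = 4, endian = "little")
  close(con)
  meta <- list(dims = dim(vol$values), voxel_size = vol$voxel_size,
               slice_pitch = vol$slice_pitch, origin = vol$origin)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image volume written by [write_volume()]
#' @param path Path to the raw file.
#' @return An `image_volume`.
#' @export
read_volume <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  n <- prod(meta$dims)
  con <- file(path, "rb")
  vals <- readBin(con, "numeric", n, size = 4, endian = "little")
  close(con)
  if (length(vals) < n) stop("truncated volume file")
  structure(list(values = array(vals, dim = meta$dims),
                 voxel_size = meta$voxel_size,
                 slice_pitch = meta$slice_pitch, origin = meta$origin),
            class = "image_volume")
}

#' Export simulated event truth as CSV tables
#'
#' Writes the three truth tables (`events`, `photons`, `interactions`) as
#' plain CSV files, for inspection or cross-language use on small runs.
#'
#' @param truth An `event_truth`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_event_truth_csv <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(truth$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$photons, file.path(dir, "photons.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$interactions, file.path(dir, "interactions.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Save / load a trained positioner checkpoint
#'
#' The checkpoint is a little-endian binary stream of the parameter
#' tensors with a JSON sidecar (architecture descriptor, target scaling,
#' training metadata, loss history), so a model can be reused across
#' sessions.
#'
#' @param model A `positioner_model`.
#' @param path Checkpoint path (sidecar at `paste0(path, ".json")`).
#' @return `path`, invisibly.
#' @export
save_positioner <- function(model, path) {
  tensors <- c(list(model$params$W_in, model$params$b_in),
               unlist(lapply(model$params$blocks, function(b) {
                 list(b$W1, b$b1, b$W2, b$b2)
               }), recursive = FALSE),
               list(model$params$W_out, model$params$b_out))
  con <- file(path, "wb")
  for (tn in tensors) writeBin(as.numeric(tn), con, size = 8,
                               endian = "little")
  close(con)
  meta <- list(schema = "mapet-positioner", version = 1L,
               n_in = nrow(model$params$W_in),
               width = ncol(model$params$W_in),
               n_blocks = length(model$params$blocks),
               center = as.numeric(model$center),
               scale = as.numeric(model$scale),
               loss_history = model$loss_history, config = model$config)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_positioner
#' @param path Checkpoint path written by [save_positioner()].
#' @export
load_positioner <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  if (!identical(meta$schema, "mapet-positioner")) {
    stop("not a positioner checkpoint: ", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nr, nc = NULL) {
    n <- if (is.null(nc)) nr else nr * nc
    v <- readBin(con, "numeric", n, size = 8, endian = "little")
    if (length(v) < n) stop("truncated checkpoint")
    if (is.null(nc)) v else matrix(v, nr, nc)
  }
  w <- meta$width
  params <- list(W_in = rd(meta$n_in, w), b_in = rd(w),
                 blocks = lapply(seq_len(meta$n_blocks), function(i) {
                   list(W1 = rd(w, w), b1 = rd(w),
                        W2 = rd(w, w), b2 = rd(w))
                 }),
                 W_out = rd(w, 3), b_out = rd(3))
  structure(list(params = params, center = meta$center,
                 scale = meta$scale, loss_history = meta$loss_history,
                 config = meta$config),
            class = "positioner_model")
}

#' Export an image volume as NIfTI
#'
#' @param vol An `image_volume`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI export")
  }
  zstep <- if (!is.null(vol$slice_pitch)) vol$slice_pitch else vol$voxel_size
  img <- RNifti::asNifti(vol$values,
                         pixdim = c(vol$voxel_size, vol$voxel_size, zstep))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Geometry / phantom / optics configuration from YAML
#'
#' @param path YAML file with optional blocks `annulus`, `sensors`,
#'   `virtual`, `optics`, `daq`, `physics`.
#' @return A list with the constructed component objects.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(f, args) do.call(f, if (is.null(args)) list() else args)
  list(geometry = build_geometry(build(annulus_spec, y$annulus),
                                 build(sensor_grid, y$sensors),
                                 build(virtual_detector_spec, y$virtual)),
       optics = build(optical_model, y$optics),
       daq = build(daq_config, y$daq))
}

#' Generate seeded test fixtures for the NU4 protocols
#'
#' Produces small, fully self-contained simulated data sets mirroring the
#' NU4 measurement layouts: `"resolution"` (point source at 5/10/15/18 mm
#' radial offsets, at the axial centre and at a quarter of the axial FOV),
#' `"sensitivity"` (15 axial positions at 5 mm spacing), `"countrate"` (a
#' decaying-activity sweep), and `"training"` (a positioning data set).
#'
#' @param kind Fixture kind.
#' @param n_events Annihilations per acquisition.
#' @param seed Master seed.
#' @param g A `scanner_geometry`.
#' @param ... Passed to the underlying generators.
#' @return A list of acquisitions (contents depend on `kind`).
#' @export
make_fixtures <- function(kind = c("resolution", "sensitivity",
                                   "countrate", "training"),
                          n_events = 5000, seed = 1,
                          g = build_geometry(), ...) {
  kind <- match.arg(kind)
  if (kind == "resolution") {
    offsets <- c(5, 10, 15, 18)
    zpos <- c(0, g$spec$length / 4)
    acqs <- list()
    k <- 0
    for (z in zpos) for (r in offsets) {
      k <- k + 1
      cfg <- run_config(geometry = g,
                        phantom = point_source("Na22", 1.85e6, c(r, 0, z)),
                        n_events = n_events, seed = seed + k, ...)
      acqs[[k]] <- list(radial_mm = r, z_mm = z, cfg = cfg)
    }
    return(acqs)
  }
  if (kind == "sensitivity") {
    zs <- seq(-35, 35, by = 5)
    lapply(seq_along(zs), function(k) {
      list(z_mm = zs[k],
           cfg = run_config(geometry = g,
                            phantom = point_source("Na22", 1.85e6,
                                                   c(0, 0, zs[k])),
                            n_events = n_events, seed = seed + k, ...))
    })
  } else if (kind == "countrate") {
    args <- list(...)
    n_acq <- if (is.null(args$n_acq)) 6 else args$n_acq
    a0 <- if (is.null(args$activity0)) 16e6 else args$activity0
    half <- nuclide_data("F18")$half_life
    tpts <- seq(0, 10 * 3600, length.out = n_acq)
    lapply(seq_len(n_acq), function(k) {
      act <- a0 * 2^(-tpts[k] / half)
      list(time_s = tpts[k], activity_Bq = act,
           cfg = run_config(geometry = g,
                            phantom = mouse_phantom(activity = act),
                            n_events = n_events, seed = seed + k))
    })
  } else {
    make_positioning_dataset(g, n_events = n_events, seed = seed, ...)
  }
}
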