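# File formats: HDF5 container (primary, lossless at 32-bit float), TIFF
# interchange, YAML experiment configs, JSON reports.

h5_write_f32 <- function(file, name, data) {
  d <- dim(data)
  if (is.null(d)) d <- length(data)
  rhdf5::h5createDataset(file, name, dims = d, storage.mode = "double",
                         H5type = "H5T_IEEE_F32LE", chunk = d)
  rhdf5::h5write(data, file, name)
}

#' Write an experiment container (HDF5)
#'
#' Stores sinograms, volumes and schedules in a single HDF5 file with a
#' fixed schema: `/sinogram` + `/angles` for a plain sinogram,
#' `/time/<t>/sinogram` + `/time/<t>/angles` per time step,
#' `/channels/<c>/sinogram` per channel (sharing `/angles`), `/volume` for
#' an image volume, and geometry scalars under `/geometry/*`.  Bulk floating
#' point data (sinograms, volumes) is stored as 32-bit floats; angle lists
#' are coordinates and kept at full double precision.  The configuration,
#' when given, is stored as a YAML string in the `/config` dataset.
#'
#' @param path output file; must not exist unless `overwrite = TRUE`.
#' @param sinogram optional [sinogram] (writes `/sinogram`, `/angles`).
#' @param time_steps optional list of [sinogram]s (writes `/time/...`).
#' @param channels optional list of per-channel [sinogram]s sharing one
#'   geometry (writes `/channels/...` and `/angles`).
#' @param volume optional numeric array (writes `/volume`).
#' @param config optional list, serialized as YAML.
#' @param overwrite replace an existing file.
#' @return `path`, invisibly.
#' @export
write_container <- function(path, sinogram = NULL, time_steps = NULL,
                            channels = NULL, volume = NULL, config = NULL,
                            overwrite = FALSE) {
  if (file.exists(path)) {
    if (!overwrite) stop_invalid("file exists: ", path)
    unlink(path)
  }
  rhdf5::h5createFile(path)
  on.exit(rhdf5::H5close(), add = TRUE)
  geo <- NULL
  if (!is.null(sinogram)) {
    h5_write_f32(path, "sinogram", sinogram$values)
    rhdf5::h5write(sinogram$geometry$angles, path, "angles")
    geo <- sinogram$geometry
  }
  if (!is.null(time_steps)) {
    rhdf5::h5createGroup(path, "time")
    for (t in seq_along(time_steps)) {
      grp <- sprintf("time/%d", t)
      rhdf5::h5createGroup(path, grp)
      h5_write_f32(path, paste0(grp, "/sinogram"), time_steps[[t]]$values)
      rhdf5::h5write(time_steps[[t]]$geometry$angles, path,
                     paste0(grp, "/angles"))
    }
    geo <- time_steps[[1]]$geometry
  }
  if (!is.null(channels)) {
    rhdf5::h5createGroup(path, "channels")
    for (c0 in seq_along(channels)) {
      grp <- sprintf("channels/%d", c0)
      rhdf5::h5createGroup(path, grp)
      h5_write_f32(path, paste0(grp, "/sinogram"), channels[[c0]]$values)
    }
    if (is.null(sinogram))
      rhdf5::h5write(channels[[1]]$geometry$angles, path, "angles")
    geo <- channels[[1]]$geometry
  }
  if (!is.null(volume)) h5_write_f32(path, "volume", volume)
  if (!is.null(geo)) {
    rhdf5::h5createGroup(path, "geometry")
    rhdf5::h5write(geo$num_detector_pixels, path, "geometry/num_detector_pixels")
    rhdf5::h5write(geo$image_size, path, "geometry/image_size")
    rhdf5::h5write(geo$detector_pixel_size, path, "geometry/detector_pixel_size")
    rhdf5::h5write(geo$rotation_center, path, "geometry/rotation_center")
  }
  if (!is.null(config))
    rhdf5::h5write(yaml::as.yaml(config), path, "config")
  invisible(path)
}

#' Read an experiment container (HDF5)
#'
#' Inverse of [write_container()].  Validates the schema and names the
#' missing dataset in its error message when a mandatory dataset (e.g.
#' `/angles` for a stored sinogram) is absent.
#'
#' @param path HDF5 file written by [write_container()].
#' @return List with any of `sinogram`, `time_steps`, `channels`, `volume`,
#'   `config` that the file contains.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  on.exit(rhdf5::H5close(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  entries <- gsub("//", "/", paste0(ls$group, "/", ls$name))
  has <- function(nm) nm %in% entries
  out <- list()
  make_geo <- function(angles) {
    if (!has("/geometry/num_detector_pixels"))
      stop("container schema error: missing dataset /geometry/num_detector_pixels")
    projection_geometry(
      angles,
      as.integer(rhdf5::h5read(path, "geometry/num_detector_pixels")),
      as.integer(rhdf5::h5read(path, "geometry/image_size")),
      as.numeric(rhdf5::h5read(path, "geometry/detector_pixel_size")),
      as.numeric(rhdf5::h5read(path, "geometry/rotation_center")))
  }
  if (has("/sinogram")) {
    if (!has("/angles"))
      stop("container schema error: missing dataset /angles")
    ang <- as.numeric(rhdf5::h5read(path, "angles"))
    out$sinogram <- sinogram(rhdf5::h5read(path, "sinogram"), make_geo(ang))
  }
  if (has("/time")) {
    ts <- ls$name[ls$group == "/time"]
    ts <- sort(as.integer(ts))
    out$time_steps <- lapply(ts, function(t) {
      if (!has(sprintf("/time/%d/angles", t)))
        stop(sprintf("container schema error: missing dataset /time/%d/angles", t))
      ang <- as.numeric(rhdf5::h5read(path, sprintf("time/%d/angles", t)))
      sinogram(rhdf5::h5read(path, sprintf("time/%d/sinogram", t)),
               make_geo(ang), time_index = t)
    })
  }
  if (has("/channels")) {
    if (!has("/angles"))
      stop("container schema error: missing dataset /angles")
    ang <- as.numeric(rhdf5::h5read(path, "angles"))
    geo <- make_geo(ang)
    cs <- sort(as.integer(ls$name[ls$group == "/channels"]))
    out$channels <- lapply(cs, function(c0)
      sinogram(rhdf5::h5read(path, sprintf("channels/%d/sinogram", c0)),
               geo, channel_index = c0))
  }
  if (has("/volume")) out$volume <- rhdf5::h5read(path, "volume")
  if (has("/config"))
    out$config <- yaml::yaml.load(as.character(rhdf5::h5read(path, "config")))
  out
}

#' Write a volume as multi-page 32-bit TIFF
#'
#' The TIFF writer stores 32-bit float pages in the [0, 1] range, so the
#' volume is affinely rescaled and the `(offset, scale)` pair is recorded in
#' a JSON sidecar (`<path>.range.json`) that [read_tiff_volume()] applies to
#' restore physical values.  Pages are the slices along the first axis.
#'
#' @param volume `depth x N x N` array or `N x N` matrix.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_tiff_volume <- function(volume, path) {
  if (is.matrix(volume)) volume <- array(volume, dim = c(1L, dim(volume)))
  lo <- min(volume); hi <- max(volume)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(volume)[1]), function(s)
    (matrix(volume[s, , ], dim(volume)[2]) - lo) / scale)
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  jsonlite::write_json(list(offset = lo, scale = scale),
                       paste0(path, ".range.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tiff_volume
#' @param path_in TIFF file written by [write_tiff_volume()] (or any float
#'   TIFF; without a sidecar the raw [0, 1] values are returned).
#' @return `read_tiff_volume`: a `depth x N x N` array.
#' @export
read_tiff_volume <- function(path_in) {
  pages <- tiff::readTIFF(path_in, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vol <- array(0, dim = c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (s in seq_along(pages)) vol[s, , ] <- pages[[s]]
  side <- paste0(path_in, ".range.json")
  if (file.exists(side)) {
    rg <- jsonlite::fromJSON(side)
    vol <- vol * rg$scale + rg$offset
  }
  vol
}

#' Save / load a trained model checkpoint (HDF5)
#'
#' The checkpoint holds the network configuration, the weight vector, the
#' normalization statistics, the training provenance, and the split scheme
#' (as JSON), so a saved model can be reloaded and applied bit-identically.
#'
#' @param fit a `noise2inverse` object.
#' @param path checkpoint file.
#' @return `save_model`: `path` invisibly; `load_model`: the restored
#'   `noise2inverse` object (without the original call).
#' @export
save_model <- function(fit, path) {
  if (!inherits(fit, "noise2inverse")) stop_invalid("fit must be a noise2inverse object")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::H5close(), add = TRUE)
  m <- fit$model
  cfg <- m$config
  rhdf5::h5write(m$weights, path, "weights")
  rhdf5::h5createGroup(path, "normalization")
  for (nm in names(m$normalization))
    rhdf5::h5write(m$normalization[[nm]], path, paste0("normalization/", nm))
  rhdf5::h5createGroup(path, "config")
  for (nm in c("depth", "in_channels", "out_channels", "dilation_cycle",
               "weight_init_seed"))
    rhdf5::h5write(cfg[[nm]], path, paste0("config/", nm))
  rhdf5::h5write(cfg$pad_mode, path, "pad_mode")
  rhdf5::h5write(fit$strategy, path, "strategy")
  rhdf5::h5write(c(context = fit$context), path, "context")
  rhdf5::h5write(fit$filter_name, path, "filter_name")
  rhdf5::h5write(as.character(scheme_to_json(fit$scheme)), path, "scheme_json")
  if (length(fit$loss_history))
    rhdf5::h5write(fit$loss_history, path, "loss_history")
  pr <- m$provenance
  if (length(pr))
    rhdf5::h5write(yaml::as.yaml(pr), path, "provenance")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  on.exit(rhdf5::H5close(), add = TRUE)
  cf <- lapply(rhdf5::h5read(path, "config"), as.integer)
  cfg <- msd_config(cf$depth, cf$in_channels, cf$out_channels,
                    cf$dilation_cycle, cf$weight_init_seed,
                    as.character(rhdf5::h5read(path, "pad_mode")))
  ns <- lapply(rhdf5::h5read(path, "normalization"), as.numeric)
  model <- structure(list(config = cfg,
                          weights = as.numeric(rhdf5::h5read(path, "weights")),
                          normalization = ns,
                          provenance = list()),
                     class = "denoising_model")
  ls <- rhdf5::h5ls(path)
  if ("loss_history" %in% ls$name)
    model$loss_history <- as.numeric(rhdf5::h5read(path, "loss_history"))
  if ("provenance" %in% ls$name)
    model$provenance <- yaml::yaml.load(as.character(rhdf5::h5read(path, "provenance")))
  scheme <- scheme_from_json(as.character(rhdf5::h5read(path, "scheme_json")))
  structure(list(model = model, scheme = scheme,
                 strategy = as.character(rhdf5::h5read(path, "strategy")),
                 context = as.integer(rhdf5::h5read(path, "context")),
                 filter_name = as.character(rhdf5::h5read(path, "filter_name")),
                 loss_history = model$loss_history,
                 npairs = NA_integer_, call = NULL),
            class = "noise2inverse")
}
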