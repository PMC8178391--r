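# Synthetic ground-truth generators.  All generators are pure functions of
# (parameters, seed): they draw through with_seed() and never touch the
# global RNG state of the caller.
#
# Default attenuation values are per-pixel line-attenuation coefficients
# chosen so that line integrals through a fully contained object stay in the
# low single digits (max p of roughly 2-3), i.e. transmissions where photon
# counting at a few hundred incident photons per ray gives visible but
# non-starved noise.

#' Default material attenuation table
#'
#' Material id 0 is background (air, attenuation 0); 1 is the embedding
#' matrix disk; 2 low-density pores; 3 and 4 denser inclusions; 9 is the
#' growing inclusion material of dynamic phantoms (contrast below the
#' matrix, like water in a porous electrode).  Values are attenuation per
#' pixel traversed.
#'
#' @return Named numeric vector mapping material id to attenuation.
#' @export
default_attenuation_table <- function() {
  c("0" = 0, "1" = 0.02, "2" = 0.005, "3" = 0.04, "4" = 0.03, "9" = 0.011)
}

labeled_volume <- function(labels, attenuation_table) {
  ids <- sort(unique(as.vector(labels)))
  missing <- setdiff(as.character(ids), names(attenuation_table))
  if (length(missing))
    stop_invalid("attenuation table lacks material id(s): ",
                 paste(missing, collapse = ", "))
  if (any(attenuation_table < 0)) stop_invalid("attenuation must be >= 0")
  att <- array(attenuation_table[as.character(labels)], dim = dim(labels))
  structure(list(labels = labels, attenuation_table = attenuation_table,
                 attenuation = att),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("Labeled volume: %d slices of %dx%d, materials {%s}\n",
              d[1], d[2], d[3],
              paste(sort(unique(as.vector(x$labels))), collapse = ", ")))
  invisible(x)
}

# squared-distance helper grids for an N x N slice, centred coordinates
slice_grids <- function(N) {
  c0 <- (N - 1) / 2
  x <- matrix(rep(0:(N - 1), N), N) - c0
  list(x = x, y = t(x))
}

#' Static porous 3D phantom
#'
#' A cylindrical matrix (material 1) filling the inscribed circle of radius
#' `N/2 - 2`, containing `num_features` randomly placed, non-overlapping
#' ellipsoids and vertical cylinders of materials 2-4 (pores and denser
#' inclusions).  Features span several slices so that adjacent slices are
#' informative context for 2.5D denoising.  Placement is rejection-sampled;
#' if a feature cannot be placed after 500 attempts the generator stops with
#' an error rather than silently packing fewer features.
#'
#' @param N slice side length (>= 16).
#' @param depth number of slices.
#' @param num_features number of inclusions to place.
#' @param seed integer seed; the volume is a pure function of it.
#' @param attenuation_table material id to attenuation mapping.
#' @return A `labeled_volume` with fields `labels` (`depth x N x N` integer
#'   array), `attenuation_table`, and the derived `attenuation` array.
#' @export
static_phantom <- function(N, depth = 8, num_features = 12, seed = 1,
                           attenuation_table = default_attenuation_table()) {
  if (N < 16) stop_invalid("N must be >= 16")
  if (depth < 1) stop_invalid("depth must be >= 1")
  R <- N / 2 - 2
  g <- slice_grids(N)
  base <- matrix(0L, N, N)
  base[g$x^2 + g$y^2 <= R^2] <- 1L
  labels <- array(0L, dim = c(depth, N, N))
  for (s in seq_len(depth)) labels[s, , ] <- base

  if (num_features > 0) {
    feats <- with_seed(seed, function() {
      placed <- list()
      for (k in seq_len(num_features)) {
        ok <- FALSE
        for (try in 1:500) {
          kind <- sample(c("ellipsoid", "cylinder"), 1)
          mat <- sample(2:4, 1)
          a <- runif(1, 0.04 * N, 0.10 * N)   # in-plane semi-axes
          b <- runif(1, 0.04 * N, 0.10 * N)
          cz <- runif(1, max(2, 0.25 * depth), max(3, 0.75 * depth))
          az <- if (kind == "cylinder") depth else runif(1, depth / 4, depth)
          rmax <- max(a, b)
          rho <- runif(1, 0, max(0, R - rmax - 1))
          phi <- runif(1, 0, 2 * pi)
          cand <- list(kind = kind, mat = mat, a = a, b = b, az = az,
                       cx = rho * cos(phi), cy = rho * sin(phi), cz = cz)
          overlaps <- any(vapply(placed, function(p) {
            sqrt((p$cx - cand$cx)^2 + (p$cy - cand$cy)^2) <
              (max(p$a, p$b) + rmax + 1)
          }, TRUE))
          if (!overlaps) { ok <- TRUE; break }
        }
        if (!ok)
          stop("could not place feature ", k, " of ", num_features,
               " without overlap after 500 attempts; reduce num_features or increase N")
        placed[[k]] <- cand
      }
      placed
    })
    for (p in feats) {
      inplane <- (g$x - p$cx)^2 / p$a^2 + (g$y - p$cy)^2 / p$b^2
      for (s in seq_len(depth)) {
        zterm <- if (p$kind == "cylinder") 0 else (s - p$cz)^2 / (p$az / 2)^2
        mask <- inplane + zterm <= 1
        sl <- labels[s, , ]
        sl[mask] <- p$mat
        labels[s, , ] <- sl
      }
    }
  }
  labeled_volume(labels, attenuation_table)
}

#' Dynamically evolving phantom sequence
#'
#' A static base volume (the phantom before the process starts) that remains
#' bitwise identical for all time steps before `start_step`; from
#' `start_step` on, spherical inclusions of a new material (id 9) grow
#' monotonically with radius `r0 + growth_rate * (t - start_step)` voxels,
#' emulating e.g. a water bubble forming inside a porous structure.  Time
#' steps are 1-based; `start_step` is the first step at which anything
#' changes.
#'
#' @param N,depth,seed,attenuation_table as in [static_phantom()].
#' @param T_steps total number of time steps.
#' @param start_step integer in `[1, T_steps]`; steps before it are static.
#' @param growth_rate positive real, voxels of radius growth per step.
#' @param num_inclusions number of growth sites (default 2).
#' @param num_features static features in the base volume.
#' @param r0 initial inclusion radius at `start_step` (default 1.5).
#' @return Object of class `dynamic_volume_sequence`: list with `volumes`
#'   (list of `labeled_volume` per step), `start_step`, and the growth
#'   parameters.
#' @export
dynamic_phantom <- function(N, depth = 1, T_steps = 12, start_step = 7,
                            growth_rate = 1, seed = 1, num_inclusions = 2,
                            num_features = 6, r0 = 1.5,
                            attenuation_table = default_attenuation_table()) {
  if (start_step < 1 || start_step > T_steps)
    stop_invalid("start_step must lie in [1, T_steps]")
  if (growth_rate <= 0) stop_invalid("growth_rate must be positive")
  base <- static_phantom(N, depth, num_features, seed, attenuation_table)
  R <- N / 2 - 2
  sites <- with_seed(seed + 1L, function() {
    lapply(seq_len(num_inclusions), function(i) {
      rho <- runif(1, 0, 0.6 * R)
      phi <- runif(1, 0, 2 * pi)
      list(cx = rho * cos(phi), cy = rho * sin(phi),
           cz = runif(1, 1, depth))
    })
  })
  g <- slice_grids(N)
  vols <- vector("list", T_steps)
  for (t in seq_len(T_steps)) {
    if (t < start_step) {
      vols[[t]] <- base
      next
    }
    r <- r0 + growth_rate * (t - start_step)
    labels <- base$labels
    for (p in sites) {
      for (s in seq_len(depth)) {
        dz2 <- if (depth == 1) 0 else (s - p$cz)^2
        mask <- (g$x - p$cx)^2 + (g$y - p$cy)^2 + dz2 <= r^2
        # the inclusion only grows inside the object disk
        mask <- mask & (g$x^2 + g$y^2 <= R^2)
        sl <- labels[s, , ]
        sl[mask] <- 9L
        labels[s, , ] <- sl
      }
    }
    vols[[t]] <- labeled_volume(labels, attenuation_table)
  }
  structure(list(volumes = vols, start_step = start_step,
                 growth_rate = growth_rate, r0 = r0),
            class = "dynamic_volume_sequence")
}

#' @export
print.dynamic_volume_sequence <- function(x, ...) {
  cat(sprintf("Dynamic phantom: %d time steps, process starts at step %d (growth %.2f vox/step)\n",
              length(x$volumes), x$start_step, x$growth_rate))
  invisible(x)
}

#' Multi-channel spectral phantom slice
#'
#' A labeled 2D slice (matrix disk plus circular grains of `num_materials`
#' materials) in which every material carries a characteristic positive
#' `C`-vector signature — a sparse set of "peaks" on a small broadband
#' baseline, playing the role of a diffractogram.  The defining
#' correspondence property holds by construction: two pixels with the same
#' label have identical channel vectors wherever they sit in the slice.
#'
#' @param N slice side.
#' @param num_materials number of distinct grain materials (>= 1).
#' @param C number of channels (>= 1).
#' @param seed integer seed.
#' @param peak_scale attenuation scale of the strongest peaks (default 0.03,
#'   keeping line integrals in the photon-friendly range).
#' @return Object of class `spectral_slice`: `labels` (`N x N` integer
#'   matrix), `signature_table` (`(num_materials + 1) x C` matrix, row
#'   `m + 1` is material `m`'s signature, material 0 = background all-zero),
#'   and `channels` (`N x N x C` attenuation array).
#' @export
spectral_phantom <- function(N, num_materials = 4, C = 11, seed = 1,
                             peak_scale = 0.03) {
  if (C < 1 || num_materials < 1) stop_invalid("C and num_materials must be >= 1")
  if (N < 16) stop_invalid("N must be >= 16")
  R <- N / 2 - 2
  g <- slice_grids(N)
  labels <- matrix(0L, N, N)
  labels[g$x^2 + g$y^2 <= R^2] <- 1L

  out <- with_seed(seed, function() {
    sig <- matrix(0, num_materials + 1, C)
    for (m in seq_len(num_materials)) {
      baseline <- runif(1, 0.05, 0.15) * peak_scale
      sig[m + 1, ] <- baseline
      npk <- sample(1:3, 1)
      pk <- sample.int(C, min(npk, C))
      sig[m + 1, pk] <- sig[m + 1, pk] + runif(length(pk), 0.5, 1) * peak_scale
    }
    grains <- list()
    ngrain <- max(2 * num_materials, 6)
    for (k in seq_len(ngrain)) {
      for (try in 1:500) {
        r <- runif(1, 0.06 * N, 0.16 * N)
        rho <- runif(1, 0, max(0, R - r - 1))
        phi <- runif(1, 0, 2 * pi)
        cand <- list(cx = rho * cos(phi), cy = rho * sin(phi), r = r,
                     mat = ((k - 1) %% num_materials) + 1)
        ex <- Filter(Negate(is.null), grains)
        overlaps <- any(vapply(ex, function(p)
          sqrt((p$cx - cand$cx)^2 + (p$cy - cand$cy)^2) < p$r + r + 1, TRUE))
        if (!overlaps) { grains[[k]] <- cand; break }
      }
    }
    list(sig = sig, grains = grains)
  })
  for (p in out$grains) {
    if (is.null(p)) next
    labels[(g$x - p$cx)^2 + (g$y - p$cy)^2 <= p$r^2] <- as.integer(p$mat + 1)
  }
  # material ids: 0 background, 1 matrix, 2..(num_materials+1) grains.
  # signature row for the matrix disk: a flat low baseline.
  sig <- rbind(0, c(rep(0.1 * peak_scale, C)))
  sig <- rbind(sig, out$sig[-1, , drop = FALSE])
  channels <- array(0, dim = c(N, N, C))
  for (c0 in seq_len(C)) {
    look <- sig[, c0]
    channels[, , c0] <- matrix(look[labels + 1L], N, N)
  }
  structure(list(labels = labels, signature_table = sig, channels = channels),
            class = "spectral_slice")
}

#' @export
print.spectral_slice <- function(x, ...) {
  cat(sprintf("Spectral slice: %dx%d, %d channels, %d materials\n",
              nrow(x$labels), ncol(x$labels), dim(x$channels)[3],
              nrow(x$signature_table) - 1))
  invisible(x)
}

#' Interlaced angle schedule for dynamic acquisition
#'
#' Time step `s` (1-based) receives `angles_per_step` equally spaced angles
#' offset by `(s - 1) * delta / num_steps` where `delta = 2*pi /
#' angles_per_step`, so the union over one group of `num_steps` consecutive
#' steps tiles the full turn evenly: consecutive gaps in the union are all
#' `2*pi / (num_steps * angles_per_step)` when `jitter_sd = 0`.  Optional
#' Gaussian jitter (one rigid angular offset per step, emulating small
#' rotation-speed deviations) perturbs each step's grid as a whole.
#'
#' @param num_steps time steps per interlacing group.
#' @param angles_per_step angles within one step, spread over a full turn.
#' @param jitter_sd standard deviation (radians) of the per-step offset.
#' @param seed integer seed for the jitter.
#' @param offset global angular offset of the first step.
#' @return List of numeric angle vectors, one per step.
#' @export
interlaced_schedule <- function(num_steps, angles_per_step, jitter_sd = 0,
                                seed = 1, offset = 0) {
  if (num_steps < 1) stop_invalid("num_steps must be >= 1")
  if (angles_per_step < 1) stop_invalid("angles_per_step must be >= 1")
  delta <- 2 * pi / angles_per_step
  jit <- if (jitter_sd > 0)
    with_seed(seed, function() rnorm(num_steps, sd = jitter_sd))
  else rep(0, num_steps)
  lapply(seq_len(num_steps), function(s) {
    (offset + (s - 1) * delta / num_steps + jit[s] +
       (0:(angles_per_step - 1)) * delta) %% (2 * pi)
  })
}

#' Attenuation slice of a labeled volume
#'
#' @param volume a `labeled_volume`.
#' @param slice 1-based slice index.
#' @return `N x N` numeric matrix of attenuation values.
#' @export
volume_slice <- function(volume, slice) {
  if (slice < 1 || slice > dim(volume$labels)[1]) stop_invalid("slice out of range")
  matrix(volume$attenuation[slice, , ], dim(volume$labels)[2])
}
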