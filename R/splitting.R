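#' Split schemes for self-supervised training
#'
#' A `split_scheme` holds `J` disjoint *target* index sets that together
#' cover every measurement unit (angle or time step) exactly once, plus a
#' matching *input* set for each target.  Training pairs reconstruct the
#' input and target from the corresponding sets, which is what makes the
#' noise in the two reconstructions statistically independent.
#' All indices are 1-based.
#'
#' @param target_sets,input_sets lists of integer vectors, one per section.
#' @param unit_kind `"angle"` or `"time_step"`.
#' @param num_units total number of measurement units the scheme refers to.
#' @return Object of class `split_scheme` with fields `J`, `target_sets`,
#'   `input_sets`, `unit_kind`, `num_units`.
#' @seealso [angular_split()], [dynamic_split()], [multichannel_split()],
#'   [verify_conditions()]
#' @export
split_scheme <- function(target_sets, input_sets, unit_kind, num_units) {
  if (length(target_sets) != length(input_sets))
    stop_invalid("target_sets and input_sets must have equal length")
  if (length(target_sets) < 1) stop_invalid("need at least one section")
  unit_kind <- match.arg(unit_kind, c("angle", "time_step"))
  structure(list(J = length(target_sets),
                 target_sets = lapply(target_sets, function(x) sort(as.integer(x))),
                 input_sets = lapply(input_sets, function(x) sort(as.integer(x))),
                 unit_kind = unit_kind,
                 num_units = as.integer(num_units)),
            class = "split_scheme")
}

#' @export
print.split_scheme <- function(x, ...) {
  sizes_t <- vapply(x$target_sets, length, 1L)
  sizes_i <- vapply(x$input_sets, length, 1L)
  cat(sprintf("Split scheme (%s domain): J = %d over %d units; section sizes input %s : target %s\n",
              x$unit_kind, x$J, x$num_units,
              paste(unique(sizes_i), collapse = "/"),
              paste(unique(sizes_t), collapse = "/")))
  invisible(x)
}

#' Strided angular split
#'
#' Assigns angle `k` (1-based) to target section `j = ((k - 1) mod J) + 1`,
#' so adjacent angles always land in different target sections and each
#' section samples the angular range near-uniformly.  The input set of each
#' section is the complement of its target set.  When `num_angles` is not
#' divisible by `J` the leftover angles go to the lowest-index target
#' sections, so section sizes differ by at most one.
#'
#' With `J = 3`, each input section covers 2/3 of the angles and each target
#' 1/3; `J = 2` gives the symmetric 1:1 split.
#'
#' @param num_angles positive integer.
#' @param J number of target sections, `2 <= J <= num_angles` (with `J = 1`
#'   the input sections would be empty).
#' @return A [split_scheme] with `unit_kind = "angle"`.
#' @export
angular_split <- function(num_angles, J) {
  if (J < 2) stop_invalid("J must be >= 2 (J = 1 leaves no input section)")
  if (J > num_angles) stop_invalid("J must not exceed num_angles")
  all_idx <- seq_len(num_angles)
  targets <- lapply(seq_len(J), function(j) all_idx[(all_idx - 1) %% J == (j - 1)])
  inputs <- lapply(targets, function(t) setdiff(all_idx, t))
  split_scheme(targets, inputs, "angle", num_angles)
}

#' Round-robin time-step split for dynamic acquisitions
#'
#' For a group of `K` interlaced time steps, input section `j` is the single
#' time step `j` and its target section is all remaining `K - 1` steps.
#' Unlike the angular split, the target here is reconstructed from *more*
#' measurements than the input: combining the other time steps gives the
#' target denser angular sampling, so the trained network also learns to
#' suppress sparse-angle streak artifacts.
#'
#' @param num_time_steps_in_group integer `K >= 2`.
#' @return A [split_scheme] with `unit_kind = "time_step"` and `J = K`.
#' @export
dynamic_split <- function(num_time_steps_in_group) {
  K <- num_time_steps_in_group
  if (K < 2) stop_invalid("need at least 2 time steps in a group")
  # input j = {j}; target j = complement (note the inverted size relation)
  inputs <- lapply(seq_len(K), identity)
  targets <- lapply(seq_len(K), function(j) setdiff(seq_len(K), j))
  split_scheme(targets, inputs, "time_step", K)
}

#' Extract an angular section of a sinogram
#'
#' Returns the sub-sinogram of the selected rows with a derived geometry
#' containing exactly the selected angles (original angular values kept).
#'
#' @param sino a [sinogram].
#' @param index_set integer vector of 1-based row indices.
#' @return A [sinogram] with `length(index_set)` rows.
#' @export
extract_section <- function(sino, index_set) {
  if (!inherits(sino, "sinogram")) stop_invalid("sino must be a sinogram")
  idx <- as.integer(index_set)
  if (length(idx) == 0) stop_invalid("index set must be nonempty")
  if (any(idx < 1 | idx > nrow(sino$values)))
    stop_invalid("index out of range")
  g <- sino$geometry
  g2 <- projection_geometry(g$angles[idx], g$num_detector_pixels, g$image_size,
                            g$detector_pixel_size, g$rotation_center)
  sinogram(sino$values[idx, , drop = FALSE], g2,
           slice_index = sino$slice_index, time_index = sino$time_index,
           channel_index = sino$channel_index,
           provenance = if (!is.null(sino$provenance)) sino$provenance[idx])
}

#' Merge sinograms of interlaced time steps
#'
#' Concatenates sinograms whose angle lists are pairwise disjoint into one
#' sinogram sorted by angle, achieving the denser angular sampling that
#' interlaced acquisition is designed for.  The returned sinogram's
#' `provenance` records the source time step (position in the input list)
#' of every row.  Duplicate angles across inputs are an error, since rows
#' measured at the same angle in input and target sections would correlate
#' their noise.
#'
#' @param sinograms list of [sinogram]s with equal detector size.
#' @return A merged [sinogram].
#' @export
combine_time_steps <- function(sinograms) {
  if (!is.list(sinograms) || length(sinograms) == 0)
    stop_invalid("sinograms must be a nonempty list")
  if (length(sinograms) == 1) return(sinograms[[1]])
  ndet <- vapply(sinograms, function(s) ncol(s$values), 1L)
  if (length(unique(ndet)) != 1)
    stop_invalid("all sinograms must share the detector size")
  g1 <- sinograms[[1]]$geometry
  all_angles <- unlist(lapply(sinograms, function(s) s$geometry$angles))
  if (anyDuplicated(all_angles))
    stop_invalid("duplicate angles across time steps; interlaced sampling requires disjoint angle lists")
  vals <- do.call(rbind, lapply(sinograms, function(s) s$values))
  src <- rep(seq_along(sinograms),
             vapply(sinograms, function(s) nrow(s$values), 1L))
  ord <- order(all_angles)
  g <- projection_geometry(all_angles[ord], g1$num_detector_pixels,
                           g1$image_size, g1$detector_pixel_size,
                           g1$rotation_center)
  sinogram(vals[ord, , drop = FALSE], g, provenance = src[ord])
}

#' Angular split shared across channels
#'
#' Multi-channel (diffraction-tomography-like) data is split in the rotation
#' angle only: one angular [split_scheme] is applied identically to every
#' channel, so each training input and target carries the full channel
#' vector and channels are never separated between input and target.  That
#' preserves the per-voxel correspondence between channels (the
#' "diffractogram") which the network can exploit.
#'
#' @param sinograms list of per-channel [sinogram]s with identical geometry.
#' @param J number of target sections.
#' @return A [split_scheme] with `unit_kind = "angle"`.
#' @export
multichannel_split <- function(sinograms, J) {
  if (!is.list(sinograms) || length(sinograms) == 0)
    stop_invalid("sinograms must be a nonempty list of channels")
  g1 <- sinograms[[1]]$geometry
  same <- vapply(sinograms, function(s) {
    g <- s$geometry
    length(g$angles) == length(g1$angles) &&
      all(g$angles == g1$angles) &&
      g$num_detector_pixels == g1$num_detector_pixels
  }, TRUE)
  if (!all(same))
    stop_invalid("all channels must share an identical geometry")
  angular_split(length(g1$angles), J)
}

#' Check the two Noise2Inverse conditions on a split scheme
#'
#' Condition 1: every input set is disjoint from its target set, so the noise
#' in the two reconstructions of a pair is statistically independent (an
#' overlap would teach the network to reproduce noise).  Condition 2: every
#' measurement unit is used in the target sections equally often (and at
#' least once), so no part of the measurement is over- or under-weighted in
#' the targets.  For angular splits each unit appears in exactly one target
#' set; for the round-robin time-step split each unit appears in `K - 1`
#' target sets, which is equally often as well.
#'
#' @param scheme a [split_scheme].
#' @param num_units total number of measurement units (defaults to the
#'   scheme's own `num_units`).
#' @return A `condition_report` with logical fields `condition1_pass`,
#'   `condition2_pass` and a character vector `violations`.
#' @export
verify_conditions <- function(scheme, num_units = scheme$num_units) {
  if (!inherits(scheme, "split_scheme")) stop_invalid("scheme must be a split_scheme")
  viol <- character(0)
  c1 <- TRUE
  for (j in seq_len(scheme$J)) {
    ov <- intersect(scheme$target_sets[[j]], scheme$input_sets[[j]])
    if (length(ov) > 0) {
      c1 <- FALSE
      viol <- c(viol, sprintf(
        "condition 1: input and target of section %d overlap at unit(s) %s",
        j, paste(ov, collapse = ", ")))
    }
    if (length(scheme$target_sets[[j]]) == 0 ||
        length(scheme$input_sets[[j]]) == 0) {
      c1 <- FALSE
      viol <- c(viol, sprintf("section %d has an empty index set", j))
    }
  }
  counts <- tabulate(unlist(scheme$target_sets), nbins = num_units)
  c2 <- all(counts == counts[1]) && counts[1] >= 1L
  if (!c2) {
    missing <- which(counts == 0L)
    if (length(missing))
      viol <- c(viol, sprintf("condition 2: unit(s) %s appear in no target set",
                              paste(missing, collapse = ", ")))
    uneven <- which(counts != max(counts))
    uneven <- setdiff(uneven, missing)
    if (length(uneven))
      viol <- c(viol, sprintf(
        "condition 2: unit(s) %s are used as target less often than others",
        paste(uneven, collapse = ", ")))
  }
  structure(list(condition1_pass = c1, condition2_pass = c2,
                 violations = viol),
            class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("Noise2Inverse conditions: independence %s, equal coverage %s\n",
              if (x$condition1_pass) "PASS" else "FAIL",
              if (x$condition2_pass) "PASS" else "FAIL"))
  for (v in x$violations) cat("  - ", v, "\n", sep = "")
  invisible(x)
}

#' Serialize / deserialize a split scheme as JSON
#'
#' The JSON document records the unit kind, `J`, the total unit count and the
#' 1-based index sets, and is intended to be stored alongside trained models
#' for provenance.
#'
#' @param scheme a [split_scheme].
#' @param path file to write; with `NULL`, the JSON text is returned.
#' @return `scheme_to_json`: JSON string (invisibly when written to a file);
#'   `scheme_from_json`: the [split_scheme].
#' @export
scheme_to_json <- function(scheme, path = NULL) {
  txt <- jsonlite::toJSON(list(unit_kind = scheme$unit_kind, J = scheme$J,
                               num_units = scheme$num_units,
                               target_sets = scheme$target_sets,
                               input_sets = scheme$input_sets),
                          auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname scheme_to_json
#' @param json JSON text or a file path containing it.
#' @export
scheme_from_json <- function(json) {
  is_path <- length(json) == 1 && !grepl("[{\n]", json) && file.exists(json)
  x <- jsonlite::fromJSON(if (is_path) json else paste(json, collapse = "\n"),
                          simplifyVector = FALSE)
  split_scheme(lapply(x$target_sets, unlist), lapply(x$input_sets, unlist),
               x$unit_kind, x$num_units)
}
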