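#' Voxel-wise group-average activity map
#'
#' Arithmetic mean of normalized volumes across the fish of one condition.
#'
#' @param volumes list of normalized [brain_volume()] with equal dims.
#' @param group_label label for the map (defaults to the first volume's).
#' @return object of class `group_map`: `group_label`, `mean_volume`
#'   (numeric 3D array), `n_fish`.
#' @export
group_mean_map <- function(volumes, group_label = NULL) {
  if (!length(volumes)) stop("no volumes supplied", call. = FALSE)
  for (v in volumes) {
    stopifnot(inherits(v, "brain_volume"))
    if (!v$normalized) {
      stop("group maps require normalized volumes; run normalize_volume()",
           call. = FALSE)
    }
    if (!identical(v$dims, volumes[[1]]$dims)) {
      stop("volumes have mixed dimensions", call. = FALSE)
    }
  }
  acc <- Reduce(`+`, lapply(volumes, `[[`, "voxels"))
  structure(list(
    group_label = group_label %||% volumes[[1]]$group_label,
    mean_volume = acc / length(volumes),
    n_fish = length(volumes)
  ), class = "group_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalized difference map between a group and its baseline
#'
#' Voxel-wise `(group - baseline) / baseline`, e.g. `(+S - nsc) / nsc`:
#' positive values mean increased expression relative to the
#' no-social-cue baseline, negative decreased. Voxels where the baseline
#' mean falls below `eps` (normalized units) are unreliable ratios and are
#' set to `NA`.
#'
#' @param group,baseline [group_mean_map()] results with matching dims.
#' @param eps minimum baseline intensity for a defined ratio.
#' @return numeric 3D array (NA where undefined).
#' @export
difference_map <- function(group, baseline, eps = 0.1) {
  stopifnot(inherits(group, "group_map"), inherits(baseline, "group_map"))
  if (!identical(dim(group$mean_volume), dim(baseline$mean_volume))) {
    stop("group and baseline map dimensions differ", call. = FALSE)
  }
  out <- (group$mean_volume - baseline$mean_volume) / baseline$mean_volume
  out[baseline$mean_volume < eps] <- NA_real_
  out
}

#' Regional activation relative to a baseline group
#'
#' For each fish the region value is the mean normalized intensity inside
#' the mask; the activation percentage subtracts and then divides the
#' group's average by the baseline group's average:
#' `100 * (group mean - baseline mean) / baseline mean`. Per-fish values
#' are retained as the sampling units for group statistics; `per_fish_percent`
#' expresses each fish relative to the baseline-group mean.
#'
#' @param volumes list of normalized [brain_volume()] for the test group.
#' @param baseline_volumes list of normalized [brain_volume()] for the
#'   baseline group (typically the matched no-social-cue siblings, or the
#'   control no-social-cue group — name the choice via `baseline_label`).
#' @param mask a [region_mask()] with dims matching the volumes.
#' @param group_label,baseline_label labels recorded in the result.
#' @return object of class `activation_result`: `mask_name`, `group_label`,
#'   `baseline_label`, `percent_change`, `per_fish_values`,
#'   `per_fish_baseline`, `per_fish_percent`, `n`, `n_baseline`.
#' @export
region_activation <- function(volumes, baseline_volumes, mask,
                              group_label = NULL, baseline_label = NULL) {
  stopifnot(inherits(mask, "region_mask"))
  if (!length(volumes) || !length(baseline_volumes)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  mask_means <- function(vs) {
    vapply(vs, function(v) {
      stopifnot(inherits(v, "brain_volume"))
      if (!v$normalized) {
        stop("region activation requires normalized volumes", call. = FALSE)
      }
      if (!identical(v$dims, dim(mask$voxels))) {
        stop("mask '", mask$name, "' does not align with volume dims",
             call. = FALSE)
      }
      mean(v$voxels[mask$voxels])
    }, numeric(1))
  }
  g <- mask_means(volumes)
  b <- mask_means(baseline_volumes)
  bmean <- mean(b)
  structure(list(
    mask_name = mask$name,
    group_label = group_label %||% volumes[[1]]$group_label,
    baseline_label = baseline_label %||% baseline_volumes[[1]]$group_label,
    percent_change = 100 * (mean(g) - bmean) / bmean,
    per_fish_values = g,
    per_fish_baseline = b,
    per_fish_percent = 100 * (g - bmean) / bmean,
    n = length(g), n_baseline = length(b)
  ), class = "activation_result")
}

#' @export
print.activation_result <- function(x, ...) {
  cat(sprintf("%s: %s vs %s -> %+.1f%% (n = %d vs %d)\n",
              x$mask_name, x$group_label, x$baseline_label,
              x$percent_change, x$n, x$n_baseline))
  invisible(x)
}

#' Export a horizontal section of a map as PNG
#'
#' Writes one z-plane of a (difference or mean) map as a grayscale PNG for
#' quick visual inspection, linearly rescaled between the given limits.
#'
#' @param map numeric 3D array.
#' @param z 1-based plane index.
#' @param path PNG output path.
#' @param limits intensity limits mapped to black/white.
#' @return `path`, invisibly.
#' @export
export_section_png <- function(map, z, path,
                               limits = stats::quantile(map, c(0.01, 0.99),
                                                        na.rm = TRUE)) {
  stopifnot(length(dim(map)) == 3, z >= 1, z <= dim(map)[3])
  sl <- map[, , z]
  sl <- (sl - limits[1]) / (limits[2] - limits[1])
  sl[is.na(sl)] <- 0
  sl[sl < 0] <- 0; sl[sl > 1] <- 1
  png::writePNG(t(sl), path)
  invisible(path)
}

#' Write region masks as NIfTI volumes
#'
#' @param masks named list of [region_mask()].
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
write_masks_nifti <- function(masks, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(masks, function(m) {
    p <- file.path(dir, paste0(m$name, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(m$voxels),
                                             dim = dim(m$voxels))), p)
    p
  }, character(1))
  invisible(paths)
}

#' Read a region mask from a NIfTI volume
#'
#' @param path NIfTI file; any nonzero voxel is inside the region.
#' @param name region label (defaults to the file stem).
#' @return a [region_mask()].
#' @export
read_mask_nifti <- function(path, name = NULL) {
  arr <- as.array(RNifti::readNifti(path))
  name <- name %||% sub("\\.nii(\\.gz)?$", "", basename(path))
  region_mask(name, array(arr != 0, dim = dim(arr)))
}
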