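#' Synthetic brain envelope for phantom volumes
#'
#' An ellipsoidal "tissue" region centred in the voxel grid, scaled so the
#' tissue fills most of the volume with a thin dark non-tissue rim (corners
#' and edges), mimicking a dissected brain that nearly fills the imaging
#' field of view. The histogram-mode background estimate of
#' [normalize_volume()] relies on tissue being the modal intensity
#' population, while the dark rim anchors the bias (additive offset)
#' estimate.
#'
#' @param dims voxel counts `(x, y, z)`.
#' @param scale ellipsoid semi-axes as a fraction of the full grid extent
#'   per axis; the default leaves roughly 10-15% of voxels outside tissue.
#' @return logical array of `dims`, TRUE inside tissue.
#' @export
synthetic_brain_mask <- function(dims, scale = 0.62) {
  dims <- as.integer(dims)
  c0 <- (dims + 1) / 2
  ax <- scale * dims
  d2 <- outer(
    outer(((seq_len(dims[1]) - c0[1]) / ax[1])^2,
          ((seq_len(dims[2]) - c0[2]) / ax[2])^2, "+"),
    ((seq_len(dims[3]) - c0[3]) / ax[3])^2, "+"
  )
  d2 <= 1
}

#' Construct a named 3D region mask
#'
#' @param name region label (e.g. `"PTN"`, `"tectum"`, `"dHc"`).
#' @param voxels logical 3D array, TRUE inside the region.
#' @return object of class `region_mask`.
#' @export
region_mask <- function(name, voxels) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.logical(voxels) || length(dim(voxels)) != 3) {
    stop("voxels must be a logical 3D array", call. = FALSE)
  }
  if (!any(voxels)) stop("region mask '", name, "' is empty", call. = FALSE)
  structure(list(name = name, voxels = voxels), class = "region_mask")
}

#' Spherical region masks placed inside the synthetic brain
#'
#' Generates disjoint spherical masks at fixed fractional positions within
#' the voxel grid, all inside the synthetic tissue envelope, for planting
#' and recovering regional activations.
#'
#' @param dims voxel counts `(x, y, z)`.
#' @param names region labels; up to six supported positions.
#' @param radius_frac sphere radius as a fraction of the smallest dimension.
#' @return named list of [region_mask()] objects.
#' @export
synthetic_region_masks <- function(dims,
                                   names = c("PTN", "tectum"),
                                   radius_frac = 0.1) {
  dims <- as.integer(dims)
  centres <- list(
    c(0.35, 0.35, 0.5), c(0.65, 0.65, 0.5), c(0.35, 0.65, 0.4),
    c(0.65, 0.35, 0.6), c(0.5, 0.35, 0.35), c(0.5, 0.65, 0.65)
  )
  if (length(names) > length(centres)) {
    stop("at most ", length(centres), " synthetic regions supported",
         call. = FALSE)
  }
  r <- radius_frac * min(dims)
  masks <- lapply(seq_along(names), function(i) {
    ctr <- centres[[i]] * dims
    d2 <- outer(
      outer((seq_len(dims[1]) - ctr[1])^2,
            (seq_len(dims[2]) - ctr[2])^2, "+"),
      (seq_len(dims[3]) - ctr[3])^2, "+"
    )
    region_mask(names[i], d2 <= r^2)
  })
  stats::setNames(masks, names)
}

#' A registered brain volume with group metadata
#'
#' @param voxels numeric 3D array of fluorescence intensities.
#' @param fish_id identifier string.
#' @param group_label condition label (e.g. `"C_nsc"`, `"Fi_-S"`).
#' @param normalized has [normalize_volume()] been applied?
#' @param norm_info the `normalization_info` sidecar, if normalized.
#' @return object of class `brain_volume`.
#' @export
brain_volume <- function(voxels, fish_id = "fish", group_label = "unknown",
                         normalized = FALSE, norm_info = NULL) {
  if (!is.numeric(voxels) || length(dim(voxels)) != 3) {
    stop("voxels must be a numeric 3D array", call. = FALSE)
  }
  structure(list(voxels = voxels, dims = dim(voxels), fish_id = fish_id,
                 group_label = group_label, normalized = normalized,
                 norm_info = norm_info),
            class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  cat(sprintf("brain volume %s [%s]: %d x %d x %d voxels, %s\n",
              x$fish_id, x$group_label, x$dims[1], x$dims[2], x$dims[3],
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Simulate a cohort of registered brain volumes with planted activations
#'
#' Each fish volume is built as
#' `gain_i * (signal + noise) + offset_i`, where the signal is
#' `background_level` inside the tissue envelope (times the planted fold
#' change inside any affected mask) and zero outside, noise is Gaussian
#' (`background_sd` in tissue, `background_sd / 5` in the dark rim), and
#' `gain_i` / `offset_i` are per-fish session distortions drawn around
#' `session_gain` / `session_offset` (see [volume_sim_params()]).
#'
#' @param params a [volume_sim_params()] object.
#' @param masks named list of [region_mask()] with dims matching
#'   `params$dims`; must cover every name in `params$planted_effects`.
#' @param group_label label stamped on each generated volume.
#' @return list with `volumes` (list of [brain_volume()]) and `truth`
#'   (list: `true_region_folds` named vector over all masks, `gains`,
#'   `offsets` per fish, `brain` tissue mask).
#' @export
generate_volume_cohort <- function(params, masks = list(),
                                   group_label = "group") {
  stopifnot(inherits(params, "volume_sim_params"))
  p <- params
  for (m in masks) {
    stopifnot(inherits(m, "region_mask"))
    if (!identical(dim(m$voxels), as.integer(p$dims))) {
      stop("mask '", m$name, "' dims do not match volume dims", call. = FALSE)
    }
  }
  mask_names <- vapply(masks, function(m) m$name, character(1))
  missing <- setdiff(names(p$planted_effects), mask_names)
  if (length(missing)) {
    stop("planted_effects name masks not supplied: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  brain <- synthetic_brain_mask(p$dims)
  signal <- array(0, dim = p$dims)
  signal[brain] <- p$background_level
  folds <- stats::setNames(rep(1, length(masks)), mask_names)
  for (nm in names(p$planted_effects)) {
    folds[nm] <- p$planted_effects[[nm]]
    i <- match(nm, mask_names)
    signal[masks[[i]]$voxels] <- p$background_level * folds[nm]
  }
  dark_sd <- p$background_sd / 5
  n_vox <- prod(p$dims)

  with_seed(p$seed, {
    gains <- p$session_gain * stats::rlnorm(p$n_fish_per_group, 0,
                                            sqrt(log(1 + 0.1^2)))
    offsets <- stats::rnorm(p$n_fish_per_group, p$session_offset,
                            0.1 * abs(p$session_offset) + 1)
    volumes <- vector("list", p$n_fish_per_group)
    for (i in seq_len(p$n_fish_per_group)) {
      noise <- stats::rnorm(n_vox, 0, p$background_sd)
      noise[!brain] <- noise[!brain] * (dark_sd / p$background_sd)
      vox <- gains[i] * (signal + array(noise, dim = p$dims)) + offsets[i]
      volumes[[i]] <- brain_volume(
        vox, fish_id = sprintf("%s_%02d", group_label, i),
        group_label = group_label
      )
    }
    list(volumes = volumes,
         truth = list(true_region_folds = folds, gains = gains,
                      offsets = offsets, brain = brain))
  })
}

#' Read or write a brain volume as NIfTI
#'
#' Volumes travel as NIfTI (`.nii` / `.nii.gz`); the group metadata lives in
#' the filename or an external table, not in the image header.
#'
#' @param x a [brain_volume()] (write) or file path (read).
#' @param path output path for writing.
#' @param ... passed to [brain_volume()] when reading (fish_id, group_label).
#' @return `write_volume_nifti` returns `path` invisibly;
#'   `read_volume_nifti` returns a [brain_volume()].
#' @export
write_volume_nifti <- function(x, path) {
  stopifnot(inherits(x, "brain_volume"))
  RNifti::writeNifti(RNifti::asNifti(x$voxels), path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path, ...) {
  arr <- as.array(RNifti::readNifti(path))
  brain_volume(array(as.numeric(arr), dim = dim(arr)), ...)
}
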