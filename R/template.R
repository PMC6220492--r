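TPM_CLASSES <- c("air", "soft", "bone", "gm", "wm", "csf")

#' Construct a tissue-probability-map set
#'
#' A `suteac_tpms` holds one probability volume per tissue class in
#' \{air, soft, bone, GM, WM, CSF\}, all on one grid, with per-voxel class
#' sums equal to 1.
#'
#' @param maps named list of probability `suteac_volume`s covering
#'   `TPM_CLASSES`.
#' @param provenance free-text note on how the set was built.
#' @param check when `TRUE` (default) verify the unit-sum invariant.
#' @return object of class `suteac_tpms`.
#' @export
tpm_set <- function(maps, provenance = "", check = TRUE) {
  if (!all(TPM_CLASSES %in% names(maps)))
    stop("maps must cover classes: ", paste(TPM_CLASSES, collapse = ", "))
  maps <- maps[TPM_CLASSES]
  for (m in maps) {
    stopifnot(is_volume(m))
    stop_if_grid_mismatch(maps[[1]], m)
    if (min(m$data) < -1e-9 || max(m$data) > 1 + 1e-9)
      stop("class map outside [0, 1]")
  }
  if (check) {
    s <- Reduce(`+`, lapply(maps, function(m) m$data))
    if (max(abs(s - 1)) > 1e-6)
      stop("per-voxel class sums deviate from 1 by up to ",
           format(max(abs(s - 1))))
  }
  structure(list(maps = maps, provenance = provenance),
            class = "suteac_tpms")
}

is_tpms <- function(x) inherits(x, "suteac_tpms")

tpm_sum <- function(maps) Reduce(`+`, lapply(maps, function(m) m$data))

#' Build the UTE first-echo template
#'
#' The template is the voxel-wise arithmetic mean of the aligned first-echo
#' UTE images. Registration is pluggable: each image is brought onto the
#' grid of the first with its supplied affine (identity when the cohort is
#' already aligned); deformable registration is out of scope and handled
#' upstream.
#'
#' @param images list of >= 2 intensity `suteac_volume`s.
#' @param transforms optional list of 4x4 affines (template world to
#'   subject world), one per image; `NULL` means identity for all.
#' @return the template `suteac_volume`.
#' @export
build_template <- function(images, transforms = NULL) {
  if (length(images) < 2L) stop("need at least 2 images")
  if (!is.null(transforms) && length(transforms) != length(images))
    stop("transforms and images counts differ")
  ref <- images[[1]]
  acc <- array(0, dim(ref$data))
  for (i in seq_along(images)) {
    tf <- if (is.null(transforms)) diag(4) else transforms[[i]]
    acc <- acc + resample_to(images[[i]], ref, tf, "trilinear")$data
  }
  with_data(ref, acc / length(images))
}

#' Average aligned probability masks into a temporary TPM
#'
#' Masks are resampled (trilinear) onto the first mask's grid and averaged
#' voxel-wise; binary expert masks therefore become soft probabilities where
#' subjects disagree.
#'
#' @param masks list of probability `suteac_volume`s with values in \[0,1\].
#' @param transforms optional list of 4x4 affines, as in
#'   [build_template()].
#' @return probability `suteac_volume`.
#' @export
average_masks <- function(masks, transforms = NULL) {
  if (length(masks) < 1L) stop("need at least one mask")
  for (m in masks)
    if (min(m$data) < -1e-9 || max(m$data) > 1 + 1e-9)
      stop("mask values outside [0, 1]")
  out <- if (length(masks) == 1L) {
    tf <- if (is.null(transforms)) diag(4) else transforms[[1]]
    resample_to(masks[[1]], masks[[1]], tf, "trilinear")
  } else {
    build_template(masks, transforms)
  }
  dat <- pmin(pmax(out$data, 0), 1)
  volume(array(dat, dim(out$data)), out$spacing, out$origin, "probability")
}

#' Normalize raw class maps to unit per-voxel sums
#'
#' Each voxel's class values are divided by their sum. Voxels with zero
#' total mass are assigned to air (probability 1): outside-head background
#' is air.
#'
#' @param raw named list of non-negative `suteac_volume`s covering all six
#'   classes.
#' @return a `suteac_tpms`.
#' @export
normalize_tpms <- function(raw) {
  if (!all(TPM_CLASSES %in% names(raw)))
    stop("raw must cover classes: ", paste(TPM_CLASSES, collapse = ", "))
  raw <- raw[TPM_CLASSES]
  for (m in raw) if (min(m$data) < 0) stop("negative class values")
  s <- tpm_sum(raw)
  zero <- s <= 0
  s[zero] <- 1
  maps <- lapply(raw, function(m) {
    d <- m$data / s
    d[zero] <- 0
    volume(array(d, dim(d)), m$spacing, m$origin, "probability")
  })
  maps$air$data[zero] <- 1
  tpm_set(maps, provenance = "normalize_tpms")
}

#' Renormalize class maps keeping protected classes fixed
#'
#' Air and bone probabilities come from the expert-mask averaging stage and
#' are trusted as-is; the remaining classes are rescaled multiplicatively by
#' (1 - sum of protected) / (sum of non-protected) so the per-voxel total is
#' exactly 1. The same rule fills the deficit when the total is below 1.
#' Where the non-protected sum is zero, any remaining deficit is assigned to
#' soft tissue inside the protected-coverage gap.
#'
#' @param tpms named list of probability `suteac_volume`s (or a
#'   `suteac_tpms`).
#' @param protected character vector of protected class names.
#' @return a `suteac_tpms`.
#' @export
renormalize_protected <- function(tpms, protected = c("air", "bone")) {
  maps <- if (is_tpms(tpms)) tpms$maps else tpms
  if (!all(TPM_CLASSES %in% names(maps)))
    stop("need all classes: ", paste(TPM_CLASSES, collapse = ", "))
  maps <- maps[TPM_CLASSES]
  other <- setdiff(TPM_CLASSES, protected)
  ps <- tpm_sum(maps[protected])
  if (max(ps) > 1 + 1e-9) {
    if (max(ps) > 1 + 0.05)
      stop("protected class sum exceeds 1 by more than 5%; refusing to clip")
    warning("protected class sums slightly above 1 were clipped")
    excess <- pmax(ps - 1, 0) / ps
    for (p in protected) maps[[p]]$data <- maps[[p]]$data * (1 - excess)
    ps <- pmin(ps, 1)
  }
  os <- tpm_sum(maps[other])
  factor <- ifelse(os > 0, (1 - ps) / os, 0)
  out <- maps
  for (cl in other) {
    d <- maps[[cl]]$data * factor
    out[[cl]] <- volume(array(pmin(pmax(d, 0), 1), dim(d)),
                        maps[[cl]]$spacing, maps[[cl]]$origin, "probability")
  }
  # degenerate voxels: nothing to rescale, put the deficit into soft tissue
  deficit <- os <= 0 & ps < 1 - 1e-12
  if (any(deficit))
    out$soft$data[deficit] <- out$soft$data[deficit] + (1 - ps[deficit])
  tpm_set(out, provenance = "renormalize_protected")
}

#' Build six-class TPMs from a cohort of phantoms
#'
#' The cohort template workflow on synthetic data: one-hot expert
#' masks are taken from each subject's ground-truth labels and averaged per
#' class across the (pre-aligned) cohort; the averaged air and bone maps
#' are kept as-is (they play the role of trusted expert maps) while the
#' remaining classes are rescaled around them to restore unit per-voxel
#' sums. An optional smoothing of the averaged masks emulates
#' inter-subject registration blur.
#'
#' @param phantoms list of `suteac_phantom` bundles on one grid.
#' @param smooth_fwhm_mm optional FWHM (mm) applied to each averaged class
#'   map before normalization; 0 disables.
#' @return a `suteac_tpms`.
#' @export
cohort_tpms <- function(phantoms, smooth_fwhm_mm = 0) {
  stopifnot(length(phantoms) >= 2L)
  raw <- list()
  for (cl in TPM_CLASSES) {
    masks <- lapply(phantoms, function(ph) {
      m <- class_mask(ph$labels, cl)
      volume(array(as.double(m), dim(m)), ph$labels$spacing,
             ph$labels$origin, "probability")
    })
    avg <- average_masks(masks)
    if (smooth_fwhm_mm > 0) avg <- gaussian_smooth(avg, smooth_fwhm_mm)
    raw[[cl]] <- avg
  }
  renormalize_protected(raw)
}

#' Write a TPM set to disk
#' @param tpms a `suteac_tpms`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_tpms <- function(tpms, dir) {
  stopifnot(is_tpms(tpms))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cl in names(tpms$maps))
    write_volume(tpms$maps[[cl]], file.path(dir, paste0("tpm_", cl, ".nii.gz")))
  jsonlite::write_json(list(classes = names(tpms$maps),
                            provenance = tpms$provenance),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a TPM set written by [write_tpms()]
#' @param dir directory containing `tpm_<class>.nii.gz` files.
#' @return a `suteac_tpms`.
#' @export
read_tpms <- function(dir) {
  maps <- lapply(TPM_CLASSES, function(cl)
    read_volume(file.path(dir, paste0("tpm_", cl, ".nii.gz")),
                units = "probability"))
  names(maps) <- TPM_CLASSES
  tpm_set(maps, provenance = paste("read from", dir))
}
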