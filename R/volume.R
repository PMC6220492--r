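#' @importFrom stats dnorm lm coef median pnorm rnorm rpois runif sd var
#' @importFrom utils combn
NULL

VOLUME_UNITS <- c("intensity", "HU", "mu_cm_inv", "r2star_per_ms",
                  "probability", "activity")

#' Construct a 3-D volume
#'
#' A `suteac_volume` is the container used throughout the package for every
#' scalar field: UTE echoes, R2* maps, tissue probabilities, CT volumes in
#' Hounsfield units, 511 keV attenuation maps in cm^-1, and activity maps.
#' Voxel indexing is 0-based; world coordinates (mm) of voxel `i` are
#' `origin + i * spacing`, with axes in a fixed RAS-like order.
#'
#' @param data numeric 3-D array.
#' @param spacing voxel size in mm per axis (length 3, strictly positive).
#' @param origin world position (mm) of voxel (0,0,0).
#' @param units one of `"intensity"`, `"HU"`, `"mu_cm_inv"`,
#'   `"r2star_per_ms"`, `"probability"`, `"activity"`. Probability volumes
#'   must lie in \[0, 1\]; attenuation (`mu_cm_inv`) volumes must be
#'   non-negative.
#' @return object of class `suteac_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   units = "intensity") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("origin must have length 3")
  units <- match.arg(units, VOLUME_UNITS)
  storage.mode(data) <- "double"
  if (units == "probability" &&
      (min(data, na.rm = TRUE) < -1e-9 || max(data, na.rm = TRUE) > 1 + 1e-9))
    stop("probability volume has values outside [0, 1]")
  if (units == "mu_cm_inv" && min(data, na.rm = TRUE) < -1e-12)
    stop("mu_cm_inv volume has negative values")
  structure(list(data = data, spacing = spacing, origin = origin,
                 units = units),
            class = "suteac_volume")
}

is_volume <- function(x) inherits(x, "suteac_volume")

#' @export
print.suteac_volume <- function(x, ...) {
  cat(sprintf("suteac_volume: %s, spacing %s mm, units '%s'\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"), x$units))
  cat(sprintf("  range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.suteac_volume <- function(x) dim(x$data)

#' Replace the data of a volume, keeping its grid
#' @param v a `suteac_volume` providing the grid.
#' @param data replacement array (same dimensions).
#' @param units optional new units tag.
#' @return a `suteac_volume`.
#' @export
with_data <- function(v, data, units = v$units) {
  stopifnot(is_volume(v))
  if (!all(dim(data) == dim(v$data))) stop("dimension mismatch")
  volume(data, v$spacing, v$origin, units)
}

same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$data) == dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("volumes are not on the same grid")
}

#' Read a 3-D NIfTI-1 volume
#'
#' Reads a single-volume NIfTI file. Spacing is taken from the header
#' `pixdim`; the units tag is taken from a JSON sidecar written by
#' [write_volume()] when present, otherwise from `units`.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param units fallback units hint when no sidecar exists.
#' @return a `suteac_volume`.
#' @export
read_volume <- function(path, units = "intensity") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    dim(img) <- d[1:3]
  } else if (length(d) != 3L) {
    stop("expected a single 3-D volume, got dimensions ",
         paste(d, collapse = "x"))
  }
  dat <- as.array(img)
  if (any(!is.finite(dat))) stop("non-finite voxel values in ", path)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- c(0, 0, 0)
  side <- sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$units)) units <- meta$units
    if (!is.null(meta$origin)) origin <- as.numeric(meta$origin)
  }
  volume(array(as.double(dat), dim = dim(dat)), spacing, origin, units)
}

sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".json")
}

#' Write a volume as NIfTI-1
#'
#' Stores the data as float32 and writes a small JSON sidecar holding the
#' units tag and origin, so [read_volume()] recovers them.
#'
#' @param v a `suteac_volume` (must be finite everywhere).
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(is_volume(v))
  if (any(!is.finite(v$data))) stop("refusing to write non-finite voxels")
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path, datatype = "float")
  jsonlite::write_json(list(units = v$units, origin = v$origin),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Resample a volume onto a reference grid
#'
#' Pull-back resampling: for every voxel of `reference`, its world
#' coordinate is mapped through `transform` (a 4x4 affine taking reference
#' world coordinates to input world coordinates) and the input volume is
#' interpolated there. Out-of-field positions are filled with 0. Nearest
#' interpolation is intended for label-derived volumes.
#'
#' @param v input `suteac_volume`.
#' @param reference `suteac_volume` defining the output grid.
#' @param transform 4x4 affine (mm), default identity.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return a `suteac_volume` on the reference grid.
#' @export
resample_to <- function(v, reference, transform = diag(4),
                        interpolation = c("trilinear", "nearest")) {
  stopifnot(is_volume(v), is_volume(reference))
  interpolation <- match.arg(interpolation)
  transform <- as.matrix(transform)
  if (!all(dim(transform) == c(4, 4))) stop("transform must be 4x4")
  if (abs(det(transform)) < 1e-12) stop("singular transform")
  identity_tf <- all(abs(transform - diag(4)) < 1e-12)
  if (identity_tf && same_grid(v, reference))
    return(volume(v$data, v$spacing, v$origin, v$units))

  dref <- dim(reference$data)
  ii <- (seq_len(dref[1]) - 1)
  jj <- (seq_len(dref[2]) - 1)
  kk <- (seq_len(dref[3]) - 1)
  wx <- reference$origin[1] + ii * reference$spacing[1]
  wy <- reference$origin[2] + jj * reference$spacing[2]
  wz <- reference$origin[3] + kk * reference$spacing[3]
  n <- prod(dref)
  X <- rep(wx, times = dref[2] * dref[3])
  Y <- rep(rep(wy, each = dref[1]), times = dref[3])
  Z <- rep(wz, each = dref[1] * dref[2])
  if (!identity_tf) {
    P <- transform %*% rbind(X, Y, Z, rep(1, n))
    X <- P[1, ]; Y <- P[2, ]; Z <- P[3, ]
  }
  # continuous 0-based voxel coordinates in the input grid
  cx <- (X - v$origin[1]) / v$spacing[1]
  cy <- (Y - v$origin[2]) / v$spacing[2]
  cz <- (Z - v$origin[3]) / v$spacing[3]
  vals <- if (interpolation == "nearest") {
    sample_nearest3(v$data, cx, cy, cz)
  } else {
    sample_trilinear3(v$data, cx, cy, cz)
  }
  volume(array(vals, dref), reference$spacing, reference$origin, v$units)
}

sample_nearest3 <- function(arr, cx, cy, cz) {
  d <- dim(arr)
  ix <- as.integer(round(cx)); iy <- as.integer(round(cy))
  iz <- as.integer(round(cz))
  ok <- ix >= 0L & ix < d[1] & iy >= 0L & iy < d[2] & iz >= 0L & iz < d[3]
  out <- numeric(length(cx))
  idx <- ix[ok] + d[1] * (iy[ok] + d[2] * iz[ok]) + 1L
  out[ok] <- arr[idx]
  out
}

sample_trilinear3 <- function(arr, cx, cy, cz) {
  d <- dim(arr)
  x0 <- floor(cx); y0 <- floor(cy); z0 <- floor(cz)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  out <- numeric(length(cx))
  # corners outside the grid contribute 0 (air background)
  at <- function(ix, iy, iz) {
    ok <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3]
    v <- numeric(length(ix))
    idx <- ix[ok] + d[1] * (iy[ok] + d[2] * iz[ok]) + 1
    v[ok] <- arr[idx]
    v
  }
  out <- at(x0,     y0,     z0)     * (1 - fx) * (1 - fy) * (1 - fz) +
         at(x0 + 1, y0,     z0)     * fx       * (1 - fy) * (1 - fz) +
         at(x0,     y0 + 1, z0)     * (1 - fx) * fy       * (1 - fz) +
         at(x0 + 1, y0 + 1, z0)     * fx       * fy       * (1 - fz) +
         at(x0,     y0,     z0 + 1) * (1 - fx) * (1 - fy) * fz +
         at(x0 + 1, y0,     z0 + 1) * fx       * (1 - fy) * fz +
         at(x0,     y0 + 1, z0 + 1) * (1 - fx) * fy       * fz +
         at(x0 + 1, y0 + 1, z0 + 1) * fx       * fy       * fz
  out
}

gaussian_kernel_1d <- function(fwhm_mm, spacing_mm) {
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing_mm
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

shift_pad0 <- function(arr, axis, by) {
  # shift array along one axis, filling with zeros
  if (by == 0L) return(arr)
  d <- dim(arr)
  out <- array(0, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  sx <- ix; sx[[axis]] <- src
  dx <- ix; dx[[axis]] <- dst
  out[dx[[1]], dx[[2]], dx[[3]]] <- arr[sx[[1]], sx[[2]], sx[[3]]]
  out
}

#' Separable Gaussian smoothing
#'
#' Convolves with a normalized Gaussian kernel per axis. `fwhm_mm` is a
#' full-width-at-half-maximum in mm (the neuroimaging convention), converted
#' to voxels through the volume spacing; sigma = fwhm / (2 sqrt(2 ln 2)).
#' Boundaries use constant-0 padding: the physical background of an
#' attenuation map is air (mu = 0), so mass leaving the field of view decays
#' toward zero rather than being reflected.
#'
#' @param v a `suteac_volume`.
#' @param fwhm_mm kernel FWHM in mm (> 0).
#' @return the smoothed `suteac_volume`.
#' @export
gaussian_smooth <- function(v, fwhm_mm) {
  stopifnot(is_volume(v))
  if (!is.finite(fwhm_mm) || fwhm_mm <= 0) stop("fwhm_mm must be positive")
  out <- smooth_axes(v$data, fwhm_mm, v$spacing, axes = 1:3)
  if (v$units == "probability") out[out < 0] <- 0
  volume(out, v$spacing, v$origin, v$units)
}

smooth_axes <- function(arr, fwhm_mm, spacing, axes) {
  out <- arr
  for (axis in axes) {
    k <- gaussian_kernel_1d(fwhm_mm, spacing[axis])
    r <- (length(k) - 1L) %/% 2L
    acc <- array(0, dim(out))
    for (j in seq_along(k)) {
      acc <- acc + k[j] * shift_pad0(out, axis, j - r - 1L)
    }
    out <- acc
  }
  out
}

smooth_2d_slice <- function(mat, fwhm_mm, spacing_mm) {
  a <- array(mat, c(dim(mat), 1L))
  smooth_axes(a, fwhm_mm, c(spacing_mm, spacing_mm, 1), axes = 1:2)[, , 1L]
}
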