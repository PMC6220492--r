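#' Parallel-beam scan geometry
#'
#' 2-D slice-wise parallel-beam geometry for the desk-scale emission
#' simulator: `n_angles` views over 180 degrees and `n_radial` radial bins
#' of width `bin_width_mm`. Rays are sampled along their length at
#' `bin_width_mm / oversample` steps. No time-of-flight, point-spread or
#' scatter modelling: the simulator isolates attenuation-induced bias.
#'
#' @param n_angles number of projection angles over 180 degrees (>= 8).
#' @param n_radial number of radial bins.
#' @param bin_width_mm radial bin width in mm (> 0).
#' @param oversample ray-length sampling density relative to the bin width.
#' @return object of class `suteac_geometry`.
#' @export
scan_geometry <- function(n_angles = 180L, n_radial = 128L,
                          bin_width_mm = 2, oversample = 2L) {
  if (n_angles < 8L) stop("need at least 8 angles")
  if (bin_width_mm <= 0) stop("bin width must be positive")
  structure(list(n_angles = as.integer(n_angles),
                 n_radial = as.integer(n_radial),
                 bin_width_mm = bin_width_mm,
                 oversample = as.integer(oversample)),
            class = "suteac_geometry")
}

geometry_angles <- function(g) (seq_len(g$n_angles) - 1) * pi / g$n_angles

new_sinogram <- function(values, geom, slices, grid, units) {
  structure(list(values = values, geom = geom, slices = slices,
                 grid = grid, units = units),
            class = "suteac_sinogram")
}

#' @export
print.suteac_sinogram <- function(x, ...) {
  cat(sprintf("suteac_sinogram (%s): %d bins x %d angles x %d slices\n",
              x$units, dim(x$values)[1], dim(x$values)[2],
              dim(x$values)[3]))
  invisible(x)
}

# bilinear sampling stencil for one projection angle: linear indices into
# the padded slice vector (1 = outside, contributes 0) and weights, for the
# n_radial x n_t grid of sample points
angle_stencil <- function(g, nx, ny, spacing, theta) {
  r <- (seq_len(g$n_radial) - (g$n_radial + 1) / 2) * g$bin_width_mm
  nt <- g$oversample * g$n_radial + 1L
  dt <- g$bin_width_mm / g$oversample
  t <- (seq_len(nt) - (nt + 1) / 2) * dt
  ct <- cos(theta); st <- sin(theta)
  px <- outer(r * ct, -t * st, `+`)
  py <- outer(r * st, t * ct, `+`)
  cx <- px / spacing[1] + (nx - 1) / 2
  cy <- py / spacing[2] + (ny - 1) / 2
  x0 <- floor(cx); y0 <- floor(cy)
  fx <- cx - x0; fy <- cy - y0
  corner <- function(ix, iy) {
    ok <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
    as.vector(ifelse(ok, ix + nx * iy + 2, 1))  # padded vector, slot 1 is 0
  }
  fx <- as.vector(fx); fy <- as.vector(fy)
  list(
    idx = cbind(corner(x0, y0), corner(x0 + 1, y0),
                corner(x0, y0 + 1), corner(x0 + 1, y0 + 1)),
    w = cbind((1 - fx) * (1 - fy), fx * (1 - fy),
              (1 - fx) * fy, fx * fy),
    n_radial = g$n_radial, nt = nt, dl_cm = dt / 10
  )
}

fwd_angle <- function(slice_pad, stc) {
  vals <- if (!is.null(stc$S)) {
    as.vector(Matrix::crossprod(stc$S, slice_pad))
  } else {
    slice_pad[stc$idx[, 1]] * stc$w[, 1] +
      slice_pad[stc$idx[, 2]] * stc$w[, 2] +
      slice_pad[stc$idx[, 3]] * stc$w[, 3] +
      slice_pad[stc$idx[, 4]] * stc$w[, 4]
  }
  .rowSums(vals, stc$n_radial, stc$nt) * stc$dl_cm
}

back_angle <- function(proj, stc, npix) {
  b <- rep(proj * stc$dl_cm, times = stc$nt)
  if (!is.null(stc$S)) return(as.vector(stc$S %*% b)[-1L])
  s <- rowsum(as.vector(stc$w * b), as.vector(stc$idx))
  acc <- numeric(npix + 1L)
  acc[as.integer(rownames(s))] <- s
  acc[-1L]
}

# attach a sparse scatter operator so repeated backprojections are cheap;
# the same matrix drives the forward gather, so projector and
# backprojector are an exact adjoint pair by construction
with_scatter <- function(stc, npix) {
  npts <- nrow(stc$idx)
  stc$S <- Matrix::sparseMatrix(i = as.vector(stc$idx),
                                j = rep(seq_len(npts), 4L),
                                x = as.vector(stc$w),
                                dims = c(npix + 1L, npts))
  stc
}

.stencil_cache <- new.env(parent = emptyenv())

cached_stencils <- function(g, nx, ny, spacing) {
  key <- paste(g$n_angles, g$n_radial, g$bin_width_mm, g$oversample,
               nx, ny, paste(signif(spacing, 10), collapse = ","),
               sep = "|")
  hit <- .stencil_cache[[key]]
  if (!is.null(hit)) return(hit)
  npix <- nx * ny
  st <- lapply(geometry_angles(g), function(th)
    with_scatter(angle_stencil(g, nx, ny, spacing, th), npix))
  # keep the cache to one geometry to bound memory
  rm(list = ls(.stencil_cache), envir = .stencil_cache)
  assign(key, st, envir = .stencil_cache)
  st
}

#' Forward-project a volume into a sinogram
#'
#' Length-weighted parallel-beam line integrals, slice by slice. Distances
#' are converted from mm to cm, so attenuation volumes in cm^-1 integrate
#' directly to dimensionless optical depths. The operation is linear in the
#' input.
#'
#' @param v a `suteac_volume`.
#' @param g a [scan_geometry()].
#' @param slices z-slice indices to project; `NULL` means all.
#' @return a line-integral `suteac_sinogram`.
#' @export
forward_project <- function(v, g, slices = NULL) {
  stopifnot(is_volume(v), inherits(g, "suteac_geometry"))
  d <- dim(v$data)
  if (is.null(slices)) slices <- seq_len(d[3])
  out <- array(0, c(g$n_radial, g$n_angles, length(slices)))
  stencils <- cached_stencils(g, d[1], d[2], v$spacing)
  for (si in seq_along(slices)) {
    slice_pad <- c(0, v$data[, , slices[si]])
    for (ai in seq_len(g$n_angles))
      out[, ai, si] <- fwd_angle(slice_pad, stencils[[ai]])
  }
  new_sinogram(out, g, slices,
               list(nx = d[1], ny = d[2], nz = d[3], spacing = v$spacing,
                    origin = v$origin),
               units = "line-integral")
}

#' Attenuation correction factors from an attenuation map
#'
#' ACF(l) = exp(-integral of mu along the line of response l), the
#' fraction of annihilation photon pairs surviving along each line.
#'
#' @param mu attenuation `suteac_volume` (cm^-1, non-negative).
#' @param g a [scan_geometry()].
#' @param slices z-slice indices; `NULL` means all.
#' @return factor `suteac_sinogram` with values in (0, 1\].
#' @export
attenuation_factors <- function(mu, g, slices = NULL) {
  if (min(mu$data) < 0) stop("negative attenuation coefficients")
  li <- forward_project(mu, g, slices)
  new_sinogram(exp(-li$values), g, li$slices, li$grid, units = "factor")
}

#' Simulate attenuated emission data
#'
#' The noiseless sinogram is the attenuated forward projection of the
#' activity, ACF(mu_true) * P(activity), rescaled so its total equals
#' `total_counts`, then Poisson-sampled.
#'
#' @param activity activity `suteac_volume`.
#' @param mu_true true attenuation `suteac_volume` (cm^-1).
#' @param g a [scan_geometry()].
#' @param total_counts expected total counts over the whole sinogram.
#' @param seed integer seed for the Poisson draw.
#' @param poisson set `FALSE` to return the noiseless mean sinogram.
#' @param slices z-slice indices; `NULL` means all.
#' @return counts `suteac_sinogram`.
#' @export
simulate_emission <- function(activity, mu_true, g, total_counts = 5e6,
                              seed = 1L, poisson = TRUE, slices = NULL) {
  if (total_counts <= 0) stop("total_counts must be positive")
  stop_if_grid_mismatch(activity, mu_true)
  if (max(activity$data) <= 0) stop("zero activity")
  proj <- forward_project(activity, g, slices)
  acf <- attenuation_factors(mu_true, g, slices)
  mean_sino <- proj$values * acf$values
  mean_sino <- mean_sino * (total_counts / sum(mean_sino))
  vals <- if (poisson) {
    set.seed(as.integer(seed))
    array(rpois(length(mean_sino), mean_sino), dim(mean_sino))
  } else {
    mean_sino
  }
  new_sinogram(vals, g, proj$slices, proj$grid, units = "counts")
}

largest_divisor_at_most <- function(n, k) {
  for (d in seq(min(k, n), 1L)) if (n %% d == 0L) return(d)
  1L
}

#' OSEM reconstruction of attenuated emission data
#'
#' Ordered-subset EM with the attenuated system model
#' `Ptilde = diag(acf) P`, where `P` is the parallel-beam projector and its
#' exact adjoint is the backprojector. Per subset:
#' `lambda <- lambda / s * Ptilde^T (y / (Ptilde lambda))` with
#' `s = Ptilde^T 1` over the subset's angles. With one subset this is MLEM.
#' A Gaussian post-filter is applied in-plane to the final image. If
#' `subsets` does not divide the number of angles it is reduced to the
#' largest divisor, with a warning.
#'
#' @param y counts `suteac_sinogram`.
#' @param acf factor `suteac_sinogram` on the same geometry.
#' @param iterations number of full OSEM iterations (default 3).
#' @param subsets requested number of angular subsets (default 21).
#' @param postfilter_fwhm_mm Gaussian post-filter FWHM in mm (default 5);
#'   0 disables.
#' @param initial optional initial image value inside the field of view.
#' @return reconstructed activity `suteac_volume` (zero outside the
#'   reconstructed slices).
#' @export
reconstruct <- function(y, acf, iterations = 3L, subsets = 21L,
                        postfilter_fwhm_mm = 5.0, initial = 1) {
  stopifnot(inherits(y, "suteac_sinogram"), inherits(acf, "suteac_sinogram"))
  g <- y$geom
  if (!identical(dim(y$values), dim(acf$values)))
    stop("counts and factor sinograms do not match")
  ns <- largest_divisor_at_most(g$n_angles, subsets)
  if (ns != subsets)
    warning(sprintf("subsets reduced from %d to %d to divide %d angles",
                    subsets, ns, g$n_angles))
  nx <- y$grid$nx; ny <- y$grid$ny
  spacing <- y$grid$spacing
  npix <- nx * ny
  # interleaved subsets, standard OSEM ordering
  subset_angles <- lapply(seq_len(ns), function(s)
    seq(s, g$n_angles, by = ns))

  # field-of-view support circle
  cxy <- expand.grid(x = seq_len(nx) - (nx + 1) / 2,
                     y = seq_len(ny) - (ny + 1) / 2)
  fov_r <- g$n_radial / 2 * g$bin_width_mm
  fov <- (cxy$x * spacing[1])^2 + (cxy$y * spacing[2])^2 < fov_r^2

  stencils <- cached_stencils(g, nx, ny, spacing)

  out <- array(0, c(nx, ny, max(y$grid$nz, max(y$slices))))
  for (si in seq_along(y$slices)) {
    # subset sensitivities s = Ptilde^T 1 are fixed across iterations
    sens_sub <- lapply(subset_angles, function(sa) {
      sens <- numeric(npix)
      for (ai in sa)
        sens <- sens + back_angle(acf$values[, ai, si], stencils[[ai]], npix)
      sens
    })
    lambda <- as.numeric(fov) * initial
    for (it in seq_len(iterations)) {
      for (s in seq_len(ns)) {
        sa <- subset_angles[[s]]
        num <- numeric(npix)
        for (ai in sa) {
          stc <- stencils[[ai]]
          fp <- fwd_angle(c(0, lambda), stc) * acf$values[, ai, si]
          yy <- y$values[, ai, si]
          ratio <- ifelse(fp > 0, yy / fp, 0)
          num <- num + back_angle(ratio * acf$values[, ai, si], stc, npix)
        }
        sens <- sens_sub[[s]]
        upd <- ifelse(sens > 0, num / sens, 0)
        lambda <- lambda * upd
      }
    }
    img <- matrix(lambda, nx, ny)
    if (postfilter_fwhm_mm > 0)
      img <- smooth_2d_slice(img, postfilter_fwhm_mm, spacing[1])
    out[, , y$slices[si]] <- img
  }
  volume(out, spacing, y$grid$origin, "activity")
}
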