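#' Tissue attenuation coefficients at 511 keV
#'
#' Defaults follow the segmentation-based head AC convention: air 0, soft
#' tissue 0.100, bone 0.151 cm^-1; the brain compartments used by the
#' multi-compartment variant are GM 0.099, WM 0.099, CSF 0.096 cm^-1.
#'
#' @param air,soft,bone,gm,wm,csf coefficients in cm^-1 (all >= 0; air
#'   must be 0).
#' @return named numeric vector of class `suteac_ac_coefficients`.
#' @export
ac_coefficients <- function(air = 0, soft = 0.100, bone = 0.151,
                            gm = 0.099, wm = 0.099, csf = 0.096) {
  x <- c(air = air, soft = soft, bone = bone, gm = gm, wm = wm, csf = csf)
  if (any(x < 0)) stop("attenuation coefficients must be >= 0")
  if (x[["air"]] != 0) stop("air must have a zero attenuation coefficient")
  structure(x, class = "suteac_ac_coefficients")
}

#' Fit a cubic calibration mapping R2* to bone attenuation
#'
#' Least-squares third-order polynomial mapping R2* (1/ms) to linear
#' attenuation coefficients (cm^-1), for continuous subject-specific bone
#' values. The fit must be non-decreasing over the sampled R2* range
#' (checked on a dense grid); physically, denser bone has both shorter T2*
#' and higher attenuation.
#'
#' @param r2s_samples R2* sample values (1/ms), at least 8, spanning the
#'   bone range.
#' @param mu_samples matching attenuation samples (cm^-1).
#' @param degree polynomial degree (fixed at 3).
#' @param clamp attenuation clamp range applied when the calibration is
#'   evaluated; default keeps bone between the soft-tissue value and a
#'   plausible cortical-bone ceiling.
#' @return object of class `suteac_calibration` with fields `coefficients`
#'   (c0..c3), `range` (valid R2* range) and `clamp`.
#' @export
fit_r2star_calibration <- function(r2s_samples, mu_samples, degree = 3L,
                                   clamp = c(0.100, 0.20)) {
  if (degree != 3L) stop("calibration degree is fixed at 3")
  r2s_samples <- as.numeric(r2s_samples)
  mu_samples <- as.numeric(mu_samples)
  if (length(r2s_samples) != length(mu_samples))
    stop("sample vectors differ in length")
  if (length(r2s_samples) < 8L) stop("need at least 8 sample pairs")
  X <- cbind(1, r2s_samples, r2s_samples^2, r2s_samples^3)
  if (qr(X)$rank < 4L) stop("rank-deficient design: samples do not span a cubic")
  cf <- qr.solve(X, mu_samples)
  rng <- range(r2s_samples)
  grid <- seq(rng[1], rng[2], length.out = 512)
  vals <- cf[1] + cf[2] * grid + cf[3] * grid^2 + cf[4] * grid^3
  if (any(diff(vals) < -1e-10))
    stop("fitted calibration is not non-decreasing over the sample range")
  structure(list(coefficients = unname(cf), range = rng, clamp = clamp),
            class = "suteac_calibration")
}

#' Evaluate an R2* calibration
#' @param calib a `suteac_calibration`.
#' @param r2s numeric vector or array of R2* values (1/ms).
#' @return attenuation values (cm^-1), clamped to `calib$clamp`.
#' @export
eval_calibration <- function(calib, r2s) {
  stopifnot(inherits(calib, "suteac_calibration"))
  cf <- calib$coefficients
  mu <- cf[1] + cf[2] * r2s + cf[3] * r2s^2 + cf[4] * r2s^3
  pmin(pmax(mu, calib$clamp[1]), calib$clamp[2])
}

#' Default R2*-to-attenuation calibration
#'
#' A documented stand-in for scanner-specific bone calibration: a monotone
#' cubic fitted through anchor pairs running from (0 /ms, 0.100 cm^-1) at
#' the soft-tissue end to (2.0 /ms, 0.151 cm^-1) at cortical bone. Results
#' obtained with it are calibration-dependent and should be re-fitted
#' against CT where available.
#' @return a `suteac_calibration`.
#' @export
default_r2star_calibration <- function() {
  r <- seq(0, 2.4, length.out = 13)
  mu <- 0.100 + 0.051 * (r / 2.0)
  fit_r2star_calibration(r, mu)
}

#' Assemble a segmentation-based attenuation map
#'
#' Thresholds the posteriors (air 0.1 / bone 0.2), assigns air 0 and soft
#' tissue its fixed coefficient, assigns bone either the fixed coefficient
#' (`mode = "fix"`) or the clamped cubic calibration of the voxel R2*
#' (`mode = "cont"`), smooths the assembled map with a Gaussian kernel, and
#' finally pastes fallback values (e.g. a vendor map) outside the template
#' coverage, unsmoothed across the seam.
#'
#' @param seg a `suteac_segmentation`.
#' @param coeffs an [ac_coefficients()].
#' @param mode `"fix"` or `"cont"`.
#' @param r2s R2* `suteac_volume`; required for `mode = "cont"`.
#' @param calib a `suteac_calibration`; required for `mode = "cont"`.
#' @param smoothing_fwhm_mm Gaussian FWHM in mm (default 2); 0 disables.
#' @param air_threshold,bone_threshold posterior thresholds for
#'   [hard_label()].
#' @param coverage_mask optional `suteac_volume`; voxels where it is 0 are
#'   outside template coverage.
#' @param fallback optional attenuation `suteac_volume` pasted outside
#'   coverage.
#' @return attenuation `suteac_volume` (cm^-1).
#' @export
make_ac_map <- function(seg, coeffs = ac_coefficients(),
                        mode = c("fix", "cont"), r2s = NULL, calib = NULL,
                        smoothing_fwhm_mm = 2.0,
                        air_threshold = 0.1, bone_threshold = 0.2,
                        coverage_mask = NULL, fallback = NULL) {
  mode <- match.arg(mode)
  labels <- hard_label(seg, air_threshold, bone_threshold)
  ref <- seg$posteriors$air
  tc <- tissue_codes()
  mu <- array(coeffs[["soft"]], dim(labels$labels))
  mu[labels$labels == tc[["air"]]] <- 0
  bone_sel <- labels$labels == tc[["bone"]]
  if (mode == "fix") {
    mu[bone_sel] <- coeffs[["bone"]]
  } else {
    if (is.null(r2s) || is.null(calib))
      stop("mode 'cont' requires r2s and calib")
    stop_if_grid_mismatch(ref, r2s)
    mu[bone_sel] <- eval_calibration(calib, r2s$data[bone_sel])
  }
  out <- volume(mu, ref$spacing, ref$origin, "mu_cm_inv")
  if (smoothing_fwhm_mm > 0) out <- gaussian_smooth(out, smoothing_fwhm_mm)
  if (!is.null(fallback)) {
    if (is.null(coverage_mask))
      stop("fallback requires a coverage_mask")
    stop_if_grid_mismatch(ref, fallback)
    stop_if_grid_mismatch(ref, coverage_mask)
    outside <- coverage_mask$data <= 0
    out$data[outside] <- fallback$data[outside]
  }
  out
}

#' Multi-compartment attenuation map from six-class labels
#'
#' Assigns a distinct coefficient to each of bone, soft non-brain tissue,
#' GM, WM, CSF and air, then applies the standard 2-mm Gaussian smoothing.
#'
#' @param labels6 `suteac_labels` over the six head classes.
#' @param coeffs an [ac_coefficients()].
#' @param smoothing_fwhm_mm Gaussian FWHM in mm (default 2); 0 disables.
#' @return attenuation `suteac_volume` (cm^-1).
#' @export
make_mc_ac_map <- function(labels6, coeffs = ac_coefficients(),
                           smoothing_fwhm_mm = 2.0) {
  stopifnot(is_labels(labels6))
  tc <- tissue_codes()
  if (!all(labels6$table %in% tc))
    stop("unknown label codes in labels6")
  lut <- numeric(max(tc) + 1L)
  for (nm in names(labels6$table)) {
    if (!nm %in% names(coeffs)) stop("unknown label: ", nm)
    lut[labels6$table[[nm]] + 1L] <- coeffs[[nm]]
  }
  mu <- array(lut[labels6$labels + 1L], dim(labels6$labels))
  out <- volume(mu, labels6$spacing, labels6$origin, "mu_cm_inv")
  if (smoothing_fwhm_mm > 0) out <- gaussian_smooth(out, smoothing_fwhm_mm)
  out
}

#' Reference attenuation map from ground-truth labels
#'
#' The piecewise-constant reference map: bone 0.151, soft tissue 0.100, air
#' 0 cm^-1 (defaults), with brain classes folded into soft tissue. No
#' smoothing is applied.
#'
#' @param truth `suteac_labels` (three- or six-class).
#' @param coeffs an [ac_coefficients()].
#' @return attenuation `suteac_volume` (cm^-1).
#' @export
reference_ac_from_labels <- function(truth, coeffs = ac_coefficients()) {
  stopifnot(is_labels(truth))
  three <- if (all(names(truth$table) %in% c("air", "soft", "bone")))
    truth else fold_to_three(truth)
  tc <- tissue_codes()
  lut <- numeric(max(tc) + 1L)
  lut[tc[["soft"]] + 1L] <- coeffs[["soft"]]
  lut[tc[["bone"]] + 1L] <- coeffs[["bone"]]
  mu <- array(lut[three$labels + 1L], dim(three$labels))
  volume(mu, truth$spacing, truth$origin, "mu_cm_inv")
}

#' Convert a CT volume (HU) to 511 keV attenuation coefficients
#'
#' Standard bilinear model anchored at air (-1000 HU, 0 cm^-1) and water
#' (0 HU, 0.096 cm^-1): below the breakpoint mu = 0.096 (HU + 1000) / 1000;
#' above it the slope changes to `slope_high` to account for the different
#' energy scaling of bone mineral. Negative results are clamped to 0.
#'
#' @param ct `suteac_volume` in HU.
#' @param breakpoint_hu HU value where the slope changes (default 0).
#' @param slope_high slope above the breakpoint in cm^-1 per HU (default
#'   6.4e-5).
#' @return attenuation `suteac_volume` (cm^-1).
#' @export
hu_to_mu <- function(ct, breakpoint_hu = 0, slope_high = 6.4e-5) {
  stopifnot(is_volume(ct))
  hu <- ct$data
  mu_break <- 0.096 * (breakpoint_hu + 1000) / 1000
  mu <- ifelse(hu <= breakpoint_hu,
               0.096 * (hu + 1000) / 1000,
               mu_break + slope_high * (hu - breakpoint_hu))
  mu[mu < 0] <- 0
  volume(array(mu, dim(hu)), ct$spacing, ct$origin, "mu_cm_inv")
}

#' Classify a CT volume into air / soft / bone
#'
#' Voxels strictly below -500 HU are air, strictly above 300 HU are bone,
#' the rest soft tissue.
#'
#' @param ct `suteac_volume` in HU.
#' @param air_hu,bone_hu thresholds (defaults -500 and 300 HU).
#' @return `suteac_labels` over \{air, soft, bone\}.
#' @export
classify_ct <- function(ct, air_hu = -500, bone_hu = 300) {
  stopifnot(is_volume(ct))
  tc <- tissue_codes()
  lab <- array(tc[["soft"]], dim(ct$data))
  lab[ct$data < air_hu] <- tc[["air"]]
  lab[ct$data > bone_hu] <- tc[["bone"]]
  label_mask(lab, tc[c("air", "soft", "bone")], ct$spacing, ct$origin)
}

#' Classify a vendor UTE attenuation map into air / soft / bone
#'
#' The vendor map encodes its segmentation in the coefficients themselves:
#' voxels equal to the bone coefficient (0.151 cm^-1) are bone, voxels
#' equal to 0 are air, everything else is soft tissue. Equality is tested
#' within `eps`.
#'
#' @param ac attenuation `suteac_volume` (cm^-1).
#' @param bone_value bone coefficient (default 0.151).
#' @param eps equality tolerance (default 1e-6).
#' @return `suteac_labels` over \{air, soft, bone\}.
#' @export
classify_vendor_ute <- function(ac, bone_value = 0.151, eps = 1e-6) {
  stopifnot(is_volume(ac))
  tc <- tissue_codes()
  lab <- array(tc[["soft"]], dim(ac$data))
  lab[abs(ac$data) < eps] <- tc[["air"]]
  lab[abs(ac$data - bone_value) < eps] <- tc[["bone"]]
  label_mask(lab, tc[c("air", "soft", "bone")], ac$spacing, ac$origin)
}
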