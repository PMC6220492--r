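#' Default tissue parameter table for the head phantom
#'
#' Per-class proton density (arbitrary units), effective transverse
#' relaxation rate R2* (1/ms), true 511 keV linear attenuation coefficient
#' (cm^-1) and FDG-like activity (arbitrary units). R2* values are chosen so
#' that the echo-time pair 0.07 / 2.46 ms strongly suppresses bone signal in
#' the second echo while leaving soft tissue almost unchanged — the contrast
#' mechanism UTE-based bone segmentation relies on. Activity follows a
#' GM:WM:CSF ratio of 4:1:0.1, a typical grey-to-white FDG uptake contrast.
#'
#' @return data.frame with columns `class`, `pd`, `r2star`, `mu_true`,
#'   `activity`.
#' @export
tissue_params_default <- function() {
  data.frame(
    class    = c("air", "soft", "bone", "gm", "wm", "csf"),
    pd       = c(0,     100,    60,     95,   90,   105),
    r2star   = c(0,     0.02,   2.0,    0.025, 0.025, 0.005),
    mu_true  = c(0,     0.100,  0.151,  0.099, 0.099, 0.096),
    activity = c(0,     0,      0,      4,    1,    0.1),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic dual-echo UTE head phantom
#'
#' Describes the nested head geometry (scalp soft tissue, closed skull
#' shell, CSF rim, GM rind, WM core, ventricular CSF, facial air cavities),
#' the tissue parameter table, acquisition echo times, and degradation
#' settings. All geometry is in mm; ellipsoids are given as semi-axes
#' relative to the grid centre.
#'
#' @param n grid size in voxels (scalar, isotropic grid).
#' @param spacing_mm isotropic voxel size in mm.
#' @param head_semi outer head ellipsoid semi-axes (mm).
#' @param skull_outer_semi outer skull ellipsoid semi-axes (mm).
#' @param skull_thickness_mm skull shell thickness (mm).
#' @param skull_center_offset skull/brain complex centre offset from the
#'   grid centre (mm); axis 2 is anterior, axis 3 superior.
#' @param brain_semi brain ellipsoid semi-axes (mm).
#' @param wm_semi white-matter core semi-axes (mm).
#' @param ventricle_semi lateral-ventricle ellipsoid semi-axes (mm).
#' @param ventricle_offsets list of centre offsets (mm) for the ventricles.
#' @param sinus_centers list of centre offsets (mm) for facial air cavities.
#' @param sinus_radius_mm air cavity radius (mm).
#' @param tissue_params tissue parameter table, see
#'   [tissue_params_default()].
#' @param te1_ms,te2_ms UTE echo times (ms), defaults 0.07 and 2.46.
#' @param noise_sigma noise level as a fraction of the mean soft-tissue
#'   echo-1 intensity; default 0.03 (3 percent, a typical magnitude-MR
#'   noise floor).
#' @param noise_model `"rician"` (magnitude MR) or `"gaussian"`.
#' @param bias_amplitude peak relative amplitude of the multiplicative
#'   polynomial bias field (0 disables it).
#' @param bias_order polynomial order of the bias field.
#' @param seed integer seed controlling noise and bias reproducibly.
#' @return object of class `suteac_phantom_spec`.
#' @export
phantom_spec <- function(n = 96L,
                         spacing_mm = 2,
                         head_semi = c(70, 85, 78),
                         skull_outer_semi = c(58, 68, 62),
                         skull_thickness_mm = 6,
                         skull_center_offset = c(0, 0, 8),
                         brain_semi = c(46, 56, 50),
                         wm_semi = c(32, 40, 34),
                         ventricle_semi = c(7, 18, 9),
                         ventricle_offsets = list(c(-11, -2, 8),
                                                  c(11, -2, 8)),
                         sinus_centers = list(c(-9, 52, -34),
                                              c(9, 52, -34)),
                         sinus_radius_mm = 11,
                         tissue_params = tissue_params_default(),
                         te1_ms = 0.07, te2_ms = 2.46,
                         noise_sigma = 0.03,
                         noise_model = c("rician", "gaussian"),
                         bias_amplitude = 0, bias_order = 2L,
                         seed = 17L) {
  noise_model <- match.arg(noise_model)
  if (skull_thickness_mm <= 0)
    stop("skull thickness must be positive")
  inner <- skull_outer_semi - skull_thickness_mm
  if (any(inner <= brain_semi))
    stop("geometrically impossible: brain does not fit inside the skull")
  if (any(skull_outer_semi >= head_semi))
    stop("geometrically impossible: skull not inside the head")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (te2_ms <= te1_ms || te1_ms <= 0) stop("need te2_ms > te1_ms > 0")
  stopifnot(all(c("class", "pd", "r2star", "mu_true", "activity") %in%
                  names(tissue_params)))
  structure(list(n = as.integer(n), spacing_mm = spacing_mm,
                 head_semi = head_semi,
                 skull_outer_semi = skull_outer_semi,
                 skull_thickness_mm = skull_thickness_mm,
                 skull_center_offset = skull_center_offset,
                 brain_semi = brain_semi, wm_semi = wm_semi,
                 ventricle_semi = ventricle_semi,
                 ventricle_offsets = ventricle_offsets,
                 sinus_centers = sinus_centers,
                 sinus_radius_mm = sinus_radius_mm,
                 tissue_params = tissue_params,
                 te1_ms = te1_ms, te2_ms = te2_ms,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 bias_amplitude = bias_amplitude,
                 bias_order = as.integer(bias_order),
                 seed = as.integer(seed)),
            class = "suteac_phantom_spec")
}

#' Simulate a UTE echo image from proton density and R2*
#'
#' Mono-exponential magnitude signal model: I(x) = PD(x) exp(-TE R2*(x)),
#' with TE in ms and R2* in 1/ms.
#'
#' @param pd_map proton-density `suteac_volume` (non-negative).
#' @param r2star_map R2* `suteac_volume` (1/ms).
#' @param te_ms echo time in ms (> 0).
#' @return intensity `suteac_volume`.
#' @export
simulate_ute_echo <- function(pd_map, r2star_map, te_ms) {
  stopifnot(is_volume(pd_map), is_volume(r2star_map))
  stop_if_grid_mismatch(pd_map, r2star_map)
  if (te_ms <= 0) stop("te_ms must be positive")
  if (min(pd_map$data) < 0) stop("negative proton density")
  with_data(pd_map, pd_map$data * exp(-te_ms * r2star_map$data),
            units = "intensity")
}

#' Add noise to a volume
#'
#' @param v a `suteac_volume`.
#' @param sigma noise standard deviation (absolute units); 0 returns the
#'   input unchanged.
#' @param model `"gaussian"` adds N(0, sigma); `"rician"` replaces each
#'   value m by sqrt((m + n1)^2 + n2^2) with independent N(0, sigma) draws,
#'   the magnitude-image noise model.
#' @param seed integer seed.
#' @return a `suteac_volume`.
#' @export
add_noise <- function(v, sigma, model = c("gaussian", "rician"), seed = 1L) {
  stopifnot(is_volume(v))
  model <- match.arg(model)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(v)
  set.seed(as.integer(seed))
  n <- length(v$data)
  out <- if (model == "gaussian") {
    v$data + array(rnorm(n, 0, sigma), dim(v$data))
  } else {
    n1 <- array(rnorm(n, 0, sigma), dim(v$data))
    n2 <- array(rnorm(n, 0, sigma), dim(v$data))
    sqrt((v$data + n1)^2 + n2^2)
  }
  with_data(v, out)
}

inside_ellipsoid <- function(coords, center, semi) {
  ((coords$x - center[1]) / semi[1])^2 +
    ((coords$y - center[2]) / semi[2])^2 +
    ((coords$z - center[3]) / semi[3])^2 <= 1
}

phantom_coords <- function(n, spacing) {
  w <- (seq_len(n) - 1) * spacing
  ctr <- mean(range(w))
  d3 <- c(n, n, n)
  list(x = array(rep(w - ctr, times = n * n), d3),
       y = array(rep(rep(w - ctr, each = n), times = n), d3),
       z = array(rep(w - ctr, each = n * n), d3))
}

#' Generate a synthetic dual-echo UTE head phantom with ground truth
#'
#' Builds the nested tissue label geometry, derives proton-density, R2*,
#' true attenuation and activity maps from the tissue table, simulates both
#' UTE echoes with the mono-exponential model, then applies the optional
#' polynomial bias field and noise. The ground-truth label mask plays the
#' role of a manual expert segmentation when evaluating the method.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `suteac_phantom`: a list with `labels`,
#'   `pd_map`, `r2star_map`, `mu_true`, `activity_map`, `region_atlas`,
#'   `head_mask`, `echo1`, `echo2`, `te1_ms`, `te2_ms`, `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "suteac_phantom_spec"))
  n <- spec$n; sp <- spec$spacing_mm
  co <- phantom_coords(n, sp)
  tc <- tissue_codes()
  ctr0 <- c(0, 0, 0)
  skc <- spec$skull_center_offset
  inner_semi <- spec$skull_outer_semi - spec$skull_thickness_mm

  lab <- array(tc[["air"]], c(n, n, n))
  head <- inside_ellipsoid(co, ctr0, spec$head_semi)
  lab[head] <- tc[["soft"]]
  sk_out <- inside_ellipsoid(co, skc, spec$skull_outer_semi)
  sk_in <- inside_ellipsoid(co, skc, inner_semi)
  lab[sk_out & !sk_in] <- tc[["bone"]]
  lab[sk_in] <- tc[["csf"]]                       # subarachnoid rim
  brain <- inside_ellipsoid(co, skc, spec$brain_semi)
  lab[brain] <- tc[["gm"]]
  wm <- inside_ellipsoid(co, skc, spec$wm_semi)
  lab[wm] <- tc[["wm"]]
  vent <- array(FALSE, c(n, n, n))
  for (off in spec$ventricle_offsets)
    vent <- vent | inside_ellipsoid(co, off, spec$ventricle_semi)
  lab[vent] <- tc[["csf"]]
  for (cen in spec$sinus_centers) {
    sphere <- inside_ellipsoid(co, cen, rep(spec$sinus_radius_mm, 3))
    lab[sphere & !sk_out] <- tc[["air"]]          # cavities in facial soft tissue
  }

  labels <- label_mask(lab, tc, spacing = sp)

  # parameter maps via table lookup
  tp <- spec$tissue_params
  lut <- function(col) {
    m <- numeric(max(tc) + 1L)
    m[tc[tp$class] + 1L] <- tp[[col]]
    array(m[lab + 1L], dim(lab))
  }
  pd_map <- volume(lut("pd"), sp, units = "intensity")
  r2star_map <- volume(lut("r2star"), sp, units = "r2star_per_ms")
  mu_true <- volume(lut("mu_true"), sp, units = "mu_cm_inv")
  activity_map <- volume(lut("activity"), sp, units = "activity")
  head_mask <- volume(array(as.double(head), dim(lab)), sp,
                      units = "probability")

  region_atlas <- make_region_atlas(lab, co, spec)

  e1 <- simulate_ute_echo(pd_map, r2star_map, spec$te1_ms)
  e2 <- simulate_ute_echo(pd_map, r2star_map, spec$te2_ms)
  if (spec$bias_amplitude > 0) {
    bf <- bias_field(co, spec$head_semi, spec$bias_amplitude,
                     spec$bias_order, spec$seed)
    e1 <- with_data(e1, e1$data * bf)
    e2 <- with_data(e2, e2$data * bf)
  }
  if (spec$noise_sigma > 0) {
    soft_mean <- mean(e1$data[lab == tc[["soft"]]])
    sig <- spec$noise_sigma * soft_mean
    e1 <- add_noise(e1, sig, spec$noise_model, seed = spec$seed)
    e2 <- add_noise(e2, sig, spec$noise_model, seed = spec$seed + 1L)
  }

  structure(list(labels = labels, pd_map = pd_map, r2star_map = r2star_map,
                 mu_true = mu_true, activity_map = activity_map,
                 region_atlas = region_atlas, head_mask = head_mask,
                 echo1 = e1, echo2 = e2,
                 te1_ms = spec$te1_ms, te2_ms = spec$te2_ms, spec = spec),
            class = "suteac_phantom")
}

# five disjoint named brain regions: a cerebellum-like inferior-posterior
# band, a periventricular shell, frontal and occipital cortex, deep WM
make_region_atlas <- function(lab, co, spec) {
  tc <- tissue_codes()
  n <- spec$n
  brainish <- lab %in% tc[c("gm", "wm", "csf")] &
    inside_ellipsoid(co, spec$skull_center_offset, spec$brain_semi)
  skc <- spec$skull_center_offset
  zr <- co$z - skc[3]; yr <- co$y - skc[2]
  vent <- array(FALSE, dim(lab))
  perivent <- array(FALSE, dim(lab))
  for (off in spec$ventricle_offsets) {
    vent <- vent | inside_ellipsoid(co, off, spec$ventricle_semi)
    perivent <- perivent |
      inside_ellipsoid(co, off, spec$ventricle_semi + 8)
  }
  perivent <- perivent & !vent & brainish
  cereb <- brainish & zr < -28 & yr < -5 & !perivent
  frontal <- brainish & lab == tc[["gm"]] & yr > 25 & !perivent & !cereb
  occip <- brainish & lab == tc[["gm"]] & yr < -25 & !perivent & !cereb
  deepwm <- brainish & lab == tc[["wm"]] & !perivent & !cereb
  atlas <- array(0L, dim(lab))
  atlas[cereb] <- 1L
  atlas[perivent] <- 2L
  atlas[frontal] <- 3L
  atlas[occip] <- 4L
  atlas[deepwm] <- 5L
  label_mask(atlas,
             c(none = 0L, cerebellum = 1L, periventricular = 2L,
               frontal = 3L, occipital = 4L, deep_wm = 5L),
             spacing = spec$spacing_mm)
}

bias_field <- function(co, head_semi, amplitude, order, seed) {
  set.seed(seed + 1000L)
  u <- co$x / head_semi[1]; v <- co$y / head_semi[2]
  w <- co$z / head_semi[3]
  f <- array(0, dim(u))
  for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j)) {
    if (i + j + k == 0) next
    f <- f + rnorm(1) * u^i * v^j * w^k
  }
  rng <- max(abs(f))
  if (rng > 0) f <- f / rng
  1 + amplitude * f
}

#' Write a phantom bundle to disk
#'
#' Writes every volume of the bundle as NIfTI plus a JSON manifest with the
#' seed and echo times.
#' @param ph a `suteac_phantom`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  stopifnot(inherits(ph, "suteac_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("pd_map", "r2star_map", "mu_true", "activity_map",
               "head_mask", "echo1", "echo2"))
    write_volume(ph[[nm]], file.path(dir, paste0(nm, ".nii.gz")))
  write_volume(labels_as_volume(ph$labels),
               file.path(dir, "labels.nii.gz"))
  write_volume(labels_as_volume(ph$region_atlas),
               file.path(dir, "region_atlas.nii.gz"))
  jsonlite::write_json(
    list(seed = ph$spec$seed, te1_ms = ph$te1_ms, te2_ms = ph$te2_ms,
         n = ph$spec$n, spacing_mm = ph$spec$spacing_mm,
         label_table = as.list(ph$labels$table),
         atlas_table = as.list(ph$region_atlas$table)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
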