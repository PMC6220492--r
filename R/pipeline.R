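#' Configuration for the end-to-end phantom workflow
#'
#' Collects every tunable of the pipeline: phantom geometry scale, cohort
#' used for template construction, segmentation thresholds, attenuation
#' coefficients, smoothing kernels (2 mm for AC maps, 5 mm PET
#' post-filter), OSEM settings (3 iterations, 21 subsets requested), count
#' level, and seeds. The `fast` profile reconstructs 3 brain slices of a
#' 96^3 phantom; `full` reconstructs 9 slices.
#'
#' @param profile `"fast"` or `"full"`.
#' @param seed master seed; every stage derives its own seed from it.
#' @param phantom_n phantom grid size (voxels per axis).
#' @param phantom_spacing_mm voxel size in mm.
#' @param noise_sigma phantom noise fraction (default 0.03).
#' @param cohort_size number of jittered subjects for template building.
#' @param cohort_jitter geometry jitter: relative semi-axis scale range.
#' @param tpm_smooth_fwhm_mm smoothing of averaged cohort masks (mm).
#' @param air_threshold,bone_threshold posterior thresholds (0.1 / 0.2).
#' @param coeffs an [ac_coefficients()].
#' @param ac_fwhm_mm AC-map smoothing FWHM (mm).
#' @param pet_fwhm_mm PET post-filter FWHM (mm).
#' @param osem_iterations,osem_subsets OSEM settings.
#' @param n_angles,n_radial,bin_width_mm scan geometry.
#' @param total_counts expected counts over the reconstructed slice set.
#' @param n_slices number of reconstructed brain slices (overrides the
#'   profile default when given).
#' @return object of class `suteac_run_config`.
#' @export
run_config <- function(profile = c("fast", "full"),
                       seed = 17L,
                       phantom_n = 96L, phantom_spacing_mm = 2,
                       noise_sigma = 0.03,
                       cohort_size = 5L, cohort_jitter = 0.03,
                       tpm_smooth_fwhm_mm = 2,
                       air_threshold = 0.1, bone_threshold = 0.2,
                       coeffs = ac_coefficients(),
                       ac_fwhm_mm = 2, pet_fwhm_mm = 5,
                       osem_iterations = 3L, osem_subsets = 21L,
                       n_angles = 180L, n_radial = 128L, bin_width_mm = 2,
                       total_counts = 5e6, n_slices = NULL) {
  profile <- match.arg(profile)
  if (is.null(n_slices)) n_slices <- if (profile == "fast") 3L else 9L
  if (air_threshold <= 0 || air_threshold >= 1 ||
      bone_threshold <= 0 || bone_threshold >= 1)
    stop("thresholds must lie in (0, 1)")
  structure(list(profile = profile, seed = as.integer(seed),
                 phantom_n = as.integer(phantom_n),
                 phantom_spacing_mm = phantom_spacing_mm,
                 noise_sigma = noise_sigma,
                 cohort_size = as.integer(cohort_size),
                 cohort_jitter = cohort_jitter,
                 tpm_smooth_fwhm_mm = tpm_smooth_fwhm_mm,
                 air_threshold = air_threshold,
                 bone_threshold = bone_threshold,
                 coeffs = coeffs, ac_fwhm_mm = ac_fwhm_mm,
                 pet_fwhm_mm = pet_fwhm_mm,
                 osem_iterations = as.integer(osem_iterations),
                 osem_subsets = as.integer(osem_subsets),
                 n_angles = as.integer(n_angles),
                 n_radial = as.integer(n_radial),
                 bin_width_mm = bin_width_mm,
                 total_counts = total_counts,
                 n_slices = as.integer(n_slices)),
            class = "suteac_run_config")
}

#' Generate the jittered template-building cohort
#'
#' Cohort subjects share the test subject's tissue parameters but have
#' their head geometry scaled and shifted by small seeded perturbations,
#' emulating inter-subject anatomical variability after affine alignment.
#'
#' @param config a [run_config()].
#' @return list of `suteac_phantom` bundles.
#' @export
pipeline_cohort <- function(config) {
  set.seed(config$seed + 100L)
  lapply(seq_len(config$cohort_size), function(i) {
    sc <- 1 + runif(3, -config$cohort_jitter, config$cohort_jitter)
    shift <- runif(3, -2, 2)
    base <- phantom_spec(n = config$phantom_n,
                         spacing_mm = config$phantom_spacing_mm,
                         noise_sigma = config$noise_sigma,
                         seed = config$seed + i)
    spec <- phantom_spec(
      n = config$phantom_n, spacing_mm = config$phantom_spacing_mm,
      head_semi = base$head_semi * sc,
      skull_outer_semi = base$skull_outer_semi * sc,
      skull_thickness_mm = base$skull_thickness_mm * sc[1],
      skull_center_offset = base$skull_center_offset + shift,
      brain_semi = base$brain_semi * sc,
      wm_semi = base$wm_semi * sc,
      ventricle_semi = base$ventricle_semi,
      ventricle_offsets = lapply(base$ventricle_offsets,
                                 function(o) o + shift),
      sinus_centers = lapply(base$sinus_centers, function(o) o + shift),
      sinus_radius_mm = base$sinus_radius_mm * sc[1],
      noise_sigma = config$noise_sigma,
      seed = config$seed + i)
    generate_phantom(spec)
  })
}

brain_mask_of <- function(ph) {
  tc <- tissue_codes()
  ph$labels$labels %in% tc[c("gm", "wm", "csf")]
}

pick_brain_slices <- function(ph, n_slices) {
  bm <- brain_mask_of(ph)
  dim(bm) <- dim(ph$labels$labels)
  per_slice <- apply(bm, 3, sum)
  ctr <- which.max(per_slice)
  span <- max(1L, round(6 / ph$labels$spacing[3]))  # ~12 mm apart
  offs <- (seq_len(n_slices) - (n_slices + 1) / 2) * span
  sl <- sort(unique(pmax(1L, pmin(dim(bm)[3], ctr + round(offs)))))
  sl
}

# restrict a region atlas to the reconstructed slices, dropping regions
# that end up empty there
subset_atlas <- function(atlas, slices) {
  lab <- array(0L, dim(atlas$labels))
  lab[, , slices] <- atlas$labels[, , slices]
  keep <- vapply(atlas$table, function(code)
    code == 0L || any(lab == code), logical(1))
  label_mask(lab, atlas$table[keep], atlas$spacing, atlas$origin)
}

bone_free_ac <- function(truth, coeffs) {
  tc <- tissue_codes()
  mu <- array(coeffs[["soft"]], dim(truth$labels))
  mu[truth$labels == tc[["air"]]] <- 0
  volume(mu, truth$spacing, truth$origin, "mu_cm_inv")
}

synthetic_ct_from_labels <- function(truth, seed) {
  # pseudo-CT in HU for the CT-group comparison arm (synthetic stand-in)
  tc <- tissue_codes()
  hu_lut <- numeric(max(tc) + 1L)
  hu_lut[tc[["air"]] + 1L] <- -1000
  hu_lut[tc[["soft"]] + 1L] <- 40
  hu_lut[tc[["bone"]] + 1L] <- 900
  hu_lut[tc[["gm"]] + 1L] <- 40
  hu_lut[tc[["wm"]] + 1L] <- 30
  hu_lut[tc[["csf"]] + 1L] <- 10
  hu <- array(hu_lut[truth$labels + 1L], dim(truth$labels))
  ct <- volume(hu, truth$spacing, truth$origin, "HU")
  add_noise(ct, 25, "gaussian", seed = seed)
}

#' Run the full phantom-to-report workflow
#'
#' Executes the complete workflow: jittered cohort generation,
#' template / TPM construction, GMM segmentation of the test subject's
#' first echo, R2* mapping, attenuation-map assembly (reference, fixed
#' bone, continuous R2*-based bone, 6-class multi-compartment, bone-free
#' vendor analogue, pseudo-CT), attenuated OSEM reconstruction per map, and
#' the quantitative evaluation suite. Deterministic for a fixed config.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, the report is written as
#'   `report.json` plus CSV tables, and key volumes as NIfTI.
#' @param verbose print stage progress.
#' @return object of class `suteac_report` (a nested list; see the methods
#'   vignette).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "suteac_run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  say("stage 1/6: cohort + TPM construction")
  cohort <- pipeline_cohort(config)
  tpms <- cohort_tpms(cohort, smooth_fwhm_mm = config$tpm_smooth_fwhm_mm)
  ute_template <- build_template(lapply(cohort, function(p) p$echo1))

  say("stage 2/6: test phantom")
  test_spec <- phantom_spec(n = config$phantom_n,
                            spacing_mm = config$phantom_spacing_mm,
                            noise_sigma = config$noise_sigma,
                            seed = config$seed)
  ph <- generate_phantom(test_spec)
  truth3 <- fold_to_three(ph$labels)

  say("stage 3/6: segmentation + R2*")
  seg <- fit_gmm_with_priors(ph$echo1, tpms, config = gmm_config())
  labels3 <- hard_label(seg, config$air_threshold, config$bone_threshold)
  r2s <- compute_r2star(echo_pair(ph$echo1, ph$echo2,
                                  ph$te1_ms, ph$te2_ms))

  say("stage 4/6: attenuation maps")
  calib <- default_r2star_calibration()
  ac <- list(
    ref = reference_ac_from_labels(ph$labels, config$coeffs),
    sute_fix = make_ac_map(seg, config$coeffs, "fix",
                           smoothing_fwhm_mm = config$ac_fwhm_mm,
                           air_threshold = config$air_threshold,
                           bone_threshold = config$bone_threshold),
    sute_cont = make_ac_map(seg, config$coeffs, "cont", r2s = r2s,
                            calib = calib,
                            smoothing_fwhm_mm = config$ac_fwhm_mm,
                            air_threshold = config$air_threshold,
                            bone_threshold = config$bone_threshold),
    mcac = make_mc_ac_map(ph$labels, config$coeffs,
                          smoothing_fwhm_mm = config$ac_fwhm_mm),
    no_bone = bone_free_ac(ph$labels, config$coeffs)
  )

  say("stage 5/6: emission simulation + OSEM reconstruction")
  g <- scan_geometry(config$n_angles, config$n_radial,
                     config$bin_width_mm)
  slices <- pick_brain_slices(ph, config$n_slices)
  y <- simulate_emission(ph$activity_map, ph$mu_true, g,
                         total_counts = config$total_counts,
                         seed = config$seed + 500L, slices = slices)
  pet <- lapply(ac, function(a) {
    acf <- attenuation_factors(a, g, slices)
    reconstruct(y, acf, iterations = config$osem_iterations,
                subsets = config$osem_subsets,
                postfilter_fwhm_mm = config$pet_fwhm_mm)
  })

  say("stage 6/6: evaluation")
  head_reg <- ph$head_mask$data > 0.5
  seg_acc <- tissue_accuracy(labels3, truth3, head_reg)

  ct <- synthetic_ct_from_labels(ph$labels, seed = config$seed + 900L)
  ct_labels <- classify_ct(ct)
  ac_ct <- hu_to_mu(ct)
  ct_acc <- tissue_accuracy(ct_labels, truth3, head_reg)
  ct_diff <- diff_stats(ac$ref, ac_ct, head_reg)

  fix_diff <- diff_stats(ac$ref, ac$sute_fix, head_reg)

  bm <- brain_mask_of(ph)
  dim(bm) <- dim(ph$labels$labels)
  slice_sel <- array(FALSE, dim(bm))
  slice_sel[, , slices] <- TRUE
  bm_slices <- bm & slice_sel

  atlas_sl <- subset_atlas(ph$region_atlas, slices)
  re_tables <- list()
  re_means <- list()
  for (nm in setdiff(names(pet), "ref")) {
    rem <- relative_error_map(pet$ref, pet[[nm]], bm_slices)
    re_tables[[nm]] <- regional_stats(rem, atlas_sl)
    re_means[[nm]] <-
      re_tables[[nm]]$mean[re_tables[[nm]]$region == "full_brain"]
  }
  # same comparisons in the test-minus-reference orientation (so an
  # under-corrected arm reads negative)
  bias_means <- lapply(re_means, function(x) -x)

  rep_hist <- representative_histogram(
    pet, rep(list(bm_slices), length(pet)), n_bins = 150L)

  mw <- mann_whitney_u(
    re_tables$no_bone$mean[re_tables$no_bone$region != "full_brain"],
    re_tables$sute_fix$mean[re_tables$sute_fix$region != "full_brain"])

  report <- structure(list(
    config = unclass(config)[setdiff(names(unclass(config)), "coeffs")],
    coefficients = as.list(unclass(config$coeffs)),
    slices = slices,
    segmentation = list(accuracy = seg_acc,
                        loglik_iterations = length(seg$loglik_trace)),
    ct_arm = list(accuracy = ct_acc, diff = as.list(ct_diff)),
    ac_diff_sute_fix = as.list(fix_diff),
    regional_re = re_tables,
    full_brain_re = re_means,
    full_brain_bias = bias_means,
    representative_histogram = list(
      arms = names(pet),
      curve = rep_hist$representative,
      singular_values = rep_hist$singular_values),
    mann_whitney_nobone_vs_fix = mw,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "suteac_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    rj <- report
    rj$elapsed_s <- NULL  # keep the written report byte-reproducible
    jsonlite::write_json(rj, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns", force = TRUE)
    utils::write.csv(seg_acc, file.path(out_dir, "segmentation_accuracy.csv"),
                     row.names = FALSE)
    for (nm in names(re_tables))
      utils::write.csv(re_tables[[nm]],
                       file.path(out_dir, paste0("regional_re_", nm, ".csv")),
                       row.names = FALSE)
    write_volume(ac$sute_fix, file.path(out_dir, "ac_sute_fix.nii.gz"))
    write_volume(ac$sute_cont, file.path(out_dir, "ac_sute_cont.nii.gz"))
    write_volume(ute_template, file.path(out_dir, "ute_template.nii.gz"))
  }
  report
}

#' @export
print.suteac_report <- function(x, ...) {
  cat("suteac pipeline report\n")
  cat("  segmentation accuracy (head region):\n")
  print(x$segmentation$accuracy, row.names = FALSE)
  cat("  full-brain RE% vs reference reconstruction:\n")
  for (nm in names(x$full_brain_re))
    cat(sprintf("    %-10s %+6.2f%%\n", nm, x$full_brain_re[[nm]]))
  invisible(x)
}
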