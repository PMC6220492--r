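seg_from_posteriors <- function(air, bone, soft, spacing = c(2, 2, 2)) {
  mk <- function(a) volume(a, spacing, units = "probability")
  structure(list(posteriors = list(air = mk(air), bone = mk(bone),
                                   soft = mk(soft))),
            class = "suteac_segmentation")
}

test_that("attenuation assignment: fixed bone, air zero, smoothing bounds", {
  d <- c(12, 12, 12)
  air <- array(0, d); bone <- array(0, d); soft <- array(0, d)
  air[1:4, , ] <- 1
  bone[5:8, , ] <- 1
  soft[9:12, , ] <- 1
  seg <- seg_from_posteriors(air, bone, soft)

  raw <- make_ac_map(seg, mode = "fix", smoothing_fwhm_mm = 0)
  expect_equal(unique(as.vector(raw$data[6, , ])), 0.151)
  expect_equal(unique(as.vector(raw$data[2, , ])), 0)
  expect_equal(unique(as.vector(raw$data[11, , ])), 0.100)

  # smoothing a soft/bone step stays strictly inside [0.100, 0.151]
  sm <- make_ac_map(seg, mode = "fix", smoothing_fwhm_mm = 4)
  seam <- sm$data[8:9, 6, 6]
  expect_true(all(seam > 0.100 & seam < 0.151))
  expect_lte(max(sm$data), 0.151 + 1e-12)

  # cont mode with the constant calibration equals fix mode
  const_cal <- fit_r2star_calibration(seq(0, 2.4, length.out = 9),
                                      rep(0.151, 9),
                                      clamp = c(0, 0.2))
  r2s <- volume(array(1.3, d), c(2, 2, 2), units = "r2star_per_ms")
  cont <- make_ac_map(seg, mode = "cont", r2s = r2s, calib = const_cal,
                      smoothing_fwhm_mm = 0)
  expect_equal(cont$data, raw$data)
  expect_error(make_ac_map(seg, mode = "cont"), "requires")
})

test_that("calibration fitting recovers cubics and enforces monotonicity", {
  r <- seq(0, 2, length.out = 12)
  truth <- c(0.1, 0.02, 0.005, 0.001)
  mu <- truth[1] + truth[2] * r + truth[3] * r^2 + truth[4] * r^3
  fit <- fit_r2star_calibration(r, mu)
  expect_lt(max(abs(fit$coefficients - truth)), 1e-10)
  pred <- eval_calibration(fit, r)
  expect_lt(max(abs(pred - pmin(pmax(mu, fit$clamp[1]), fit$clamp[2]))),
            1e-8)

  # constant samples give a constant polynomial
  cfit <- fit_r2star_calibration(r, rep(0.12, 12))
  expect_equal(cfit$coefficients[1], 0.12, tolerance = 1e-10)
  expect_lt(max(abs(cfit$coefficients[2:4])), 1e-10)

  # decreasing samples are rejected
  expect_error(fit_r2star_calibration(r, 0.2 - 0.05 * r),
               "non-decreasing")
  expect_error(fit_r2star_calibration(r[1:5], mu[1:5]), "at least 8")
  expect_error(fit_r2star_calibration(rep(1, 10), rep(0.1, 10)),
               "rank-deficient")
})

test_that("multi-compartment map assigns the six printed coefficients", {
  ph <- fixture("ph_small", function()
    generate_phantom(phantom_spec(n = 48L, spacing_mm = 4, noise_sigma = 0)))
  tc <- tissue_codes()
  mc <- make_mc_ac_map(ph$labels, smoothing_fwhm_mm = 0)
  expect_equal(unique(mc$data[ph$labels$labels == tc[["csf"]]]), 0.096)
  expect_equal(unique(mc$data[ph$labels$labels == tc[["gm"]]]), 0.099)
  expect_equal(unique(mc$data[ph$labels$labels == tc[["wm"]]]), 0.099)
  expect_equal(unique(mc$data[ph$labels$labels == tc[["bone"]]]), 0.151)

  # an all-soft volume is invariant to smoothing in the interior
  lab <- label_mask(array(tc[["soft"]], c(9, 9, 9)), spacing = c(2, 2, 2))
  flat <- make_mc_ac_map(lab, smoothing_fwhm_mm = 2)
  expect_equal(flat$data[4:6, 4:6, 4:6], array(0.1, c(3, 3, 3)),
               tolerance = 1e-12)
})

test_that("reference map folds brain tissue to soft and stays piecewise", {
  ph <- fixture("ph_small", function()
    generate_phantom(phantom_spec(n = 48L, spacing_mm = 4, noise_sigma = 0)))
  tc <- tissue_codes()
  ref <- reference_ac_from_labels(ph$labels)
  expect_equal(sort(unique(as.vector(ref$data))), c(0, 0.100, 0.151))
  expect_equal(unique(ref$data[ph$labels$labels == tc[["gm"]]]), 0.100)
  expect_equal(unique(ref$data[ph$labels$labels == tc[["bone"]]]), 0.151)
  expect_equal(unique(ref$data[ph$labels$labels == tc[["air"]]]), 0)

  # classification of the reference map round-trips the labels exactly
  back <- classify_vendor_ute(ref)
  expect_identical(back$labels, fold_to_three(ph$labels)$labels)
})

test_that("HU conversion and CT classification follow their thresholds", {
  hu <- volume(array(c(-1000, -800, -500, 0, 300, 500, 1500, 40),
                     c(2, 2, 2)), c(1, 1, 1), units = "HU")
  mu <- hu_to_mu(hu)
  expect_equal(mu$data[1], 0)                      # air anchor
  expect_equal(mu$data[4], 0.096)                  # water anchor
  expect_true(all(diff(mu$data[order(hu$data)]) >= 0))  # monotone

  lab <- classify_ct(hu)
  tc <- tissue_codes()
  expect_equal(lab$labels[2], tc[["air"]])         # -800 HU
  expect_equal(lab$labels[6], tc[["bone"]])        # 500 HU
  expect_equal(lab$labels[3], tc[["soft"]])        # -500 HU exactly: soft
})

test_that("vendor-map classification honours its equality tolerance", {
  ac <- volume(array(c(0.151, 0, 0.100, 0.13, 0.1509999, 0.05, 0.1495, 0),
                     c(2, 2, 2)), c(1, 1, 1), units = "mu_cm_inv")
  tc <- tissue_codes()
  lab <- classify_vendor_ute(ac)
  expect_equal(lab$labels[1], tc[["bone"]])
  expect_equal(lab$labels[2], tc[["air"]])
  expect_equal(lab$labels[3], tc[["soft"]])
  expect_equal(lab$labels[4], tc[["soft"]])   # smoothed seam value
  expect_equal(lab$labels[7], tc[["soft"]])   # outside default eps
  lab2 <- classify_vendor_ute(ac, eps = 1e-3)
  expect_equal(lab2$labels[5], tc[["bone"]])  # 0.1509999 within eps = 1e-3
  expect_equal(classify_vendor_ute(ac, eps = 1e-2)$labels[7],
               tc[["bone"]])
})
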