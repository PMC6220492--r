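const_vol <- function(val, d = c(4, 4, 4), units = "intensity")
  volume(array(val, d), c(2, 2, 2), units = units)

test_that("template building is the voxel-wise mean of aligned images", {
  v <- rand_vol(c(5, 5, 5), seed = 2)
  expect_equal(build_template(list(v, v, v))$data, v$data)
  expect_equal(build_template(list(const_vol(10), const_vol(20)))$data,
               array(15, c(4, 4, 4)))
  vols <- lapply(1:5, function(s) rand_vol(c(5, 5, 5), seed = s))
  want <- Reduce(`+`, lapply(vols, function(v) v$data)) / 5
  expect_lt(max(abs(build_template(vols)$data - want)), 1e-12)
  expect_error(build_template(list(v)), "at least 2")
})

test_that("mask averaging matches brute-force mean and stays in [0,1]", {
  ones <- const_vol(1, units = "probability")
  zero <- const_vol(0, units = "probability")
  expect_equal(average_masks(list(ones, ones, ones, ones, ones))$data,
               array(1, c(4, 4, 4)))
  avg <- average_masks(list(ones, ones, zero, zero, zero))
  expect_equal(avg$data, array(0.4, c(4, 4, 4)))
  expect_error(average_masks(list(const_vol(2, units = "intensity"))),
               "outside")

  # brute-force trilinear + mean oracle on a 6^3 case with a shift
  m1 <- rand_vol(c(6, 6, 6), seed = 5)
  m2 <- rand_vol(c(6, 6, 6), seed = 6)
  tf <- diag(4); tf[1, 4] <- 2  # one voxel shift in world mm
  got <- average_masks(list(m1, m2), list(diag(4), tf))
  want <- (m1$data + resample_to(m2, m1, tf)$data) / 2
  expect_lt(max(abs(got$data - want)), 1e-12)
})

test_that("normalize_tpms rescales to unit sums with air fallback", {
  mk <- function(val) const_vol(val, units = "probability")
  raw <- list(air = mk(0.5), soft = mk(0.5), bone = mk(0.5),
              gm = mk(0), wm = mk(0), csf = mk(0))
  out <- normalize_tpms(raw)
  expect_equal(out$maps$air$data[1], 1 / 3, tolerance = 1e-12)
  expect_equal(out$maps$bone$data[1], 1 / 3, tolerance = 1e-12)

  # already normalized: fixed point
  raw2 <- list(air = mk(0.2), soft = mk(0.3), bone = mk(0.5),
               gm = mk(0), wm = mk(0), csf = mk(0))
  out2 <- normalize_tpms(raw2)
  expect_equal(out2$maps$soft$data[1], 0.3, tolerance = 1e-12)

  # all-zero voxel becomes pure air
  raw3 <- lapply(raw2, function(m) m)
  for (nm in names(raw3)) raw3[[nm]]$data[1, 1, 1] <- 0
  out3 <- normalize_tpms(raw3)
  expect_equal(out3$maps$air$data[1, 1, 1], 1)
  expect_equal(out3$maps$soft$data[1, 1, 1], 0)
})

test_that("protected renormalization rescales only non-protected classes", {
  mk <- function(val) const_vol(val, units = "probability")
  # sum 1.2 with air+bone = 0.4: GM/WM scaled by 0.75
  t1 <- list(air = mk(0.2), soft = mk(0), bone = mk(0.2),
             gm = mk(0.4), wm = mk(0.4), csf = mk(0))
  o1 <- renormalize_protected(t1)
  expect_equal(o1$maps$gm$data[1], 0.3, tolerance = 1e-12)
  expect_equal(o1$maps$wm$data[1], 0.3, tolerance = 1e-12)
  expect_equal(o1$maps$air$data[1], 0.2)
  expect_equal(o1$maps$bone$data[1], 0.2)

  # protected sum already 1: soft collapses to 0
  t2 <- list(air = mk(0.5), soft = mk(0.5), bone = mk(0.5),
             gm = mk(0), wm = mk(0), csf = mk(0))
  o2 <- renormalize_protected(t2)
  expect_equal(o2$maps$soft$data[1], 0)

  # unit-sum voxel untouched
  t3 <- list(air = mk(0.1), soft = mk(0.6), bone = mk(0.1),
             gm = mk(0.1), wm = mk(0.05), csf = mk(0.05))
  o3 <- renormalize_protected(t3)
  for (cl in names(t3))
    expect_equal(o3$maps[[cl]]$data, t3[[cl]]$data, tolerance = 1e-12)

  # deficit (sum < 1) is filled so sums return to exactly 1
  t4 <- list(air = mk(0.1), soft = mk(0.2), bone = mk(0.1),
             gm = mk(0.2), wm = mk(0), csf = mk(0))
  o4 <- renormalize_protected(t4)
  s <- Reduce(`+`, lapply(o4$maps, function(m) m$data))
  expect_equal(max(abs(s - 1)), 0, tolerance = 1e-12)
  expect_equal(o4$maps$air$data[1], 0.1)

  # order independence over non-protected classes
  set.seed(31)
  rnd <- lapply(1:6, function(i) {
    v <- rand_vol(c(4, 4, 4), seed = 40 + i)
    with_data(v, v$data * 0.3, units = "probability")
  })
  names(rnd) <- c("air", "soft", "bone", "gm", "wm", "csf")
  a <- renormalize_protected(rnd)
  perm <- rnd[c("air", "bone", "csf", "wm", "gm", "soft")]
  b <- renormalize_protected(perm)
  for (cl in names(a$maps))
    expect_equal(a$maps[[cl]]$data, b$maps[[cl]]$data, tolerance = 1e-14)
})

test_that("cohort TPMs recover background air and mid-skull bone", {
  tpms <- cohort_tpms_cached()
  ph <- default_phantom()
  tc <- tissue_codes()
  # deep background: interior corner region away from the head
  expect_gt(min(tpms$maps$air$data[4:10, 4:10, 4:10]), 0.9)
  # mid-skull: bone probability above 0.5 at shell-core voxels
  bone <- class_mask(ph$labels, "bone")
  core <- bone &
    gaussian_smooth(volume(array(as.double(bone), dim(bone)),
                           ph$labels$spacing, units = "probability"),
                    4)$data > 0.9
  expect_gt(sum(core), 100)
  expect_gt(mean(tpms$maps$bone$data[core] > 0.5), 0.99)
})
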