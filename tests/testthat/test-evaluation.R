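test_that("dice matches exhaustive counting on random mask pairs", {
  expect_equal(dice(array(TRUE, c(2, 2, 2)), array(TRUE, c(2, 2, 2))), 1)
  expect_equal(dice(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2))), 1)
  a <- array(c(rep(TRUE, 10), rep(FALSE, 17)), c(3, 3, 3))
  b <- array(c(rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 12)), c(3, 3, 3))
  expect_equal(dice(a, b), 2 * 5 / (10 + 10))
  expect_equal(dice(a, !a), 0)

  # literal as-printed variant: union denominator, 2 for identical masks
  expect_equal(dice(a, a, variant = "union"), 2)

  set.seed(77)
  for (i in 1:100) {
    a <- array(runif(64) < runif(1), c(4, 4, 4))
    b <- array(runif(64) < runif(1), c(4, 4, 4))
    inter <- 0; na <- 0; nb <- 0
    for (j in 1:64) {            # exhaustive voxel counting
      na <- na + a[j]; nb <- nb + b[j]
      inter <- inter + (a[j] && b[j])
    }
    want <- if (na + nb == 0) 1 else 2 * inter / (na + nb)
    expect_identical(dice(a, b), want)
    expect_identical(dice(a, b), dice(b, a))  # symmetry
  }
})

test_that("FP/FN rates follow their denominators and degenerate rules", {
  d <- c(3, 3, 3)
  a <- array(FALSE, d); a[1:10] <- TRUE
  expect_equal(fp_fn_rates(a, a), c(fp_rate = 0, fn_rate = 0))

  sup <- array(FALSE, d); sup[1:20] <- TRUE
  sub <- array(FALSE, d); sub[1:10] <- TRUE
  expect_equal(fp_fn_rates(sup, sub), c(fp_rate = 0.5, fn_rate = 0))

  empty <- array(FALSE, d)
  expect_equal(fp_fn_rates(empty, sub), c(fp_rate = 0, fn_rate = 1))
  expect_equal(fp_fn_rates(empty, empty), c(fp_rate = 0, fn_rate = 0))

  set.seed(13)
  for (i in 1:100) {
    p <- array(runif(27) < 0.5, d)
    r <- array(runif(27) < 0.5, d)
    fp <- 0; fn <- 0
    for (j in 1:27) {
      fp <- fp + (p[j] && !r[j])
      fn <- fn + (r[j] && !p[j])
    }
    got <- fp_fn_rates(p, r)
    expect_equal(got[["fp_rate"]], if (sum(p) == 0) 0 else fp / sum(p))
    expect_equal(got[["fn_rate"]], if (sum(r) == 0) 0 else fn / sum(r))
  }
})

test_that("difference statistics obey the triangle inequality", {
  d <- c(4, 4, 4)
  a <- rand_vol(d, seed = 1, units = "mu_cm_inv")
  m <- array(TRUE, d)
  expect_equal(unname(diff_stats(a, a, m)), c(0, 0, 0, 0))

  b <- with_data(a, a$data + 0.01)
  st <- diff_stats(a, b, m)
  expect_equal(st[["diff_mean"]], -0.01, tolerance = 1e-12)
  expect_equal(st[["absdiff_mean"]], 0.01, tolerance = 1e-12)
  expect_equal(st[["diff_sd"]], 0)

  for (s in 1:20) {
    x <- rand_vol(d, seed = 200 + s)
    y <- rand_vol(d, seed = 300 + s)
    st <- diff_stats(x, y, m)
    expect_gte(st[["absdiff_mean"]], abs(st[["diff_mean"]]) - 1e-14)
  }
  expect_error(diff_stats(a, b, array(FALSE, d)), "empty")
})

test_that("relative-error maps have the stated sign convention and floor", {
  d <- c(4, 4, 4)
  ref <- rand_vol(d, seed = 4, min = 1, max = 2)
  m <- array(TRUE, d)
  expect_true(all(relative_error_map(ref, ref, m)$data == 0))

  x <- with_data(ref, 0.9 * ref$data)
  r <- relative_error_map(ref, x, m)
  expect_equal(unique(round(as.vector(r$data), 10)), 10)

  hot <- with_data(ref, 1.2 * ref$data)
  expect_true(all(relative_error_map(ref, hot, m)$data < 0))

  # near-zero reference voxels are excluded, not imputed
  ref0 <- with_data(ref, ref$data)
  ref0$data[1, 1, 1] <- 0
  r0 <- relative_error_map(ref0, x, m)
  expect_true(is.na(r0$data[1, 1, 1]))
})

test_that("regional statistics aggregate means exactly", {
  d <- c(4, 4, 2)
  re <- array(NA_real_, d)
  atlas_lab <- array(0L, d)
  atlas_lab[1:8] <- 1L; atlas_lab[9:20] <- 2L
  re[1:8] <- 1; re[9:20] <- 3
  atlas <- label_mask(atlas_lab, c(none = 0L, a = 1L, b = 2L))
  tab <- regional_stats(volume(re, c(1, 1, 1)), atlas)
  expect_equal(tab$mean[tab$region == "a"], 1)
  expect_equal(tab$mean[tab$region == "b"], 3)
  expect_equal(tab$sd[tab$region == "a"], 0)
  # whole-brain row is the voxel-weighted mean of the regions
  expect_equal(tab$mean[tab$region == "full_brain"],
               (8 * 1 + 12 * 3) / 20)

  # constant map: every region equals the constant
  rc <- array(2.5, d)
  tabc <- regional_stats(volume(rc, c(1, 1, 1)), atlas)
  expect_true(all(tabc$mean == 2.5))
  expect_true(all(tabc$sd == 0))
})

test_that("representative histogram equals the power-iteration component", {
  set.seed(55)
  imgs <- lapply(1:4, function(i)
    rand_vol(c(8, 8, 8), seed = 500 + i, min = 0, max = i))
  masks <- rep(list(array(TRUE, c(8, 8, 8))), 4)
  rh <- representative_histogram(imgs, masks, n_bins = 20L)
  expect_equal(dim(rh$histograms), c(4L, 20L))
  expect_true(all(rowSums(rh$histograms) == 512))

  v1 <- power_iteration_pc1(rh$histograms)
  if (sum(v1) < 0) v1 <- -v1
  v1 <- v1 * rh$singular_values[1] / sqrt(4)
  expect_lt(max(abs(rh$representative - v1)), 1e-8)

  # permutation invariance over subjects
  rh2 <- representative_histogram(imgs[c(3, 1, 4, 2)],
                                  masks, n_bins = 20L)
  expect_equal(rh2$representative, rh$representative, tolerance = 1e-9)

  # identical subjects: rank-1 matrix reproduced exactly
  same <- representative_histogram(imgs[c(1, 1, 1)],
                                   masks[1:3], n_bins = 20L)
  approx <- sqrt(3) * outer(rep(1 / sqrt(3), 3), same$representative)
  expect_lt(max(abs(approx - same$histograms)), 1e-8)
  expect_error(representative_histogram(imgs[1], masks[1]), "at least 2")
})

test_that("Mann-Whitney matches enumeration and a standard implementation", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)

  # identical tied samples: p = 1
  expect_gte(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 0.99)

  # brute-force enumeration agreement for all n_a, n_b <= 5
  set.seed(3)
  for (na in 1:5) for (nb in 1:5) {
    a <- sample(1:6, na, replace = TRUE)  # ties likely
    b <- sample(1:6, nb, replace = TRUE)
    want <- mw_brute(a, b)
    got <- mann_whitney_u(a, b)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }

  # large-sample normal approximation against wilcox.test
  set.seed(9)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  got <- mann_whitney_u(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})
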