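# Independent oracles and shared fixtures (all generated in code).

rand_vol <- function(d = c(6, 6, 6), spacing = c(2, 2, 2), seed = 1,
                     units = "intensity", min = 0, max = 1) {
  set.seed(seed)
  volume(array(runif(prod(d), min, max), d), spacing, units = units)
}

# dense triple-loop separable convolution with zero padding — the
# brute-force smoothing oracle
brute_smooth <- function(arr, fwhm_mm, spacing) {
  kern <- lapply(1:3, function(ax) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing[ax]
    r <- max(1L, ceiling(4 * sigma))
    k <- exp(-((-r):r)^2 / (2 * sigma^2))
    k / sum(k)
  })
  d <- dim(arr)
  conv_axis <- function(a, k, ax) {
    r <- (length(k) - 1L) %/% 2L
    out <- array(0, d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
      s <- 0
      for (o in -r:r) {
        ii <- c(i, j, l)
        ii[ax] <- ii[ax] + o
        if (ii[ax] >= 1 && ii[ax] <= d[ax])
          s <- s + k[o + r + 1] * a[ii[1], ii[2], ii[3]]
      }
      out[i, j, l] <- s
    }
    out
  }
  for (ax in 1:3) arr <- conv_axis(arr, kern[[ax]], ax)
  arr
}

# plain dense EM for a prior-weighted Gaussian mixture (one Gaussian per
# class), written independently of the package implementation
reference_em <- function(y, P, max_iter = 100L, tol = 1e-6,
                         vfloor_frac = 1e-4) {
  K <- ncol(P)
  n <- length(y)
  vfloor <- vfloor_frac * var(y)
  mu <- sig2 <- numeric(K)
  for (k in 1:K) {
    mu[k] <- sum(P[, k] * y) / sum(P[, k])
    sig2[k] <- max(sum(P[, k] * (y - mu[k])^2) / sum(P[, k]), vfloor)
  }
  # tied initial means (uninformative priors): spread over quantiles, the
  # same symmetry-breaking rule the tested implementation documents
  tie_tol <- 1e-8 * (max(y) - min(y) + 1e-12)
  groups <- split(1:K, round(mu / max(tie_tol, 1e-300)))
  for (grp in groups)
    if (length(grp) > 1L)
      mu[grp] <- stats::quantile(y, (seq_along(grp) - 0.5) / length(grp),
                                 names = FALSE)
  ll_prev <- -Inf
  trace <- numeric(0)
  R <- matrix(0, n, K)
  for (it in 1:max_iter) {
    L <- matrix(0, n, K)
    for (k in 1:K)
      L[, k] <- P[, k] * dnorm(y, mu[k], sqrt(sig2[k]))
    tot <- rowSums(L)
    ll <- sum(log(tot))
    R <- L / tot
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * abs(ll_prev)) break
    ll_prev <- ll
    for (k in 1:K) {
      Nk <- sum(R[, k])
      mu[k] <- sum(R[, k] * y) / Nk
      sig2[k] <- max(sum(R[, k] * (y - mu[k])^2) / Nk, vfloor)
    }
  }
  list(mu = mu, sig2 = sig2, loglik = trace)
}

# direct-definition Mann-Whitney U and exact permutation p-value
mw_brute <- function(a, b) {
  U <- 0
  for (x in a) for (z in b) U <- U + (x > z) + 0.5 * (x == z)
  pooled <- c(a, b)
  m <- length(a); n <- length(b)
  mu <- m * n / 2
  sets <- utils::combn(m + n, m)
  devs <- apply(sets, 2, function(ix) {
    aa <- pooled[ix]; bb <- pooled[-ix]
    u <- 0
    for (x in aa) for (z in bb) u <- u + (x > z) + 0.5 * (x == z)
    abs(u - mu)
  })
  list(U = U, p = mean(devs >= abs(U - mu) - 1e-9))
}

# leading principal component of t(H) %*% H by power iteration
power_iteration_pc1 <- function(H, iters = 2000L) {
  G <- crossprod(H)
  v <- rep(1, ncol(H))
  for (i in seq_len(iters)) {
    v2 <- G %*% v
    v <- as.vector(v2) / sqrt(sum(v2^2))
  }
  v
}

# cached expensive fixtures (built once per test run)
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

noiseless_phantom <- function() fixture("ph0", function()
  generate_phantom(phantom_spec(noise_sigma = 0)))

default_phantom <- function() fixture("ph17", function()
  generate_phantom(phantom_spec(seed = 17)))

pipeline_cohort_cached <- function() fixture("cohort", function()
  pipeline_cohort(run_config()))

cohort_tpms_cached <- function() fixture("tpms", function()
  cohort_tpms(pipeline_cohort_cached(), smooth_fwhm_mm = 2))

pipeline_report_cached <- function() fixture("report", function()
  suppressWarnings(run_pipeline(run_config())))

tiny_config <- function() run_config(phantom_n = 48L, phantom_spacing_mm = 4,
                                     cohort_size = 3L,
                                     n_angles = 60L, n_radial = 64L,
                                     bin_width_mm = 3,
                                     total_counts = 2e5, n_slices = 1L)
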