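#' Configuration for prior-guided Gaussian-mixture segmentation
#'
#' @param gaussians_per_class number of Gaussians per tissue class: either a
#'   single integer or a named vector (e.g. `c(soft = 2)`) overriding the
#'   default of 1 for selected classes.
#' @param max_iterations maximum EM iterations.
#' @param loglik_tolerance relative log-likelihood change below which EM
#'   stops.
#' @param variance_floor variance floor as a fraction of the global
#'   intensity variance; prevents component collapse.
#' @param bias_correction `"none"` or `"polynomial"` (a smooth
#'   multiplicative field, log-domain least squares, re-estimated each
#'   iteration).
#' @param bias_order polynomial order of the bias field.
#' @return object of class `suteac_gmm_config`.
#' @export
gmm_config <- function(gaussians_per_class = 1L,
                       max_iterations = 100L,
                       loglik_tolerance = 1e-6,
                       variance_floor = 1e-4,
                       bias_correction = c("none", "polynomial"),
                       bias_order = 3L) {
  bias_correction <- match.arg(bias_correction)
  if (max_iterations < 1L) stop("max_iterations must be >= 1")
  if (loglik_tolerance <= 0) stop("loglik_tolerance must be positive")
  if (variance_floor <= 0) stop("variance_floor must be positive")
  structure(list(gaussians_per_class = gaussians_per_class,
                 max_iterations = as.integer(max_iterations),
                 loglik_tolerance = loglik_tolerance,
                 variance_floor = variance_floor,
                 bias_correction = bias_correction,
                 bias_order = as.integer(bias_order)),
            class = "suteac_gmm_config")
}

expand_components <- function(classes, gpc) {
  counts <- rep(1L, length(classes))
  names(counts) <- classes
  if (length(gpc) == 1L && is.null(names(gpc))) {
    counts[] <- as.integer(gpc)
  } else if (!is.null(names(gpc))) {
    counts[names(gpc)] <- as.integer(gpc)
  }
  list(class = rep(classes, counts), counts = counts)
}

#' Fit a Gaussian mixture with voxel-wise spatial priors
#'
#' EM segmentation of an intensity image where each tissue class carries a
#' voxel-wise prior probability (a TPM). E-step: the posterior for
#' component j of class k at voxel x is proportional to
#' `prior_k(x) * w_kj * N(I(x); mu_kj, sigma^2_kj)`. M-step: standard
#' posterior-weighted updates of means, variances (floored) and
#' within-class weights. Classes with zero prior everywhere are dropped
#' with a warning. Likelihoods are evaluated in log space so extreme
#' intensities cannot underflow.
#'
#' @param image intensity `suteac_volume`.
#' @param priors a `suteac_tpms` (or named list of probability volumes) on
#'   the image grid.
#' @param mask optional `suteac_volume` or logical array restricting the
#'   fit; `NULL` fits every voxel.
#' @param config a [gmm_config()].
#' @return object of class `suteac_segmentation`: `posteriors` (named list
#'   of probability volumes), `class_params` (data.frame of per-component
#'   mean / variance / weight), `loglik_trace`, `bias_field` (or `NULL`).
#' @export
fit_gmm_with_priors <- function(image, priors, mask = NULL,
                                config = gmm_config()) {
  stopifnot(is_volume(image))
  maps <- if (is_tpms(priors)) priors$maps else priors
  classes <- names(maps)
  for (m in maps) stop_if_grid_mismatch(image, m)
  if (any(!is.finite(image$data))) stop("non-finite intensities")

  msel <- if (is.null(mask)) {
    rep(TRUE, length(image$data))
  } else if (is_volume(mask)) {
    as.vector(mask$data > 0.5)
  } else {
    as.vector(mask)
  }
  if (!any(msel)) stop("empty mask")

  y <- as.vector(image$data)[msel]
  P <- vapply(maps, function(m) as.vector(m$data)[msel],
              numeric(sum(msel)))
  mass <- colSums(P)
  if (any(mass == 0)) {
    warning("dropping classes with zero prior mass: ",
            paste(classes[mass == 0], collapse = ", "))
    keep <- mass > 0
    P <- P[, keep, drop = FALSE]
    classes_kept <- classes[keep]
  } else {
    classes_kept <- classes
  }

  ec <- expand_components(classes_kept, config$gaussians_per_class)
  comp_class <- match(ec$class, classes_kept)
  C <- length(comp_class)
  n <- length(y)

  gvar <- var(y)
  vfloor <- config$variance_floor * gvar

  # init: prior-weighted class moments; classes whose priors carry no
  # spatial information (tied initial means, e.g. flat priors) are spread
  # over intensity quantiles so EM can break the symmetry
  Kc <- length(classes_kept)
  m0s <- v0s <- numeric(Kc)
  for (k in seq_len(Kc)) {
    pk <- P[, k]
    m0s[k] <- sum(pk * y) / sum(pk)
    v0s[k] <- max(sum(pk * (y - m0s[k])^2) / sum(pk), vfloor)
  }
  tie_tol <- 1e-8 * (max(y) - min(y) + 1e-12)
  groups <- split(seq_len(Kc), round(m0s / max(tie_tol, 1e-300)))
  for (grp in groups) {
    if (length(grp) > 1L)
      m0s[grp] <- stats::quantile(y, (seq_along(grp) - 0.5) / length(grp),
                                  names = FALSE)
  }
  mu <- sig2 <- w <- numeric(C)
  for (k in seq_len(Kc)) {
    m0 <- m0s[k]
    v0 <- v0s[k]
    idx <- which(comp_class == k)
    off <- if (length(idx) > 1L)
      seq(-0.5, 0.5, length.out = length(idx)) else 0
    mu[idx] <- m0 + off * sqrt(v0)
    sig2[idx] <- v0
    w[idx] <- 1 / length(idx)
  }

  bias_log <- rep(0, n)
  design <- NULL
  if (config$bias_correction == "polynomial")
    design <- poly_design(image, msel, config$bias_order)

  trace <- numeric(0)
  ll_prev <- -Inf
  logP <- log(P)
  R <- NULL
  for (iter in seq_len(config$max_iterations)) {
    yc <- y * exp(-bias_log)
    logL <- matrix(0, n, C)
    for (j in seq_len(C))
      logL[, j] <- logP[, comp_class[j]] + log(w[j]) +
        dnorm(yc, mu[j], sqrt(sig2[j]), log = TRUE)
    mx <- do.call(pmax, c(as.data.frame(logL), list(-Inf)))
    ok <- is.finite(mx)
    S <- rowSums(exp(logL - mx))
    ll <- sum(mx[ok] + log(S[ok]))
    R <- exp(logL - (mx + log(S)))
    R[!ok, ] <- 0

    trace <- c(trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < config$loglik_tolerance * abs(ll_prev)) {
      ll_prev <- ll
      break
    }
    ll_prev <- ll

    Nc <- colSums(R)
    Nc[Nc < 1e-12] <- 1e-12
    mu <- colSums(R * yc) / Nc
    for (j in seq_len(C))
      sig2[j] <- max(sum(R[, j] * (yc - mu[j])^2) / Nc[j], vfloor)
    for (k in seq_along(classes_kept)) {
      idx <- which(comp_class == k)
      w[idx] <- Nc[idx] / sum(Nc[idx])
    }

    if (!is.null(design)) {
      pred <- as.vector(R %*% mu)
      fl <- 1e-6 * max(abs(y))
      use <- y > fl & pred > fl
      resid <- log(y[use]) - log(pred[use])
      fit <- stats::lm.fit(design[use, , drop = FALSE], resid)
      bias_log <- as.vector(design %*% fit$coefficients)
      bias_log <- bias_log - mean(bias_log)  # unit mean gain
    }
  }

  d3 <- dim(image$data)
  posteriors <- list()
  for (cl in classes) {
    arr <- array(0, d3)
    k <- match(cl, classes_kept)
    if (!is.na(k)) {
      idx <- which(comp_class == k)
      arr[msel] <- rowSums(R[, idx, drop = FALSE])
    }
    arr[arr > 1] <- 1
    posteriors[[cl]] <- volume(arr, image$spacing, image$origin,
                               "probability")
  }
  bias_field <- NULL
  if (!is.null(design)) {
    bf <- array(1, d3)
    bf[msel] <- exp(bias_log)
    bias_field <- volume(bf, image$spacing, image$origin, "intensity")
  }
  structure(list(
    posteriors = posteriors,
    class_params = data.frame(class = ec$class,
                              component = unlist(lapply(ec$counts, seq_len)),
                              mean = mu, variance = sig2, weight = w),
    loglik_trace = trace,
    bias_field = bias_field),
    class = "suteac_segmentation")
}

poly_design <- function(image, msel, order) {
  d3 <- dim(image$data)
  u <- (seq_len(d3[1]) - 1) / max(d3[1] - 1, 1) * 2 - 1
  v <- (seq_len(d3[2]) - 1) / max(d3[2] - 1, 1) * 2 - 1
  w <- (seq_len(d3[3]) - 1) / max(d3[3] - 1, 1) * 2 - 1
  U <- rep(u, times = d3[2] * d3[3])[msel]
  V <- rep(rep(v, each = d3[1]), times = d3[3])[msel]
  W <- rep(w, each = d3[1] * d3[2])[msel]
  cols <- list()
  for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j))
    cols[[length(cols) + 1L]] <- U^i * V^j * W^k
  do.call(cbind, cols)
}

#' Threshold posteriors into air / soft / bone labels
#'
#' Voxels whose air posterior exceeds `air_threshold` (default 0.1) are
#' labelled air; voxels whose bone posterior exceeds `bone_threshold`
#' (default 0.2) are then labelled bone, overriding air where both rules
#' fire (a missed skull voxel is the costlier PET error); everything else
#' is soft tissue.
#'
#' @param result a `suteac_segmentation`.
#' @param air_threshold air posterior threshold in (0, 1).
#' @param bone_threshold bone posterior threshold in (0, 1).
#' @return `suteac_labels` over \{air, soft, bone\}.
#' @export
hard_label <- function(result, air_threshold = 0.1, bone_threshold = 0.2) {
  stopifnot(inherits(result, "suteac_segmentation"))
  if (air_threshold <= 0 || air_threshold >= 1 ||
      bone_threshold <= 0 || bone_threshold >= 1)
    stop("thresholds must be in (0, 1)")
  tc <- tissue_codes()
  pa <- result$posteriors$air$data
  pb <- result$posteriors$bone$data
  lab <- array(tc[["soft"]], dim(pa))
  lab[pa > air_threshold] <- tc[["air"]]
  lab[pb > bone_threshold] <- tc[["bone"]]
  label_mask(lab, tc[c("air", "soft", "bone")],
             result$posteriors$air$spacing, result$posteriors$air$origin)
}
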