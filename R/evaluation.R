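#' Dice overlap coefficient
#'
#' Default (`variant = "sum"`) is the standard Dice statistic
#' 2|A intersect B| / (|A| + |B|). The `"union"` variant,
#' 2|A intersect B| / |A union B|, is exposed for audit; it equals 2 for
#' identical non-empty masks. Two empty masks score 1 (perfect agreement);
#' one empty mask scores 0.
#'
#' @param a,b logical arrays (or 0/1 arrays) on the same grid.
#' @param variant `"sum"` or `"union"`.
#' @return numeric scalar.
#' @export
dice <- function(a, b, variant = c("sum", "union")) {
  variant <- match.arg(variant)
  if (!all(dim(a) == dim(b))) stop("grid mismatch")
  a <- as.logical(a); b <- as.logical(b)
  na <- sum(a); nb <- sum(b)
  inter <- sum(a & b)
  if (variant == "sum") {
    if (na + nb == 0) return(1.0)
    2 * inter / (na + nb)
  } else {
    un <- sum(a | b)
    if (un == 0) return(1.0)
    2 * inter / un
  }
}

#' False-positive and false-negative rates of a segmentation
#'
#' `fp_rate` is the fraction of predicted-positive voxels that are not in
#' the reference; `fn_rate` is the fraction of reference-positive voxels the
#' prediction missed. Both are 0 when their denominator is empty, except
#' that an empty prediction against a non-empty reference gives
#' `fn_rate = 1`. Evaluation is restricted to `region` (e.g. the head).
#'
#' @param pred,ref logical arrays on one grid.
#' @param region optional logical array restricting the comparison.
#' @return named numeric vector `c(fp_rate, fn_rate)`.
#' @export
fp_fn_rates <- function(pred, ref, region = NULL) {
  if (!all(dim(pred) == dim(ref))) stop("grid mismatch")
  pred <- as.logical(pred); ref <- as.logical(ref)
  if (!is.null(region)) {
    if (!all(dim(region) == dim(pred))) stop("grid mismatch")
    region <- as.logical(region)
    pred <- pred & region
    ref <- ref & region
  }
  np <- sum(pred); nr <- sum(ref)
  fp <- if (np == 0) 0 else sum(pred & !ref) / np
  fn <- if (nr == 0) 0 else sum(ref & !pred) / nr
  c(fp_rate = fp, fn_rate = fn)
}

#' Dice / FP / FN per tissue class within a region
#'
#' @param pred,ref `suteac_labels` sharing a grid; six-class inputs are
#'   folded to air / soft / bone.
#' @param region logical array or mask `suteac_volume` (e.g. head region).
#' @return data.frame with one row per class.
#' @export
tissue_accuracy <- function(pred, ref, region = NULL) {
  stopifnot(is_labels(pred), is_labels(ref))
  p3 <- if (all(names(pred$table) %in% c("air", "soft", "bone")))
    pred else fold_to_three(pred)
  r3 <- if (all(names(ref$table) %in% c("air", "soft", "bone")))
    ref else fold_to_three(ref)
  reg <- if (is.null(region)) NULL else
    if (is_volume(region)) region$data > 0.5 else as.logical(region)
  rows <- lapply(c("air", "soft", "bone"), function(cl) {
    pm <- class_mask(p3, cl); rm <- class_mask(r3, cl)
    if (!is.null(reg)) { pm <- pm & reg; rm <- rm & reg }
    rates <- fp_fn_rates(pm, rm)
    data.frame(class = cl, dice = dice(pm, rm),
               fp_rate = rates[["fp_rate"]], fn_rate = rates[["fn_rate"]])
  })
  do.call(rbind, rows)
}

#' Difference statistics between two attenuation maps
#'
#' Mean and SD of the signed difference (a - b) and of the absolute
#' difference, over the head mask only, so background voxels do not dilute
#' the statistics.
#'
#' @param ac_a,ac_b attenuation `suteac_volume`s on one grid.
#' @param head_mask logical array or mask `suteac_volume`.
#' @return named numeric vector `(diff_mean, diff_sd, absdiff_mean,
#'   absdiff_sd)` in cm^-1.
#' @export
diff_stats <- function(ac_a, ac_b, head_mask) {
  stopifnot(is_volume(ac_a), is_volume(ac_b))
  stop_if_grid_mismatch(ac_a, ac_b)
  m <- if (is_volume(head_mask)) head_mask$data > 0.5 else
    as.logical(head_mask)
  if (!any(m)) stop("empty head mask")
  d <- (ac_a$data - ac_b$data)[m]
  c(diff_mean = mean(d), diff_sd = sd(d),
    absdiff_mean = mean(abs(d)), absdiff_sd = sd(abs(d)))
}

#' Voxel-wise relative-error map between two PET images
#'
#' R(x) = 100 (ref(x) - test(x)) / ref(x), percent; a test image hotter
#' than the reference gives negative values. Voxels where the reference is
#' below a floor (default 1e-6 of its in-mask mean) are excluded (NA)
#' rather than imputed.
#'
#' @param pet_ref,pet_x `suteac_volume`s on one grid.
#' @param mask logical array or mask `suteac_volume`.
#' @param ref_floor optional absolute floor on the reference.
#' @return `suteac_volume` of percent errors, NA outside the defined set.
#' @export
relative_error_map <- function(pet_ref, pet_x, mask, ref_floor = NULL) {
  stopifnot(is_volume(pet_ref), is_volume(pet_x))
  stop_if_grid_mismatch(pet_ref, pet_x)
  m <- if (is_volume(mask)) mask$data > 0.5 else as.logical(mask)
  if (!any(m)) stop("empty mask")
  if (is.null(ref_floor))
    ref_floor <- 1e-6 * mean(pet_ref$data[m])
  ok <- m & pet_ref$data > ref_floor
  if (!any(ok)) stop("empty mask after reference flooring")
  r <- array(NA_real_, dim(pet_ref$data))
  r[ok] <- 100 * (pet_ref$data[ok] - pet_x$data[ok]) / pet_ref$data[ok]
  volume(r, pet_ref$spacing, pet_ref$origin, "intensity")
}

#' Regional statistics of a relative-error map
#'
#' Mean and SD of defined voxels per atlas region, plus a whole-brain row
#' pooling every labelled region.
#'
#' @param re_map `suteac_volume` from [relative_error_map()].
#' @param atlas `suteac_labels` whose non-zero codes are regions.
#' @return data.frame with columns `region`, `mean`, `sd`, `n_voxels`.
#' @export
regional_stats <- function(re_map, atlas) {
  stopifnot(is_volume(re_map), is_labels(atlas))
  vals <- as.vector(re_map$data)
  lab <- as.vector(atlas$labels)
  regions <- atlas$table[atlas$table != 0L]
  rows <- lapply(names(regions), function(nm) {
    v <- vals[lab == regions[[nm]]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) stop("region fully undefined: ", nm)
    data.frame(region = nm, mean = mean(v),
               sd = if (length(v) > 1L) sd(v) else 0, n_voxels = length(v))
  })
  pooled <- vals[lab %in% regions & !is.na(vals)]
  rows[[length(rows) + 1L]] <-
    data.frame(region = "full_brain", mean = mean(pooled),
               sd = sd(pooled), n_voxels = length(pooled))
  do.call(rbind, rows)
}

#' Representative intensity histogram across subjects
#'
#' Each subject's masked intensities are binned into `n_bins` bins over
#' that subject's own range (bin width fixed within a subject, varying
#' across subjects). The subjects-by-bins count matrix is decomposed by SVD
#' and the representative curve is the leading right-singular vector,
#' sign-fixed so its dominant mass is non-negative and scaled by the
#' leading singular value divided by sqrt(number of subjects).
#'
#' @param images list of >= 2 `suteac_volume`s.
#' @param masks list of masks (logical array or `suteac_volume`), one per
#'   image.
#' @param n_bins number of histogram bins (default 150).
#' @return list with `histograms` (subjects x bins matrix), `bin_edges`
#'   (list per subject), `representative` (length `n_bins` curve),
#'   `singular_values`.
#' @export
representative_histogram <- function(images, masks, n_bins = 150L) {
  if (length(images) < 2L) stop("need at least 2 subjects")
  if (length(masks) != length(images)) stop("one mask per image required")
  H <- matrix(0, length(images), n_bins)
  edges <- vector("list", length(images))
  for (i in seq_along(images)) {
    m <- masks[[i]]
    m <- if (is_volume(m)) m$data > 0.5 else as.logical(m)
    if (!any(m)) stop("empty mask for subject ", i)
    v <- images[[i]]$data[m]
    rng <- range(v)
    if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1e-12
    br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    H[i, ] <- graphics::hist(v, breaks = br, plot = FALSE)$counts
    edges[[i]] <- br
  }
  sv <- svd(H)
  curve <- sv$v[, 1]
  if (sum(curve) < 0) curve <- -curve
  curve <- curve * sv$d[1] / sqrt(nrow(H))
  list(histograms = H, bin_edges = edges, representative = curve,
       singular_values = sv$d)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with mid-ranks for ties. For combined sample sizes up to
#' `exact_max` the two-sided p-value is computed by exact enumeration of
#' all group assignments (a permutation test on U, valid under ties);
#' larger samples use the normal approximation with tie correction.
#'
#' @param sample_a,sample_b numeric vectors (non-empty).
#' @param alternative only `"two.sided"` is provided.
#' @param exact_max maximum combined size for exact enumeration
#'   (default 16).
#' @return list with `U` (statistic for sample_a) and `p`.
#' @export
mann_whitney_u <- function(sample_a, sample_b,
                           alternative = "two.sided", exact_max = 16L) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("empty sample")
  if (alternative != "two.sided") stop("only two-sided is implemented")
  m <- length(sample_a); n <- length(sample_b)
  u_stat <- function(ra) sum(ra) - m * (m + 1) / 2
  pooled <- c(sample_a, sample_b)
  rk <- rank(pooled)
  U <- u_stat(rk[seq_len(m)])
  mu <- m * n / 2
  if (m + n <= exact_max) {
    sets <- combn(m + n, m)
    devs <- apply(sets, 2, function(ix) abs(u_stat(rk[ix]) - mu))
    p <- mean(devs >= abs(U - mu) - 1e-9)
  } else {
    N <- m + n
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sig2 <- m * n / 12 * (N + 1 - tie_term)
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sig2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  list(U = U, p = p)
}
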