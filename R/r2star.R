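#' Dual-echo pair container
#'
#' @param echo1,echo2 intensity `suteac_volume`s on one grid.
#' @param te1_ms,te2_ms echo times in ms with `te2_ms > te1_ms > 0`;
#'   defaults match a dual-echo UTE brain protocol (0.07 / 2.46 ms).
#' @return object of class `suteac_echo_pair`.
#' @export
echo_pair <- function(echo1, echo2, te1_ms = 0.07, te2_ms = 2.46) {
  stopifnot(is_volume(echo1), is_volume(echo2))
  stop_if_grid_mismatch(echo1, echo2)
  if (!(te2_ms > te1_ms && te1_ms > 0))
    stop("echo times must satisfy te2_ms > te1_ms > 0")
  structure(list(echo1 = echo1, echo2 = echo2,
                 te1_ms = te1_ms, te2_ms = te2_ms),
            class = "suteac_echo_pair")
}

#' Compute the R2* map from a dual-echo pair
#'
#' Two-point log-ratio estimate of the effective transverse relaxation
#' rate: R2*(x) = (ln I1(x) - ln I2(x)) / (TE2 - TE1), in 1/ms for echo
#' times in ms (natural logarithm). Intensities are floored before taking
#' logs so that noise-dominated background voxels stay finite, and negative
#' estimates (possible when noise makes I2 > I1) are clamped to 0. Cortical
#' bone, with its very short T2*, shows up as the high-R2* tissue.
#'
#' @param pair a [echo_pair()].
#' @param intensity_floor positive floor applied to both echoes before the
#'   logarithm; default 1e-6 of the global maximum intensity.
#' @return R2* `suteac_volume` (units 1/ms).
#' @export
compute_r2star <- function(pair, intensity_floor = NULL) {
  stopifnot(inherits(pair, "suteac_echo_pair"))
  if (is.null(intensity_floor))
    intensity_floor <- 1e-6 * max(pair$echo1$data, pair$echo2$data)
  if (!is.finite(intensity_floor) || intensity_floor <= 0)
    stop("intensity_floor must be positive")
  dte <- pair$te2_ms - pair$te1_ms
  r <- (log(pmax(pair$echo1$data, intensity_floor)) -
          log(pmax(pair$echo2$data, intensity_floor))) / dte
  r[r < 0] <- 0
  volume(array(r, dim(r)), pair$echo1$spacing, pair$echo1$origin,
         "r2star_per_ms")
}
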