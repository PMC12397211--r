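# Gaze preprocessing: confidence filtering, pixel-to-degree mapping, gap
# interpolation and Savitzky-Golay velocity estimation.

#' Convert horizontal screen pixels to visual degrees
#'
#' Linear, screen-centred mapping assuming the monitor spans `fov_deg`
#' horizontally: `deg = (x_px - screen_width_px/2) * fov_deg /
#' screen_width_px` (80/1920 deg per pixel with the defaults).
#'
#' @param x_px Horizontal pixel position(s).
#' @param screen_width_px Screen width in pixels.
#' @param fov_deg Horizontal field of view in degrees.
#' @return Degrees of visual angle, centred on the screen midline.
#' @export
px_to_deg <- function(x_px, screen_width_px = 1920, fov_deg = 80) {
  (x_px - screen_width_px / 2) * fov_deg / screen_width_px
}

#' @rdname px_to_deg
#' @param x_deg Degrees of visual angle to map back to pixels.
#' @export
deg_to_px <- function(x_deg, screen_width_px = 1920, fov_deg = 80) {
  x_deg * screen_width_px / fov_deg + screen_width_px / 2
}

#' Mark low-confidence gaze samples invalid
#'
#' Samples with pupil-detection confidence below the threshold are flagged
#' invalid; nothing is resampled or removed, so sample alignment is
#' preserved. The number of newly invalidated samples is attached as the
#' `"n_removed"` attribute.
#'
#' @param series Gaze tibble with columns `confidence` and (optionally)
#'   `valid`.
#' @param threshold Confidence threshold in `[0, 1]` (default 0.8).
#' @return The series with an updated logical `valid` column.
#' @export
filter_confidence <- function(series, threshold = 0.8) {
  if (threshold < 0 || threshold > 1)
    stop_input("threshold must be in [0, 1]")
  valid0 <- col_or(series, "valid", rep(TRUE, nrow(series)))
  series$valid <- valid0
  newly <- valid0 & series$confidence < threshold
  series$valid <- valid0 & series$confidence >= threshold
  attr(series, "n_removed") <- sum(newly)
  series
}

#' Linearly interpolate short invalid gaps
#'
#' Runs of invalid samples lasting at most `max_gap` seconds are filled by
#' linear interpolation between the neighbouring valid samples and marked
#' both `valid` and `interpolated`; longer runs (and runs touching the
#' series ends) remain invalid. Originally valid samples are never altered.
#'
#' @param series Gaze tibble with `t`, `gaze_x`, `valid`.
#' @param max_gap Longest gap to fill, seconds (default 0.1).
#' @return The series with `gaze_x` filled where interpolated and a logical
#'   `interpolated` column.
#' @export
interpolate_gaps <- function(series, max_gap = 0.1) {
  n <- nrow(series)
  valid <- col_or(series, "valid", rep(TRUE, n))
  series$interpolated <- rep(FALSE, n)
  if (all(valid) || sum(valid) < 2) {
    series$valid <- valid
    return(series)
  }
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  fill <- approx(series$t[valid], series$gaze_x[valid], xout = series$t,
                 rule = 1)$y
  for (k in which(!r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1 || i1 == n) next                      # edge runs stay invalid
    gap <- series$t[i1 + 1] - series$t[i0 - 1]
    if (gap <= max_gap + 1e-12) {
      idx <- i0:i1
      series$gaze_x[idx] <- fill[idx]
      series$valid[idx] <- TRUE
      series$interpolated[idx] <- TRUE
    }
  }
  series
}

#' Estimate gaze velocity by Savitzky-Golay differentiation
#'
#' Fits a quadratic in a sliding window (default 50 ms, 7 samples at
#' 120 Hz) and returns its analytic derivative at the window centre. Exact
#' on affine signals; samples whose window touches an invalid sample or a
#' series edge get `NA` (never a silent 0).
#'
#' @param series Gaze tibble with `t`, `gaze_x` and optionally `valid`, or
#'   a bare numeric vector (then `sample_rate` must be given).
#' @param window Window length in seconds (default 0.05).
#' @param order Polynomial order (default 2).
#' @param sample_rate Sampling rate in Hz; inferred from `t` if omitted.
#' @return Numeric vector of velocities, deg/s, same length as the input.
#' @export
estimate_velocity <- function(series, window = 0.05, order = 2,
                              sample_rate = NULL) {
  if (is.data.frame(series)) {
    x <- series$gaze_x
    valid <- col_or(series, "valid")
    if (!is.null(valid)) x[!valid] <- NA_real_
    if (is.null(sample_rate))
      sample_rate <- 1 / median(diff(series$t))
  } else {
    x <- as.numeric(series)
    if (is.null(sample_rate))
      stop_input("sample_rate is required when passing a bare vector")
  }
  n_w <- round(window * sample_rate)
  if (n_w < 3)
    stop_input("window of %g s is shorter than 3 samples at %g Hz",
               window, sample_rate)
  if (n_w %% 2 == 0) n_w <- n_w + 1
  sg <- signal::sgolay(p = order, n = n_w, m = 1, ts = 1 / sample_rate)
  cc <- sg[(n_w + 1) / 2, ]                      # central-row derivative
  v <- stats::filter(x, rev(cc), sides = 2)
  as.numeric(v)
}
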