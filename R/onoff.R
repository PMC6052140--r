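#' Spatial-frequency calibration
#'
#' Maps a receptive-field scale (the pixel offset `k` of the eight
#' peripheral samples) to retinal spatial frequency in cycles per degree.
#' The mapping is `sf(k) = sf_at_scale_1 / k`: doubling the surround offset
#' halves the sampled frequency. The default, 22.4 cyc/deg at `k = 1`,
#' corresponds to a 640 x 480 monochrome camera with a 16 mm lens.
#'
#' @param sf_at_scale_1 spatial frequency in cyc/deg sampled at scale 1.
#' @param focal_length_mm,pixel_pitch_mm alternative parameterisation: if
#'   both are given, `sf_at_scale_1` is computed as `1 / (2 * deg_per_pixel)`
#'   where `deg_per_pixel = atan(pixel_pitch_mm / focal_length_mm)` in
#'   degrees (one cycle at scale k spans 2k pixels).
#' @return A `calibration` object.
#' @examples
#' spatial_frequency(1:10, calibration())
#' @export
calibration <- function(sf_at_scale_1 = 22.4,
                        focal_length_mm = NULL, pixel_pitch_mm = NULL) {
  if (!is.null(focal_length_mm) && !is.null(pixel_pitch_mm)) {
    deg_per_pixel <- atan(pixel_pitch_mm / focal_length_mm) * 180 / pi
    sf_at_scale_1 <- 1 / (2 * deg_per_pixel)
  }
  stopifnot(is.numeric(sf_at_scale_1), length(sf_at_scale_1) == 1L,
            sf_at_scale_1 > 0)
  structure(list(sf_at_scale_1 = sf_at_scale_1), class = "onoff_calibration")
}

#' @rdname calibration
#' @param k receptive-field scale(s), positive integer pixel offsets.
#' @param cal a [calibration] object.
#' @export
spatial_frequency <- function(k, cal = calibration()) {
  if (any(k < 1)) stop("scale k must be >= 1")
  cal$sf_at_scale_1 / k
}

#' Aggregation rule for signed receptive-field responses
#'
#' Positions are classified by the sign of the center-minus-surround
#' response; the aggregator controls how classified responses are combined
#' into ON and OFF strengths.
#'
#' Modes:
#' \describe{
#'   \item{power}{`on = sum(r^gamma)` over `r > 0`, `off = sum(|r|^gamma)`
#'     over `r < 0`. The default (`gamma = 2`) weights the few
#'     large-magnitude responses on letter strokes above the many weak
#'     halo responses, which is what makes thin dark text OFF-dominant.}
#'   \item{sum}{linear magnitude sums (`gamma = 1`). For frames whose
#'     non-background content is interior to the sampling grid this is
#'     provably balanced (the signed responses sum to exactly zero), so it
#'     cannot express polarity dominance of interior content.}
#'   \item{count}{strengths equal the position counts.}
#'   \item{threshold}{linear sums and counts restricted to `|r| > threshold`.}
#' }
#' Zero responses never contribute to either channel.
#'
#' @param mode one of `"power"`, `"sum"`, `"count"`, `"threshold"`.
#' @param gamma exponent for power mode, `>= 1`.
#' @param threshold gray-level cut for threshold mode, `>= 0`.
#' @return An `aggregator` spec.
#' @export
aggregator <- function(mode = c("power", "sum", "count", "threshold"),
                       gamma = 2, threshold = 0) {
  mode <- match.arg(mode)
  stopifnot(gamma >= 1, threshold >= 0)
  structure(list(mode = mode, gamma = gamma, threshold = threshold),
            class = "onoff_aggregator")
}

#' Aggregate signed responses into ON/OFF strengths and counts
#'
#' @param responses numeric vector of signed center-surround responses in
#'   gray levels.
#' @param spec an [aggregator].
#' @return Named list: `on_strength`, `off_strength`, `on_count`,
#'   `off_count`.
#' @examples
#' aggregate_responses(c(10, -10), aggregator("power", gamma = 2))
#' @export
aggregate_responses <- function(responses, spec = aggregator()) {
  if (!all(is.finite(responses))) stop("responses must be finite")
  pos <- responses[responses > 0]
  neg <- -responses[responses < 0]
  out <- switch(spec$mode,
    power = list(on_strength = sum(pos^spec$gamma),
                 off_strength = sum(neg^spec$gamma),
                 on_count = length(pos), off_count = length(neg)),
    sum = list(on_strength = sum(pos), off_strength = sum(neg),
               on_count = length(pos), off_count = length(neg)),
    count = list(on_strength = length(pos), off_strength = length(neg),
                 on_count = length(pos), off_count = length(neg)),
    threshold = {
      p <- pos[pos > spec$threshold]
      n <- neg[neg > spec$threshold]
      list(on_strength = sum(p), off_strength = sum(n),
           on_count = length(p), off_count = length(n))
    })
  lapply(out, as.numeric)
}

#' Regular sampling grid of receptive-field centers
#'
#' Every interior pixel at least `margin` pixels from each frame edge is a
#' center, so all eight peripheral samples stay in-frame for every scale up
#' to `margin`. One shared grid is used for all scales. A 640 x 480 frame
#' with margin 10 yields (640 - 20) * (480 - 20) = 285,200 positions.
#'
#' @param width,height frame dimensions in pixels.
#' @param margin sampling margin, normally `max(scales)`.
#' @return Data frame with 0-based columns `x`, `y`, one row per center.
#' @export
sampling_grid <- function(width, height, margin) {
  if (width <= 2 * margin) {
    stop(sprintf("empty grid: width %d <= 2 * margin %d", width, margin))
  }
  if (height <= 2 * margin) {
    stop(sprintf("empty grid: height %d <= 2 * margin %d", height, margin))
  }
  xs <- margin:(width - margin - 1L)
  ys <- margin:(height - margin - 1L)
  data.frame(x = rep(xs, times = length(ys)),
             y = rep(ys, each = length(xs)))
}

#' Single center-surround receptive-field response
#'
#' The response at `(x, y)` and scale `k` is the center gray level minus
#' the mean of the 8 peripheral pixels at offsets `(+-k, 0)`, `(0, +-k)`,
#' `(+-k, +-k)`. Positive responses are ON-stimulating (bright center on
#' darker surround), negative responses OFF-stimulating, zero neither.
#'
#' @param frame a [gray_frame].
#' @param x,y 0-based pixel coordinates of the center (x = column, y = row).
#' @param k scale: pixel offset of the surround, `>= 1`.
#' @return Signed response in gray levels.
#' @export
rf_response <- function(frame, x, y, k) {
  stopifnot(k >= 1)
  h <- nrow(frame); w <- ncol(frame)
  if (x - k < 0 || x + k >= w || y - k < 0 || y + k >= h) {
    stop(sprintf("surround of (%d, %d) at scale %d falls outside the %dx%d frame",
                 x, y, k, w, h))
  }
  M <- unclass(frame)
  r <- y + 1L; c <- x + 1L
  surround <- c(M[r - k, c], M[r + k, c], M[r, c - k], M[r, c + k],
                M[r - k, c - k], M[r - k, c + k],
                M[r + k, c - k], M[r + k, c + k])
  M[r, c] - mean(surround)
}

# Signed response matrix for every grid center at one scale (vectorised).
# rows/cols are 1-based matrix indices of the grid interior.
response_matrix <- function(M, rows, cols, k) {
  S <- (M[rows - k, cols] + M[rows + k, cols] +
        M[rows, cols - k] + M[rows, cols + k] +
        M[rows - k, cols - k] + M[rows - k, cols + k] +
        M[rows + k, cols - k] + M[rows + k, cols + k]) / 8
  M[rows, cols] - S
}

#' Analyze a frame at multiple receptive-field scales
#'
#' Scans the frame with center-surround receptive fields at every position
#' of one shared sampling grid (margin = `max(scales)`), classifies each
#' position as ON- or OFF-stimulating by response sign, and aggregates
#' per-scale strengths. Deterministic: identical frames give identical
#' profiles.
#'
#' @param frame a [gray_frame] (or matrix / 3-channel array, converted via
#'   [to_grayscale]).
#' @param scales strictly increasing positive integer scales (default 1:10).
#' @param cal a [calibration] for the cyc/deg labels.
#' @param spec an [aggregator].
#' @return An `onoff_profile`: a data frame with one row per scale and
#'   columns `scale_k`, `spatial_frequency_cpd`, `on_strength`,
#'   `off_strength`, `on_count`, `off_count`, `polarity_index`, plus frame
#'   metadata in attributes (`frame_width`, `frame_height`,
#'   `mean_luminance`, `margin`, `aggregator`).
#' @examples
#' txt <- render_text(text_stimulus_spec("ON OFF", glyph_height = 24))
#' analyze_frame(txt)
#' @export
analyze_frame <- function(frame, scales = 1:10, cal = calibration(),
                          spec = aggregator()) {
  frame <- to_grayscale(frame)
  scales <- as.integer(scales)
  if (length(scales) < 1L || any(scales < 1L) || is.unsorted(scales, strictly = TRUE)) {
    stop("scales must be a strictly increasing sequence of positive integers")
  }
  m <- max(scales)
  h <- nrow(frame); w <- ncol(frame)
  # validates the grid and fixes the shared margin
  sampling_grid(w, h, m)
  rows <- (m + 1L):(h - m)
  cols <- (m + 1L):(w - m)
  M <- unclass(frame)
  per_scale <- lapply(scales, function(k) {
    r <- response_matrix(M, rows, cols, k)
    aggregate_responses(as.numeric(r), spec)
  })
  on_s <- vapply(per_scale, `[[`, numeric(1), "on_strength")
  off_s <- vapply(per_scale, `[[`, numeric(1), "off_strength")
  prof <- data.frame(
    scale_k = scales,
    spatial_frequency_cpd = spatial_frequency(scales, cal),
    on_strength = on_s,
    off_strength = off_s,
    on_count = vapply(per_scale, `[[`, numeric(1), "on_count"),
    off_count = vapply(per_scale, `[[`, numeric(1), "off_count"),
    polarity_index = ifelse(on_s + off_s > 0, (on_s - off_s) / (on_s + off_s),
                            NA_real_)
  )
  structure(prof,
            class = c("onoff_profile", "data.frame"),
            frame_width = w, frame_height = h,
            mean_luminance = mean(M), margin = m,
            aggregator = spec)
}

#' Polarity index: normalized ON/OFF balance
#'
#' `(on - off) / (on + off)`: +1 pure ON, -1 pure OFF, 0 balanced. When
#' both strengths are zero (e.g. a uniform frame) the index is undefined
#' and reported as `NA`, never as 0.
#'
#' @param profile an `onoff_profile` from [analyze_frame].
#' @param k scale(s) to extract; `NULL` (default) returns all scales.
#' @return Named numeric vector of polarity indices (names = scales).
#' @export
polarity_index <- function(profile, k = NULL) {
  stopifnot(inherits(profile, "onoff_profile"))
  idx <- if (is.null(k)) seq_len(nrow(profile)) else match(k, profile$scale_k)
  if (anyNA(idx)) stop("scale not present in profile: ", paste(k[is.na(idx)], collapse = ", "))
  stats::setNames(profile$polarity_index[idx], profile$scale_k[idx])
}

#' OFF share of total strength
#'
#' `off / (on + off)` per scale; 0.5 is balanced, 1 pure OFF. `NA` when
#' both strengths are zero.
#'
#' @inheritParams polarity_index
#' @return Named numeric vector.
#' @export
off_share <- function(profile, k = NULL) {
  (1 - polarity_index(profile, k)) / 2
}

#' @export
print.onoff_profile <- function(x, ...) {
  cat(sprintf("ON/OFF profile of a %d x %d frame (mean luminance %.1f, margin %d, aggregator %s)\n",
              attr(x, "frame_width"), attr(x, "frame_height"),
              attr(x, "mean_luminance"), attr(x, "margin"),
              attr(x, "aggregator")$mode))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Plot ON and OFF strength against spatial frequency
#'
#' ON strength in green and OFF strength in red over the sampled
#' cyc/deg range (log-scaled x axis), the conventional display for
#' relative pathway input strength.
#'
#' @param profile an `onoff_profile`.
#' @param main plot title.
#' @param file optional PNG path; when given the plot is written there.
#' @return Invisibly, the profile.
#' @export
plot_profile <- function(profile, main = "Relative ON and OFF input strength",
                         file = NULL) {
  stopifnot(inherits(profile, "onoff_profile"))
  if (!is.null(file)) {
    grDevices::png(file, width = 720, height = 480)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  sf <- profile$spatial_frequency_cpd
  ylim <- range(0, profile$on_strength, profile$off_strength)
  graphics::plot(sf, profile$on_strength, type = "b", col = "forestgreen",
                 lwd = 2, log = "x", xlim = rev(range(sf)), ylim = ylim,
                 xlab = "spatial frequency (cyc/deg)",
                 ylab = "aggregated strength", main = main)
  graphics::lines(sf, profile$off_strength, type = "b", col = "red2", lwd = 2)
  graphics::legend("topleft", legend = c("ON", "OFF"), lwd = 2,
                   col = c("forestgreen", "red2"), bty = "n")
  invisible(profile)
}
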