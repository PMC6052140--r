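# Embedded axis-aligned stroke font on a 3 x 5 coordinate grid
# (x in 0..2, y in 0..4, y = 0 at the top). Each glyph is a list of
# segments c(x1, y1, x2, y2); segments are horizontal or vertical only so
# stroke width can be controlled exactly. Legibility is approximate by
# design: only the contrast structure (thin strokes on a uniform field)
# matters for the analysis.
.stroke_font <- list(
  "A" = list(c(0,0,2,0), c(0,0,0,4), c(2,0,2,4), c(0,2,2,2)),
  "B" = list(c(0,0,0,4), c(0,0,2,0), c(0,2,2,2), c(0,4,2,4), c(2,0,2,2), c(2,2,2,4)),
  "C" = list(c(0,0,2,0), c(0,0,0,4), c(0,4,2,4)),
  "D" = list(c(0,0,0,4), c(0,0,1,0), c(0,4,1,4), c(2,1,2,3), c(1,0,2,1), c(1,4,2,3)),
  "E" = list(c(0,0,0,4), c(0,0,2,0), c(0,2,2,2), c(0,4,2,4)),
  "F" = list(c(0,0,0,4), c(0,0,2,0), c(0,2,2,2)),
  "G" = list(c(0,0,2,0), c(0,0,0,4), c(0,4,2,4), c(2,2,2,4), c(1,2,2,2)),
  "H" = list(c(0,0,0,4), c(2,0,2,4), c(0,2,2,2)),
  "I" = list(c(1,0,1,4), c(0,0,2,0), c(0,4,2,4)),
  "J" = list(c(2,0,2,4), c(0,4,2,4), c(0,3,0,4)),
  "K" = list(c(0,0,0,4), c(0,2,2,2), c(2,0,2,2), c(2,2,2,4)),
  "L" = list(c(0,0,0,4), c(0,4,2,4)),
  "M" = list(c(0,0,0,4), c(2,0,2,4), c(0,0,2,0), c(1,0,1,2)),
  "N" = list(c(0,0,0,4), c(2,0,2,4), c(0,0,2,0)),
  "O" = list(c(0,0,2,0), c(0,4,2,4), c(0,0,0,4), c(2,0,2,4)),
  "P" = list(c(0,0,0,4), c(0,0,2,0), c(0,2,2,2), c(2,0,2,2)),
  "Q" = list(c(0,0,2,0), c(0,4,2,4), c(0,0,0,4), c(2,0,2,4), c(1,3,1,4)),
  "R" = list(c(0,0,0,4), c(0,0,2,0), c(0,2,2,2), c(2,0,2,2), c(2,3,2,4)),
  "S" = list(c(0,0,2,0), c(0,2,2,2), c(0,4,2,4), c(0,0,0,2), c(2,2,2,4)),
  "T" = list(c(0,0,2,0), c(1,0,1,4)),
  "U" = list(c(0,0,0,4), c(2,0,2,4), c(0,4,2,4)),
  "V" = list(c(0,0,0,3), c(2,0,2,3), c(0,3,1,4), c(2,3,1,4)),
  "W" = list(c(0,0,0,4), c(2,0,2,4), c(0,4,2,4), c(1,2,1,4)),
  "X" = list(c(0,0,0,1), c(2,0,2,1), c(1,1,1,3), c(0,3,0,4), c(2,3,2,4), c(0,2,2,2)),
  "Y" = list(c(0,0,0,2), c(2,0,2,2), c(0,2,2,2), c(1,2,1,4)),
  "Z" = list(c(0,0,2,0), c(0,4,2,4), c(1,1,1,3)),
  "0" = list(c(0,0,2,0), c(0,4,2,4), c(0,0,0,4), c(2,0,2,4)),
  "1" = list(c(1,0,1,4), c(0,4,2,4)),
  "2" = list(c(0,0,2,0), c(2,0,2,2), c(0,2,2,2), c(0,2,0,4), c(0,4,2,4)),
  "3" = list(c(0,0,2,0), c(0,2,2,2), c(0,4,2,4), c(2,0,2,4)),
  "4" = list(c(0,0,0,2), c(2,0,2,4), c(0,2,2,2)),
  "5" = list(c(0,0,2,0), c(0,0,0,2), c(0,2,2,2), c(2,2,2,4), c(0,4,2,4)),
  "6" = list(c(0,0,2,0), c(0,0,0,4), c(0,2,2,2), c(2,2,2,4), c(0,4,2,4)),
  "7" = list(c(0,0,2,0), c(2,0,2,4)),
  "8" = list(c(0,0,2,0), c(0,2,2,2), c(0,4,2,4), c(0,0,0,4), c(2,0,2,4)),
  "9" = list(c(0,0,2,0), c(0,0,0,2), c(0,2,2,2), c(2,0,2,4), c(0,4,2,4)),
  "." = list(c(1,4,1,4)),
  "-" = list(c(0,2,2,2)),
  " " = list()
)

# vertical segments in diagonal-ish glyphs (V) are still axis-aligned:
# c(0,3,1,4) is drawn as an L-shaped pair of unit segments.
.expand_segment <- function(seg) {
  if (seg[1] == seg[3] || seg[2] == seg[4]) return(list(seg))
  # split a one-step diagonal into vertical + horizontal unit segments
  list(c(seg[1], seg[2], seg[1], seg[4]), c(seg[1], seg[4], seg[3], seg[4]))
}

#' Specification of a polarity-controlled text stimulus
#'
#' Describes a line (or `\n`-separated lines) of text rendered with the
#' package's embedded axis-aligned stroke font on a uniform background.
#' `polarity = "dark_on_light"` gives foreground 0 on background 255 (the
#' conventional reading page); `"light_on_dark"` the exact photometric
#' inverse. With levels (0, 255) the two polarities are bitwise inverses
#' of each other.
#'
#' @param text character string; letters A-Z (case-folded), digits, space,
#'   `.`, `-` and newlines are supported.
#' @param polarity `"dark_on_light"` or `"light_on_dark"`.
#' @param glyph_height capital height in pixels.
#' @param stroke_width stroke thickness in pixels, `>= 1`.
#' @param foreground_level,background_level gray levels; defaults follow
#'   `polarity`.
#' @param margin border of pure background around the text block, in
#'   pixels. Keep `margin >= analysis margin + max scale` so every stroke
#'   pixel is interior to the sampling grid.
#' @param width,height frame size in pixels; `NULL` sizes the frame to the
#'   text block plus margins.
#' @return A `text_stimulus_spec` list.
#' @export
text_stimulus_spec <- function(text,
                               polarity = c("dark_on_light", "light_on_dark"),
                               glyph_height = 32, stroke_width = 1,
                               foreground_level = NULL,
                               background_level = NULL,
                               margin = 24, width = NULL, height = NULL) {
  polarity <- match.arg(polarity)
  if (!nzchar(text)) stop("text must be non-empty")
  stopifnot(stroke_width >= 1, glyph_height >= 8, margin >= 0)
  if (is.null(foreground_level)) {
    foreground_level <- if (polarity == "dark_on_light") 0 else 255
  }
  if (is.null(background_level)) {
    background_level <- if (polarity == "dark_on_light") 255 else 0
  }
  if (foreground_level == background_level) {
    stop("foreground and background levels must differ")
  }
  structure(list(text = text, polarity = polarity,
                 glyph_height = as.integer(glyph_height),
                 stroke_width = as.integer(stroke_width),
                 foreground_level = foreground_level,
                 background_level = background_level,
                 margin = as.integer(margin),
                 width = width, height = height),
            class = "text_stimulus_spec")
}

#' Render a text stimulus to a grayscale frame
#'
#' Deterministic for a fixed spec (and seed): glyphs come from an embedded
#' stroke font, so output is bit-reproducible across platforms with no
#' system-font dependency. Strokes are axis-aligned segments thickened to
#' `stroke_width` pixels. The achieved ink fraction (share of pixels at
#' the foreground level) is attached as attribute `ink_fraction`.
#'
#' @param spec a [text_stimulus_spec].
#' @param seed reserved for randomized layout variants; the current
#'   renderer has no stochastic element and ignores it.
#' @return A [gray_frame] with attribute `ink_fraction`.
#' @examples
#' f <- render_text(text_stimulus_spec("READ", glyph_height = 24))
#' attr(f, "ink_fraction")
#' @export
render_text <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "text_stimulus_spec"))
  gh <- spec$glyph_height
  sw <- spec$stroke_width
  gw <- max(5L, as.integer(round(0.6 * gh)))
  # gap scales with stroke width so very thick glyphs never merge
  gap <- max(as.integer(round(0.4 * gw)), sw + 2L)
  pitch <- as.integer(round(1.5 * gh))

  lines <- strsplit(toupper(spec$text), "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0L) lines <- ""
  widths <- vapply(lines, function(ln) {
    n <- nchar(ln)
    if (n == 0L) 0L else n * gw + (n - 1L) * gap
  }, integer(1))
  block_w <- max(widths)
  block_h <- (length(lines) - 1L) * pitch + gh

  w <- if (is.null(spec$width)) block_w + 2L * spec$margin else as.integer(spec$width)
  h <- if (is.null(spec$height)) block_h + 2L * spec$margin else as.integer(spec$height)
  if (block_w + 2L * spec$margin > w || block_h + 2L * spec$margin > h) {
    stop(sprintf("text block %dx%d px plus margin %d does not fit a %dx%d frame",
                 block_w, block_h, spec$margin, w, h))
  }

  M <- matrix(spec$background_level, nrow = h, ncol = w)
  lo <- (sw - 1L) %/% 2L
  hi <- sw %/% 2L
  x0 <- spec$margin
  y0 <- spec$margin
  for (li in seq_along(lines)) {
    chars <- strsplit(lines[li], "")[[1]]
    cx <- x0
    cy <- y0 + (li - 1L) * pitch
    for (ch in chars) {
      glyph <- .stroke_font[[ch]]
      if (is.null(glyph)) stop(sprintf("unsupported character '%s'", ch))
      for (seg0 in glyph) {
        for (seg in .expand_segment(seg0)) {
          xs <- cx + round(seg[c(1, 3)] / 2 * (gw - 1L))
          ys <- cy + round(seg[c(2, 4)] / 4 * (gh - 1L))
          r1 <- max(1L, min(ys) - lo + 1L); r2 <- min(h, max(ys) + hi + 1L)
          c1 <- max(1L, min(xs) - lo + 1L); c2 <- min(w, max(xs) + hi + 1L)
          M[r1:r2, c1:c2] <- spec$foreground_level
        }
      }
      cx <- cx + gw + gap
    }
  }
  frame <- gray_frame(M)
  attr(frame, "ink_fraction") <- mean(M == spec$foreground_level &
                                        spec$foreground_level != spec$background_level)
  frame
}

#' Match two frames to a common mean luminance
#'
#' Shifts each frame about its mean so both means equal `target_mean`
#' (a pure additive offset, which the center-surround analysis is exactly
#' invariant to). A shift that would push any pixel outside \[0, 255\] is
#' an error reporting the feasible target range; pixels are never clipped
#' silently.
#'
#' @param a,b [gray_frame]s.
#' @param target_mean desired mean gray level for both frames.
#' @return List of the two shifted frames, means within 0.5 of the target.
#' @export
match_mean_luminance <- function(a, b, target_mean = 128) {
  list(shift_mean(a, target_mean), shift_mean(b, target_mean))
}

shift_mean <- function(frame, target_mean) {
  m <- mean(frame)
  delta <- target_mean - m
  if (abs(delta) < 1e-12) return(frame)
  lo_t <- m - min(frame)           # smallest feasible target
  hi_t <- m + 255 - max(frame)     # largest feasible target
  if (target_mean < lo_t - 1e-9 || target_mean > hi_t + 1e-9) {
    stop(sprintf(paste0("luminance matching would clip: target %.2f outside ",
                        "feasible range [%.2f, %.2f] for this frame"),
                 target_mean, lo_t, hi_t))
  }
  out <- gray_frame(unclass(frame) + delta)
  attr(out, "ink_fraction") <- attr(frame, "ink_fraction")
  out
}

#' Checkerboard control stimulus
#'
#' Two-level periodic pattern, phase fixed at the origin. Because the
#' pattern maps onto its own photometric inverse under a half-period
#' translation, ON and OFF strengths are balanced up to border effects at
#' every scale.
#'
#' @param width,height frame size in pixels.
#' @param square square size in pixels, `>= 1`.
#' @param levels two gray values.
#' @return A [gray_frame].
#' @export
checkerboard <- function(width, height, square = 8, levels = c(0, 255)) {
  stopifnot(square >= 1, length(levels) == 2)
  xi <- (seq_len(width) - 1L) %/% square
  yi <- (seq_len(height) - 1L) %/% square
  parity <- outer(yi, xi, `+`) %% 2L
  gray_frame(matrix(levels[parity + 1L], nrow = height, ncol = width))
}

#' 1/f-noise natural-scene surrogate
#'
#' Gaussian noise shaped to a 1/f amplitude spectrum (the canonical
#' second-order statistic of natural scenes), rescaled to mean 128 with
#' all values inside \[20, 235\]. Deterministic per seed. Because the
#' generative distribution is symmetric about its mean, ON and OFF
#' strengths are balanced in expectation at every scale.
#'
#' @param width,height frame size, each `>= 64`.
#' @param seed integer seed.
#' @return A [gray_frame].
#' @export
pink_noise <- function(width = 128, height = width, seed = 1) {
  stopifnot(width >= 64, height >= 64)
  z <- with_preserved_seed(seed, matrix(stats::rnorm(width * height), height, width))
  fx <- seq_len(width) - 1L
  fx[fx > width / 2] <- fx[fx > width / 2] - width
  fy <- seq_len(height) - 1L
  fy[fy > height / 2] <- fy[fy > height / 2] - height
  f <- sqrt(outer((fy / height)^2, (fx / width)^2, `+`))
  amp <- 1 / f
  amp[1, 1] <- 0
  img <- Re(stats::fft(stats::fft(z) * amp, inverse = TRUE)) / (width * height)
  dev <- img - mean(img)
  dev <- dev * (107 / max(abs(dev)))
  gray_frame(128 + dev)
}

# run expr with a fixed seed, restoring the caller's RNG state afterwards
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}
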