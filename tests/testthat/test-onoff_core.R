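test_that("grayscale conversion uses BT.601 weights and passes gray input through", {
  arr <- array(100, c(4, 4, 3))
  expect_equal(unclass(to_grayscale(arr)), matrix(100, 4, 4))
  white <- array(255, c(2, 2, 3))
  expect_equal(unclass(to_grayscale(white)), matrix(255, 2, 2))
  mixed <- array(0, c(1, 1, 3))
  mixed[, , ] <- c(100, 200, 50)
  expect_equal(to_grayscale(mixed)[1, 1], 153, tolerance = 0.5 / 153)
  m <- matrix(17, 3, 5)
  expect_identical(unclass(to_grayscale(m)), m)
  expect_error(to_grayscale(array(1, c(2, 2, 2))), "channels")
})

test_that("sampling grid covers every interior pixel exactly once", {
  g <- sampling_grid(22, 22, 10)
  expect_equal(nrow(g), 4)
  expect_equal(nrow(unique(g)), 4)
  expect_true(all(g$x >= 10 & g$x < 12 & g$y >= 10 & g$y < 12))
  g2 <- sampling_grid(30, 25, 5)
  expect_equal(nrow(g2), (30 - 10) * (25 - 10))
  expect_error(sampling_grid(20, 480, 10), "width")
  expect_error(sampling_grid(480, 20, 10), "height")
})

test_that("receptive-field response is center minus mean of 8 surround pixels", {
  uni <- gray_frame(matrix(128, 9, 9))
  for (k in 1:3) expect_equal(rf_response(uni, 4, 4, k), 0)

  M <- matrix(0, 5, 5); M[3, 3] <- 255
  expect_equal(rf_response(gray_frame(M), 2, 2, 1), 255)

  # width-1 horizontal dark stroke: 2 in-stroke surround pixels at 0,
  # 6 bright ones at 255
  M2 <- matrix(255, 7, 7); M2[4, ] <- 0
  expect_equal(rf_response(gray_frame(M2), 3, 3, 1), -(6 * 255) / 8)
  expect_equal(-(6 * 255) / 8, -191.25)

  expect_error(rf_response(uni, 0, 4, 1), "outside")
})

test_that("aggregation modes follow their formulas and ignore zero responses", {
  r <- aggregate_responses(c(10, -10), aggregator("power", gamma = 2))
  expect_equal(r[c("on_strength", "off_strength", "on_count", "off_count")],
               list(on_strength = 100, off_strength = 100,
                    on_count = 1, off_count = 1))

  thin <- c(96, 96, -191.25)
  pw <- aggregate_responses(thin, aggregator("power", gamma = 2))
  expect_equal(pw$on_strength, 2 * 96^2)
  expect_equal(pw$off_strength, 191.25^2, tolerance = 1e-12)
  expect_equal(pw$off_strength / (pw$on_strength + pw$off_strength),
               0.665, tolerance = 1e-3)

  ct <- aggregate_responses(thin, aggregator("count"))
  expect_equal(c(ct$on_strength, ct$off_strength), c(2, 1))

  sm <- aggregate_responses(c(5, 0, 0, -3), aggregator("sum"))
  expect_equal(c(sm$on_strength, sm$off_strength, sm$on_count, sm$off_count),
               c(5, 3, 1, 1))

  th <- aggregate_responses(c(5, 40, -3, -50), aggregator("threshold", threshold = 10))
  expect_equal(c(th$on_strength, th$off_strength, th$on_count, th$off_count),
               c(40, 50, 1, 1))

  z <- aggregate_responses(numeric(0), aggregator())
  expect_true(all(unlist(z) == 0))
})

test_that("spatial-frequency calibration follows the 1/k law", {
  cal <- calibration()
  expect_identical(spatial_frequency(1, cal), 22.4)
  expect_equal(spatial_frequency(2, cal), 11.2)
  expect_equal(spatial_frequency(10, cal), 2.24)
  expect_error(spatial_frequency(0, cal), ">= 1")
  cal2 <- calibration(sf_at_scale_1 = 30)
  expect_equal(spatial_frequency(3, cal2), 10)
  # lens/pixel parameterisation reduces to 1/(2 deg-per-pixel)
  cal3 <- calibration(focal_length_mm = 16, pixel_pitch_mm = 16 * tan(pi / 180))
  expect_equal(cal3$sf_at_scale_1, 0.5)
})

test_that("analyze_frame matches the naive double-loop oracle exactly", {
  for (seed in c(7, 8)) {
    f <- structured_frame(32, 28, seed)
    ref <- naive_profile(f, 1:3, gamma = 2, mode = "power")
    prof <- analyze_frame(f, scales = 1:3, spec = aggregator("power", gamma = 2))
    expect_equal(prof$on_strength, unname(ref[, "on"]))
    expect_equal(prof$off_strength, unname(ref[, "off"]))
    expect_equal(prof$on_count, unname(ref[, "n_on"]))
    expect_equal(prof$off_count, unname(ref[, "n_off"]))
  }
  f <- structured_frame(24, 24, 9)
  ref <- naive_profile(f, c(1, 2), mode = "count")
  prof <- analyze_frame(f, scales = c(1, 2), spec = aggregator("count"))
  expect_equal(prof$on_strength, unname(ref[, "on"]))
  expect_equal(prof$off_strength, unname(ref[, "off"]))
})

test_that("uniform frames give a zero profile with undefined polarity", {
  prof <- analyze_frame(gray_frame(matrix(77, 40, 40)), scales = 1:5)
  expect_true(all(prof$on_strength == 0 & prof$off_strength == 0))
  expect_true(all(prof$on_count == 0 & prof$off_count == 0))
  expect_true(all(is.na(prof$polarity_index)))
  expect_true(all(is.na(polarity_index(prof))))
})

test_that("photometric inversion swaps ON and OFF exactly in every mode", {
  f <- structured_frame(40, 30, 11)
  fi <- invert_frame(f)
  for (spec in list(aggregator("power", gamma = 2), aggregator("sum"),
                    aggregator("count"), aggregator("threshold", threshold = 15))) {
    a <- analyze_frame(f, scales = 1:4, spec = spec)
    b <- analyze_frame(fi, scales = 1:4, spec = spec)
    expect_identical(a$on_strength, b$off_strength)
    expect_identical(a$off_strength, b$on_strength)
    expect_identical(a$on_count, b$off_count)
    expect_identical(a$off_count, b$on_count)
  }
})

test_that("additive brightness offsets leave profiles bit-identical", {
  f <- render_text(text_stimulus_spec("AB", glyph_height = 16, margin = 12,
                                      foreground_level = 40,
                                      background_level = 200))
  base <- analyze_frame(f, scales = 1:6)
  for (c_off in c(-20, 15, 35)) {
    shifted <- gray_frame(unclass(f) + c_off)
    expect_identical(profile_values(analyze_frame(shifted, scales = 1:6)),
                     profile_values(base))
  }
})

test_that("signed responses over the grid sum to zero for interior content", {
  # content pixels at distance >= margin + k from every edge appear once
  # as center (+1) and 8 times as surround (-1/8)
  m <- 6
  M <- matrix(50, 40, 40)
  set.seed(42)
  M[(2 * m + 1):(40 - 2 * m), (2 * m + 1):(40 - 2 * m)] <-
    sample(0:255, (40 - 4 * m)^2, replace = TRUE)
  f <- gray_frame(M)
  rows <- (m + 1):(40 - m); cols <- (m + 1):(40 - m)
  for (k in 1:m) {
    resp <- vapply(seq_len(length(rows) * length(cols)) - 1L, function(i) {
      x <- cols[i %% length(cols) + 1L] - 1L
      y <- rows[i %/% length(cols) + 1L] - 1L
      rf_response(f, x, y, k)
    }, numeric(1))
    expect_equal(sum(resp), 0, tolerance = 1e-9)
  }
  # corollary: linear magnitude sums balance ON and OFF exactly
  prof <- analyze_frame(f, scales = 1:m, spec = aggregator("sum"))
  expect_equal(prof$on_strength, prof$off_strength, tolerance = 1e-12)
})

test_that("polarity index is the normalized ON/OFF difference", {
  f <- structured_frame(26, 26, 5)
  prof <- analyze_frame(f, scales = 1:2)
  expect_equal(unname(polarity_index(prof, 1)),
               (prof$on_strength[1] - prof$off_strength[1]) /
                 (prof$on_strength[1] + prof$off_strength[1]))
  expect_equal(unname(off_share(prof)),
               prof$off_strength / (prof$on_strength + prof$off_strength))
  expect_error(polarity_index(prof, 9), "not present")
  # frozen value from direct evaluation of (on - off)/(on + off)
  on <- 2 * 96^2; off <- 191.25^2
  expect_equal((on - off) / (on + off), -0.32985, tolerance = 1e-4)
})

test_that("profile metadata and frequency labels are carried along", {
  f <- structured_frame(30, 26, 3)
  prof <- analyze_frame(f, scales = 1:5, cal = calibration(20))
  expect_equal(prof$spatial_frequency_cpd, 20 / (1:5))
  expect_true(all(diff(prof$spatial_frequency_cpd) < 0))
  expect_equal(attr(prof, "frame_width"), 30)
  expect_equal(attr(prof, "frame_height"), 26)
  expect_equal(attr(prof, "mean_luminance"), mean(f))
  expect_equal(attr(prof, "margin"), 5)
  expect_error(analyze_frame(f, scales = c(3, 2)), "strictly increasing")
})
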