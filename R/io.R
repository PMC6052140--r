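#' Read a raster image as a grayscale frame
#'
#' Supports PNG and TIFF (via the png and tiff packages) and PGM (both
#' ASCII `P2` and binary `P5`, parsed directly). Color inputs are
#' converted with [to_grayscale]; 8-bit values are returned on the 0--255
#' scale.
#'
#' @param path image file path.
#' @return A [gray_frame].
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = tiff::readTIFF(path) * 255,
    pgm = ,
    pnm = read_pgm(path),
    stop(sprintf("unsupported image format '%s' for %s", ext, path)))
  to_grayscale(arr)
}

# minimal PGM (P2/P5) reader; maxval <= 255 assumed (8-bit pipeline)
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (!length(ch) || !nzchar(ch)) break
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (!length(ch) || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) break else next
      }
      tok <- paste0(tok, ch)
    }
    tok
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop(path, " is not a PGM (P2/P5) file")
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (anyNA(c(w, h, maxval)) || w < 1 || h < 1) {
    stop("malformed PGM header in ", path)
  }
  if (maxval > 255) stop("only 8-bit PGM supported: ", path)
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n = w * h))
  } else {
    scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  if (length(vals) != w * h) stop("truncated PGM pixel data in ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a grayscale frame to disk
#'
#' PNG via the png package; PGM written as ASCII `P2` (diffable plain
#' text). Values are rounded to integers and must lie in \[0, 255\].
#'
#' @param frame a [gray_frame].
#' @param path output path ending in `.png` or `.pgm`.
#' @return Invisibly, `path`.
#' @export
write_frame <- function(frame, path) {
  M <- round(unclass(to_grayscale(frame)))
  if (min(M) < 0 || max(M) > 255) stop("pixel values outside [0, 255]")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(M / 255, path)
  } else if (ext %in% c("pgm", "pnm")) {
    lines <- c("P2", sprintf("%d %d", ncol(M), nrow(M)), "255",
               apply(M, 1, paste, collapse = " "))
    writeLines(lines, path)
  } else {
    stop("unsupported output format: ", path)
  }
  invisible(path)
}

# order file names by natural numeric chunks: f2 < f10
natural_order <- function(names) {
  keys <- lapply(names, function(nm) {
    chunks <- regmatches(nm, gregexpr("[0-9]+|[^0-9]+", nm))[[1]]
    nums <- suppressWarnings(as.numeric(chunks))
    list(chunks = chunks, nums = nums)
  })
  maxlen <- max(vapply(keys, function(k) length(k$chunks), integer(1)))
  cmp <- matrix("", nrow = length(names), ncol = maxlen)
  for (i in seq_along(keys)) {
    k <- keys[[i]]
    for (j in seq_along(k$chunks)) {
      cmp[i, j] <- if (is.na(k$nums[j])) k$chunks[j] else
        sprintf("%020.5f", k$nums[j])
    }
  }
  do.call(order, c(lapply(seq_len(maxlen), function(j) cmp[, j]),
                   list(names)))
}

#' Read an image file or a directory of frames
#'
#' A directory is treated as a video: every readable image file inside is
#' loaded in natural numeric filename order (`f1, f2, f10`). All frames
#' must share one size.
#'
#' @param path image file or directory.
#' @return List of [gray_frame]s, named by source filename.
#' @export
read_frames <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|pgm|pnm|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (!length(files)) stop("no readable frames in directory ", path)
    files <- files[natural_order(basename(files))]
    frames <- lapply(files, read_frame)
    dims <- vapply(frames, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      bad <- files[which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]]
      stop(sprintf("frame %s has dimensions %dx%d, expected %dx%d",
                   basename(bad), dims[2, match(bad, files)],
                   dims[1, match(bad, files)], dims[2, 1], dims[1, 1]))
    }
    names(frames) <- basename(files)
    frames
  } else if (file.exists(path)) {
    stats::setNames(list(read_frame(path)), basename(path))
  } else {
    stop("no such file or directory: ", path)
  }
}

fmt6 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 6))
}

#' Write an ON/OFF profile as CSV or JSON
#'
#' CSV has fixed column order (`scale_k, spatial_frequency_cpd,
#' on_strength, off_strength, on_count, off_count, polarity_index`), `.`
#' decimal separator and 6 significant digits, for cross-platform
#' diffability. JSON additionally carries the frame metadata and, when
#' given, the seed of the run.
#'
#' @param profile an `onoff_profile`.
#' @param path output path.
#' @param seed optional seed to record in the JSON artifact.
#' @return Invisibly, `path`.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "onoff_profile"))
  out <- data.frame(
    scale_k = profile$scale_k,
    spatial_frequency_cpd = fmt6(profile$spatial_frequency_cpd),
    on_strength = fmt6(profile$on_strength),
    off_strength = fmt6(profile$off_strength),
    on_count = profile$on_count,
    off_count = profile$off_count,
    polarity_index = fmt6(profile$polarity_index))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
write_profile_json <- function(profile, path, seed = NULL) {
  stopifnot(inherits(profile, "onoff_profile"))
  agg <- attr(profile, "aggregator")
  obj <- list(
    frame = list(width = attr(profile, "frame_width"),
                 height = attr(profile, "frame_height"),
                 mean_luminance = attr(profile, "mean_luminance")),
    margin = attr(profile, "margin"),
    aggregator = list(mode = agg$mode, gamma = agg$gamma,
                      threshold = agg$threshold),
    seed = seed,
    package_version = as.character(utils::packageVersion("onoffscan")),
    profile = as.data.frame(profile))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
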