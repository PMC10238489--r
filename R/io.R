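# Movie container and file interchange: minimal baseline TIFF (uncompressed
# 16-bit grayscale, one page per frame) plus JSON ground-truth sidecars.
# The TIFF codec is in-repo because the R environment ships no TIFF package;
# it writes only the baseline tags a scientific reader needs and reads only
# what it writes (plus equivalent files from tifffile/Fiji).

#' Construct a time-lapse movie object
#'
#' @param frames list of numeric matrices (one per frame, identical dims);
#'   rows increase from the apical toward the basal side of the field.
#' @param pixel_size um per pixel.
#' @param frame_interval seconds between frames.
#' @param anaphase_onset 1-based index of the anaphase-onset frame (time 0).
#' @param background_subtracted has the camera offset been removed already?
#' @return object of class `time_lapse_movie`.
#' @export
time_lapse_movie <- function(frames, pixel_size, frame_interval,
                             anaphase_onset, background_subtracted = FALSE) {
  stopifnot(is.list(frames), length(frames) >= 2)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share the same dimensions")
  if (anaphase_onset < 1 || anaphase_onset > length(frames))
    stop("anaphase_onset frame index out of range")
  stopifnot(pixel_size > 0, frame_interval > 0)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 anaphase_onset = as.integer(anaphase_onset),
                 background_subtracted = isTRUE(background_subtracted)),
            class = "time_lapse_movie")
}

#' @export
print.time_lapse_movie <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("time_lapse_movie: %d frames of %d x %d px, %.3f um/px, %g s/frame\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$frame_interval))
  cat(sprintf("  anaphase onset at frame %d; background %ssubtracted\n",
              x$anaphase_onset,
              if (x$background_subtracted) "" else "not "))
  invisible(x)
}

#' Write a movie as a multi-page 16-bit grayscale TIFF
#'
#' Values are rounded and clipped to the 16-bit range. Little-endian,
#' uncompressed baseline TIFF, one image file directory per frame.
#'
#' @param movie a [time_lapse_movie()] (or plain list of matrices).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  frames <- if (inherits(movie, "time_lapse_movie")) movie$frames else movie
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)   # header; first IFD at 8
  n_entries <- 8L
  ifd_size <- 2L + n_entries * 12L + 4L
  data_size <- nr * nc * 2L
  offset <- 8L
  for (k in seq_along(frames)) {
    ifd_off <- offset
    data_off <- ifd_off + ifd_size
    next_ifd <- if (k < length(frames)) data_off + data_size else 0L
    w2(n_entries)
    entry <- function(tag, type, count, value) {
      w2(tag); w2(type); w4(count); w4(value)
    }
    entry(256L, 4L, 1L, nc)            # ImageWidth
    entry(257L, 4L, 1L, nr)            # ImageLength
    entry(258L, 3L, 1L, 16L)           # BitsPerSample
    entry(259L, 3L, 1L, 1L)            # Compression: none
    entry(262L, 3L, 1L, 1L)            # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off)      # StripOffsets
    entry(277L, 3L, 1L, 1L)            # SamplesPerPixel
    entry(279L, 4L, 1L, data_size)     # StripByteCounts
    w4(next_ifd)
    v <- pmin(pmax(round(t(frames[[k]])), 0), 65535)  # row-major pixel order
    writeBin(as.integer(v), con, size = 2, endian = "little")
    offset <- data_off + data_size
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF written by [write_movie_tiff()]
#'
#' Understands uncompressed 8/16-bit single-sample baseline TIFF in either
#' byte order, with one strip per page (or contiguous multi-strip pages).
#'
#' @param path TIFF file.
#' @param pixel_size,frame_interval,anaphase_onset movie metadata (not stored
#'   in the TIFF); when all are supplied a [time_lapse_movie()] is returned,
#'   otherwise a plain list of matrices.
#' @export
read_movie_tiff <- function(path, pixel_size = NULL, frame_interval = NULL,
                            anaphase_onset = NULL) {
  raw <- readBin(path, "raw", file.size(path))
  endian <- if (rawToChar(raw[1:2]) == "II") "little" else "big"
  rint <- function(off, size, n = 1L)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            signed = size >= 4, endian = endian)
  stopifnot(rint(2, 2) == 42L)
  ifd <- rint(4, 4)
  frames <- list()
  while (ifd != 0) {
    n <- rint(ifd, 2)
    tags <- list()
    for (e in seq_len(n)) {
      base <- ifd + 2 + (e - 1) * 12
      tag <- rint(base, 2); type <- rint(base + 2, 2); cnt <- rint(base + 4, 4)
      sz <- c(1L, 1L, 2L, 4L)[match(type, c(1L, 2L, 3L, 4L))]
      vals <- if (sz * cnt <= 4) rint(base + 8, sz, cnt)
      else rint(rint(base + 8, 4), sz, cnt)
      tags[[as.character(tag)]] <- vals
    }
    nc <- tags[["256"]]; nr <- tags[["257"]]
    bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]][1]
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1L)
      stop("compressed TIFF not supported")
    offs <- tags[["273"]]; counts <- tags[["279"]]
    bytes <- unlist(lapply(seq_along(offs), function(i)
      raw[(offs[i] + 1):(offs[i] + counts[i])]))
    v <- readBin(bytes, "integer", n = nr * nc, size = bits / 8L,
                 signed = FALSE, endian = endian)
    frames[[length(frames) + 1L]] <- matrix(v, nrow = nr, byrow = TRUE)
    ifd <- rint(ifd + 2 + n * 12, 4)
  }
  if (!is.null(pixel_size) && !is.null(frame_interval) && !is.null(anaphase_onset))
    time_lapse_movie(frames, pixel_size, frame_interval, anaphase_onset)
  else frames
}

#' Write ground truth to a JSON sidecar
#'
#' Contours as coordinate lists, schedules as per-frame arrays; restores as
#' a `ground_truth`-shaped list with [read_ground_truth()].
#' @param truth `ground_truth` object from [simulate_division()].
#' @param path output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  as_rc <- function(m) list(row = m[, 1], col = m[, 2])
  out <- list(
    contours = lapply(truth$contours, as_rc),
    furrow_points = lapply(truth$furrow_points, function(m)
      if (is.null(m)) list() else as_rc(m)),
    ring_diameter = truth$ring_diameter,
    constriction = truth$constriction,
    polar_pulse = truth$polar_pulse,
    furrow_basal_distance = truth$furrow_basal_distance,
    d0 = truth$d0, delta0 = truth$delta0,
    final_gmc_area = truth$final_gmc_area)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  x$contours <- lapply(x$contours, function(d) cbind(d$row, d$col))
  x$furrow_points <- lapply(x$furrow_points, function(d)
    if (is.null(d) || !length(d)) NULL else cbind(d$row, d$col))
  class(x) <- "ground_truth"
  x
}
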