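# File formats. B-scan stacks travel as uncompressed little-endian 32-bit
# float multi-page TIFF (one page per frame) plus a JSON sidecar carrying the
# acquisition header (frame rate, pixel pitches), or as raw float32 with the
# same sidecar. Masks and RGB renderings are 8-bit PNG; metrics are CSV.
# All writers are byte-deterministic for fixed input.

TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, samples = 277L,
               rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L)

write_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2, endian = "little")
write_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4, endian = "little")

tiff_ifd_entry <- function(con, tag, type, count, value) {
  write_u16(con, tag); write_u16(con, type); write_u32(con, count)
  if (type == 3L) {                      # SHORT, left-justified in 4 bytes
    write_u16(con, value); write_u16(con, 0L)
  } else write_u32(con, value)           # LONG
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a B-scan series to disk
#'
#' Stores the stack as an uncompressed multi-page 32-bit float TIFF (one
#' page per frame, little-endian, single strip per page) or as raw float32,
#' plus a JSON sidecar `<path>.json` holding the acquisition header
#' (dimensions, frame rate, pixel pitches, dtype).
#'
#' @param series a [bscan_series()].
#' @param path output file path.
#' @param format `"tiff"` (default) or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(series, path, format = c("tiff", "raw")) {
  if (!inherits(series, "bscan_series")) validation_error("'series' must be a bscan_series")
  format <- match.arg(format)
  d <- dim(series$data)
  header <- list(n_frames = d[1], n_depth = d[2], n_ascans = d[3],
                 frame_rate_hz = series$frame_rate_hz,
                 axial_um_per_px = series$axial_um_per_px,
                 lateral_um_per_px = series$lateral_um_per_px,
                 dtype = "float32", format = format)
  jsonlite::write_json(header, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "raw") {
    # frame-major, row-major within frame
    for (fr in seq_len(d[1]))
      writeBin(as.numeric(t(series$data[fr, , ])), con, size = 4, endian = "little")
    return(invisible(path))
  }
  bytes_per_page <- d[2] * d[3] * 4L
  n_entries <- length(TIFF_TAGS)
  ifd_size <- 2L + 12L * n_entries + 4L
  # layout: 8-byte header, then per page [pixel data][IFD]
  writeChar("II", con, nchars = 2, eos = NULL)
  write_u16(con, 42L)
  write_u32(con, 8L + bytes_per_page)          # offset of first IFD
  for (fr in seq_len(d[1])) {
    page_off <- 8L + (fr - 1L) * (bytes_per_page + ifd_size)
    writeBin(as.numeric(t(series$data[fr, , ])), con, size = 4, endian = "little")
    write_u16(con, n_entries)
    tiff_ifd_entry(con, TIFF_TAGS[["width"]], 4L, 1L, d[3])
    tiff_ifd_entry(con, TIFF_TAGS[["height"]], 4L, 1L, d[2])
    tiff_ifd_entry(con, TIFF_TAGS[["bits"]], 3L, 1L, 32L)
    tiff_ifd_entry(con, TIFF_TAGS[["compression"]], 3L, 1L, 1L)
    tiff_ifd_entry(con, TIFF_TAGS[["photometric"]], 3L, 1L, 1L)
    tiff_ifd_entry(con, TIFF_TAGS[["strip_offsets"]], 4L, 1L, page_off)
    tiff_ifd_entry(con, TIFF_TAGS[["samples"]], 3L, 1L, 1L)
    tiff_ifd_entry(con, TIFF_TAGS[["rows_per_strip"]], 4L, 1L, d[2])
    tiff_ifd_entry(con, TIFF_TAGS[["strip_bytes"]], 4L, 1L, bytes_per_page)
    tiff_ifd_entry(con, TIFF_TAGS[["sample_format"]], 3L, 1L, 3L)
    next_ifd <- if (fr == d[1]) 0L else page_off + bytes_per_page + ifd_size + bytes_per_page
    write_u32(con, next_ifd)
  }
  invisible(path)
}

read_exact <- function(con, what, n, size, signed = TRUE) {
  v <- readBin(con, what, n = n, size = size, endian = "little", signed = signed)
  if (length(v) != n) format_error("truncated file")
  v
}

#' Read a B-scan series from disk
#'
#' Reads a stack written by [write_stack()]: a multi-page float32 TIFF or a
#' raw float32 file, with its JSON sidecar header. The pixel data must match
#' the sidecar dimensions exactly and all amplitudes must be finite and
#' non-negative.
#'
#' @param path stack file path (sidecar expected at `<path>.json`).
#' @return a [bscan_series()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    format_error(sprintf("missing sidecar header %s", sc))
  hdr <- jsonlite::read_json(sc, simplifyVector = TRUE)
  need <- c("n_frames", "n_depth", "n_ascans", "frame_rate_hz",
            "axial_um_per_px", "lateral_um_per_px", "dtype")
  if (!all(need %in% names(hdr)))
    format_error("sidecar header is missing required fields")
  if (!identical(hdr$dtype, "float32"))
    format_error(sprintf("unsupported dtype '%s'", hdr$dtype))
  d <- as.integer(c(hdr$n_frames, hdr$n_depth, hdr$n_ascans))
  if (any(d < 1) || hdr$frame_rate_hz <= 0)
    format_error("sidecar header dimensions/frame rate invalid")
  raw_fmt <- identical(hdr$format, "raw")
  con <- file(path, "rb")
  on.exit(close(con))
  stack <- array(0, dim = d)
  if (raw_fmt) {
    for (fr in seq_len(d[1]))
      stack[fr, , ] <- t(matrix(read_exact(con, numeric(), d[2] * d[3], 4), d[3], d[2]))
  } else {
    magic <- readChar(con, 2, useBytes = TRUE)
    if (!identical(magic, "II")) format_error("not a little-endian TIFF")
    if (read_exact(con, integer(), 1, 2) != 42L) format_error("bad TIFF magic number")
    ifd_off <- read_exact(con, integer(), 1, 4)
    fr <- 0L
    while (ifd_off != 0L) {
      fr <- fr + 1L
      if (fr > d[1]) format_error(sprintf("TIFF has more pages than the %d in the header", d[1]))
      seek(con, ifd_off)
      n_entries <- read_exact(con, integer(), 1, 2)
      tags <- list()
      for (i in seq_len(n_entries)) {
        tag <- read_exact(con, integer(), 1, 2, signed = FALSE)
        type <- read_exact(con, integer(), 1, 2)
        cnt <- read_exact(con, integer(), 1, 4)
        val <- if (type == 3L) {
          v <- read_exact(con, integer(), 1, 2); read_exact(con, integer(), 1, 2); v
        } else read_exact(con, integer(), 1, 4)
        if (cnt != 1L) format_error("unsupported TIFF: multi-valued tag")
        tags[[as.character(tag)]] <- val
      }
      ifd_off <- read_exact(con, integer(), 1, 4)
      g <- function(id) tags[[as.character(TIFF_TAGS[[id]])]]
      if (is.null(g("width")) || is.null(g("height")) ||
          is.null(g("strip_offsets")) || is.null(g("strip_bytes")))
        format_error("TIFF page missing required tags")
      if (!is.null(g("compression")) && g("compression") != 1L)
        format_error("unsupported TIFF: compressed data")
      if (!is.null(g("bits")) && g("bits") != 32L ||
          !is.null(g("sample_format")) && g("sample_format") != 3L)
        format_error("unsupported TIFF: expected 32-bit IEEE float samples")
      if (g("width") != d[3] || g("height") != d[2])
        format_error(sprintf(
          "TIFF page %d is %d x %d but the header says %d x %d",
          fr, g("height"), g("width"), d[2], d[3]))
      if (g("strip_bytes") != d[2] * d[3] * 4L)
        format_error("TIFF strip size does not match page dimensions")
      seek(con, g("strip_offsets"))
      px <- read_exact(con, numeric(), d[2] * d[3], 4)
      stack[fr, , ] <- t(matrix(px, d[3], d[2]))
    }
    if (fr != d[1])
      format_error(sprintf("TIFF has %d pages but the header says %d", fr, d[1]))
  }
  if (anyNA(stack) || any(!is.finite(stack)))
    validation_error("stack contains non-finite values")
  if (any(stack < 0)) validation_error("stack contains negative amplitudes")
  bscan_series(stack, hdr$frame_rate_hz, hdr$axial_um_per_px, hdr$lateral_um_per_px)
}

#' Write a dynamic-contrast image as 8-bit RGB PNG
#'
#' Channels must lie in [0, 1]; quantization to 255 levels rounds half up.
#'
#' @param image a `dynamic_image`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_rgb <- function(image, path) {
  if (!inherits(image, "dynamic_image")) validation_error("'image' must be a dynamic_image")
  arr <- array(c(image$r, image$g, image$b),
               dim = c(nrow(image$r), ncol(image$r), 3))
  if (anyNA(arr) || any(arr < 0) || any(arr > 1))
    validation_error("image channels must lie in [0, 1]")
  png::writePNG(floor(arr * 255 + 0.5) / 255, path)
  invisible(path)
}

#' Read an RGB PNG back into a dynamic_image
#'
#' Intended for round-tripping images produced by [write_rgb()]; band and
#' frame provenance are not stored in the PNG and default to placeholders.
#'
#' @param path PNG path.
#' @return a `dynamic_image` in state `"averaged"`.
#' @export
read_rgb <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  arr <- png::readPNG(path)
  if (length(dim(arr)) != 3 || dim(arr)[3] < 3)
    format_error("expected a 3-channel RGB PNG")
  new_dynamic_image(arr[, , 1], arr[, , 2], arr[, , 3],
                    bands = band_spec(), n_frames_used = 0L,
                    state = "averaged")
}

#' Write / read ROI masks as single-channel 8-bit PNG
#'
#' Masks are stored as 0/255 grayscale; on reading, any value above 0 is
#' treated as inside the region.
#'
#' @param roi an [roi_mask()].
#' @param path PNG path.
#' @return `path` invisibly (writer); an [roi_mask()] (reader).
#' @export
write_mask <- function(roi, path) {
  if (!inherits(roi, "roi_mask")) roi <- roi_mask(roi)
  png::writePNG(roi$mask * 1.0, path)
  invisible(path)
}

#' @rdname write_mask
#' @param label label for the mask read from `path`.
#' @export
read_mask <- function(path, label = "roi") {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] != 1) format_error("mask PNG must be single-channel")
    arr <- arr[, , 1]
  }
  roi_mask(arr > 0, label)
}

METRICS_COLUMNS <- c("sample_id", "group", "exposure_min", "roi", "motility",
                     "peak_hue_deg", "second_peak_hue_deg", "thickness_um")

#' Write / read metrics tables as CSV
#'
#' Fixed schema `(sample_id, group, exposure_min, roi, motility,
#' peak_hue_deg, second_peak_hue_deg, thickness_um)`, comma-separated,
#' "." decimal, UTF-8, no index column. Numbers are written with 9
#' significant digits, so a round trip preserves at least 6.
#'
#' @param records data.frame containing the schema columns.
#' @param path CSV path.
#' @return `path` invisibly (writer); a data.frame (reader).
#' @export
write_metrics <- function(records, path) {
  if (!is.data.frame(records)) validation_error("'records' must be a data.frame")
  missing_cols <- setdiff(METRICS_COLUMNS, names(records))
  if (length(missing_cols))
    validation_error(sprintf("records are missing column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  records <- records[METRICS_COLUMNS]
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "NA", sprintf("%.9g", x)) else as.character(x)
  }
  body <- do.call(paste, c(lapply(records, fmt), sep = ","))
  writeLines(c(paste(METRICS_COLUMNS, collapse = ","), body), path)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), METRICS_COLUMNS))
    format_error("CSV does not carry the metrics schema")
  df
}

#' Write / read configuration objects as JSON
#'
#' Serializes [phantom_config()], [toxicity_course()], [band_spec()] or
#' [study_config()] objects to pretty-printed JSON and reconstructs them,
#' re-running all constructor validation on read.
#'
#' @param config a supported configuration object.
#' @param path JSON path.
#' @return `path` invisibly (writer); the reconstructed object (reader).
#' @export
write_config <- function(config, path) {
  kind <- class(config)[1]
  if (!kind %in% c("phantom_config", "toxicity_course", "band_spec", "study_config"))
    config_error(sprintf("cannot serialize objects of class '%s'", kind))
  payload <- serialize_cfg(config)
  jsonlite::write_json(list(kind = kind, config = payload), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

serialize_cfg <- function(x) {
  if (inherits(x, "phantom_config")) {
    out <- unclass(x)
    out$layers <- lapply(x$layers, function(l) {
      l <- unclass(l)
      if (is.null(l$single_tone_hz)) l$single_tone_hz <- NULL
      l
    })
    out
  } else if (inherits(x, "study_config")) {
    out <- unclass(x)
    out$phantom <- serialize_cfg(x$phantom)
    out$course <- unclass(x$course)
    out$bands <- unclass(x$bands)
    out
  } else unclass(x)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(obj$kind) || is.null(obj$config))
    format_error("config JSON must carry 'kind' and 'config'")
  deserialize_cfg(obj$kind, obj$config)
}

deserialize_cfg <- function(kind, cfg) {
  switch(kind,
    band_spec = band_spec(unlist(cfg$slow), unlist(cfg$medium), unlist(cfg$fast)),
    toxicity_course = do.call(toxicity_course, cfg),
    phantom_config = {
      layers <- lapply(cfg$layers, function(l) {
        l$z_range <- unlist(l$z_range)
        l$band_power_fractions <- unlist(l$band_power_fractions)
        do.call(layer_spec, l)
      })
      cfg$layers <- NULL
      do.call(phantom_config, c(list(layers = layers), cfg))
    },
    study_config = {
      phantom <- deserialize_cfg("phantom_config", cfg$phantom)
      course <- do.call(toxicity_course, cfg$course)
      bands <- band_spec(unlist(cfg$bands$slow), unlist(cfg$bands$medium),
                         unlist(cfg$bands$fast))
      cfg$exposure_grid_min <- unlist(cfg$exposure_grid_min)
      cfg$phantom <- NULL; cfg$course <- NULL; cfg$bands <- NULL
      do.call(study_config,
              c(list(phantom = phantom, course = course, bands = bands), cfg))
    },
    format_error(sprintf("unknown config kind '%s'", kind)))
}
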