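# Minimal GeoTIFF codec: uncompressed float32, pixel-interleaved, north-up,
# little-endian. Carries the geotransform (ModelPixelScale + ModelTiepoint),
# a GDAL-style nodata tag, and a JSON ImageDescription with band labels,
# date and value kind. Intentionally small: exactly the files this pipeline
# writes, plus generic uncompressed float32 GeoTIFFs from other producers.

.tif_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L, DOUBLE = 12L)
.tif_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)

raw_le <- function(x, size, what = "integer") {
  writeBin(x, raw(), size = size, endian = "little", useBytes = TRUE)
}

#' Write a raster as GeoTIFF
#'
#' Float32, single strip, pixel-interleaved, little-endian, with
#' ModelPixelScaleTag/ModelTiepointTag for the geotransform, the GDAL nodata
#' tag, and band labels + date + kind stored as JSON in ImageDescription.
#' `NA` cells are written as the raster's `nodata` sentinel. The raster is
#' validated against its declared `kind` before writing.
#'
#' @param r a [sat_raster].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path) {
  validate_raster(r)
  d <- dim(r$values)
  nr <- d[1L]; nc <- d[2L]; nb <- d[3L]
  v <- aperm(r$values, c(3L, 2L, 1L))  # band fastest, then col, then row
  v <- as.vector(v)
  v[is.na(v)] <- r$nodata
  pix <- raw_le(as.double(v), 4L)
  data_size <- length(pix)
  desc <- jsonlite::toJSON(list(
    bands = r$bands,
    date = if (is.null(r$date)) NULL else format(r$date),
    kind = r$kind), auto_unbox = TRUE, null = "null")
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0L))
  nodata_raw <- c(charToRaw(format(r$nodata, scientific = FALSE)), as.raw(0L))

  entries <- list()
  extra <- raw(0)
  ifd_offset <- 8L + data_size
  # 12-byte entries + count (2) + next-IFD pointer (4)
  add <- function(tag, type, values, raw_values = NULL) {
    n <- if (is.null(raw_values)) length(values) else length(raw_values) %/% .tif_type_size[[as.character(type)]]
    val_raw <- if (!is.null(raw_values)) raw_values
      else if (type == .tif_types[["SHORT"]]) raw_le(as.integer(values), 2L)
      else if (type == .tif_types[["LONG"]]) raw_le(as.integer(values), 4L)
      else if (type == .tif_types[["DOUBLE"]]) raw_le(as.double(values), 8L)
      else stopf("unhandled TIFF type %d", type)
    entries[[length(entries) + 1L]] <<- list(tag = tag, type = type, n = n, raw = val_raw)
  }
  add(256L, 4L, nc)               # ImageWidth
  add(257L, 4L, nr)               # ImageLength
  add(258L, 3L, rep(32L, nb))     # BitsPerSample
  add(259L, 3L, 1L)               # Compression: none
  add(262L, 3L, 1L)               # Photometric: BlackIsZero
  add(270L, 2L, NULL, raw_values = desc_raw)   # ImageDescription
  add(273L, 4L, 8L)               # StripOffsets (single strip at byte 8)
  add(277L, 3L, nb)               # SamplesPerPixel
  add(278L, 4L, nr)               # RowsPerStrip
  add(279L, 4L, data_size)        # StripByteCounts
  add(284L, 3L, 1L)               # PlanarConfig: chunky
  if (nb > 1L) add(338L, 3L, rep(0L, nb - 1L))  # ExtraSamples: unspecified
  add(339L, 3L, rep(3L, nb))      # SampleFormat: IEEE float
  add(33550L, 12L, c(r$res, r$res, 0))                 # ModelPixelScale
  add(33922L, 12L, c(0, 0, 0, r$origin[1], r$origin[2], 0))  # ModelTiepoint
  add(34735L, 3L, c(1L, 1L, 0L, 1L, 1024L, 0L, 1L, 1L))       # GeoKeys: user-defined model
  add(42113L, 2L, NULL, raw_values = nodata_raw)       # GDAL_NODATA

  n_ent <- length(entries)
  ifd_size <- 2L + 12L * n_ent + 4L
  ext_offset <- ifd_offset + ifd_size
  ifd <- raw_le(n_ent, 2L)
  for (e in entries) {
    sz <- length(e$raw)
    ifd <- c(ifd, raw_le(e$tag, 2L), raw_le(e$type, 2L), raw_le(e$n, 4L))
    if (sz <= 4L) {
      ifd <- c(ifd, e$raw, raw(4L - sz))
    } else {
      ifd <- c(ifd, raw_le(ext_offset, 4L))
      extra <- c(extra, e$raw)
      ext_offset <- ext_offset + sz
      if (sz %% 2L == 1L) { extra <- c(extra, raw(1)); ext_offset <- ext_offset + 1L }
    }
  }
  ifd <- c(ifd, raw_le(0L, 4L))

  header <- c(charToRaw("II"), raw_le(42L, 2L), raw_le(ifd_offset, 4L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, pix, ifd, extra), con, useBytes = TRUE)
  invisible(path)
}

read_u <- function(buf, off, size) {  # unsigned little-endian integer at 0-based offset
  b <- as.integer(buf[(off + 1L):(off + size)])
  sum(b * 256^(seq_len(size) - 1L))
}

#' Read a GeoTIFF written by [write_raster()]
#'
#' Supports uncompressed float32, pixel-interleaved, little-endian files
#' (one or more strips). The geotransform, nodata sentinel and the JSON
#' band-label sidecar in ImageDescription are restored; nodata cells become
#' `NA`.
#'
#' @param path file path.
#' @return A [sat_raster].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  buf <- readBin(path, "raw", n = file.size(path))
  if (rawToChar(buf[1:2]) != "II") stopf("%s: not a little-endian TIFF", path)
  if (read_u(buf, 2L, 2L) != 42L) stopf("%s: bad TIFF magic", path)
  ifd <- read_u(buf, 4L, 4L)
  n_ent <- read_u(buf, ifd, 2L)
  tags <- list()
  for (i in seq_len(n_ent)) {
    off <- ifd + 2L + (i - 1L) * 12L
    tag <- read_u(buf, off, 2L)
    type <- read_u(buf, off + 2L, 2L)
    n <- read_u(buf, off + 4L, 4L)
    sz <- .tif_type_size[[as.character(type)]] * n
    voff <- if (sz <= 4L) off + 8L else read_u(buf, off + 8L, 4L)
    raw_v <- buf[(voff + 1L):(voff + sz)]
    val <- switch(as.character(type),
      `1` = as.integer(raw_v),
      `2` = {
        s <- raw_v; z <- which(s == as.raw(0L))
        rawToChar(if (length(z)) s[seq_len(z[1L] - 1L)] else s)
      },
      `3` = vapply(seq_len(n), function(k) read_u(raw_v, (k - 1L) * 2L, 2L), 0),
      `4` = vapply(seq_len(n), function(k) read_u(raw_v, (k - 1L) * 4L, 4L), 0),
      `12` = readBin(raw_v, "double", n = n, size = 8L, endian = "little"),
      stopf("%s: unhandled TIFF type %d (tag %d)", path, type, tag))
    tags[[as.character(tag)]] <- val
  }
  need <- function(tag) tags[[as.character(tag)]] %||% stopf("%s: missing TIFF tag %d", path, tag)
  nc <- need(256L); nr <- need(257L)
  nb <- tags[["277"]] %||% 1L
  if (!is.null(tags[["259"]]) && tags[["259"]] != 1L)
    stopf("%s: compressed TIFF not supported", path)
  if (!all((tags[["258"]] %||% 32L) == 32L) || !all((tags[["339"]] %||% 3L) == 3L))
    stopf("%s: only float32 samples supported", path)
  if ((tags[["284"]] %||% 1L) != 1L) stopf("%s: only chunky planar layout supported", path)
  offs <- need(273L); cnts <- need(279L)
  pix_raw <- do.call(c, lapply(seq_along(offs), function(k)
    buf[(offs[k] + 1L):(offs[k] + cnts[k])]))
  v <- readBin(pix_raw, "double", n = nr * nc * nb, size = 4L, endian = "little")
  vals <- aperm(array(v, c(nb, nc, nr)), c(3L, 2L, 1L))

  scale <- tags[["33550"]] %||% c(1, 1, 0)
  tie <- tags[["33922"]] %||% rep(0, 6)
  if (abs(scale[1] - scale[2]) > 1e-9 * scale[1])
    stopf("%s: non-square pixels not supported", path)
  origin <- c(tie[4] - tie[1] * scale[1], tie[5] + tie[2] * scale[2])
  meta <- list(bands = NULL, date = NULL, kind = "other")
  if (!is.null(tags[["270"]])) {
    parsed <- try(jsonlite::fromJSON(tags[["270"]]), silent = TRUE)
    if (!inherits(parsed, "try-error") && is.list(parsed)) meta <- utils::modifyList(meta, parsed)
  }
  nodata <- if (!is.null(tags[["42113"]])) as.numeric(tags[["42113"]]) else NA_real_
  if (!is.na(nodata)) vals[abs(vals - nodata) < 1e-6 * max(1, abs(nodata))] <- NA_real_
  bands <- meta$bands %||% paste0("band", seq_len(nb))
  sat_raster(vals, bands, scale[1], origin,
             date = meta$date, kind = meta$kind %||% "other",
             nodata = if (is.na(nodata)) -9999 else nodata)
}
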