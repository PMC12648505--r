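#' @title Volume I/O: minimal baseline TIFF codec
#' @description No TIFF package is available in the supported environment,
#' so the package carries a minimal baseline codec: little-endian,
#' uncompressed, strip-based, single-sample grayscale, multi-page; 8/16-bit
#' unsigned and 32/64-bit float samples.  Voxel spacing, origin and channel
#' are stored as JSON in the ImageDescription tag and recovered on read.
#' Files written by [write_volume()] are readable by standard TIFF readers
#' (e.g. tifffile, ImageJ).
#' @name volume-io
NULL

tiff_type <- function(bits) switch(bits,
  uint8 = list(bps = 8L, fmt = 1L, what = "integer", size = 1L, signed = FALSE),
  uint16 = list(bps = 16L, fmt = 1L, what = "integer", size = 2L, signed = FALSE),
  float32 = list(bps = 32L, fmt = 3L, what = "double", size = 4L, signed = TRUE),
  float64 = list(bps = 64L, fmt = 3L, what = "double", size = 8L, signed = TRUE),
  stop("unsupported sample type: ", bits))

#' Write a volume as a multi-page TIFF
#'
#' Pages are z-slices (rows y, columns x).  Spacing/origin/channel metadata
#' travel in the ImageDescription tag as JSON; `float64` sample format
#' round-trips doubles bit-exactly.
#'
#' @param volume a `lymph_volume` or `lymph_mask`.
#' @param path output path.
#' @param bits sample type: "float64" (default), "float32", "uint16", "uint8".
#' @param config_md5 optional provenance hash stored in the metadata.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, bits = "float64",
                         config_md5 = NA_character_) {
  dat <- volume$data
  if (is.logical(dat)) dat <- array(as.integer(dat), dim(dat))
  ty <- tiff_type(bits)
  dims <- dim(dat)
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  desc <- jsonlite::toJSON(list(spacing_um = volume$spacing_um,
                                origin_um = volume$origin_um,
                                channel = if (!is.null(volume$channel))
                                  volume$channel else "",
                                config_md5 = config_md5),
                           auto_unbox = TRUE, digits = NA, na = "null")
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0))
  if (length(desc_raw) %% 2) desc_raw <- c(desc_raw, as.raw(0))

  page_bytes <- ny * nx * ty$size
  n_entry <- function(first) if (first) 11L else 10L
  ifd_size <- function(first) 2L + 12L * n_entry(first) + 4L
  data_off <- 8L
  ifd0_off <- data_off + nz * page_bytes
  ifd_offs <- ifd0_off + cumsum(c(0L, vapply(seq_len(nz - 1), function(i)
    ifd_size(i == 1), integer(1))))
  desc_off <- ifd_offs[nz] + ifd_size(nz == 1)

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w16(42L); w32(ifd0_off)
  # pixel data: page-major, row-major (y rows, x columns)
  perm <- aperm(dat, c(3, 2, 1))             # x fastest, then y, then z
  if (ty$what == "integer")
    writeBin(as.integer(perm), con, size = ty$size, endian = "little")
  else
    writeBin(as.double(perm), con, size = ty$size, endian = "little")
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3L && count == 1L) { w16(value); w16(0L) } else w32(value)
  }
  for (z in seq_len(nz)) {
    first <- z == 1L
    w16(n_entry(first))
    entry(256L, 4L, 1L, nx)
    entry(257L, 4L, 1L, ny)
    entry(258L, 3L, 1L, ty$bps)
    entry(259L, 3L, 1L, 1L)
    entry(262L, 3L, 1L, 1L)
    if (first) entry(270L, 2L, length(desc_raw), desc_off)
    entry(273L, 4L, 1L, data_off + (z - 1L) * page_bytes)
    entry(277L, 3L, 1L, 1L)
    entry(278L, 4L, 1L, ny)
    entry(279L, 4L, 1L, page_bytes)
    entry(339L, 3L, 1L, ty$fmt)
    w32(if (z < nz) ifd_offs[z + 1L] else 0L)
  }
  writeBin(desc_raw, con)
  invisible(path)
}

rd_int <- function(raw, off, size, endian_le, signed = FALSE) {
  b <- as.integer(raw[off + seq_len(size)])
  if (!endian_le) b <- rev(b)
  sum(b * 256^(seq_len(size) - 1))
}

#' Read a volume from a TIFF stack
#'
#' Supports the baseline subset written by [write_volume()] (uncompressed,
#' strip-based, single-sample grayscale; 8/16-bit unsigned or 32/64-bit
#' float; little- or big-endian).  Spacing is taken from the JSON
#' ImageDescription when present, otherwise from `spacing_um`; with neither
#' the read fails.
#'
#' @param path TIFF path.
#' @param spacing_um optional (z, y, x) spacing override, um.
#' @param channel optional channel label override.
#' @return a `lymph_volume`.
#' @export
read_volume <- function(path, spacing_um = NULL, channel = NULL) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop("unreadable TIFF: file too short")
  bo <- rawToChar(raw[1:2])
  if (!bo %in% c("II", "MM")) stop("unreadable TIFF: bad byte-order mark")
  le <- bo == "II"
  if (rd_int(raw, 2, 2, le) != 42) stop("unreadable TIFF: bad magic")
  ifd <- rd_int(raw, 4, 4, le)
  pages <- list()
  desc <- NULL
  while (ifd != 0) {
    n <- rd_int(raw, ifd, 2, le)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd + 2 + (k - 1) * 12
      tag <- rd_int(raw, e, 2, le)
      type <- rd_int(raw, e + 2, 2, le)
      count <- rd_int(raw, e + 4, 4, le)
      tsize <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)[type]
      nbytes <- tsize * count
      voff <- if (nbytes <= 4) e + 8 else rd_int(raw, e + 8, 4, le)
      vals <- if (type == 2) {
        b <- raw[voff + seq_len(count)]
        nul <- which(b == as.raw(0))
        rawToChar(b[seq_len(if (length(nul)) nul[1] - 1 else count)])
      } else if (type == 3) {
        vapply(seq_len(count), function(j) rd_int(raw, voff + (j - 1) * 2, 2, le),
               numeric(1))
      } else if (type == 4) {
        vapply(seq_len(count), function(j) rd_int(raw, voff + (j - 1) * 4, 4, le),
               numeric(1))
      } else NULL
      tags[[as.character(tag)]] <- vals
    }
    pages[[length(pages) + 1L]] <- tags
    if (!is.null(tags[["270"]]) && is.null(desc)) desc <- tags[["270"]]
    ifd <- rd_int(raw, ifd + 2 + n * 12, 4, le)
  }
  if (length(pages) < 2) stop("3D stack required (got ", length(pages), " page(s))")
  g <- function(tags, tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) default else v
  }
  nx <- g(pages[[1]], 256); ny <- g(pages[[1]], 257)
  bps <- g(pages[[1]], 258, 8); fmt <- g(pages[[1]], 339, 1)
  if (g(pages[[1]], 259, 1) != 1) stop("compressed TIFF not supported")
  nz <- length(pages)
  dat <- array(0, c(nz, ny, nx))
  for (z in seq_len(nz)) {
    tg <- pages[[z]]
    if (!identical(c(g(tg, 256), g(tg, 257)), c(nx, ny)))
      stop("inconsistent page shapes")
    offs <- g(tg, 273); cnts <- g(tg, 279)
    buf <- unlist(lapply(seq_along(offs), function(i)
      raw[offs[i] + seq_len(cnts[i])]), use.names = FALSE)
    px <- if (fmt == 3) {
      readBin(buf, "double", n = ny * nx, size = bps / 8,
              endian = if (le) "little" else "big")
    } else {
      readBin(buf, "integer", n = ny * nx, size = bps / 8, signed = bps > 8,
              endian = if (le) "little" else "big")
    }
    if (fmt == 1 && bps > 8) px[px < 0] <- px[px < 0] + 2^bps
    dat[z, , ] <- matrix(px, ny, nx, byrow = TRUE)
  }
  meta <- if (!is.null(desc))
    tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL) else NULL
  sp <- if (!is.null(spacing_um)) spacing_um else meta$spacing_um
  if (is.null(sp))
    stop("missing spacing: no metadata in file and no spacing_um override")
  volume3d(dat, sp,
           if (!is.null(meta$origin_um)) meta$origin_um else c(0, 0, 0),
           if (!is.null(channel)) channel
           else if (!is.null(meta$channel)) meta$channel else "")
}

#' Write a rendered phantom with its ground truth
#'
#' Volume as float TIFF, labels as uint8 TIFF, the true graph as CSV tables
#' plus GraphML, true valves as CSV/JSON, and the analytic metrics as CSV.
#'
#' @param spec a `phantom_spec`.
#' @param dir output directory.
#' @param spacing_um render spacing.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(spec, dir, spacing_um = c(1.8, 1.8, 1.8)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- render_volume(spec, spacing_um)
  write_volume(r$volume, file.path(dir, "phantom.tif"), "float32")
  write_volume(r$truth$label_volume, file.path(dir, "labels.tif"), "uint8")
  write_graph_csv(r$truth$true_graph, file.path(dir, "true_graph"))
  write_graphml(r$truth$true_graph, file.path(dir, "true_graph.graphml"))
  write_valves_csv(r$truth$true_valves, file.path(dir, "true_valves.csv"))
  jsonlite::write_json(spec[c("box_um", "seed")],
                       file.path(dir, "spec_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  am <- r$truth$analytic
  write.csv(data.frame(metric = c("volume_density", "length_density_mm_per_mm3",
                                  "capillary_length_fraction",
                                  "valve_density_per_mm3"),
                       value = c(am$volume_density,
                                 am$length_density_mm_per_mm3,
                                 am$capillary_length_fraction,
                                 am$valve_density_per_mm3)),
            file.path(dir, "analytic_metrics.csv"), row.names = FALSE)
  invisible(dir)
}
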