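#' Voxel volumes
#'
#' A `cr_volume` is a regular voxel grid of HU-like intensities with
#' (possibly anisotropic) spacing and an origin, both in mm. Voxel
#' `[i, j, k]` is centred at `origin + (c(i, j, k) - 1) * spacing`. This is
#' the source of every surface mesh in the package.
#'
#' @param intensities 3D numeric array of intensities (HU).
#' @param spacing_mm Length-3 positive voxel spacing (mm).
#' @param origin_mm Length-3 origin: centre of voxel `[1, 1, 1]` (mm).
#' @param scene Optional analytic scene description attached by the phantom
#'   generator (used to re-rasterise under a rigid repositioning instead of
#'   resampling voxels).
#' @return An object of class `cr_volume`.
#' @export
volume <- function(intensities, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0),
                   scene = NULL) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3,
            all(dim(intensities) > 0))
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  stopifnot(length(spacing_mm) == 3, all(spacing_mm > 0), length(origin_mm) == 3)
  structure(list(intensities = intensities, spacing_mm = spacing_mm,
                 origin_mm = origin_mm, scene = scene),
            class = "cr_volume")
}

#' @export
print.cr_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<cr_volume> %d x %d x %d voxels, spacing (%g, %g, %g) mm, HU range [%g, %g]\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Read and write volumes in a self-describing grid format
#'
#' The format is a short ASCII header (magic line, grid shape, spacing,
#' origin, payload encoding) followed by the intensities as little-endian
#' float64 in column-major (x fastest) order. It exists so phantom volumes
#' can be exchanged without a DICOM stack; it carries everything needed to
#' reconstruct the `cr_volume`.
#'
#' @param vol A [volume()].
#' @param path File path (conventionally `.crvol`).
#' @return `read_volume()` returns a [volume()]; `write_volume()` returns
#'   `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "cr_volume"))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("crvol 1",
           paste("shape", paste(dim(vol$intensities), collapse = " ")),
           paste("spacing_mm", paste(format(vol$spacing_mm, digits = 17), collapse = " ")),
           paste("origin_mm", paste(format(vol$origin_mm, digits = 17), collapse = " ")),
           "data float64 little")
  # header ends with a blank line; the binary payload follows immediately
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n\n"), con, eos = NULL)
  writeBin(as.numeric(vol$intensities), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_line <- function() {
    chars <- character()
    repeat {
      ch <- suppressWarnings(readChar(con, 1, useBytes = TRUE))
      if (length(ch) == 0 || ch == "\n") break
      chars <- c(chars, ch)
      if (length(chars) > 1000) stop("crvol header line too long (malformed file)",
                                     call. = FALSE)
    }
    paste(chars, collapse = "")
  }
  magic <- read_line()
  if (!identical(magic, "crvol 1")) stop("not a crvol file: bad magic line", call. = FALSE)
  fields <- list()
  repeat {
    ln <- read_line()
    if (!nzchar(ln)) break
    parts <- strsplit(ln, " ", fixed = TRUE)[[1]]
    fields[[parts[1]]] <- parts[-1]
  }
  shape <- as.integer(fields$shape)
  if (length(shape) != 3) stop("crvol header: bad shape", call. = FALSE)
  n <- prod(shape)
  vals <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  if (length(vals) != n) stop("crvol payload truncated", call. = FALSE)
  volume(array(vals, dim = shape),
         spacing_mm = as.numeric(fields$spacing_mm),
         origin_mm = as.numeric(fields$origin_mm))
}

# voxel-centre coordinates along one axis
axis_coords <- function(vol, axis) {
  vol$origin_mm[axis] + (seq_len(dim(vol$intensities)[axis]) - 1) * vol$spacing_mm[axis]
}
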