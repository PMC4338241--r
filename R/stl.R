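#' Read and write STL surface files
#'
#' Binary and ASCII STL (Standard Tessellation Language). STL itself carries
#' no units; this package fixes mm throughout. Binary STL stores float32
#' coordinates, so a write/read round trip preserves geometry to float32
#' precision. On reading, identical vertex triples are welded back into an
#' indexed mesh.
#'
#' @param m A [mesh()].
#' @param path File path.
#' @param mode `"binary"` (default) or `"ascii"`.
#' @return `write_stl()` returns `path` invisibly; `read_stl()` returns a
#'   [mesh()].
#' @export
write_stl <- function(m, path, mode = c("binary", "ascii")) {
  mode <- match.arg(mode)
  a <- m$vertices[m$faces[, 1], , drop = FALSE]
  b <- m$vertices[m$faces[, 2], , drop = FALSE]
  c_ <- m$vertices[m$faces[, 3], , drop = FALSE]
  n <- face_normals(m)
  nf <- nrow(m$faces)
  if (mode == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC("cranioreg binary STL (mm)", width = -80))
    writeBin(header[1:80], con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    # per-facet payload: normal, 3 vertices (float32), attribute count (uint16)
    block <- rbind(t(n), t(a), t(b), t(c_))
    fbytes <- writeBin(as.numeric(block), raw(), size = 4, endian = "little")
    rec <- rbind(matrix(fbytes, nrow = 48), matrix(as.raw(0), nrow = 2, ncol = nf))
    writeBin(as.vector(rec), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    body <- rbind(
      sprintf("  facet normal %.9e %.9e %.9e", n[, 1], n[, 2], n[, 3]),
      "    outer loop",
      sprintf("      vertex %.9e %.9e %.9e", a[, 1], a[, 2], a[, 3]),
      sprintf("      vertex %.9e %.9e %.9e", b[, 1], b[, 2], b[, 3]),
      sprintf("      vertex %.9e %.9e %.9e", c_[, 1], c_[, 2], c_[, 3]),
      "    endloop",
      "  endfacet")
    writeLines(c("solid cranioreg", as.vector(body), "endsolid cranioreg"), con)
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  head5 <- readChar(con, 5, useBytes = TRUE)
  close(con)
  if (identical(head5, "solid")) {
    # could still be a binary file whose header begins with "solid";
    # try ASCII first and fall back
    tri <- tryCatch(read_stl_ascii(path), error = function(e) NULL)
    if (!is.null(tri)) return(weld_triangles(tri))
  }
  weld_triangles(read_stl_binary(path))
}

read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, raw(), 80))
  nf <- readBin(con, integer(), 1, size = 4, endian = "little")
  if (is.na(nf) || nf < 0) stop("STL parse error at byte 80: bad triangle count", call. = FALSE)
  expected <- 84 + nf * 50
  if (sz < expected) {
    stop(sprintf("STL parse error at byte %d: declared %d triangles but file holds %d bytes (expected %d)",
                 sz, nf, sz, expected), call. = FALSE)
  }
  payload <- readBin(con, raw(), nf * 50)
  if (length(payload) < nf * 50) {
    stop(sprintf("STL parse error at byte %d: truncated triangle records",
                 84 + length(payload)), call. = FALSE)
  }
  rec <- matrix(payload, nrow = 50)
  fbytes <- as.vector(rec[1:48, , drop = FALSE])
  vals <- matrix(readBin(fbytes, numeric(), n = 12 * nf, size = 4,
                         endian = "little"), nrow = 12)
  tris <- matrix(0, nrow = 3 * nf, ncol = 3)
  tris[seq(1, 3 * nf, by = 3), ] <- t(vals[4:6, , drop = FALSE])
  tris[seq(2, 3 * nf, by = 3), ] <- t(vals[7:9, , drop = FALSE])
  tris[seq(3, 3 * nf, by = 3), ] <- t(vals[10:12, , drop = FALSE])
  tris
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0 || length(vlines) %% 3 != 0) {
    stop("STL ASCII parse error: vertex count not a multiple of 3", call. = FALSE)
  }
  vals <- lapply(strsplit(trimws(vlines), "\\s+"), function(p) as.numeric(p[2:4]))
  tris <- do.call(rbind, vals)
  if (any(!is.finite(tris))) stop("STL ASCII parse error: non-numeric vertex", call. = FALSE)
  tris
}

# weld a triangle soup (3 consecutive rows per face) into an indexed mesh
weld_triangles <- function(tris) {
  key <- paste(tris[, 1], tris[, 2], tris[, 3])
  fac <- factor(key, levels = unique(key))
  idx <- as.integer(fac)
  verts <- tris[!duplicated(idx), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  mesh(verts, faces)
}
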