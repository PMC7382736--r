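inferFormat <- function(path) {
  ext <- tolower(sub(".*\\.", "", basename(path)))
  if (!ext %in% c("stl", "obj", "off"))
    stop("cannot infer mesh format from extension '", ext,
         "'; pass format = \"stl\", \"obj\" or \"off\"")
  ext
}

#' Read a triangle mesh from STL, OBJ or OFF
#'
#' STL (ASCII or binary, auto-detected), Wavefront OBJ (`v`/`f` records,
#' 1-based indices) and OFF are supported; CRLF and LF line endings both
#' work. Duplicate vertices within 1e-8 of the bounding-box diagonal are
#' unified (STL stores per-facet vertices, so merging is required before any
#' topology analysis). File-stored facet normals are discarded: the winding
#' order is the authoritative source of orientation.
#'
#' @param path path to the mesh file.
#' @param format `"stl"`, `"obj"` or `"off"`; inferred from the extension
#'   when `NULL`.
#' @return a [TriangleMesh-class].
#' @seealso [writeMesh()]
#' @export
readMesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) format <- inferFormat(path)
  format <- match.arg(format, c("stl", "obj", "off"))
  raw_ <- switch(format,
    stl = readSTL(path),
    obj = readOBJ(path),
    off = readOFF(path))
  if (nrow(raw_$faces) == 0L)
    stop("empty mesh: ", path, " contains no faces")
  bbDiag <- sqrt(sum((apply(raw_$vertices, 2L, max) -
                      apply(raw_$vertices, 2L, min))^2))
  mg <- mergeVertices(raw_$vertices, raw_$faces, 1e-8 * max(bbDiag, 1e-300))
  triangleMesh(mg$vertices, mg$faces)
}

#' Write a triangle mesh to STL, OBJ or OFF
#'
#' `"stl"` writes ASCII STL; `"stlb"` writes binary STL (80-byte header,
#' uint32 facet count, 50-byte little-endian records). STL facet normals are
#' recomputed from the winding (degenerate faces get a zero normal). A
#' written file parses back to an equal mesh: identical face count, vertices
#' within 1e-6 (binary STL stores 32-bit floats).
#'
#' @param mesh a non-empty [TriangleMesh-class].
#' @param path output path.
#' @param format `"stl"`, `"stlb"`, `"obj"` or `"off"`; inferred from the
#'   extension when `NULL` (`.stl` implies ASCII).
#' @return invisibly, `path`.
#' @export
writeMesh <- function(mesh, path, format = NULL) {
  if (nFaces(mesh) == 0L) stop("refusing to write an empty mesh")
  if (is.null(format)) format <- inferFormat(path)
  format <- match.arg(format, c("stl", "stlb", "obj", "off"))
  switch(format,
    stl = writeSTLascii(mesh, path),
    stlb = writeSTLbinary(mesh, path),
    obj = writeOBJ(mesh, path),
    off = writeOFF(mesh, path))
  invisible(path)
}

readSTL <- function(path) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(size, 84L))
  if (length(head) >= 84L) {
    nTri <- readBin(head[81:84], "integer", size = 4L, endian = "little")
    if (!is.na(nTri) && nTri >= 0L && size == 84 + 50 * as.numeric(nTri))
      return(readSTLbinaryBody(con, path, nTri))
  }
  magic <- rawToChar(head[seq_len(min(5L, length(head)))])
  if (!identical(tolower(magic), "solid"))
    stop("not an STL file (byte offset 0): ", path)
  readSTLascii(path)
}

readSTLbinaryBody <- function(con, path, nTri) {
  seek(con, 84L)
  body <- readBin(con, "raw", n = 50L * nTri)
  if (length(body) < 50L * nTri)
    stop(sprintf("truncated binary STL %s: expected %d bytes after offset 84, got %d",
                 path, 50L * nTri, length(body)))
  # 12 floats (normal + 3 vertices) then a 2-byte attribute per facet
  sel <- rep((seq_len(nTri) - 1L) * 50L, each = 48L) + rep(1:48, nTri)
  floats <- readBin(body[sel], "double", size = 4L, n = 12L * nTri,
                    endian = "little")
  fm <- matrix(floats, ncol = 12L, byrow = TRUE)
  vertices <- matrix(t(fm[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
  faces <- matrix(seq_len(3L * nTri), ncol = 3L, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

readSTLascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  vIdx <- grep("^\\s*vertex\\s", lines)
  if (length(vIdx) %% 3L != 0L)
    stop(sprintf("malformed ASCII STL %s: %d vertex lines (not a multiple of 3); last at line %d",
                 path, length(vIdx), if (length(vIdx)) max(vIdx) else 0L))
  parse1 <- function(ln, lineNo) {
    xs <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1L]][2:4]))
    if (anyNA(xs))
      stop(sprintf("malformed vertex at line %d of %s", lineNo, path))
    xs
  }
  vertices <- t(mapply(parse1, lines[vIdx], vIdx))
  dimnames(vertices) <- NULL
  nTri <- length(vIdx) %/% 3L
  faces <- matrix(seq_len(3L * nTri), ncol = 3L, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

writeSTLascii <- function(mesh, path) {
  fg <- faceGeometry(mesh)
  u <- as.matrix(fg[, c("ux", "uy", "uz")])
  u[!is.finite(u)] <- 0
  f <- mesh@faces
  v <- mesh@vertices
  fmt <- function(x) sprintf("%.9g", x)
  out <- c("solid meshvol",
           as.vector(rbind(
             sprintf("  facet normal %s %s %s", fmt(u[, 1]), fmt(u[, 2]), fmt(u[, 3])),
             "    outer loop",
             sprintf("      vertex %s %s %s", fmt(v[f[, 1], 1]), fmt(v[f[, 1], 2]), fmt(v[f[, 1], 3])),
             sprintf("      vertex %s %s %s", fmt(v[f[, 2], 1]), fmt(v[f[, 2], 2]), fmt(v[f[, 2], 3])),
             sprintf("      vertex %s %s %s", fmt(v[f[, 3], 1]), fmt(v[f[, 3], 2]), fmt(v[f[, 3], 3])),
             "    endloop",
             "  endfacet")),
           "endsolid meshvol")
  writeLines(out, path)
}

writeSTLbinary <- function(mesh, path) {
  fg <- faceGeometry(mesh)
  u <- as.matrix(fg[, c("ux", "uy", "uz")])
  u[!is.finite(u)] <- 0
  f <- mesh@faces
  v <- mesh@vertices
  n <- nrow(f)
  floats <- t(cbind(u, v[f[, 1L], , drop = FALSE], v[f[, 2L], , drop = FALSE],
                    v[f[, 3L], , drop = FALSE]))  # 12 x n
  fraw <- writeBin(as.numeric(floats), raw(), size = 4L, endian = "little")
  body <- raw(50L * n)
  sel <- rep((seq_len(n) - 1L) * 50L, each = 48L) + rep(1:48, n)
  body[sel] <- fraw
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "meshvol binary STL"))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(n), con, size = 4L, endian = "little")
  writeBin(body, con)
}

readOBJ <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  toks <- strsplit(trimws(lines), "\\s+")
  tag <- vapply(toks, function(x) if (length(x)) x[[1L]] else "", character(1))
  vl <- toks[tag == "v"]
  fl <- toks[tag == "f"]
  vertices <- if (length(vl)) {
    t(vapply(vl, function(x) as.numeric(x[2:4]), numeric(3)))
  } else matrix(numeric(0), 0L, 3L)
  faces <- if (length(fl)) {
    t(vapply(fl, function(x) {
      if (length(x) != 4L)
        stop("only triangular OBJ faces are supported (line: ",
             paste(x, collapse = " "), ")")
      idx <- as.integer(vapply(strsplit(x[2:4], "/"), `[[`, character(1), 1L))
      if (anyNA(idx) || any(idx < 1L))
        stop("invalid OBJ face indices: ", paste(x, collapse = " "))
      idx
    }, integer(3)))
  } else matrix(integer(0), 0L, 3L)
  if (anyNA(vertices)) stop("malformed OBJ vertex line in ", path)
  dimnames(vertices) <- NULL
  list(vertices = vertices, faces = faces)
}

writeOBJ <- function(mesh, path) {
  v <- mesh@vertices
  f <- mesh@faces
  writeLines(c(sprintf("v %.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]),
               sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L])), path)
}

readOFF <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines) || !grepl("^\\s*OFF", lines[[1L]]))
    stop("not an OFF file (line 1): ", path)
  first <- trimws(sub("^\\s*OFF", "", lines[[1L]]))
  if (nzchar(first)) {
    counts <- as.integer(strsplit(first, "\\s+")[[1L]])
    body <- lines[-1L]
  } else {
    counts <- as.integer(strsplit(trimws(lines[[2L]]), "\\s+")[[1L]])
    body <- lines[-(1:2)]
  }
  nv <- counts[1L]; nf <- counts[2L]
  if (is.na(nv) || is.na(nf) || length(body) < nv + nf)
    stop(sprintf("truncated OFF %s: need %d vertex + %d face lines, found %d",
                 path, nv, nf, length(body)))
  vertices <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                       function(x) as.numeric(x[1:3]), numeric(3)))
  faces <- t(vapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                    function(x) {
                      if (as.integer(x[1L]) != 3L)
                        stop("only triangular OFF faces are supported")
                      as.integer(x[2:4]) + 1L  # OFF is 0-based
                    }, integer(3)))
  if (anyNA(vertices)) stop("malformed OFF vertex line in ", path)
  dimnames(vertices) <- NULL
  list(vertices = vertices, faces = faces)
}

writeOFF <- function(mesh, path) {
  v <- mesh@vertices
  f <- mesh@faces
  writeLines(c("OFF",
               sprintf("%d %d 0", nrow(v), nrow(f)),
               sprintf("%.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]),
               sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L)),
             path)
}
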