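# Subdivide triangle (A, B, C) into m^2 congruent triangles (barycentric
# grid), preserving winding. Returns a list of 3 x 3 vertex matrices.
subdivideTriangle <- function(A, B, C, m) {
  pts <- function(i, j) A + (B - A) * (i / m) + (C - A) * (j / m)
  out <- vector("list", m * m)
  k <- 0L
  for (i in 0:(m - 1L)) {
    for (j in 0:(m - 1L - i)) {
      k <- k + 1L
      out[[k]] <- rbind(pts(i, j), pts(i + 1L, j), pts(i, j + 1L))
      if (i + j < m - 1L) {
        k <- k + 1L
        out[[k]] <- rbind(pts(i + 1L, j), pts(i + 1L, j + 1L), pts(i, j + 1L))
      }
    }
  }
  out[seq_len(k)]
}

# Quad patch from corner o spanned by e1, e2, gridded m x m; winding chosen
# so the outward normal is cross(e1, e2).
gridQuad <- function(o, e1, e2, m) {
  out <- vector("list", 2L * m * m)
  k <- 0L
  for (i in 0:(m - 1L)) {
    for (j in 0:(m - 1L)) {
      p00 <- o + e1 * (i / m) + e2 * (j / m)
      p10 <- o + e1 * ((i + 1L) / m) + e2 * (j / m)
      p01 <- o + e1 * (i / m) + e2 * ((j + 1L) / m)
      p11 <- o + e1 * ((i + 1L) / m) + e2 * ((j + 1L) / m)
      out[[k + 1L]] <- rbind(p00, p10, p11)
      out[[k + 2L]] <- rbind(p00, p11, p01)
      k <- k + 2L
    }
  }
  out
}

# Triangle soup (list of 3 x 3 matrices) -> merged TriangleMesh.
soupToMesh <- function(tris) {
  v <- do.call(rbind, tris)
  f <- matrix(seq_len(nrow(v)), ncol = 3L, byrow = TRUE)
  bbDiag <- sqrt(sum((apply(v, 2L, max) - apply(v, 2L, min))^2))
  mg <- mergeVertices(v, f, 1e-8 * max(bbDiag, 1e-300))
  triangleMesh(mg$vertices, mg$faces)
}

#' Benchmark quadrangular pyramid mesh
#'
#' Closed, consistently oriented pyramid with rectangular base
#' `[0, l] x [0, w]` at height 0 and apex above the base centroid at height
#' `h`; analytic volume l w h / 3. `subdivision` refines every face into a
#' triangle grid (level k splits each edge into 2^k parts), so the face
#' count grows while the enclosed volume is exactly unchanged — the handle
#' used to show the estimators are insensitive to facet count.
#'
#' @param l,w,h base length, base width, height (all > 0).
#' @param subdivision refinement level >= 0; level 0 gives 4 side + 2 base
#'   triangles.
#' @return a closed [TriangleMesh-class].
#' @examples
#' volume(signedTetVolume(makePyramid(30, 30, 20)))  # 6000
#' @export
makePyramid <- function(l, w, h, subdivision = 3L) {
  if (l <= 0 || w <= 0 || h <= 0) stop("pyramid dimensions must be positive")
  if (subdivision < 0L) stop("subdivision must be >= 0")
  m <- as.integer(2^subdivision)
  apex <- c(l / 2, w / 2, h)
  c1 <- c(0, 0, 0); c2 <- c(l, 0, 0); c3 <- c(l, w, 0); c4 <- c(0, w, 0)
  tris <- c(
    gridQuad(c(0, 0, 0), c(0, w, 0), c(l, 0, 0), m),  # base, outward -z
    subdivideTriangle(c1, c2, apex, m),
    subdivideTriangle(c2, c3, apex, m),
    subdivideTriangle(c3, c4, apex, m),
    subdivideTriangle(c4, c1, apex, m))
  soupToMesh(tris)
}

#' Benchmark cube mesh
#'
#' Closed axis-aligned cube `[0, a]^3`, each of the 6 faces an m x m grid of
#' 2 m^2 triangles (12 m^2 faces total), outward winding; analytic volume
#' a^3 at every subdivision.
#'
#' @param a edge length (> 0).
#' @param subdivision grid level m >= 1.
#' @return a closed [TriangleMesh-class].
#' @examples
#' nFaces(makeCube(10, subdivision = 4))  # 192
#' @export
makeCube <- function(a, subdivision = 4L) {
  if (a <= 0) stop("cube edge must be positive")
  m <- as.integer(subdivision)
  if (m < 1L) stop("subdivision must be >= 1")
  ex <- c(a, 0, 0); ey <- c(0, a, 0); ez <- c(0, 0, a)
  o <- c(0, 0, 0)
  tris <- c(
    gridQuad(o, ey, ex, m),            # z = 0, outward -z
    gridQuad(ez, ex, ey, m),           # z = a, outward +z
    gridQuad(o, ex, ez, m),            # y = 0, outward -y
    gridQuad(ey, ez, ex, m),           # y = a, outward +y
    gridQuad(o, ez, ey, m),            # x = 0, outward -x
    gridQuad(ex, ey, ez, m))           # x = a, outward +x
  soupToMesh(tris)
}

# Icosphere: icosahedron refined by repeated 4-way splitting, vertices
# projected to the unit sphere.
icosphere <- function(level) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lv in seq_len(level)) {
    nv <- nrow(v)
    midCache <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midCache[[key]]
      if (!is.null(hit)) return(hit)
      p <- (verts[i, ] + verts[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      verts <<- rbind(verts, p)
      idx <- nrow(verts)
      midCache[[key]] <- idx
      idx
    }
    newF <- matrix(0L, 4L * nrow(f), 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1L]; b <- f[t, 2L]; cc <- f[t, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newF[4L * t - 3L, ] <- c(a, ab, ca)
      newF[4L * t - 2L, ] <- c(b, bc, ab)
      newF[4L * t - 1L, ] <- c(cc, ca, bc)
      newF[4L * t, ] <- c(ab, bc, ca)
    }
    v <- verts
    f <- newF
  }
  list(vertices = v, faces = f)
}

#' Specify a synthetic hematoma phantom
#'
#' Builds a [BlobSpec-class] with class-appropriate defaults. The phantom is
#' a star-shaped solid: an ellipsoid with semi-axes `baseRadii` whose radius
#' is modulated by `bumpCount` spherical-Gaussian bumps of relative height
#' `bumpAmplitude` and angular width `bumpWidth`, placed in seeded random
#' directions. `regular` has no bumps (smooth, round-to-ellipsoid margins),
#' `irregular` many small bumps of alternating sign (frayed margins),
#' `lobular` 2-4 large positive bumps (multilobular outline). Default radii
#' (18, 14, 13) give roughly 13.7 units^3 x 10^3 — a mid-sized hematoma when
#' units are mm (about 13.7 ml).
#'
#' @param shapeClass `"regular"`, `"irregular"` or `"lobular"`.
#' @param baseRadii numeric(3) ellipsoid semi-axes.
#' @param bumpCount number of bumps (class default when `NULL`).
#' @param bumpAmplitude relative bump height in [0, 1) (class default when
#'   `NULL`; lobular requires >= 0.3).
#' @param bumpWidth angular width in radians (class default when `NULL`).
#' @param subdivisionLevel icosphere refinement level (level L gives
#'   20 * 4^L faces).
#' @param seed integer seed controlling bump placement.
#' @return a [BlobSpec-class].
#' @seealso [makeBlob()]
#' @export
blobSpec <- function(shapeClass = c("regular", "irregular", "lobular"),
                     baseRadii = c(18, 14, 13), bumpCount = NULL,
                     bumpAmplitude = NULL, bumpWidth = NULL,
                     subdivisionLevel = 3L, seed = 1L) {
  shapeClass <- match.arg(shapeClass)
  defaults <- switch(shapeClass,
    regular   = list(count = 0L, amp = 0,    width = 0.5),
    irregular = list(count = 12L, amp = 0.12, width = 0.35),
    lobular   = list(count = 3L, amp = 0.35, width = 0.7))
  if (is.null(bumpCount)) bumpCount <- defaults$count
  if (is.null(bumpAmplitude)) bumpAmplitude <- defaults$amp
  if (is.null(bumpWidth)) bumpWidth <- defaults$width
  if (shapeClass == "lobular" &&
      (bumpCount < 2L || bumpCount > 4L || bumpAmplitude < 0.3))
    stop("lobular blobs need 2-4 bumps with amplitude >= 0.3")
  if (shapeClass == "irregular" && bumpCount < 5L)
    stop("irregular blobs need many (>= 5) small bumps")
  new("BlobSpec", shapeClass = shapeClass, baseRadii = as.numeric(baseRadii),
      bumpCount = as.integer(bumpCount), bumpAmplitude = as.numeric(bumpAmplitude),
      bumpWidth = as.numeric(bumpWidth),
      subdivisionLevel = as.integer(subdivisionLevel), seed = as.integer(seed))
}

#' Generate a synthetic hematoma phantom mesh
#'
#' Deterministically realizes a [BlobSpec-class]: a unit icosphere is built
#' at the requested subdivision level and every vertex direction d is moved
#' to radius r(d) = rho(d) (1 + sum of bumps), where rho(d) is the ellipsoid
#' radius along d and each bump is a spherical Gaussian
#' A exp(-(angle(d, d_j) / width)^2) at a seeded random direction d_j
#' (lobular bumps all positive, irregular bumps of alternating sign). The
#' construction is star-shaped, so the mesh is closed, consistently
#' oriented and self-intersection-free by construction.
#'
#' @param spec a [BlobSpec-class].
#' @return a closed [TriangleMesh-class]; identical for identical specs.
#' @examples
#' b <- makeBlob(blobSpec("lobular", seed = 7))
#' isClosed(b)
#' @export
makeBlob <- function(spec) {
  stopifnot(is(spec, "BlobSpec"))
  validObject(spec)
  ico <- icosphere(spec@subdivisionLevel)
  d <- ico$vertices
  r <- spec@baseRadii
  rho <- 1 / sqrt((d[, 1L] / r[1L])^2 + (d[, 2L] / r[2L])^2 + (d[, 3L] / r[3L])^2)
  mod <- rep(1, nrow(d))
  if (spec@bumpCount > 0L) {
    dirs <- withSeed(spec@seed, {
      m <- matrix(stats::rnorm(3L * spec@bumpCount), ncol = 3L)
      m / sqrt(rowSums(m^2))
    })
    signs <- switch(spec@shapeClass,
      lobular = rep(1, spec@bumpCount),
      irregular = rep_len(c(1, -1), spec@bumpCount),
      rep(1, spec@bumpCount))
    for (j in seq_len(spec@bumpCount)) {
      ang <- acos(pmin(1, pmax(-1, d %*% dirs[j, ])))
      mod <- mod + signs[j] * spec@bumpAmplitude * exp(-(ang / spec@bumpWidth)^2)
    }
  }
  if (any(mod <= 0))
    stop("bump amplitude produces a non-positive radius; reduce bumpAmplitude")
  triangleMesh(d * (rho * mod), ico$faces)
}

#' Remove a surface patch, producing a non-closed mesh
#'
#' Deletes the faces of a cap or disk from a closed mesh so the result has
#' boundary edges — the "non-closed model" corruption whose effect on each
#' estimator is the package's central robustness experiment. `"base_cap"`
#' removes every face lying in the bottom plane (minimum z), `"top_cap"`
#' every face in the top plane; `list(type = "disk", direction =, angle =)`
#' removes faces whose centroid direction from the mesh centroid is within
#' `angle` radians of `direction`.
#'
#' @param mesh a closed [TriangleMesh-class].
#' @param patch `"base_cap"`, `"top_cap"`, or a disk specification list.
#' @return an open [TriangleMesh-class] with strictly fewer faces.
#' @examples
#' isClosed(openVariant(makePyramid(30, 30, 20), "base_cap"))  # FALSE
#' @export
openVariant <- function(mesh, patch = "base_cap") {
  if (!isClosed(mesh)) stop("openVariant expects a closed mesh")
  v <- mesh@vertices
  f <- mesh@faces
  if (is.character(patch)) {
    patch <- match.arg(patch, c("base_cap", "top_cap"))
    zs <- matrix(v[f, 3L], ncol = 3L)
    zref <- if (patch == "base_cap") min(v[, 3L]) else max(v[, 3L])
    tol <- 1e-7 * max(diff(range(v[, 3L])), 1e-300)
    drop <- rowSums(abs(zs - zref) <= tol) == 3L
  } else if (is.list(patch) && identical(patch$type, "disk")) {
    ctr <- colMeans(v)
    fg <- faceGeometry(mesh)
    dirs <- cbind(fg$avgx - ctr[1L], fg$avgy - ctr[2L], fg$avgz - ctr[3L])
    dirs <- dirs / sqrt(rowSums(dirs^2))
    dd <- as.numeric(patch$direction)
    dd <- dd / sqrt(sum(dd^2))
    drop <- acos(pmin(1, pmax(-1, dirs %*% dd))) <= patch$angle
  } else stop("patch must be \"base_cap\", \"top_cap\" or list(type = \"disk\", ...)")
  if (!any(drop)) stop("patch selects no faces")
  triangleMesh(v, f[!drop, , drop = FALSE])
}

#' Reverse the winding of a random subset of faces
#'
#' Flips the orientation (and therefore the implied normal) of a seeded
#' random fraction of faces — the "incorrect normal information" corruption
#' a marching-cubes reconstruction can produce. Vertices are untouched.
#'
#' @param mesh a [TriangleMesh-class].
#' @param fraction fraction of faces to flip, in (0, 1]; 1 flips every face
#'   (global sign reversal).
#' @param seed integer seed selecting the face subset.
#' @return a [TriangleMesh-class] with the same vertices.
#' @examples
#' volume(signedTetVolume(corruptNormals(makeCube(10), 1, seed = 1)))  # -1000
#' @export
corruptNormals <- function(mesh, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  m <- nFaces(mesh)
  k <- max(1L, min(m, as.integer(round(fraction * m))))
  pick <- if (k == m) seq_len(m) else withSeed(seed, sample.int(m, k))
  f <- mesh@faces
  f[pick, c(2L, 3L)] <- f[pick, c(3L, 2L)]
  triangleMesh(mesh@vertices, f)
}
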