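#' Construct a triangle mesh
#'
#' @param vertices numeric matrix (or coercible) with one row per vertex and
#'   columns x, y, z.
#' @param faces matrix of 1-based vertex-index triples, one row per triangle.
#'   Counter-clockwise winding (seen from outside) encodes the outward normal.
#' @return a [TriangleMesh-class].
#' @examples
#' tet <- triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'                     rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
#' volume(signedTetVolume(tet))  # 1/6
#' @export
triangleMesh <- function(vertices, faces) {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  f <- as.matrix(faces)
  storage.mode(f) <- "integer"
  if (nrow(v) == 0L) v <- matrix(numeric(0), 0L, 3L)
  if (nrow(f) == 0L) f <- matrix(integer(0), 0L, 3L)
  dimnames(v) <- NULL
  dimnames(f) <- NULL
  new("TriangleMesh", vertices = v, faces = f)
}

# Bounding box as a 2 x 3 matrix (row 1 min, row 2 max).
meshBBox <- function(mesh) {
  apply(mesh@vertices, 2L, range)
}

bboxDiagonal <- function(mesh) {
  bb <- meshBBox(mesh)
  sqrt(sum((bb[2L, ] - bb[1L, ])^2))
}

#' Rigidly transform a mesh
#'
#' `translateMesh` shifts every vertex by `offset`; `rotateMesh` applies a
#' right-handed rotation by `angle` radians about a coordinate axis through
#' the origin. Face connectivity and winding are untouched, so enclosed
#' volume is invariant.
#'
#' @param mesh a [TriangleMesh-class].
#' @param offset numeric(3) translation vector.
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param angle rotation angle in radians.
#' @return a transformed [TriangleMesh-class].
#' @export
translateMesh <- function(mesh, offset) {
  stopifnot(length(offset) == 3L)
  triangleMesh(sweep(mesh@vertices, 2L, as.numeric(offset), "+"), mesh@faces)
}

#' @rdname translateMesh
#' @export
rotateMesh <- function(mesh, axis = c("z", "x", "y"), angle) {
  axis <- match.arg(axis)
  ca <- cos(angle); sa <- sin(angle)
  R <- switch(axis,
    x = rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca)),
    y = rbind(c(ca, 0, sa), c(0, 1, 0), c(-sa, 0, ca)),
    z = rbind(c(ca, -sa, 0), c(sa, ca, 0), c(0, 0, 1)))
  triangleMesh(mesh@vertices %*% t(R), mesh@faces)
}

# Unify vertices that coincide within tol (grid snapping on tol-sized cells).
# STL stores per-facet vertices, so merging is a precondition for any
# topology analysis.
mergeVertices <- function(vertices, faces, tol) {
  if (nrow(vertices) == 0L) return(list(vertices = vertices, faces = faces))
  if (tol <= 0) tol <- .Machine$double.eps
  key <- paste(round(vertices[, 1L] / tol), round(vertices[, 2L] / tol),
               round(vertices[, 3L] / tol))
  first <- !duplicated(key)
  newIdx <- match(key, key[first])
  v <- vertices[first, , drop = FALSE]
  f <- matrix(newIdx[faces], ncol = 3L)
  # drop faces collapsed to fewer than 3 distinct vertices
  keep <- f[, 1L] != f[, 2L] & f[, 2L] != f[, 3L] & f[, 1L] != f[, 3L]
  list(vertices = v, faces = f[keep, , drop = FALSE])
}

#' Per-face geometry: edge lengths, Heron area, unit normal, centroid
#'
#' For each requested triangle returns the edge lengths a, b, c, the
#' semi-perimeter s = (a + b + c) / 2, the area by Heron's formula
#' sqrt(s (s - a)(s - b)(s - c)), the unit normal u from the normalized cross
#' product (P1 - P0) x (P2 - P0) (direction set by winding), and the centroid
#' avg = (P0 + P1 + P2) / 3. Degenerate (collinear) faces get area 0, an NA
#' normal and `degenerate = TRUE`; no error is raised because real
#' segmentation meshes contain sliver faces.
#'
#' @param mesh a [TriangleMesh-class].
#' @param faces integer vector of face indices (default: all faces).
#' @return data.frame with columns a, b, c, s, area, ux, uy, uz, avgx, avgy,
#'   avgz, degenerate; one row per requested face.
#' @examples
#' m <- triangleMesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
#'                   rbind(c(1, 2, 3)))
#' faceGeometry(m)$area  # 6
#' @export
faceGeometry <- function(mesh, faces = seq_len(nFaces(mesh))) {
  if (any(faces < 1L | faces > nFaces(mesh)))
    stop("face index out of range")
  f <- mesh@faces[faces, , drop = FALSE]
  P0 <- mesh@vertices[f[, 1L], , drop = FALSE]
  P1 <- mesh@vertices[f[, 2L], , drop = FALSE]
  P2 <- mesh@vertices[f[, 3L], , drop = FALSE]
  a <- sqrt(rowSums((P1 - P0)^2))
  b <- sqrt(rowSums((P2 - P1)^2))
  cc <- sqrt(rowSums((P0 - P2)^2))
  s <- (a + b + cc) / 2
  her <- s * (s - a) * (s - b) * (s - cc)
  area <- sqrt(pmax(her, 0))
  e1 <- P1 - P0
  e2 <- P2 - P0
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  nrm <- sqrt(rowSums(cr^2))
  scale2 <- pmax(a, b, cc)^2
  degenerate <- !is.finite(area) | area <= 1e-12 * pmax(scale2, .Machine$double.eps)
  u <- cr / ifelse(nrm > 0, nrm, NA_real_)
  u[degenerate, ] <- NA_real_
  area[degenerate] <- 0
  avg <- (P0 + P1 + P2) / 3
  data.frame(a = a, b = b, c = cc, s = s, area = area,
             ux = u[, 1L], uy = u[, 2L], uz = u[, 3L],
             avgx = avg[, 1L], avgy = avg[, 2L], avgz = avg[, 3L],
             degenerate = degenerate)
}

# Directed edge table: one row per half-edge, columns from, to, face.
halfEdges <- function(mesh) {
  f <- mesh@faces
  m <- nrow(f)
  data.frame(from = c(f[, 1L], f[, 2L], f[, 3L]),
             to   = c(f[, 2L], f[, 3L], f[, 1L]),
             face = rep.int(seq_len(m), 3L))
}

# Integer-free undirected edge key (double exact below 2^53).
edgeKey <- function(i, j, n) {
  pmin(i, j) * (n + 1) + pmax(i, j)
}

#' Watertightness and orientation diagnostics
#'
#' Edge-multiset analysis of a mesh: closed (watertight) iff every undirected
#' edge is used by exactly two faces; consistently oriented iff every shared
#' edge is traversed once in each direction. Also counts boundary edges (used
#' once), non-manifold edges (used three or more times) and degenerate
#' faces. Only closed, consistently oriented meshes admit a well-defined
#' signed volume; the projection method silently degrades on anything else,
#' which is why these diagnostics exist.
#'
#' @param mesh a [TriangleMesh-class].
#' @return a [TopologyReport-class].
#' @examples
#' topologyReport(makeCube(10))
#' @export
topologyReport <- function(mesh) {
  he <- halfEdges(mesh)
  n <- nVertices(mesh)
  if (nrow(he) == 0L)
    return(new("TopologyReport", isClosed = FALSE,
               isConsistentlyOriented = FALSE, boundaryEdgeCount = 0L,
               degenerateFaceCount = 0L, nonManifoldEdgeCount = 0L))
  und <- edgeKey(he$from, he$to, n)
  cnt <- table(und)
  boundary <- sum(cnt == 1L)
  nonManifold <- sum(cnt >= 3L)
  closed <- all(cnt == 2L)
  # same-direction duplicates mean two faces disagree about the edge
  dirKey <- he$from * (n + 1) + he$to
  oriented <- !anyDuplicated(dirKey) && nonManifold == 0L && boundary == 0L
  degen <- sum(faceGeometry(mesh)$degenerate)
  new("TopologyReport", isClosed = closed,
      isConsistentlyOriented = oriented,
      boundaryEdgeCount = as.integer(boundary),
      degenerateFaceCount = as.integer(degen),
      nonManifoldEdgeCount = as.integer(nonManifold))
}

#' Repair face orientation of a closed mesh
#'
#' Propagates a consistent winding over the face-adjacency graph
#' (breadth-first: two faces sharing an edge must traverse it in opposite
#' directions), then picks the global sign per connected component so the
#' signed enclosed volume is positive. This restores the "accurate normal
#' information" that the projection method requires after, e.g., a marching
#' cubes reconstruction has left flipped facets.
#'
#' @param mesh a closed, edge-manifold [TriangleMesh-class].
#' @return a [TriangleMesh-class] with consistent outward winding.
#' @examples
#' bad <- corruptNormals(makeCube(10), fraction = 0.3, seed = 1)
#' volume(signedTetVolume(reorientMesh(bad)))  # 1000
#' @export
reorientMesh <- function(mesh) {
  m <- nFaces(mesh)
  if (m == 0L) stop("cannot reorient an empty mesh")
  n <- nVertices(mesh)
  f <- mesh@faces
  und <- matrix(edgeKey(c(f[, 1L], f[, 2L], f[, 3L]),
                        c(f[, 2L], f[, 3L], f[, 1L]), n), ncol = 3L)
  cnt <- table(und)
  if (any(cnt >= 3L)) {
    key <- as.numeric(names(cnt)[cnt >= 3L][1L])
    stop(sprintf("non-manifold edge (%d, %d): shared by %d faces",
                 key %/% (n + 1), key %% (n + 1), max(cnt)))
  }
  if (any(cnt == 1L))
    stop("mesh has boundary edges; reorientation requires a closed mesh")
  # adjacency: each undirected edge -> its two incident faces
  ek <- as.vector(und)
  fid <- rep(seq_len(m), 3L)
  o <- order(ek)
  ek <- ek[o]; fid <- fid[o]
  # pairs: positions 1,3,5,... match 2,4,6,...
  fA <- fid[seq(1L, length(fid), by = 2L)]
  fB <- fid[seq(2L, length(fid), by = 2L)]
  adj <- vector("list", m)
  for (i in seq_along(fA)) {
    adj[[fA[i]]] <- c(adj[[fA[i]]], fB[i])
    adj[[fB[i]]] <- c(adj[[fB[i]]], fA[i])
  }
  flipped <- logical(m)
  visited <- logical(m)
  comp <- integer(m)
  ncomp <- 0L
  dirEdges <- function(i) {
    tri <- f[i, ]
    if (flipped[i]) tri <- tri[c(1L, 3L, 2L)]
    rbind(c(tri[1L], tri[2L]), c(tri[2L], tri[3L]), c(tri[3L], tri[1L]))
  }
  for (start in seq_len(m)) {
    if (visited[start]) next
    ncomp <- ncomp + 1L
    queue <- start
    visited[start] <- TRUE
    comp[start] <- ncomp
    while (length(queue)) {
      i <- queue[[1L]]
      queue <- queue[-1L]
      de <- dirEdges(i)
      for (g in adj[[i]]) {
        if (visited[g]) next
        dg <- dirEdges(g)
        # find the shared undirected edge and compare traversal direction
        same <- FALSE
        for (r in 1:3) for (q in 1:3) {
          if (de[r, 1L] == dg[q, 1L] && de[r, 2L] == dg[q, 2L]) same <- TRUE
        }
        if (same) flipped[g] <- !flipped[g]
        visited[g] <- TRUE
        comp[g] <- ncomp
        queue <- c(queue, g)
      }
    }
  }
  fOut <- f
  fOut[flipped, c(2L, 3L)] <- fOut[flipped, c(3L, 2L)]
  out <- triangleMesh(mesh@vertices, fOut)
  # per-component sign so each shell encloses positive volume
  tet <- tetContrib(out)
  for (k in seq_len(ncomp)) {
    idx <- comp == k
    if (sum(tet[idx]) < 0)
      fOut[idx, c(2L, 3L)] <- fOut[idx, c(3L, 2L)]
  }
  triangleMesh(mesh@vertices, fOut)
}

# Per-face signed tetrahedron contribution det(P0, P1, P2) / 6.
tetContrib <- function(mesh) {
  f <- mesh@faces
  P0 <- mesh@vertices[f[, 1L], , drop = FALSE]
  P1 <- mesh@vertices[f[, 2L], , drop = FALSE]
  P2 <- mesh@vertices[f[, 3L], , drop = FALSE]
  (P0[, 1L] * (P1[, 2L] * P2[, 3L] - P1[, 3L] * P2[, 2L]) -
   P0[, 2L] * (P1[, 1L] * P2[, 3L] - P1[, 3L] * P2[, 1L]) +
   P0[, 3L] * (P1[, 1L] * P2[, 2L] - P1[, 2L] * P2[, 1L])) / 6
}

#' Signed tetrahedron-sum volume (exact oracle)
#'
#' Sums det(P0, P1, P2)/6 over all faces: the exact enclosed volume of a
#' closed, consistently oriented mesh (up to floating-point rounding),
#' independent of translation. Serves as the brute-force reference the other
#' estimators are validated against; it is deliberately the most literal
#' implementation possible.
#'
#' @param mesh a closed [TriangleMesh-class].
#' @return a [VolumeEstimate-class] with method `"tet_oracle"`. The value is
#'   signed: a consistently inward-wound mesh gives the negative volume.
#' @examples
#' volume(signedTetVolume(makePyramid(30, 30, 20)))  # 6000
#' @export
signedTetVolume <- function(mesh) {
  if (nFaces(mesh) == 0L) stop("empty mesh")
  rep_ <- topologyReport(mesh)
  if (!rep_@isClosed)
    stop("signed tetrahedron sum is undefined for an open mesh (",
         rep_@boundaryEdgeCount, " boundary edges)")
  w <- character()
  if (!rep_@isConsistentlyOriented)
    w <- "mesh is not consistently oriented; signed sum is unreliable"
  new("VolumeEstimate", method = "tet_oracle",
      volume = sum(tetContrib(mesh)), params = list(), warnings = w)
}

# Parity ray casting along +x with deterministic jitter re-casts on
# degenerate hits. points: k x 3 matrix. Returns logical vector.
rayParityInside <- function(points, mesh, jitterSeed = 0L, maxTries = 4L) {
  f <- mesh@faces
  A <- mesh@vertices[f[, 1L], , drop = FALSE]
  B <- mesh@vertices[f[, 2L], , drop = FALSE]
  C <- mesh@vertices[f[, 3L], , drop = FALSE]
  diag_ <- bboxDiagonal(mesh)
  epsB <- 1e-10
  epsX <- 1e-12 * max(diag_, 1)
  triYmin <- pmin(A[, 2L], B[, 2L], C[, 2L])
  triYmax <- pmax(A[, 2L], B[, 2L], C[, 2L])
  triZmin <- pmin(A[, 3L], B[, 3L], C[, 3L])
  triZmax <- pmax(A[, 3L], B[, 3L], C[, 3L])
  triXmax <- pmax(A[, 1L], B[, 1L], C[, 1L])
  denom <- (B[, 2L] - A[, 2L]) * (C[, 3L] - A[, 3L]) -
           (C[, 2L] - A[, 2L]) * (B[, 3L] - A[, 3L])
  jitters <- withSeed(jitterSeed, matrix(stats::runif(3L * maxTries, -1, 1),
                                         ncol = 3L))
  castOnce <- function(P) {
    k <- nrow(P)
    crossings <- integer(k)
    bad <- logical(k)
    ord <- order(P[, 2L])
    ys <- P[ord, 2L]
    for (t in seq_len(nrow(f))) {
      if (abs(denom[t]) < 1e-14 * max(diag_^2, 1)) next  # edge-on to +x rays
      i1 <- findInterval(triYmin[t] - epsX, ys) + 1L
      i2 <- findInterval(triYmax[t] + epsX, ys)
      if (i2 < i1) next
      idx <- ord[i1:i2]
      idx <- idx[P[idx, 3L] >= triZmin[t] - epsX & P[idx, 3L] <= triZmax[t] + epsX]
      idx <- idx[P[idx, 1L] <= triXmax[t] + epsX]
      if (!length(idx)) next
      py <- P[idx, 2L]; pz <- P[idx, 3L]
      w1 <- ((py - A[t, 2L]) * (C[t, 3L] - A[t, 3L]) -
             (C[t, 2L] - A[t, 2L]) * (pz - A[t, 3L])) / denom[t]
      w2 <- ((B[t, 2L] - A[t, 2L]) * (pz - A[t, 3L]) -
             (py - A[t, 2L]) * (B[t, 3L] - A[t, 3L])) / denom[t]
      w0 <- 1 - w1 - w2
      nearEdge <- (abs(w0) < epsB | abs(w1) < epsB | abs(w2) < epsB) &
                  (w0 > -epsB & w1 > -epsB & w2 > -epsB)
      inside2d <- w0 > epsB & w1 > epsB & w2 > epsB
      xhit <- w0 * A[t, 1L] + w1 * B[t, 1L] + w2 * C[t, 1L]
      dx <- xhit - P[idx, 1L]
      grazing <- inside2d & abs(dx) < epsX
      bad[idx[nearEdge | grazing]] <- TRUE
      hit <- inside2d & dx > epsX
      crossings[idx[hit]] <- crossings[idx[hit]] + 1L
    }
    list(inside = crossings %% 2L == 1L, bad = bad)
  }
  P <- points
  res <- castOnce(P)
  inside <- res$inside
  bad <- res$bad
  tries <- 0L
  while (any(bad) && tries < maxTries) {
    tries <- tries + 1L
    delta <- jitters[tries, ] * (1e-7 * diag_)
    sub <- sweep(points[bad, , drop = FALSE], 2L, delta, "+")
    r2 <- castOnce(sub)
    inside[bad] <- r2$inside
    bad[bad] <- r2$bad
  }
  inside
}

#' Monte-Carlo rejection-sampling volume (stochastic oracle)
#'
#' Samples points uniformly in the mesh bounding box, classifies each by ray
#' parity, and scales the inside fraction by the box volume. An independent
#' stochastic check on the deterministic estimators; the standard error
#' bboxVolume * sqrt(p (1 - p) / n) is recorded in the params.
#'
#' @param mesh a closed [TriangleMesh-class].
#' @param nSamples number of sample points (>= 1000).
#' @param seed integer seed; identical seeds give identical estimates.
#' @return a [VolumeEstimate-class] with method `"mc_oracle"` and params
#'   `nSamples`, `seed`, `stderr`.
#' @export
monteCarloVolume <- function(mesh, nSamples = 100000L, seed = 1L) {
  if (nSamples < 1000L) stop("nSamples must be at least 1000")
  rep_ <- topologyReport(mesh)
  if (!rep_@isClosed) stop("Monte-Carlo volume requires a closed mesh")
  bb <- meshBBox(mesh)
  ext <- bb[2L, ] - bb[1L, ]
  boxVol <- prod(ext)
  P <- withSeed(seed, {
    cbind(stats::runif(nSamples, bb[1L, 1L], bb[2L, 1L]),
          stats::runif(nSamples, bb[1L, 2L], bb[2L, 2L]),
          stats::runif(nSamples, bb[1L, 3L], bb[2L, 3L]))
  })
  p <- mean(rayParityInside(P, mesh))
  new("VolumeEstimate", method = "mc_oracle", volume = boxVol * p,
      params = list(nSamples = as.integer(nSamples), seed = as.integer(seed),
                    stderr = boxVol * sqrt(p * (1 - p) / nSamples)),
      warnings = character())
}
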