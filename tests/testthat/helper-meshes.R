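# Shared fixtures, all built in code.

relErr <- function(a, b) abs(a - b) / max(1, abs(b))

# Unit right tetrahedron (volume 1/6), outward winding.
unitTetra <- function() {
  triangleMesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
}

# Seeded random non-degenerate triangle meshes (single faces) for
# per-face geometry properties.
randomTriangles <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      v <- matrix(runif(9, -5, 5), 3L, 3L)
      e1 <- v[2L, ] - v[1L, ]; e2 <- v[3L, ] - v[1L, ]
      cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
              e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])
      if (sqrt(sum(cr^2)) > 1e-3) return(v)
    }
  })
}

# Analytic inside test for the benchmark pyramid (base [0,l]x[0,w] at z = 0,
# apex over the centre at z = h) -- the independent oracle for point
# classification.
pointInPyramidAnalytic <- function(P, l = 30, w = 30, h = 20) {
  P[, 3] >= 0 & P[, 3] <= h &
    abs(P[, 1] - l / 2) <= (l / 2) * (1 - P[, 3] / h) &
    abs(P[, 2] - w / 2) <= (w / 2) * (1 - P[, 3] / h)
}

# Closed phantom set spanning the benchmark solids and all blob classes.
closedPhantoms <- function(level = 2L) {
  list(
    pyramid = makePyramid(30, 30, 20, subdivision = 2),
    cube = makeCube(10, subdivision = 2),
    regular = makeBlob(blobSpec("regular", seed = 1, subdivisionLevel = level)),
    irregular = makeBlob(blobSpec("irregular", seed = 2, subdivisionLevel = level)),
    lobular = makeBlob(blobSpec("lobular", seed = 3, subdivisionLevel = level)))
}
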