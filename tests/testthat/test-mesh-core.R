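test_that("face geometry: Heron area, normals and centroid identities", {
  # right triangle with legs 3 and 4
  m <- triangleMesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)), rbind(c(1, 2, 3)))
  expect_equal(faceGeometry(m)$area, 6)
  # equilateral, side 2
  m <- triangleMesh(rbind(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0)),
                    rbind(c(1, 2, 3)))
  expect_equal(faceGeometry(m)$area, sqrt(3), tolerance = 1e-12)
  # collinear face: degenerate flag, area 0, no error
  m <- triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), rbind(c(1, 2, 3)))
  fg <- faceGeometry(m)
  expect_true(fg$degenerate)
  expect_identical(fg$area, 0)
  expect_true(is.na(fg$ux))
  # property: Heron equals half cross-product norm; unit normal; centroid
  for (v in randomTriangles(50, seed = 101)) {
    m <- triangleMesh(v, rbind(c(1, 2, 3)))
    fg <- faceGeometry(m)
    e1 <- v[2L, ] - v[1L, ]; e2 <- v[3L, ] - v[1L, ]
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    expect_equal(fg$area, sqrt(sum(cr^2)) / 2, tolerance = 1e-9)
    expect_equal(sqrt(fg$ux^2 + fg$uy^2 + fg$uz^2), 1, tolerance = 1e-12)
    expect_equal(fg$s, (fg$a + fg$b + fg$c) / 2, tolerance = 1e-12)
    expect_equal(c(fg$avgx, fg$avgy, fg$avgz), colMeans(v), tolerance = 1e-12)
  }
})

test_that("topology report detects closure, orientation and bad edges", {
  cube <- makeCube(10, subdivision = 1)
  rep_ <- topologyReport(cube)
  expect_true(rep_@isClosed)
  expect_true(rep_@isConsistentlyOriented)
  expect_identical(rep_@boundaryEdgeCount, 0L)
  expect_true(isClosed(cube) && isOriented(cube))
  # one face removed: the 3 edges of that face become boundary edges
  holed <- triangleMesh(meshVertices(cube), meshFaces(cube)[-1L, ])
  rep_ <- topologyReport(holed)
  expect_false(rep_@isClosed)
  expect_identical(rep_@boundaryEdgeCount, 3L)
  # one face winding flipped: still closed, no longer consistently oriented
  f <- meshFaces(cube)
  f[1L, c(2, 3)] <- f[1L, c(3, 2)]
  flipped <- triangleMesh(meshVertices(cube), f)
  rep_ <- topologyReport(flipped)
  expect_true(rep_@isClosed)
  expect_false(rep_@isConsistentlyOriented)
  # three faces on one edge: non-manifold
  fan <- triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                            c(0, -1, 0)),
                      rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)))
  expect_identical(topologyReport(fan)@nonManifoldEdgeCount, 1L)
})

test_that("signed tet-sum oracle: exact values, rigid invariance, open-mesh error", {
  expect_equal(volume(signedTetVolume(makeCube(1, subdivision = 1))), 1)
  expect_equal(volume(signedTetVolume(unitTetra())), 1 / 6, tolerance = 1e-15)
  pyr <- makePyramid(30, 30, 20)
  expect_equal(volume(signedTetVolume(pyr)), 6000, tolerance = 1e-12)
  # invariance under translation and rotation
  for (mesh in list(pyr, makeBlob(blobSpec("lobular", seed = 4,
                                           subdivisionLevel = 2)))) {
    v0 <- volume(signedTetVolume(mesh))
    moved <- rotateMesh(translateMesh(mesh, c(-11, 7, 123)), "y", 0.83)
    expect_equal(volume(signedTetVolume(moved)), v0, tolerance = 1e-9 * abs(v0))
  }
  expect_error(signedTetVolume(openVariant(pyr, "base_cap")), "open")
})

test_that("reorientation restores outward winding from any flipped subset", {
  cube <- makeCube(10, subdivision = 2)
  set.seed(7)
  for (k in c(3L, 10L, nFaces(cube))) {
    f <- meshFaces(cube)
    pick <- sample.int(nrow(f), k)
    f[pick, c(2, 3)] <- f[pick, c(3, 2)]
    fixed <- reorientMesh(triangleMesh(meshVertices(cube), f))
    expect_equal(volume(signedTetVolume(fixed)), 1000, tolerance = 1e-12)
    expect_true(isOriented(fixed))
  }
  # idempotence on an already consistent mesh
  expect_identical(meshFaces(reorientMesh(cube)), meshFaces(cube))
  # preconditions
  holed <- triangleMesh(meshVertices(cube), meshFaces(cube)[-1L, ])
  expect_error(reorientMesh(holed), "boundary")
  fan <- triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                            c(0, -1, 0)),
                      rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)))
  expect_error(reorientMesh(fan), "non-manifold")
})

test_that("Monte-Carlo oracle: exact for the aligned cube, 3-sigma on the pyramid, deterministic", {
  cube <- makeCube(10, subdivision = 1)
  mc <- monteCarloVolume(cube, 2000, seed = 5)
  # the bounding box IS the solid, so every sample is inside
  expect_equal(volume(mc), 1000)
  expect_equal(estimateParams(mc)$stderr, 0)
  pyr <- makePyramid(30, 30, 20)
  mc1 <- monteCarloVolume(pyr, 200000, seed = 1)
  expect_lt(abs(volume(mc1) - 6000), 3 * estimateParams(mc1)$stderr)
  mc2 <- monteCarloVolume(pyr, 200000, seed = 1)
  expect_identical(volume(mc1), volume(mc2))
  expect_error(monteCarloVolume(pyr, 10, seed = 1), "1000")
  expect_error(monteCarloVolume(openVariant(pyr, "base_cap"), 2000, seed = 1),
               "closed")
})

test_that("mesh validity rejects malformed vertex/face data", {
  expect_error(triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0)), rbind(c(1, 2, 3))),
               "out of range|at least 3")
  expect_error(triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                            rbind(c(1, 2, 2))), "repeats")
})
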