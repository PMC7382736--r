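test_that("benchmark solids are closed with subdivision-independent exact volumes", {
  expect_identical(nFaces(makePyramid(30, 30, 20, subdivision = 0)), 6L)
  for (s in 0:3) {
    pyr <- makePyramid(30, 30, 20, subdivision = s)
    rep_ <- topologyReport(pyr)
    expect_true(rep_@isClosed && rep_@isConsistentlyOriented)
    expect_equal(volume(signedTetVolume(pyr)), 6000, tolerance = 1e-12)
  }
  for (m in c(1L, 2L, 4L)) {
    cube <- makeCube(10, subdivision = m)
    expect_identical(nFaces(cube), 12L * m * m)
    expect_true(isClosed(cube))
    expect_equal(volume(signedTetVolume(cube)), 1000, tolerance = 1e-12)
  }
  expect_error(makePyramid(-1, 30, 20), "positive")
  expect_error(makeCube(0), "positive")
})

test_that("blob phantoms: ellipsoid limit, determinism, valid shape classes", {
  # smooth ellipsoid converges to the analytic volume
  b <- makeBlob(blobSpec("regular", baseRadii = c(2, 1.5, 1),
                         subdivisionLevel = 4))
  expect_equal(volume(signedTetVolume(b)), 4 / 3 * pi * 2 * 1.5 * 1,
               tolerance = 0.005)
  # identical spec, identical mesh
  s1 <- makeBlob(blobSpec("irregular", seed = 11, subdivisionLevel = 2))
  s2 <- makeBlob(blobSpec("irregular", seed = 11, subdivisionLevel = 2))
  expect_identical(meshVertices(s1), meshVertices(s2))
  expect_identical(meshFaces(s1), meshFaces(s2))
  # star-shaped construction is closed and oriented for every class
  for (cl in c("regular", "irregular", "lobular")) {
    m <- makeBlob(blobSpec(cl, seed = 5, subdivisionLevel = 2))
    rep_ <- topologyReport(m)
    expect_true(rep_@isClosed && rep_@isConsistentlyOriented)
  }
  # spec validity rules
  expect_error(blobSpec("lobular", bumpAmplitude = 0.1), "lobular")
  expect_error(blobSpec("irregular", bumpCount = 2), "irregular")
  expect_error(blobSpec("regular", bumpAmplitude = 1.2), "regular|amplitude")
})

test_that("cap removal opens the mesh by exactly the planar patch", {
  pyr <- makePyramid(30, 30, 20)  # base grid is 8x8 -> 128 base triangles
  open_ <- openVariant(pyr, "base_cap")
  expect_identical(nFaces(pyr) - nFaces(open_), 128L)
  rep_ <- topologyReport(open_)
  expect_false(rep_@isClosed)
  expect_gt(rep_@boundaryEdgeCount, 0L)
  # removed faces were exactly those in the z = 0 plane
  zmax <- max(meshVertices(open_)[meshFaces(open_), 3])
  fg <- faceGeometry(open_)
  expect_true(all(abs(fg$uz) < 1 - 1e-9 | fg$avgz > 0))
  cube <- makeCube(10)
  openc <- openVariant(cube, "top_cap")
  expect_identical(nFaces(cube) - nFaces(openc), 32L)  # 2 * 4^2 top triangles
  expect_false(isClosed(openc))
  # disk patch on a blob removes a small face set
  blob <- makeBlob(blobSpec("regular", subdivisionLevel = 2))
  holed <- openVariant(blob, list(type = "disk", direction = c(1, 0, 0),
                                  angle = 0.3))
  expect_lt(nFaces(holed), nFaces(blob))
  expect_false(isClosed(holed))
  # errors: empty patch, already-open input
  expect_error(openVariant(blob, list(type = "disk", direction = c(1, 0, 0),
                                      angle = 1e-9)), "no faces")
  expect_error(openVariant(open_, "base_cap"), "closed")
})

test_that("normal corruption flips a seeded subset and reorientation undoes it", {
  cube <- makeCube(10, subdivision = 2)
  # fraction 1: global sign flip
  expect_equal(volume(signedTetVolume(corruptNormals(cube, 1, seed = 1))),
               -1000, tolerance = 1e-12)
  # deterministic subset for a fixed seed
  a <- corruptNormals(cube, 0.1, seed = 42)
  b <- corruptNormals(cube, 0.1, seed = 42)
  expect_identical(meshFaces(a), meshFaces(b))
  expect_identical(meshVertices(a), meshVertices(cube))
  # corrupt then reorient restores the oracle volume
  bad <- corruptNormals(cube, 0.3, seed = 9)
  expect_false(isOriented(bad))
  expect_equal(volume(signedTetVolume(reorientMesh(bad))), 1000,
               tolerance = 1e-12)
  expect_error(corruptNormals(cube, 0), "fraction")
  expect_error(corruptNormals(cube, 1.5), "fraction")
})
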