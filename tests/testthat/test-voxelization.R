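test_that("octree structure: depth-1 split, aligned cube resolves without boundary cells", {
  cube <- makeCube(10, subdivision = 2)
  oc1 <- buildOctree(cube, depth = 1)
  expect_identical(nrow(octreeCells(oc1)), 8L)
  # grid-aligned faces are touching contacts, not intersections: every leaf
  # is inside and the enclosed volume is exact
  cells <- octreeCells(oc1)
  expect_true(all(cells$state == "inside"))
  oc3 <- buildOctree(cube, depth = 3)
  cells3 <- octreeCells(oc3)
  expect_identical(sum(cells3$state == "boundary"), 0L)
  expect_equal(sum(cells3$side[cells3$state == "inside"]^3), 1000,
               tolerance = 1e-12)
  # children partition the parent: total leaf volume is the root volume
  expect_equal(sum(cells3$side^3), oc3@rootSide^3, tolerance = 1e-9)
})

test_that("leaf classification matches the analytic pyramid inside test", {
  pyr <- makePyramid(30, 30, 20, subdivision = 2)
  set.seed(13)
  P <- cbind(runif(10000, -2, 32), runif(10000, -2, 32), runif(10000, -2, 22))
  truth <- pointInPyramidAnalytic(P)
  # stay clear of the surface where inside/outside is ill-posed
  margin <- abs(pmax(abs(P[, 1] - 15), abs(P[, 2] - 15)) -
                15 * (1 - P[, 3] / 20)) > 1e-6 &
            abs(P[, 3]) > 1e-6 & abs(P[, 3] - 20) > 1e-6
  got <- pointInMesh(pyr, P)
  expect_identical(got[margin], truth[margin])
  # single obvious cases
  expect_true(pointInMesh(pyr, rbind(c(15, 15, 5))))
  expect_false(pointInMesh(pyr, rbind(c(100, 0, 0))))
})

test_that("boundary cell count grows like a surface (about 4x per depth)", {
  blob <- makeBlob(blobSpec("regular", subdivisionLevel = 2))
  counts <- vapply(3:5, function(d) {
    sum(octreeCells(buildOctree(blob, d))$state == "boundary")
  }, numeric(1))
  ratios <- counts[-1] / counts[-length(counts)]
  expect_true(all(ratios > 3 & ratios < 6))
})

test_that("slice-aligned refinement reproduces slice method 2 on every phantom", {
  for (mesh in closedPhantoms()) {
    vv <- volume(voxelVolume(mesh, segments = 5))
    sv <- volume(sliceVolume(mesh, segments = 5, rule = "method2"))
    expect_equal(vv, sv, tolerance = 1e-9 * abs(sv))
  }
})

test_that("inside volume sandwiches the oracle monotonically", {
  pyr <- makePyramid(30, 30, 20, subdivision = 2)
  prev <- 0
  for (s in 3:5) {
    est <- voxelVolume(pyr, segments = s)
    p <- estimateParams(est)
    expect_gte(p$insideVolume, prev)
    expect_lte(p$insideVolume, 6000 + 1e-9)
    expect_gte(p$insideVolume + p$boundaryCells * p$leafSize^3, 6000 - 1e-9)
    expect_equal(volume(est), p$insideVolume + p$boundaryVolume,
                 tolerance = 1e-9 * 6000)
    prev <- p$insideVolume
  }
})

test_that("per-voxel sub-slicing converges with at least halving error per depth", {
  pyr <- makePyramid(30, 30, 20, subdivision = 2)
  errs <- vapply(3:5, function(s) {
    abs(volume(voxelVolume(pyr, segments = s, refinement = "sub_slices",
                           subSlices = 4)) - 6000)
  }, numeric(1))
  expect_true(all(errs[-1] <= errs[-length(errs)] / 2))
  # and the blob invariant: inside volume never exceeds the total
  blob <- makeBlob(blobSpec("lobular", seed = 3, subdivisionLevel = 2))
  est <- voxelVolume(blob, segments = 4, refinement = "sub_slices",
                     subSlices = 4)
  expect_lte(estimateParams(est)$insideVolume, volume(est))
})

test_that("voxel estimates ignore missing caps and flipped normals", {
  pyr <- makePyramid(30, 30, 20, subdivision = 2)
  vc <- volume(voxelVolume(pyr, segments = 5))
  vo <- volume(voxelVolume(openVariant(pyr, "base_cap"), segments = 5))
  expect_equal(vo, vc, tolerance = 1e-6 * abs(vc))
  vf <- volume(voxelVolume(corruptNormals(pyr, 0.5, seed = 4), segments = 5))
  expect_equal(vf, vc, tolerance = 1e-6 * abs(vc))
  cube <- makeCube(10, subdivision = 2)
  vc <- volume(voxelVolume(cube, segments = 5))
  vo <- volume(voxelVolume(openVariant(cube, "top_cap"), segments = 5))
  expect_equal(vo, vc, tolerance = 1e-6 * abs(vc))
})

test_that("unresolvably coarse grids fall back to a flagged boundary-only estimate", {
  slab <- makePyramid(30, 30, 1.5, subdivision = 1)  # root cube side 30
  est <- voxelVolume(slab, segments = 2)
  expect_match(estimateWarnings(est), "boundary-only", all = FALSE)
  expect_identical(estimateParams(est)$insideVolume, 0)
  expect_error(voxelVolume(makeCube(10), segments = 1), "segments")
})
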