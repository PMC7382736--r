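test_that("cross-sections have the analytic areas and close their contours", {
  cube <- makeCube(10)
  cs <- crossSection(cube, "z", 5)
  expect_length(cs@polygons, 1L)
  expect_equal(cs@area, 100, tolerance = 1e-9)
  expect_identical(cs@openChainCount, 0L)
  # pyramid cross-sections shrink linearly: side 30 (1 - z/h)
  pyr <- makePyramid(30, 30, 20)
  expect_equal(crossSection(pyr, "z", 10)@area, 225, tolerance = 1e-3)
  expect_equal(crossSection(pyr, "z", 5)@area, (30 * 0.75)^2, tolerance = 1e-3)
  # plane outside the solid
  miss <- crossSection(cube, "z", 25)
  expect_identical(miss@area, 0)
  expect_length(miss@polygons, 0L)
  # slicing works along any axis
  expect_equal(crossSection(cube, "x", 5)@area, 100, tolerance = 1e-9)
})

test_that("frustum rule is exact for pyramids and both rules for prisms", {
  pyr <- makePyramid(30, 30, 20, subdivision = 2)
  for (s in 3:6) {
    expect_equal(volume(sliceVolume(pyr, segments = s, rule = "method1")),
                 6000, tolerance = 1e-5 * 6000)
  }
  cube <- makeCube(10, subdivision = 2)
  for (rule in c("method1", "method2")) {
    expect_equal(volume(sliceVolume(cube, segments = 6, rule = rule)), 1000,
                 tolerance = 1e-9 * 1000)
  }
  # frustum beats trapezoid on the pyramid at every resolution
  for (s in 3:6) {
    e1 <- abs(volume(sliceVolume(pyr, segments = s, rule = "method1")) - 6000)
    e2 <- abs(volume(sliceVolume(pyr, segments = s, rule = "method2")) - 6000)
    expect_lt(e1, e2)
  }
})

test_that("trapezoid error on the pyramid matches the closed form", {
  # S(z) = 900 (1 - z/20)^2 gives composite-trapezoid error
  # (b - a) h^2 S''/12 = 20 * (20/128)^2 * 4.5 / 12 at 128 intervals
  analytic <- 6000 + 20 * (20 / 128)^2 * 4.5 / 12
  expect_equal(analytic, 6000.18310546875)  # frozen closed form
  got <- volume(sliceVolume(makePyramid(30, 30, 20), segments = 7,
                            rule = "method2"))
  expect_equal(got, analytic, tolerance = 1e-3 / analytic)
})

test_that("trapezoid error shrinks about 4x per slice doubling on smooth phantoms", {
  blob <- makeBlob(blobSpec("regular", seed = 1))
  oracle <- volume(signedTetVolume(blob))
  errs <- vapply(4:6, function(s) {
    abs(volume(sliceVolume(blob, segments = s, rule = "method2")) - oracle)
  }, numeric(1))
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 3 & ratios < 8))
})

test_that("slice estimates ignore missing caps and flipped normals", {
  pyr <- makePyramid(30, 30, 20, subdivision = 2)
  openP <- openVariant(pyr, "base_cap")
  cube <- makeCube(10, subdivision = 2)
  openC <- openVariant(cube, "top_cap")
  for (rule in c("method1", "method2")) {
    vc <- volume(sliceVolume(pyr, segments = 5, rule = rule))
    vo <- volume(sliceVolume(openP, segments = 5, rule = rule))
    expect_equal(vo, vc, tolerance = 1e-6 * abs(vc))
    vc <- volume(sliceVolume(cube, segments = 5, rule = rule))
    vo <- volume(sliceVolume(openC, segments = 5, rule = rule))
    expect_equal(vo, vc, tolerance = 1e-6 * abs(vc))
  }
  # contours never read orientation
  bad <- corruptNormals(pyr, 0.4, seed = 2)
  expect_equal(volume(sliceVolume(bad, segments = 5, rule = "method1")),
               volume(sliceVolume(pyr, segments = 5, rule = "method1")),
               tolerance = 1e-12 * 6000)
  # gap-closing is counted on planes through the hole
  blob <- makeBlob(blobSpec("regular", subdivisionLevel = 2))
  holed <- openVariant(blob, list(type = "disk", direction = c(1, 0, 0),
                                  angle = 0.4))
  zs <- meshVertices(holed)[, 3]
  csum <- sum(vapply(seq(min(zs), max(zs), length.out = 20), function(z) {
    crossSection(holed, "z", z)@openChainCount
  }, integer(1)))
  expect_gt(csum, 0L)
})

test_that("a dense area stack integrates to the oracle volume within 1 percent", {
  blob <- makeBlob(blobSpec("lobular", seed = 3))
  oracle <- volume(signedTetVolume(blob))
  st <- sliceStack(blob, "z", 256)
  trap <- sum((st@areas[-1] + st@areas[-length(st@areas)]) / 2) * st@step
  expect_equal(trap, oracle, tolerance = 0.01 * abs(oracle))
  df <- as.data.frame(st)
  expect_identical(names(df), c("position", "area"))
  expect_identical(nrow(df), 257L)
})

test_that("degenerate slicing inputs error cleanly", {
  flat <- triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(c(1, 2, 3)))
  expect_error(sliceVolume(flat, axis = "z", segments = 3), "extent")
  expect_error(sliceVolume(makeCube(10), segments = 0), "segments")
})
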