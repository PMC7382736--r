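#' Accessors for meshvol objects
#'
#' Small generic accessors so slot access never appears in user code:
#' `volume()` extracts the scalar estimate from a [VolumeEstimate-class],
#' `nVertices()`/`nFaces()` the mesh sizes, `meshVertices()`/`meshFaces()`
#' the coordinate and index matrices, and `isClosed()`/`isOriented()` the
#' watertightness and orientation flags (computed on the fly for a mesh).
#'
#' @param x a meshvol object.
#' @return `volume()` a numeric scalar; `nVertices()`/`nFaces()` integers;
#'   `meshVertices()` an n x 3 numeric matrix; `meshFaces()` an m x 3 integer
#'   matrix; `isClosed()`/`isOriented()` logicals.
#' @examples
#' m <- makeCube(10)
#' nFaces(m)
#' isClosed(m)
#' volume(signedTetVolume(m))
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volume", function(x) standardGeneric("volume"))

#' @rdname accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname accessors
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname accessors
#' @export
setGeneric("isClosed", function(x) standardGeneric("isClosed"))

#' @rdname accessors
#' @export
setGeneric("isOriented", function(x) standardGeneric("isOriented"))

#' @rdname accessors
#' @export
setMethod("volume", "VolumeEstimate", function(x) x@volume)

#' @rdname accessors
#' @export
setMethod("nVertices", "TriangleMesh", function(x) nrow(x@vertices))

#' @rdname accessors
#' @export
setMethod("nFaces", "TriangleMesh", function(x) nrow(x@faces))

#' @rdname accessors
#' @export
setMethod("meshVertices", "TriangleMesh", function(x) x@vertices)

#' @rdname accessors
#' @export
setMethod("meshFaces", "TriangleMesh", function(x) x@faces)

#' @rdname accessors
#' @export
setMethod("isClosed", "TopologyReport", function(x) x@isClosed)

#' @rdname accessors
#' @export
setMethod("isClosed", "TriangleMesh", function(x) topologyReport(x)@isClosed)

#' @rdname accessors
#' @export
setMethod("isOriented", "TopologyReport", function(x) x@isConsistentlyOriented)

#' @rdname accessors
#' @export
setMethod("isOriented", "TriangleMesh",
          function(x) topologyReport(x)@isConsistentlyOriented)

#' Method tag of a volume estimate
#'
#' @param x a [VolumeEstimate-class].
#' @return character scalar, the estimator tag.
#' @export
estimateMethod <- function(x) {
  stopifnot(is(x, "VolumeEstimate"))
  x@method
}

#' Parameters recorded with a volume estimate
#'
#' @param x a [VolumeEstimate-class].
#' @return named list of method parameters.
#' @export
estimateParams <- function(x) {
  stopifnot(is(x, "VolumeEstimate"))
  x@params
}

#' Diagnostics recorded with a volume estimate
#'
#' @param x a [VolumeEstimate-class].
#' @return character vector of warnings (may be empty).
#' @export
estimateWarnings <- function(x) {
  stopifnot(is(x, "VolumeEstimate"))
  x@warnings
}

#' Convert a volume in cubic millimetres to millilitres
#'
#' The mesh coordinates are treated as millimetres; 1 ml = 1000 mm^3.
#'
#' @param x a [VolumeEstimate-class] or a numeric volume in mm^3.
#' @return numeric scalar, millilitres.
#' @export
asMilliliters <- function(x) {
  if (is(x, "VolumeEstimate")) x <- volume(x)
  x / 1000
}

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces\n",
              nVertices(object), nFaces(object)))
  if (nVertices(object) > 0L) {
    bb <- apply(object@vertices, 2L, range)
    cat(sprintf("  bbox: [%.4g, %.4g] x [%.4g, %.4g] x [%.4g, %.4g]\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
  invisible(NULL)
})

setMethod("show", "TopologyReport", function(object) {
  cat("TopologyReport\n")
  cat(sprintf("  closed: %s   consistently oriented: %s\n",
              object@isClosed, object@isConsistentlyOriented))
  cat(sprintf("  boundary edges: %d   non-manifold edges: %d   degenerate faces: %d\n",
              object@boundaryEdgeCount, object@nonManifoldEdgeCount,
              object@degenerateFaceCount))
  invisible(NULL)
})

setMethod("show", "VolumeEstimate", function(object) {
  cat(sprintf("VolumeEstimate [%s]: %.6f\n", object@method, object@volume))
  if (length(object@params)) {
    p <- vapply(object@params, function(v) paste(format(v), collapse = ","),
                character(1))
    cat("  params:", paste(names(p), p, sep = "=", collapse = ", "), "\n")
  }
  for (w in object@warnings) cat("  warning:", w, "\n")
  invisible(NULL)
})

setMethod("show", "CrossSection", function(object) {
  cat(sprintf("CrossSection %s = %.6g: %d loop(s), area %.6f (%d gap-closed)\n",
              object@axis, object@coord, length(object@polygons),
              object@area, object@openChainCount))
  invisible(NULL)
})

setMethod("show", "SliceStack", function(object) {
  cat(sprintf("SliceStack along %s: %d intervals, step %.6g\n",
              object@axis, object@nSlices, object@step))
  invisible(NULL)
})

setMethod("show", "BlobSpec", function(object) {
  cat(sprintf("BlobSpec [%s]: radii (%.3g, %.3g, %.3g), %d bump(s) amp %.3g width %.3g, level %d, seed %d\n",
              object@shapeClass, object@baseRadii[1], object@baseRadii[2],
              object@baseRadii[3], object@bumpCount, object@bumpAmplitude,
              object@bumpWidth, object@subdivisionLevel, object@seed))
  invisible(NULL)
})

setMethod("show", "Octree", function(object) {
  tab <- table(object@cells$state)
  cat(sprintf("Octree: depth %d, root side %.6g, %d leaf cells (%s)\n",
              object@depth, object@rootSide, nrow(object@cells),
              paste(names(tab), as.integer(tab), sep = ":", collapse = ", ")))
  invisible(NULL)
})
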