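#' @import methods
NULL

#' Triangle surface mesh
#'
#' An indexed triangle mesh: a matrix of 3D vertex coordinates and a matrix of
#' vertex-index triples. Counter-clockwise winding (seen from outside) encodes
#' the outward normal; stored file normals are discarded on input because the
#' winding is the only self-consistent source of orientation.
#'
#' Coordinates are dimensionless model units; when a mesh is declared to be in
#' millimetres, volumes divide by 1000 to give millilitres (see
#' [asMilliliters()]).
#'
#' @slot vertices numeric matrix, one row per vertex, columns x, y, z.
#' @slot faces integer matrix, one row per triangle, 1-based vertex indices.
#'
#' @seealso [triangleMesh()] for construction, [readMesh()] for file input.
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix"),
  validity = function(object) {
    v <- object@vertices
    f <- object@faces
    msg <- character()
    if (ncol(v) != 3L && nrow(v) > 0L)
      msg <- c(msg, "vertices must have 3 columns")
    if (ncol(f) != 3L && nrow(f) > 0L)
      msg <- c(msg, "faces must have 3 columns")
    if (!is.numeric(v)) msg <- c(msg, "vertices must be numeric")
    if (nrow(f) > 0L) {
      if (nrow(v) < 3L)
        msg <- c(msg, "a mesh with faces needs at least 3 vertices")
      if (any(f < 1L) || any(f > nrow(v)))
        msg <- c(msg, "face indices out of range")
      if (any(f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]))
        msg <- c(msg, "a face repeats a vertex index")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Topology and orientation diagnostics of a mesh
#'
#' Result of [topologyReport()]. A mesh is closed (watertight) when every
#' undirected edge is shared by exactly two faces, and consistently oriented
#' when every shared edge is traversed once in each direction. Only a closed,
#' consistently oriented mesh has a well-defined signed volume.
#'
#' @slot isClosed logical, every edge shared by exactly 2 faces.
#' @slot isConsistentlyOriented logical, shared edges traversed in opposite
#'   directions.
#' @slot boundaryEdgeCount integer, edges used by exactly one face.
#' @slot degenerateFaceCount integer, faces with (near-)zero area.
#' @slot nonManifoldEdgeCount integer, edges used by three or more faces.
#' @export
setClass("TopologyReport",
  representation(isClosed = "logical", isConsistentlyOriented = "logical",
                 boundaryEdgeCount = "integer", degenerateFaceCount = "integer",
                 nonManifoldEdgeCount = "integer"),
  validity = function(object) {
    if (object@isClosed && object@boundaryEdgeCount != 0L)
      "a closed mesh cannot have boundary edges" else TRUE
  }
)

#' A single volume measurement
#'
#' Scalar volume plus provenance: which estimator produced it, with which
#' parameters, and any diagnostics raised along the way (e.g. the mesh was
#' open, so the projection value is unreliable).
#'
#' @slot method character, one of `"projection"`, `"slice1"`, `"slice2"`,
#'   `"voxel"`, `"tada"`, `"tet_oracle"`, `"mc_oracle"`.
#' @slot volume numeric scalar, model units cubed.
#' @slot params named list of method parameters.
#' @slot warnings character vector of diagnostics.
#' @export
setClass("VolumeEstimate",
  representation(method = "character", volume = "numeric", params = "list",
                 warnings = "character"),
  validity = function(object) {
    ok <- c("projection", "slice1", "slice2", "voxel", "tada",
            "tet_oracle", "mc_oracle")
    msg <- character()
    if (length(object@method) != 1L || !object@method %in% ok)
      msg <- c(msg, paste("method must be one of:", paste(ok, collapse = ", ")))
    if (length(object@volume) != 1L || !is.finite(object@volume))
      msg <- c(msg, "volume must be a finite scalar")
    if (length(msg)) msg else TRUE
  }
)

#' Planar cross-section of a mesh
#'
#' The intersection of a mesh with an axis-aligned plane: closed 2D polygon
#' loops and their total enclosed area (shoelace per loop; nested loops
#' alternate sign so holes subtract). For open meshes, contour chains that do
#' not close are joined nearest-endpoint-first and counted in
#' `openChainCount`.
#'
#' @slot axis character, `"x"`, `"y"` or `"z"`.
#' @slot coord numeric, plane position along `axis`.
#' @slot polygons list of 2-column matrices, each a closed vertex loop in the
#'   plane (in-plane coordinates, axis order preserved).
#' @slot area numeric, total enclosed area (>= 0).
#' @slot openChainCount integer, chains that required gap-closing.
#' @export
setClass("CrossSection",
  representation(axis = "character", coord = "numeric", polygons = "list",
                 area = "numeric", openChainCount = "integer"),
  validity = function(object) {
    if (object@area < 0) "area must be non-negative" else TRUE
  }
)

#' Stack of uniformly spaced cross-section areas
#'
#' Areas sampled at `nSlices + 1` uniformly spaced planes spanning the mesh
#' extent along one axis; the substrate of the slice-accumulation volume
#' rules.
#'
#' @slot axis character, slicing axis.
#' @slot nSlices integer, number of slice intervals.
#' @slot step numeric, plane spacing (extent / nSlices).
#' @slot positions numeric, the nSlices + 1 plane coordinates.
#' @slot areas numeric, cross-section area at each plane.
#' @export
setClass("SliceStack",
  representation(axis = "character", nSlices = "integer", step = "numeric",
                 positions = "numeric", areas = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@step <= 0) msg <- c(msg, "step must be positive")
    if (length(object@areas) != object@nSlices + 1L)
      msg <- c(msg, "areas must have nSlices + 1 entries")
    if (length(msg)) msg else TRUE
  }
)

#' Specification of a synthetic hematoma phantom
#'
#' Parameters of a star-shaped blob mesh: an icosphere deformed to an
#' ellipsoid with seeded Gaussian radial bumps. The three shape classes
#' mirror how clinical hematomas are described: `regular` (smooth, round to
#' ellipsoid; no bumps), `irregular` (many small bumps, frayed margin) and
#' `lobular` (a few large lobes).
#'
#' @slot shapeClass character, `"regular"`, `"irregular"` or `"lobular"`.
#' @slot baseRadii numeric(3), ellipsoid semi-axes (a, b, c).
#' @slot bumpCount integer, number of radial bumps.
#' @slot bumpAmplitude numeric, relative bump height (0 = smooth).
#' @slot bumpWidth numeric, angular bump width (radians).
#' @slot subdivisionLevel integer, icosphere refinement level.
#' @slot seed integer, seed for bump placement.
#' @seealso [blobSpec()], [makeBlob()]
#' @export
setClass("BlobSpec",
  representation(shapeClass = "character", baseRadii = "numeric",
                 bumpCount = "integer", bumpAmplitude = "numeric",
                 bumpWidth = "numeric", subdivisionLevel = "integer",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@shapeClass %in% c("regular", "irregular", "lobular"))
      msg <- c(msg, "shapeClass must be regular, irregular or lobular")
    if (length(object@baseRadii) != 3L || any(object@baseRadii <= 0))
      msg <- c(msg, "baseRadii must be 3 positive semi-axes")
    if (object@shapeClass == "regular" && object@bumpAmplitude != 0)
      msg <- c(msg, "regular blobs have bumpAmplitude 0")
    if (object@bumpAmplitude < 0 || object@bumpAmplitude >= 1)
      msg <- c(msg, "bumpAmplitude must lie in [0, 1) so the radius stays positive")
    if (length(msg)) msg else TRUE
  }
)

#' Octree decomposition of a mesh's bounding cube
#'
#' Leaf cells of an adaptive octree over the mesh bounding cube: cells whose
#' (open) interior intersects the surface are subdivided to the maximum depth
#' and marked `boundary`; all other cells become `inside`/`outside` leaves at
#' the depth where they separated from the surface.
#'
#' @slot cells data.frame with columns x, y, z (min corner), side, depth,
#'   state (`"inside"`, `"outside"`, `"boundary"`).
#' @slot origin numeric(3), min corner of the root cube.
#' @slot rootSide numeric, root cube edge length (max bbox extent).
#' @slot depth integer, maximum subdivision depth.
#' @export
setClass("Octree",
  representation(cells = "data.frame", origin = "numeric",
                 rootSide = "numeric", depth = "integer"),
  validity = function(object) {
    msg <- character()
    need <- c("x", "y", "z", "side", "depth", "state")
    if (!all(need %in% names(object@cells)))
      msg <- c(msg, "cells must have columns x, y, z, side, depth, state")
    if (object@rootSide <= 0) msg <- c(msg, "rootSide must be positive")
    if (length(msg)) msg else TRUE
  }
)
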