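Package: meshvol
Title: Triangle-Mesh Volumetry for Hematoma and Benchmark Solids
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Volume measurement of closed and non-closed triangle surface
    meshes, built for intracerebral-hematoma volumetry but applicable to any
    segmented solid. Implements the signed projection (divergence-theorem)
    method, two slice-accumulation rules (conical-frustum and trapezoid),
    and an octree voxelization with boundary-voxel refinement, together with
    mesh I/O (STL, OBJ, OFF), watertightness and orientation diagnostics,
    orientation repair, brute-force volume oracles, deterministic benchmark
    and hematoma-phantom mesh generators, mesh corruptions (cap removal,
    normal flipping), and a batch comparison harness including the clinical
    ABC/2 (Tada) estimate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'seed-utils.R'
    'mesh-core.R'
    'mesh-io.R'
    'generators.R'
    'projection.R'
    'slicing.R'
    'voxelization.R'
    'compare.R'
    'meshvol-package.R'
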