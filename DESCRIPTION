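Package: cellneighbors
Title: Inference of Cell Neighborhood Graphs from Nuclei Centroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers which cells in a tissue are physical neighbors using only
    the positions of nuclei centroids. Candidate contacts are the edges of the
    Delaunay triangulation of the centroids (2D triangles, or triangular faces
    of 3D tetrahedra); each candidate edge is scored by the nucleus-nucleus
    distance and the maximum angle subtended with shared triangulation
    neighbors, and both thresholds are chosen automatically by maximizing a
    communicability-efficiency statistic, so the method has no free
    parameters and is invariant to scaling, rotation and reflection. Includes
    a distance-only baseline filter, precision/recall-style evaluation of
    predicted neighbor graphs against ground-truth edge lists, a seeded
    synthetic-tissue generator with exact clipped-Voronoi adjacency as ground
    truth, centroid extraction from nuclear-marker images, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deldir,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
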