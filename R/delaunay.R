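#' Build the Delaunay candidate graph of a centroid set
#'
#' Neighboring cells must be close together and unobstructed by a third
#' cell, so the natural primitive of a cell-contact graph is the triangle,
#' not the edge. The Delaunay triangulation of the nuclei centroids is used
#' as the candidate graph: it is the dual of the Voronoi tessellation (two
#' cells whose Voronoi regions touch are joined by a Delaunay edge), it
#' contains the nearest-neighbor graph, and it is stable under small
#' displacements of the points. In 3D the Delaunay cells are tetrahedra;
#' each tetrahedron is decomposed into its four triangular faces so that the
#' downstream per-edge angle statistic is defined identically in 2D and 3D.
#'
#' Exactly degenerate configurations (4 cocircular points in 2D, 5
#' cospherical in 3D, e.g. a perfect square lattice) have no unique
#' triangulation; the triangulation produced by the underlying routine is
#' accepted as-is. `joggle` optionally perturbs the input by a tiny
#' deterministic random displacement (a fraction of the bounding-box
#' diagonal) to break such ties explicitly.
#'
#' @param centroids a [centroid_set()].
#' @param joggle numeric scalar, fraction of the bounding-box diagonal used
#'   to perturb the points before triangulating (0 disables; try `1e-9` for
#'   exactly degenerate inputs). Reported features are still computed from
#'   the *unperturbed* coordinates.
#' @return An object of class `candidate_graph`: list with `nodes` (ids),
#'   `edges` (2-column integer matrix of id pairs, each row sorted),
#'   `triangles` (3-column integer matrix of id triples), and `dim`.
#' @examples
#' cs <- centroid_set(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1.2)))
#' g <- build_candidate_graph(cs)
#' nrow(g$edges)
#' @export
build_candidate_graph <- function(centroids, joggle = 0) {
  stopifnot(inherits(centroids, "centroid_set"))
  P <- centroids$coords
  d <- centroids$dim
  n <- nrow(P)
  if (n < d + 1L) {
    stop("triangulation needs at least ", d + 1L, " points in ", d, "D, got ", n)
  }
  # affine-rank check: collinear (2D) or coplanar (3D) input has no
  # full-dimensional triangulation
  ctr <- sweep(P, 2, colMeans(P))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[d] <= 1e-10 * sv[1]) {
    stop(
      "degenerate configuration: points are ",
      if (d == 2L) "collinear" else "coplanar"
    )
  }
  Q <- P
  if (joggle > 0) {
    eps <- joggle * bbox_diagonal(P)
    Q <- P + with_local_seed(
      20230603L,
      matrix(stats::runif(n * d, -eps, eps), n, d)
    )
  }
  tri_idx <- if (d == 2L) delaunay_triangles_2d(Q) else delaunay_faces_3d(Q)
  tri <- t(apply(tri_idx, 1, sort))
  tri <- unique(tri)
  tri <- tri[order(tri[, 1], tri[, 2], tri[, 3]), , drop = FALSE]
  edges <- normalize_edges(rbind(
    tri[, c(1, 2)], tri[, c(1, 3)], tri[, c(2, 3)]
  ))
  ids <- centroids$ids
  tri_ids <- matrix(ids[tri], ncol = 3)
  edge_ids <- matrix(ids[edges], ncol = 2)
  # id relabelling may break row-wise ordering; restore the canonical form
  edge_ids <- normalize_edges(edge_ids)
  tri_ids <- t(apply(tri_ids, 1, sort))
  tri_ids <- tri_ids[order(tri_ids[, 1], tri_ids[, 2], tri_ids[, 3]), , drop = FALSE]
  colnames(tri_ids) <- c("i", "j", "k")
  structure(
    list(nodes = ids, edges = edge_ids, triangles = tri_ids, dim = d),
    class = "candidate_graph"
  )
}

#' @export
print.candidate_graph <- function(x, ...) {
  cat(
    "Delaunay candidate graph:", length(x$nodes), "nodes,",
    nrow(x$edges), "edges,", nrow(x$triangles),
    if (x$dim == 2L) "triangles\n" else "triangular faces\n"
  )
  invisible(x)
}

# 2D Delaunay triangles (row indices) via deldir
delaunay_triangles_2d <- function(P) {
  dd <- deldir::deldir(P[, 1], P[, 2], suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  if (length(tl) == 0L) stop("triangulation produced no triangles")
  t(vapply(tl, function(tr) as.integer(tr$ptNum), integer(3)))
}

# 3D: Delaunay tetrahedra decomposed into their 4 triangular faces
delaunay_faces_3d <- function(P) {
  tets <- delaunay_tetrahedra(P)
  faces <- rbind(
    tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
    tets[, c(1, 3, 4)], tets[, c(2, 3, 4)]
  )
  faces
}

# Incremental (Bowyer-Watson) 3D Delaunay triangulation.
#
# Coordinates are rescaled to the unit box (a similarity, so the Delaunay
# complex is unchanged) and the algorithm runs inside a large enclosing
# super-tetrahedron. The cavity of every insertion is checked to be a
# closed triangulated ball; a failure indicates a near-degenerate
# (cospherical) configuration and raises an error suggesting the joggle
# option of build_candidate_graph().
delaunay_tetrahedra <- function(P) {
  n <- nrow(P)
  mn <- apply(P, 2, min)
  span <- max(apply(P, 2, max) - mn)
  if (span <= 0) stop("degenerate configuration: all points coincide")
  Q <- sweep(P, 2, mn) / span

  R <- 3e3
  super <- rbind(
    c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)
  ) * R + matrix(0.5, 4, 3)
  V <- rbind(Q, super)
  sidx <- n + 1:4

  tets <- matrix(sidx, nrow = 1)
  cc <- circumcenters3(V, tets)
  centers <- cc$centers
  r2 <- cc$r2

  for (p in seq_len(n)) {
    d2 <- (centers[, 1] - V[p, 1])^2 + (centers[, 2] - V[p, 2])^2 +
      (centers[, 3] - V[p, 3])^2
    bad <- which(d2 <= r2 * (1 + 1e-12))
    if (length(bad) == 0L) {
      stop("internal triangulation failure: point outside all circumspheres")
    }
    bt <- tets[bad, , drop = FALSE]
    faces <- rbind(
      bt[, c(1, 2, 3)], bt[, c(1, 2, 4)], bt[, c(1, 3, 4)], bt[, c(2, 3, 4)]
    )
    faces <- t(apply(faces, 1, sort))
    key <- paste(faces[, 1], faces[, 2], faces[, 3])
    cnt <- table(key)
    if (any(cnt > 2L)) {
      stop(
        "numerically degenerate (near-cospherical) configuration; ",
        "re-run build_candidate_graph() with a small joggle"
      )
    }
    boundary <- faces[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
    boundary <- unique(boundary)
    new_tets <- cbind(boundary, p)
    cc <- circumcenters3(V, new_tets)
    keep <- setdiff(seq_len(nrow(tets)), bad)
    tets <- rbind(tets[keep, , drop = FALSE], new_tets)
    centers <- rbind(centers[keep, , drop = FALSE], cc$centers)
    r2 <- c(r2[keep], cc$r2)
  }

  real <- rowSums(matrix(tets %in% seq_len(n), nrow = nrow(tets))) == 4L
  tets <- tets[real, , drop = FALSE]
  if (nrow(tets) == 0L) stop("degenerate configuration: no tetrahedra formed")
  tets
}

# circumcenters and squared circumradii of tetrahedra (rows of `tets` index V)
circumcenters3 <- function(V, tets) {
  m <- nrow(tets)
  centers <- matrix(NA_real_, m, 3)
  r2 <- numeric(m)
  for (t in seq_len(m)) {
    a <- V[tets[t, 1], ]
    A <- rbind(
      V[tets[t, 2], ] - a,
      V[tets[t, 3], ] - a,
      V[tets[t, 4], ] - a
    )
    b <- 0.5 * rowSums(A^2)
    x <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(x)) {
      stop(
        "numerically degenerate tetrahedron encountered; ",
        "re-run build_candidate_graph() with a small joggle"
      )
    }
    centers[t, ] <- a + x
    r2[t] <- sum(x^2)
  }
  list(centers = centers, r2 = r2)
}
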