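#' Per-edge geometric features: distance and maximum subtended angle
#'
#' Each candidate edge (i, j) is characterized by two quantities:
#' the nucleus-nucleus Euclidean distance `r` (a pairwise feature) and the
#' maximum angle `theta` subtended with shared triangulation neighbors
#' (a non-pairwise feature). For every triangle (i, j, k) of the candidate
#' graph containing the edge, the angle at the shared neighbor k between
#' the rays k->i and k->j is computed; `theta` is the maximum over all such
#' k, in degrees. A small `theta` means i and j are close relative to every
#' shared neighbor; `theta` near 180 degrees means some cell k sits almost
#' on the segment between i and j and is likely blocking their contact.
#'
#' @param graph a [build_candidate_graph()] result.
#' @param centroids the [centroid_set()] the graph was built from.
#' @return An object of class `edge_features`: a data frame with columns
#'   `i`, `j` (ids), `r` (length units) and `theta` (degrees), one row per
#'   candidate edge, carrying the observed feature extrema as attribute
#'   `ranges` (`r_min`, `r_max`, `theta_min`, `theta_max`).
#' @examples
#' cs <- centroid_set(rbind(c(0, 0), c(1, 0), c(0.5, 0.5 * sqrt(3))))
#' fe <- compute_edge_features(build_candidate_graph(cs), cs)
#' fe$theta  # equilateral triangle: all 60 degrees
#' @export
compute_edge_features <- function(graph, centroids) {
  stopifnot(inherits(graph, "candidate_graph"), inherits(centroids, "centroid_set"))
  tri <- graph$triangles
  P <- centroids$coords
  ai <- id_index(centroids, tri[, 1])
  bi <- id_index(centroids, tri[, 2])
  ci <- id_index(centroids, tri[, 3])

  A <- P[ai, , drop = FALSE]
  B <- P[bi, , drop = FALSE]
  C <- P[ci, , drop = FALSE]
  # squared side lengths: a2 opposite vertex A, etc.
  a2 <- rowSums((B - C)^2)
  b2 <- rowSums((A - C)^2)
  c2 <- rowSums((A - B)^2)
  if (any(a2 == 0) || any(b2 == 0) || any(c2 == 0)) {
    stop("degenerate triangle with coincident vertices")
  }
  ang <- function(opp2, s1_2, s2_2) {
    cosv <- (s1_2 + s2_2 - opp2) / (2 * sqrt(s1_2 * s2_2))
    acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  }
  # angle at C subtends edge (A,B), etc.
  at_c <- ang(c2, a2, b2)
  at_a <- ang(a2, b2, c2)
  at_b <- ang(b2, a2, c2)

  ekey <- c(
    edge_key(tri[, 1], tri[, 2]),
    edge_key(tri[, 2], tri[, 3]),
    edge_key(tri[, 1], tri[, 3])
  )
  eang <- c(at_c, at_a, at_b)
  theta_by_edge <- tapply(eang, ekey, max)

  edges <- graph$edges
  ii <- id_index(centroids, edges[, 1])
  jj <- id_index(centroids, edges[, 2])
  r <- sqrt(rowSums((P[ii, , drop = FALSE] - P[jj, , drop = FALSE])^2))
  theta <- unname(theta_by_edge[edge_key(edges[, 1], edges[, 2])])
  if (anyNA(theta)) {
    stop("internal error: candidate edge not contained in any triangle")
  }
  edge_features(data.frame(i = edges[, 1], j = edges[, 2], r = r, theta = theta))
}

#' Construct an edge-feature table
#'
#' Validates a table of per-edge features and caches the observed extrema.
#' Normally produced by [compute_edge_features()]; exposed so that feature
#' tables can also be built directly (e.g. in simulations).
#'
#' @param df data frame with columns `i`, `j`, `r` (> 0) and `theta`
#'   (degrees, in (0, 180]).
#' @return An `edge_features` data frame with a `ranges` attribute.
#' @export
edge_features <- function(df) {
  stopifnot(is.data.frame(df), all(c("i", "j", "r", "theta") %in% names(df)))
  if (nrow(df) == 0L) stop("empty feature table")
  if (any(df$r <= 0)) stop("all r must be positive")
  if (any(df$theta <= 0 | df$theta > 180)) stop("theta must lie in (0, 180] degrees")
  rownames(df) <- NULL
  attr(df, "ranges") <- c(
    r_min = min(df$r), r_max = max(df$r),
    theta_min = min(df$theta), theta_max = max(df$theta)
  )
  class(df) <- c("edge_features", "data.frame")
  df
}

#' Observed feature extrema of an edge-feature table
#'
#' @param features an [edge_features()] table.
#' @return Named numeric vector `r_min`, `r_max`, `theta_min`, `theta_max`.
#' @export
feature_ranges <- function(features) {
  stopifnot(inherits(features, "edge_features"))
  attr(features, "ranges")
}

#' @export
print.edge_features <- function(x, ...) {
  rg <- attr(x, "ranges")
  cat(
    sprintf(
      "Edge features: %d candidate edges; r in [%.4g, %.4g], theta in [%.4g, %.4g] deg\n",
      nrow(x), rg["r_min"], rg["r_max"], rg["theta_min"], rg["theta_max"]
    )
  )
  NextMethod()
}
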