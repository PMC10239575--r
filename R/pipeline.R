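#' Infer the cell neighbor graph from nuclei centroids
#'
#' The full pipeline: Delaunay candidate graph
#' ([build_candidate_graph()]), per-edge distance/angle features
#' ([compute_edge_features()]), automatic threshold selection by
#' efficiency maximization ([optimize_thresholds()] or, for the pairwise
#' baseline, [optimize_distance_only()]), and edge filtering
#' ([filter_edges()]). The procedure has no free parameters and is
#' invariant to translation, rotation, reflection and uniform scaling of
#' the input.
#'
#' @param centroids a [centroid_set()].
#' @param mode `"joint"` (distance and angle thresholds, the full method)
#'   or `"distance_only"` (pairwise baseline).
#' @param theta_bounds optional angle-normalization bounds passed to the
#'   optimizer (default: observed extrema; see [loss_mean()]).
#' @param joggle passed to [build_candidate_graph()].
#' @return Object of class `neighbor_inference`: list with `centroids`,
#'   `candidate` (the candidate graph), `features`, `thresholds`, and
#'   `graph` (the filtered [neighbor_graph][filter_edges()]).
#' @examples
#' tis <- generate_tissue(40, dim = 2, lattice = "hexagonal", jitter = 0.08, seed = 7)
#' fit <- infer_neighbors(tis$centroids)
#' fit$thresholds
#' evaluate_graph(fit$graph, tis$truth_edges, tis$centroids$ids)
#' @export
infer_neighbors <- function(centroids, mode = c("joint", "distance_only"),
                            theta_bounds = NULL, joggle = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(centroids, "centroid_set"))
  cand <- build_candidate_graph(centroids, joggle = joggle)
  feats <- compute_edge_features(cand, centroids)
  th <- if (mode == "joint") {
    optimize_thresholds(feats, theta_bounds = theta_bounds)
  } else {
    optimize_distance_only(feats)
  }
  graph <- filter_edges(cand, feats, th)
  structure(
    list(
      centroids = centroids, candidate = cand, features = feats,
      thresholds = th, graph = graph
    ),
    class = "neighbor_inference"
  )
}

#' @export
print.neighbor_inference <- function(x, ...) {
  print(x$centroids)
  print(x$thresholds)
  print(x$graph)
  invisible(x)
}
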