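#' Fraction of candidate edges connected at given thresholds
#'
#' The joint empirical cumulative distribution function (ECDF) of the edge
#' features: the fraction of candidate pairs with `r_ij <= r` and
#' `theta_ij <= theta`. This is the "benefit" term of the communicability
#' efficiency: the share of candidate contacts retained.
#'
#' @param features an [edge_features()] table.
#' @param r distance threshold (length units).
#' @param theta angle threshold (degrees).
#' @return Fraction in \[0, 1\].
#' @export
ecdf_fraction <- function(features, r, theta) {
  stopifnot(inherits(features, "edge_features"))
  mean(features$r <= r & features$theta <= theta)
}

#' Mean-normalized connectivity loss at given thresholds
#'
#' The "cost" term of the communicability efficiency: the average of the two
#' min-max-normalized threshold coordinates,
#' `L = ((r - r_min)/(r_max - r_min) + (theta - theta_min)/(theta_max - theta_min)) / 2`,
#' where the extrema are those observed over the candidate edges. It equals
#' the expected ECDF under the null in which each feature is uniform over
#' its observed range: the fraction of edges that a random tissue with no
#' preferred spacing would retain. L is 0 at the joint minima and 1 at the
#' joint maxima. If one feature takes a single value (collapsed range), no
#' filtering is possible along that axis and its term is defined as 0.
#'
#' By default the angle is normalized by the observed extrema; pass
#' `theta_bounds = c(0, 180)` to normalize over the full geometric range
#' instead.
#'
#' @param r distance threshold, within the observed `[r_min, r_max]`.
#' @param theta angle threshold (degrees), within bounds.
#' @param features an [edge_features()] table.
#' @param theta_bounds optional length-2 numeric overriding the angle
#'   normalization bounds (default: observed extrema).
#' @return Loss in \[0, 1\].
#' @export
loss_mean <- function(r, theta, features, theta_bounds = NULL) {
  stopifnot(inherits(features, "edge_features"))
  rg <- attr(features, "ranges")
  tb <- theta_bounds %||% unname(rg[c("theta_min", "theta_max")])
  tol_r <- 1e-9 * max(abs(rg[c("r_min", "r_max")]), 1)
  tol_t <- 1e-9 * 180
  if (r < rg["r_min"] - tol_r || r > rg["r_max"] + tol_r) {
    stop("r outside the observed range [", rg["r_min"], ", ", rg["r_max"], "]")
  }
  if (theta < tb[1] - tol_t || theta > tb[2] + tol_t) {
    stop("theta outside the loss normalization bounds [", tb[1], ", ", tb[2], "]")
  }
  norm01 <- function(x, lo, hi) if (hi > lo) (x - lo) / (hi - lo) else 0
  unname(
    0.5 * (norm01(r, rg["r_min"], rg["r_max"]) + norm01(theta, tb[1], tb[2]))
  )
}

#' Communicability efficiency at given thresholds
#'
#' `E(r, theta) = F(r, theta) - L(r, theta)`: the fraction of candidate
#' contacts retained ([ecdf_fraction()]) minus the fraction a spatially
#' random tissue would retain ([loss_mean()]). E weighs the number of
#' connected cells against the cost of raising the thresholds: at the joint
#' feature minima L = 0 but almost nothing is connected; at the joint maxima
#' F = 1 but L = 1, so E = 0. The thresholds maximizing E connect the most
#' cells at the least cost.
#'
#' @inheritParams loss_mean
#' @return Efficiency value (at most 1, and 0 exactly at the joint maxima).
#' @export
efficiency <- function(r, theta, features, theta_bounds = NULL) {
  ecdf_fraction(features, r, theta) - loss_mean(r, theta, features, theta_bounds)
}

#' Communicability-efficiency surface over the observed feature grid
#'
#' Evaluates F, L and E on the Cartesian grid of sorted unique observed
#' `r` values times sorted unique observed `theta` values. F is piecewise
#' constant with jumps only at observed feature values while L is strictly
#' increasing, so the maximum of E over the continuous domain is attained
#' on this grid; it is also the natural resolution for plotting.
#'
#' @inheritParams loss_mean
#' @param features an [edge_features()] table.
#' @return Object of class `efficiency_surface`: list with sorted unique
#'   `r`, `theta`, and matrices `F`, `L`, `E` (rows index `r`, columns
#'   `theta`), satisfying `E = F - L`.
#' @seealso [write_surface()] to export as a delimited table.
#' @export
efficiency_surface <- function(features, theta_bounds = NULL) {
  stopifnot(inherits(features, "edge_features"))
  rg <- attr(features, "ranges")
  tb <- theta_bounds %||% unname(rg[c("theta_min", "theta_max")])
  rs <- sort(unique(features$r))
  ts <- sort(unique(features$theta))
  m <- nrow(features)
  # F[a, b] = #{edges: r <= rs[a], theta <= ts[b]} / m
  r_le <- outer(features$r, rs, "<=") # m x |rs|
  t_le <- outer(features$theta, ts, "<=") # m x |ts|
  Fm <- crossprod(r_le, t_le) / m
  norm01 <- function(x, lo, hi) if (hi > lo) (x - lo) / (hi - lo) else rep(0, length(x))
  Lr <- norm01(rs, rg["r_min"], rg["r_max"])
  Lt <- norm01(ts, tb[1], tb[2])
  Lm <- 0.5 * outer(Lr, Lt, "+")
  structure(
    list(r = rs, theta = ts, F = Fm, L = Lm, E = Fm - Lm, theta_bounds = tb),
    class = "efficiency_surface"
  )
}

#' @export
print.efficiency_surface <- function(x, ...) {
  cat(
    sprintf(
      "Efficiency surface: %d x %d grid; max E = %.4f\n",
      length(x$r), length(x$theta), max(x$E)
    )
  )
  invisible(x)
}

#' Select the critical thresholds by maximizing the efficiency
#'
#' Returns the pair `(r*, theta*)` maximizing the communicability
#' efficiency E over the candidate grid of observed feature values (see
#' [efficiency_surface()]); an edge is then declared a true neighbor iff
#' `r_ij <= r*` and `theta_ij <= theta*` ([filter_edges()]). Ties are broken
#' toward the smaller `r`, then the smaller `theta` (the stricter graph),
#' which makes the output deterministic. The attained maximum is always
#' `>= 0` because the grid contains the joint maxima, where E = 0.
#'
#' @inheritParams efficiency_surface
#' @param keep_surface logical; attach the full [efficiency_surface()] to
#'   the result (for inspection/export).
#' @return Object of class `nf_thresholds`: list with `r_star`,
#'   `theta_star`, `efficiency` (value at the optimum), `mode = "joint"`,
#'   and optionally `surface`.
#' @export
optimize_thresholds <- function(features, theta_bounds = NULL, keep_surface = TRUE) {
  surf <- efficiency_surface(features, theta_bounds)
  best <- which(surf$E == max(surf$E), arr.ind = TRUE)
  # ties: smallest r, then smallest theta (grid vectors are sorted)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  structure(
    list(
      r_star = surf$r[best[1]],
      theta_star = surf$theta[best[2]],
      efficiency = surf$E[best[1], best[2]],
      mode = "joint",
      surface = if (keep_surface) surf else NULL
    ),
    class = "nf_thresholds"
  )
}

#' Distance-only threshold baseline
#'
#' Ablation of the angle term: maximizes the one-dimensional efficiency
#' `E(r) = F(r) - L(r)` with `F` the ECDF of the candidate edge lengths and
#' `L(r) = (r - r_min)/(r_max - r_min)` (the fraction of edges a uniform
#' length distribution would retain). The angle threshold is set to the
#' observed maximum so it never constrains: this reproduces classical
#' pairwise distance thresholding and serves as the comparison point for
#' the non-pairwise (angle-aware) filter.
#'
#' @param features an [edge_features()] table.
#' @return `nf_thresholds` with `mode = "distance_only"` and
#'   `theta_star = theta_max`.
#' @export
optimize_distance_only <- function(features) {
  stopifnot(inherits(features, "edge_features"))
  rg <- attr(features, "ranges")
  rs <- sort(unique(features$r))
  Fv <- vapply(rs, function(r) mean(features$r <= r), numeric(1))
  Lv <- if (rg["r_max"] > rg["r_min"]) {
    (rs - rg["r_min"]) / (rg["r_max"] - rg["r_min"])
  } else {
    rep(0, length(rs))
  }
  Ev <- Fv - Lv
  best <- which(Ev == max(Ev))[1] # rs sorted: first max is the smallest r
  structure(
    list(
      r_star = rs[best],
      theta_star = unname(rg["theta_max"]),
      efficiency = Ev[best],
      mode = "distance_only",
      surface = NULL
    ),
    class = "nf_thresholds"
  )
}

#' @export
print.nf_thresholds <- function(x, ...) {
  cat(
    sprintf(
      "Critical thresholds (%s): r* = %.6g, theta* = %.6g deg (E = %.4f)\n",
      x$mode, x$r_star, x$theta_star, x$efficiency
    )
  )
  invisible(x)
}

#' Filter the candidate graph at the critical thresholds
#'
#' An edge (i, j) is kept — i.e. the two cells are declared neighbors —
#' iff `r_ij <= r*` and `theta_ij <= theta*` (both inequalities closed).
#' The node set is unchanged; nodes whose every candidate edge is removed
#' remain as isolated nodes.
#'
#' @param graph a [build_candidate_graph()] result.
#' @param features the matching [compute_edge_features()] table.
#' @param thresholds an `nf_thresholds` object.
#' @return Object of class `neighbor_graph`: list with `nodes`, `edges`
#'   (data frame `i`, `j`, `r`, `theta`, `kept`), `fraction_removed`, and
#'   `thresholds`.
#' @export
filter_edges <- function(graph, features, thresholds) {
  stopifnot(
    inherits(graph, "candidate_graph"),
    inherits(features, "edge_features"),
    inherits(thresholds, "nf_thresholds")
  )
  if (nrow(features) != nrow(graph$edges)) {
    stop("features and graph disagree on the number of candidate edges")
  }
  kept <- features$r <= thresholds$r_star & features$theta <= thresholds$theta_star
  edges <- data.frame(
    i = features$i, j = features$j,
    r = features$r, theta = features$theta, kept = kept
  )
  structure(
    list(
      nodes = graph$nodes,
      edges = edges,
      fraction_removed = 1 - mean(kept),
      thresholds = thresholds[c("r_star", "theta_star", "efficiency", "mode")]
    ),
    class = "neighbor_graph"
  )
}

#' Kept edges of a neighbor graph
#'
#' @param graph a `neighbor_graph`.
#' @return 2-column integer matrix of the kept (neighbor) edges.
#' @export
kept_edges <- function(graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  normalize_edges(graph$edges[graph$edges$kept, c("i", "j")])
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(
    sprintf(
      "Neighbor graph: %d nodes, %d/%d candidate edges kept (%.1f%% removed; %s filter)\n",
      length(x$nodes), sum(x$edges$kept), nrow(x$edges),
      100 * x$fraction_removed, x$thresholds$mode
    )
  )
  invisible(x)
}
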