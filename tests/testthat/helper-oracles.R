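# Independent oracles and fixture generators used across the suite.

# Brute-force 2D Delaunay edge set by the empty-circumcircle test over all
# point triples. Assumes general position (random fixtures).
brute_delaunay_edges_2d <- function(P) {
  n <- nrow(P)
  edges <- NULL
  for (a in 1:(n - 2)) {
    for (b in (a + 1):(n - 1)) {
      for (c in (b + 1):n) {
        A <- rbind(P[b, ] - P[a, ], P[c, ] - P[a, ])
        if (abs(det(A)) < 1e-12) next
        x <- solve(A, 0.5 * rowSums(A^2))
        ctr <- P[a, ] + x
        r2 <- sum(x^2)
        others <- setdiff(1:n, c(a, b, c))
        d2 <- colSums((t(P[others, , drop = FALSE]) - ctr)^2)
        if (all(d2 > r2 * (1 - 1e-9))) {
          edges <- rbind(edges, c(a, b), c(a, c), c(b, c))
        }
      }
    }
  }
  cellneighbors:::normalize_edges(edges)
}

# Brute-force 3D Delaunay edge set by the empty-circumsphere test over all
# point quadruples.
brute_delaunay_edges_3d <- function(P) {
  n <- nrow(P)
  edges <- NULL
  quads <- utils::combn(n, 4)
  for (q in seq_len(ncol(quads))) {
    v <- quads[, q]
    A <- rbind(P[v[2], ] - P[v[1], ], P[v[3], ] - P[v[1], ], P[v[4], ] - P[v[1], ])
    if (abs(det(A)) < 1e-12) next
    x <- solve(A, 0.5 * rowSums(A^2))
    ctr <- P[v[1], ] + x
    r2 <- sum(x^2)
    others <- setdiff(1:n, v)
    d2 <- colSums((t(P[others, , drop = FALSE]) - ctr)^2)
    if (all(d2 > r2 * (1 - 1e-9))) {
      pr <- utils::combn(v, 2)
      edges <- rbind(edges, t(pr))
    }
  }
  cellneighbors:::normalize_edges(edges)
}

brute_delaunay_edges <- function(P) {
  if (ncol(P) == 2) brute_delaunay_edges_2d(P) else brute_delaunay_edges_3d(P)
}

# random points in general position
random_points <- function(n, d) matrix(stats::runif(n * d), n, d)

# random feature table; with prob. 1/2 the features take few distinct
# values so that ties and degenerate ranges are exercised
random_feature_table <- function(m = NULL) {
  if (is.null(m)) m <- sample(5:50, 1)
  if (stats::runif(1) < 0.5) {
    r <- sample(stats::runif(4, 0.5, 5), m, replace = TRUE)
    theta <- sample(stats::runif(4, 10, 175), m, replace = TRUE)
  } else {
    r <- stats::runif(m, 0.5, 5)
    theta <- stats::runif(m, 10, 175)
  }
  edge_features(data.frame(i = seq_len(m), j = seq_len(m) + m, r = r, theta = theta))
}

# Exhaustive threshold optimization on the observed grid, computed
# independently (direct counting, no shared code with the package path).
exhaustive_optimum <- function(features) {
  rs <- sort(unique(features$r))
  ts <- sort(unique(features$theta))
  rmin <- min(features$r)
  rmax <- max(features$r)
  tmin <- min(features$theta)
  tmax <- max(features$theta)
  best <- c(-Inf, NA, NA)
  for (r in rs) {
    for (th in ts) {
      F_ <- sum(features$r <= r & features$theta <= th) / nrow(features)
      Lr <- if (rmax > rmin) (r - rmin) / (rmax - rmin) else 0
      Lt <- if (tmax > tmin) (th - tmin) / (tmax - tmin) else 0
      E_ <- F_ - (Lr + Lt) / 2
      if (E_ > best[1] + 1e-12) best <- c(E_, r, th)
    }
  }
  list(E = best[1], r_star = best[2], theta_star = best[3])
}

# random similarity transform: uniform scale, rotation (optionally a
# reflection), translation
random_similarity <- function(d) {
  M <- matrix(stats::rnorm(d * d), d, d)
  Q <- qr.Q(qr(M))
  s <- exp(stats::runif(1, -1, 1))
  t <- stats::rnorm(d, sd = 5)
  list(
    scale = s,
    apply = function(P) sweep(P %*% Q * s, 2, t, `+`)
  )
}

edge_set_key <- function(edges) {
  e <- cellneighbors:::normalize_edges(edges)
  paste(e[, 1], e[, 2], sep = "|")
}
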