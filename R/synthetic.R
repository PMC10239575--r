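#' Generate a synthetic tissue with exact ground-truth adjacency
#'
#' Produces a seeded centroid set together with the exact neighbor graph of
#' the corresponding space-filling cells. Centroids are lattice points
#' (hexagonal in 2D, square/cubic via `"cubic"`, or uniform random draws)
#' inside a rectangular box, optionally perturbed by isotropic jitter
#' (uniform in a disc/ball of radius `jitter` times the lattice spacing).
#' The ground truth defines two cells as neighbors iff their Voronoi
#' regions, clipped to the box, share a facet of positive measure — the
#' standard abstraction of membrane contact for space-filling cells, and
#' exact by construction. The box is clipped (not periodic) on purpose:
#' boundary cells are precisely where candidate-graph errors concentrate,
#' so they must be present in test tissues.
#'
#' Low jitter on a lattice emulates highly regular epithelia; high jitter
#' or `lattice = "uniform"` emulates irregular tissues. Zero-measure
#' point/edge contacts (e.g. diagonal cells of a perfect square lattice)
#' are excluded.
#'
#' @param n number of cells (at least `dim + 2`).
#' @param dim 2 or 3.
#' @param lattice `"hexagonal"` (2D only), `"cubic"` (square grid in 2D,
#'   cubic in 3D), or `"uniform"` (uniform random positions; `jitter`
#'   ignored).
#' @param jitter displacement radius as a fraction of the lattice spacing,
#'   in `[0, 0.5)`.
#' @param seed integer RNG seed; the result is reproducible bit-for-bit.
#' @return Object of class `synthetic_tissue`: list with `centroids` (a
#'   [centroid_set()], ids `1:n`), `truth_edges` (2-column id matrix), and
#'   `params` (n, dim, lattice, jitter, spacing, box, seed).
#' @examples
#' tis <- generate_tissue(30, dim = 2, lattice = "hexagonal", jitter = 0.05, seed = 1)
#' nrow(tis$truth_edges)
#' @export
generate_tissue <- function(n, dim = 2,
                            lattice = c("hexagonal", "cubic", "uniform"),
                            jitter = 0.1, seed = 1) {
  lattice <- match.arg(lattice)
  dim <- as.integer(dim)
  n <- as.integer(n)
  if (!dim %in% c(2L, 3L)) stop("dim must be 2 or 3")
  if (n < dim + 2L) stop("need n >= dim + 2, got ", n)
  if (jitter < 0 || jitter >= 0.5) stop("jitter must lie in [0, 0.5)")
  if (lattice == "hexagonal" && dim != 2L) {
    stop("hexagonal lattice is only defined for dim = 2")
  }
  spacing <- 1
  gen <- function() {
    if (lattice == "uniform") {
      L <- n^(1 / dim) * spacing # unit cell density
      P <- matrix(stats::runif(n * dim, 0, L), n, dim)
      box <- rbind(rep(0, dim), rep(L, dim))
      return(list(P = P, box = box))
    }
    base <- lattice_points(n, dim, lattice, spacing)
    P <- base$P
    if (jitter > 0) P <- P + jitter_displacements(n, dim, jitter * spacing)
    # half a lattice pitch of margin per axis, widened if jitter can exceed it
    margin <- pmax(base$pitch / 2, if (jitter > 0) jitter * spacing * 1.01 else 0)
    box <- rbind(
      apply(base$P, 2, min) - margin,
      apply(base$P, 2, max) + margin
    )
    list(P = P, box = box)
  }
  g <- with_local_seed(seed, gen())
  cs <- centroid_set(g$P)
  truth <- voronoi_adjacency(g$P, g$box)
  structure(
    list(
      centroids = cs,
      truth_edges = truth,
      params = list(
        n = n, dim = dim, lattice = lattice, jitter = jitter,
        spacing = spacing, box = g$box, seed = as.integer(seed)
      )
    ),
    class = "synthetic_tissue"
  )
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  p <- x$params
  cat(
    sprintf(
      "Synthetic tissue: n=%d, %dD %s lattice, jitter=%.2f, seed=%d; %d true contacts\n",
      p$n, p$dim, p$lattice, p$jitter, p$seed, nrow(x$truth_edges)
    )
  )
  invisible(x)
}

# Lattice positions for the first n sites (row-major), plus per-axis pitch.
lattice_points <- function(n, dim, lattice, spacing) {
  if (lattice == "hexagonal") {
    ncol_ <- ceiling(sqrt(n))
    nrow_ <- ceiling(n / ncol_)
    rows <- rep(seq_len(nrow_), each = ncol_)[seq_len(n)]
    cols <- rep(seq_len(ncol_), times = nrow_)[seq_len(n)]
    x <- (cols - 1 + ((rows - 1) %% 2) * 0.5) * spacing
    y <- (rows - 1) * spacing * sqrt(3) / 2
    return(list(P = cbind(x, y), pitch = c(spacing, spacing * sqrt(3) / 2)))
  }
  k <- ceiling(n^(1 / dim))
  grids <- do.call(expand.grid, rep(list(seq_len(k) - 1), dim))
  P <- as.matrix(grids)[seq_len(n), , drop = FALSE] * spacing
  dimnames(P) <- NULL
  list(P = P, pitch = rep(spacing, dim))
}

# isotropic displacements uniform in a disc (2D) / ball (3D) of radius `rad`
jitter_displacements <- function(n, dim, rad) {
  u <- matrix(stats::rnorm(n * dim), n, dim)
  u <- u / sqrt(rowSums(u^2))
  r <- rad * stats::runif(n)^(1 / dim)
  u * r
}

#' Adjacency of box-clipped Voronoi regions
#'
#' Two points are adjacent iff their Voronoi regions, intersected with the
#' rectangular box, share a facet of positive measure (length in 2D, area
#' in 3D). Zero-measure contacts — shared corners or edges arising from
#' degenerate (cocircular/cospherical) configurations — are excluded.
#'
#' In 2D the clipped tessellation comes from the `deldir` package; in 3D
#' each candidate facet is computed directly as the bisector plane of the
#' pair clipped by the box and by the dominance half-spaces of all other
#' points.
#'
#' @param coords numeric matrix of points (rows), 2 or 3 columns.
#' @param box 2 x d matrix: first row lower corner, second row upper corner.
#' @return 2-column integer matrix of adjacent row-index pairs (i < j).
#' @export
voronoi_adjacency <- function(coords, box) {
  coords <- as.matrix(coords)
  d <- ncol(coords)
  box <- matrix(as.numeric(box), nrow = 2)
  if (any(box[2, ] <= box[1, ])) stop("degenerate clipping box")
  inside <- coords >= matrix(box[1, ], nrow(coords), d, byrow = TRUE) &
    coords <= matrix(box[2, ], nrow(coords), d, byrow = TRUE)
  if (!all(inside)) stop("all points must lie inside the clipping box")
  if (d == 2L) voronoi_adjacency_2d(coords, box) else voronoi_adjacency_3d(coords, box)
}

voronoi_adjacency_2d <- function(P, box) {
  dd <- deldir::deldir(
    P[, 1], P[, 2],
    rw = c(box[1, 1], box[2, 1], box[1, 2], box[2, 2]),
    suppressMsge = TRUE
  )
  seg <- dd$dirsgs
  len <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
  tol <- 1e-8 * sqrt(sum((box[2, ] - box[1, ])^2))
  # a pair may contribute several collinear sub-segments; sum its lengths
  key <- edge_key(seg$ind1, seg$ind2)
  total <- tapply(len, key, sum)
  pairs <- unique(cbind(pmin(seg$ind1, seg$ind2), pmax(seg$ind1, seg$ind2)))
  keep <- total[edge_key(pairs[, 1], pairs[, 2])] > tol
  normalize_edges(pairs[keep, , drop = FALSE])
}

# 3D: for each candidate pair, the shared facet lies in the bisector plane;
# clip the box cross-section of that plane by the dominance half-planes of
# the remaining points (nearest first, stopping as soon as the polygon
# vanishes) and test for positive area.
voronoi_adjacency_3d <- function(P, box) {
  n <- nrow(P)
  diag_len <- sqrt(sum((box[2, ] - box[1, ])^2))
  area_tol <- (1e-7 * diag_len)^2
  res_i <- integer(0)
  res_j <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (clipped_bisector_facet_area(P, i, j, box, diag_len) > area_tol) {
        res_i <- c(res_i, i)
        res_j <- c(res_j, j)
      }
    }
  }
  normalize_edges(cbind(res_i, res_j))
}

clipped_bisector_facet_area <- function(P, i, j, box, diag_len) {
  pi_ <- P[i, ]
  pj <- P[j, ]
  u <- pj - pi_
  m <- (pi_ + pj) / 2
  u <- u / sqrt(sum(u^2))
  # orthonormal in-plane basis
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- c(
    u[2] * a[3] - u[3] * a[2],
    u[3] * a[1] - u[1] * a[3],
    u[1] * a[2] - u[2] * a[1]
  )
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    u[2] * e1[3] - u[3] * e1[2],
    u[3] * e1[1] - u[1] * e1[3],
    u[1] * e1[2] - u[2] * e1[1]
  )
  # start from a generous square in plane coordinates (s, t): x = m + s e1 + t e2
  S <- 2 * diag_len
  poly <- cbind(c(-S, S, S, -S), c(-S, -S, S, S))
  # box constraints: lo_k <= m_k + s e1_k + t e2_k <= hi_k
  for (k in 1:3) {
    poly <- clip_halfplane(poly, -e1[k], -e2[k], m[k] - box[1, k])
    if (nrow(poly) < 3L) return(0)
    poly <- clip_halfplane(poly, e1[k], e2[k], box[2, k] - m[k])
    if (nrow(poly) < 3L) return(0)
  }
  # dominance constraints |x - pi| <= |x - pk|, nearest k first
  others <- setdiff(seq_len(nrow(P)), c(i, j))
  d2m <- colSums((t(P[others, , drop = FALSE]) - m)^2)
  others <- others[order(d2m)]
  d2m <- sort(d2m)
  half_d2 <- sum((pj - pi_)^2) / 4
  r_poly <- sqrt(max(rowSums(poly^2)))
  for (t in seq_along(others)) {
    # a constraint whose generator is too far from the current polygon
    # cannot cut it; generators are sorted, so stop at the first such
    if (sqrt(d2m[t]) > r_poly + sqrt(half_d2 + r_poly^2)) break
    k <- others[t]
    w <- P[k, ] - pi_
    # 2 x.w <= |pk|^2 - |pi|^2  =>  s (2 e1.w) + t (2 e2.w) <= c
    alpha <- 2 * sum(e1 * w)
    beta <- 2 * sum(e2 * w)
    gamma <- sum(P[k, ]^2) - sum(pi_^2) - 2 * sum(m * w)
    poly <- clip_halfplane(poly, alpha, beta, gamma)
    if (nrow(poly) < 3L) return(0)
    r_poly <- sqrt(max(rowSums(poly^2)))
  }
  polygon_area(poly)
}

# Sutherland-Hodgman clip of a convex polygon by alpha*s + beta*t <= gamma
clip_halfplane <- function(poly, alpha, beta, gamma) {
  v <- alpha * poly[, 1] + beta * poly[, 2] - gamma
  if (all(v <= 0)) return(poly)
  if (all(v >= 0)) return(poly[0, , drop = FALSE])
  np <- nrow(poly)
  nxt <- c(2:np, 1)
  out_s <- numeric(0)
  out_t <- numeric(0)
  for (q in seq_len(np)) {
    q2 <- nxt[q]
    in1 <- v[q] <= 0
    in2 <- v[q2] <= 0
    if (in1) {
      out_s <- c(out_s, poly[q, 1])
      out_t <- c(out_t, poly[q, 2])
    }
    if (xor(in1, in2)) {
      lam <- v[q] / (v[q] - v[q2])
      out_s <- c(out_s, poly[q, 1] + lam * (poly[q2, 1] - poly[q, 1]))
      out_t <- c(out_t, poly[q, 2] + lam * (poly[q2, 2] - poly[q, 2]))
    }
  }
  cbind(out_s, out_t)
}

polygon_area <- function(poly) {
  if (nrow(poly) < 3L) return(0)
  s <- poly[, 1]
  t <- poly[, 2]
  np <- nrow(poly)
  nxt <- c(2:np, 1)
  abs(sum(s * t[nxt] - s[nxt] * t)) / 2
}
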