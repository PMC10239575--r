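test_that("canonical small configurations triangulate correctly", {
  # three points: one triangle, three edges
  cs <- centroid_set(rbind(c(0, 0), c(1, 0), c(0, 1)), ids = 0:2)
  g <- build_candidate_graph(cs)
  expect_equal(g$edges, cbind(i = c(0L, 0L, 1L), j = c(1L, 2L, 2L)))
  expect_equal(nrow(g$triangles), 1L)
  expect_equal(as.integer(g$triangles[1, ]), 0:2)

  # interior point joined to all three hull points: 6 edges, 3 triangles
  cs4 <- centroid_set(rbind(c(0, 0), c(2, 0), c(1, 2), c(1, 0.5)))
  g4 <- build_candidate_graph(cs4)
  expect_equal(nrow(g4$edges), 6L)
  expect_equal(nrow(g4$triangles), 3L)
  # every triangle uses the interior point 4
  expect_true(all(apply(g4$triangles, 1, function(tr) 4L %in% tr)))

  # single tetrahedron decomposes into its 4 faces
  cs3 <- centroid_set(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  g3 <- build_candidate_graph(cs3)
  expect_equal(nrow(g3$edges), 6L)
  expect_equal(nrow(g3$triangles), 4L)
})

test_that("every edge belongs to a triangle and the graph is simple", {
  for (d in 2:3) {
    set.seed(100 + d)
    cs <- centroid_set(random_points(30, d))
    g <- build_candidate_graph(cs)
    expect_false(any(g$edges[, 1] == g$edges[, 2]))
    expect_equal(anyDuplicated(g$edges), 0L)
    tri_edges <- unique(edge_set_key(rbind(
      g$triangles[, c(1, 2)], g$triangles[, c(1, 3)], g$triangles[, c(2, 3)]
    )))
    expect_setequal(edge_set_key(g$edges), tri_edges)
  }
})

test_that("edge set matches the brute-force empty-circumcircle/sphere oracle", {
  set.seed(42)
  for (rep in 1:10) {
    for (d in 2:3) {
      n <- sample((d + 2):12, 1)
      P <- random_points(n, d)
      g <- build_candidate_graph(centroid_set(P))
      expect_setequal(edge_set_key(g$edges), edge_set_key(brute_delaunay_edges(P)))
    }
  }
})

test_that("candidate graph includes the nearest-neighbor graph", {
  set.seed(7)
  for (d in 2:3) {
    P <- random_points(40, d)
    g <- build_candidate_graph(centroid_set(P))
    keys <- edge_set_key(g$edges)
    dd <- as.matrix(stats::dist(P))
    diag(dd) <- Inf
    nn <- apply(dd, 1, which.min)
    expect_true(all(edge_set_key(cbind(seq_len(40), nn)) %in% keys))
  }
})

test_that("interior 2D edges lie in two triangles, hull edges in one", {
  set.seed(11)
  P <- random_points(25, 2)
  g <- build_candidate_graph(centroid_set(P))
  tri_edges <- rbind(
    g$triangles[, c(1, 2)], g$triangles[, c(1, 3)], g$triangles[, c(2, 3)]
  )
  counts <- table(paste(pmin(tri_edges[, 1], tri_edges[, 2]),
    pmax(tri_edges[, 1], tri_edges[, 2]),
    sep = "|"
  ))
  expect_true(all(counts %in% 1:2))
  hull <- grDevices::chull(P)
  hull_edges <- edge_set_key(cbind(hull, c(hull[-1], hull[1])))
  expect_true(all(counts[hull_edges] == 1L))
  expect_true(all(counts[setdiff(names(counts), hull_edges)] == 2L))
})

test_that("degenerate and undersized inputs are rejected", {
  expect_error(
    build_candidate_graph(centroid_set(rbind(c(0, 0), c(1, 0), c(2, 0)))),
    "collinear"
  )
  expect_error(
    build_candidate_graph(centroid_set(rbind(
      c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)
    ))),
    "coplanar"
  )
  expect_error(
    build_candidate_graph(centroid_set(rbind(c(0, 0), c(1, 0)))),
    "at least 3"
  )
  expect_error(
    centroid_set(rbind(c(0, 0), c(1, 0), c(1, 0) + 1e-12)),
    "coincide"
  )
  expect_error(centroid_set(rbind(c(0, 0), c(1, 0)), ids = c(1, 1)), "duplicate")
})

test_that("edge features reproduce hand-computed distance and angle cases", {
  # equilateral triangle, side 1: every edge r = 1, theta = 60 degrees
  eq <- centroid_set(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)))
  fe <- compute_edge_features(build_candidate_graph(eq), eq)
  expect_equal(fe$r, rep(1, 3), tolerance = 1e-12)
  expect_equal(fe$theta, rep(60, 3), tolerance = 1e-9)

  # right angle at the apex
  rt <- centroid_set(rbind(c(0, 0), c(1, 0), c(0.5, 0.5)), ids = 1:3)
  fr <- compute_edge_features(build_candidate_graph(rt), rt)
  row <- fr[fr$i == 1 & fr$j == 2, ]
  expect_equal(row$r, 1)
  expect_equal(row$theta, 90, tolerance = 1e-9)

  # nearly blocking third nucleus: theta close to 180
  bl <- centroid_set(rbind(c(0, 0), c(2, 0), c(1, 0.1)), ids = 1:3)
  fb <- compute_edge_features(build_candidate_graph(bl), bl)
  row <- fb[fb$i == 1 & fb$j == 2, ]
  expect_equal(row$r, 2)
  expect_equal(row$theta, 168.578813725, tolerance = 1e-6)
})

test_that("theta is the maximum angle over all shared triangle neighbors", {
  # edge (1,2) shared by triangles with apexes 3 (67.4 deg) and 4 (90 deg)
  cs <- centroid_set(rbind(c(0, 0), c(2, 0), c(1, 1.5), c(1, -1)), ids = 1:4)
  g <- build_candidate_graph(cs)
  expect_equal(nrow(g$triangles), 2L)
  fe <- compute_edge_features(g, cs)
  row <- fe[fe$i == 1 & fe$j == 2, ]
  expect_equal(row$theta, 90, tolerance = 1e-9)
  rg <- feature_ranges(fe)
  expect_equal(unname(rg["theta_max"]), max(fe$theta))
  expect_true(all(fe$theta > 0 & fe$theta <= 180))
  expect_true(all(fe$r > 0))
})

test_that("similarity transforms preserve the complex and angles, scale r", {
  set.seed(21)
  for (d in 2:3) {
    P <- random_points(30, d)
    cs <- centroid_set(P)
    g <- build_candidate_graph(cs)
    fe <- compute_edge_features(g, cs)
    for (rep in 1:3) {
      tr <- random_similarity(d)
      cs2 <- centroid_set(tr$apply(P))
      g2 <- build_candidate_graph(cs2)
      fe2 <- compute_edge_features(g2, cs2)
      expect_setequal(edge_set_key(g2$edges), edge_set_key(g$edges))
      expect_setequal(
        paste(g2$triangles[, 1], g2$triangles[, 2], g2$triangles[, 3]),
        paste(g$triangles[, 1], g$triangles[, 2], g$triangles[, 3])
      )
      ord1 <- order(fe$i, fe$j)
      ord2 <- order(fe2$i, fe2$j)
      expect_equal(fe2$theta[ord2], fe$theta[ord1], tolerance = 1e-6)
      expect_equal(fe2$r[ord2], fe$r[ord1] * tr$scale, tolerance = 1e-9)
    }
  }
})
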