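toy_features <- function(r, theta) {
  edge_features(data.frame(
    i = seq_along(r), j = seq_along(r) + length(r), r = r, theta = theta
  ))
}

test_that("ecdf_fraction counts the qualifying pairs", {
  fe <- toy_features(c(1, 2, 3), c(10, 20, 30))
  expect_equal(ecdf_fraction(fe, 2, 20), 2 / 3)
  expect_equal(ecdf_fraction(fe, 3, 30), 1)
  expect_equal(ecdf_fraction(fe, 0.5, 5), 0)
  # both conditions must hold jointly
  expect_equal(ecdf_fraction(fe, 3, 5), 0)
})

test_that("loss_mean is the mean of the min-max-normalized coordinates", {
  fe <- toy_features(c(1, 2, 3), c(10, 20, 30))
  expect_equal(loss_mean(1, 10, fe), 0)
  expect_equal(loss_mean(3, 30, fe), 1)
  expect_equal(loss_mean(2, 20, fe), 0.5)
  expect_error(loss_mean(0.5, 20, fe), "outside")
  expect_error(loss_mean(2, 40, fe), "outside")
  # fixed angle bounds option changes the normalization
  expect_equal(loss_mean(2, 90, fe, theta_bounds = c(0, 180)), 0.5)
})

test_that("efficiency is F minus L and vanishes at the joint maxima", {
  fe <- toy_features(c(1, 2, 3), c(10, 20, 30))
  expect_equal(efficiency(2, 20, fe), 2 / 3 - 0.5)
  expect_equal(efficiency(3, 30, fe), 0)
  # at the joint minima L = 0 and F = multiplicity of the minimum / m
  fe2 <- toy_features(c(1, 1, 2), c(10, 10, 30))
  expect_equal(efficiency(1, 10, fe2), 2 / 3)
})

test_that("optimize_thresholds removes the outlier edge in the 2x2 grid case", {
  fe <- toy_features(c(rep(1, 5), 10), c(rep(60, 5), 170))
  th <- optimize_thresholds(fe)
  expect_equal(th$r_star, 1)
  expect_equal(th$theta_star, 60)
  expect_equal(th$efficiency, 5 / 6)
  expect_equal(th$mode, "joint")
})

test_that("degenerate feature ranges keep all edges with E = 1", {
  fe <- toy_features(rep(2, 4), rep(60, 4))
  th <- optimize_thresholds(fe)
  expect_equal(th$r_star, 2)
  expect_equal(th$theta_star, 60)
  expect_equal(th$efficiency, 1)
})

test_that("attained efficiency is never negative", {
  set.seed(13)
  for (rep in 1:20) {
    th <- optimize_thresholds(random_feature_table())
    expect_gte(th$efficiency, 0)
  }
})

test_that("efficiency surface satisfies its structural invariants", {
  set.seed(29)
  fe <- random_feature_table(40)
  surf <- efficiency_surface(fe)
  expect_equal(surf$E, surf$F - surf$L)
  expect_true(all(surf$F >= 0 & surf$F <= 1))
  expect_true(all(surf$L >= 0 & surf$L <= 1))
  # F and L nondecreasing along both axes
  expect_true(all(diff(surf$F) >= 0) && all(diff(t(surf$F)) >= 0))
  expect_true(all(diff(surf$L) >= 0) && all(diff(t(surf$L)) >= 0))
  # exactly zero at the joint maxima
  expect_identical(surf$E[length(surf$r), length(surf$theta)], 0)
})

test_that("optimizer matches the independent exhaustive grid search", {
  set.seed(37)
  for (rep in 1:15) {
    fe <- random_feature_table()
    th <- optimize_thresholds(fe)
    ex <- exhaustive_optimum(fe)
    expect_equal(th$r_star, ex$r_star)
    expect_equal(th$theta_star, ex$theta_star)
    expect_equal(th$efficiency, ex$E, tolerance = 1e-12)
  }
})

test_that("filter_edges applies the closed conjunction of both thresholds", {
  cs <- centroid_set(rbind(c(0, 0), c(2, 0), c(1, 1.5), c(1, -1)), ids = 1:4)
  g <- build_candidate_graph(cs)
  fe <- compute_edge_features(g, cs)
  # thresholds at the maxima keep everything
  th_max <- structure(
    list(
      r_star = max(fe$r), theta_star = max(fe$theta),
      efficiency = 0, mode = "joint", surface = NULL
    ),
    class = "nf_thresholds"
  )
  ng <- filter_edges(g, fe, th_max)
  expect_true(all(ng$edges$kept))
  expect_equal(ng$fraction_removed, 0)
  # an edge below r* but above theta* is removed
  th_part <- structure(
    list(
      r_star = max(fe$r), theta_star = 89, efficiency = 0,
      mode = "joint", surface = NULL
    ),
    class = "nf_thresholds"
  )
  ng2 <- filter_edges(g, fe, th_part)
  removed <- ng2$edges[!ng2$edges$kept, ]
  expect_true(all(removed$theta > 89))
  expect_true(any(removed$r <= max(fe$r)))
  expect_equal(ng2$fraction_removed, nrow(removed) / nrow(fe))
})

test_that("outlier edge is removed and fraction_removed reported", {
  fe <- toy_features(c(rep(1, 5), 10), c(rep(60, 5), 170))
  cs <- centroid_set(random_points(12, 2)) # nodes only used for bookkeeping
  g <- build_candidate_graph(cs)
  # synthesize a graph whose edge table matches the toy features
  g$edges <- cellneighbors:::normalize_edges(cbind(fe$i, fe$j))
  ng <- filter_edges(g, fe, optimize_thresholds(fe))
  expect_equal(sum(ng$edges$kept), 5L)
  expect_equal(ng$fraction_removed, 1 / 6)
})

test_that("filter is monotone in the thresholds", {
  set.seed(41)
  fe <- random_feature_table(30)
  mk <- function(r, t) {
    structure(
      list(r_star = r, theta_star = t, efficiency = 0, mode = "joint", surface = NULL),
      class = "nf_thresholds"
    )
  }
  cs <- centroid_set(random_points(40, 2))
  g <- build_candidate_graph(cs)
  g$edges <- cellneighbors:::normalize_edges(cbind(fe$i, fe$j))
  for (rep in 1:20) {
    r1 <- runif(1, min(fe$r), max(fe$r))
    t1 <- runif(1, min(fe$theta), max(fe$theta))
    r2 <- runif(1, r1, max(fe$r))
    t2 <- runif(1, t1, max(fe$theta))
    k1 <- edge_set_key(kept_edges(filter_edges(g, fe, mk(r1, t1))))
    k2 <- edge_set_key(kept_edges(filter_edges(g, fe, mk(r2, t2))))
    expect_true(all(k1 %in% k2))
  }
})

test_that("thresholds are scale invariant up to the scale factor", {
  set.seed(43)
  P <- random_points(35, 2)
  cs <- centroid_set(P)
  fit <- infer_neighbors(cs)
  for (c_ in c(0.01, 3.7, 250)) {
    cs2 <- centroid_set(P * c_)
    fit2 <- infer_neighbors(cs2)
    expect_equal(fit2$thresholds$r_star, fit$thresholds$r_star * c_, tolerance = 1e-9)
    expect_equal(fit2$thresholds$theta_star, fit$thresholds$theta_star, tolerance = 1e-9)
    expect_setequal(edge_set_key(kept_edges(fit2$graph)), edge_set_key(kept_edges(fit$graph)))
  }
})

test_that("distance-only baseline maximizes the 1-D efficiency", {
  fe <- toy_features(c(1, 1, 1, 1, 1, 10), c(10, 20, 30, 40, 50, 60))
  th <- optimize_distance_only(fe)
  expect_equal(th$r_star, 1)
  expect_equal(th$efficiency, 5 / 6)
  expect_equal(th$mode, "distance_only")
  expect_equal(th$theta_star, 60) # observed maximum: never constrains

  # degenerate: all distances equal
  fe2 <- toy_features(rep(2, 5), seq(10, 50, 10))
  th2 <- optimize_distance_only(fe2)
  expect_equal(th2$r_star, 2)
  expect_equal(th2$efficiency, 1)

  # joint-mode kept set is a subset when the r thresholds coincide
  set.seed(47)
  for (rep in 1:10) {
    fe3 <- random_feature_table(25)
    thj <- optimize_thresholds(fe3)
    thd <- optimize_distance_only(fe3)
    if (thj$r_star == thd$r_star) {
      kj <- fe3$r <= thj$r_star & fe3$theta <= thj$theta_star
      kd <- fe3$r <= thd$r_star & fe3$theta <= thd$theta_star
      expect_true(all(which(kj) %in% which(kd)))
    }
  }
})
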