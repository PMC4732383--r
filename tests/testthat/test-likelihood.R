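test_that("a zero-length single branch returns the root-prior mass", {
  ss <- state_space(rownames(three_area_geo()$distance), 2)
  scn <- uniform_scenario(three_area_geo())
  t1 <- ape::read.tree(text = "(a:0);")
  ll <- tree_likelihood(t1, c(a = "A"), ss, scn, dec_params(0.1, 0.05))
  expect_equal(ll, -log(n_states(ss)))
})

test_that("pruning equals joint enumeration on small trees", {
  set.seed(31)
  for (i in 1:30) {
    n_tip <- sample(2:4, 1)
    n_area <- if (n_tip == 4) 2 else 3
    geo <- if (n_area == 2) two_area_geo() else three_area_geo()
    ss <- state_space(rownames(geo$distance), sample(2:n_area, 1))
    tree <- sim_bd_tree(n_tip, 0.4, 0, seed = 3000 + i)
    p <- random_params()
    labs <- sample(ss$label[-1], n_tip, replace = TRUE)
    names(labs) <- tree$tip.label
    ll <- tree_likelihood(tree, labs, ss, uniform_scenario(geo), p)
    expect_equal(ll, brute_force_loglik(tree, labs, ss, geo, p),
                 tolerance = 1e-10)
  }
})

test_that("DEC+J with j = 0 is numerically identical to DEC", {
  dist <- arc_distances(5)
  ss <- state_space(rownames(dist), 2)
  scn <- uniform_scenario(epoch_geography(dist))
  tree <- sim_bd_tree(25, 0.3, 0, seed = 61)
  h <- sim_range_history(tree, ss, scn, dec_params(0.1, 0.02, j = 0.3),
                         seed = 62)
  p <- dec_params(0.08, 0.01, j = 0)
  expect_equal(
    tree_likelihood(tree, h$tip_ranges, ss, scn, p, dec_model("DEC")),
    tree_likelihood(tree, h$tip_ranges, ss, scn, p, dec_model("DEC+J")),
    tolerance = 1e-12
  )
})

test_that("with x = 0 the distance matrix is irrelevant", {
  dist <- arc_distances(5, rescale = FALSE)
  ss <- state_space(rownames(dist), 2)
  scn1 <- uniform_scenario(epoch_geography(dist))
  dist2 <- dist * 12.5
  dist2[1, 3] <- dist2[3, 1] <- 9999
  scn2 <- uniform_scenario(epoch_geography(dist2))
  tree <- sim_bd_tree(25, 0.3, 0, seed = 63)
  h <- sim_range_history(tree, ss, scn1, dec_params(0.1, 0.02, j = 0.3),
                         seed = 64)
  p <- dec_params(0.08, 0.01, j = 0.4, x = 0)
  expect_identical(tree_likelihood(tree, h$tip_ranges, ss, scn1, p),
                   tree_likelihood(tree, h$tip_ranges, ss, scn2, p))
})

test_that("distance rescaling is absorbed by the rate parameters", {
  dist <- arc_distances(5, rescale = FALSE)
  ss <- state_space(rownames(dist), 2)
  scn <- uniform_scenario(epoch_geography(dist))
  tree <- sim_bd_tree(25, 0.3, 0, seed = 65)
  h <- sim_range_history(tree, ss, scn,
                         dec_params(0.1, 0.02, j = 0.3, x = -0.5),
                         seed = 66)
  cc <- 4.2
  scn_scaled <- uniform_scenario(epoch_geography(dist * cc))
  # DEC+x (no jumps): d -> d * c^(-x) alone restores the likelihood
  p <- dec_params(0.08, 0.01, j = 0, x = -0.7)
  p_adj <- dec_params(0.08 * cc^0.7, 0.01, j = 0, x = -0.7)
  expect_equal(tree_likelihood(tree, h$tip_ranges, ss, scn, p),
               tree_likelihood(tree, h$tip_ranges, ss, scn_scaled, p_adj),
               tolerance = 1e-10)
  # DEC+J+x with distance-modified jumps: j rescales alongside d
  pj <- dec_params(0.08, 0.01, j = 0.5, x = -0.7)
  pj_adj <- dec_params(0.08 * cc^0.7, 0.01, j = 0.5 * cc^0.7, x = -0.7)
  expect_equal(tree_likelihood(tree, h$tip_ranges, ss, scn, pj),
               tree_likelihood(tree, h$tip_ranges, ss, scn_scaled, pj_adj),
               tolerance = 1e-10)
})

test_that("stratification with identical epochs changes nothing", {
  dist <- arc_distances(5)
  ss <- state_space(rownames(dist), 2)
  flat <- uniform_scenario(epoch_geography(dist))
  strat <- dec_scenario(list(
    epoch_geography(dist, start_age = Inf, end_age = 10),
    epoch_geography(dist, start_age = 10, end_age = 4),
    epoch_geography(dist, start_age = 4, end_age = 0)
  ))
  tree <- sim_bd_tree(25, 0.3, 0, seed = 67)
  h <- sim_range_history(tree, ss, flat, dec_params(0.1, 0.02, j = 0.3),
                         seed = 68)
  p <- dec_params(0.07, 0.01, j = 0.2, x = -1)
  expect_equal(tree_likelihood(tree, h$tip_ranges, ss, strat, p),
               tree_likelihood(tree, h$tip_ranges, ss, flat, p),
               tolerance = 1e-10)
})

test_that("likelihood is invariant to tip order and newick round-trips", {
  dist <- arc_distances(4)
  ss <- state_space(rownames(dist), 2)
  scn <- uniform_scenario(epoch_geography(dist))
  tree <- sim_bd_tree(12, 0.3, 0, seed = 69)
  h <- sim_range_history(tree, ss, scn, dec_params(0.1, 0.02, j = 0.3),
                         seed = 70)
  p <- dec_params(0.07, 0.01, j = 0.2)
  ll <- tree_likelihood(tree, h$tip_ranges, ss, scn, p)
  shuffled <- h$tip_ranges[sample(nrow(h$tip_ranges)), ]
  expect_equal(tree_likelihood(tree, shuffled, ss, scn, p), ll)
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tree, f)
  expect_equal(tree_likelihood(read_dated_tree(f), h$tip_ranges, ss, scn,
                               p),
               ll, tolerance = 1e-10)
})

test_that("tips in areas unavailable at the present are rejected", {
  dist <- arc_distances(4)
  areas <- rownames(dist)
  scn <- dec_scenario(list(
    epoch_geography(dist, start_age = Inf, end_age = 5),
    epoch_geography(dist, start_age = 5, end_age = 0,
                    allowed = areas[-1])
  ))
  ss <- state_space(areas, 2)
  tree <- sim_bd_tree(3, 0.3, 0, seed = 71)
  tips <- stats::setNames(c(areas[1], areas[2], areas[3]),
                          tree$tip.label)
  expect_error(
    tree_likelihood(tree, tips, ss, scn, dec_params(0.1, 0.01)),
    "unavailable at the present")
})
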