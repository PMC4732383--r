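test_that("dispersal rate combines d, multiplier and distance^x", {
  geo <- two_area_geo(100)
  expect_equal(dispersal_rate("A", "B", dec_params(0.1, 0), geo), 0.1)
  m1 <- matrix(c(0, 1, 1, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  mult <- matrix(c(0, 0.5, 0.5, 0), 2, 2,
                 dimnames = list(c("A", "B"), c("A", "B")))
  geo_u <- epoch_geography(m1, multiplier = mult)
  expect_equal(dispersal_rate("A", "B", dec_params(0.1, 0, x = -1), geo_u),
               0.05)
  # 9999 km sentinel: dispersal possible but vanishingly unlikely
  geo_s <- two_area_geo(9999)
  r <- dispersal_rate("A", "B", dec_params(0.1, 0, x = -2), geo_s)
  expect_equal(r, 0.1 * 9999^-2)
  expect_gt(r, 0)
  expect_lt(r, 1.1e-9)
  # unavailable target: rate 0, not an error
  geo_b <- epoch_geography(m1 * 100, allowed = "A")
  expect_equal(dispersal_rate("A", "B", dec_params(0.1, 0), geo_b), 0)
})

test_that("Q has one-step expansion and contraction structure", {
  ss2 <- state_space(c("A", "B"), 2)
  Q <- build_Q(ss2, dec_params(1, 0), two_area_geo())
  expect_equal(Q["A", "A+B"], 1)
  expect_equal(Q["A", "B"], 0)       # no one-step range *replacement*
  Qe <- build_Q(ss2, dec_params(1, 0.2), two_area_geo())
  expect_equal(Qe["A+B", "A"], 0.2)
  expect_equal(Qe["A", "_"], 0.2)    # singleton extinction to null
  expect_true(all(abs(rowSums(Qe)) < 1e-12))
  expect_true(all(Qe["_", ] == 0))   # null is absorbing
  # expansion rate sums dist^x over source areas
  geo3 <- three_area_geo(100, 250, 150)
  ss3 <- state_space(c("A", "B", "C"), 3)
  p <- dec_params(0.3, 0, x = -1)
  Q3 <- build_Q(ss3, p, geo3)
  expect_equal(Q3["A+B", "A+B+C"], 0.3 * (250^-1 + 150^-1))
  # max_range_size caps expansion
  ss3c <- state_space(c("A", "B", "C"), 2)
  Qc <- build_Q(ss3c, p, geo3)
  expect_false("A+B+C" %in% colnames(Qc))
  expect_true(all(abs(rowSums(Qc)) < 1e-12))
})

test_that("cladogenesis table covers the DEC and DEC+J event menus", {
  ss2 <- state_space(c("A", "B"), 2)
  geo <- two_area_geo()
  # DEC singleton: sympatric copy only
  ct <- tidy(cladogenesis_table(ss2, dec_params(0.1, 0.1), geo), ss2)
  a_rows <- ct[ct$parent == "A", ]
  expect_identical(nrow(a_rows), 1L)
  expect_equal(a_rows$prob, 1)
  # DEC widespread: subset x2 + vicariance x2, each 1/4
  ab <- ct[ct$parent == "A+B", ]
  expect_equal(sum(ab$prob), 1)
  expect_equal(sum(ab$prob[ab$type == "subset"]), 0.5)
  expect_equal(sum(ab$prob[ab$type == "vicariance"]), 0.5)
  # DEC+J singleton with unit modifiers, j = 1: copy 1/2, jump 1/2
  ctj <- tidy(cladogenesis_table(ss2, dec_params(0.1, 0.1, j = 1),
                                 epoch_geography(
                                   matrix(c(0, 1, 1, 0), 2, 2,
                                          dimnames = list(c("A", "B"),
                                                          c("A", "B"))))),
              ss2)
  aj <- ctj[ctj$parent == "A", ]
  expect_equal(sum(aj$prob[aj$type == "sympatry"]), 0.5)
  expect_equal(sum(aj$prob[aj$type == "jump"]), 0.5)
})

test_that("every parent's outcome probabilities sum to one", {
  geo3 <- three_area_geo()
  ss3 <- state_space(c("A", "B", "C"), 3)
  for (p in list(dec_params(0.1, 0.1), dec_params(0.1, 0.1, j = 0.7),
                 dec_params(0.1, 0.1, j = 0.7, x = -1.5))) {
    ct <- cladogenesis_table(ss3, p, geo3)
    sums <- tapply(ct$prob, ct$parent, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    # null never appears as parent or daughter
    expect_false(1L %in% c(ct$parent, ct$left, ct$right))
  }
})

test_that("template-filled Q and cladogenesis tables match the reference
          builders", {
  dist <- arc_distances(6)
  areas <- rownames(dist)
  old <- epoch_geography(dist, start_age = Inf, end_age = 10,
                         allowed = areas[-(1:2)])
  young <- epoch_geography(dist, start_age = 10, end_age = 0)
  scn <- dec_scenario(list(old, young))
  ss <- state_space(areas, 3)
  set.seed(21)
  for (i in 1:5) {
    p <- random_params()
    eng <- decarc:::scenario_engine(ss, scn, p)
    for (k in 1:2) {
      expect_equal(eng$Qs[[k]], build_Q(ss, p, scn$epochs[[k]]),
                   ignore_attr = TRUE)
      ref <- cladogenesis_table(ss, p, scn$epochs[[k]])
      ct <- eng$clads[[k]]
      keep <- ct$prob > 0
      o1 <- order(ct$parent[keep], ct$left[keep], ct$right[keep])
      o2 <- order(ref$parent, ref$left, ref$right)
      expect_identical(ct$parent[keep][o1], ref$parent[o2])
      expect_identical(ct$left[keep][o1], ref$left[o2])
      expect_identical(ct$right[keep][o1], ref$right[o2])
      expect_equal(ct$prob[keep][o1], ref$prob[o2], tolerance = 1e-12)
    }
  }
})
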