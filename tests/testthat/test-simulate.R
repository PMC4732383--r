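test_that("birth-death trees are reproducible and correctly sized", {
  t1 <- sim_bd_tree(2, 0.3, 0, seed = 101)
  expect_identical(length(t1$tip.label), 2L)
  expect_identical(t1$Nnode, 1L)
  a <- sim_bd_tree(40, 0.3, 0.05, seed = 102)
  b <- sim_bd_tree(40, 0.3, 0.05, seed = 102)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_lt(max(abs(node_ages(a)[1:40])), 1e-8)
  expect_error(sim_bd_tree(10, 0.1, 0.2, seed = 1), "birth > death")
})

test_that("pure-birth root ages match the Yule expectation", {
  # E[T_root] for a Yule tree with n sampled tips is sum_{k=2}^{n} 1/(k b)
  # (while k lineages exist the next divergence is Exp(k b) away);
  # checked against naive draws from that construction
  set.seed(103)
  n <- 8; b <- 0.3; reps <- 500
  ages <- vapply(seq_len(reps), function(i) {
    max(node_ages(sim_bd_tree(n, b, 0)))
  }, numeric(1))
  naive <- vapply(seq_len(reps), function(i) {
    sum(stats::rexp(n - 1, rate = b * (2:n)))
  }, numeric(1))
  se <- sqrt(stats::var(ages) / reps + stats::var(naive) / reps)
  expect_lt(abs(mean(ages) - mean(naive)), 4 * se)
  expect_lt(abs(mean(ages) - sum(1 / (b * (2:n)))), 4 * sd(ages) / sqrt(reps))
})

test_that("a null process copies the root range to every tip", {
  dist <- arc_distances(5)
  ss <- state_space(rownames(dist), 2)
  scn <- uniform_scenario(epoch_geography(dist))
  tree <- sim_bd_tree(15, 0.3, 0, seed = 104)
  h <- sim_range_history(tree, ss, scn, dec_params(0, 0, j = 0),
                         root_range = "I02", seed = 105)
  expect_true(all(h$tip_ranges$range == "I02"))
  expect_identical(nrow(h$events), 0L)
})

test_that("histories are seed-reproducible and replay exactly", {
  dist <- arc_distances(6)
  ss <- state_space(rownames(dist), 2)
  scn <- arc_scenario(dist, boundary_age = 8, n_unavailable = 2)
  tree <- sim_bd_tree(40, 0.3, 0, seed = 106)
  p <- dec_params(0.05, 0.01, j = 0.3, x = -1)
  h1 <- sim_range_history(tree, ss, scn, p, seed = 107)
  h2 <- sim_range_history(tree, ss, scn, p, seed = 107)
  expect_identical(h1$tip_ranges, h2$tip_ranges)
  expect_identical(h1$events, h2$events)
  expect_identical(replay_history(h1)$range, h1$tip_ranges$range)
  # microendemic default: every tip is a single area
  expect_false(any(grepl("+", h1$tip_ranges$range, fixed = TRUE)))
})

test_that("area availability is respected through time", {
  dist <- arc_distances(6)
  ss <- state_space(rownames(dist), 2)
  scn <- arc_scenario(dist, boundary_age = 10, n_unavailable = 2)
  blocked <- rownames(dist)[1:2]
  found_old <- FALSE
  for (s in 1:10) {
    tree <- sim_bd_tree(30, 0.2, 0, seed = 200 + s)
    if (max(node_ages(tree)) < 12) next
    h <- sim_range_history(tree, ss, scn,
                           dec_params(0.08, 0.01, j = 0.3, x = -1),
                           seed = 300 + s)
    old_events <- h$events[h$events$age > 10, ]
    touches <- vapply(strsplit(paste(old_events$from, old_events$to,
                                     sep = "+"), "[+| ]"), function(x) {
      any(x %in% blocked)
    }, logical(1))
    expect_false(any(touches))
    found_old <- found_old || nrow(old_events) > 0
  }
  expect_true(found_old)
})

test_that("single-branch expansion probability matches the closed form", {
  # 2 areas, max range 2, start {A}: P(state != {A} at t) under d with
  # no return (e = 0) is 1 - exp(-d t) in a one-way race to {A,B}
  dist_km <- 150
  geo <- epoch_geography(matrix(c(0, dist_km, dist_km, 0), 2, 2,
                                dimnames = list(c("A", "B"),
                                                c("A", "B"))))
  ss <- state_space(c("A", "B"), 2)
  scn <- uniform_scenario(geo)
  d <- 0.08; x <- -0.5; t_len <- 6
  rate <- d * dist_km^x
  tree <- ape::read.tree(text = "(t1:6,t2:6);")
  set.seed(108)
  n_rep <- 4000
  expanded <- 0L
  p <- dec_params(d, 0, j = 0, x = x)
  eng <- decarc:::scenario_engine(ss, scn, p)
  for (i in seq_len(n_rep)) {
    st <- decarc:::sim_branch(eng, range_index(ss, "A"), t_len, 0, 1L,
                              function(...) NULL)
    expanded <- expanded + (ss$label[st] == "A+B")
  }
  p_hat <- expanded / n_rep
  p_true <- 1 - exp(-rate * t_len)
  expect_lt(abs(p_hat - p_true),
            3 * sqrt(p_true * (1 - p_true) / n_rep))
})

test_that("one-branch simulation frequencies match branch transition
          probabilities", {
  # links the Gillespie simulator and the likelihood propagator as
  # mutual oracles on a 3-area system with contraction and distance
  geo <- three_area_geo(120, 260, 140)
  ss <- state_space(rownames(geo$distance), 2)
  scn <- uniform_scenario(geo)
  p <- dec_params(0.02, 0.01, j = 0, x = -0.8)
  eng <- decarc:::scenario_engine(ss, scn, p)
  start <- range_index(ss, "A+B")
  t_len <- 8
  set.seed(109)
  n_rep <- 6000
  got <- integer(length(ss$bits))
  for (i in seq_len(n_rep)) {
    st <- decarc:::sim_branch(eng, start, t_len, 0, 1L,
                              function(...) NULL)
    if (is.null(st)) st <- 1L  # extinct -> null state
    got[st] <- got[st] + 1L
  }
  P <- branch_transition(build_Q(ss, p, geo), t_len)
  for (s in seq_along(ss$bits)) {
    p_s <- P[start, s]
    se <- sqrt(max(p_s * (1 - p_s), 1e-12) / n_rep)
    expect_lt(abs(got[s] / n_rep - p_s), max(3 * se, 3 / n_rep))
  }
})

test_that("recovery experiments are reproducible and structured", {
  rep1 <- recovery_experiment(2, n_tips = 20,
                              true_params = dec_params(0.05, 0.01,
                                                       j = 0.3, x = 0),
                              models = c("DEC", "DEC+J"),
                              sim_model = dec_model("DEC+J"),
                              birth = 0.3, seed = 11)
  rep2 <- recovery_experiment(2, n_tips = 20,
                              true_params = dec_params(0.05, 0.01,
                                                       j = 0.3, x = 0),
                              models = c("DEC", "DEC+J"),
                              sim_model = dec_model("DEC+J"),
                              birth = 0.3, seed = 11)
  expect_identical(rep1$fits, rep2$fits)
  expect_identical(nrow(rep1$fits), 4L)
  expect_true(all(c("bias", "rmse", "median_rel_error") %in%
                    names(rep1$summary)))
  expect_identical(sum(rep1$fits$best), 2L)
  gl <- glance(rep1)
  expect_identical(gl$n_replicates, 2L)
})
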