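test_that("uniform tip areas need no changes", {
  tr <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1.5,t4:1.5):0.5);")
  asr <- fitch_asr(tr, c(t1 = "a", t2 = "a", t3 = "a", t4 = "a"))
  expect_identical(asr$score, 0)
  expect_true(all(vapply(asr$mpr, identical, logical(1), "a")))
  expect_identical(nrow(count_dispersal_events(asr)$events), 0L)
})

test_that("the ((a,a),(b,b)) cherry pair is the textbook Fitch case", {
  tr <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
  asr <- fitch_asr(tr, c(t1 = "a", t2 = "a", t3 = "b", t4 = "b"))
  expect_identical(asr$score, 1)
  expect_setequal(asr$mpr[[5]], c("a", "b"))   # root is ambiguous
  expect_identical(asr$mpr[[6]], "a")
  expect_identical(asr$mpr[[7]], "b")
  ev <- count_dispersal_events(asr, "deltran")
  expect_identical(ev$total, 1L)
  expect_identical(ev$min_changes, 1)
  # root resolves to "a" (lowest index), so the change is a -> b
  expect_identical(unname(ev$counts["a", "b"]), 1L)
  expect_identical(ev$directionality$events,
                   c(0L, 1L))  # one change toward the later-listed area
  rev_dir <- count_dispersal_events(asr, "deltran",
                                    area_order = c("b", "a"))
  expect_identical(rev_dir$directionality$events, c(1L, 0L))
})

test_that("change counts equal the Sankoff oracle on random trees", {
  skip_if_not_installed("phangorn")
  set.seed(41)
  for (i in 1:60) {
    n_tip <- 10
    tr <- ape::rtree(n_tip)
    areas <- sample(letters[1:4], n_tip, replace = TRUE)
    names(areas) <- tr$tip.label
    if (length(unique(areas)) == 1) next
    asr <- fitch_asr(tr, areas)
    expect_identical(as.numeric(asr$score), phangorn_sankoff_score(tr, areas))
    # both resolutions are most-parsimonious
    expect_identical(count_dispersal_events(asr, "deltran")$total,
                     as.integer(asr$score))
    expect_identical(count_dispersal_events(asr, "acctran")$total,
                     as.integer(asr$score))
  }
})

test_that("the Fitch minimum is invariant to relabeling areas", {
  set.seed(43)
  tr <- ape::rtree(12)
  areas <- sample(c("w", "x", "y"), 12, replace = TRUE)
  names(areas) <- tr$tip.label
  perm <- c(w = "y", x = "w", y = "x")
  relabeled <- stats::setNames(perm[areas], names(areas))
  expect_identical(fitch_asr(tr, areas)$score,
                   fitch_asr(tr, relabeled)$score)
})

test_that("polytomies and incomplete tip data are rejected", {
  poly <- ape::read.tree(text = "(t1:1,t2:1,t3:1);")
  expect_error(fitch_asr(poly, c(t1 = "a", t2 = "a", t3 = "b")),
               "polytomies")
  tr <- ape::read.tree(text = "((t1:1,t2:1):1,t3:2);")
  expect_error(fitch_asr(tr, c(t1 = "a", t2 = "b")), "no area")
})

test_that("dispersal events on simulated one-way histories point the
          simulated way", {
  # zero dispersal after the root: all tips in the root area, 0 events
  dist <- arc_distances(4)
  ss <- state_space(rownames(dist), 1)
  scn <- uniform_scenario(epoch_geography(dist))
  tree <- sim_bd_tree(20, 0.3, 0, seed = 45)
  h0 <- sim_range_history(tree, ss, scn, dec_params(0, 0, j = 0),
                          root_range = "I01", seed = 46)
  asr0 <- fitch_asr(tree, stats::setNames(h0$tip_ranges$range,
                                          h0$tip_ranges$taxon))
  expect_identical(asr0$score, 0)
  # low-density jump-only histories: counted direction matches the log
  set.seed(47)
  hits <- 0; n_rep <- 40; usable <- 0
  for (r in seq_len(n_rep)) {
    tr <- sim_bd_tree(25, 0.3, 0)
    h <- sim_range_history(tr, ss, scn, dec_params(0, 0, j = 0.015),
                           root_range = "I01")
    jumps <- h$events[h$events$type == "jump", ]
    if (nrow(jumps) == 0) next
    usable <- usable + 1
    asr <- fitch_asr(tr, stats::setNames(h$tip_ranges$range,
                                         h$tip_ranges$taxon))
    ev <- count_dispersal_events(asr, "deltran")
    sim_counts <- table(factor(h$events$from[h$events$type == "jump"],
                               levels = rownames(dist)))
    got <- stats::setNames(rep(0L, nrow(dist)), rownames(dist))
    got[rownames(ev$counts)] <- as.integer(rowSums(ev$counts))
    if (all(got == as.integer(sim_counts))) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / usable, 0.9)
})

test_that("lineage accumulation counts branch crossings per area", {
  tr <- ape::read.tree(text = "((t1:2,t2:2):3,t3:5);")
  areas <- c(t1 = "a", t2 = "a", t3 = "b")
  asr <- fitch_asr(tr, areas)
  resolved <- resolve_asr(asr, "deltran")
  ltt <- lineage_accumulation(tr, resolved, bin_width = 2)
  expect_identical(sort(unique(ltt$age)), c(0, 2, 4))
  # a node sitting exactly on a bin boundary: its daughters start there,
  # so only branches strictly spanning the boundary count
  tot <- tapply(ltt$lineages, ltt$age, sum)
  expect_identical(as.integer(tot[c("4", "2", "0")]), c(2L, 2L, 3L))
  # area identity at t = 0: two a tips and one b tip
  expect_identical(ltt$lineages[ltt$age == 0 & ltt$area == "a"], 2L)
  expect_identical(ltt$lineages[ltt$age == 0 & ltt$area == "b"], 1L)
  expect_error(lineage_accumulation(tr, c("a", "a", "b"), 2), "every node")
})

test_that("a mid-branch change is credited to the older area first", {
  # one branch root(age 4) -> tip, parent area a, child area b: the
  # change sits at age 2, so at age 3 the lineage is still in a
  tr <- ape::read.tree(text = "(t1:4,t2:4);")
  node_areas <- c("b", "a", "a")  # t1 = b, t2 = a, root = a
  ltt <- lineage_accumulation(tr, node_areas, bin_width = 1)
  expect_identical(ltt$lineages[ltt$age == 3 & ltt$area == "a"], 2L)
  expect_identical(ltt$lineages[ltt$age == 3 & ltt$area == "b"], 0L)
  expect_identical(ltt$lineages[ltt$age == 1 & ltt$area == "b"], 1L)
})

test_that("binned counts match an independent per-branch enumeration", {
  set.seed(49)
  for (r in 1:5) {
    tree <- sim_bd_tree(20, 0.35, 0)
    node_areas <- sample(c("p", "q", "r"),
                         20 + tree$Nnode, replace = TRUE)
    ages <- node_ages(tree)
    ltt <- lineage_accumulation(tree, node_areas, bin_width = 1.5)
    # oracle: loop over edges, step through bin boundaries one by one
    for (t in unique(ltt$age)) {
      counts <- c(p = 0L, q = 0L, r = 0L)
      for (ei in seq_len(nrow(tree$edge))) {
        pa <- ages[tree$edge[ei, 1]]
        ca <- ages[tree$edge[ei, 2]]
        if (!(pa > t && ca <= t)) next
        area <- if (t >= (pa + ca) / 2) node_areas[tree$edge[ei, 1]]
        else node_areas[tree$edge[ei, 2]]
        counts[area] <- counts[area] + 1L
      }
      got <- ltt$lineages[ltt$age == t]
      names(got) <- ltt$area[ltt$age == t]
      expect_identical(got[names(counts)], counts)
    }
  }
})
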