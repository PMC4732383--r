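# Independent oracles used across the suite.  These deliberately avoid the
# package's pruning / propagation code paths: the likelihood oracle sums
# the joint probability over every explicit assignment of node states and
# cladogenetic outcomes, and the matrix exponential oracle is a truncated
# Taylor series.

# exp(Q t) by scaled Taylor series
taylor_expm <- function(Q, t, order = 60) {
  n_half <- max(0, ceiling(log2(max(abs(Q)) * t + 1e-12)) + 4)
  M <- Q * (t / 2^n_half)
  P <- diag(nrow(Q))
  term <- diag(nrow(Q))
  for (k in seq_len(order)) {
    term <- term %*% M / k
    P <- P + term
  }
  for (i in seq_len(n_half)) P <- P %*% P
  P
}

# Joint-enumeration likelihood for tiny trees under a single-epoch
# scenario.  Every internal node is assigned one cladogenesis-table row
# (parent state + ordered daughter pair); the likelihood is the sum over
# all combinations of: root prior x cladogenesis probabilities x branch
# transition factors.
brute_force_loglik <- function(tree, tip_range_labels, ss, geo, params,
                               jump_distance = TRUE) {
  Q <- build_Q(ss, params, geo)
  ct <- cladogenesis_table(ss, params, geo, jump_distance)
  ages <- decarc::node_ages(tree)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  tip_state <- decarc::range_index(ss, tip_range_labels[tree$tip.label])
  # transition matrix per edge (child-indexed), via the Taylor oracle
  P_edge <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    c_ <- tree$edge[i, 2]
    P_edge[[c_]] <- taylor_expm(Q, ages[p] - ages[c_])
  }
  children <- lapply(seq_len(n_tip + tree$Nnode), function(n) {
    tree$edge[tree$edge[, 1] == n, 2]
  })
  internal <- which(lengths(children) > 0)
  n_rows_per_node <- length(ct$prob)
  combo <- expand.grid(rep(list(seq_len(n_rows_per_node)),
                           length(internal)))
  root_states <- which(ss$size > 0)
  total <- 0
  for (r in seq_len(nrow(combo))) {
    rows <- as.integer(combo[r, ])
    prob <- 1 / length(root_states)  # uniform prior over the root row's
    # parent state; rows sharing a parent state sum to 1, so summing over
    # rows integrates the prior correctly
    for (k in seq_along(internal)) {
      n <- internal[k]
      row <- rows[k]
      prob <- prob * ct$prob[row]
      # branch factors from this node's daughter slots down to children;
      # a non-tip child's branch ends in that child's own (pre-
      # cladogenesis) parent state
      ch <- children[[n]]
      starts <- c(ct$left[row], ct$right[row])
      for (side in 1:2) {
        c_ <- ch[side]
        end_state <- if (c_ <= n_tip) {
          tip_state[c_]
        } else {
          ct$parent[rows[match(c_, internal)]]
        }
        prob <- prob * P_edge[[c_]][starts[side], end_state]
      }
    }
    total <- total + prob
  }
  unname(log(total))
}

# uniform-cost Sankoff parsimony score via phangorn (independent of the
# package's own dynamic program)
phangorn_sankoff_score <- function(tree, tip_areas) {
  areas <- sort(unique(tip_areas))
  dat <- matrix(tip_areas[tree$tip.label], ncol = 1,
                dimnames = list(tree$tip.label, NULL))
  pd <- phangorn::phyDat(dat, type = "USER", levels = areas)
  cost <- matrix(1, length(areas), length(areas))
  diag(cost) <- 0
  as.numeric(phangorn::parsimony(tree, pd, method = "sankoff",
                                 cost = cost))
}

# small fixed two-area geography used in many tests
two_area_geo <- function(d_ab = 100) {
  epoch_geography(matrix(c(0, d_ab, d_ab, 0), 2, 2,
                         dimnames = list(c("A", "B"), c("A", "B"))))
}

three_area_geo <- function(d12 = 100, d13 = 250, d23 = 150) {
  m <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"),
                                       c("A", "B", "C")))
  m["A", "B"] <- m["B", "A"] <- d12
  m["A", "C"] <- m["C", "A"] <- d13
  m["B", "C"] <- m["C", "B"] <- d23
  epoch_geography(m)
}

random_params <- function(max_d = 0.5, max_e = 0.3, with_j = TRUE,
                          with_x = TRUE) {
  dec_params(d = runif(1, 0.01, max_d), e = runif(1, 0.005, max_e),
             j = if (with_j) runif(1, 0, 1) else 0,
             x = if (with_x) runif(1, -2, 0) else 0)
}
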