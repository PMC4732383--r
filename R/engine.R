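# Internal fast path for repeated likelihood evaluation.
#
# Everything that does not depend on (d, e, j, x) -- the sparsity pattern
# of Q, the cladogenesis row structure, the per-parent row blocks -- is
# precomputed once per (state space, scenario) in a "template"; each
# optimizer evaluation only fills numeric values into it.  The filled
# matrices are checked against the reference builders build_Q() /
# cladogenesis_table() in the test suite.

epoch_template <- function(ss, geo, jump_distance) {
  S <- length(ss$bits)
  A <- ss$n_areas
  blocked <- match(setdiff(geo$areas, geo$allowed), geo$areas)
  # --- anagenetic structure -------------------------------------------
  exp_qi <- exp_qj <- integer(0)      # one entry per (state, target area)
  pair_entry <- pair_from <- pair_to <- integer(0)
  con_qi <- con_qj <- integer(0)
  for (i in seq_len(S)) {
    b <- ss$bits[i]
    if (b == 0L) next
    members <- bit_members(b)
    for (a in members) {
      con_qi <- c(con_qi, i)
      con_qj <- c(con_qj,
                  ss$.lookup[bitwAnd(b, bitwNot(as.integer(2^(a - 1)))) + 1L])
    }
    if (length(members) < ss$max_range_size) {
      for (a2 in setdiff(seq_len(A), members)) {
        exp_qi <- c(exp_qi, i)
        exp_qj <- c(exp_qj, ss$.lookup[b + as.integer(2^(a2 - 1)) + 1L])
        id <- length(exp_qi)
        pair_entry <- c(pair_entry, rep.int(id, length(members)))
        pair_from <- c(pair_from, members)
        pair_to <- c(pair_to, rep.int(a2, length(members)))
      }
    }
  }
  # --- cladogenesis structure (rows contiguous per parent) ------------
  parent <- left <- right <- integer(0)
  base_w <- numeric(0)
  type <- character(0)
  jpair_row <- jpair_from <- jpair_to <- integer(0)
  jump_nmem <- integer(0)   # indexed like rows; 0 for non-jump rows
  singleton <- function(a) ss$.lookup[as.integer(2^(a - 1)) + 1L]
  for (i in seq_len(S)) {
    b <- ss$bits[i]
    if (b == 0L) next
    members <- bit_members(b)
    k <- length(members)
    add <- function(l, r, w, t) {
      if (l == r) {
        parent <<- c(parent, i); left <<- c(left, l); right <<- c(right, r)
        base_w <<- c(base_w, w); type <<- c(type, t)
        jump_nmem <<- c(jump_nmem, 0L)
      } else {
        parent <<- c(parent, i, i); left <<- c(left, l, r)
        right <<- c(right, r, l); base_w <<- c(base_w, w / 2, w / 2)
        type <<- c(type, t, t); jump_nmem <<- c(jump_nmem, 0L, 0L)
      }
    }
    if (k == 1) {
      add(i, i, 1, "sympatry")
    } else {
      for (a in members) {
        add(singleton(a), i, 1, "subset")
        rem <- ss$.lookup[bitwAnd(b, bitwNot(as.integer(2^(a - 1)))) + 1L]
        add(singleton(a), rem, 1, "vicariance")
      }
    }
    for (a2 in setdiff(seq_len(A), members)) {
      # ordered jump rows (parent-range daughter first, then reversed)
      for (ord in 1:2) {
        parent <- c(parent, i)
        left <- c(left, if (ord == 1) i else singleton(a2))
        right <- c(right, if (ord == 1) singleton(a2) else i)
        base_w <- c(base_w, 0)
        type <- c(type, "jump")
        jump_nmem <- c(jump_nmem, k)
        id <- length(parent)
        jpair_row <- c(jpair_row, rep.int(id, k))
        jpair_from <- c(jpair_from, members)
        jpair_to <- c(jpair_to, rep.int(a2, k))
      }
    }
  }
  # contiguous blocks per parent
  blk <- rle(parent)
  blk_end <- cumsum(blk$lengths)
  blk_start <- blk_end - blk$lengths + 1L
  list(
    S = S, A = A, blocked = blocked, jump_distance = jump_distance,
    multiplier = geo$multiplier, distance = geo$distance,
    exp_qi = exp_qi, exp_qj = exp_qj, n_exp = length(exp_qi),
    pair_entry = pair_entry, pair_idx = cbind(pair_from, pair_to),
    con_qi = con_qi, con_qj = con_qj,
    clad_parent = parent, clad_left = left, clad_right = right,
    clad_base_w = base_w, clad_type = type,
    jump_rows = which(jump_nmem > 0L), jump_nmem = jump_nmem,
    jpair_row = jpair_row, jpair_idx = cbind(jpair_from, jpair_to),
    blk_parent = blk$values, blk_start = blk_start, blk_end = blk_end
  )
}

modifier_matrix <- function(tpl, x, use_distance) {
  m <- tpl$multiplier
  if (use_distance && x != 0) {
    dp <- tpl$distance
    nz <- dp > 0
    dp[nz] <- dp[nz]^x
    m <- m * dp
  }
  if (length(tpl$blocked)) m[, tpl$blocked] <- 0
  diag(m) <- 0
  m
}

fill_Q <- function(tpl, params) {
  Q <- matrix(0, tpl$S, tpl$S)
  if (params$e > 0) {
    # accumulate duplicate-free contraction entries
    Q[cbind(tpl$con_qi, tpl$con_qj)] <- params$e
  }
  if (params$d > 0 && tpl$n_exp > 0) {
    mod <- modifier_matrix(tpl, params$x, use_distance = TRUE)
    agg <- rowsum(mod[tpl$pair_idx], tpl$pair_entry)
    vals <- params$d * as.vector(agg)
    keep <- vals > 0
    Q[cbind(tpl$exp_qi, tpl$exp_qj)[keep, , drop = FALSE]] <- vals[keep]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

fill_clad <- function(tpl, params) {
  w <- tpl$clad_base_w
  if (params$j > 0 && length(tpl$jump_rows)) {
    mod <- modifier_matrix(tpl, params$x,
                           use_distance = tpl$jump_distance)
    sums <- rowsum(mod[tpl$jpair_idx], tpl$jpair_row)
    rows <- as.integer(rownames(sums))
    w[rows] <- (params$j / 2) * sums[, 1] / tpl$jump_nmem[rows]
  }
  cs <- cumsum(w)
  tot <- cs[tpl$blk_end] - c(0, cs[tpl$blk_end[-length(tpl$blk_end)]])
  blk_of_row <- rep.int(seq_along(tpl$blk_parent),
                        tpl$blk_end - tpl$blk_start + 1L)
  # zero-probability rows are kept so row blocks stay aligned with the
  # template (engine_combine relies on contiguity)
  prob <- w / tot[blk_of_row]
  list(parent = tpl$clad_parent, left = tpl$clad_left,
       right = tpl$clad_right, prob = prob, type = tpl$clad_type,
       n_states = tpl$S)
}
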