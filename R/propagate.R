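#' Branch transition probabilities
#'
#' The probability matrix `exp(Q t)` of the anagenetic CTMC over a branch
#' of duration `t` Myr.  Rows index the state at the older (rootward) end.
#'
#' @param Q Rate matrix from [build_Q()].
#' @param t Branch duration in Myr, `>= 0`.
#' @return Row-stochastic S×S probability matrix.
#' @export
branch_transition <- function(Q, t) {
  if (t < 0) stop("branch duration must be non-negative", call. = FALSE)
  if (t == 0) {
    return(diag(nrow(Q)))
  }
  P <- expm::expm(Q * t)
  pmax(P, 0)
}

# Eigendecomposition-backed propagator: one O(S^3) decomposition per Q,
# then a branch costs a couple of matrix(-vector) products.  DEC
# generators are generically diagonalizable; if the decomposition
# reproduces Q poorly (defective or ill-conditioned eigenvectors) fall
# back to expm per call.
make_propagator <- function(Q) {
  S <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- FALSE
  Vinv <- NULL
  if (!is.null(eg)) {
    Vinv <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vinv)) {
      Qhat <- eg$vectors %*% (eg$values * Vinv)
      scale <- max(abs(Q), 1e-8)
      use_eigen <- max(abs(Re(Qhat) - Q)) < 1e-9 * max(scale, 1) &&
        max(abs(Im(Qhat))) < 1e-9 * max(scale, 1)
    }
  }
  rate <- max(-diag(Q), 1e-300)
  A <- Q / rate + diag(S)  # substochastic jump matrix for uniformization
  if (use_eigen) {
    real <- max(abs(Im(eg$values))) < 1e-12 &&
      max(abs(Im(eg$vectors))) < 1e-12
    list(type = if (real) "eigen_real" else "eigen", S = S,
         V = if (real) Re(eg$vectors) else eg$vectors,
         lam = if (real) Re(eg$values) else eg$values,
         Vinv = if (real) Re(Vinv) else Vinv,
         Q = Q, unif_rate = rate, A = A)
  } else {
    list(type = "unif", S = S, Q = Q, unif_rate = rate, A = A)
  }
}

# w = exp(Q t) %*% f by uniformization (stable for defective Q, e.g.
# when e = 0 makes eigenvalues repeat); long intervals are chunked so
# the Poisson weights never underflow
unif_matvec <- function(prop, t, f) {
  m_total <- prop$unif_rate * t
  if (m_total > 60) {
    # a long series is dearer than one Pade exponential
    return(as.vector(expm::expm(prop$Q * t) %*% f))
  }
  n_chunk <- max(1L, ceiling(m_total / 50))
  m <- m_total / n_chunk
  for (chunk in seq_len(n_chunk)) {
    K <- ceiling(m + 8 * sqrt(m) + 12)
    pk <- exp(-m)
    v <- f
    w <- pk * v
    for (k in seq_len(K)) {
      v <- as.vector(prop$A %*% v)
      pk <- pk * m / k
      w <- w + pk * v
    }
    f <- w
  }
  f[f < 0] <- 0
  f
}

# full transition matrix exp(Q t) from a propagator
prop_matrix <- function(prop, t) {
  if (t == 0) return(diag(prop$S))
  if (prop$type == "eigen_real") {
    pmax(prop$V %*% (exp(prop$lam * t) * prop$Vinv), 0)
  } else if (prop$type == "eigen") {
    pmax(Re(prop$V %*% (exp(prop$lam * t) * prop$Vinv)), 0)
  } else {
    branch_transition(prop$Q, t)
  }
}

# w = exp(Q t) %*% f without forming the matrix (hot path of pruning)
prop_matvec <- function(prop, t, f) {
  if (t == 0) return(f)
  if (prop$type == "eigen_real") {
    w <- (prop$V %*% (exp(prop$lam * t) * (prop$Vinv %*% f)))[, 1]
  } else if (prop$type == "eigen") {
    w <- Re(prop$V %*% (exp(prop$lam * t) * (prop$Vinv %*% f)))[, 1]
  } else {
    return(unif_matvec(prop, t, f))
  }
  w[w < 0] <- 0
  w
}

#' Epoch-spanning branch transition matrix
#'
#' Cuts a branch at every epoch boundary it crosses, multiplies the
#' per-segment transition matrices in old-to-young order, and, on entering
#' each younger epoch, zeroes the probability mass of states containing
#' areas unavailable in that epoch (masking without renormalization: a
#' lineage occupying an area that does not exist there simply cannot have
#' existed).
#'
#' @param scenario A [dec_scenario()].
#' @param ss State space (with null).
#' @param params A [dec_params()].
#' @param older_age,younger_age Branch endpoint ages in Ma,
#'   `older_age >= younger_age >= 0`.
#' @return Probability matrix; rows index the state at `older_age`.
#' @export
stratified_branch_transition <- function(scenario, ss, params,
                                         older_age, younger_age) {
  eng <- scenario_engine(ss, scenario, params)
  engine_branch_matrix(eng, older_age, younger_age)
}

# Parameter-independent precomputation for a (state space, scenario)
# pair; reused across optimizer evaluations.
scenario_templates <- function(ss, scenario, jump_distance = TRUE) {
  stopifnot(inherits(scenario, "dec_scenario"))
  if (!identical(scenario$areas, ss$areas)) {
    stop("scenario and state space disagree on areas", call. = FALSE)
  }
  lapply(scenario$epochs, function(e) {
    tpl <- epoch_template(ss, e, jump_distance)
    tpl$mask <- allowed_state_mask(ss, e$allowed)
    tpl
  })
}

# Per-parameter-set machinery for one scenario: per-epoch Q, propagator,
# allowed-state mask and cladogenesis table.
scenario_engine <- function(ss, scenario, params, jump_distance = TRUE,
                            templates = NULL) {
  if (is.null(templates)) {
    templates <- scenario_templates(ss, scenario, jump_distance)
  }
  epochs <- scenario$epochs
  Qs <- lapply(templates, fill_Q, params = params)
  props <- lapply(Qs, make_propagator)
  clads <- lapply(templates, fill_clad, params = params)
  list(ss = ss, scenario = scenario, params = params,
       starts = vapply(epochs, function(e) e$start_age, numeric(1)),
       ends = vapply(epochs, function(e) e$end_age, numeric(1)),
       Qs = Qs, props = props,
       masks = lapply(templates, `[[`, "mask"),
       tpls = templates, clads = clads)
}

engine_epoch_at <- function(eng, age) {
  i <- which(age <= eng$starts & age > eng$ends)
  if (length(i) == 0 && age <= 0) i <- length(eng$starts)
  if (length(i) == 0) {
    stop("age ", age, " Ma is outside the scenario", call. = FALSE)
  }
  i[1]
}

engine_branch_matrix <- function(eng, older_age, younger_age) {
  if (older_age < younger_age) {
    stop("older_age must be >= younger_age", call. = FALSE)
  }
  S <- length(eng$ss$bits)
  if (older_age == younger_age) return(diag(S))
  e_old <- engine_epoch_at(eng, older_age)
  e_young <- engine_epoch_at(eng, max(younger_age, 0))
  P <- NULL
  t_hi <- older_age
  for (k in e_old:e_young) {
    t_lo <- max(eng$ends[k], younger_age)
    if (k > e_old) {
      # crossing into epoch k: mask states containing unavailable areas
      P <- P * rep(eng$masks[[k]], each = S)
    }
    if (t_hi > t_lo) {
      Pk <- prop_matrix(eng$props[[k]], t_hi - t_lo)
      P <- if (is.null(P)) Pk else P %*% Pk
    }
    t_hi <- t_lo
  }
  if (is.null(P)) P <- diag(S)
  P
}

# conditional-likelihood vector propagated up a branch:
# w[i] = sum_j P[i, j] f[j], computed segment-wise from the tip end
engine_branch_up <- function(eng, older_age, younger_age, f) {
  if (length(eng$starts) == 1L) {
    return(prop_matvec(eng$props[[1]], older_age - younger_age, f))
  }
  e_old <- engine_epoch_at(eng, older_age)
  e_young <- engine_epoch_at(eng, max(younger_age, 0))
  w <- f
  for (k in e_young:e_old) {
    t_hi <- min(eng$starts[k], older_age)
    t_lo <- max(eng$ends[k], younger_age)
    if (t_hi > t_lo) w <- prop_matvec(eng$props[[k]], t_hi - t_lo, w)
    if (k > e_old) w <- w * eng$masks[[k]]
  }
  w
}

# combine two daughter vectors through the epoch's cladogenesis table;
# rows are contiguous per parent, so per-parent sums are cumsum
# differences over the template's row blocks
engine_combine <- function(eng, age, w_left, w_right) {
  k <- engine_epoch_at(eng, max(age, 0))
  tpl <- eng$tpls[[k]]
  v <- eng$clads[[k]]$prob * w_left[tpl$clad_left] * w_right[tpl$clad_right]
  cs <- cumsum(v)
  out <- numeric(tpl$S)
  out[tpl$blk_parent] <-
    cs[tpl$blk_end] - c(0, cs[tpl$blk_end[-length(tpl$blk_end)]])
  out
}
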