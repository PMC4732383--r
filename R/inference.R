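#' Node ages of a dated tree
#'
#' @param tree An ultrametric `ape::phylo` with branch lengths in Myr.
#' @return Numeric vector of ages (Ma, present = 0) indexed by ape node
#'   number (tips first).
#' @export
node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths) - depths
}

validate_dated_tree <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo'",
                                     call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; a dated tree is required",
         call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  if (length(tree$tip.label) > 1 && max(tabulate(tree$edge[, 1])) > 2) {
    stop("tree must be fully bifurcating", call. = FALSE)
  }
  ages <- node_ages(tree)
  tip_ages <- ages[seq_along(tree$tip.label)]
  if (any(tip_ages > tol)) {
    bad <- tree$tip.label[which.max(tip_ages)]
    stop("tree is not ultrametric (tolerance ", tol, " Myr): tip '", bad,
         "' sits at age ", signif(max(tip_ages), 4), " Ma", call. = FALSE)
  }
  ages[seq_along(tree$tip.label)] <- 0
  ages
}

# normalize tip range input to a tibble(taxon, range) and check coverage
as_tip_ranges <- function(tip_ranges, tree) {
  if (is.character(tip_ranges) && !is.null(names(tip_ranges))) {
    tip_ranges <- tibble::tibble(taxon = names(tip_ranges),
                                 range = unname(tip_ranges))
  }
  if (!is.data.frame(tip_ranges) ||
      !all(c("taxon", "range") %in% names(tip_ranges))) {
    stop("tip_ranges must be a data frame with columns 'taxon' and ",
         "'range', or a named character vector", call. = FALSE)
  }
  missing <- setdiff(tree$tip.label, tip_ranges$taxon)
  if (length(missing)) {
    stop("no range given for tip(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tip_ranges$taxon)) {
    stop("duplicated taxa in tip_ranges", call. = FALSE)
  }
  tibble::as_tibble(tip_ranges[match(tree$tip.label, tip_ranges$taxon),
                               c("taxon", "range")])
}

# topology digest reused across likelihood evaluations
tree_topology <- function(tree) {
  list(n_tip = length(tree$tip.label), n_node = tree$Nnode,
       children = children_list(tree), po_nodes = postorder_nodes(tree))
}

# Felsenstein pruning: conditional likelihood vectors (pre-cladogenesis
# state at each node), with per-node rescaling against underflow.
dec_pruning <- function(eng, tree, tip_state, ages, topo = NULL) {
  if (is.null(topo)) topo <- tree_topology(tree)
  S <- length(eng$ss$bits)
  n_tip <- topo$n_tip
  n_node <- topo$n_node
  f <- vector("list", n_tip + n_node)
  w <- vector("list", n_tip + n_node)  # daughter vector propagated to parent
  for (i in seq_len(n_tip)) {
    v <- numeric(S)
    v[tip_state[i]] <- 1
    f[[i]] <- v
  }
  children <- topo$children
  logscale <- 0
  for (n in topo$po_nodes) {
    ch <- children[[n]]
    for (c_ in ch) {
      w[[c_]] <- engine_branch_up(eng, ages[n], ages[c_], f[[c_]])
    }
    v <- engine_combine(eng, ages[n], w[[ch[1]]], w[[ch[2]]])
    s <- max(v)
    if (s <= 0 || !is.finite(s)) {
      return(list(f = f, w = w, logscale = -Inf, failed = TRUE))
    }
    f[[n]] <- v / s
    logscale <- logscale + log(s)
  }
  list(f = f, w = w, logscale = logscale, failed = FALSE)
}

children_list <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[i, 2])
  }
  ch
}

postorder_nodes <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  unique(po$edge[, 1])
}

root_prior_states <- function(eng, root_age) {
  k <- engine_epoch_at(eng, root_age)
  which(eng$masks[[k]] & eng$ss$size > 0L)
}

#' Log-likelihood of tip ranges under a DEC-family model
#'
#' Felsenstein pruning over the dated tree: tip conditional likelihoods are
#' indicator vectors over the range state space; daughter vectors are
#' carried up each branch by (epoch-spanning) transition matrices and
#' combined at nodes through the cladogenesis table of the epoch the node
#' falls in.  The root likelihood averages over all states available at
#' the root age (uniform root prior over non-null allowed states).
#'
#' @param tree Dated ultrametric `ape::phylo` (branch lengths in Myr).
#' @param tip_ranges Data frame with columns `taxon`, `range` (range
#'   labels such as `"Bali"` or `"Bali+Lombok"`), or a named character
#'   vector.
#' @param ss A [state_space()] (with null).
#' @param scenario A [dec_scenario()].
#' @param params A [dec_params()].
#' @param model A [dec_model()]; controls whether jump weights carry the
#'   distance modifier.
#' @return The natural-log likelihood (scalar).
#' @export
tree_likelihood <- function(tree, tip_ranges, ss, scenario, params,
                            model = dec_model("DEC+J+x")) {
  ages <- validate_dated_tree(tree)
  tr <- as_tip_ranges(tip_ranges, tree)
  tip_state <- range_index(ss, tr$range)
  eng <- scenario_engine(ss, scenario, params,
                         jump_distance = model$jump_distance)
  check_tip_availability(eng, tip_state)
  dec_loglik(eng, tree, tip_state, ages)
}

check_tip_availability <- function(eng, tip_state) {
  mask0 <- eng$masks[[length(eng$masks)]]
  if (any(!mask0[tip_state])) {
    stop("tip range(s) contain areas unavailable at the present: ",
         paste(unique(eng$ss$label[tip_state[!mask0[tip_state]]]),
               collapse = ", "), call. = FALSE)
  }
}

dec_loglik <- function(eng, tree, tip_state, ages, topo = NULL) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  if (n_tip == 1) {
    # degenerate single-branch "tree": propagate the lone tip to the root
    rs <- root_prior_states(eng, ages[root])
    wv <- engine_branch_up(eng, ages[root], 0, {
      v <- numeric(length(eng$ss$bits)); v[tip_state[1]] <- 1; v
    })
    return(log(mean(wv[rs])))
  }
  pr <- dec_pruning(eng, tree, tip_state, ages, topo)
  if (pr$failed) return(-Inf)
  rs <- root_prior_states(eng, ages[root])
  lik <- mean(pr$f[[root]][rs])
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logscale
}

#' Default multi-start grid for DEC fits
#'
#' DEC likelihood surfaces (especially with `+J`) can be multi-modal, so
#' optimization is restarted from a small deterministic grid:
#' `(d, e)` in `{(0.01, 0.01), (0.1, 0.01), (0.01, 0.1)}`, crossed with
#' starts for the extra parameters: `j` in `{1e-9, 0.01, 0.5}` (DEC+J;
#' the near-zero start guarantees the nested DEC optimum is reachable),
#' `x` in `{0, -1}` (DEC+x), and paired `(j, x)` in `{(1e-9, 0),
#' (0.01, 0), (0.5, -1)}` for DEC+J+x — boundary, weak-effect and
#' strong-effect corners, which cover the modes the full cross finds at
#' half the cost.
#'
#' @param model A [dec_model()].
#' @return A data frame of starting values, one row per start.
#' @export
default_starts <- function(model) {
  de <- data.frame(d = c(0.01, 0.1, 0.01), e = c(0.01, 0.01, 0.1))
  # models with free j also start at the j ~ 0 boundary so the nested
  # DEC optimum is always reachable
  extra <- if (all(c("j", "x") %in% model$free)) {
    data.frame(j = c(1e-9, 0.01, 0.5), x = c(0, 0, -1))
  } else if ("j" %in% model$free) {
    data.frame(j = c(1e-9, 0.01, 0.5), x = 0)
  } else if ("x" %in% model$free) {
    data.frame(j = 0, x = c(0, -1))
  } else {
    data.frame(j = 0, x = 0)
  }
  g <- merge(de, extra)
  g[order(g$d, g$e, g$j, g$x), c("d", "e", "j", "x")]
}

#' Parameter bounds for DEC fits
#'
#' @return A list of `c(lower, upper)` bounds per parameter: `d`, `e` in
#'   `[1e-12, 5]` events/Myr, `j` in `[0, 3]`, `x` in `[-10, 2]`.
#' @export
dec_bounds <- function() {
  list(d = c(1e-12, 5), e = c(1e-12, 5), j = c(0, 3), x = c(-10, 2))
}

#' Maximum-likelihood fit of a DEC-family model
#'
#' Maximizes [tree_likelihood()] with bounded quasi-Newton (`L-BFGS-B`)
#' search from a deterministic multi-start grid.  `d`, `e` and `j` are
#' optimized on the log scale, `x` on the linear scale.  The fit is fully
#' deterministic (no randomness is used).
#'
#' @inheritParams tree_likelihood
#' @param model A [dec_model()] naming the free parameters.
#' @param starts Data frame of starting values (columns `d`, `e`, `j`,
#'   `x`); defaults to [default_starts()].
#' @param bounds Parameter bounds, see [dec_bounds()].
#' @param control Passed to [stats::optim()] (`factr`, `maxit`).
#' @return An object of class `dec_fit` with the estimates, `lnL`, `k`,
#'   convergence flag, evaluation count, and the data needed for
#'   [ancestral_marginals()].
#' @export
fit_dec <- function(tree, tip_ranges, ss, scenario,
                    model = dec_model("DEC"), starts = default_starts(model),
                    bounds = dec_bounds(),
                    control = list(factr = 1e8, maxit = 200)) {
  ages <- validate_dated_tree(tree)
  tr <- as_tip_ranges(tip_ranges, tree)
  tip_state <- range_index(ss, tr$range)
  free <- model$free
  log_scaled <- c(d = TRUE, e = TRUE, j = TRUE, x = FALSE)
  lo_raw <- vapply(bounds, `[`, numeric(1), 1)[free]
  hi_raw <- vapply(bounds, `[`, numeric(1), 2)[free]
  # j = 0 is the nested boundary; on the log scale use a floor that is
  # numerically indistinguishable from 0
  lo_raw[free == "j"] <- pmax(lo_raw[free == "j"], 1e-9)
  to_theta <- function(p) {
    vapply(seq_along(free), function(i) {
      if (log_scaled[free[i]]) log(max(p[[free[i]]], lo_raw[i]))
      else p[[free[i]]]
    }, numeric(1))
  }
  from_theta <- function(th) {
    p <- list(d = 0, e = 0, j = 0, x = 0)
    for (i in seq_along(free)) {
      p[[free[i]]] <- if (log_scaled[free[i]]) exp(th[i]) else th[i]
    }
    p
  }
  templates <- scenario_templates(ss, scenario, model$jump_distance)
  topo <- tree_topology(tree)
  n_eval <- 0L
  nll <- function(th) {
    n_eval <<- n_eval + 1L
    p <- from_theta(th)
    prm <- dec_params(p$d, p$e, p$j, p$x)
    eng <- scenario_engine(ss, scenario, prm, templates = templates)
    ll <- tryCatch(dec_loglik(eng, tree, tip_state, ages, topo),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  lower <- mapply(function(p, v) if (log_scaled[p]) log(v) else v,
                  free, lo_raw)
  upper <- mapply(function(p, v) if (log_scaled[p]) log(v) else v,
                  free, hi_raw)
  best <- NULL
  any_conv <- FALSE
  for (r in seq_len(nrow(starts))) {
    th0 <- to_theta(unlist(starts[r, c("d", "e", "j", "x")]))
    res <- tryCatch(
      stats::optim(th0, nll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = control),
      error = function(e) NULL
    )
    if (is.null(res)) next
    any_conv <- any_conv || res$convergence == 0
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("all optimizer starts failed", call. = FALSE)
  }
  p <- from_theta(best$par)
  structure(
    list(model = model, params = dec_params(p$d, p$e, p$j, p$x),
         k = model$k, lnL = -best$value, converged = any_conv,
         n_eval = n_eval, n_tips = length(tree$tip.label),
         tree = tree, tip_ranges = tr, ss = ss, scenario = scenario),
    class = "dec_fit"
  )
}

#' @export
print.dec_fit <- function(x, ...) {
  cat("DEC-family fit: ", x$model$type, "\n", sep = "")
  est <- unlist(x$params[x$model$free])
  cat("  ", paste(sprintf("%s = %.6g", names(est), est), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  lnL = %.6f  (k = %d, n_tips = %d, %s, %d evaluations)\n",
              x$lnL, x$k, x$n_tips,
              if (x$converged) "converged" else "NOT converged", x$n_eval))
  invisible(x)
}

#' Ancestral-range marginal probabilities
#'
#' Marginal probabilities of each range state at each internal node (the
#' node pie charts of range-evolution figures), computed with the up-down
#' algorithm: the tipward conditional likelihoods from pruning are
#' multiplied by rootward partial likelihoods propagated from the uniform
#' root prior, and normalized per node.  Probabilities refer to the state
#' *at* the node, immediately before cladogenesis.
#'
#' @param fit A [fit_dec()] result, or supply `tree`, `tip_ranges`, `ss`,
#'   `scenario`, `params`, `model` explicitly.
#' @param ... Unused.
#' @return A tibble with columns `node` (ape node number), `state` (range
#'   label) and `prob`, covering all non-null states with positive
#'   probability; probabilities sum to 1 per node.
#' @export
ancestral_marginals <- function(fit, ...) {
  UseMethod("ancestral_marginals")
}

#' @rdname ancestral_marginals
#' @export
ancestral_marginals.dec_fit <- function(fit, ...) {
  ancestral_marginals_impl(fit$tree, fit$tip_ranges, fit$ss, fit$scenario,
                           fit$params, fit$model)
}

#' @rdname ancestral_marginals
#' @param tree,tip_ranges,ss,scenario,params,model As in
#'   [tree_likelihood()].
#' @export
ancestral_marginals.phylo <- function(fit, tip_ranges, ss, scenario, params,
                                      model = dec_model("DEC+J+x"), ...) {
  ancestral_marginals_impl(fit, tip_ranges, ss, scenario, params, model)
}

ancestral_marginals_impl <- function(tree, tip_ranges, ss, scenario, params,
                                     model) {
  ages <- validate_dated_tree(tree)
  tr <- as_tip_ranges(tip_ranges, tree)
  tip_state <- range_index(ss, tr$range)
  eng <- scenario_engine(ss, scenario, params,
                         jump_distance = model$jump_distance)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  S <- length(ss$bits)
  pr <- dec_pruning(eng, tree, tip_state, ages)
  if (pr$failed) stop("likelihood underflow: marginals undefined",
                      call. = FALSE)
  children <- children_list(tree)
  up <- vector("list", n_tip + tree$Nnode)
  g <- numeric(S)
  g[root_prior_states(eng, ages[root])] <- 1
  up[[root]] <- g / sum(g)
  for (n in rev(postorder_nodes(tree))) {  # preorder over internal nodes
    ch <- children[[n]]
    ct <- eng$clads[[engine_epoch_at(eng, max(ages[n], 0))]]
    contrib <- up[[n]][ct$parent] * ct$prob
    for (side in 1:2) {
      c_ <- ch[side]
      sib <- ch[3 - side]
      own_state <- if (side == 1) ct$left else ct$right
      sib_state <- if (side == 1) ct$right else ct$left
      v <- contrib * pr$w[[sib]][sib_state]
      edge_top <- numeric(S)
      agg <- rowsum(v, own_state)
      edge_top[as.integer(rownames(agg))] <- agg[, 1]
      P <- engine_branch_matrix(eng, ages[n], ages[c_])
      u <- as.vector(crossprod(P, edge_top))
      tot <- sum(u)
      up[[c_]] <- if (tot > 0) u / tot else u
    }
  }
  out <- lapply((n_tip + 1L):(n_tip + tree$Nnode), function(n) {
    m <- up[[n]] * pr$f[[n]]
    m[ss$size == 0L] <- 0
    m <- m / sum(m)
    keep <- which(m > 0)
    tibble::tibble(node = n, state = ss$label[keep], prob = m[keep])
  })
  dplyr::bind_rows(out)
}
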