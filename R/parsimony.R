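#' Maximum-parsimony ancestral-area reconstruction
#'
#' An assumption-free counterpart to the model-based estimates: areas are
#' treated as an unordered multistate character with uniform unit costs,
#' and ancestral states are reconstructed by Fitch/Sankoff parsimony on
#' the (undated) topology.  Every tip must occupy exactly one area
#' (microendemics).  The Sankoff dynamic program is used throughout so the
#' machinery extends to arbitrary cost matrices, and the up-pass yields
#' for each internal node the full set of states occurring in at least one
#' most-parsimonious reconstruction (MPR).
#'
#' @param tree An `ape::phylo` (binary; branch lengths not used).
#' @param tip_areas Named character vector (names = tip labels) or a data
#'   frame with columns `taxon` and `area`, giving one area per tip.
#' @param cost Optional square cost matrix (dimnames = area names);
#'   defaults to uniform unit costs.
#' @return An object of class `parsimony_asr`: list with `tree`, `areas`,
#'   `tip_area` (indices), `mpr` (list of per-node MPR area sets),
#'   `score` (minimal number of area changes) and the internal cost
#'   tables used for resolution.
#' @examples
#' tr <- ape::read.tree(text = "((t1,t2),(t3,t4));")
#' fitch_asr(tr, c(t1 = "a", t2 = "a", t3 = "b", t4 = "b"))
#' @export
fitch_asr <- function(tree, tip_areas, cost = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo'",
                                     call. = FALSE)
  if (max(tabulate(tree$edge[, 1])) > 2) {
    stop("polytomies are not supported; resolve the tree first (e.g. ",
         "ape::multi2di) before reconstruction", call. = FALSE)
  }
  if (is.data.frame(tip_areas)) {
    stopifnot(all(c("taxon", "area") %in% names(tip_areas)))
    tip_areas <- stats::setNames(as.character(tip_areas$area),
                                 tip_areas$taxon)
  }
  missing <- setdiff(tree$tip.label, names(tip_areas))
  if (length(missing)) {
    stop("no area given for tip(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tip_areas <- tip_areas[tree$tip.label]
  areas <- if (!is.null(cost)) rownames(cost) else sort(unique(tip_areas))
  if (!all(tip_areas %in% areas)) {
    stop("tip areas outside the cost matrix: ",
         paste(setdiff(tip_areas, areas), collapse = ", "), call. = FALSE)
  }
  A <- length(areas)
  if (is.null(cost)) {
    cost <- matrix(1, A, A, dimnames = list(areas, areas))
    diag(cost) <- 0
  }
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  tip_idx <- match(tip_areas, areas)
  down <- matrix(Inf, n_all, A)  # tipward (subtree) cost per node state
  down[cbind(seq_len(n_tip), tip_idx)] <- 0
  children <- children_list(tree)
  po <- postorder_nodes(tree)
  for (n in po) {
    acc <- numeric(A)
    for (c_ in children[[n]]) {
      # min over child state of (cost of change + child subtree cost)
      acc <- acc + apply(cost + rep(down[c_, ], each = A), 1, min)
    }
    down[n, ] <- acc
  }
  root <- n_tip + 1L
  score <- min(down[root, ])
  up <- matrix(Inf, n_all, A)  # rootward cost per node state
  up[root, ] <- 0
  for (n in rev(po)) {
    ch <- children[[n]]
    for (side in seq_along(ch)) {
      c_ <- ch[side]
      sib_cost <- numeric(A)
      for (s_ in ch[-side]) {
        sib_cost <- sib_cost + apply(cost + rep(down[s_, ], each = A), 1,
                                     min)
      }
      # up[c_, s] = min_p [ up[n, p] + sib(p) + cost(p, s) ]
      through <- up[n, ] + sib_cost
      up[c_, ] <- apply(cost + rep(through, times = A), 2, min)
    }
  }
  mpr <- lapply(seq_len(n_all), function(n) {
    if (n <= n_tip) return(areas[tip_idx[n]])
    areas[which(down[n, ] + up[n, ] <= score + 1e-9)]
  })
  structure(
    list(tree = tree, areas = areas, tip_area = tip_idx, cost = cost,
         down = down, up = up, mpr = mpr, score = score),
    class = "parsimony_asr"
  )
}

#' @export
print.parsimony_asr <- function(x, ...) {
  cat("Parsimony ancestral-area reconstruction\n")
  cat("  ", length(x$tree$tip.label), " tips, ", length(x$areas),
      " areas, minimal changes = ", x$score, "\n", sep = "")
  amb <- sum(lengths(x$mpr[-seq_along(x$tree$tip.label)]) > 1)
  cat("  ", amb, " internal node(s) with ambiguous MPR state\n", sep = "")
  invisible(x)
}

#' Resolve an MPR to one area per node
#'
#' Walks the tree from the root, choosing at each node a state that still
#' attains the minimal change count given the parent's resolved state.
#' Under `"deltran"` ties are broken in favour of the parent's state
#' (changes are delayed toward the tips); under `"acctran"` in favour of a
#' change (changes are accelerated toward the root).  Remaining ties go to
#' the lowest area index.  Both rules produce most-parsimonious
#' reconstructions, so their total change counts are identical.
#'
#' @param asr A [fitch_asr()] result.
#' @param resolution `"deltran"` (default) or `"acctran"`.
#' @return Character vector of areas indexed by ape node number.
#' @export
resolve_asr <- function(asr, resolution = c("deltran", "acctran")) {
  resolution <- match.arg(resolution)
  tree <- asr$tree
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  A <- length(asr$areas)
  state <- integer(n_tip + tree$Nnode)
  state[seq_len(n_tip)] <- asr$tip_area
  state[root] <- which.min(asr$down[root, ])
  children <- children_list(tree)
  for (n in rev(postorder_nodes(tree))) {
    p <- state[n]
    for (c_ in children[[n]]) {
      if (c_ <= n_tip) next
      val <- asr$cost[p, ] + asr$down[c_, ]
      cand <- which(val <= min(val) + 1e-9)
      state[c_] <- if (resolution == "deltran") {
        if (p %in% cand) p else cand[1]
      } else {
        if (length(cand) > 1 && p %in% cand) setdiff(cand, p)[1] else cand[1]
      }
    }
  }
  stats::setNames(asr$areas[state],
                  c(tree$tip.label, rep("", tree$Nnode)))
}

#' Count inferred dispersal events
#'
#' Resolves the reconstruction to one area per node and counts ordered
#' parent-to-child area changes.  Because every resolution is itself an
#' MPR, the total equals the parsimony minimum (`min_changes`), matching
#' the "at least N events" reading of parsimony event counts; the
#' per-pair split, however, depends on the resolution rule.
#'
#' @param asr A [fitch_asr()] result.
#' @param resolution `"deltran"` (default) or `"acctran"`.
#' @param area_order Optional character vector giving the areas in
#'   geographic order (e.g. east to west along an arc); defaults to the
#'   reconstruction's area set.  Used only for the directionality tally.
#' @return A list of class `dispersal_summary`: `counts` (from×to
#'   matrix), `events` (tibble with `parent`, `child`, `from`, `to`),
#'   `directionality` (events toward lower versus higher positions in
#'   `area_order`), `total`, `min_changes` and the resolution used.
#' @export
count_dispersal_events <- function(asr,
                                   resolution = c("deltran", "acctran"),
                                   area_order = NULL) {
  resolution <- match.arg(resolution)
  if (is.null(area_order)) area_order <- asr$areas
  if (!all(asr$areas %in% area_order)) {
    stop("area_order must contain every reconstructed area",
         call. = FALSE)
  }
  states <- resolve_asr(asr, resolution)
  tree <- asr$tree
  A <- length(asr$areas)
  counts <- matrix(0L, A, A, dimnames = list(asr$areas, asr$areas))
  from <- states[tree$edge[, 1]]
  to <- states[tree$edge[, 2]]
  changed <- from != to
  if (any(changed)) {
    tab <- table(factor(from[changed], levels = asr$areas),
                 factor(to[changed], levels = asr$areas))
    counts <- counts + unclass(tab)
  }
  events <- tibble::tibble(parent = tree$edge[changed, 1],
                           child = tree$edge[changed, 2],
                           from = unname(from[changed]),
                           to = unname(to[changed]))
  step <- match(events$to, area_order) - match(events$from, area_order)
  directionality <- tibble::tibble(
    direction = c("toward_first_area", "toward_last_area"),
    events = c(sum(step < 0), sum(step > 0))
  )
  structure(list(counts = counts, events = events,
                 directionality = directionality,
                 total = sum(changed), min_changes = asr$score,
                 resolution = resolution),
            class = "dispersal_summary")
}

#' @export
print.dispersal_summary <- function(x, ...) {
  cat("Dispersal events (", x$resolution, " resolution): ", x$total,
      " changes (parsimony minimum ", x$min_changes, ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Per-area lineage accumulation through time
#'
#' Counts, at each bin boundary from the present back to the root, the
#' number of lineages reconstructed in each area (the per-area
#' lineage-through-time curves).  A branch whose parent and child areas
#' differ is assigned the ancestral area on its older half and the
#' descendant area on its younger half (change placed at the branch
#' midpoint).
#'
#' @param tree Dated ultrametric `ape::phylo`.
#' @param node_areas Character vector of single areas indexed by ape node
#'   number (tips then internal nodes), e.g. from [resolve_asr()].
#' @param bin_width Bin width in Myr (default 2).
#' @return A tibble with columns `age` (Ma), `area` and `lineages`.
#' @export
lineage_accumulation <- function(tree, node_areas, bin_width = 2) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  n_all <- length(tree$tip.label) + tree$Nnode
  if (length(node_areas) != n_all || anyNA(node_areas)) {
    stop("node_areas must assign one area to every node; resolve the ",
         "reconstruction first (see resolve_asr)", call. = FALSE)
  }
  ages <- node_ages(tree)
  root_age <- max(ages)
  times <- seq(0, by = bin_width,
               length.out = floor(root_age / bin_width + 1e-9) + 1)
  areas <- sort(unique(node_areas))
  p_age <- ages[tree$edge[, 1]]
  c_age <- ages[tree$edge[, 2]]
  p_area <- node_areas[tree$edge[, 1]]
  c_area <- node_areas[tree$edge[, 2]]
  mid <- (p_age + c_age) / 2
  out <- lapply(times, function(t) {
    crossing <- p_age > t & c_age <= t
    area_at_t <- ifelse(t >= mid, p_area, c_area)[crossing]
    tibble::tibble(age = t, area = areas,
                   lineages = as.integer(table(
                     factor(area_at_t, levels = areas))))
  })
  dplyr::bind_rows(out)
}
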