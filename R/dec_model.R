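#' DEC-family model specification
#'
#' The family has four members. `DEC` estimates the anagenetic
#' range-expansion rate `d` and range-contraction rate `e` (both per area,
#' events/Myr).  `+J` adds founder-event (jump) cladogenesis with a free
#' dimensionless weight `j`; `+x` adds distance dependence, multiplying
#' every dispersal rate by `distance^x` with a free exponent `x`
#' (typically negative).  The cladogenetic weights for sympatry, subset
#' sympatry and vicariance are fixed at 1, so the four models carry 2, 3,
#' 3 and 4 free parameters.
#'
#' @param type One of `"DEC"`, `"DEC+J"`, `"DEC+x"`, `"DEC+J+x"`.
#' @param jump_distance Should the `distance^x` modifier also scale the
#'   cladogenetic jump weights (the convention of the reference software),
#'   or only anagenetic dispersal?
#' @return An object of class `dec_model`: list with `type`, `free`
#'   (character vector of free parameters), `k`, and `jump_distance`.
#' @examples
#' dec_model("DEC+J+x")$k
#' @export
dec_model <- function(type = c("DEC", "DEC+J", "DEC+x", "DEC+J+x"),
                      jump_distance = TRUE) {
  type <- match.arg(type)
  free <- c("d", "e",
            if (grepl("+J", type, fixed = TRUE)) "j",
            if (grepl("+x", type, fixed = TRUE)) "x")
  structure(list(type = type, free = free, k = length(free),
                 jump_distance = jump_distance),
            class = "dec_model")
}

#' @export
print.dec_model <- function(x, ...) {
  cat("DEC-family model ", x$type, ": free parameters ",
      paste(x$free, collapse = ", "), " (k = ", x$k, ")\n", sep = "")
  invisible(x)
}

#' DEC parameter set
#'
#' @param d,e Anagenetic expansion / contraction rates (events/Myr),
#'   non-negative.
#' @param j Founder-event weight (dimensionless, `>= 0`; 0 disables jumps).
#' @param x Distance exponent (dimensionless; 0 disables distance effects).
#' @return A named list of class `dec_params`.
#' @export
dec_params <- function(d, e, j = 0, x = 0) {
  if (d < 0 || e < 0 || j < 0) {
    stop("d, e and j must be non-negative", call. = FALSE)
  }
  structure(list(d = d, e = e, j = j, x = x), class = "dec_params")
}

# pairwise dispersal modifier matrix: multiplier * distance^x, zeroed into
# unavailable areas (columns)
dispersal_modifiers <- function(geo, x, use_distance = TRUE) {
  m <- geo$multiplier
  if (use_distance && x != 0) {
    dist_pow <- geo$distance
    nz <- dist_pow > 0
    dist_pow[nz] <- dist_pow[nz]^x
    m <- m * dist_pow
  }
  blocked <- setdiff(geo$areas, geo$allowed)
  if (length(blocked)) m[, blocked] <- 0
  diag(m) <- 0
  m
}

#' Anagenetic dispersal rate between two areas
#'
#' `d * multiplier[from, to] * distance[from, to]^x`; with `x = 0` the
#' distance drops out.  A target area unavailable in the epoch yields rate
#' 0 (not an error).  The 9999 km sentinel combined with a negative `x`
#' gives a tiny but non-zero rate — dispersal "possible but unlikely".
#'
#' @param from_area,to_area Area names.
#' @param params A [dec_params()].
#' @param geo A [epoch_geography()].
#' @return Numeric rate (events/Myr).
#' @examples
#' geo <- epoch_geography(matrix(c(0, 100, 100, 0), 2, 2,
#'   dimnames = list(c("A", "B"), c("A", "B"))))
#' dispersal_rate("A", "B", dec_params(d = 0.1, e = 0), geo)
#' @export
dispersal_rate <- function(from_area, to_area, params, geo) {
  stopifnot(from_area %in% geo$areas, to_area %in% geo$areas,
            from_area != to_area)
  mod <- dispersal_modifiers(geo, params$x)
  params$d * mod[from_area, to_area]
}

#' Anagenetic rate matrix over the range state space
#'
#' Builds the dense S×S generator `Q` of the range CTMC for one epoch.
#' Range expansion adds one area `b` to range `R` at rate
#' `d * sum_{a in R} multiplier[a,b] * distance[a,b]^x` (only while
#' `|R| < max_range_size` and `b` is available); range contraction removes
#' one area at rate `e` per area, a singleton contracting to the null
#' (absorbing) range.  Rows sum to zero; the null row is zero.
#'
#' @param ss A [state_space()] built with `include_null = TRUE`.
#' @param params A [dec_params()].
#' @param geo A [epoch_geography()] with the same areas.
#' @param use_distance Apply the `distance^x` modifier (on by default; the
#'   exponent itself lives in `params$x`).
#' @return Dense numeric S×S matrix with state labels as dimnames.
#' @export
build_Q <- function(ss, params, geo, use_distance = TRUE) {
  stopifnot(inherits(ss, "dec_state_space"), inherits(geo, "dec_epoch"))
  if (!ss$include_null) {
    stop("build_Q needs the state space built with include_null = TRUE",
         call. = FALSE)
  }
  if (!identical(geo$areas, ss$areas)) {
    stop("epoch geography and state space disagree on areas", call. = FALSE)
  }
  S <- length(ss$bits)
  A <- ss$n_areas
  mod <- dispersal_modifiers(geo, params$x, use_distance)
  Q <- matrix(0, S, S, dimnames = list(ss$label, ss$label))
  for (i in seq_len(S)) {
    b <- ss$bits[i]
    if (b == 0L) next
    members <- bit_members(b)
    # contraction: drop one area (null target allowed)
    if (params$e > 0) {
      for (a in members) {
        tgt <- ss$.lookup[bitwAnd(b, bitwNot(as.integer(2^(a - 1)))) + 1L]
        Q[i, tgt] <- Q[i, tgt] + params$e
      }
    }
    # expansion: add one area
    if (params$d > 0 && length(members) < ss$max_range_size) {
      for (a2 in setdiff(seq_len(A), members)) {
        rate <- params$d * sum(mod[members, a2])
        if (rate > 0) {
          tgt <- ss$.lookup[b + as.integer(2^(a2 - 1)) + 1L]
          Q[i, tgt] <- Q[i, tgt] + rate
        }
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Cladogenesis event table
#'
#' Enumerates the possible daughter-range pairs at a speciation node for
#' every parent range, with normalized probabilities.  For a singleton
#' parent `{a}`: sympatric copying (weight 1) and, with `j > 0`, a founder
#' jump to each available outside area `b` with weight
#' `j * multiplier[a,b] * distance[a,b]^x`.  For a widespread parent `R`:
#' subset sympatry (one daughter a member singleton, the other `R`;
#' weight 1 per member) and narrow vicariance (a member singleton versus
#' the remainder; weight 1 per member), plus jumps with weight `j` times
#' the mean modifier from the members of `R` to the target.  Each
#' unordered outcome is split equally between left/right daughter
#' assignments, and weights are normalized per parent.
#'
#' @inheritParams build_Q
#' @param jump_distance Scale jump weights by `distance^x`?
#' @return A list of class `dec_clad_table` with integer vectors `parent`,
#'   `left`, `right` (state indices), numeric `prob`, and character `type`
#'   (`"sympatry"`, `"subset"`, `"vicariance"`, `"jump"`).
#' @export
cladogenesis_table <- function(ss, params, geo, jump_distance = TRUE) {
  stopifnot(inherits(ss, "dec_state_space"), inherits(geo, "dec_epoch"))
  mod_j <- dispersal_modifiers(geo, params$x, use_distance = jump_distance)
  A <- ss$n_areas
  allowed_idx <- match(geo$allowed, ss$areas)
  parent <- left <- right <- integer(0)
  prob <- numeric(0)
  type <- character(0)
  for (i in seq_along(ss$bits)) {
    b <- ss$bits[i]
    if (b == 0L) next
    members <- bit_members(b)
    k <- length(members)
    ev_l <- ev_r <- integer(0)
    ev_w <- numeric(0)
    ev_t <- character(0)
    add <- function(l, r, w, t) {
      if (l == r) {
        ev_l <<- c(ev_l, l); ev_r <<- c(ev_r, r)
        ev_w <<- c(ev_w, w); ev_t <<- c(ev_t, t)
      } else {
        ev_l <<- c(ev_l, l, r); ev_r <<- c(ev_r, r, l)
        ev_w <<- c(ev_w, w / 2, w / 2); ev_t <<- c(ev_t, t, t)
      }
    }
    singleton <- function(a) ss$.lookup[as.integer(2^(a - 1)) + 1L]
    if (k == 1) {
      add(i, i, 1, "sympatry")
    } else {
      for (a in members) {
        add(singleton(a), i, 1, "subset")
        rem <- ss$.lookup[bitwAnd(b, bitwNot(as.integer(2^(a - 1)))) + 1L]
        add(singleton(a), rem, 1, "vicariance")
      }
    }
    if (params$j > 0) {
      for (a2 in intersect(setdiff(seq_len(A), members), allowed_idx)) {
        w <- params$j * mean(mod_j[members, a2])
        if (w > 0) add(i, singleton(a2), w, "jump")
      }
    }
    tot <- sum(ev_w)
    parent <- c(parent, rep.int(i, length(ev_w)))
    left <- c(left, ev_l)
    right <- c(right, ev_r)
    prob <- c(prob, ev_w / tot)
    type <- c(type, ev_t)
  }
  structure(list(parent = parent, left = left, right = right,
                 prob = prob, type = type, n_states = length(ss$bits)),
            class = "dec_clad_table")
}

#' @export
print.dec_clad_table <- function(x, ...) {
  cat("Cladogenesis table:", length(x$prob), "ordered daughter-pair rows,",
      length(unique(x$parent)), "parent states\n")
  invisible(x)
}

#' Tidy a cladogenesis table
#'
#' @param x A `dec_clad_table`.
#' @param ss The [state_space()] it was built from (for labels).
#' @param ... Unused.
#' @return A tibble with columns `parent`, `left`, `right`, `type`, `prob`.
#' @export
tidy.dec_clad_table <- function(x, ss = NULL, ...) {
  lab <- function(i) if (is.null(ss)) i else ss$label[i]
  tibble::tibble(parent = lab(x$parent), left = lab(x$left),
                 right = lab(x$right), type = x$type, prob = x$prob)
}
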