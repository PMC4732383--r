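#' Build a constrained geographic-range state space
#'
#' A geographic range is a non-empty subset of discrete areas; the CTMC that
#' describes anagenetic range evolution runs over all subsets of at most
#' `max_range_size` areas.  Ranges are stored as fixed-width bit patterns
#' (area `i` maps to bit `i - 1`), so the space is cheap to index and its
#' ordering is fully deterministic: the null range first (when included),
#' then by range size, then by the index tuple of member areas in the order
#' produced by [utils::combn()].
#'
#' The null (empty) range is an internal absorbing state: a singleton range
#' reaches it at the local-extinction rate `e`.  It is never valid as tip
#' data and is excluded from the conventional state count — 12 areas with a
#' maximum range size of 3 give `choose(12,1) + choose(12,2) + choose(12,3)
#' = 298` non-null states.
#'
#' @param areas Character vector of unique area names, at most 14.
#' @param max_range_size Largest number of areas a single range may span.
#' @param include_null Prepend the empty range as an absorbing state?
#'   Required for likelihood work; drop it only for counting/enumeration.
#'
#' @return An object of class `dec_state_space`: a list with elements
#'   `areas`, `n_areas`, `max_range_size`, `include_null`, `bits` (integer
#'   bit patterns, one per state), `size` (number of areas per state) and
#'   `label` (human-readable `"A+B"` labels; the null range is `"_"`).
#' @examples
#' ss <- state_space(c("Bali", "Lombok", "Sumbawa"), max_range_size = 2)
#' ss$label
#' @export
state_space <- function(areas, max_range_size = length(areas),
                        include_null = TRUE) {
  areas <- as.character(areas)
  if (anyDuplicated(areas)) {
    stop("area names must be unique", call. = FALSE)
  }
  n <- length(areas)
  if (n < 1 || n > 14) {
    stop("between 1 and 14 areas are supported, got ", n, call. = FALSE)
  }
  if (max_range_size < 1 || max_range_size > n) {
    stop("'max_range_size' must lie in [1, ", n, "], got ", max_range_size,
         call. = FALSE)
  }
  bits <- integer(0)
  for (k in seq_len(max_range_size)) {
    combos <- utils::combn(n, k)
    bits <- c(bits, as.integer(colSums(matrix(2^(combos - 1), nrow = k))))
  }
  if (include_null) bits <- c(0L, bits)
  size <- vapply(bits, bit_count, integer(1))
  label <- vapply(bits, function(b) range_label(b, areas), character(1))
  lookup <- rep(NA_integer_, 2^n)
  lookup[bits + 1L] <- seq_along(bits)
  structure(
    list(areas = areas, n_areas = n, max_range_size = max_range_size,
         include_null = include_null, bits = bits, size = size,
         label = label, .lookup = lookup),
    class = "dec_state_space"
  )
}

#' @export
print.dec_state_space <- function(x, ...) {
  cat("Range state space: ", x$n_areas, " areas, max range size ",
      x$max_range_size, "\n", sep = "")
  cat("  ", sum(x$size > 0), " non-null states",
      if (x$include_null) " (+ null)", "\n", sep = "")
  cat("  areas: ", paste(x$areas, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of states in a state space
#'
#' @param ss A `dec_state_space`.
#' @param include_null Count the null range if present?
#' @return Integer number of states.
#' @export
n_states <- function(ss, include_null = FALSE) {
  stopifnot(inherits(ss, "dec_state_space"))
  if (include_null) length(ss$bits) else sum(ss$size > 0L)
}

bit_count <- function(b) {
  n <- 0L
  while (b > 0L) {
    n <- n + bitwAnd(b, 1L)
    b <- bitwShiftR(b, 1L)
  }
  n
}

bit_members <- function(b) which(bitwAnd(b, 2^(0:13)) > 0)

range_label <- function(bits, areas) {
  if (bits == 0L) return("_")
  paste(areas[bit_members(bits)], collapse = "+")
}

#' Convert range labels to state indices
#'
#' Labels are `"+"`-separated area names (e.g. `"Bali+Lombok"`); the null
#' range is written `"_"`.  Unknown areas or ranges outside the state space
#' (too many areas) are hard errors: observed data must live in the space
#' the model is defined over.
#'
#' @param ss A `dec_state_space`.
#' @param labels Character vector of range labels.
#' @return Integer state indices into `ss`.
#' @export
range_index <- function(ss, labels) {
  stopifnot(inherits(ss, "dec_state_space"))
  vapply(labels, function(lab) {
    if (identical(lab, "_")) {
      if (!ss$include_null) stop("null range is not in this state space",
                                 call. = FALSE)
      return(match(0L, ss$bits))
    }
    parts <- strsplit(lab, "+", fixed = TRUE)[[1]]
    idx <- match(parts, ss$areas)
    if (anyNA(idx)) {
      stop("unknown area(s) in range '", lab, "': ",
           paste(parts[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    b <- sum(2^(unique(idx) - 1))
    pos <- ss$.lookup[b + 1L]
    if (is.na(pos)) {
      stop("range '", lab, "' is not a state of this space (max range size ",
           ss$max_range_size, ")", call. = FALSE)
    }
    pos
  }, integer(1), USE.NAMES = FALSE)
}

# state indices whose areas are all within the allowed set (null always ok)
allowed_state_mask <- function(ss, allowed_areas) {
  allowed_bits <- sum(2^(match(allowed_areas, ss$areas) - 1))
  bitwAnd(ss$bits, bitwNot(as.integer(allowed_bits))) == 0L
}
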