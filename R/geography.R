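#' Per-epoch geography: distances, dispersal multipliers, availability
#'
#' An epoch bundles everything the model needs to know about the world in a
#' time slice: the inter-area distance matrix (km), a matrix of manual
#' dispersal multipliers in `[0, 1]` (hard constraints use 0, soft
#' constraints values such as 0.5), and which areas existed at all.
#' Ages are in Ma with the present at 0 and `start_age > end_age`; the
#' oldest epoch may use `start_age = Inf` to cover any root age.
#'
#' Distances must be symmetric with a zero diagonal and positive
#' off-diagonals.  The sentinel value `9999` km marks pairs between which
#' dispersal is geologically implausible: it is deliberately a genuine
#' (huge) distance rather than a hard zero, so that under a negative
#' distance exponent dispersal remains possible but vanishingly unlikely.
#'
#' @param distance Symmetric numeric A×A matrix with area names as
#'   dimnames; kilometres.
#' @param start_age,end_age Epoch bounds in Ma, `start_age > end_age >= 0`.
#' @param multiplier Optional A×A dispersal-multiplier matrix in `[0, 1]`;
#'   defaults to all ones off the diagonal.
#' @param allowed Character vector of areas available during the epoch;
#'   defaults to all.  Dispersal into an unavailable area has rate zero.
#' @return An object of class `dec_epoch`.
#' @export
epoch_geography <- function(distance, start_age = Inf, end_age = 0,
                            multiplier = NULL, allowed = NULL) {
  distance <- validate_area_matrix(distance, "distance")
  areas <- rownames(distance)
  A <- length(areas)
  off <- distance[row(distance) != col(distance)]
  if (any(off <= 0)) {
    bad <- which(distance <= 0 & row(distance) != col(distance),
                 arr.ind = TRUE)[1, ]
    stop("non-positive off-diagonal distance at [", areas[bad[1]], ", ",
         areas[bad[2]], "]", call. = FALSE)
  }
  if (is.null(multiplier)) {
    multiplier <- matrix(1, A, A, dimnames = list(areas, areas))
    diag(multiplier) <- 0
  } else {
    multiplier <- validate_area_matrix(multiplier, "multiplier",
                                       require_symmetric = FALSE)
    if (!identical(rownames(multiplier), areas)) {
      stop("multiplier area names do not match distance area names",
           call. = FALSE)
    }
    if (any(multiplier < 0 | multiplier > 1)) {
      stop("dispersal multipliers must lie in [0, 1]", call. = FALSE)
    }
  }
  if (is.null(allowed)) allowed <- areas
  if (!all(allowed %in% areas)) {
    stop("allowed areas not in the area set: ",
         paste(setdiff(allowed, areas), collapse = ", "), call. = FALSE)
  }
  if (!(start_age > end_age) || end_age < 0) {
    stop("epoch needs start_age > end_age >= 0 (ages in Ma)", call. = FALSE)
  }
  structure(
    list(areas = areas, distance = distance, multiplier = multiplier,
         allowed = allowed, start_age = start_age, end_age = end_age),
    class = "dec_epoch"
  )
}

#' @export
print.dec_epoch <- function(x, ...) {
  cat("Epoch ", format(x$start_age), "-", format(x$end_age), " Ma: ",
      length(x$areas), " areas (", length(x$allowed), " available)\n",
      sep = "")
  invisible(x)
}

validate_area_matrix <- function(m, what, require_symmetric = TRUE,
                                 tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop(what, " matrix must be square", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(what, " matrix needs area names as row and column names",
         call. = FALSE)
  }
  if (!identical(rownames(m), colnames(m))) {
    stop(what, " matrix row/column names disagree", call. = FALSE)
  }
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop(what, " matrix has non-finite entries",
                               call. = FALSE)
  if (require_symmetric) {
    d <- abs(m - t(m))
    if (any(d > tol)) {
      bad <- which(d == max(d), arr.ind = TRUE)[1, ]
      stop(what, " matrix is asymmetric at [", rownames(m)[bad[1]], ", ",
           colnames(m)[bad[2]], "]", call. = FALSE)
    }
  }
  if (any(abs(diag(m)) > tol)) {
    stop(what, " matrix diagonal must be zero", call. = FALSE)
  }
  m
}

#' Time-stratified scenario
#'
#' Orders epochs from oldest to youngest and checks that they tile
#' `[root age, 0]` without gaps or overlap, the youngest ending at the
#' present.
#'
#' @param epochs A list of [epoch_geography()] objects (any order).
#' @return An object of class `dec_scenario`.
#' @export
dec_scenario <- function(epochs) {
  if (inherits(epochs, "dec_epoch")) epochs <- list(epochs)
  stopifnot(length(epochs) >= 1,
            all(vapply(epochs, inherits, logical(1), "dec_epoch")))
  ord <- order(vapply(epochs, function(e) e$end_age, numeric(1)),
               decreasing = TRUE)
  epochs <- epochs[ord]
  areas <- epochs[[1]]$areas
  for (e in epochs) {
    if (!identical(e$areas, areas)) {
      stop("all epochs must share one area ordering", call. = FALSE)
    }
  }
  starts <- vapply(epochs, function(e) e$start_age, numeric(1))
  ends <- vapply(epochs, function(e) e$end_age, numeric(1))
  if (ends[length(epochs)] != 0) {
    stop("the youngest epoch must end at the present (age 0)", call. = FALSE)
  }
  if (length(epochs) > 1 &&
      any(abs(ends[-length(ends)] - starts[-1]) > 1e-9)) {
    stop("epochs must be contiguous: each end age must equal the next ",
         "epoch's start age", call. = FALSE)
  }
  structure(list(epochs = epochs, areas = areas), class = "dec_scenario")
}

#' @export
print.dec_scenario <- function(x, ...) {
  cat("Stratified scenario:", length(x$epochs), "epoch(s),",
      length(x$areas), "areas\n")
  for (e in x$epochs) print(e)
  invisible(x)
}

#' Single-epoch (non-stratified) scenario
#'
#' @param geo A `dec_epoch` or a distance matrix (passed to
#'   [epoch_geography()]).
#' @param ... Passed on to [epoch_geography()] when `geo` is a matrix.
#' @return A `dec_scenario` with one epoch covering all of time.
#' @export
uniform_scenario <- function(geo, ...) {
  if (!inherits(geo, "dec_epoch")) {
    geo <- epoch_geography(geo, start_age = Inf, end_age = 0, ...)
  } else {
    geo$start_age <- Inf
    geo$end_age <- 0
  }
  dec_scenario(list(geo))
}

# epoch index containing an age; boundaries belong to the older epoch,
# except age 0 which belongs to the youngest
scenario_epoch_at <- function(scenario, age) {
  starts <- vapply(scenario$epochs, function(e) e$start_age, numeric(1))
  ends <- vapply(scenario$epochs, function(e) e$end_age, numeric(1))
  i <- which(age <= starts & age > ends)
  if (length(i) == 0 && age == 0) i <- length(scenario$epochs)
  if (length(i) == 0) {
    stop("age ", age, " Ma is outside the scenario's epochs", call. = FALSE)
  }
  i[1]
}

#' Adjacency-based dispersal-constraint matrices
#'
#' Builds a 0/1 dispersal-multiplier matrix from a user-supplied adjacency
#' list.  Three schemes are supported: `"unconstrained"` (all pairs open),
#' `"adjacent_only"` (only listed adjacent pairs open), and
#' `"adjacent_except_sunda"` (adjacency, but every pair within a named
#' free-dispersal group — classically the Sunda Arc chain
#' W-Java/E-Java/Bali/Lombok/Sumbawa/Flores — is opened regardless of
#' adjacency).  Adjacency is geological knowledge, not something inferred
#' from distances, so it is always explicit input.
#'
#' @param areas Character vector of area names.
#' @param scheme One of `"unconstrained"`, `"adjacent_only"`,
#'   `"adjacent_except_sunda"`.
#' @param adjacency List of length-2 character vectors, the adjacent pairs
#'   (undirected).  Required for the two constrained schemes.
#' @param open_group Character vector of areas forming the free-dispersal
#'   group for `"adjacent_except_sunda"`.
#' @return A symmetric 0/1 multiplier matrix with zero diagonal.
#' @examples
#' adjacency_constraint(c("A", "B", "C"), "adjacent_only",
#'                      adjacency = list(c("A", "B"), c("B", "C")))
#' @export
adjacency_constraint <- function(areas,
                                 scheme = c("unconstrained", "adjacent_only",
                                            "adjacent_except_sunda"),
                                 adjacency = NULL, open_group = NULL) {
  scheme <- match.arg(scheme)
  A <- length(areas)
  m <- matrix(0, A, A, dimnames = list(areas, areas))
  if (scheme == "unconstrained") {
    m[] <- 1
    diag(m) <- 0
    return(m)
  }
  if (is.null(adjacency)) {
    stop("scheme '", scheme, "' needs an explicit adjacency list",
         call. = FALSE)
  }
  for (pair in adjacency) {
    if (length(pair) != 2 || !all(pair %in% areas)) {
      stop("bad adjacency pair: ", paste(pair, collapse = "/"),
           call. = FALSE)
    }
    m[pair[1], pair[2]] <- 1
    m[pair[2], pair[1]] <- 1
  }
  if (scheme == "adjacent_except_sunda") {
    if (is.null(open_group) || length(open_group) < 2) {
      stop("'adjacent_except_sunda' needs an open_group of >= 2 areas",
           call. = FALSE)
    }
    if (!all(open_group %in% areas)) {
      stop("open_group areas not in the area set: ",
           paste(setdiff(open_group, areas), collapse = ", "), call. = FALSE)
    }
    m[open_group, open_group] <- 1
  }
  diag(m) <- 0
  m
}

#' Load one epoch's geography from matrix files
#'
#' Reads a distance matrix (and optionally a multiplier matrix) from TSV
#' files whose first row and first column carry area names, validates them,
#' and assembles a [epoch_geography()].  The `9999` km sentinel passes
#' through unchanged; entries equal to it are reported via the
#' `soft_excluded` attribute on the distance matrix.
#'
#' @param distance_file Path to the distance TSV.
#' @param multiplier_file Optional path to the multiplier TSV.
#' @param allowed_areas Areas available during the epoch (default all).
#' @param interval Numeric `c(start_age, end_age)` in Ma.
#' @return A `dec_epoch`.
#' @export
load_epoch_geography <- function(distance_file, multiplier_file = NULL,
                                 allowed_areas = NULL,
                                 interval = c(Inf, 0)) {
  distance <- read_area_matrix(distance_file)
  multiplier <- if (!is.null(multiplier_file)) {
    read_area_matrix(multiplier_file)
  }
  geo <- epoch_geography(distance, start_age = interval[1],
                         end_age = interval[2], multiplier = multiplier,
                         allowed = allowed_areas)
  soft <- which(geo$distance == 9999 & upper.tri(geo$distance),
                arr.ind = TRUE)
  attr(geo$distance, "soft_excluded") <-
    if (nrow(soft)) {
      cbind(from = rownames(geo$distance)[soft[, 1]],
            to = colnames(geo$distance)[soft[, 2]])
    }
  geo
}

#' Read / write square area matrices as TSV
#'
#' First row and first column are area names; the diagonal may be written
#' as `"."` (read back as 0).
#'
#' @param path File path.
#' @return `read_area_matrix()` returns a named numeric matrix.
#' @export
read_area_matrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = 1,
                           colClasses = "character")
  m <- as.matrix(raw)
  m[m == "."] <- "0"
  suppressWarnings(storage.mode(m) <- "double")
  if (any(is.na(m))) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("non-numeric entry at [", rownames(m)[bad[1]], ", ",
         colnames(m)[bad[2]], "] in ", path, call. = FALSE)
  }
  m
}

#' @rdname read_area_matrix
#' @param m Named square numeric matrix.
#' @param dot_diagonal Write the diagonal as `"."`?
#' @export
write_area_matrix <- function(m, path, dot_diagonal = TRUE) {
  out <- format(m, trim = TRUE, scientific = FALSE, digits = 15)
  if (dot_diagonal) diag(out) <- "."
  df <- data.frame(area = rownames(m), out, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
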