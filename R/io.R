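#' Read and validate a dated Newick tree
#'
#' Wraps [ape::read.tree()] with the checks the range-evolution machinery
#' needs: branch lengths present, unique tip labels, fully bifurcating,
#' ultrametric within `tol` (naming the offending tip otherwise).
#'
#' @param path Newick file.
#' @param tol Ultrametricity tolerance in Myr.
#' @return An `ape::phylo`.
#' @export
read_dated_tree <- function(path, tol = 1e-6) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file ", path,
                          call. = FALSE)
  validate_dated_tree(tree, tol)
  tree
}

#' Read a Lagrange-style geographic-range ("geog") file
#'
#' Format: a header line `n_taxa n_areas (A1 A2 ...)` followed by one line
#' per taxon, `label` then a 0/1 string of length `n_areas` (tab- or
#' space-delimited).
#'
#' @param path Geog file.
#' @param ss Optional [state_space()]; when given, area names must match
#'   and every range must be a state of the space (ranges wider than
#'   `max_range_size` are rejected).
#' @return A tibble with columns `taxon` and `range` (plus attribute
#'   `"areas"`).
#' @export
read_geog <- function(path, ss = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- regmatches(lines[1],
                    regexec("^\\s*(\\d+)\\s+(\\d+)\\s*\\(([^)]*)\\)\\s*$",
                            lines[1]))[[1]]
  if (length(hdr) != 4) {
    stop("line 1: malformed geog header (expected 'n_taxa n_areas ",
         "(A1 A2 ...)')", call. = FALSE)
  }
  n_taxa <- as.integer(hdr[2])
  n_areas <- as.integer(hdr[3])
  areas <- strsplit(trimws(hdr[4]), "\\s+")[[1]]
  if (length(areas) != n_areas) {
    stop("line 1: header announces ", n_areas, " areas but names ",
         length(areas), call. = FALSE)
  }
  if (!is.null(ss) && !identical(areas, ss$areas)) {
    stop("geog areas do not match the state space's area ordering",
         call. = FALSE)
  }
  body <- lines[-1]
  if (length(body) != n_taxa) {
    stop("header announces ", n_taxa, " taxa but file has ", length(body),
         call. = FALSE)
  }
  taxon <- character(n_taxa)
  range <- character(n_taxa)
  for (i in seq_along(body)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(parts) != 2 || !grepl("^[01]+$", parts[2])) {
      stop("line ", i + 1, ": expected 'label 0/1string'", call. = FALSE)
    }
    if (nchar(parts[2]) != n_areas) {
      stop("line ", i + 1, " ('", parts[1], "'): presence string has ",
           nchar(parts[2]), " characters, expected ", n_areas,
           call. = FALSE)
    }
    present <- which(strsplit(parts[2], "")[[1]] == "1")
    if (length(present) == 0) {
      stop("line ", i + 1, " ('", parts[1], "'): all-zero range (every ",
           "taxon must occupy at least one area)", call. = FALSE)
    }
    if (!is.null(ss) && length(present) > ss$max_range_size) {
      stop("line ", i + 1, " ('", parts[1], "'): range spans ",
           length(present), " areas, exceeding the maximum range size ",
           ss$max_range_size, call. = FALSE)
    }
    taxon[i] <- parts[1]
    range[i] <- paste(areas[present], collapse = "+")
  }
  if (anyDuplicated(taxon)) {
    stop("duplicate taxa in geog file: ",
         paste(unique(taxon[duplicated(taxon)]), collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(taxon = taxon, range = range)
  attr(out, "areas") <- areas
  out
}

#' @rdname read_geog
#' @param tip_ranges Tibble with `taxon`, `range` columns.
#' @param areas Area ordering to encode against.
#' @export
write_geog <- function(tip_ranges, areas, path) {
  lines <- sprintf("%d %d (%s)", nrow(tip_ranges), length(areas),
                   paste(areas, collapse = " "))
  for (i in seq_len(nrow(tip_ranges))) {
    members <- strsplit(tip_ranges$range[i], "+", fixed = TRUE)[[1]]
    idx <- match(members, areas)
    if (anyNA(idx)) {
      stop("range '", tip_ranges$range[i], "' uses unknown area(s)",
           call. = FALSE)
    }
    bits <- rep("0", length(areas))
    bits[idx] <- "1"
    lines <- c(lines, paste0(tip_ranges$taxon[i], "\t",
                             paste(bits, collapse = "")))
  }
  writeLines(lines, path)
  invisible(path)
}
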