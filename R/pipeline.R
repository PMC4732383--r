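#' The twelve standard DEC-family model variants
#'
#' Crosses the four model types with the three constraint schemes the way
#' comparative island-biogeography studies do: distance-free models
#' (`DEC`, `DEC+J`) under each constraint scheme, and distance models
#' (`DEC+x`, `DEC+J+x`) likewise, where the "unconstrained" distance
#' variants rely on distance alone (hard constraints off; implausible
#' pairs carry the 9999 km sentinel instead).
#'
#' @return A tibble with columns `name`, `type`, `scheme`.
#' @export
standard_model_set <- function() {
  tibble::tibble(
    type = rep(c("DEC", "DEC+J", "DEC+x", "DEC+J+x"), each = 3),
    scheme = rep(c("unconstrained", "adjacent_only",
                   "adjacent_except_sunda"), times = 4)
  ) |>
    dplyr::mutate(name = paste(.data$type, .data$scheme))
}

#' Run the full model-comparison pipeline
#'
#' Fits a set of DEC-family model variants in both time-stratified and
#' non-stratified form, compares them by AICc, and derives the follow-up
#' products for the best model: ancestral-range marginals, a parsimony
#' reconstruction with dispersal-event counts, and per-area
#' lineage-accumulation curves.  Fully deterministic given its inputs.
#'
#' @param config A named list (or path to a YAML file with the same keys):
#'   \describe{
#'     \item{tree}{`ape::phylo` or Newick path.}
#'     \item{tip_ranges}{data frame (`taxon`, `range`) or geog-file path.}
#'     \item{max_range_size}{state-space cap (default 3).}
#'     \item{epochs}{list of epoch descriptions, each with `distance`
#'       (matrix or TSV path), optional `multiplier`, optional `allowed`,
#'       and `start_age`/`end_age`; oldest may use `start_age = Inf` /
#'       `"Inf"`.}
#'     \item{adjacency}{list of adjacent area pairs (for the constrained
#'       schemes).}
#'     \item{open_group}{areas with free mutual dispersal under
#'       `adjacent_except_sunda`.}
#'     \item{variants}{data frame like [standard_model_set()] (default);
#'       subset it to run fewer models.}
#'     \item{stratified}{logical vector, default `c(TRUE, FALSE)`: which
#'       contexts to run.}
#'     \item{bin_width}{LTT bin width in Myr (default 2).}
#'     \item{seed}{integer, recorded in the log (the pipeline itself uses
#'       no randomness).}
#'   }
#' @param out_dir Optional directory; when given, writes
#'   `comparison.tsv`, `marginals_best.tsv`, `parsimony_nodes.tsv`,
#'   `dispersal_events.tsv`, `ltt.tsv` and `log.yaml`.
#' @return A list of class `dec_pipeline`: `comparison` (tibble over all
#'   contexts/variants), `best` (name + context), `best_fit`,
#'   `marginals`, `parsimony`, `events`, `ltt`, `log`.
#' @export
run_dec_pipeline <- function(config, out_dir = NULL) {
  t0 <- Sys.time()
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  # yaml represents pairs and tables as nested lists
  if (!is.null(config$adjacency)) {
    config$adjacency <- lapply(config$adjacency, unlist)
  }
  if (!is.null(config$variants) && !is.data.frame(config$variants)) {
    config$variants <- as.data.frame(lapply(config$variants, unlist),
                                     stringsAsFactors = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  tree <- config$tree
  if (is.character(tree)) tree <- read_dated_tree(tree)
  validate_dated_tree(tree)
  epochs <- lapply(config$epochs, function(e) {
    d <- e$distance
    if (is.character(d)) d <- read_area_matrix(d)
    m <- e$multiplier
    if (is.character(m)) m <- read_area_matrix(m)
    start <- e$start_age
    if (identical(start, "Inf")) start <- Inf
    epoch_geography(d, start_age = start, end_age = e$end_age,
                    multiplier = m, allowed = e$allowed)
  })
  scenario_strat <- dec_scenario(epochs)
  areas <- scenario_strat$areas
  tips <- config$tip_ranges
  if (is.character(tips)) tips <- read_geog(tips)
  max_range_size <- config$max_range_size %||% 3
  ss <- state_space(areas, max_range_size)
  tips <- as_tip_ranges(tips, tree)
  variants <- config$variants %||% standard_model_set()
  contexts <- config$stratified %||% c(TRUE, FALSE)
  # non-stratified context: the youngest (modern) geography at all times
  modern <- epochs[[length(epochs)]]
  scenario_flat <- uniform_scenario(
    epoch_geography(modern$distance, multiplier = modern$multiplier))
  apply_scheme <- function(scn, scheme) {
    constraint <- adjacency_constraint(areas, scheme,
                                       adjacency = config$adjacency,
                                       open_group = config$open_group)
    scn$epochs <- lapply(scn$epochs, function(e) {
      e$multiplier <- e$multiplier * constraint
      e
    })
    scn
  }
  fits <- list()
  comparison <- list()
  for (strat in contexts) {
    base_scn <- if (strat) scenario_strat else scenario_flat
    ctx_fits <- vector("list", nrow(variants))
    for (v in seq_len(nrow(variants))) {
      scn <- apply_scheme(base_scn, variants$scheme[v])
      ctx_fits[[v]] <- fit_dec(tree, tips, ss, scn,
                               dec_model(variants$type[v]))
    }
    names(ctx_fits) <- variants$name
    cmp <- compare_models(ctx_fits, n = length(tree$tip.label))
    cmp$stratified <- strat
    fits[[as.character(strat)]] <- ctx_fits
    comparison[[as.character(strat)]] <- cmp
  }
  comparison <- dplyr::bind_rows(comparison)
  best_row <- which.min(comparison$AICc)
  best_ctx <- as.character(comparison$stratified[best_row])
  best_name <- comparison$model[best_row]
  best_fit <- fits[[best_ctx]][[best_name]]
  marginals <- ancestral_marginals(best_fit)
  # parsimony stage requires microendemic (single-area) tips
  single <- !grepl("+", tips$range, fixed = TRUE)
  parsimony <- events <- ltt <- NULL
  if (all(single)) {
    asr <- fitch_asr(tree, stats::setNames(tips$range, tips$taxon))
    events <- count_dispersal_events(asr, "deltran")
    resolved <- resolve_asr(asr, "deltran")
    ltt <- lineage_accumulation(tree, resolved,
                                bin_width = config$bin_width %||% 2)
    n_tip <- length(tree$tip.label)
    parsimony <- tibble::tibble(
      node = seq_along(asr$mpr),
      mpr_states = vapply(asr$mpr, paste, character(1), collapse = ","),
      resolved = unname(resolved)
    )
  }
  log <- list(
    n_tips = length(tree$tip.label), areas = areas,
    max_range_size = max_range_size,
    n_models = nrow(comparison),
    best_model = best_name, best_stratified = as.logical(best_ctx),
    seed = config$seed, r_version = as.character(getRversion()),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  out <- structure(
    list(comparison = comparison,
         best = list(model = best_name,
                     stratified = as.logical(best_ctx)),
         best_fit = best_fit, fits = fits, marginals = marginals,
         parsimony = parsimony, events = events, ltt = ltt, log = log),
    class = "dec_pipeline"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
      as.data.frame(comparison), file.path(out_dir, "comparison.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      as.data.frame(marginals), file.path(out_dir, "marginals_best.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(parsimony)) {
      utils::write.table(
        as.data.frame(parsimony),
        file.path(out_dir, "parsimony_nodes.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        as.data.frame(events$events),
        file.path(out_dir, "dispersal_events.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        as.data.frame(ltt), file.path(out_dir, "ltt.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    yaml::write_yaml(log, file.path(out_dir, "log.yaml"))
  }
  out
}

#' @export
print.dec_pipeline <- function(x, ...) {
  cat("DEC model-comparison pipeline: ", nrow(x$comparison),
      " fitted models\n", sep = "")
  cat("  best: ", x$best$model,
      if (x$best$stratified) " (time-stratified)" else
        " (non-stratified)", "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
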