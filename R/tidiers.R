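#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DEC-family fit
#'
#' @param x A [fit_dec()] result.
#' @param ... Unused.
#' @return One row per free parameter: `term`, `estimate`.
#' @export
tidy.dec_fit <- function(x, ...) {
  tibble::tibble(term = x$model$free,
                 estimate = unlist(x$params[x$model$free],
                                   use.names = FALSE))
}

#' @rdname tidy.dec_fit
#' @return `glance()`: a one-row tibble with `model`, `k`, `logLik`,
#'   `AICc`, `converged`, `n_eval`, `n_tips`.
#' @export
glance.dec_fit <- function(x, ...) {
  tibble::tibble(model = x$model$type, k = x$k, logLik = x$lnL,
                 AICc = aicc(x$lnL, x$k, x$n_tips),
                 converged = x$converged, n_eval = x$n_eval,
                 n_tips = x$n_tips)
}

#' Tidy a parsimony reconstruction
#'
#' @param x A [fitch_asr()] result.
#' @param ... Unused.
#' @return One row per node: `node`, `is_tip`, `mpr_states`
#'   (comma-separated), `ambiguous`.
#' @export
tidy.parsimony_asr <- function(x, ...) {
  n_tip <- length(x$tree$tip.label)
  tibble::tibble(
    node = seq_along(x$mpr),
    is_tip = seq_along(x$mpr) <= n_tip,
    mpr_states = vapply(x$mpr, paste, character(1), collapse = ","),
    ambiguous = lengths(x$mpr) > 1
  )
}

#' @rdname tidy.parsimony_asr
#' @export
glance.parsimony_asr <- function(x, ...) {
  n_tip <- length(x$tree$tip.label)
  tibble::tibble(n_tips = n_tip, n_areas = length(x$areas),
                 min_changes = x$score,
                 n_ambiguous_nodes =
                   sum(lengths(x$mpr[-seq_len(n_tip)]) > 1))
}

#' Tidy a recovery report
#'
#' @param x A [recovery_experiment()] result.
#' @param ... Unused.
#' @return The per-replicate fit table.
#' @export
tidy.recovery_report <- function(x, ...) x$fits

#' @rdname tidy.recovery_report
#' @export
glance.recovery_report <- function(x, ...) {
  wide <- stats::setNames(x$summary$median_rel_error,
                          paste0("median_rel_error_", x$summary$parameter))
  dplyr::bind_cols(
    tibble::tibble(n_replicates = x$n_replicates,
                   fitted_model = x$fitted_model,
                   j_selected_freq = x$j_selected_freq),
    tibble::as_tibble(as.list(wide))
  )
}
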