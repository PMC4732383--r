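#' Akaike information criterion with small-sample correction
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n - k - 1)`.  The sample size `n` is the
#' number of tree tips.
#'
#' @param lnL Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size; must exceed `k + 1`.
#' @return Numeric AICc value.
#' @examples
#' aicc(-361.5730074, k = 2, n = 191)  # 727.210
#' @export
aicc <- function(lnL, k, n) {
  if (any(n <= k + 1)) {
    stop("AICc needs n > k + 1 (got n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aicc
#' @export
aic <- function(lnL, k) -2 * lnL + 2 * k

#' Likelihood-ratio test between nested DEC-family fits
#'
#' DEC-type models are nested within their `+J` counterparts, so the pair
#' can be compared by a chi-squared LRT: statistic `2 (lnL_full -
#' lnL_nested)` on `df = k_full - k_nested` degrees of freedom (1 for DEC
#' versus DEC+J).  A statistic slightly below zero is an optimizer
#' artefact: within `1e-6` it is clipped silently, beyond that it is
#' clipped with a warning.
#'
#' @param nested,full [fit_dec()] results (or lists with elements `lnL`
#'   and `k`).
#' @param df Degrees of freedom; defaults to `full$k - nested$k`.
#' @return A tibble with `statistic`, `df` and `p_value`.
#' @export
lrt <- function(nested, full, df = NULL) {
  if (is.null(df)) {
    if (is.null(nested$k) || is.null(full$k)) {
      stop("supply df explicitly when fits carry no parameter counts",
           call. = FALSE)
    }
    df <- full$k - nested$k
  }
  df <- as.integer(round(df))
  if (df < 1) stop("'full' must have more free parameters than 'nested'",
                   call. = FALSE)
  stat <- 2 * (full$lnL - nested$lnL)
  if (stat < -1e-6) {
    warning("full model fits worse than nested model (optimizer failure?); ",
            "statistic clipped to 0", call. = FALSE)
  }
  stat <- max(stat, 0)
  tibble::tibble(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Evidence ratios and relative model probabilities from AICc
#'
#' Evidence ratios are `exp(-(AICc_i - min AICc)/2)`, so the best model
#' scores 1; normalizing them over the compared models gives relative
#' model probabilities (Akaike weights).
#'
#' @param aicc_values Numeric vector of AICc values (>= 2 models).
#' @return A list with `weight_ratio` and `relative_probability`.
#' @export
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) < 2) {
    stop("at least two models are needed for model weights", call. = FALSE)
  }
  wr <- exp(-(aicc_values - min(aicc_values)) / 2)
  list(weight_ratio = wr, relative_probability = wr / sum(wr))
}

#' Model-comparison table
#'
#' Assembles fitted models into a comparison table: free-parameter counts,
#' log-likelihoods, AICc, evidence ratios (best model = 1) and relative
#' model probabilities (also as rounded percentages).
#'
#' @param fits A list of [fit_dec()] results (or of lists with `lnL` and
#'   `k`), or a data frame with columns `model`, `k`, `lnL`.
#' @param n AICc sample size (number of tips).
#' @param model_names Optional names for the rows (defaults to list names
#'   or the fits' model types).
#' @return A `dec_comparison` tibble with columns `model`,
#'   `free_parameters`, `lnL`, `AICc`, `AICc_weight`,
#'   `relative_probability` and `relative_probability_percent`; rows stay
#'   in input order.
#' @export
compare_models <- function(fits, n, model_names = NULL) {
  if (is.data.frame(fits)) {
    stopifnot(all(c("model", "k", "lnL") %in% names(fits)))
    tab <- tibble::tibble(model = as.character(fits$model),
                          free_parameters = as.integer(fits$k),
                          lnL = as.numeric(fits$lnL))
  } else {
    if (is.null(model_names)) {
      model_names <- names(fits)
      if (is.null(model_names)) {
        model_names <- vapply(fits, function(f) {
          if (!is.null(f$model$type)) f$model$type else "model"
        }, character(1))
      }
    }
    tab <- tibble::tibble(
      model = unname(model_names),
      free_parameters = unname(vapply(fits, function(f) as.integer(f$k),
                                      integer(1))),
      lnL = unname(vapply(fits, function(f) f$lnL, numeric(1)))
    )
  }
  if (anyDuplicated(tab$model)) {
    stop("duplicate model names in comparison", call. = FALSE)
  }
  tab$AICc <- aicc(tab$lnL, tab$free_parameters, n)
  if (nrow(tab) >= 2) {
    w <- akaike_weights(tab$AICc)
    tab$AICc_weight <- w$weight_ratio
    tab$relative_probability <- w$relative_probability
  } else {
    tab$AICc_weight <- 1
    tab$relative_probability <- 1
  }
  tab$relative_probability_percent <-
    as.integer(round(100 * tab$relative_probability))
  attr(tab, "n") <- n
  class(tab) <- c("dec_comparison", class(tab))
  tab
}

#' Write a comparison table as TSV
#'
#' Columns written: `model`, `free_parameters`, `lnL`, `AICc`,
#' `AICc_weight`, `relative_probability_percent`.
#'
#' @param comparison A [compare_models()] table.
#' @param path Output file.
#' @export
write_comparison <- function(comparison, path) {
  cols <- c("model", "free_parameters", "lnL", "AICc", "AICc_weight",
            "relative_probability_percent")
  utils::write.table(as.data.frame(comparison)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
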