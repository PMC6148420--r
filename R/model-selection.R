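# Information-criterion model comparison: AICc, BIC, Akaike weights, and
# weight-based averaging of the asymptotic length across models.

#' Akaike information criterion
#'
#' @param log_lik Maximised log-likelihood.
#' @param k Number of parameters counted by the criterion (here: structural
#'   parameters + 1 for the residual variance).
#' @return `-2 * log_lik + 2 * k`.
#' @export
aic <- function(log_lik, k) {
  stopifnot(is.finite(log_lik), is.finite(k), k >= 1)
  -2 * log_lik + 2 * k
}

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2 k (k + 1) / (n - k - 1)`; converges to AIC as n grows.
#'
#' @inheritParams aic
#' @param n Number of observations; must exceed `k + 1`.
#' @export
aicc <- function(log_lik, k, n) {
  stopifnot(is.finite(n))
  if (n <= k + 1) {
    stop("AICc correction undefined for n <= k + 1 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  aic(log_lik, k) + 2 * k * (k + 1) / (n - k - 1)
}

#' Bayesian information criterion
#'
#' `BIC = -2 * log_lik + k * ln(n)` (natural logarithm penalty).
#'
#' @inheritParams aicc
#' @export
bic <- function(log_lik, k, n) {
  stopifnot(is.finite(log_lik), is.finite(k), k >= 1, is.finite(n), n >= 1)
  -2 * log_lik + k * log(n)
}

#' Akaike weights from AICc differences
#'
#' `w_i = exp(-delta_i / 2) / sum(exp(-delta_k / 2))`.
#'
#' @param delta_aicc Numeric vector of AICc differences (all >= 0, at least
#'   one equal to 0).
#' @return Vector of weights summing to 1.
#' @export
#' @examples
#' akaike_weights(c(0, 0.94, 2.57, 23.89, 1213.01))
akaike_weights <- function(delta_aicc) {
  if (length(delta_aicc) == 0L) stop("empty delta vector", call. = FALSE)
  stopifnot(all(is.finite(delta_aicc)), all(delta_aicc >= 0),
            any(delta_aicc == 0))
  w <- exp(-delta_aicc / 2)
  w / sum(w)
}

#' Build a model-selection table from growth fits
#'
#' Assembles per-model AICc, delta-AICc, Akaike weight, BIC, and delta-BIC,
#' sorted by ascending AICc. Ties are broken by smaller `k`, then by model
#' name.
#'
#' @param fits List of [fit_growth()] results, all on the same data.
#' @return A `data.frame` of class `selection_table` with columns `model`,
#'   `k`, `aicc`, `delta_aicc`, `weight`, `bic`, `delta_bic`.
#' @export
build_selection_table <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "growth_fit")))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L) {
    stop("all fits must be on the same data (n differs: ",
         paste(unique(ns), collapse = ", "), ")", call. = FALSE)
  }
  n <- ns[[1L]]
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    log_lik = vapply(fits, `[[`, numeric(1), "log_lik"),
    stringsAsFactors = FALSE
  )
  tab$aicc <- mapply(aicc, tab$log_lik, tab$k, MoreArgs = list(n = n))
  tab$bic <- mapply(bic, tab$log_lik, tab$k, MoreArgs = list(n = n))
  tab <- tab[order(tab$aicc, tab$k, tab$model), , drop = FALSE]
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab$delta_bic <- tab$bic - min(tab$bic)
  tab$weight <- akaike_weights(tab$delta_aicc)
  tab <- tab[, c("model", "k", "aicc", "delta_aicc", "weight", "bic", "delta_bic")]
  rownames(tab) <- NULL
  class(tab) <- c("selection_table", "data.frame")
  attr(tab, "n") <- n
  tab
}

#' Build a selection table from criterion inputs
#'
#' Variant of [build_selection_table()] taking raw `(model, k, log_lik)`
#' triplets, useful when log-likelihoods come from elsewhere (e.g. implied by
#' published AICc values).
#'
#' @param model Character vector of model labels.
#' @param k Parameter counts.
#' @param log_lik Log-likelihoods.
#' @param n Common number of observations.
#' @return A `selection_table`, see [build_selection_table()].
#' @export
selection_table_from_loglik <- function(model, k, log_lik, n) {
  stopifnot(length(model) == length(k), length(k) == length(log_lik))
  tab <- data.frame(model = model, k = k, log_lik = log_lik,
                    stringsAsFactors = FALSE)
  tab$aicc <- mapply(aicc, tab$log_lik, tab$k, MoreArgs = list(n = n))
  tab$bic <- mapply(bic, tab$log_lik, tab$k, MoreArgs = list(n = n))
  tab <- tab[order(tab$aicc, tab$k, tab$model), , drop = FALSE]
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab$delta_bic <- tab$bic - min(tab$bic)
  tab$weight <- akaike_weights(tab$delta_aicc)
  tab <- tab[, c("model", "k", "aicc", "delta_aicc", "weight", "bic", "delta_bic")]
  rownames(tab) <- NULL
  class(tab) <- c("selection_table", "data.frame")
  attr(tab, "n") <- n
  tab
}

#' Model-averaged asymptotic length
#'
#' Averages `L_inf` across models with Akaike weights, renormalised over the
#' models that possess an asymptote (the Schnute endpoint parameterisation
#' does not, and in practice carries no weight).
#'
#' @param table A `selection_table`.
#' @param linf Named numeric vector of asymptotic lengths, or a list of
#'   [fit_growth()] results (named or in table order) from which `L_inf` is
#'   extracted; `NA` marks models without an asymptote.
#' @param weights Optional replacement weights (e.g. published rounded
#'   weights), same order as `table$model`; defaults to `table$weight`.
#' @return Weighted mean `L_inf` in mm.
#' @export
#' @examples
#' model_average_linf_values(c(0.53, 0.33, 0.15), c(951.30, 938.80, 870.48))
model_average_Linf <- function(table, linf, weights = NULL) {
  stopifnot(inherits(table, "selection_table"))
  if (is.list(linf) && all(vapply(linf, inherits, logical(1), "growth_fit"))) {
    vals <- vapply(linf, function(f) asymptotic_length(f$model, f$params),
                   numeric(1))
    names(vals) <- vapply(linf, `[[`, character(1), "model")
    linf <- vals
  }
  linf <- linf[table$model]
  w <- if (is.null(weights)) table$weight else weights
  stopifnot(length(w) == nrow(table))
  keep <- !is.na(linf)
  if (!any(keep) || sum(w[keep]) <= 0) {
    stop("no weight on any model with a defined asymptotic length", call. = FALSE)
  }
  model_average_linf_values(w[keep], linf[keep])
}

#' Weighted average of asymptotic lengths
#'
#' The arithmetic core of [model_average_Linf()]. By default weights are
#' renormalised to sum to 1 over the supplied models (the correct behaviour
#' when models without an asymptote were dropped). With
#' `renormalize = FALSE` the plain weighted sum is returned, which is the
#' arithmetic obtained when already-rounded published weights (that may not
#' sum exactly to 1) are applied as-is.
#'
#' @param weights Non-negative weights.
#' @param linf Asymptotic lengths (mm), same length as `weights`.
#' @param renormalize Divide by `sum(weights)` (default `TRUE`).
#' @return Weighted mean in mm.
#' @export
model_average_linf_values <- function(weights, linf, renormalize = TRUE) {
  stopifnot(length(weights) == length(linf), all(weights >= 0),
            sum(weights) > 0)
  if (renormalize) sum(weights * linf) / sum(weights) else sum(weights * linf)
}

#' @export
print.selection_table <- function(x, digits = 2, ...) {
  cat(sprintf("Model selection over %d models (n = %s)\n", nrow(x),
              format(attr(x, "n"))))
  print.data.frame(x, digits = 6, row.names = FALSE)
  invisible(x)
}

#' Write a selection table as delimited text
#'
#' Column order mirrors the published comparison tables:
#' model, k, AICc, delta-AICc, AICc weight, BIC, delta-BIC.
#'
#' @param table A `selection_table`.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "selection_table"))
  utils::write.table(as.data.frame(table), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
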