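#' @keywords internal
"_PACKAGE"

# Five length-at-age models used in multi-model fish growth studies.
# Parameters are plain named lists/vectors; model ids are lower-case strings.

#' Admissible growth model identifiers
#'
#' The five length-at-age models supported by the package, in the naming used
#' throughout: `"von_bertalanffy"`, `"gompertz"`, `"logistic"`, `"schnute"`
#' (the a,b != 0 curve family, with age/length endpoints fixed from data),
#' and `"schnute_richards"`.
#'
#' @return Character vector of the five model ids.
#' @export
#' @examples
#' growth_model_ids()
growth_model_ids <- function() {
  c("von_bertalanffy", "gompertz", "logistic", "schnute", "schnute_richards")
}

# structural parameters estimated by least squares, per model
.structural_params <- list(
  von_bertalanffy  = c("L_inf", "K", "t0"),
  gompertz         = c("L_inf", "K", "t0"),
  logistic         = c("L_inf", "K", "t_infl"),
  schnute          = c("a", "b"),
  schnute_richards = c("L_inf", "alpha", "a", "b", "c")
)

# fixed (non-estimated) parameters, per model
.fixed_params <- list(
  schnute = c("T1", "T2", "L1", "L2")
)

#' Number of structural (estimated) parameters of a growth model
#'
#' @param model A growth model id, see [growth_model_ids()].
#' @return Integer count of parameters estimated by least squares: 3 for the
#'   von Bertalanffy, Gompertz and logistic models, 2 for the Schnute model
#'   (its four age/length endpoints are fixed from the data), 5 for the
#'   Schnute-Richards model.
#' @export
n_structural_params <- function(model) {
  model <- match_model(model)
  length(.structural_params[[model]])
}

match_model <- function(model) {
  if (!is.character(model) || length(model) != 1L || !(model %in% growth_model_ids())) {
    stop("unknown growth model ", deparse(substitute(model)), ": '",
         paste(model, collapse = ","), "'. Admissible values: ",
         paste(growth_model_ids(), collapse = ", "), call. = FALSE)
  }
  model
}

check_params <- function(model, params) {
  model <- match_model(model)
  need <- c(.structural_params[[model]], .fixed_params[[model]])
  params <- as.list(params)
  missing <- setdiff(need, names(params))
  if (length(missing) > 0L) {
    stop("parameters for model '", model, "' must contain: ",
         paste(need, collapse = ", "), " (missing: ",
         paste(missing, collapse = ", "), ")", call. = FALSE)
  }
  bad <- !vapply(params[need], function(p) is.numeric(p) && length(p) == 1L && is.finite(p),
                 logical(1))
  if (any(bad)) {
    stop("non-finite or non-scalar parameter value(s): ",
         paste(need[bad], collapse = ", "), call. = FALSE)
  }
  if (model == "schnute") {
    if (params$a == 0 || params$b == 0) {
      stop("Schnute curve family with a = 0 or b = 0 is not supported; ",
           "only the a != 0, b != 0 family is implemented", call. = FALSE)
    }
    if (params$T2 <= params$T1) stop("Schnute endpoints require T2 > T1", call. = FALSE)
    if (params$L1 <= 0 || params$L2 <= params$L1) {
      stop("Schnute endpoints require L2 > L1 > 0", call. = FALSE)
    }
  }
  if (model == "schnute_richards" && params$b == 0) {
    stop("Schnute-Richards with b = 0 is not supported", call. = FALSE)
  }
  params[need]
}

#' Predicted length at age under a growth model
#'
#' Evaluates the closed-form length-at-age curve of one of the five supported
#' models. The Gompertz model is, by default, evaluated in the form
#' `L_inf * exp(-(1/K) * exp(-K (t - t0)))`; the textbook form without the
#' `1/K` factor is available with `gompertz_form = "standard"`.
#'
#' @param model Growth model id, see [growth_model_ids()].
#' @param params Named list or vector of parameters. Required fields:
#'   von Bertalanffy / Gompertz `L_inf, K, t0`; logistic `L_inf, K, t_infl`;
#'   Schnute `a, b` plus fixed endpoints `T1, T2, L1, L2`; Schnute-Richards
#'   `L_inf, alpha, a, b, c`.
#' @param age Numeric vector of ages (years, >= 0 allowed; finite).
#' @param gompertz_form `"printed"` (default, with the `1/K` factor) or
#'   `"standard"`.
#' @return Numeric vector of predicted total lengths (mm), same order as `age`.
#' @export
#' @examples
#' vb <- list(L_inf = 916.05, K = 0.28, t0 = -0.17)
#' predict_length("von_bertalanffy", vb, age = 1:8)
predict_length <- function(model, params, age,
                           gompertz_form = c("printed", "standard")) {
  model <- match_model(model)
  p <- check_params(model, params)
  gompertz_form <- match.arg(gompertz_form)
  stopifnot(is.numeric(age), all(is.finite(age)))
  t <- as.numeric(age)
  switch(model,
    von_bertalanffy = p$L_inf * (1 - exp(-p$K * (t - p$t0))),
    gompertz = if (gompertz_form == "printed") {
      p$L_inf * exp(-(1 / p$K) * exp(-p$K * (t - p$t0)))
    } else {
      p$L_inf * exp(-exp(-p$K * (t - p$t0)))
    },
    logistic = p$L_inf / (1 + exp(-p$K * (t - p$t_infl))),
    schnute = {
      num <- 1 - exp(-p$a * (t - p$T1))
      den <- 1 - exp(-p$a * (p$T2 - p$T1))
      inner <- p$L1^p$b + (p$L2^p$b - p$L1^p$b) * num / den
      # inner interpolates between positive endpoint powers for t in [T1, T2];
      # guard against numerically negative values outside that range
      sign(inner) * abs(inner)^(1 / p$b)
    },
    schnute_richards = {
      base <- 1 + p$alpha * exp(-p$a * t^p$c)
      pmax(base, .Machine$double.eps)^(1 / p$b) * p$L_inf
    }
  )
}

#' Asymptotic length of a growth model
#'
#' Returns the asymptotic (maximum average) length `L_inf` for the four models
#' that possess one. The Schnute a,b != 0 family is parameterised through its
#' endpoint lengths rather than an asymptote, so `NA` is returned for it
#' (flagged "undefined").
#'
#' @inheritParams predict_length
#' @return Length in mm, or `NA_real_` for the Schnute model.
#' @export
#' @examples
#' asymptotic_length("von_bertalanffy", list(L_inf = 916.05, K = 0.28, t0 = -0.17))
asymptotic_length <- function(model, params) {
  model <- match_model(model)
  if (model == "schnute") return(NA_real_)
  p <- check_params(model, params)
  p$L_inf
}
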