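# Simple indicators of sampling bias in age-length data: per-age summary
# statistics, the bolstering simulation that tops every age class up to a
# common sample size, the Froese-Binohlan empirical check of the asymptotic
# length against the largest observed fish, and frequency histograms.

#' Per-age-class summary statistics
#'
#' One row per observed age with the count, mean and sample standard
#' deviation (n - 1 denominator) of length. Ages observed only once get an
#' `NA` standard deviation (flagged, not fabricated).
#'
#' @param data An [age_length_table()].
#' @return Data frame with columns `age`, `n_obs`, `mean_length`, `sd_length`.
#' @export
per_age_stats <- function(data) {
  stopifnot(inherits(data, "age_length"), nrow(data) > 0L)
  ages <- sort(unique(data$age))
  out <- data.frame(
    age = ages,
    n_obs = vapply(ages, function(a) sum(data$age == a), numeric(1)),
    mean_length = vapply(ages, function(a) mean(data$length_mm[data$age == a]),
                         numeric(1)),
    sd_length = vapply(ages, function(a) {
      x <- data$length_mm[data$age == a]
      if (length(x) < 2L) NA_real_ else stats::sd(x)
    }, numeric(1))
  )
  rownames(out) <- NULL
  out
}

#' Bolster an age-length table to a common per-age sample size
#'
#' Emulates an ideal sampling outcome: every observed age class is topped up
#' to `target_per_age` records by drawing simulated lengths from a normal
#' distribution with that class's observed mean and standard deviation.
#' Original records are preserved verbatim (they form the byte-identical
#' prefix of the result); non-positive draws are rejected and redrawn.
#'
#' @param data An [age_length_table()].
#' @param target_per_age Target records per age class (default 200); must be
#'   at least the largest existing class count (classes are never
#'   downsampled).
#' @param seed Integer seed for the normal draws.
#' @return An [age_length_table()] with provenance `"bolstered"`; simulated
#'   records carry `source = "simulated"`.
#' @export
bolster_dataset <- function(data, target_per_age = 200L, seed = 1L) {
  stopifnot(inherits(data, "age_length"))
  stats_tab <- per_age_stats(data)
  if (anyNA(stats_tab$sd_length)) {
    stop("age class(es) with a single observation have no computable SD (ages ",
         paste(stats_tab$age[is.na(stats_tab$sd_length)], collapse = ", "),
         "); merge classes or supply more data before bolstering", call. = FALSE)
  }
  if (target_per_age < max(stats_tab$n_obs)) {
    stop("target_per_age (", target_per_age,
         ") is below an existing class count (",
         max(stats_tab$n_obs), "); downsampling is not supported", call. = FALSE)
  }
  set.seed(as.integer(seed))
  sim_age <- numeric(0)
  sim_len <- numeric(0)
  for (i in seq_len(nrow(stats_tab))) {
    deficit <- target_per_age - stats_tab$n_obs[i]
    if (deficit == 0L) next
    draws <- stats::rnorm(deficit, stats_tab$mean_length[i], stats_tab$sd_length[i])
    while (any(draws <= 0)) {
      bad <- draws <= 0
      draws[bad] <- stats::rnorm(sum(bad), stats_tab$mean_length[i],
                                 stats_tab$sd_length[i])
    }
    sim_age <- c(sim_age, rep(stats_tab$age[i], deficit))
    sim_len <- c(sim_len, draws)
  }
  out <- age_length_table(
    c(data$age, sim_age),
    c(data$length_mm, sim_len),
    provenance = "bolstered",
    source = c(data$source, rep("simulated", length(sim_age)))
  )
  attr(out, "bolster_seed") <- as.integer(seed)
  attr(out, "target_per_age") <- as.integer(target_per_age)
  out
}

#' Froese-Binohlan empirical asymptotic length
#'
#' Predicts the asymptotic length from the largest fish in a dataset via the
#' empirical relationship
#' `log10(L_inf) = 0.044 + 0.9841 * log10(L_max)` (lengths in mm in and out).
#' A modelled asymptote well below this prediction is a symptom of missing
#' large, old individuals.
#'
#' @param L_max Largest observed total length (mm, > 0); vectorised.
#' @return Predicted asymptotic length (mm).
#' @export
#' @examples
#' froese_binohlan_Linf(1013)
froese_binohlan_Linf <- function(L_max) {
  stopifnot(is.numeric(L_max), all(is.finite(L_max)))
  if (any(L_max <= 0)) stop("L_max must be positive", call. = FALSE)
  10^(0.044 + 0.9841 * log10(L_max))
}

#' Frequency histogram of lengths or ages
#'
#' Length histograms use left-closed, right-open bins anchored at 0
#' (default width 10 mm); age histograms use unit integer bins. Counts always
#' sum to the number of records.
#'
#' @param data An [age_length_table()].
#' @param variable `"length"` or `"age"`.
#' @param bin_width Bin width in mm for length histograms (> 0); ignored for
#'   age.
#' @return Data frame with columns `bin_left` and `count` (only non-empty
#'   bins between the data range are guaranteed present; empty interior bins
#'   are included).
#' @export
frequency_histogram <- function(data, variable = c("length", "age"),
                                bin_width = 10) {
  stopifnot(inherits(data, "age_length"))
  variable <- match.arg(variable)
  if (variable == "length") {
    stopifnot(bin_width > 0)
    x <- data$length_mm
    left <- floor(x / bin_width) * bin_width
    bins <- seq(min(left), max(left), by = bin_width)
  } else {
    x <- data$age
    left <- floor(x)
    bins <- seq(min(left), max(left), by = 1)
  }
  counts <- vapply(bins, function(b) sum(left == b), numeric(1))
  data.frame(bin_left = bins, count = counts)
}

#' Write a histogram as two-column delimited text
#'
#' @param hist A [frequency_histogram()] result.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path, sep = ",") {
  utils::write.table(hist, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
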