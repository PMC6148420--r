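# Shared fixtures: the published parameter sets used as generating truths /
# evaluation points, small dataset builders, and an independent brute-force
# grid oracle for the von Bertalanffy least-squares surface.

# parameter sets printed for the raw-data fits
raw_params <- function() {
  list(
    von_bertalanffy  = list(L_inf = 916.05, K = 0.28, t0 = -0.17),
    gompertz         = list(L_inf = 820.64, K = 0.51, t0 = 1.29),
    logistic         = list(L_inf = 778.88, K = 0.76, t_infl = 1.92),
    schnute          = list(a = 3.36, b = -0.33,
                            T1 = 1, T2 = 8, L1 = 141, L2 = 1013),
    schnute_richards = list(L_inf = 730.91, alpha = -0.003, a = 0.12,
                            b = 0.003, c = 2.18)
  )
}

# parameter sets printed for the bolstered-data fits
bolstered_params <- function() {
  list(
    von_bertalanffy  = list(L_inf = 951.30, K = 0.25, t0 = -0.33),
    gompertz         = list(L_inf = 870.48, K = 0.62, t0 = 1.34),
    logistic         = list(L_inf = 834.34, K = 0.62, t_infl = 2.10),
    schnute          = list(a = 6.06, b = -0.78,
                            T1 = 1, T2 = 8, L1 = 141, L2 = 1013),
    schnute_richards = list(L_inf = 938.80, alpha = -0.0046, a = 0.67,
                            b = 0.0019, c = 0.72)
  )
}

# noiseless (or noisy) table sampled from a model curve, equal records per age
make_curve_table <- function(model, params, ages = 1:8, per_age = 5,
                             sd = 0, seed = 1) {
  mu <- predict_length(model, params, ages)
  age <- rep(ages, each = per_age)
  len <- rep(mu, each = per_age)
  if (sd > 0) {
    set.seed(seed)
    len <- len + rnorm(length(len), 0, sd)
  }
  age_length_table(age, pmax(len, 1), provenance = "synthetic")
}

# independent oracle: dense grid search over the VB least-squares surface
grid_rss_vb <- function(data, linf = seq(600, 1200, length.out = 50),
                        k = seq(0.05, 0.8, length.out = 50),
                        t0 = seq(-1.5, 1, length.out = 50)) {
  best <- Inf
  for (L in linf) {
    for (K in k) {
      # vectorise over t0 for speed
      for (T0 in t0) {
        pred <- L * (1 - exp(-K * (data$age - T0)))
        rss <- sum((data$length_mm - pred)^2)
        if (rss < best) best <- rss
      }
    }
  }
  best
}

# count of local maxima in a histogram count vector
n_local_maxima <- function(counts) {
  n <- length(counts)
  if (n == 1L) return(1L)
  left <- c(Inf, counts[-n])   # treat edges as maxima only if above neighbour
  right <- c(counts[-1L], -Inf)
  sum(counts > left & counts >= right) +
    (counts[1L] > counts[2L])
}
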