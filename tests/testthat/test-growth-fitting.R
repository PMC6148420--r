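test_that("default starting values follow the documented heuristics", {
  d <- age_length_table(c(1, 4, 8), c(141, 600, 1013))
  expect_equal(default_initial_values("von_bertalanffy", d),
               list(L_inf = 1.05 * 1013, K = 0.3, t0 = 0))
  sch <- default_initial_values("schnute", d)
  expect_equal(sch[c("a", "b")], list(a = 0.3, b = 1))
  expect_equal(sch[c("T1", "T2", "L1", "L2")],
               list(T1 = 1, T2 = 8, L1 = 141, L2 = 1013))
  sr <- default_initial_values("schnute_richards", d)
  expect_equal(sr, list(L_inf = 1.05 * 1013, alpha = -0.9, a = 0.3,
                        b = 0.1, c = 1))
})

test_that("noise-free data recover the generating parameters exactly", {
  truth <- list(L_inf = 900, K = 0.3, t0 = -0.2)
  d <- make_curve_table("von_bertalanffy", truth, per_age = 5)
  f <- fit_growth("von_bertalanffy", d)
  expect_true(f$converged)
  expect_equal(f$params$L_inf, truth$L_inf, tolerance = 1e-6)
  expect_equal(f$params$K, truth$K, tolerance = 1e-6)
  expect_equal(f$params$t0, truth$t0, tolerance = 1e-5)
  expect_lt(f$rss, 1e-10)
  expect_equal(f$k, 4L)
})

test_that("Levenberg-Marquardt matches a dense grid-search oracle", {
  truth <- list(L_inf = 900, K = 0.3, t0 = -0.2)
  d <- make_curve_table("von_bertalanffy", truth, per_age = 3, sd = 35,
                        seed = 7)
  expect_lte(nrow(d), 30)
  f <- fit_growth("von_bertalanffy", d)
  oracle <- grid_rss_vb(d,
                        linf = seq(750, 1100, length.out = 60),
                        k = seq(0.1, 0.6, length.out = 60),
                        t0 = seq(-1.2, 0.6, length.out = 60))
  # the optimiser can only do as well or better than the grid, and the grid
  # must land within half a percent of the optimum
  expect_lte(f$rss, oracle * (1 + 1e-10))
  expect_lt((oracle - f$rss) / f$rss, 0.005)
})

test_that("fitting is a fixed point and never worse than its start", {
  d <- make_curve_table("von_bertalanffy",
                        list(L_inf = 916, K = 0.28, t0 = -0.17),
                        per_age = 10, sd = 40, seed = 3)
  f <- fit_growth("von_bertalanffy", d)
  # refitting from the optimum reproduces it
  f2 <- fit_growth("von_bertalanffy", d, init = f$params, restarts = 1)
  expect_equal(unlist(f2$params), unlist(f$params), tolerance = 1e-8)
  # converged RSS does not exceed the RSS at the initial values
  init <- default_initial_values("von_bertalanffy", d)
  rss_init <- sum((d$length_mm -
                     predict_length("von_bertalanffy", init, d$age))^2)
  expect_lte(f$rss, rss_init)
})

test_that("log-likelihood is invariant to record order", {
  d <- make_curve_table("von_bertalanffy",
                        list(L_inf = 900, K = 0.3, t0 = -0.2),
                        per_age = 6, sd = 30, seed = 5)
  set.seed(9)
  perm <- sample(nrow(d))
  d2 <- age_length_table(d$age[perm], d$length_mm[perm])
  f1 <- fit_growth("von_bertalanffy", d)
  f2 <- fit_growth("von_bertalanffy", d2)
  expect_equal(f1$log_lik, f2$log_lik, tolerance = 1e-8)
})

test_that("criterion parameter counts follow the structural + variance rule", {
  d <- make_curve_table("von_bertalanffy",
                        list(L_inf = 900, K = 0.3, t0 = -0.2),
                        per_age = 5, sd = 25, seed = 2)
  ks <- c(von_bertalanffy = 4L, gompertz = 4L, logistic = 4L, schnute = 3L,
          schnute_richards = 6L)
  for (m in names(ks)) {
    f <- suppressWarnings(fit_growth(m, d, restarts = 3, seed = 1))
    expect_equal(f$k, ks[[m]], info = m)
  }
})

test_that("Wald intervals behave sensibly", {
  truth <- list(L_inf = 900, K = 0.3, t0 = -0.2)
  d <- make_curve_table("von_bertalanffy", truth, per_age = 25, sd = 40,
                        seed = 11)
  f <- fit_growth("von_bertalanffy", d)
  ci <- confidence_intervals(f, 0.95)
  expect_true(all(ci$low <= ci$estimate & ci$estimate <= ci$high))
  # near-zero residuals give collapsing intervals
  d0 <- make_curve_table("von_bertalanffy", truth, per_age = 5)
  ci0 <- confidence_intervals(fit_growth("von_bertalanffy", d0), 0.95)
  expect_true(all(ci0$high - ci0$low < 1e-3))
})

test_that("95% Wald intervals cover the generating L_inf at nominal-ish rate", {
  truth <- list(L_inf = 916, K = 0.28, t0 = -0.17)
  n_rep <- 100
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    spec <- synthetic_spec("von_bertalanffy", truth, n_total = 800,
                           sampling = "uniform", noise_sd = 40,
                           seed = 5000 + r)
    d <- generate_dataset(spec)
    f <- fit_growth("von_bertalanffy", d, restarts = 1)
    ci <- confidence_intervals(f, 0.95)
    row <- ci[ci$parameter == "L_inf", ]
    covered[r] <- row$low <= truth$L_inf && truth$L_inf <= row$high
  }
  expect_gte(mean(covered), 0.85)
})

test_that("age-length tables round-trip through delimited text", {
  d <- make_curve_table("von_bertalanffy",
                        list(L_inf = 900, K = 0.3, t0 = -0.2),
                        per_age = 2, sd = 10, seed = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_age_length(d, csv)
  d2 <- read_age_length(csv)
  expect_equal(d2$age, d$age)
  expect_equal(d2$length_mm, d$length_mm, tolerance = 1e-12)
  # tab-separated input is sniffed from the header
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_age_length(d, tsv, sep = "\t")
  d3 <- read_age_length(tsv)
  expect_equal(d3$length_mm, d$length_mm, tolerance = 1e-12)
  # column mapping
  alt <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("edad,talla", "1,150", "2,300"), alt)
  d4 <- read_age_length(alt, col_age = "edad", col_length = "talla")
  expect_equal(d4$length_mm, c(150, 300))
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(age_length_table(numeric(0), numeric(0)), "non-empty")
  expect_error(age_length_table(1, -5), "positive")
  d <- age_length_table(c(1, 2), c(150, 300))
  expect_error(fit_growth("von_bertalanffy", d), "distinct ages")
  f <- fit_growth("von_bertalanffy",
                  make_curve_table("von_bertalanffy",
                                   list(L_inf = 900, K = 0.3, t0 = -0.2)))
  expect_error(confidence_intervals(f, 1.2))
})
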