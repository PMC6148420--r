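# Orchestration of the full analysis: fit all five growth models, compare
# them, run the bias indicators, bolster and refit, and push the fitted
# growth scenarios through the per-recruit model. All stochastic stages take
# explicit seeds; outputs are delimited tables plus a JSON report.

#' Run the full growth analysis pipeline
#'
#' Executes fit -> select -> bias indicators -> bolster -> refit -> select ->
#' per-recruit, writing every table plus a machine-readable JSON report and
#' a short plain-text summary into `out_dir`. Any stage failure aborts with
#' the stage name; tables already written are left in place.
#'
#' @param data An [age_length_table()], or a path to a delimited file
#'   readable by [read_age_length()].
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed governing the bolstering draws.
#' @param target_per_age Per-age sample size for the bolstering stage.
#' @param restarts Named list of per-model restart counts; defaults per
#'   [fit_growth()].
#' @param pr_demographics `NULL` to use [gulf_corvina_config()] defaults for
#'   the per-recruit stage, a named list of overrides for it, or `FALSE` to
#'   skip the per-recruit stage.
#' @param e_grid_step Exploitation-rate grid step for the per-recruit scan.
#' @param gompertz_form Passed to [fit_growth()].
#' @return A list of class `analysis_report` (also serialised to
#'   `report.json`): raw and bolstered fits and selection tables, indicator
#'   summary, per-recruit scenario table, seeds and configuration echo.
#' @export
run_full_analysis <- function(data, out_dir, seed = 1L,
                              target_per_age = 200L,
                              restarts = list(),
                              pr_demographics = NULL,
                              e_grid_step = 0.005,
                              gompertz_form = c("printed", "standard")) {
  gompertz_form <- match.arg(gompertz_form)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  raw <- stage("load", {
    if (is.character(data)) read_age_length(data) else {
      stopifnot(inherits(data, "age_length"))
      data
    }
  })
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  n_restarts <- function(m) {
    restarts[[m]] %||% (if (m == "schnute_richards") 25L else 5L)
  }
  fit_all <- function(d, seed_offset) {
    fits <- lapply(growth_model_ids(), function(m) {
      suppressWarnings(fit_growth(m, d, restarts = n_restarts(m),
                                  seed = seed + seed_offset,
                                  gompertz_form = gompertz_form))
    })
    stats::setNames(fits, growth_model_ids())
  }

  raw_fits <- stage("fit_raw", fit_all(raw, 0L))
  raw_sel <- stage("select_raw", build_selection_table(raw_fits))

  indicators <- stage("indicators", {
    L_max <- max(raw$length_mm)
    fb <- froese_binohlan_Linf(L_max)
    linf <- vapply(raw_fits, function(f) asymptotic_length(f$model, f$params),
                   numeric(1))
    list(L_max = L_max, froese_binohlan_Linf = fb,
         model_Linf = as.list(linf),
         Linf_gap = as.list(fb - linf),
         length_histogram = frequency_histogram(raw, "length"),
         age_histogram = frequency_histogram(raw, "age"))
  })

  bolstered <- stage("bolster",
                     bolster_dataset(raw, target_per_age = target_per_age,
                                     seed = seed))
  bol_fits <- stage("fit_bolstered", fit_all(bolstered, 1000L))
  bol_sel <- stage("select_bolstered", build_selection_table(bol_fits))

  pr_summary <- NULL
  if (!isFALSE(pr_demographics)) {
    pr_summary <- stage("per_recruit", {
      overrides <- if (is.list(pr_demographics)) pr_demographics else list()
      scen <- list(
        vb_raw = raw_fits$von_bertalanffy,
        sr_raw = raw_fits$schnute_richards,
        vb_bolstered = bol_fits$von_bertalanffy,
        sr_bolstered = bol_fits$schnute_richards
      )
      cfgs <- lapply(names(scen), function(nm) {
        f <- scen[[nm]]
        do.call(gulf_corvina_config,
                c(list(growth_model = f$model, growth_params = f$params,
                       label = nm), overrides))
      })
      compare_growth_scenarios(cfgs, E_grid = seq(0, 1, by = e_grid_step))
    })
  }

  stage("write_outputs", {
    write_age_length(bolstered, file.path(out_dir, "bolstered_data.csv"))
    write_selection_table(raw_sel, file.path(out_dir, "selection_raw.csv"))
    write_selection_table(bol_sel, file.path(out_dir, "selection_bolstered.csv"))
    write_histogram(indicators$length_histogram,
                    file.path(out_dir, "length_histogram.csv"))
    write_histogram(indicators$age_histogram,
                    file.path(out_dir, "age_histogram.csv"))
    for (m in names(raw_fits)) {
      write_growth_fit(raw_fits[[m]], file.path(out_dir, paste0("fit_raw_", m, ".json")))
      write_growth_fit(bol_fits[[m]], file.path(out_dir, paste0("fit_bolstered_", m, ".json")))
    }
    if (!is.null(pr_summary)) {
      utils::write.table(pr_summary, file.path(out_dir, "per_recruit_summary.csv"),
                         sep = ",", row.names = FALSE, quote = FALSE)
    }
  })

  report <- list(
    n_raw = nrow(raw),
    raw_fits = lapply(raw_fits, function(f)
      list(params = f$params, rss = f$rss, log_lik = f$log_lik, k = f$k,
           converged = f$converged)),
    raw_selection = as.data.frame(raw_sel),
    best_raw_model = raw_sel$model[1L],
    bolstered_fits = lapply(bol_fits, function(f)
      list(params = f$params, rss = f$rss, log_lik = f$log_lik, k = f$k,
           converged = f$converged)),
    bolstered_selection = as.data.frame(bol_sel),
    best_bolstered_model = bol_sel$model[1L],
    indicator_summary = indicators[c("L_max", "froese_binohlan_Linf",
                                     "model_Linf", "Linf_gap")],
    per_recruit_summary = pr_summary,
    config = list(seed = seed, target_per_age = target_per_age,
                  e_grid_step = e_grid_step, gompertz_form = gompertz_form,
                  restarts = restarts)
  )
  stage("write_report", {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
    summary_lines <- c(
      sprintf("records (raw): %d", nrow(raw)),
      sprintf("best model, raw data: %s", raw_sel$model[1L]),
      sprintf("best model, bolstered data: %s", bol_sel$model[1L]),
      sprintf("L_max = %.1f mm; Froese-Binohlan L_inf = %.1f mm",
              indicators$L_max, indicators$froese_binohlan_Linf),
      if (!is.null(pr_summary)) {
        apply(pr_summary, 1L, function(r)
          sprintf("per-recruit %s: FNSSBR = %s, YPR/YPRmax = %s",
                  r[["scenario"]], r[["fnssbr"]], r[["ypr_ratio"]]))
      }
    )
    writeLines(unlist(summary_lines), file.path(out_dir, "summary.txt"))
  })
  class(report) <- "analysis_report"
  invisible(report)
}
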