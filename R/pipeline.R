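#' Configuration for an end-to-end screening study run
#'
#' Describes one orchestrated run of the pipeline: where the cohort comes
#' from (exactly one of a [cohort_config()] to simulate, or a CSV path to
#' load), the screening rule, which continuous score feeds the ROC
#' analysis, and (optionally) where to persist outputs.
#'
#' The continuous marker behind the ROC analysis is an explicit choice,
#' not a guess: by default the SAMS time (higher = diseased) is used for
#' all three state variables; set `roc_score`/`roc_direction` to analyse
#' a different marker such as `predicted_vo2` with
#' `"lower_is_diseased"`.
#'
#' @param cohort a [cohort_config()] to simulate, or a path to a cohort
#'   CSV to load.
#' @param rule a [screening_rule()].
#' @param band_table CRF band edges ([crf_band_table()]).
#' @param roc_score cohort column used as the ROC score.
#' @param roc_direction `"higher_is_diseased"` or `"lower_is_diseased"`.
#' @param outdir optional output directory; when set, the cohort, the
#'   per-child classifications, the configuration and all report tables
#'   are persisted there.
#' @param conf_level confidence level used throughout.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       rule = screening_rule(),
                       band_table = crf_band_table(),
                       roc_score = "sams_time",
                       roc_direction = "higher_is_diseased",
                       outdir = NULL,
                       conf_level = 0.95) {
  src_sim <- inherits(cohort, "cohort_config") || is.list(cohort)
  src_csv <- is.character(cohort) && length(cohort) == 1
  if (!xor(src_sim, src_csv)) {
    stop_config("`cohort` must be exactly one of: a cohort_config, or a CSV path",
                field = "cohort")
  }
  structure(
    list(cohort = cohort, rule = rule, band_table = band_table,
         roc_score = roc_score, roc_direction = roc_direction,
         outdir = outdir, conf_level = conf_level),
    class = "run_config"
  )
}

#' Run the full screening study pipeline
#'
#' Executes simulate/load -> classify -> association models -> diagnostic
#' accuracy -> ROC as one seeded, reproducible run. Following the study
#' protocol this package models, the concurrent-validity models are
#' fitted first and the diagnostic-accuracy stage is gated on them (it
#' runs after the models; its results are always reported, with the gate
#' outcome recorded). Identical configuration (including the simulation
#' seed) yields byte-identical persisted outputs.
#'
#' The three reference states evaluated against the KidFit screen are
#' overweight/obesity (BMI percentile >= 85), motor proficiency in the
#' lowest BOT2 quartile, and reduced CRF (measured VO2peak at or below
#' the sex-specific cut-off). States that depend on laboratory measures
#' use the measured subset only; records with a missing state are
#' excluded from that comparison.
#'
#' @param config a [run_config()].
#' @return An object of class `kidfit_report`: list with
#'   `cohort_summary`, `ttests`, `regressions`, `diagnostics` (per-state
#'   [diagnostic_summary()] objects plus cell counts), `roc` (per-state
#'   [roc_curve()] results), `gate`, `n_used`, `paths`.
#' @export
#' @examples
#' rep <- run_study(run_config(cohort = cohort_config(n = 57, seed = 11)))
#' rep$diagnostics$motor$summary$efficiency_rate
run_study <- function(config) {
  if (!inherits(config, "run_config")) stop_config("`config` must be a run_config")
  created <- character(0)
  cleanup <- function() if (length(created)) unlink(created, force = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cleanup()
      stop_input(sprintf("stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  cohort <- stage("cohort", {
    if (inherits(config$cohort, "cohort_config")) {
      generate_cohort(config$cohort)
    } else {
      co <- read_cohort(config$cohort)
      if (nrow(co) == 0) stop_config("loaded cohort is empty", field = "cohort")
      co
    }
  })

  classified <- stage("classify", classify_cohort(cohort, config$rule,
                                                  config$band_table))

  cohort_summary <- stage("summarise", {
    vars <- intersect(c("age", "sams_time", "mstp_score", "predicted_vo2",
                        "vo2peak", "bmi_percentile", "bot2_total_raw",
                        "bot2_gross_raw", "bot2_percentile"),
                      names(classified))
    do.call(rbind, lapply(vars, function(v) {
      x <- classified[[v]][!is.na(classified[[v]])]
      data.frame(variable = v, n = length(x), mean = mean(x), sd = sd(x))
    }))
  })

  ttests <- stage("ttests", {
    vars <- intersect(c("age", "sams_time", "mstp_score", "vo2peak",
                        "bmi_percentile", "bot2_percentile"),
                      names(classified))
    do.call(rbind, lapply(vars, function(v) {
      a <- classified[[v]][classified$sex == "female"]
      b <- classified[[v]][classified$sex == "male"]
      if (sum(!is.na(a)) < 2 || sum(!is.na(b)) < 2) return(NULL)
      tt <- ttest_independent(a, b)
      data.frame(variable = v, t = tt$t, df = tt$df, p = tt$p,
                 mean_difference = tt$mean_difference)
    }))
  })

  regressions <- stage("regress", {
    outcomes <- intersect(c("vo2peak", "bot2_total_raw", "bot2_gross_raw",
                            "bmi_percentile"), names(classified))
    sex01 <- as.numeric(classified$sex == "male")  # boys coded 1
    out <- list()
    for (oc in outcomes) {
      m1 <- fit_ols(classified[[oc]],
                    list(sams_time = classified$sams_time,
                         mstp_score = classified$mstp_score))
      m2 <- fit_ols(classified[[oc]],
                    list(sams_time = classified$sams_time,
                         mstp_score = classified$mstp_score,
                         age = classified$age, sex01 = sex01))
      out[[oc]] <- list(model1 = m1, model2 = m2)
    }
    out
  })
  gate <- all(vapply(regressions, function(m) m$model1$model_p < 0.05,
                     logical(1)))

  states <- stage("states", {
    list(
      bmi = ifelse(is.na(classified$bmi_percentile), NA,
                   classified$bmi_percentile >= 85),
      motor = classified$motor_quartile == 1L,
      crf = classified$crf_reduced
    )
  })

  screen_pos <- classified$kidfit == "positive"
  diagnostics <- stage("evaluate", {
    lapply(states, function(st) {
      keep <- !is.na(st)
      if (!any(keep)) return(NULL)
      tab <- build_confusion(screen_pos[keep], st[keep])
      list(counts = tab,
           n = sum(keep),
           summary = diagnostic_summary(tab, conf_level = config$conf_level))
    })
  })

  roc <- stage("roc", {
    scores <- classified[[config$roc_score]]
    if (is.null(scores)) {
      stop_config(sprintf("roc_score column `%s` not found", config$roc_score),
                  field = "roc_score")
    }
    lapply(states, function(st) {
      keep <- !is.na(st) & !is.na(scores)
      if (length(unique(st[keep])) < 2) return(NULL)
      roc_curve(scores[keep], st[keep], direction = config$roc_direction,
                conf_level = config$conf_level)
    })
  })

  report <- structure(
    list(cohort = classified, cohort_summary = cohort_summary,
         ttests = ttests, regressions = regressions, gate = gate,
         diagnostics = diagnostics, roc = roc,
         n_used = vapply(diagnostics,
                         function(d) if (is.null(d)) 0L else as.integer(d$n),
                         integer(1)),
         paths = character(0)),
    class = "kidfit_report"
  )

  if (!is.null(config$outdir)) {
    report$paths <- stage("report", {
      dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
      paths <- write_report(report, config$outdir)
      created <<- paths
      if (inherits(config$cohort, "cohort_config")) {
        cfg_path <- file.path(config$outdir, "cohort_config.json")
        write_cohort_config(config$cohort, cfg_path)
        paths <- c(paths, cfg_path)
      }
      created <<- paths
      paths
    })
  }
  report
}

#' Persist a study report
#'
#' Writes the cohort with per-child classifications, the summary tables
#' (cohort moments, t-tests, regression models, diagnostic accuracy in
#' the published layout, ROC) as CSV, and a full-precision JSON report.
#' All rounding for the CSV report goes through one formatting layer so
#' internal precision is never lost in the JSON.
#'
#' @param report a `kidfit_report` from [run_study()].
#' @param outdir output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(outdir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  w(as.data.frame(report$cohort), "cohort_classified.csv")
  w(report$cohort_summary, "cohort_summary.csv")
  if (!is.null(report$ttests)) w(report$ttests, "ttests.csv")

  reg_rows <- do.call(rbind, lapply(names(report$regressions), function(oc) {
    do.call(rbind, lapply(c("model1", "model2"), function(m) {
      fit <- report$regressions[[oc]][[m]]
      data.frame(outcome = oc, model = m, n = fit$n,
                 r_squared = fit$r_squared, model_p = fit$model_p,
                 predictor = fit$betas$predictor, beta = fit$betas$beta,
                 p = fit$betas$p)
    }))
  }))
  w(reg_rows, "regressions.csv")

  diag_rows <- do.call(rbind, lapply(names(report$diagnostics), function(st) {
    d <- report$diagnostics[[st]]
    if (is.null(d)) return(NULL)
    vals <- format_diagnostic_summary(d$summary)
    cbind(data.frame(state = st, n = d$n), as.data.frame(t(vals)))
  }))
  w(diag_rows, "diagnostic_accuracy.csv")

  roc_rows <- do.call(rbind, lapply(names(report$roc), function(st) {
    r <- report$roc[[st]]
    if (is.null(r)) return(NULL)
    data.frame(state = st, auc = r$auc, se = r$auc_se,
               ci_lower = r$ci[1], ci_upper = r$ci[2],
               p_value = r$p_value, band = as.character(r$band))
  }))
  if (!is.null(roc_rows)) w(roc_rows, "roc.csv")

  json_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report_to_list(report), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, json_path)
  invisible(paths)
}

report_to_list <- function(report) {
  list(
    gate = report$gate,
    n_used = as.list(report$n_used),
    cohort_summary = report$cohort_summary,
    ttests = report$ttests,
    regressions = lapply(report$regressions, function(m) {
      lapply(m, function(fit) {
        list(n = fit$n, r_squared = fit$r_squared, model_p = fit$model_p,
             betas = fit$betas)
      })
    }),
    diagnostics = lapply(report$diagnostics, function(d) {
      if (is.null(d)) return(NULL)
      list(counts = unclass(d$counts), n = d$n,
           proportions = d$summary$proportions,
           likelihood_ratios = d$summary$likelihood_ratios,
           odds_ratio = d$summary$odds_ratio,
           efficiency_rate = d$summary$efficiency_rate,
           fisher_p = d$summary$fisher_p)
    }),
    roc = lapply(report$roc, function(r) {
      if (is.null(r)) return(NULL)
      list(auc = r$auc, se = r$auc_se, ci = r$ci, p_value = r$p_value,
           band = as.character(r$band))
    })
  )
}

#' @export
print.kidfit_report <- function(x, ...) {
  cat("<kidfit_report>\n")
  cat(sprintf("  cohort: %d children; association gate %s\n",
              nrow(x$cohort), if (x$gate) "passed" else "NOT passed"))
  for (st in names(x$diagnostics)) {
    d <- x$diagnostics[[st]]
    if (is.null(d)) next
    vals <- format_diagnostic_summary(d$summary)
    cat(sprintf("  %-6s (n=%2d): sens %s spec %s ER %s OR %s\n", st, d$n,
                vals["sensitivity"], vals["specificity"],
                vals["efficiency_rate"], vals["odds_ratio"]))
  }
  invisible(x)
}
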