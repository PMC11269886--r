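#' Simulate a full synthetic study and write its input files
#'
#' Generates the snake survey, the fledgling cohort, and the predation
#' events, and writes `fledglings.csv`, `snakes.csv` (survey and consumer
#' captures combined), `events.csv`, `truth.json` (the generator parameters
#' plus realized counts, for parameter-recovery tests) and a run manifest to
#' `out_dir`. Byte-identical given the same config (including seed).
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the three tables and the written paths.
#' @export
run_simulation <- function(config = synthetic_config(), out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  snakes <- simulate_snake_population(config)
  fledglings <- simulate_fledgling_cohort(config)
  sim <- simulate_predation_events(config, snakes, fledglings)
  all_captures <- rbind(snakes, sim$consumer_captures)

  cfg <- config
  class(cfg) <- NULL
  write_results(
    list(fledglings = fledglings, snakes = all_captures,
         events = sim$events),
    out_dir, seed = config$seed, config = cfg
  )
  truth <- c(cfg, list(
    realized = list(
      n_fledglings = nrow(fledglings),
      n_dead = sum(fledglings$fate != "CENSORED"),
      n_ingested = sum(fledglings$fate == "INGESTED"),
      n_slimed = sum(fledglings$fate == "SLIMED"),
      n_survey_events = nrow(snakes),
      n_consumer_events = nrow(sim$consumer_captures)
    )
  ))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(fledglings = fledglings, snakes = all_captures,
                 events = sim$events,
                 paths = file.path(out_dir, c("fledglings.csv", "snakes.csv",
                                              "events.csv", "truth.json"))))
}

#' Run the full predation analysis
#'
#' Orchestrates the four analyses on the two (optionally three) input
#' tables: (1) the mortality table by cause; (2) the ingestion-failure rate
#' with its Wilson interval; (3) the prey-size logistic regression
#' (outcome coded 1 = ingested, 0 = slimed) with a Wald z test; (4) the
#' predator-size bootstrap comparing mean consumer SVL to resampled means
#' from the endotherm-attracted survey population; and, when an events table
#' is supplied, (5) the RPM summary and (6) the prey-vs-predator-mass OLS
#' with a Wald t test. Results are written as CSV tables plus a plain-text
#' report and a manifest.
#'
#' @param fledgling_path,snake_path Paths to the two input CSVs.
#' @param events_path Optional path to a predation-events CSV; without it
#'   the RPM and OLS stages are skipped with a note in the report.
#' @param out_dir Output directory.
#' @param seed Integer seed for the bootstrap resampling.
#' @param alpha Significance/interval level used throughout.
#' @param boot A [bootstrap_config()]; its `seed` is overridden by `seed`.
#' @param exclude_multi_prey_from_ols Drop double-meal events from the OLS
#'   and scatter (default `TRUE`; they stay in the RPM summary).
#' @param make_figures Also write figures (requires ggplot2)?
#' @return Invisibly, a list of stage results
#'   (`mortality`, `failure_rate`, `glm`, `bootstrap`, `rpm`, `ols`,
#'   `report`, `parse_reports`).
#' @export
run_analysis <- function(fledgling_path, snake_path, events_path = NULL,
                         out_dir, seed = 1L, alpha = 0.05,
                         boot = bootstrap_config(alpha = alpha),
                         exclude_multi_prey_from_ols = TRUE,
                         make_figures = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  fl <- stage("read fledglings", read_fledgling_table(fledgling_path))
  sn <- stage("read snakes", read_snake_captures(snake_path))
  ev <- if (!is.null(events_path))
    stage("read events", read_predation_events(events_path)) else NULL

  mort <- stage("mortality table", mortality_table(fl$records))
  fr <- stage("failure rate", ingestion_failure_rate(
    mort$counts[["SLIMED"]], mort$counts[["INGESTED"]], alpha = alpha))

  glm_birds <- fl$records[fl$records$fate %in% c("INGESTED", "SLIMED"), ]
  glm_fit <- stage("prey-size GLM", fit_logistic(
    as.integer(glm_birds$fate == "INGESTED"), glm_birds$mass_g))

  boot$seed <- as.integer(stage_seed(seed, "bootstrap"))
  boot$alpha <- alpha
  svls <- stage("truncate survey",
                truncate_survey(sn$records, boot$threshold_mm))
  consumers <- sn$records[sn$records$context == "CONSUMER", , drop = FALSE]
  boot_res <- stage("bootstrap", {
    res <- bootstrap_mean_distribution(svls, boot)
    if (nrow(consumers) > 0) {
      cons_first <- consumers[!duplicated(consumers$snake_id), , drop = FALSE]
      res <- compare_observed(res, cons_first$svl_mm)
    }
    res
  })

  rpm <- ols <- NULL
  if (!is.null(ev) && nrow(ev$records) > 0 &&
      any(ev$records$outcome == "INGESTED" &
            !is.na(ev$records$predator_mass_g))) {
    rpm <- stage("RPM summary", rpm_summary(ev$records))
    oe <- ev$records[ev$records$outcome == "INGESTED" &
                       !is.na(ev$records$predator_mass_g), , drop = FALSE]
    if (exclude_multi_prey_from_ols)
      oe <- oe[!grepl(";", oe$bird_ids, fixed = TRUE), , drop = FALSE]
    if (nrow(oe) >= 3 && length(unique(oe$predator_mass_g)) > 1)
      ols <- stage("prey-vs-predator OLS",
                   fit_ols(oe$predator_mass_g, oe$prey_mass_g))
  }

  results <- list(mortality = mort, failure_rate = fr, glm = glm_fit,
                  bootstrap = boot_res, rpm = rpm, ols = ols,
                  parse_reports = list(fledglings = fl$report,
                                       snakes = sn$report,
                                       events = if (!is.null(ev)) ev$report))
  report <- render_report(results, alpha = alpha)
  results$report <- report

  tables <- list(
    mortality_table = data.frame(
      cause = names(mort$counts), count = unname(mort$counts),
      percent = unname(mort$percentages)),
    failure_rate = data.frame(
      n_slimed = fr$numerator, n_total = fr$denominator,
      proportion = fr$proportion, ci_low = fr$ci_low, ci_high = fr$ci_high,
      ci_method = fr$ci_method, alpha = fr$alpha),
    glm_fit = data.frame(
      term = names(glm_fit$coefficients),
      estimate = unname(glm_fit$coefficients),
      se = unname(glm_fit$standard_errors),
      z = unname(glm_fit$z_values),
      p = unname(glm_fit$p_values),
      converged = glm_fit$converged),
    bootstrap_result = data.frame(rep = seq_along(boot_res$sample_means),
                                  sample_mean = boot_res$sample_means),
    bootstrap_summary = data.frame(
      grand_mean = boot_res$grand_mean, ci_low = boot_res$ci_low,
      ci_high = boot_res$ci_high, observed_mean = boot_res$observed_mean,
      outside = boot_res$outside, direction = boot_res$direction,
      population_n = boot_res$population_n,
      n_per_sample = boot_res$config$n_per_sample,
      n_reps = boot_res$config$n_reps,
      threshold_mm = boot_res$config$threshold_mm,
      quantile_type = boot_res$quantile_type)
  )
  if (!is.null(rpm))
    tables$rpm_values <- data.frame(rpm = rpm$values)
  if (!is.null(ols))
    tables$ols_fit <- data.frame(
      intercept = ols$intercept, slope = ols$slope, slope_se = ols$slope_se,
      t = ols$t_value, p = ols$p_value, df_resid = ols$df_resid,
      r_squared = ols$r_squared)

  write_results(tables, out_dir, seed = seed,
                config = list(alpha = alpha,
                              threshold_mm = boot$threshold_mm,
                              n_per_sample = boot$n_per_sample,
                              n_reps = boot$n_reps,
                              replacement = boot$replacement,
                              exclude_multi_prey_from_ols =
                                exclude_multi_prey_from_ols))
  writeLines(report, file.path(out_dir, "report.txt"))
  if (make_figures)
    write_figures(results, sn$records, out_dir)
  invisible(results)
}

#' Render the plain-text analysis report
#'
#' One block per analysis stage. An unconverged GLM is reported as such and
#' its Wald statistics are withheld.
#'
#' @param results Stage results as assembled by [run_analysis()].
#' @param alpha Reporting level.
#' @return Character vector of report lines.
#' @export
render_report <- function(results, alpha = 0.05) {
  out <- c("Gape-limited predation analysis", strrep("=", 60), "")
  m <- results$mortality
  out <- c(out, "[1] Mortality by cause",
           sprintf("  total mortalities: %d", m$total_dead))
  if (!m$undefined) {
    for (f in DEATH_CAUSES) {
      label <- if (f == "CAT") "cat (predation or scavenging)" else tolower(f)
      out <- c(out, sprintf("  %-32s %4d (%d%%)", label, m$counts[[f]],
                            m$percentages[[f]]))
    }
    out <- c(out, sprintf("  snake-attributed (ingested+slimed) %d (%d%%)",
                          m$bts_attributed, m$bts_percent))
  } else {
    out <- c(out, "  no mortalities; percentages undefined")
  }

  fr <- results$failure_rate
  out <- c(out, "", "[2] Ingestion-failure (slimed) rate",
           sprintf("  %d slimed of %d snake-killed = %.2f%%",
                   fr$numerator, fr$denominator, 100 * fr$proportion),
           sprintf("  Wilson %d%% CI: %.2f%% - %.2f%%",
                   round(100 * (1 - fr$alpha)),
                   100 * fr$ci_low, 100 * fr$ci_high))

  g <- results$glm
  out <- c(out, "", "[3] Prey-size logistic regression (1 = ingested, 0 = slimed)")
  if (g$converged) {
    out <- c(out, sprintf(
      "  slope per g prey mass: %.4f (SE %.4f), Wald z = %.3f, p = %.3f",
      g$coefficients[["slope"]], g$standard_errors[["slope"]],
      g$z_values[["slope"]], g$p_values[["slope"]]),
      sprintf("  n = %d, converged in %d iterations", g$n_obs,
              g$n_iterations))
  } else {
    out <- c(out,
      "  fit did not converge (possible quasi-separation); no Wald test reported")
  }

  b <- results$bootstrap
  out <- c(out, "", "[4] Predator-size bootstrap",
           sprintf("  population: %d survey individuals > %g mm SVL",
                   b$population_n, b$config$threshold_mm),
           sprintf("  %d resamples of %d: mean of means %.0f mm (%.0f-%.0f mm %d%% quantile interval)",
                   b$config$n_reps, b$config$n_per_sample, b$grand_mean,
                   b$ci_low, b$ci_high, round(100 * (1 - b$config$alpha))))
  if (!is.na(b$observed_mean)) {
    out <- c(out, sprintf("  observed consumer mean %.0f mm: %s", b$observed_mean,
                          if (isTRUE(b$outside))
                            paste0("OUTSIDE the interval (", b$direction, ")")
                          else "within the interval"))
  } else {
    out <- c(out, "  no consumer captures in input; comparison skipped")
  }

  out <- c(out, "", "[5] Relative prey mass (RPM)")
  if (!is.null(results$rpm)) {
    r <- results$rpm
    se_txt <- if (is.na(r$se)) "NA (n = 1)" else sprintf("%.1f%%", 100 * r$se)
    out <- c(out, sprintf(
      "  n = %d: mean %.1f%% +/- %s, range %.1f%% - %.1f%%",
      r$n, 100 * r$mean, se_txt, 100 * r$min, 100 * r$max))
  } else {
    out <- c(out, "  no predation-events table supplied; skipped")
  }

  out <- c(out, "", "[6] Prey mass vs predator mass (OLS)")
  if (!is.null(results$ols)) {
    o <- results$ols
    out <- c(out, sprintf(
      "  slope %.4f g prey per g predator (SE %.4f), t(%d) = %.3f, p = %.3f",
      o$slope, o$slope_se, o$df_resid, o$t_value, o$p_value))
  } else {
    out <- c(out, "  skipped (no events table, too few events, or constant predictor)")
  }
  out
}

# Optional figures; requires ggplot2 (Suggests).
write_figures <- function(results, captures, out_dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warning("ggplot2 not available; figures skipped")
    return(invisible(NULL))
  }
  b <- results$bootstrap
  survey <- captures[captures$context == "SURVEY", , drop = FALSE]
  survey <- survey[!duplicated(survey$snake_id), , drop = FALSE]
  consumers <- captures[captures$context == "CONSUMER", , drop = FALSE]
  df <- rbind(data.frame(svl = survey$svl_mm, group = "survey"),
              if (nrow(consumers) > 0)
                data.frame(svl = consumers$svl_mm, group = "consumer"))
  p1 <- ggplot2::ggplot(df, ggplot2::aes(x = svl, fill = group)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            position = "identity", alpha = 0.5, bins = 40) +
    ggplot2::geom_vline(xintercept = b$grand_mean, linetype = "dotted") +
    ggplot2::annotate("rect", xmin = b$ci_low, xmax = b$ci_high,
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::labs(x = "SVL (mm)", y = "density",
                  title = "Survey vs consumer size distributions")
  if (!is.na(b$observed_mean))
    p1 <- p1 + ggplot2::geom_vline(xintercept = b$observed_mean)
  ggplot2::ggsave(file.path(out_dir, "size_distributions.pdf"), p1,
                  width = 7, height = 5)

  m <- results$mortality
  md <- data.frame(cause = names(m$counts), count = unname(m$counts))
  p2 <- ggplot2::ggplot(md, ggplot2::aes(x = cause, y = count)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = "Mortalities by cause", x = NULL, y = "count")
  ggplot2::ggsave(file.path(out_dir, "mortality_causes.pdf"), p2,
                  width = 6, height = 4)

  if (!is.null(results$rpm)) {
    rv <- data.frame(rpm = results$rpm$values)
    p3 <- ggplot2::ggplot(rv, ggplot2::aes(x = rpm)) +
      ggplot2::geom_histogram(bins = 20) +
      ggplot2::geom_vline(xintercept = c(0.2, 0.4, 0.6, 0.8),
                          colour = "grey60") +
      ggplot2::labs(title = "Relative prey mass", x = "RPM", y = "count")
    ggplot2::ggsave(file.path(out_dir, "rpm_histogram.pdf"), p3,
                    width = 6, height = 4)
  }
  invisible(NULL)
}
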