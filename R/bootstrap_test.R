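#' Configuration for the predator-size bootstrap test
#'
#' Defaults mirror the study design: consumers number 52, so each resample
#' draws 52 snakes; 5000 resamples; a 95% quantile interval; the
#' endotherm-attraction threshold at 900 mm SVL. Sampling is with
#' replacement by default, with a without-replacement mode available because
#' "subsampling" is ambiguous between the two.
#'
#' @param threshold_mm Lower SVL bound (strict) for the endotherm-attracted
#'   population, mm.
#' @param n_per_sample Snakes per resample.
#' @param n_reps Number of resamples.
#' @param alpha Two-sided level of the quantile interval.
#' @param replacement Sample with replacement?
#' @param seed Integer seed; every resampling run is reproducible given it.
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(threshold_mm = 900, n_per_sample = 52L,
                             n_reps = 5000L, alpha = 0.05,
                             replacement = TRUE, seed = 1L) {
  stopifnot(threshold_mm > 0, n_per_sample >= 1, n_reps >= 1,
            alpha > 0, alpha < 1, is.logical(replacement))
  structure(list(
    threshold_mm = threshold_mm,
    n_per_sample = as.integer(n_per_sample),
    n_reps = as.integer(n_reps),
    alpha = alpha,
    replacement = replacement,
    seed = as.integer(seed)
  ), class = "bootstrap_config")
}

#' Truncate the survey to endotherm-attracted individuals
#'
#' Reduces survey capture events to one SVL per unique individual — the
#' first capture's measurement, so recaptured snakes are not overweighted —
#' and keeps individuals strictly larger than the threshold ("larger than
#' 900 mm" is a strict inequality; a 900-mm snake is excluded).
#'
#' @param captures Data.frame of capture events with `snake_id`, `event_id`,
#'   `svl_mm` and `context` columns; only `SURVEY` rows are used. Rows are
#'   assumed to be in capture order (first row per snake = first capture).
#' @param threshold_mm Strict lower SVL bound, mm.
#' @return Numeric vector of SVLs, one per qualifying individual.
#' @export
truncate_survey <- function(captures, threshold_mm = 900) {
  stopifnot(is.data.frame(captures),
            all(c("snake_id", "svl_mm", "context") %in% names(captures)))
  survey <- captures[captures$context == "SURVEY", , drop = FALSE]
  first <- survey[!duplicated(survey$snake_id), , drop = FALSE]
  svls <- first$svl_mm[first$svl_mm > threshold_mm]
  if (length(svls) == 0)
    stop("no snakes above threshold (", threshold_mm, " mm)")
  svls
}

#' Bootstrap distribution of the mean SVL
#'
#' Draws `n_reps` samples of `n_per_sample` SVLs from the truncated survey
#' population (with or without replacement per config), records each sample
#' mean, and forms a quantile interval at `alpha/2` and `1 - alpha/2` using
#' order statistics with linear interpolation between closest ranks
#' (`stats::quantile` type 7). Quantile dialects shift these bounds by
#' millimetres, so the definition is recorded in the result. Fully
#' reproducible given `config$seed`.
#'
#' @param svls Numeric vector: one SVL per individual in the truncated
#'   survey population.
#' @param config A [bootstrap_config()].
#' @return A `bootstrap_result` list: `sample_means` (length `n_reps`),
#'   `grand_mean`, `ci_low`, `ci_high`, `quantile_type`, `population_n`,
#'   `config`, plus `observed_mean`/`outside`/`direction` slots filled by
#'   [compare_observed()].
#' @export
bootstrap_mean_distribution <- function(svls, config = bootstrap_config()) {
  stopifnot(inherits(config, "bootstrap_config"))
  svls <- as.numeric(svls)
  if (length(svls) == 0) stop("empty SVL population")
  if (anyNA(svls)) stop("missing SVL values")
  if (!config$replacement && config$n_per_sample > length(svls))
    stop("n_per_sample exceeds population size with replacement = FALSE")

  means <- withr::with_seed(config$seed, {
    if (config$replacement) {
      draws <- sample(svls, config$n_per_sample * config$n_reps,
                      replace = TRUE)
      colMeans(matrix(draws, nrow = config$n_per_sample))
    } else {
      vapply(seq_len(config$n_reps), function(i)
        mean(sample(svls, config$n_per_sample, replace = FALSE)),
        numeric(1))
    }
  })
  ci <- unname(quantile(means, c(config$alpha / 2, 1 - config$alpha / 2),
                        type = 7))
  structure(list(
    sample_means = means,
    grand_mean = mean(means),
    ci_low = ci[1], ci_high = ci[2],
    quantile_type = "order statistics, linear interpolation (type 7)",
    population_n = length(svls),
    config = config,
    observed_mean = NA_real_,
    outside = NA,
    direction = NA_character_
  ), class = "bootstrap_result")
}

#' Compare the observed consumer mean to the bootstrap interval
#'
#' Completes a [bootstrap_mean_distribution()] result with the mean SVL of
#' the snakes captured after successful ingestion (one value per unique
#' individual). The interval is treated as closed: an observed mean exactly
#' on a bound counts as inside, the conservative convention.
#'
#' @param result A `bootstrap_result`.
#' @param consumer_svls Numeric vector of consumer SVLs (per individual).
#' @return The completed `bootstrap_result` with `observed_mean`, `outside`,
#'   and `direction` (`"above"`, `"below"`, or `"within"`).
#' @export
compare_observed <- function(result, consumer_svls) {
  stopifnot(inherits(result, "bootstrap_result"))
  consumer_svls <- as.numeric(consumer_svls)
  if (length(consumer_svls) == 0) stop("no consumer SVLs")
  if (anyNA(consumer_svls)) stop("missing consumer SVL values")
  obs <- mean(consumer_svls)
  result$observed_mean <- obs
  result$outside <- obs < result$ci_low || obs > result$ci_high
  result$direction <- if (obs > result$ci_high) "above"
    else if (obs < result$ci_low) "below" else "within"
  result
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrap of mean SVL: %d samples of %d from %d snakes > %g mm\n",
    x$config$n_reps, x$config$n_per_sample, x$population_n,
    x$config$threshold_mm))
  cat(sprintf("  mean of sample means %.0f mm (%.0f-%.0f mm %d%% quantile interval)\n",
              x$grand_mean, x$ci_low, x$ci_high,
              round(100 * (1 - x$config$alpha))))
  if (!is.na(x$observed_mean))
    cat(sprintf("  observed consumer mean %.0f mm: %s the interval\n",
                x$observed_mean,
                if (isTRUE(x$outside)) paste0("OUTSIDE (", x$direction, ")")
                else "within"))
  invisible(x)
}
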