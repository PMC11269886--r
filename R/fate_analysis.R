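#' Classify the fate of a tracked fledgling from field evidence
#'
#' Deterministic cause-of-mortality assignment for known-fate telemetry.
#' Evidence precedence, highest first:
#'
#' 1. `ALIVE_AT_LAST_CHECK` -> `CENSORED` (fate unresolved, bird alive when
#'    monitoring ended);
#' 2. `IN_SNAKE` or `TRANSMITTER_GUT_PASSED` -> `INGESTED`;
#' 3. `SALIVA_COATED` -> `SLIMED`, *even when cat-scavenging remains are also
#'    present*: a saliva-matted carcass identifies the snake's failed
#'    ingestion attempt as the primary cause of death, and no other predator
#'    leaves that signature;
#' 4. `CARCASS_REMAINS_CAT_PATTERN` -> `CAT` (direct kill or scavenging —
#'    the two are not distinguishable from remains);
#' 5. `OTHER_CAUSE_EVIDENCE` -> `OTHER` (starvation, entanglement, ...);
#' 6. anything else, including an empty set, -> `UNKNOWN`.
#'
#' `IN_SNAKE` together with `SALIVA_COATED` is contradictory (a bird cannot
#' be both swallowed and rejected) and raises an error.
#'
#' @param evidence Character vector of evidence flags (possibly empty).
#' @return One of `"INGESTED"`, `"SLIMED"`, `"CAT"`, `"OTHER"`, `"UNKNOWN"`,
#'   `"CENSORED"`.
#' @examples
#' classify_fate(c("SALIVA_COATED", "CARCASS_REMAINS_CAT_PATTERN"))  # SLIMED
#' classify_fate("TRANSMITTER_GUT_PASSED")                           # INGESTED
#' @export
classify_fate <- function(evidence) {
  evidence <- as.character(evidence)
  bad <- validate_evidence(evidence)
  if (!is.null(bad)) stop(bad)
  if (all(c("IN_SNAKE", "SALIVA_COATED") %in% evidence))
    stop("contradictory evidence: IN_SNAKE and SALIVA_COATED cannot co-occur")
  if ("ALIVE_AT_LAST_CHECK" %in% evidence) return("CENSORED")
  if (any(c("IN_SNAKE", "TRANSMITTER_GUT_PASSED") %in% evidence))
    return("INGESTED")
  if ("SALIVA_COATED" %in% evidence) return("SLIMED")
  if ("CARCASS_REMAINS_CAT_PATTERN" %in% evidence) return("CAT")
  if ("OTHER_CAUSE_EVIDENCE" %in% evidence) return("OTHER")
  "UNKNOWN"
}

#' Tabulate fledgling mortalities by cause
#'
#' Counts dead birds by assigned fate; `CENSORED` records are excluded.
#' Percentages are of total deaths, rounded to the nearest integer for
#' reporting. Snake-attributed mortality is `INGESTED + SLIMED`. The `CAT`
#' category covers cat predation or scavenging, which carcass remains cannot
#' distinguish.
#'
#' @param records Data.frame of fledgling records with a `fate` column
#'   (e.g. `read_fledgling_table(...)$records`).
#' @return A `mortality_table` list: `counts` (named over the five death
#'   causes), `total_dead`, `percentages` (integer-rounded; `NA` and flagged
#'   `undefined` when no deaths), `bts_attributed` and `bts_percent`.
#' @export
mortality_table <- function(records) {
  stopifnot(is.data.frame(records), "fate" %in% names(records))
  fate <- records$fate
  bad <- setdiff(unique(fate), FATE_LEVELS)
  if (length(bad) > 0)
    stop("unknown fate value(s): ", paste(bad, collapse = ", "))
  dead <- fate[fate != "CENSORED"]
  counts <- vapply(DEATH_CAUSES, function(f) sum(dead == f), integer(1))
  total <- length(dead)
  if (total == 0) {
    percentages <- stats::setNames(rep(NA_real_, length(DEATH_CAUSES)),
                                   DEATH_CAUSES)
    undefined <- TRUE
    bts_pct <- NA_real_
  } else {
    percentages <- round(100 * counts / total)
    undefined <- FALSE
    bts_pct <- round(100 * (counts[["INGESTED"]] + counts[["SLIMED"]]) / total)
  }
  structure(list(
    counts = counts,
    total_dead = total,
    percentages = percentages,
    undefined = undefined,
    bts_attributed = unname(counts[["INGESTED"]] + counts[["SLIMED"]]),
    bts_percent = bts_pct
  ), class = "mortality_table")
}

#' @export
print.mortality_table <- function(x, ...) {
  cat(sprintf("Mortalities: %d\n", x$total_dead))
  for (f in DEATH_CAUSES) {
    label <- if (f == "CAT") "CAT (predation or scavenging)" else f
    pct <- if (x$undefined) "--" else sprintf("%d%%", x$percentages[[f]])
    cat(sprintf("  %-30s %4d  %s\n", label, x$counts[[f]], pct))
  }
  if (!x$undefined)
    cat(sprintf("  snake-attributed (ingested+slimed) %d  %d%%\n",
                x$bts_attributed, x$bts_percent))
  invisible(x)
}

#' Ingestion-failure rate with a Wilson score interval
#'
#' The proportion of snake-killed fledglings found slimed (killed but not
#' ingested) among all snake-killed fledglings, with a Wilson score interval.
#' The Wilson interval is used because it behaves well at small counts and
#' near the boundaries and has a closed form:
#' \deqn{\frac{\hat p + z^2/2n \pm z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}
#'       {1 + z^2/n}}
#' with \eqn{z = \Phi^{-1}(1-\alpha/2)}.
#'
#' @param n_slimed Count of unsuccessful ingestion attempts.
#' @param n_ingested Count of successful ingestions.
#' @param alpha Two-sided error level for the interval (default 0.05).
#' @return A `proportion_estimate` list: `numerator`, `denominator`,
#'   `proportion`, `ci_low`, `ci_high`, `ci_method = "WILSON"`, `alpha`.
#' @examples
#' ingestion_failure_rate(82, 89)  # 0.4795, i.e. 47.95%
#' @export
ingestion_failure_rate <- function(n_slimed, n_ingested, alpha = 0.05) {
  stopifnot(length(n_slimed) == 1, length(n_ingested) == 1,
            n_slimed >= 0, n_ingested >= 0,
            n_slimed == round(n_slimed), n_ingested == round(n_ingested),
            alpha > 0, alpha < 1)
  n <- n_slimed + n_ingested
  if (n == 0) stop("no BTS-caused mortalities: both counts are zero")
  p <- n_slimed / n
  ci <- wilson_interval(n_slimed, n, alpha)
  structure(list(
    numerator = as.integer(n_slimed),
    denominator = as.integer(n),
    proportion = p,
    ci_low = ci[1], ci_high = ci[2],
    ci_method = "WILSON",
    alpha = alpha
  ), class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("%d / %d = %.2f%% (Wilson %d%% CI: %.2f%% - %.2f%%)\n",
              x$numerator, x$denominator, 100 * x$proportion,
              round(100 * (1 - x$alpha)), 100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

wilson_interval <- function(k, n, alpha) {
  z <- qnorm(1 - alpha / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # clamp against floating-point overshoot at k = 0 or k = n so the
  # interval always contains the point estimate
  c(min(max(0, centre - half), p), max(min(1, centre + half), p))
}

#' Deduplicate capture events into unique individuals
#'
#' Snakes carry a permanent mark (PIT tag), so a `snake_id` is stable across
#' recaptures while every row is a distinct capture event.
#'
#' @param captures Data.frame of capture events with `snake_id` and
#'   `event_id` columns.
#' @return List with `n_events`, `n_individuals`, `n_recaptures`
#'   (`n_events - n_individuals`) and `recapture_map`, a named list of event
#'   ids per snake in row order.
#' @export
dedup_individuals <- function(captures) {
  stopifnot(is.data.frame(captures),
            all(c("snake_id", "event_id") %in% names(captures)))
  if (anyDuplicated(captures$event_id))
    stop("duplicate event_id in captures")
  recapture_map <- split(as.character(captures$event_id),
                         factor(captures$snake_id,
                                levels = unique(captures$snake_id)))
  list(
    n_events = nrow(captures),
    n_individuals = length(recapture_map),
    n_recaptures = nrow(captures) - length(recapture_map),
    recapture_map = recapture_map
  )
}
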