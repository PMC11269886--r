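#' Read a fledgling telemetry table
#'
#' Parses a comma-delimited table of radio-tracked fledglings into validated
#' records. Required columns are `bird_id`, `mass_g`, and at least one of
#' `fate` or `evidence`. `evidence` holds a `;`-separated set of flags (see
#' [classify_fate()]); when `fate` is missing it is derived from the evidence,
#' and when both are present each row is checked for consistency.
#'
#' Rows that fail row-level validation (non-positive or non-numeric mass,
#' unknown fate token, fate/evidence mismatch) are rejected, not silently
#' dropped: `rows_read = nrow(records) + nrow(rejects)` always holds.
#' A duplicated `bird_id` is an error, since it corrupts identity joins.
#'
#' @param source Path to a CSV file (UTF-8, header row mandatory).
#' @param schema Optional named character vector remapping file column names
#'   to the canonical ones, e.g. `c(bird_id = "band_no")`.
#' @return A list of class `parsed_table` with elements `records` (data.frame:
#'   `bird_id`, `mass_g`, `fate`, `evidence`, `notes`), `rejects` (data.frame:
#'   `row`, `reason`) and `report` (rows read / accepted / rejected).
#' @export
read_fledgling_table <- function(source, schema = NULL) {
  raw <- read_delimited(source, schema,
                        required = c("bird_id", "mass_g"),
                        either = c("fate", "evidence"))
  n <- nrow(raw)
  if (!"fate" %in% names(raw)) raw$fate <- rep(NA_character_, n)
  if (!"evidence" %in% names(raw)) raw$evidence <- rep("", n)
  if (!"notes" %in% names(raw)) raw$notes <- rep("", n)
  raw$evidence[is.na(raw$evidence)] <- ""

  reject <- data.frame(row = integer(), reason = character())
  keep <- rep(TRUE, n)
  mass <- suppressWarnings(as.numeric(raw$mass_g))
  fate <- toupper(trimws(as.character(raw$fate)))
  fate[fate == ""] <- NA_character_

  for (i in seq_len(n)) {
    ev <- parse_evidence(raw$evidence[i])
    bad <- validate_evidence(ev)
    if (is.na(mass[i]) || mass[i] <= 0) {
      reject <- rbind(reject, data.frame(row = i, reason = sprintf(
        "mass_g '%s' is not a positive number", raw$mass_g[i])))
      keep[i] <- FALSE
    } else if (!is.null(bad)) {
      reject <- rbind(reject, data.frame(row = i, reason = bad))
      keep[i] <- FALSE
    } else if (is.na(fate[i]) && nzchar(raw$evidence[i])) {
      fate[i] <- classify_fate(ev)
    } else if (is.na(fate[i])) {
      reject <- rbind(reject, data.frame(
        row = i, reason = "neither fate nor evidence given"))
      keep[i] <- FALSE
    } else if (!fate[i] %in% FATE_LEVELS) {
      reject <- rbind(reject, data.frame(row = i, reason = sprintf(
        "unknown fate token '%s'", fate[i])))
      keep[i] <- FALSE
    } else if (nzchar(raw$evidence[i]) && classify_fate(ev) != fate[i]) {
      reject <- rbind(reject, data.frame(row = i, reason = sprintf(
        "fate '%s' inconsistent with evidence (classifies as '%s')",
        fate[i], classify_fate(ev))))
      keep[i] <- FALSE
    }
  }

  records <- data.frame(
    bird_id = as.character(raw$bird_id)[keep],
    mass_g = mass[keep],
    fate = fate[keep],
    evidence = as.character(raw$evidence)[keep],
    notes = as.character(raw$notes)[keep],
    stringsAsFactors = FALSE
  )
  dup <- unique(records$bird_id[duplicated(records$bird_id)])
  if (length(dup) > 0)
    stop("duplicate bird_id: ", paste(dup, collapse = ", "))
  parsed_table(records, reject, n)
}

#' Read a snake capture-event table
#'
#' Parses a comma-delimited table of snake captures (visual-survey and
#' consumer captures). Required columns: `snake_id`, `event_id`, `svl_mm`,
#' `context`; optional: `mass_g` (empty field = unknown, never 0), `sex`
#' (unknown tokens map to `U`), `date`. A `snake_id` may recur across events
#' (recaptures); `event_id` must be unique.
#'
#' @inheritParams read_fledgling_table
#' @return A `parsed_table` list; `records` has columns `snake_id`,
#'   `event_id`, `svl_mm`, `mass_g`, `sex`, `context`, `date`.
#' @export
read_snake_captures <- function(source, schema = NULL) {
  raw <- read_delimited(source, schema,
                        required = c("snake_id", "event_id", "svl_mm", "context"))
  n <- nrow(raw)
  if (!"mass_g" %in% names(raw)) raw$mass_g <- rep(NA_character_, n)
  if (!"sex" %in% names(raw)) raw$sex <- rep("U", n)
  if (!"date" %in% names(raw)) raw$date <- rep(NA_character_, n)

  reject <- data.frame(row = integer(), reason = character())
  keep <- rep(TRUE, n)
  svl <- suppressWarnings(as.numeric(raw$svl_mm))
  mass <- suppressWarnings(as.numeric(raw$mass_g))
  context <- toupper(trimws(as.character(raw$context)))
  sex <- toupper(trimws(as.character(raw$sex)))
  sex[!sex %in% SEX_LEVELS] <- "U"

  for (i in seq_len(n)) {
    if (is.na(svl[i]) || svl[i] <= 0) {
      reject <- rbind(reject, data.frame(row = i, reason = sprintf(
        "svl_mm '%s' is not a positive number", raw$svl_mm[i])))
      keep[i] <- FALSE
    } else if (!context[i] %in% CONTEXT_LEVELS) {
      reject <- rbind(reject, data.frame(row = i, reason = sprintf(
        "unknown context '%s'", context[i])))
      keep[i] <- FALSE
    } else if (!is.na(raw$mass_g[i]) && nzchar(trimws(as.character(raw$mass_g[i]))) &&
               (is.na(mass[i]) || mass[i] <= 0)) {
      reject <- rbind(reject, data.frame(row = i, reason = sprintf(
        "mass_g '%s' is not a positive number", raw$mass_g[i])))
      keep[i] <- FALSE
    }
  }

  records <- data.frame(
    snake_id = as.character(raw$snake_id)[keep],
    event_id = as.character(raw$event_id)[keep],
    svl_mm = svl[keep],
    mass_g = mass[keep],
    sex = sex[keep],
    context = context[keep],
    date = as.character(raw$date)[keep],
    stringsAsFactors = FALSE
  )
  dup <- unique(records$event_id[duplicated(records$event_id)])
  if (length(dup) > 0)
    stop("duplicate event_id: ", paste(dup, collapse = ", "))
  parsed_table(records, reject, n)
}

#' Read a predation-event table
#'
#' Optional third input linking prey to predators for the RPM analyses.
#' Columns: `bird_ids` (`;`-separated for multi-prey meals), `prey_mass_g`,
#' `outcome` (`INGESTED`/`SLIMED`), and for ingested events `snake_event_id`
#' and `predator_mass_g`. A `SLIMED` row must carry no snake link: snakes that
#' fail to ingest are never located, so predator morphometrics cannot exist
#' for failures.
#'
#' @inheritParams read_fledgling_table
#' @return A `parsed_table` list.
#' @export
read_predation_events <- function(source, schema = NULL) {
  raw <- read_delimited(source, schema,
                        required = c("bird_ids", "prey_mass_g", "outcome"))
  n <- nrow(raw)
  if (!"snake_event_id" %in% names(raw))
    raw$snake_event_id <- rep(NA_character_, n)
  if (!"predator_mass_g" %in% names(raw))
    raw$predator_mass_g <- rep(NA_character_, n)

  reject <- data.frame(row = integer(), reason = character())
  keep <- rep(TRUE, n)
  prey <- suppressWarnings(as.numeric(raw$prey_mass_g))
  pred <- suppressWarnings(as.numeric(raw$predator_mass_g))
  outcome <- toupper(trimws(as.character(raw$outcome)))
  link <- as.character(raw$snake_event_id)
  link[!is.na(link) & !nzchar(trimws(link))] <- NA_character_

  for (i in seq_len(n)) {
    if (is.na(prey[i]) || prey[i] <= 0) {
      reject <- rbind(reject, data.frame(row = i, reason = sprintf(
        "prey_mass_g '%s' is not a positive number", raw$prey_mass_g[i])))
      keep[i] <- FALSE
    } else if (!outcome[i] %in% c("INGESTED", "SLIMED")) {
      reject <- rbind(reject, data.frame(row = i, reason = sprintf(
        "unknown outcome '%s'", outcome[i])))
      keep[i] <- FALSE
    } else if (outcome[i] == "SLIMED" && !is.na(link[i])) {
      reject <- rbind(reject, data.frame(
        row = i, reason = "SLIMED event cannot carry a snake capture link"))
      keep[i] <- FALSE
    }
  }

  records <- data.frame(
    bird_ids = as.character(raw$bird_ids)[keep],
    prey_mass_g = prey[keep],
    outcome = outcome[keep],
    snake_event_id = link[keep],
    predator_mass_g = pred[keep],
    stringsAsFactors = FALSE
  )
  parsed_table(records, reject, n)
}

#' Write result tables and a run manifest
#'
#' Writes each table as one CSV under `dest` and a `manifest.json` recording
#' the seed, the config (plus its md5 hash), per-file md5 checksums and a
#' timestamp. Written tables round-trip through the package readers.
#'
#' @param tables Named list of data.frames.
#' @param dest Output directory (created if needed).
#' @param seed Integer seed the producing analysis ran with, or `NA`.
#' @param config Optional list of run settings, stored verbatim in the
#'   manifest.
#' @return The manifest, invisibly, as a list.
#' @export
write_results <- function(tables, dest, seed = NA_integer_, config = NULL) {
  stopifnot(is.list(tables))
  if (length(tables) > 0 && is.null(names(tables)))
    stop("tables must be named")
  dir.create(dest, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dest)) stop("cannot create destination directory: ", dest)

  files <- character(0)
  for (nm in names(tables)) {
    path <- file.path(dest, paste0(nm, ".csv"))
    write.csv(tables[[nm]], path, row.names = FALSE, na = "")
    files[nm] <- path
  }
  config_hash <- NA_character_
  if (!is.null(config)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
    config_hash <- unname(tools::md5sum(tmp))
  }
  manifest <- list(
    seed = if (is.na(seed)) NULL else as.integer(seed),
    config = config,
    config_hash = config_hash,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = lapply(files, function(f) list(
      path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(dest, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' @export
print.parsed_table <- function(x, ...) {
  cat(sprintf("<parsed_table> %d rows read, %d accepted, %d rejected\n",
              x$report$rows_read, x$report$rows_accepted,
              x$report$rows_rejected))
  invisible(x)
}

# Split a ';'-separated evidence field into a flag vector.
parse_evidence <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  flags <- toupper(trimws(strsplit(x, ";", fixed = TRUE)[[1]]))
  flags[nzchar(flags)]
}

validate_evidence <- function(flags) {
  unknown <- setdiff(flags, EVIDENCE_FLAGS)
  if (length(unknown) > 0)
    return(sprintf("unknown evidence flag '%s'", unknown[1]))
  NULL
}

parsed_table <- function(records, rejects, rows_read) {
  stopifnot(rows_read == nrow(records) + nrow(rejects))
  structure(list(
    records = records,
    rejects = rejects,
    report = list(rows_read = rows_read, rows_accepted = nrow(records),
                  rows_rejected = nrow(rejects))
  ), class = "parsed_table")
}

read_delimited <- function(source, schema, required, either = NULL) {
  if (is.character(source) && !file.exists(source))
    stop("input file not found: ", source)
  raw <- read.csv(source, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (schema[[canon]] %in% names(raw))
        names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0)
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (!is.null(either) && !any(either %in% names(raw)))
    stop("need at least one of columns: ", paste(either, collapse = ", "))
  raw
}
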