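# Reading and writing observation records and rendering estimate reports.
#
# Observation CSV format: optional leading metadata comment lines of the form
# "# key: value" (keys: preservation, nominal_temp_c, collection_time,
# larval_morphology), then a header "landmark_id,status" and one row per
# recorded landmark. A JSON equivalent (fields statuses, preservation,
# nominal_temp_c, collection_time, larval_morphology) is accepted.

.parse_metadata_lines <- function(lines) {
  meta <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    m <- regmatches(body, regexec("^([A-Za-z_]+)\\s*[:=]\\s*(.*)$", body))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  meta
}

#' Read a landmark observation record
#'
#' @param path Path to an observation file; `.json` files are parsed as JSON,
#'   anything else as the metadata-comment CSV format (see package vignette).
#' @param table Optional `staging_table` used to reject unknown landmark ids.
#' @return An [observation_set()].
#' @export
read_observations <- function(path, table = NULL) {
  if (is.null(path) || length(path) != 1 || !is.character(path)) {
    stop_input("an observation file path is required")
  }
  if (!file.exists(path)) stop_input("observation file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    js <- jsonlite::fromJSON(path)
    statuses <- unlist(js$statuses %||% character(0))
    return(observation_set(
      statuses,
      preservation = js$preservation %||% "living",
      nominal_temp_c = js$nominal_temp_c,
      collection_time = js$collection_time,
      larval_morphology = js$larval_morphology %||% "not_assessed",
      table = table
    ))
  }
  lines <- readLines(path, warn = FALSE)
  meta <- .parse_metadata_lines(lines[startsWith(lines, "#")])
  df <- utils::read.csv(text = paste(lines[!startsWith(lines, "#")],
                                     collapse = "\n"),
                        stringsAsFactors = FALSE)
  if (!all(c("landmark_id", "status") %in% names(df))) {
    stop_input("observation CSV must have columns landmark_id,status")
  }
  num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(x)
  observation_set(
    stats::setNames(df$status, df$landmark_id),
    preservation = meta$preservation %||% "living",
    nominal_temp_c = num_or_null(meta$nominal_temp_c),
    collection_time = num_or_null(meta$collection_time),
    larval_morphology = meta$larval_morphology %||% "not_assessed",
    table = table
  )
}

#' Write a landmark observation record as CSV
#'
#' @param obs An [observation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  stopifnot(inherits(obs, "observation_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# preservation: %s", obs$preservation), con)
  if (!is.null(obs$nominal_temp_c)) {
    writeLines(sprintf("# nominal_temp_c: %g", obs$nominal_temp_c), con)
  }
  if (!is.null(obs$collection_time)) {
    writeLines(sprintf("# collection_time: %g", obs$collection_time), con)
  }
  if (obs$larval_morphology != "not_assessed") {
    writeLines(sprintf("# larval_morphology: %s", obs$larval_morphology), con)
  }
  writeLines("landmark_id,status", con)
  if (length(obs$statuses) > 0) {
    writeLines(paste(names(obs$statuses), obs$statuses, sep = ","), con)
  }
  invisible(path)
}

#' Render an age estimate as a self-describing report list
#'
#' Every numeric field carries its units in its name; all modelling warnings
#' (interpolation, clamping, censoring, preservation caveats) present in the
#' estimate are carried through.
#'
#' @param estimate An `age_estimate`.
#' @return A plain list suitable for JSON serialisation.
#' @export
build_report <- function(estimate) {
  stopifnot(inherits(estimate, "age_estimate"))
  labels <- names(estimate$posterior$probabilities)
  list(
    map_interval = estimate$map_interval$label,
    map_interval_index = estimate$map_interval$index,
    posterior = as.list(estimate$posterior$probabilities),
    credible_mass = estimate$credible_mass,
    credible_set = labels[estimate$credible_set + 1L],
    development_proportion_range = estimate$proportion_range,
    age_hours_before_collection = if (is.null(estimate$age_bounds_h)) NULL else
      c(lower = estimate$age_bounds_h$lower_h,
        upper = estimate$age_bounds_h$upper_h),
    adh_degree_hours = if (is.null(estimate$adh_bounds)) NULL else
      c(lower = estimate$adh_bounds[1], upper = estimate$adh_bounds[2]),
    staging_temperature_c = estimate$temp_used,
    censored = estimate$censored,
    warnings = estimate$warnings
  )
}

#' Write an age estimate report
#'
#' @param estimate An `age_estimate`.
#' @param json_path Output path for the JSON report (optional).
#' @param text_path Output path for the human-readable rendering (optional).
#' @return The report list, invisibly.
#' @export
write_report <- function(estimate, json_path = NULL, text_path = NULL) {
  rep <- build_report(estimate)
  if (!is.null(json_path)) {
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  if (!is.null(text_path)) {
    writeLines(utils::capture.output(print(estimate)), text_path)
  }
  invisible(rep)
}
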