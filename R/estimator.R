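# Likelihood-based interval estimation from landmark observations.
#
# Each staging-table cell gives an ordinal visibility category; the estimator
# reads it as a representative presence probability q and scores a recorded
# landmark status as Bernoulli evidence: log q if PRESENT, log(1 - q) if
# ABSENT, nothing if NOT_ASSESSED. Landmark independence given the interval is
# assumed (the calibration reports no joint frequencies). Preservation rules:
# hot-water-killed + ethanol (hwk_ethanol) masks the four landmarks that
# fixation destroys; direct ethanol (ethanol_direct) leaves no landmark
# scorable below the 90% interval and is handled as a censored special case.

OBS_STATUSES <- c("present", "absent", "not_assessed")
PRESERVATION_MODES <- c("living", "hwk_ethanol", "ethanol_direct")

#' Construct a landmark observation set for one egg
#'
#' @param statuses Named character vector mapping landmark ids to
#'   `"present"`, `"absent"` or `"not_assessed"`. Landmarks omitted are
#'   treated as not assessed.
#' @param preservation One of `"living"` (scored alive), `"hwk_ethanol"`
#'   (hot water killed then stored in 80% ethanol) or `"ethanol_direct"`
#'   (placed alive into 80% ethanol).
#' @param nominal_temp_c Effective rearing temperature in degrees Celsius used
#'   to select the staging-table block (optional).
#' @param collection_time Collection time in hours on the temperature
#'   profile's axis (optional; needed for chronological age).
#' @param larval_morphology For `ethanol_direct` samples: whether the
#'   specimen shows the external morphology of a first instar larva
#'   (`"present"`, `"absent"` or `"not_assessed"`).
#' @param table Optional `staging_table`; when supplied, unknown landmark ids
#'   are rejected.
#' @return An object of class `observation_set`.
#' @export
observation_set <- function(statuses = character(0),
                            preservation = "living",
                            nominal_temp_c = NULL,
                            collection_time = NULL,
                            larval_morphology = "not_assessed",
                            table = NULL) {
  statuses <- vapply(statuses, as.character, character(1))
  statuses[] <- tolower(statuses)
  bad <- setdiff(unique(statuses), OBS_STATUSES)
  if (length(bad) > 0) {
    stop_input("unknown landmark status value(s): ", paste(bad, collapse = ", "),
               " (valid: ", paste(OBS_STATUSES, collapse = ", "), ")")
  }
  if (length(statuses) > 0 && (is.null(names(statuses)) ||
                               any(names(statuses) == ""))) {
    stop_input("statuses must be a named vector of landmark ids")
  }
  if (anyDuplicated(names(statuses))) {
    stop_input("duplicate landmark id(s) in statuses")
  }
  preservation <- match.arg(tolower(preservation), PRESERVATION_MODES)
  larval_morphology <- match.arg(tolower(larval_morphology), OBS_STATUSES)
  if (!is.null(table)) {
    unknown <- setdiff(names(statuses), table$landmarks$id)
    if (length(unknown) > 0) {
      stop_input("unknown landmark id(s): ", paste(unknown, collapse = ", "),
                 "; valid ids: ", paste(table$landmarks$id, collapse = ", "))
    }
  }
  if (!is.null(nominal_temp_c) && !is_scalar_number(nominal_temp_c)) {
    stop_input("nominal_temp_c must be a finite number")
  }
  if (!is.null(collection_time) && !is_scalar_number(collection_time)) {
    stop_input("collection_time must be a finite number")
  }
  structure(
    list(statuses = statuses, preservation = preservation,
         nominal_temp_c = nominal_temp_c, collection_time = collection_time,
         larval_morphology = larval_morphology),
    class = "observation_set"
  )
}

#' @export
print.observation_set <- function(x, ...) {
  n_assessed <- sum(x$statuses != "not_assessed")
  cat(sprintf("Observation set: %d landmark(s) recorded (%d assessed), preservation %s\n",
              length(x$statuses), n_assessed, x$preservation))
  if (!is.null(x$nominal_temp_c)) {
    cat("  nominal temperature:", x$nominal_temp_c, "C\n")
  }
  if (!is.null(x$collection_time)) {
    cat("  collection time:", x$collection_time, "h\n")
  }
  if (x$larval_morphology != "not_assessed") {
    cat("  first-instar larval morphology:", x$larval_morphology, "\n")
  }
  invisible(x)
}

#' Default representative presence probabilities per visibility category
#'
#' Point probabilities standing in for the calibration's ordinal frequency
#' classes: the "absent" value is a mis-scoring floor, "rare"/"common"/
#' "prevalent" are representative points inside the `<25%`, `25-75%` and
#' `>75%` frequency ranges.
#'
#' @return Named numeric vector over `absent`, `rare`, `common`, `prevalent`.
#' @export
default_category_probs <- function() {
  c(absent = 0.01, rare = 0.125, common = 0.5, prevalent = 0.875)
}

#' Presence probability of a visibility category
#'
#' @param category Character vector of visibility levels (`"absent"`,
#'   `"rare"`, `"common"`, `"prevalent"`).
#' @param probs Named probability configuration, validated against each
#'   category's admissible frequency range (see Details).
#' @details Admissible configuration ranges: `absent` in (0, 0.05] (the
#'   mis-scoring floor), `rare` in (0, 0.25), `common` in \[0.25, 0.75\],
#'   `prevalent` in (0.75, 1].
#' @return Numeric vector of presence probabilities in (0, 1).
#' @export
category_probability <- function(category, probs = default_category_probs()) {
  validate_category_probs(probs)
  bad <- setdiff(unique(category), VISIBILITY_LEVELS)
  if (length(bad) > 0) {
    stop_input("unknown visibility category: ", paste(bad, collapse = ", "))
  }
  unname(probs[category])
}

validate_category_probs <- function(probs) {
  if (!is.numeric(probs) || !all(VISIBILITY_LEVELS %in% names(probs))) {
    stop_input("category probabilities must be a named numeric vector over ",
               paste(VISIBILITY_LEVELS, collapse = ", "))
  }
  for (lev in VISIBILITY_LEVELS) {
    r <- .category_ranges[[lev]]
    v <- probs[[lev]]
    ok <- if (lev %in% c("absent", "rare")) v > r[1] && v <= r[2] && v < 1
          else v >= r[1] && v <= r[2]
    if (!is.finite(v) || !ok) {
      stop_input("category probability for '", lev, "' (", v,
                 ") is outside its admissible range (",
                 r[1], ", ", r[2], "]")
    }
  }
  invisible(probs)
}

# Pick the calibrated temperature block nearest to temp_c (tie -> the lower,
# slower, forensically conservative temperature). Returns list(chr, temp_c,
# warning or NULL).
.nearest_calibrated <- function(temp_c, table) {
  cal <- table$temperatures
  temps_chr <- dimnames(table$cells)[[3]]
  if (is.null(temp_c)) {
    j <- which.min(cal$temp_c)
    return(list(chr = temps_chr[j], temp_c = cal$temp_c[j],
                warning = sprintf(
                  "no temperature supplied; staging categories taken from the %g C calibration",
                  cal$temp_c[j])))
  }
  d <- abs(cal$temp_c - temp_c)
  j <- which(d == min(d))
  if (length(j) > 1) j <- j[which.min(cal$temp_c[j])]
  warn <- NULL
  if (d[j] > 1e-9) {
    warn <- sprintf("temperature %g C is not calibrated; staging categories taken from nearest calibrated temperature %g C",
                    temp_c, cal$temp_c[j])
  }
  list(chr = temps_chr[j], temp_c = cal$temp_c[j], warning = warn)
}

#' Log-likelihood of each developmental interval given an observation set
#'
#' For each of the eleven intervals, sums `log q` over landmarks recorded
#' present and `log(1 - q)` over landmarks recorded absent, where `q` is the
#' representative presence probability of that landmark's visibility category
#' at that interval. Not-assessed landmarks contribute nothing. Under
#' `hwk_ethanol` preservation the four landmarks destroyed by fixation are
#' forced to not-assessed regardless of how they were recorded. Visibility
#' categories are taken from the calibrated temperature nearest the
#' observation's nominal temperature (tie broken toward the lower
#' temperature).
#'
#' @param obs An [observation_set()]; preservation must not be
#'   `"ethanol_direct"` (those samples carry no landmark information below
#'   the 90% interval; see [estimate_age()]).
#' @param table A `staging_table`.
#' @param category_probs Category probability configuration, see
#'   [category_probability()].
#' @return Numeric vector of 11 log-likelihoods named by interval label, with
#'   attributes `temp_used` (calibrated temperature actually consulted) and
#'   `warnings`.
#' @export
interval_likelihood <- function(obs, table,
                                category_probs = default_category_probs()) {
  stopifnot(inherits(obs, "observation_set"), inherits(table, "staging_table"))
  validate_category_probs(category_probs)
  if (obs$preservation == "ethanol_direct") {
    stop_input("ethanol_direct samples carry no landmark likelihood; use estimate_age()")
  }
  unknown <- setdiff(names(obs$statuses), table$landmarks$id)
  if (length(unknown) > 0) {
    stop_input("unknown landmark id(s): ", paste(unknown, collapse = ", "))
  }
  warnings <- character(0)

  sel <- .nearest_calibrated(obs$nominal_temp_c, table)
  if (!is.null(sel$warning)) warnings <- c(warnings, sel$warning)

  status <- stats::setNames(rep("not_assessed", nrow(table$landmarks)),
                            table$landmarks$id)
  status[names(obs$statuses)] <- obs$statuses
  if (obs$preservation == "hwk_ethanol") {
    masked <- table$landmarks$id[!table$landmarks$hwk_visible]
    recorded <- intersect(masked, names(obs$statuses)[obs$statuses != "not_assessed"])
    if (length(recorded) > 0) {
      warnings <- c(warnings, paste0(
        "hwk_ethanol preservation: ignoring recorded status of non-HWK-visible landmark(s): ",
        paste(recorded, collapse = ", ")))
    }
    status[masked] <- "not_assessed"
  }

  qmat <- matrix(category_probability(table$cells[, , sel$chr], category_probs),
                 nrow = nrow(table$landmarks),
                 dimnames = dimnames(table$cells)[1:2])
  pres <- names(status)[status == "present"]
  abse <- names(status)[status == "absent"]
  ll <- colSums(log(qmat[pres, , drop = FALSE])) +
        colSums(log1p(-qmat[abse, , drop = FALSE]))
  if (length(pres) + length(abse) == 0) {
    warnings <- c(warnings,
                  "no landmark assessed; likelihood is flat over all intervals")
    ll <- stats::setNames(rep(0, 11), table$intervals$label)
  }
  structure(ll, temp_used = sel$temp_c, warnings = warnings)
}

.new_posterior <- function(probabilities, prior, log_likelihoods, labels) {
  structure(
    list(probabilities = stats::setNames(probabilities, labels),
         prior = stats::setNames(prior, labels),
         log_likelihoods = stats::setNames(log_likelihoods, labels)),
    class = "interval_posterior"
  )
}

#' @export
print.interval_posterior <- function(x, digits = 3, ...) {
  cat("Posterior over developmental intervals:\n")
  print(round(x$probabilities, digits))
  invisible(x)
}

# Smallest posterior-mass-ordered credible set reaching cred_mass, extended to
# a contiguous run of intervals (development is monotone; disjoint age sets
# are not actionable). Returns 0-based interval indices.
.credible_set <- function(post, cred_mass) {
  ord <- order(-post, seq_along(post))
  k <- which(cumsum(post[ord]) >= cred_mass - 1e-9)[1]
  if (is.na(k)) k <- length(post)
  sel <- sort(ord[seq_len(k)])
  seq(min(sel), max(sel)) - 1L
}

#' Estimate the developmental interval and age of an egg
#'
#' Combines the interval likelihood with a prior into a posterior over the
#' eleven 10% developmental intervals, reports the MAP interval (ties broken
#' toward the earlier interval, conservative for minimum post-mortem interval
#' use), the smallest contiguous 95% credible set, and converts the credible
#' proportion range into chronological age and ADH bounds through the thermal
#' model.
#'
#' Samples preserved by direct immersion in ethanol are handled specially:
#' below the 90% interval no landmark is diagnosable (such samples decompose
#' markedly), so the estimate is fully censored; if first-instar larval
#' morphology is recorded present the development proportion is bounded to
#' \[0.9, 1.0\].
#'
#' @param obs An [observation_set()].
#' @param table A `staging_table`.
#' @param profile Optional [temperature_profile()] for chronological age
#'   conversion. If omitted and the observation carries a nominal calibrated
#'   temperature, a constant profile spanning one full development duration is
#'   assumed; with no thermal input at all, an interval-only estimate is
#'   returned with a warning.
#' @param prior Prior over the 11 intervals (non-negative, sums to 1);
#'   default uniform.
#' @param cred_mass Credible set mass (default 0.95).
#' @param category_probs Category probability configuration.
#' @param tol Root tolerance for age inversion, hours.
#' @return An object of class `age_estimate`: list with `map_interval`
#'   (list: `index`, `label`), `posterior` (an `interval_posterior`),
#'   `credible_set` (0-based interval indices), `credible_mass`,
#'   `proportion_range`, `age_bounds_h` (an `age_bounds` or `NULL`),
#'   `adh_bounds`, `temp_used`, `censored`, and `warnings`.
#' @examples
#' tab <- load_staging_table()
#' obs <- observation_set(
#'   c(posterior_spiracles = "present", spine_bands = "present",
#'     coil_shaped_gut = "present", fully_developed_tracheal_system = "absent"),
#'   preservation = "living", nominal_temp_c = 7.3, table = tab)
#' est <- estimate_age(obs, tab)
#' est$map_interval$label   # "90%"
#' @export
estimate_age <- function(obs, table, profile = NULL, prior = NULL,
                         cred_mass = 0.95,
                         category_probs = default_category_probs(),
                         tol = 0.01) {
  stopifnot(inherits(obs, "observation_set"), inherits(table, "staging_table"))
  labels <- table$intervals$label
  if (is.null(prior)) prior <- rep(1 / 11, 11)
  if (!is.numeric(prior) || length(prior) != 11 || any(!is.finite(prior)) ||
      any(prior < 0) || abs(sum(prior) - 1) > 1e-6) {
    stop_input("prior must be 11 non-negative probabilities summing to 1")
  }
  if (!is_scalar_number(cred_mass) || cred_mass <= 0 || cred_mass > 1) {
    stop_input("cred_mass must be in (0, 1]")
  }
  warnings <- character(0)
  censored <- FALSE

  if (obs$preservation == "ethanol_direct") {
    censored <- TRUE
    if (obs$larval_morphology == "present") {
      # Larval anatomy survives direct ethanol only from the 90% interval on.
      keep <- c(10, 11)  # 90% and 100% rows
      post <- rep(0, 11)
      post[keep] <- if (sum(prior[keep]) > 0) prior[keep] / sum(prior[keep])
                    else c(0.5, 0.5)
      warnings <- c(warnings, paste0(
        "ethanol_direct preservation: landmarks undiagnosable; estimate based ",
        "solely on first-instar larval morphology (>= 90% of development)"))
      ll <- rep(0, 11)
    } else {
      post <- prior
      warnings <- c(warnings, paste0(
        "ethanol_direct preservation causes marked decomposition: no landmark ",
        "diagnosable below the 90% interval and no larval morphology recorded; ",
        "estimate fully censored. Hot water killing before ethanol storage is ",
        "recommended."))
      ll <- rep(0, 11)
    }
    temp_used <- .nearest_calibrated(obs$nominal_temp_c, table)$temp_c
  } else {
    ll <- interval_likelihood(obs, table, category_probs)
    warnings <- c(warnings, attr(ll, "warnings"))
    temp_used <- attr(ll, "temp_used")
    w <- prior * exp(ll - max(ll))
    if (sum(w) <= 0) {
      stop("internal error: posterior normalisation failed")  # nocov
    }
    post <- w / sum(w)
  }

  map_idx <- which.max(post) - 1L  # first max = earliest interval on ties
  cred <- .credible_set(post, cred_mass)
  prop_range <- c(table$intervals$proportion_lo[min(cred) + 1L],
                  table$intervals$proportion_hi[max(cred) + 1L])

  # Thermal conversion: explicit profile beats nominal constant temperature.
  age_bounds <- NULL
  adh_bounds <- NULL
  collection_time <- obs$collection_time
  if (is.null(profile) && !is.null(obs$nominal_temp_c)) {
    dur <- as.numeric(adh_required(1, obs$nominal_temp_c, table)) /
      max(obs$nominal_temp_c - .table_base(table), .Machine$double.eps)
    profile <- constant_profile(obs$nominal_temp_c, t_start = 0)
    if (is.null(collection_time)) collection_time <- dur
  }
  if (!is.null(profile)) {
    if (is.null(collection_time)) {
      # assume collection the moment the profile could first have produced the
      # most developed credible embryo, so ages are measured over a window
      # long enough to span the credible range
      collection_time <- .time_to_reach(profile, prop_range[2], table)
      warnings <- c(warnings, paste0(
        "no collection time supplied; assuming collection when development ",
        "from the profile start first reaches the credible range"))
    }
    age_bounds <- invert_age(prop_range, profile, collection_time, table,
                             tol = tol)
    if (age_bounds$censored) {
      censored <- TRUE
      warnings <- c(warnings,
                    "age bounds censored at the temperature profile start")
    }
    adh_bounds <- c(
      accumulate_adh(profile, collection_time - age_bounds$lower_h,
                     collection_time, .table_base(table))$adh,
      accumulate_adh(profile, collection_time - age_bounds$upper_h,
                     collection_time, .table_base(table))$adh
    )
    req <- adh_required(1, temp_used, table)
    ew <- attr(req, "extrapolation_warning")
    if (!is.null(ew)) warnings <- c(warnings, ew)
  } else {
    warnings <- c(warnings,
                  "no temperature input: interval-only estimate, chronological age not computed")
  }

  structure(
    list(
      map_interval = list(index = map_idx, label = labels[map_idx + 1L]),
      posterior = .new_posterior(post, prior, as.numeric(ll), labels),
      credible_set = cred,
      credible_mass = cred_mass,
      proportion_range = prop_range,
      age_bounds_h = age_bounds,
      adh_bounds = adh_bounds,
      temp_used = temp_used,
      censored = censored,
      warnings = unique(warnings)
    ),
    class = "age_estimate"
  )
}

#' @export
print.age_estimate <- function(x, ...) {
  cat("Egg age estimate\n")
  cat(sprintf("  MAP developmental interval: %s (index %d)\n",
              x$map_interval$label, x$map_interval$index))
  cat(sprintf("  %.0f%% credible set: %s\n", 100 * x$credible_mass,
              paste0(names(x$posterior$probabilities)[x$credible_set + 1L],
                     collapse = ", ")))
  cat(sprintf("  development proportion: %.0f%% to %.0f%% of the egg stage\n",
              100 * x$proportion_range[1], 100 * x$proportion_range[2]))
  if (!is.null(x$age_bounds_h)) {
    cat(sprintf("  chronological age: %.2f to %.2f h before collection\n",
                x$age_bounds_h$lower_h, x$age_bounds_h$upper_h))
  }
  if (!is.null(x$adh_bounds)) {
    cat(sprintf("  accumulated degree hours: %.1f to %.1f ADH (base %g C)\n",
                x$adh_bounds[1], x$adh_bounds[2], 1))
  }
  if (x$censored) cat("  [censored estimate]\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
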