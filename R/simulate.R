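# Seeded synthetic landmark observations with the statistical structure of the
# staging calibration, for end-to-end validation of the estimator without any
# external data. Per-egg RNG streams are derived from (seed, egg index) so
# cohorts are order-independent and parallel-safe by contract.

.egg_seed <- function(seed, j) {
  (abs(as.integer(seed)) + 7919L * as.integer(j)) %% 2147483647L
}

# Draw one per-landmark presence-probability vector for a run.
.presence_probs <- function(cats, frequency_sampling, seed, category_probs) {
  if (frequency_sampling == "representative") {
    return(stats::setNames(category_probability(cats, category_probs),
                           names(cats)))
  }
  # uniform_in_range: one draw per landmark per run, uniform inside the
  # category's frequency range ("absent" draws inside (0, floor]).
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed((abs(as.integer(seed)) + 104729L) %% 2147483647L)
  q <- vapply(cats, function(lev) {
    r <- .category_ranges[[lev]]
    if (lev == "absent") r <- c(0, category_probs[["absent"]])
    stats::runif(1, r[1], r[2])
  }, numeric(1))
  stats::setNames(q, names(cats))
}

.simulate_one_egg <- function(q, table, preservation, true_interval,
                              temp_c, seed, j) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(.egg_seed(seed, j))
  drawn <- stats::runif(length(q)) < q
  statuses <- stats::setNames(ifelse(drawn, "present", "absent"), names(q))
  larval <- "not_assessed"
  if (preservation == "hwk_ethanol") {
    statuses[table$landmarks$id[!table$landmarks$hwk_visible]] <- "not_assessed"
  } else if (preservation == "ethanol_direct") {
    # Marked decomposition: no landmark scorable; only first-instar larval
    # anatomy survives, and only from the 90% interval onwards.
    statuses[] <- "not_assessed"
    larval <- if (true_interval >= 9) "present" else "not_assessed"
  }
  observation_set(statuses, preservation = preservation,
                  nominal_temp_c = temp_c, larval_morphology = larval,
                  table = table)
}

#' Simulate landmark observations at a known developmental interval
#'
#' For each egg and landmark, presence is drawn Bernoulli(q), where q is the
#' landmark's category presence probability at the true interval and
#' temperature — the representative point value
#' (`frequency_sampling = "representative"`) or a run-level draw uniform
#' within the category's frequency range (`"uniform_in_range"`). Preservation
#' post-processing then applies the same observability rules the estimator
#' assumes: `hwk_ethanol` sets the four non-HWK-visible landmarks to
#' not-assessed; `ethanol_direct` wipes all landmark scores and records
#' first-instar larval morphology as present only when the true interval is
#' at or beyond 90%.
#'
#' @param true_interval True interval index, integer in 0..10.
#' @param temp_c A calibrated temperature (7.3 or 25 for the packaged table).
#' @param preservation Preservation mode, see [observation_set()].
#' @param n_eggs Number of eggs to simulate.
#' @param seed Integer seed; identical configuration and seed reproduce the
#'   output exactly, and egg `j`'s draws do not depend on `n_eggs`.
#' @param frequency_sampling `"representative"` or `"uniform_in_range"`.
#' @param table A `staging_table`.
#' @param category_probs Category probability configuration.
#' @return List of [observation_set()] objects, with attributes
#'   `true_interval`, `seed`, and `presence_probs` (the q vector used).
#' @examples
#' tab <- load_staging_table()
#' obs <- simulate_observation(5, 25, n_eggs = 3, seed = 1, table = tab)
#' @export
simulate_observation <- function(true_interval, temp_c,
                                 preservation = "living",
                                 n_eggs = 1, seed = 1L,
                                 frequency_sampling = c("representative",
                                                        "uniform_in_range"),
                                 table = load_staging_table(),
                                 category_probs = default_category_probs()) {
  frequency_sampling <- match.arg(frequency_sampling)
  preservation <- match.arg(tolower(preservation), PRESERVATION_MODES)
  if (!is_scalar_number(true_interval) || true_interval %% 1 != 0 ||
      true_interval < 0 || true_interval > 10) {
    stop_input("true_interval must be an integer in 0..10")
  }
  if (!is_scalar_number(n_eggs) || n_eggs < 1 || n_eggs %% 1 != 0) {
    stop_input("n_eggs must be a positive integer")
  }
  if (!is_scalar_number(seed)) stop_input("seed must be a single integer")
  cal <- table$temperatures
  if (min(abs(cal$temp_c - temp_c)) > 1e-9) {
    stop_input("temp_c must be one of the calibrated temperatures: ",
               paste(cal$temp_c, collapse = ", "))
  }
  validate_category_probs(category_probs)

  sel <- .nearest_calibrated(temp_c, table)
  cats <- table$cells[, true_interval + 1L, sel$chr]
  q <- .presence_probs(cats, frequency_sampling, seed, category_probs)

  eggs <- lapply(seq_len(n_eggs), function(j) {
    obs <- .simulate_one_egg(q, table, preservation, true_interval,
                             temp_c, seed, j)
    attr(obs, "true_interval") <- as.integer(true_interval)
    obs
  })
  attr(eggs, "true_interval") <- as.integer(true_interval)
  attr(eggs, "seed") <- as.integer(seed)
  attr(eggs, "presence_probs") <- q
  eggs
}

#' Simulate a cohort laid at a known time under a temperature history
#'
#' End-to-end driver: advances development from oviposition to collection
#' through the thermal model, maps the reached proportion to its containing
#' 10% interval (half-open bins `[i/10, (i+1)/10)`, with 1.0 mapped to the
#' 100% interval), and simulates landmark observations there. Eggs whose
#' development reached 1.0 strictly before the collection time are flagged
#' hatched.
#'
#' @param oviposition_time Oviposition time in hours on the profile's axis.
#' @param profile A [temperature_profile()].
#' @param collection_time Collection time in hours; must not precede
#'   oviposition.
#' @param n_eggs Number of eggs.
#' @param seed Integer seed.
#' @param table A `staging_table`.
#' @param preservation Preservation mode applied to every egg.
#' @param frequency_sampling See [simulate_observation()].
#' @param jitter_sd Optional Gaussian jitter (standard deviation, on the
#'   proportion scale) applied per egg to the reached proportion, for
#'   robustness studies. Default 0: the calibration quantifies no
#'   inter-individual developmental variance, so none is simulated.
#' @param category_probs Category probability configuration.
#' @return List of [observation_set()] objects; each carries attributes
#'   `true_interval`, `proportion` and `hatched`. The list carries
#'   `proportion` (the cohort-level proportion before jitter) and
#'   `hatch_time_h`.
#' @examples
#' tab <- load_staging_table()
#' sim <- simulate_cohort_timeline(0, constant_profile(25), 8,
#'                                 n_eggs = 2, seed = 1, table = tab)
#' attr(sim[[1]], "true_interval")   # 5 (the 50% interval)
#' @export
simulate_cohort_timeline <- function(oviposition_time, profile,
                                     collection_time, n_eggs = 1, seed = 1L,
                                     table = load_staging_table(),
                                     preservation = "living",
                                     frequency_sampling = "representative",
                                     jitter_sd = 0,
                                     category_probs = default_category_probs()) {
  stopifnot(inherits(profile, "temperature_profile"))
  if (!is_scalar_number(oviposition_time) || !is_scalar_number(collection_time)) {
    stop_input("oviposition_time and collection_time must be finite numbers")
  }
  if (oviposition_time > collection_time) {
    stop_input("oviposition_time must not exceed collection_time")
  }
  if (!is_scalar_number(jitter_sd) || jitter_sd < 0) {
    stop_input("jitter_sd must be a non-negative number")
  }
  preservation <- match.arg(tolower(preservation), PRESERVATION_MODES)

  adv <- advance_development(profile, oviposition_time, collection_time, table)
  p0 <- as.numeric(adv)
  t_hatch <- attr(adv, "hatch_time_h")

  # Effective temperature for category lookup: time-mean temperature above
  # base over the window, recovered from the ADH ledger (equals the incubator
  # temperature for constant profiles).
  base <- .table_base(table)
  window_h <- collection_time - oviposition_time
  mean_temp <- if (window_h > 0) {
    base + accumulate_adh(profile, oviposition_time, collection_time,
                          base)$adh / window_h
  } else {
    .temp_at(profile, max(oviposition_time, profile$time_h[1]))
  }
  sel <- .nearest_calibrated(mean_temp, table)

  eggs <- lapply(seq_len(n_eggs), function(j) {
    p_j <- p0
    if (jitter_sd > 0) {
      old <- globalenv()$.Random.seed
      set.seed((.egg_seed(seed, j) + 31L) %% 2147483647L)
      p_j <- min(1, max(0, p0 + stats::rnorm(1, 0, jitter_sd)))
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }
    interval_j <- min(10L, as.integer(floor(p_j * 10 + 1e-9)))
    cats <- table$cells[, interval_j + 1L, sel$chr]
    q <- .presence_probs(cats, frequency_sampling, seed, category_probs)
    obs <- .simulate_one_egg(q, table, preservation, interval_j,
                             sel$temp_c, seed, j)
    obs$collection_time <- collection_time
    attr(obs, "true_interval") <- interval_j
    attr(obs, "proportion") <- p_j
    attr(obs, "hatched") <- isTRUE(p_j >= 1 && !is.na(t_hatch) &&
                                     t_hatch < collection_time - 1e-9)
    obs
  })
  attr(eggs, "proportion") <- p0
  attr(eggs, "hatch_time_h") <- t_hatch
  attr(eggs, "seed") <- as.integer(seed)
  eggs
}
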