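test_that("category probabilities default to the representative points and validate ranges", {
  expect_equal(category_probability(c("absent", "rare", "common", "prevalent")),
               c(0.01, 0.125, 0.5, 0.875))
  # configurable within each category's frequency range
  probs <- c(absent = 0.02, rare = 0.2, common = 0.3, prevalent = 0.9)
  expect_equal(category_probability("common", probs), 0.3)
  expect_error(
    category_probability("common", c(absent = 0.01, rare = 0.125,
                                     common = 0.8, prevalent = 0.875)),
    class = "eggclock_input_error")
  expect_error(
    category_probability("rare", c(absent = 0.01, rare = 0.3,
                                   common = 0.5, prevalent = 0.875)),
    class = "eggclock_input_error")
  expect_error(category_probability("sometimes"), class = "eggclock_input_error")
})

test_that("observation sets validate statuses and landmark ids", {
  tab <- the_table()
  expect_error(observation_set(c(cephalic_furrow = "maybe")),
               class = "eggclock_input_error")
  expect_error(observation_set(c(not_a_landmark = "present"), table = tab),
               "not_a_landmark", class = "eggclock_input_error")
  obs <- observation_set(c(cephalic_furrow = "PRESENT"), table = tab)
  expect_equal(unname(obs$statuses["cephalic_furrow"]), "present")
})

test_that("interval likelihood matches a brute-force enumeration from the raw CSV", {
  tab <- the_table()
  cases <- list(
    list(statuses = c(bright_peripheral_ring = "present"), temp = 25),
    list(statuses = c(posterior_spiracles = "present", spine_bands = "present",
                      coil_shaped_gut = "present",
                      fully_developed_tracheal_system = "absent"), temp = 7.3),
    list(statuses = c(cephalic_furrow = "present", dorsal_folds = "present",
                      clear_gaps = "absent"), temp = 7.3),
    list(statuses = c(stomodeal_invagination = "present",
                      thoracic_segmentation = "absent",
                      clypeolabrum = "not_assessed"), temp = 25)
  )
  for (cs in cases) {
    obs <- observation_set(cs$statuses, nominal_temp_c = cs$temp, table = tab)
    ll <- interval_likelihood(obs, tab)
    expect_equal(as.numeric(ll), brute_loglik(as.list(cs$statuses), cs$temp),
                 tolerance = 1e-12)
  }
})

test_that("signature observations recover the expected intervals", {
  tab <- the_table()
  # bright peripheral ring alone, everything else absent, living, 25 C
  obs <- full_observation("bright_peripheral_ring", tab, nominal_temp_c = 25)
  ll <- interval_likelihood(obs, tab)
  expect_equal(names(which.max(ll)), "20%")
  # late-development signature at 7.3 C points at the 90% interval
  obs90 <- observation_set(
    c(posterior_spiracles = "present", spine_bands = "present",
      coil_shaped_gut = "present", fully_developed_tracheal_system = "absent"),
    nominal_temp_c = 7.3, table = tab)
  ll90 <- interval_likelihood(obs90, tab)
  expect_equal(which.max(brute_loglik(as.list(obs90$statuses), 7.3)), 10L)
  expect_equal(names(which.max(ll90)), "90%")
})

test_that("no assessed landmark yields a flat likelihood with a warning", {
  tab <- the_table()
  obs <- observation_set(c(cephalic_furrow = "not_assessed"),
                         nominal_temp_c = 25, table = tab)
  ll <- interval_likelihood(obs, tab)
  expect_equal(as.numeric(ll), rep(0, 11))
  expect_match(paste(attr(ll, "warnings"), collapse = " "), "no landmark")
})

test_that("posterior is normalized and equals the prior under a flat likelihood", {
  tab <- the_table()
  flat <- observation_set(character(0), nominal_temp_c = 25, table = tab)
  est <- estimate_age(flat, tab)
  expect_equal(sum(est$posterior$probabilities), 1, tolerance = 1e-9)
  expect_equal(as.numeric(est$posterior$probabilities), rep(1 / 11, 11))
  expect_equal(est$credible_set, 0:10)   # no evidence: all intervals
  prior <- c(0.3, 0.2, 0.1, 0.1, 0.1, 0.05, 0.05, 0.04, 0.03, 0.02, 0.01)
  est2 <- estimate_age(flat, tab, prior = prior)
  expect_equal(as.numeric(est2$posterior$probabilities), prior)
  # normalization holds for informative observations too
  obs <- full_observation(c("cephalic_furrow", "dorsal_folds"), tab,
                          nominal_temp_c = 7.3)
  expect_equal(sum(estimate_age(obs, tab)$posterior$probabilities), 1,
               tolerance = 1e-9)
  expect_error(estimate_age(flat, tab, prior = rep(1, 11)),
               class = "eggclock_input_error")
})

test_that("single-landmark posterior equals the hand-computed Bayes normalization", {
  tab <- the_table()
  for (lm in c("cephalic_furrow", "coil_shaped_gut", "clear_gaps")) {
    for (status in c("present", "absent")) {
      obs <- observation_set(stats::setNames(status, lm),
                             nominal_temp_c = 7.3, table = tab)
      est <- estimate_age(obs, tab)
      q <- vapply(seq_len(11), function(k) {
        q_from_symbol(raw_calibration()[
          raw_calibration()$landmark_id == lm &
            as.numeric(raw_calibration()$temp_c) == 7.3,
          paste0("cat_", (k - 1) * 10)])
      }, numeric(1))
      lik <- if (status == "present") q else 1 - q
      expect_equal(as.numeric(est$posterior$probabilities), lik / sum(lik),
                   tolerance = 1e-12, label = paste(lm, status))
    }
  }
})

test_that("HWK masking makes the four fixation-destroyed landmarks uninformative", {
  tab <- the_table()
  masked <- tab$landmarks$id[!tab$landmarks$hwk_visible]
  core <- c(posterior_spiracles = "present", spine_bands = "present",
            coil_shaped_gut = "present")
  variants <- lapply(c("present", "absent", "not_assessed"), function(s) {
    observation_set(c(core, stats::setNames(rep(s, length(masked)), masked)),
                    preservation = "hwk_ethanol", nominal_temp_c = 7.3,
                    table = tab)
  })
  posts <- lapply(variants, function(o)
    as.numeric(estimate_age(o, tab)$posterior$probabilities))
  expect_equal(posts[[1]], posts[[2]], tolerance = 1e-12)
  expect_equal(posts[[2]], posts[[3]], tolerance = 1e-12)
  # and differs from the living posterior where those landmarks count
  living <- observation_set(
    c(core, stats::setNames(rep("absent", length(masked)), masked)),
    preservation = "living", nominal_temp_c = 7.3, table = tab)
  expect_false(isTRUE(all.equal(
    posts[[1]], as.numeric(estimate_age(living, tab)$posterior$probabilities))))
})

test_that("MAP ties break toward the earlier interval", {
  tab <- the_table()
  # spine bands and posterior spiracles have identical cells at 90% and 100%
  obs <- observation_set(c(spine_bands = "present",
                           posterior_spiracles = "present"),
                         nominal_temp_c = 7.3, table = tab)
  est <- estimate_age(obs, tab)
  p <- est$posterior$probabilities
  expect_equal(unname(p["90%"]), unname(p["100%"]), tolerance = 1e-12)
  expect_equal(est$map_interval$label, "90%")
})

test_that("credible sets are contiguous and carry consistent proportion ranges", {
  tab <- the_table()
  obs <- full_observation(c("stomodeal_invagination", "thoracic_segmentation",
                            "clypeolabrum"), tab, nominal_temp_c = 25)
  est <- estimate_age(obs, tab)
  expect_true(all(diff(est$credible_set) == 1) || length(est$credible_set) == 1)
  expect_true(est$map_interval$index %in% est$credible_set)
  expect_equal(est$proportion_range[1], min(est$credible_set) / 10)
  expect_equal(est$proportion_range[2], min(1, (max(est$credible_set) + 1) / 10))
  expect_true(sum(est$posterior$probabilities[est$credible_set + 1]) >= 0.95 - 1e-9)
})

test_that("age and ADH bounds follow the credible proportion range through the thermal model", {
  tab <- the_table()
  obs <- observation_set(
    c(posterior_spiracles = "present", spine_bands = "present",
      coil_shaped_gut = "present", fully_developed_tracheal_system = "absent"),
    preservation = "living", nominal_temp_c = 7.3, table = tab)
  est <- estimate_age(obs, tab)
  expect_equal(est$map_interval$label, "90%")
  expect_equal(est$proportion_range, c(0.9, 1.0))
  expect_gte(est$age_bounds_h$lower_h, 108 - 0.011)
  expect_lte(est$age_bounds_h$upper_h, 120 + 0.011)
  expect_equal(est$adh_bounds, c(680.4, 756), tolerance = 0.01)
  # explicit profile route agrees with the nominal-temperature route
  est2 <- estimate_age(obs, tab, profile = constant_profile(7.3))
  expect_equal(est2$age_bounds_h$lower_h, est$age_bounds_h$lower_h,
               tolerance = 0.02)
})

test_that("estimates without thermal input are interval-only with a warning", {
  tab <- the_table()
  obs <- observation_set(c(cephalic_furrow = "present"), table = tab)
  est <- estimate_age(obs, tab)
  expect_null(est$age_bounds_h)
  expect_match(paste(est$warnings, collapse = " "), "interval-only")
})

test_that("direct-ethanol samples are censored per the preservation findings", {
  tab <- the_table()
  # below 90%: nothing diagnosable, fully censored
  ed <- observation_set(character(0), preservation = "ethanol_direct",
                        nominal_temp_c = 7.3)
  est <- estimate_age(ed, tab)
  expect_true(est$censored)
  expect_equal(est$proportion_range, c(0, 1))
  expect_equal(est$credible_set, 0:10)
  expect_match(paste(est$warnings, collapse = " "), "decomposition")
  # at/after 90%: first-instar larval morphology bounds development to [0.9, 1]
  edl <- observation_set(character(0), preservation = "ethanol_direct",
                         larval_morphology = "present", nominal_temp_c = 7.3)
  estl <- estimate_age(edl, tab)
  expect_true(estl$censored)
  expect_equal(estl$proportion_range, c(0.9, 1.0))
  expect_equal(estl$map_interval$label, "90%")
  expect_equal(sum(estl$posterior$probabilities), 1, tolerance = 1e-9)
  expect_equal(estl$age_bounds_h$lower_h, 108, tolerance = 0.011)
  expect_equal(estl$age_bounds_h$upper_h, 120, tolerance = 0.011)
})

test_that("non-calibrated temperatures use the nearest block and warn; ties go cold", {
  tab <- the_table()
  obs <- observation_set(c(cephalic_furrow = "present"),
                         nominal_temp_c = 20, table = tab)
  ll <- interval_likelihood(obs, tab)
  expect_equal(attr(ll, "temp_used"), 25)
  expect_match(paste(attr(ll, "warnings"), collapse = " "), "nearest")
  mid <- (7.3 + 25) / 2
  obs_mid <- observation_set(c(cephalic_furrow = "present"),
                             nominal_temp_c = mid, table = tab)
  expect_equal(attr(interval_likelihood(obs_mid, tab), "temp_used"), 7.3)
})
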