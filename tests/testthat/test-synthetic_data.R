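test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(n_fledglings = 0), "n_fledglings")
  expect_error(synthetic_config(fledgling_mass_range_g = c(86, 60)))
  expect_error(synthetic_config(cause_probs = c(INGESTED = 1)), "cause_probs")
  expect_error(synthetic_config(fledgling_mass_mean_g = 500),
               "range excludes")
  expect_error(synthetic_config(attraction_threshold_mm = 5000),
               "above the attraction threshold")
})

test_that("the snake population is deterministic, sized, and in range", {
  cfg <- synthetic_config(seed = 3L)
  sn1 <- simulate_snake_population(cfg)
  sn2 <- simulate_snake_population(cfg)
  expect_identical(sn1, sn2)

  d <- dedup_individuals(sn1)
  expect_equal(d$n_individuals, 265)
  expect_gte(d$n_events, d$n_individuals)
  first <- sn1[!duplicated(sn1$snake_id), ]
  expect_true(all(first$svl_mm >= 288 & first$svl_mm <= 1989))
  expect_true(all(sn1$mass_g > 0))
  expect_true(all(sn1$context == "SURVEY"))

  # no recaptures when the rate is zero
  sn0 <- simulate_snake_population(synthetic_config(recapture_rate = 0,
                                                    seed = 3L))
  d0 <- dedup_individuals(sn0)
  expect_equal(d0$n_events, d0$n_individuals)
})

test_that("survey SVL calibration holds at large n", {
  # pool several independent populations so a single extreme draw cannot
  # dominate the calibration check
  svls <- unlist(lapply(1:5, function(s)
    simulate_snake_population(
      synthetic_config(n_survey_snakes = 10000L, recapture_rate = 0,
                       seed = s))$svl_mm))
  se <- sd(svls) / sqrt(length(svls))
  expect_lt(abs(mean(svls) - 933), 3 * se)
})

test_that("the fledgling cohort respects the mass truncation and is reproducible", {
  cfg <- synthetic_config(seed = 9L)
  fl1 <- simulate_fledgling_cohort(cfg)
  expect_identical(fl1, simulate_fledgling_cohort(cfg))
  expect_equal(nrow(fl1), 461)
  expect_true(all(fl1$mass_g >= 60.5 & fl1$mass_g <= 86.3))
  expect_true(all(fl1$fate %in% c("INGESTED", "SLIMED", "CAT", "OTHER",
                                  "UNKNOWN", "CENSORED")))
})

test_that("generated evidence always classifies back to the generated fate", {
  fl <- simulate_fledgling_cohort(synthetic_config(seed = 23L))
  refate <- vapply(fl$evidence,
                   function(e) classify_fate(strsplit(e, ";")[[1]]),
                   character(1), USE.NAMES = FALSE)
  expect_identical(refate, fl$fate)
})

test_that("generated tables pass the readers with zero rejects", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(seed = 31L)
  sim <- run_simulation(cfg, dir)
  fl <- read_fledgling_table(file.path(dir, "fledglings.csv"))
  sn <- read_snake_captures(file.path(dir, "snakes.csv"))
  ev <- read_predation_events(file.path(dir, "events.csv"))
  expect_equal(fl$report$rows_rejected, 0)
  expect_equal(sn$report$rows_rejected, 0)
  expect_equal(ev$report$rows_rejected, 0)
  expect_equal(fl$report$rows_accepted, 461)
})

test_that("slimed events carry no predator data, ingested ones are consistent", {
  cfg <- synthetic_config(seed = 41L)
  sn <- simulate_snake_population(cfg)
  fl <- simulate_fledgling_cohort(cfg)
  sim <- simulate_predation_events(cfg, sn, fl)
  ev <- sim$events

  slimed <- ev[ev$outcome == "SLIMED", ]
  expect_true(all(is.na(slimed$snake_event_id)))
  expect_true(all(is.na(slimed$predator_mass_g)))

  # every snake-killed bird appears in exactly one event
  ids <- unlist(strsplit(ev$bird_ids, ";"))
  expect_setequal(ids, fl$bird_id[fl$fate %in% c("INGESTED", "SLIMED")])
  expect_false(any(duplicated(ids)))

  # event prey mass equals the sum of the linked birds' masses
  mass_of <- stats::setNames(fl$mass_g, fl$bird_id)
  sums <- vapply(strsplit(ev$bird_ids, ";"),
                 function(b) sum(mass_of[b]), numeric(1))
  expect_equal(ev$prey_mass_g, sums)

  # linked predator masses match the consumer capture rows
  linked <- ev[!is.na(ev$snake_event_id), ]
  cc <- sim$consumer_captures
  expect_equal(linked$predator_mass_g,
               cc$mass_g[match(linked$snake_event_id, cc$event_id)])
  expect_true(all(cc$svl_mm > cfg$attraction_threshold_mm))

  # RPM recomputed per event agrees with compute_rpm
  for (i in which(!is.na(ev$predator_mass_g))[1:5]) {
    expect_equal(compute_rpm(ev[i, ]),
                 ev$prey_mass_g[i] / ev$predator_mass_g[i])
  }
})

test_that("size-selective ingestion makes consumers larger than the attacked pool", {
  cfg <- synthetic_config(seed = 53L)
  sn <- simulate_snake_population(cfg)
  fl <- simulate_fledgling_cohort(cfg)
  sim <- simulate_predation_events(cfg, sn, fl)
  pool <- truncate_survey(sn, cfg$attraction_threshold_mm)
  cons <- sim$consumer_captures
  expect_gt(mean(cons$svl_mm[!duplicated(cons$snake_id)]), mean(pool))
})

test_that("with no prey-mass effect the GLM recovers a null slope at nominal rate", {
  # type-I calibration of the whole cohort->GLM path over replicates
  n_reps <- 200
  rejected <- vapply(seq_len(n_reps), function(r) {
    fl <- simulate_fledgling_cohort(synthetic_config(seed = 7000L + r))
    birds <- fl[fl$fate %in% c("INGESTED", "SLIMED"), ]
    fit <- fit_logistic(as.integer(birds$fate == "INGESTED"), birds$mass_g)
    abs(fit$z_values[["slope"]]) > qnorm(0.975)
  }, logical(1))
  rate <- mean(rejected)
  # Monte-Carlo tolerance at 200 replicates
  expect_lt(abs(rate - 0.05), 0.05)
})

test_that("end to end, the pipeline recovers the generating structure", {
  # slimed fraction near its configured value and consumers flagged larger
  # in the majority of replicates (the size tilt the generator encodes
  # gives ~0.8 detection probability at this design size)
  n_reps <- 100
  outside_above <- logical(n_reps)
  frac <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- synthetic_config(seed = 9000L + r)
    sn <- simulate_snake_population(cfg)
    fl <- simulate_fledgling_cohort(cfg)
    sim <- simulate_predation_events(cfg, sn, fl)
    frac[r] <- mean(fl$fate[fl$fate %in% c("INGESTED", "SLIMED")] == "SLIMED")
    svls <- truncate_survey(sn, cfg$attraction_threshold_mm)
    cons <- sim$consumer_captures
    cons <- cons[!duplicated(cons$snake_id), ]
    res <- compare_observed(
      bootstrap_mean_distribution(svls, bootstrap_config(n_reps = 1000,
                                                         seed = 9500L + r)),
      cons$svl_mm)
    outside_above[r] <- isTRUE(res$outside) && res$direction == "above"
  }
  expect_lt(abs(mean(frac) - 82 / 171), 0.03)
  expect_gte(mean(outside_above), 0.6)
})
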