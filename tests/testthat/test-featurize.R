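test_that("window assignment follows the backward 120-day grid", {
  cfg <- window_config()
  idx <- as.Date("2016-06-01")
  expect_identical(assign_window(idx - 10, idx, cfg), 4L)
  expect_identical(assign_window(idx - 119, idx, cfg), 4L)
  expect_identical(assign_window(idx - 120, idx, cfg), 3L)
  expect_identical(assign_window(idx - 130, idx, cfg), 3L)
  expect_identical(assign_window(idx - 479, idx, cfg), 1L)
  expect_identical(assign_window(idx - 480, idx, cfg), NA_integer_)
  expect_identical(assign_window(idx, idx, cfg), NA_integer_)
  cfg2 <- window_config(include_index_day = TRUE)
  expect_identical(assign_window(idx, idx, cfg2), 4L)
  expect_error(assign_window(idx + 1, idx, cfg), "leakage")
})

test_that("a shorter lookback cap discards the oldest windows", {
  cfg <- window_config(lookback_cap_days = 365)
  idx <- as.Date("2016-06-01")
  expect_identical(assign_window(idx - 364, idx, cfg), 1L)
  expect_identical(assign_window(idx - 365, idx, cfg), NA_integer_)
})

test_that("window reduction keeps the most recent value, table order on ties", {
  d <- as.Date("2016-01-01")
  expect_identical(reduce_window(c(12, 7), c(d - 100, d - 40)), 7)
  expect_identical(reduce_window(numeric(0), as.Date(character(0))), NA_real_)
  expect_identical(reduce_window(c(3, 8), c(d, d)), 8)
})

test_that("medication encoding uses only the first occurrence", {
  cfg <- window_config()
  schema <- feature_schema(cfg)
  idx <- as.Date("2016-06-01")
  ev <- data.frame(date = idx - c(130, 10), med_code = "DMARD_02",
                   stringsAsFactors = FALSE)
  m <- encode_medications(ev, idx, cfg, schema)
  expect_identical(unname(m[3, "DMARD_02"]), 1L)
  expect_identical(unname(m[4, "DMARD_02"]), 0L)
  expect_identical(sum(m), 1L)

  old <- data.frame(date = idx - 500, med_code = "DMARD_02", stringsAsFactors = FALSE)
  expect_identical(sum(encode_medications(old, idx, cfg, schema)), 0L)
  none <- data.frame(date = as.Date(character(0)), med_code = character(0))
  expect_identical(sum(encode_medications(none, idx, cfg, schema)), 0L)

  cfg_cf <- window_config(carry_forward_meds = TRUE)
  mc <- encode_medications(ev, idx, cfg_cf, feature_schema(cfg_cf))
  expect_identical(unname(mc[, "DMARD_02"]), c(0L, 0L, 1L, 1L))
})

test_that("a patient with no labs featurizes to sentinel-filled lab cells, 165 columns", {
  tb <- make_patient_tables()
  tb$labs <- tb$labs[0, ]
  # lab criterion must still pass for cohort membership: relax rules here
  co <- build_cohort(make_patient_tables())
  fx <- featurize_cohort(co, tb)
  expect_identical(ncol(fx$flat), 165L)
  expect_true(all(fx$flat[, grep("^(esr|crp)@", colnames(fx$flat))] == 0))
  expect_identical(unname(fx$static[1, "age"]),
                   as.numeric(format(co$index_date, "%Y")) - 1960)
})

test_that("vectorized featurization equals the brute-force per-event oracle", {
  sim <- generate_ehr(hospital_profile("university", n_patients = 60, seed = 19))
  co <- build_cohort(sim$tables)
  cfg <- window_config()
  fx <- featurize_cohort(co, sim$tables, cfg)
  for (i in seq_len(nrow(co))) {
    oracle <- brute_force_features(co[i, ], sim$tables, cfg)
    expect_equal(matrix(fx$x[i, , ], nrow = cfg$n_windows,
                        dimnames = dimnames(oracle$tv)), oracle$tv,
                 label = sprintf("tv of %s", co$patient_id[i]))
    expect_equal(fx$static[i, ], oracle$static,
                 label = sprintf("static of %s", co$patient_id[i]))
  }
})

test_that("no leakage: perturbing the index-visit CDAI changes no feature", {
  sim <- generate_ehr(hospital_profile("university", n_patients = 40, seed = 23))
  co <- build_cohort(sim$tables)
  fx <- featurize_cohort(co, sim$tables)
  tampered <- sim$tables
  is_index <- paste(tampered$cdai$patient_id, tampered$cdai$date) %in%
    paste(co$patient_id, co$index_date)
  tampered$cdai$cdai_score[is_index] <-
    pmin(72, tampered$cdai$cdai_score[is_index] + 33)
  fx2 <- featurize_cohort(co, tampered)
  expect_identical(fx$flat, fx2$flat)
})

test_that("adding an event changes features only in that event's window", {
  tb <- make_patient_tables(cdai_days = c(10, 400), cdai_scores = c(4, 15),
                            lab_days = 350, lab_values = 30)
  co <- build_cohort(tb)
  fx1 <- featurize_cohort(co, tb)
  tb2 <- tb
  new_date <- co$index_date - 250   # window 2 under the defaults
  tb2$labs <- rbind(tb2$labs, data.frame(patient_id = "P1", date = new_date,
                                         lab_name = "ESR", value = 55))
  fx2 <- featurize_cohort(co, tb2)
  w <- assign_window(new_date, co$index_date)
  diff_cols <- which(fx1$flat[1, ] != fx2$flat[1, ])
  expect_identical(colnames(fx1$flat)[diff_cols], paste0("esr@w", w))
})

test_that("splits are deterministic, disjoint, stratified, and sized by rounding", {
  fake <- data.frame(patient_id = sprintf("Q%03d", 1:10),
                     outcome_binary = rep(c("controlled", "uncontrolled"), c(6, 4)))
  sp <- split_cohort(fake, c(0.6, 0.2, 0.2), seed = 1)
  expect_identical(lengths(sp), c(train = 6L, validation = 2L, test = 2L))
  expect_identical(sp, split_cohort(fake, c(0.6, 0.2, 0.2), seed = 1))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(unlist(sp), fake$patient_id)

  big <- data.frame(patient_id = sprintf("Q%03d", 1:578),
                    outcome_binary = rep(c("controlled", "uncontrolled"), c(347, 231)))
  sp578 <- split_cohort(big)
  expect_length(sp578$test, 116)
  # stratification: controlled share of each set near the cohort's 60%
  frac <- vapply(sp578, function(ids)
    mean(big$outcome_binary[match(ids, big$patient_id)] == "controlled"), numeric(1))
  expect_true(all(abs(frac - 0.6) < 0.02))

  expect_error(split_cohort(fake[1:2, ]), "at least 3")
})

test_that("feature container subsetting preserves alignment", {
  m <- medium_cohort()
  fx <- m$features
  sub <- fx[3:5]
  expect_identical(raforecast:::n_samples(sub), 3L)
  expect_identical(sub$flat, fx$flat[3:5, ])
  expect_identical(sub$patient_id, fx$patient_id[3:5])
  byid <- fx[fx$patient_id[3:5]]
  expect_identical(byid$flat, sub$flat)
})

test_that("features round-trip to CSV + schema JSON", {
  m <- medium_cohort()
  dir <- withr::local_tempdir()
  write_features(m$features[1:4], dir)
  df <- utils::read.csv(file.path(dir, "features.csv"), check.names = FALSE)
  expect_identical(nrow(df), 4L)
  expect_identical(ncol(df), 165L + 3L)  # id, label, category
  sc <- jsonlite::read_json(file.path(dir, "schema.json"), simplifyVector = TRUE)
  expect_identical(sc$total_dim, 165L)
})
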