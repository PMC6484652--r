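test_that("generation is deterministic and the empty profile yields empty tables", {
  p <- hospital_profile("university", n_patients = 40, seed = 3)
  a <- generate_ehr(p)
  b <- generate_ehr(p)
  expect_identical(a$tables, b$tables)
  expect_identical(a$truth$visits, b$truth$visits)

  e <- generate_ehr(hospital_profile("university", n_patients = 0))
  expect_true(all(vapply(e$tables, nrow, integer(1)) == 0L))
  expect_identical(nrow(e$truth$visits), 0L)
})

test_that("invalid profiles fail with the offending field named", {
  expect_error(hospital_profile("university", ar_phi = 1.2), "ar_phi")
  expect_error(hospital_profile("university", visit_gap_median_days = 0),
               "visit_gap_median_days")
  expect_error(hospital_profile("university",
                                race_probs = c(white = 0.9, african_american = 0.2,
                                               hispanic = 0, asian = 0, other = 0)),
               "race_probs")
  expect_error(hospital_profile("university", controlled_target = 0), "controlled_target")
  expect_error(hospital_profile("university", bogus = 1), "bogus")
})

test_that("tables respect the relational contract", {
  sim <- generate_ehr(hospital_profile("university", n_patients = 150, seed = 9))
  tb <- sim$tables
  for (child in c("diagnoses", "cdai", "labs", "meds"))
    expect_true(all(tb[[child]]$patient_id %in% tb$demographics$patient_id),
                label = paste(child, "ids in demographics"))
  expect_true(all(tb$cdai$cdai_score >= 0 & tb$cdai$cdai_score <= 72))
  expect_true(all(tb$labs$value >= 0))
  expect_true(all(tb$meds$med_class %in%
                    c("csDMARD", "biologic", "tofacitinib", "corticosteroid")))
  expect_true(all(tb$labs$lab_name %in% c("ESR", "CRP")))
  expect_s3_class(tb$cdai$date, "Date")
})

test_that("calibration targets are met at scale (controlled fraction, switch rate, gaps)", {
  p <- hospital_profile("university", n_patients = 1200, seed = 21)
  sim <- generate_ehr(p)
  rep <- check_marginals(sim$tables, p)
  expect_true(all(rep$pass), info = paste(capture.output(print(rep)), collapse = "\n"))
  expect_lt(abs(sim$truth$realized_controlled - 0.60), 0.03)
  expect_lt(abs(sim$truth$realized_switch - 0.25), 0.03)
})

test_that("safety-net cadence: median visit gap within 15 days of 180", {
  p <- hospital_profile("safety_net", n_patients = 600, seed = 13)
  rep <- check_marginals(generate_ehr(p)$tables, p)
  gap <- rep$realized[rep$metric == "median_visit_gap_days"]
  expect_lt(abs(gap - 180), 15)
})

test_that("severity couples monotonically to CDAI and labs", {
  sim <- generate_ehr(hospital_profile("university", n_patients = 800, seed = 5))
  v <- sim$truth$visits
  expect_gt(cor(v$s_adj, v$cdai, method = "spearman"), 0.8)
  labs <- sim$tables$labs
  key <- paste(v$patient_id, v$date)
  for (ln in c("ESR", "CRP")) {
    lt <- labs[labs$lab_name == ln, ]
    sev <- v$s_adj[match(paste(lt$patient_id, lt$date), key)]
    expect_gt(cor(sev, lt$value, method = "spearman"), 0.4)
  }
})

test_that("degenerate limit freezes every trajectory: constant CDAI, zero switches", {
  p <- hospital_profile("university", n_patients = 60, seed = 2,
                        switch_target = 0, ar_phi = 1 - 1e-9, ar_sigma = 0,
                        treatment_effect = 0, nonqualifying_frac = 0)
  sim <- generate_ehr(p)
  rng <- tapply(sim$tables$cdai$cdai_score, sim$tables$cdai$patient_id,
                function(x) diff(range(x)))
  expect_true(all(rng == 0))
  expect_identical(sim$truth$realized_switch, 0)
})

test_that("unattainable switch targets are rejected with guidance", {
  expect_error(solve_latent_calibration(0.6, 0.25, 0.3), "ar_phi")
  expect_error(solve_latent_calibration(0.6, 0.60, 0.9), "unattainable")
})

test_that("check_marginals rejects empty tables", {
  e <- generate_ehr(hospital_profile("university", n_patients = 0))
  expect_error(check_marginals(e$tables, hospital_profile("university")), "empty")
})

test_that("CSV round trip preserves the tables", {
  sim <- generate_ehr(hospital_profile("university", n_patients = 25, seed = 8))
  dir <- withr::local_tempdir()
  write_ehr(sim$tables, dir, truth = sim$truth)
  back <- read_ehr(dir)
  for (nm in names(sim$tables)) {
    a <- sim$tables[[nm]]; rownames(a) <- NULL
    b <- back[[nm]]; rownames(b) <- NULL
    expect_equal(a, b, label = nm)
  }
  expect_true(file.exists(file.path(dir, "profile.json")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
})

test_that("non-qualifying patients are injected at the configured rate", {
  p <- hospital_profile("university", n_patients = 200, seed = 4,
                        nonqualifying_frac = 0.2)
  sim <- generate_ehr(p)
  modes <- unique(sim$truth$visits[, c("patient_id", "mode")])
  expect_equal(sum(modes$mode != "qualifying"), 40)
  included <- apply_inclusion(sim$tables)
  bad <- modes$patient_id[modes$mode != "qualifying"]
  expect_length(intersect(included, bad), 0)
})
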