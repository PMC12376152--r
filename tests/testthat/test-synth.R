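test_that("the generator honors cohort size and longitudinal structure", {
  cfg <- generator_config(n_patients = 100, exams_per_patient = 2, seed = 10)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 200L)
  expect_equal(dplyr::n_distinct(cohort$patient_id), 100L)
  expect_equal(ncol(cohort), 134L)
  meta <- cohort_meta(cohort)
  # lesion band is stable within a patient
  stable <- meta |>
    dplyr::group_by(patient_id, side) |>
    dplyr::summarise(one_band = dplyr::n_distinct(band) == 1, .groups = "drop")
  expect_true(all(stable$one_band))
})

test_that("a fixed seed reproduces the cohort exactly", {
  cfg <- generator_config(n_patients = 15, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(generator_config(n_patients = 15, seed = 77))
  expect_identical(a, b)
  c2 <- generate_cohort(generator_config(n_patients = 15, seed = 78))
  expect_false(identical(a, c2))
})

test_that("no side is sub-intact rostral to its drawn sensory level", {
  cohort <- shared_cohort()
  meta <- cohort_meta(cohort)
  st <- segment_table()
  for (i in seq_len(nrow(cohort))) {
    for (sd in c("right", "left")) {
      side <- exam_side(cohort, sd, row = i)
      lvl <- meta$level_index[meta$exam_id == cohort$exam_id[i] & meta$side == sd]
      rostral <- st$index <= lvl
      derm <- side$segment %in% st$segment[st$is_dermatome]
      myo <- !is.na(side$ms)
      expect_true(all(side$lt[derm & rostral] == 2L, na.rm = FALSE))
      expect_true(all(side$pp[derm & rostral] == 2L))
      expect_true(all(side$ms[myo & rostral] == 5L))
    }
  }
})

test_that("every generated exam is classifiable", {
  # holds with NT injection off and at the default rate, because NT scores
  # are only injected caudal to level-critical segments
  for (nt in c(0, 0.01)) {
    cohort <- generate_cohort(
      generator_config(n_patients = 40, seed = 55, nt_rate = nt))
    lv <- cohort_levels(cohort)
    expect_equal(sum(is.na(lv$true_motor_level)), 0L)
  }
})

test_that("severity complete with no transition zone zeroes everything caudal", {
  cfg <- generator_config(
    n_patients = 10, exams_per_patient = 1, seed = 3,
    severity_probs = c(complete = 1, sensory_incomplete = 0,
                       motor_incomplete_weak = 0, motor_incomplete_strong = 0),
    transition_len_probs = c(`0` = 1, `1` = 0, `2` = 0, `3` = 0),
    nli_band_probs = c(C1_4 = 0, C5_T1 = 0, T2_L1 = 1, L2_S1 = 0,
                       S2_S45 = 0, intact = 0),
    nt_rate = 0, improvement_rate = 0)
  cohort <- generate_cohort(cfg)
  meta <- cohort_meta(cohort)
  st <- segment_table()
  for (i in seq_len(nrow(cohort))) {
    side <- exam_side(cohort, "right", row = i)
    lvl <- meta$level_index[meta$exam_id == cohort$exam_id[i] &
                              meta$side == "right"]
    caudal <- st$index > lvl
    derm <- side$segment %in% st$segment[st$is_dermatome]
    expect_true(all(side$lt[derm & caudal] == 0L))
    expect_true(all(side$pp[derm & caudal] == 0L))
    expect_true(all(side$ms[!is.na(side$ms) & caudal] == 0L))
    expect_equal(true_motor_level(side)$level, st$segment[lvl])
  }
})

test_that("an intact band yields fully intact exams", {
  cfg <- generator_config(
    n_patients = 5, exams_per_patient = 1, seed = 4,
    nli_band_probs = c(C1_4 = 0, C5_T1 = 0, T2_L1 = 0, L2_S1 = 0,
                       S2_S45 = 0, intact = 1),
    nt_rate = 0)
  cohort <- generate_cohort(cfg)
  for (i in seq_len(nrow(cohort))) {
    expect_equal(true_motor_level(exam_side(cohort, "right", row = i))$level, "INT")
    expect_equal(true_motor_level(exam_side(cohort, "left", row = i))$level, "INT")
  }
})

test_that("below-level motor scores follow the configured conditional distribution", {
  # all motor-incomplete-strong, no transition, high lesions: every myotome
  # draws ms from ms_given_sens given its own (lt, pp)
  cfg <- generator_config(
    n_patients = 500, exams_per_patient = 1, seed = 2024,
    nli_band_probs = c(C1_4 = 1, C5_T1 = 0, T2_L1 = 0, L2_S1 = 0,
                       S2_S45 = 0, intact = 0),
    severity_probs = c(complete = 0, sensory_incomplete = 0,
                       motor_incomplete_weak = 0, motor_incomplete_strong = 1),
    transition_len_probs = c(`0` = 1, `1` = 0, `2` = 0, `3` = 0),
    nt_rate = 0, improvement_rate = 0)
  tr <- extract_triplets(generate_cohort(cfg))
  expect_gte(nrow(tr), 10000L)
  m <- default_ms_given_sens()
  stat <- 0; df <- 0
  for (cell in rownames(m)) {
    lp <- as.integer(strsplit(cell, " ")[[1]])
    sub <- tr[tr$ilt == lp[1] & tr$ipp == lp[2], ]
    if (nrow(sub) < 60) next
    obs <- tabulate(sub$ms + 1L, nbins = 6L)
    keep <- m[cell, ] * nrow(sub) >= 5
    stat <- stat + sum((obs[keep] - nrow(sub) * m[cell, keep])^2 /
                         (nrow(sub) * m[cell, keep]))
    df <- df + sum(keep) - 1L
  }
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("the default cohort reproduces the dominant triplet structure", {
  tr <- extract_triplets(shared_cohort())
  counts <- dplyr::count(tr, ilt, ipp, ms, sort = TRUE)
  expect_equal(unlist(counts[1, 1:3], use.names = FALSE), c(2L, 2L, 5L))
  expect_equal(unlist(counts[2, 1:3], use.names = FALSE), c(0L, 0L, 0L))
  # sensory-determined motor levels are common enough to study the rule
  lv <- cohort_levels(shared_cohort())
  expect_gt(mean(lv$sensory_determined, na.rm = TRUE), 0.3)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(nli_band_probs = c(C1_4 = 1)),
               class = "vmscore_error_config")
  expect_error(
    generator_config(severity_probs = c(complete = 0.9, sensory_incomplete = 0.3,
                                        motor_incomplete_weak = 0,
                                        motor_incomplete_strong = 0)),
    class = "vmscore_error_config")
  expect_error(generator_config(transition_len_probs = c(0.5, 0.1, 0.1, 0.1)),
               class = "vmscore_error_config")
  expect_error(generator_config(nt_rate = 0.9), class = "vmscore_error_config")
  bad_ms <- default_ms_given_sens(); bad_ms[1, 1] <- 2
  expect_error(generator_config(ms_given_sens = bad_ms),
               class = "vmscore_error_config")
})
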