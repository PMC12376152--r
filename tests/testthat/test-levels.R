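clm <- clinical_model("ISens")
mlr <- published_models()$MLR_ISens

test_that("sensory level follows the most-caudal-intact rule", {
  expect_equal(sensory_level(side_scores())$level, "INT")
  expect_equal(sensory_level(side_scores(lt = c(C7 = 1)))$level, "C6")
  expect_equal(sensory_level(side_scores(lt = c(C2 = 0)))$level, "C1")
  expect_equal(sensory_level(side_scores(pp = c(T5 = 1)))$level, "T4")
})

test_that("NT sensory scores make the level indeterminate only when level-critical", {
  # NT at the candidate chain -> error
  expect_error(sensory_level(side_scores(lt = c(C4 = NA))),
               class = "vmscore_error_indeterminate")
  # NT caudal to the first non-intact dermatome is irrelevant
  s <- side_scores(lt = c(C6 = 1, T3 = NA))
  expect_equal(sensory_level(s)$level, "C5")
})

test_that("full motor scores combine examined and virtual scores", {
  full <- full_motor_scores(side_scores(), clm)
  expect_equal(nrow(full), 28L)
  expect_true(all(full$ms == 5L))
  expect_equal(sum(full$source == "examined"), 10L)
  # impaired T5 sensation -> clinical model virtual score 1
  full <- full_motor_scores(side_scores(lt = c(T5 = 1), pp = c(T5 = 0)), clm)
  expect_equal(full$ms[full$segment == "T5"], 1L)
  expect_equal(full$source[full$segment == "T5"], "virtual")
  # absent T5 sensation -> published linear model rounds 0.18 to 0
  full <- full_motor_scores(side_scores(lt = c(T5 = 0), pp = c(T5 = 0)), mlr)
  expect_equal(full$ms[full$segment == "T5"], 0L)
  # NT sensory score at a virtual segment -> indeterminate virtual score
  full <- full_motor_scores(side_scores(lt = c(T5 = NA)), clm)
  expect_true(is.na(full$ms[full$segment == "T5"]))
})

test_that("motor level is the most caudal >=3 segment with an intact rostral chain", {
  base <- full_motor_scores(side_scores(), clm)
  set_ms <- function(full, ...) {
    over <- c(...)
    full$ms[match(names(over), full$segment)] <- as.integer(over)
    full
  }
  st <- segment_table()
  caudal_c8 <- st$segment[st$index > segment_index("C8") & st$is_dermatome]
  f <- set_ms(base, C8 = 3, T1 = 2,
              stats::setNames(rep(0, length(setdiff(caudal_c8, c("T1")))),
                              setdiff(caudal_c8, "T1")))
  expect_equal(motor_level(f)$level, "C8")
  # C2 below 3 pushes the level to the rostral sentinel C1; a C2 grade of
  # 3 or 4 still satisfies ">= 3" with no rostral segment, so C2 itself
  # takes the level
  expect_equal(motor_level(set_ms(base, C2 = 2))$level, "C1")
  expect_equal(motor_level(set_ms(base, C2 = 4))$level, "C2")
  expect_equal(motor_level(base)$level, "INT")
  expect_equal(motor_level(base)$index, 30L)
  # a grade-4 segment stops the chain but still takes the level
  expect_equal(motor_level(set_ms(base, T6 = 4, T7 = 0))$level, "T6")
  # indeterminate at the chain -> error
  f <- base
  f$ms[f$segment == "C3"] <- NA
  expect_error(motor_level(f), class = "vmscore_error_indeterminate")
})

test_that("true motor level reproduces the motor-follows-sensory rule", {
  # sensory level C3 with strong limbs: level inferred from sensation
  s <- side_scores(lt = c(C4 = 1))
  expect_equal(sensory_level(s)$level, "C3")
  expect_equal(true_motor_level(s)$level, "C3")
  # examined key muscles decide when they carry the level
  s <- side_scores(ms = c(C8 = 3, T1 = 2))
  expect_equal(true_motor_level(s)$level, "C8")
  # complete T6 lesion: intact through T6, absent below
  s <- complete_lesion_side("T6")
  expect_equal(true_motor_level(s)$level, "T6")
  expect_equal(sensory_level(s)$level, "T6")
})

test_that("sensory-determined detection replaces sensation with normal scores", {
  expect_true(is_sensory_determined(side_scores(lt = c(C2 = 1, C3 = 1, C4 = 1),
                                                pp = c(C2 = 1, C3 = 1, C4 = 1))))
  expect_false(is_sensory_determined(side_scores()))
  # C8 weakness carries the level regardless of sensation
  expect_false(is_sensory_determined(side_scores(ms = c(C8 = 2))))
  # transition zone: impaired C4 sensation with intact C5 muscle
  expect_true(is_sensory_determined(side_scores(lt = c(C4 = 1))))
})

test_that("motor level matches a brute-force scan on random exams", {
  withr::with_seed(99, {
    for (i in 1:200) {
      side <- random_side()
      full <- full_motor_scores(side, clm)
      expect_equal(motor_level(full)$level, brute_force_motor_level(full))
    }
  })
})

test_that("motor follows sensory on any exam with intact muscles", {
  withr::with_seed(123, {
    for (i in 1:100) {
      side <- random_side(intact_ms = TRUE)
      expect_equal(true_motor_level(side)$level, sensory_level(side)$level)
    }
  })
})

test_that("motor level ignores scores caudal to the level + 1", {
  withr::with_seed(77, {
    for (i in 1:50) {
      side <- random_side()
      full <- full_motor_scores(side, clm)
      lev <- motor_level(full)
      if (lev$index >= 29L) next
      changed <- full
      caudal <- segment_index(changed$segment) > lev$index + 1L
      changed$ms[caudal] <- sample(0:5, sum(caudal), replace = TRUE)
      expect_equal(motor_level(changed)$level, lev$level)
    }
  })
})
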