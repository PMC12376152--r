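# fixtures shared across test files; everything is built in code

# assemble a wide-schema cohort from per-side score tibbles
make_cohort <- function(...) {
  exams <- list(...)
  rows <- lapply(exams, function(e) {
    stopifnot(all(c("patient_id", "exam_id", "right", "left") %in% names(e)))
    row <- list(patient_id = e$patient_id, exam_id = e$exam_id)
    for (si in c("R", "L")) {
      side <- if (si == "R") e$right else e$left
      derm <- side[side$segment %in% segment_table()$segment[segment_table()$is_dermatome], ]
      myo <- side[side$segment %in% segment_table()$segment[segment_table()$is_key_myotome], ]
      for (j in seq_len(nrow(derm))) {
        row[[paste0(si, "_LT_", derm$segment[j])]] <- derm$lt[j]
        row[[paste0(si, "_PP_", derm$segment[j])]] <- derm$pp[j]
      }
      for (j in seq_len(nrow(myo))) {
        row[[paste0(si, "_MS_", myo$segment[j])]] <- myo$ms[j]
      }
    }
    tibble::as_tibble(row)
  })
  dplyr::bind_rows(rows)
}

# a side with a complete lesion: intact through `level`, absent below
complete_lesion_side <- function(level) {
  st <- segment_table()
  idx <- segment_index(level)
  derm_caudal <- st$segment[st$is_dermatome & st$index > idx]
  myo_caudal <- st$segment[st$is_key_myotome & st$index > idx]
  side_scores(
    lt = stats::setNames(rep(0L, length(derm_caudal)), derm_caudal),
    pp = stats::setNames(rep(0L, length(derm_caudal)), derm_caudal),
    ms = stats::setNames(rep(0L, length(myo_caudal)), myo_caudal)
  )
}

# small default-condition cohort shared by several files (built once)
.fixture_env <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(
      generator_config(n_patients = 60, exams_per_patient = 2, seed = 424L)
    )
  }
  .fixture_env$cohort
}

# independent brute-force motor level: scan every segment, no early exit
brute_force_motor_level <- function(full_ms) {
  ms <- full_ms$ms[match(segment_table()$segment[-1], full_ms$segment)]
  if (all(!is.na(ms) & ms == 5L)) return("INT")
  best <- 1L # C1
  for (i in seq_along(ms)) {
    rostral_intact <- i == 1L || all(ms[seq_len(i - 1L)] == 5L)
    if (!is.na(ms[i]) && ms[i] >= 3L && rostral_intact) {
      best <- max(best, i + 1L) # segment index of dermatome i
    }
  }
  segment_table()$segment[best]
}

# a random exam side with scores drawn freely (not lesion-shaped)
random_side <- function(intact_ms = FALSE) {
  st <- segment_table()
  derm <- st$segment[st$is_dermatome]
  myo <- st$segment[st$is_key_myotome]
  side_scores(
    lt = stats::setNames(sample(0:2, 28, replace = TRUE), derm),
    pp = stats::setNames(sample(0:2, 28, replace = TRUE), derm),
    ms = if (intact_ms) NULL
         else stats::setNames(sample(0:5, 10, replace = TRUE), myo)
  )
}
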