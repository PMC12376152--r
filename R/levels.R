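# ISNCSCI level determination.
#
# Both level rules scan rostral -> caudal for the most caudal segment
# still graded normal-enough, requiring every rostral segment to be
# intact.  With virtual motor scores filled in for the segments without
# testable key muscles, motor level determination has exactly the shape of
# sensory level determination, on the full C2..S45 chain.

# scan over dermatome vectors (length 28, C2..S45); returns segment index
# on the 29-segment scale, or INT_INDEX
sensory_level_scan <- function(lt, pp) {
  for (i in seq_len(28L)) {
    intact <- lt[i] == 2L & pp[i] == 2L
    if (is.na(intact)) abort_indeterminate(DERMATOME_LABELS[i])
    if (!intact) return(i) # i == 1 -> C1; else the previous dermatome
  }
  INT_INDEX
}

# scan over a full motor score vector (length 28, C2..S45, NA = indeterminate)
motor_level_scan <- function(full_ms) {
  for (i in seq_len(28L)) {
    v <- full_ms[i]
    if (is.na(v)) abort_indeterminate(DERMATOME_LABELS[i])
    if (v < 5L) {
      if (v >= 3L) return(i + 1L)
      return(i) # i == 1 -> C1
    }
  }
  INT_INDEX
}

level_result <- function(index, basis) {
  tibble(
    level = if (index == INT_INDEX) INT_LEVEL else SEGMENT_LABELS[index],
    index = as.integer(index),
    basis = basis
  )
}

#' Sensory level of one side
#'
#' The most caudal dermatome with normal light touch and pinprick
#' (both 2) such that every rostral dermatome is also normal. Returns `C1`
#' if already C2 is not intact, and the sentinel `INT` (index 30) if all
#' 28 dermatomes are intact. A not-testable score at or rostral to the
#' candidate level makes the level indeterminate (an error with class
#' `vmscore_error_indeterminate`).
#'
#' @param side Per-side score tibble, see [side_scores()].
#' @return One-row tibble with `level`, `index`, `basis`.
#' @examples
#' sensory_level(side_scores(lt = c(C7 = 1)))
#' @export
sensory_level <- function(side) {
  v <- side_vectors(side)
  level_result(sensory_level_scan(v$lt, v$pp), basis = "examined_only")
}

#' Full motor scores: examined plus virtual
#'
#' Fills the motor score chain C2..S45: examined motor scores are copied
#' for the 10 key myotomes; every segment without a clinically testable
#' key muscle (C2-C4, T2-L1, S2-S4/5) gets the model's rounded virtual
#' motor score predicted from the segment's own (ipsilateral) sensory
#' scores. A not-testable sensory score makes that segment's virtual score
#' indeterminate (`NA`).
#'
#' @param side Per-side score tibble, see [side_scores()].
#' @param model An ipsilateral `vms_model` (feature set `ILT`, `IPP` or
#'   `ISens`); default is the consensus clinical model.
#' @return Tibble with one row per segment C2..S45: `segment`, `ms`,
#'   `source` (`"examined"` or `"virtual"`).
#' @examples
#' full_motor_scores(side_scores(lt = c(T5 = 1), pp = c(T5 = 0)))
#' @export
full_motor_scores <- function(side, model = clinical_model("ISens")) {
  v <- side_vectors(side)
  vf <- virtual_score_fun(model)
  full <- vf(v$lt, v$pp)
  full[KEY_POS_IN_DERM] <- v$ms
  tibble(
    segment = DERMATOME_LABELS,
    ms = as.integer(full),
    source = ifelse(seq_len(28L) %in% KEY_POS_IN_DERM, "examined", "virtual")
  )
}

#' Motor level from a full motor score chain
#'
#' The most caudal segment graded 3 or better provided all rostral
#' segments are graded 5 (intact), evaluated on the full C2..S45 chain of
#' examined plus virtual motor scores. Returns `C1` if C2 is below 3 and
#' `INT` if every segment is 5. An indeterminate (`NA`) score at or
#' rostral to the candidate level raises an error.
#'
#' @param full_ms Tibble as returned by [full_motor_scores()] (columns
#'   `segment`, `ms` over C2..S45).
#' @return One-row tibble with `level`, `index`, `basis`.
#' @export
motor_level <- function(full_ms) {
  m <- match(DERMATOME_LABELS, full_ms$segment)
  if (anyNA(m)) abort_validation("full_ms must cover segments C2..S45")
  level_result(motor_level_scan(as.integer(full_ms$ms[m])),
               basis = "includes_virtual")
}

#' True motor level (current ISNCSCI rules)
#'
#' The motor level as determined by the current classification rules,
#' including levels inferred from sensory function: examined motor scores
#' plus the consensus clinical model's virtual scores, which yield 5 only
#' where both sensory modalities are normal — this reproduces the
#' "motor follows sensory level" rule by construction.
#'
#' @inheritParams full_motor_scores
#' @return One-row tibble with `level`, `index`, `basis`.
#' @examples
#' # high cervical sensory impairment with strong limbs: level C3
#' true_motor_level(side_scores(lt = c(C4 = 1)))
#' @export
true_motor_level <- function(side) {
  motor_level(full_motor_scores(side, clinical_model("ISens")))
}

#' Was the motor level determined by sensory function?
#'
#' Detects sides whose motor level depends on sensory scores: all sensory
#' scores are temporarily replaced with normal scores (2) and the motor
#' level recomputed; if the temporary level differs from the true motor
#' level, the true level was determined by inclusion of sensory function
#' (levels inferred from the sensory level and levels at the transition
#' zones C4/C5 and L1/L2).
#'
#' @inheritParams full_motor_scores
#' @return Logical scalar.
#' @examples
#' is_sensory_determined(side_scores(lt = c(C3 = 1))) # TRUE
#' is_sensory_determined(side_scores())               # FALSE (intact)
#' @export
is_sensory_determined <- function(side) {
  v <- side_vectors(side)
  truth <- motor_level_scan(full_ms_vec(v, clinical_model("ISens")))
  intact <- list(lt = rep(2L, 28L), pp = rep(2L, 28L), ms = v$ms)
  temp <- motor_level_scan(full_ms_vec(intact, clinical_model("ISens")))
  temp != truth
}

# internal fast path shared by the cohort routines
full_ms_vec <- function(v, model_or_fun) {
  vf <- if (is.function(model_or_fun)) model_or_fun else virtual_score_fun(model_or_fun)
  full <- vf(v$lt, v$pp)
  full[KEY_POS_IN_DERM] <- v$ms
  as.integer(full)
}

#' Per-side levels over a cohort
#'
#' Computes, for every exam and side in a cohort table, the sensory level,
#' the true motor level, the motor level recalculated with `model`'s
#' virtual scores, and whether the motor level was determined by sensory
#' function. Sides whose level is indeterminate (not-testable scores at a
#' level-critical segment) are returned with `NA` levels.
#'
#' @param exams Cohort tibble in the wide exam schema.
#' @param model Ipsilateral `vms_model` used for the recalculated level
#'   (default: the published ISens linear model).
#' @return Tibble with one row per exam side: ids, `side`,
#'   `sensory_level`, `true_motor_level`, `recalc_motor_level` (labels),
#'   the corresponding `*_index` columns, and `sensory_determined`.
#' @export
cohort_levels <- function(exams, model = published_models()$MLR_ISens) {
  clm_fun <- virtual_score_fun(clinical_model("ISens"))
  mod_fun <- virtual_score_fun(model)
  n <- nrow(exams)
  res <- vector("list", 2L)
  for (si in 1:2) {
    s <- c("R", "L")[si]
    LT <- as.matrix(exams[paste0(s, "_LT_", DERMATOME_LABELS)])
    PP <- as.matrix(exams[paste0(s, "_PP_", DERMATOME_LABELS)])
    MS <- as.matrix(exams[paste0(s, "_MS_", KEY_MYOTOME_LABELS)])
    sl <- ml <- rl <- rep(NA_integer_, n)
    sdet <- rep(NA, n)
    for (i in seq_len(n)) {
      v <- list(lt = as.integer(LT[i, ]), pp = as.integer(PP[i, ]),
                ms = as.integer(MS[i, ]))
      ok <- tryCatch({
        sl[i] <- sensory_level_scan(v$lt, v$pp)
        ml[i] <- motor_level_scan(full_ms_vec(v, clm_fun))
        rl[i] <- motor_level_scan(full_ms_vec(v, mod_fun))
        temp <- motor_level_scan(
          full_ms_vec(list(lt = rep(2L, 28L), pp = rep(2L, 28L), ms = v$ms),
                      clm_fun))
        sdet[i] <- temp != ml[i]
        TRUE
      }, vmscore_error_indeterminate = function(e) FALSE)
      if (!ok) { sl[i] <- ml[i] <- rl[i] <- NA_integer_; sdet[i] <- NA }
    }
    lab <- function(ix) ifelse(is.na(ix), NA_character_,
                               c(SEGMENT_LABELS, INT_LEVEL)[ix])
    res[[si]] <- tibble(
      patient_id = exams$patient_id,
      exam_id = exams$exam_id,
      side = c("right", "left")[si],
      sensory_level = lab(sl), sensory_index = sl,
      true_motor_level = lab(ml), true_motor_index = ml,
      recalc_motor_level = lab(rl), recalc_motor_index = rl,
      sensory_determined = sdet
    )
  }
  dplyr::arrange(dplyr::bind_rows(res), .data$patient_id, .data$exam_id,
                 dplyr::desc(.data$side))
}
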