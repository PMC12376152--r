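# Synthetic EMSCI-like cohort generator.
#
# Each patient gets a lesion band, a severity and a sensory level; each
# side of each exam is built rostral -> caudal: intact above the level, a
# short transition zone of mixed sub-intact sensory scores, then
# severity-dependent sensory scores below.  Motor scores are 5 rostral to
# the level and otherwise drawn from a conditional distribution given the
# segment's own (lt, pp) — the coupling that makes "motor follows
# sensory" learnable from the generated data.  Not-testable scores are
# injected only caudal to every level-critical segment so generated exams
# always classify.

NLI_BANDS <- list(
  C1_4 = 1:4, C5_T1 = 5:9, T2_L1 = 10:21,
  L2_S1 = 22:26, S2_S45 = 27:28, intact = integer(0)
)

SEVERITIES <- c("complete", "sensory_incomplete",
                "motor_incomplete_weak", "motor_incomplete_strong")

# AIS-like label attached as generator metadata (never computed from scores)
SEVERITY_AIS <- c(complete = "A", sensory_incomplete = "B",
                  motor_incomplete_weak = "C", motor_incomplete_strong = "D")

# below-zone sensory score distributions per severity: P(lt = 0,1,2), P(pp = 0,1,2)
BELOW_SENS <- list(
  complete = list(lt = c(1, 0, 0), pp = c(1, 0, 0)),
  sensory_incomplete = list(lt = c(0.45, 0.35, 0.20), pp = c(0.55, 0.30, 0.15)),
  motor_incomplete_weak = list(lt = c(0.30, 0.35, 0.35), pp = c(0.40, 0.32, 0.28)),
  motor_incomplete_strong = list(lt = c(0.12, 0.28, 0.60), pp = c(0.18, 0.30, 0.52))
)

# transition-zone sensory combinations: {1,2} x {0,1,2} minus (2,2)
TRANSITION_COMBOS <- cbind(lt = c(1, 1, 1, 2, 2), pp = c(0, 1, 2, 0, 1))
TRANSITION_PROBS <- c(0.22, 0.26, 0.14, 0.16, 0.22)

#' Default motor-score distribution conditional on sensory scores
#'
#' `P(ms | lt, pp)` used below the lesion level for motor-incomplete
#' severities: a 9 x 6 matrix, rows named `"lt pp"`, columns motor grades
#' 0..5. The default concentrates mass at 5 for intact sensation and at 0
#' for absent sensation, with graded intermediate cells.
#'
#' @return Numeric matrix with rows `"0 0"` ... `"2 2"` summing to 1.
#' @export
default_ms_given_sens <- function() {
  m <- rbind(
    "0 0" = c(0.80, 0.12, 0.04, 0.02, 0.01, 0.01),
    "0 1" = c(0.40, 0.25, 0.18, 0.10, 0.05, 0.02),
    "0 2" = c(0.18, 0.18, 0.22, 0.18, 0.14, 0.10),
    "1 0" = c(0.35, 0.25, 0.20, 0.10, 0.06, 0.04),
    "1 1" = c(0.15, 0.18, 0.22, 0.20, 0.15, 0.10),
    "1 2" = c(0.05, 0.08, 0.13, 0.22, 0.27, 0.25),
    "2 0" = c(0.12, 0.15, 0.22, 0.22, 0.17, 0.12),
    "2 1" = c(0.04, 0.07, 0.12, 0.20, 0.28, 0.29),
    "2 2" = c(0.02, 0.03, 0.05, 0.12, 0.28, 0.50)
  )
  colnames(m) <- as.character(0:5)
  m
}

# reweighting applied to ms_given_sens for the weak motor-incomplete severity
WEAK_MS_WEIGHTS <- c(1, 1, 0.8, 0.5, 0.3, 0.15)

#' Generator configuration for synthetic cohorts
#'
#' Defines the study conditions of a simulated cohort: lesion-band mix
#' (defaults follow the neurological-level-of-injury distribution of a
#' large European SCI cohort: cervical high 25.2%, cervical low 25.0%,
#' thoracic 41.6%, lumbosacral 7.2%, sacral 0.2%, intact 0.8%), severity
#' mix (motor/sensory complete vs incomplete), transition zone length,
#' the conditional motor-score distribution, longitudinal improvement and
#' the not-testable rate.
#'
#' @param n_patients Number of patients.
#' @param exams_per_patient Longitudinal exams per patient (lesion band is
#'   stable within a patient; sub-maximal scores drift mildly upward
#'   across exams).
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @param nli_band_probs Named probabilities over
#'   `C1_4, C5_T1, T2_L1, L2_S1, S2_S45, intact`.
#' @param severity_probs Named probabilities over `complete`,
#'   `sensory_incomplete`, `motor_incomplete_weak`,
#'   `motor_incomplete_strong`.
#' @param transition_len_probs Probabilities of transition-zone lengths
#'   0..3 segments.
#' @param ms_given_sens Conditional motor-score matrix, see
#'   [default_ms_given_sens()].
#' @param nt_rate Per-score probability of a not-testable entry, injected
#'   only caudal to level-critical segments.
#' @param improvement_rate Per-score probability that a sub-maximal score
#'   gains one point from one exam to the next.
#' @return A `vms_generator_config` list.
#' @export
generator_config <- function(
    n_patients = 100L,
    exams_per_patient = 3L,
    seed = 20251L,
    nli_band_probs = c(C1_4 = 0.252, C5_T1 = 0.250, T2_L1 = 0.416,
                       L2_S1 = 0.072, S2_S45 = 0.002, intact = 0.008),
    severity_probs = c(complete = 0.42, sensory_incomplete = 0.12,
                       motor_incomplete_weak = 0.14,
                       motor_incomplete_strong = 0.32),
    transition_len_probs = c(`0` = 0.30, `1` = 0.35, `2` = 0.25, `3` = 0.10),
    ms_given_sens = default_ms_given_sens(),
    nt_rate = 0.01,
    improvement_rate = 0.08) {
  if (n_patients < 1L) abort_config("n_patients must be >= 1")
  if (exams_per_patient < 1L) abort_config("exams_per_patient must be >= 1")
  if (!setequal(names(nli_band_probs), names(NLI_BANDS))) {
    abort_config("nli_band_probs must be named by C1_4, C5_T1, T2_L1, L2_S1, S2_S45, intact")
  }
  if (!setequal(names(severity_probs), SEVERITIES)) {
    abort_config(paste("severity_probs must be named by",
                       paste(SEVERITIES, collapse = ", ")))
  }
  check_prob_vector(nli_band_probs, "nli_band_probs")
  check_prob_vector(severity_probs, "severity_probs")
  check_prob_vector(transition_len_probs, "transition_len_probs")
  if (!is.matrix(ms_given_sens) || !identical(dim(ms_given_sens), c(9L, 6L))) {
    abort_config("ms_given_sens must be a 9 x 6 matrix (rows '0 0'..'2 2', cols grades 0..5)")
  }
  for (r in rownames(ms_given_sens)) {
    check_prob_vector(ms_given_sens[r, ], paste0("ms_given_sens['", r, "', ]"))
  }
  if (nt_rate < 0 || nt_rate > 0.5) abort_config("nt_rate must be in [0, 0.5]")
  structure(
    list(n_patients = as.integer(n_patients),
         exams_per_patient = as.integer(exams_per_patient),
         seed = as.integer(seed),
         nli_band_probs = nli_band_probs[names(NLI_BANDS)],
         severity_probs = severity_probs[SEVERITIES],
         transition_len_probs = transition_len_probs,
         ms_given_sens = ms_given_sens,
         nt_rate = nt_rate,
         improvement_rate = improvement_rate),
    class = "vms_generator_config"
  )
}

# draw sensory + motor score vectors for one side
# level_idx: sensory level on the 29-segment scale (INT_INDEX = intact)
generate_side <- function(level_idx, tlen, severity, cfg) {
  lt <- rep(2L, 28L)
  pp <- rep(2L, 28L)
  seg_idx <- 2:29 # segment index of dermatome positions 1..28
  if (level_idx < INT_INDEX) {
    zone <- which(seg_idx > level_idx & seg_idx <= level_idx + tlen)
    below <- which(seg_idx > level_idx + tlen)
    if (length(zone)) {
      pick <- draw_int(seq_len(nrow(TRANSITION_COMBOS)), TRANSITION_PROBS,
                       n = length(zone))
      lt[zone] <- TRANSITION_COMBOS[pick, "lt"]
      pp[zone] <- TRANSITION_COMBOS[pick, "pp"]
    }
    if (length(below)) {
      bs <- BELOW_SENS[[severity]]
      lt[below] <- draw_int(0:2, bs$lt, n = length(below))
      pp[below] <- draw_int(0:2, bs$pp, n = length(below))
    }
  }
  ms <- rep(5L, 10L)
  sub <- which(seg_idx[KEY_POS_IN_DERM] > level_idx)
  for (k in sub) {
    l <- lt[KEY_POS_IN_DERM[k]]
    p <- pp[KEY_POS_IN_DERM[k]]
    if (severity %in% c("complete", "sensory_incomplete")) {
      ms[k] <- 0L
    } else {
      pr <- cfg$ms_given_sens[paste(l, p), ]
      if (severity == "motor_incomplete_weak") {
        pr <- pr * WEAK_MS_WEIGHTS
        pr <- pr / sum(pr)
      }
      ms[k] <- draw_int(0:5, pr)
    }
  }
  list(lt = lt, pp = pp, ms = ms)
}

# one exam-to-exam improvement step: sub-maximal scores caudal to the
# drawn level gain one point independently with probability rate
improve_side <- function(sv, level_idx, rate) {
  seg_idx <- 2:29
  caudal <- seg_idx > level_idx
  up <- function(v, hi, eligible) {
    hit <- eligible & v < hi & runif(length(v)) < rate
    v[hit] <- v[hit] + 1L
    v
  }
  sv$lt <- up(sv$lt, 2L, caudal)
  sv$pp <- up(sv$pp, 2L, caudal)
  sv$ms <- up(sv$ms, 5L, caudal[KEY_POS_IN_DERM])
  sv
}

# inject NT (NA) strictly caudal to every level-critical position
inject_nt <- function(sv, rate) {
  if (rate <= 0) return(sv)
  stop_s <- sensory_level_scan(sv$lt, sv$pp) # segment index
  full <- full_ms_vec(sv, clinical_model("ISens"))
  stop_m <- motor_level_scan(full)
  # first dermatome position that any rostral->caudal scan can still reach
  stop_pos <- max(stop_s, stop_m) - 1L # segment index -> dermatome position
  safe_derm <- which(seq_len(28L) > stop_pos + 1L)
  k0 <- which(sv$ms < 5L)
  k0 <- if (length(k0)) min(k0) else 11L
  safe_ms <- which(seq_len(10L) > k0)
  nt <- function(v, safe) {
    hit <- safe[runif(length(safe)) < rate]
    v[hit] <- NA_integer_
    v
  }
  sv$lt <- nt(sv$lt, safe_derm)
  sv$pp <- nt(sv$pp, safe_derm)
  sv$ms <- nt(sv$ms, safe_ms)
  sv
}

#' Generate a synthetic EMSCI-like cohort
#'
#' Draws `n_patients * exams_per_patient` exams from the configured
#' lesion/severity mix. The cohort is returned in the wide exam schema
#' (see [read_exams()]); the drawn per-side ground truth (band, severity,
#' level, transition length, AIS-like label) is attached as the `"meta"`
#' attribute, retrievable with [cohort_meta()].
#'
#' @param config A [generator_config()].
#' @return Cohort tibble (one row per exam, 134 columns).
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 10, seed = 42))
#' dim(cohort)
#' head(cohort_meta(cohort))
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "vms_generator_config"))
  withr::with_seed(config$seed, {
    n_ex <- config$n_patients * config$exams_per_patient
    cols <- exam_columns()
    M <- matrix(NA_integer_, nrow = n_ex, ncol = length(cols) - 2L,
                dimnames = list(NULL, cols[-(1:2)]))
    patient_id <- character(n_ex)
    exam_id <- character(n_ex)
    meta <- vector("list", n_ex * 2L)
    row <- 0L
    for (p in seq_len(config$n_patients)) {
      pid <- sprintf("P%05d", p)
      band <- draw_int(names(NLI_BANDS), config$nli_band_probs)
      severity <- if (band == "intact") "intact"
                  else draw_int(SEVERITIES, config$severity_probs)
      if (band == "intact") {
        lvl_r <- lvl_l <- INT_INDEX
      } else {
        cand <- NLI_BANDS[[band]]
        lvl_r <- if (length(cand) == 1L) cand else sample(cand, 1L)
        jit <- sample(c(-1L, 0L, 1L), 1L, prob = c(0.15, 0.70, 0.15))
        lvl_l <- min(max(lvl_r + jit, 1L), 28L)
      }
      tlen_r <- draw_int(0:3, config$transition_len_probs)
      tlen_l <- draw_int(0:3, config$transition_len_probs)
      sev_draw <- if (band == "intact") "motor_incomplete_strong" else severity
      side_r <- generate_side(lvl_r, tlen_r, sev_draw, config)
      side_l <- generate_side(lvl_l, tlen_l, sev_draw, config)
      for (e in seq_len(config$exams_per_patient)) {
        row <- row + 1L
        if (e > 1L) {
          side_r <- improve_side(side_r, lvl_r, config$improvement_rate)
          side_l <- improve_side(side_l, lvl_l, config$improvement_rate)
        }
        out_r <- inject_nt(side_r, config$nt_rate)
        out_l <- inject_nt(side_l, config$nt_rate)
        patient_id[row] <- pid
        exam_id[row] <- sprintf("%s_E%d", pid, e)
        M[row, paste0("R_LT_", DERMATOME_LABELS)] <- out_r$lt
        M[row, paste0("R_PP_", DERMATOME_LABELS)] <- out_r$pp
        M[row, paste0("R_MS_", KEY_MYOTOME_LABELS)] <- out_r$ms
        M[row, paste0("L_LT_", DERMATOME_LABELS)] <- out_l$lt
        M[row, paste0("L_PP_", DERMATOME_LABELS)] <- out_l$pp
        M[row, paste0("L_MS_", KEY_MYOTOME_LABELS)] <- out_l$ms
        for (si in 1:2) {
          meta[[(row - 1L) * 2L + si]] <- tibble(
            patient_id = pid, exam_id = exam_id[row],
            side = c("right", "left")[si],
            band = band,
            severity = if (band == "intact") "intact" else severity,
            ais = if (band == "intact") "E" else unname(SEVERITY_AIS[severity]),
            level_index = c(lvl_r, lvl_l)[si],
            level = c(SEGMENT_LABELS, INT_LEVEL)[c(lvl_r, lvl_l)[si]],
            transition_len = c(tlen_r, tlen_l)[si]
          )
        }
      }
    }
    cohort <- dplyr::bind_cols(
      tibble(patient_id = patient_id, exam_id = exam_id),
      as_tibble(M)
    )
    attr(cohort, "meta") <- dplyr::bind_rows(meta)
    attr(cohort, "generator_seed") <- config$seed
    cohort
  })
}

#' Ground-truth metadata of a generated cohort
#'
#' @param cohort A tibble from [generate_cohort()].
#' @return Tibble with one row per exam side: `band`, `severity`, `ais`,
#'   drawn sensory `level` / `level_index` and `transition_len`.
#' @export
cohort_meta <- function(cohort) {
  m <- attr(cohort, "meta")
  if (is.null(m)) abort_validation("cohort carries no generator metadata")
  m
}
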