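# Motor level recalculation and cohort shift statistics.
#
# A side is included in the shift analysis only when its motor level was
# determined by inclusion of sensory function (see is_sensory_determined):
# only there can a virtual-score model move the level at all.  For any
# ipsilateral model whose rounded prediction is 5 exactly at (2,2), the
# recalculated level can match the true level or sit exactly one segment
# caudal to it, never rostral and never further.

#' Recalculate the motor level with a virtual score model
#'
#' Applies [motor_level()] to the full examined-plus-virtual motor score
#' chain produced by `model` (see [full_motor_scores()]).
#'
#' @inheritParams full_motor_scores
#' @return One-row tibble with `level`, `index`, `basis`.
#' @examples
#' impaired <- side_scores(lt = c(C3 = 1, C4 = 1), pp = c(C3 = 1, C4 = 1))
#' true_motor_level(impaired)                              # C2
#' recalc_motor_level(impaired, published_models()$MLR_ISens)
#' @export
recalc_motor_level <- function(side, model) {
  motor_level(full_motor_scores(side, model))
}

#' Cohort shift analysis: recalculated vs true motor levels
#'
#' For every exam side whose motor level was determined by inclusion of
#' sensory function, computes the true motor level (current rules, i.e.
#' clinical model virtual scores), the level recalculated with `model`'s
#' virtual scores, and the shift between them in segments (positive =
#' caudal), then summarizes the shift distribution over the included
#' sides. Sides with indeterminate levels are dropped with a message.
#'
#' @param exams Cohort tibble in the wide exam schema.
#' @param model Ipsilateral `vms_model` supplying the virtual scores.
#' @return A `vms_shift` object: list with `records` (tibble of included
#'   sides: ids, `side`, `true_level`, `recalc_level`, `shift`,
#'   `sensory_determined`), `stats` (one-row tibble: `n`, `pct_match`,
#'   `pct_caudal_one`, `mean_shift`, `sd_shift`, `median_shift`,
#'   `iqr_shift`), `model_name`, `n_sides`, `n_indeterminate`. Use
#'   [tidy()] for the records and [glance()] for the stats.
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 20, seed = 7))
#' analyze_shift(cohort, published_models()$MLR_ISens)
#' @export
analyze_shift <- function(exams, model) {
  if (nrow(exams) == 0L) abort_validation("empty cohort")
  lv <- cohort_levels(exams, model)
  n_ind <- sum(is.na(lv$sensory_determined))
  inc <- lv[!is.na(lv$sensory_determined) & lv$sensory_determined, ]
  if (nrow(inc) == 0L) {
    abort("no sensory-determined levels in this cohort",
          class = "vmscore_error_validation")
  }
  records <- tibble(
    patient_id = inc$patient_id,
    exam_id = inc$exam_id,
    side = inc$side,
    true_level = inc$true_motor_level,
    recalc_level = inc$recalc_motor_level,
    shift = inc$recalc_motor_index - inc$true_motor_index,
    sensory_determined = TRUE
  )
  structure(
    list(records = records,
         stats = shift_stats(records$shift),
         model_name = paste0(class(model)[1], "_", model$feature_set),
         n_sides = nrow(lv),
         n_indeterminate = n_ind),
    class = "vms_shift"
  )
}

# summary statistics of a shift vector (segments, positive = caudal);
# quartiles use the default linear-interpolation estimator (type 7)
shift_stats <- function(shift) {
  q <- quantile(shift, c(0.25, 0.75), names = FALSE, type = 7)
  tibble(
    n = length(shift),
    pct_match = 100 * mean(shift == 0),
    pct_caudal_one = 100 * mean(shift == 1),
    mean_shift = mean(shift),
    sd_shift = if (length(shift) > 1) sd(shift) else 0,
    median_shift = median(shift),
    iqr_shift = q[2] - q[1]
  )
}

#' @export
print.vms_shift <- function(x, ...) {
  s <- x$stats
  cat("<vms_shift> model:", x$model_name, "\n")
  cat(sprintf("  included sides: %d of %d (%d indeterminate)\n",
              s$n, x$n_sides, x$n_indeterminate))
  cat(sprintf("  match: %.2f%%  one caudal: %.2f%%\n",
              s$pct_match, s$pct_caudal_one))
  cat(sprintf("  shift: %.2f +/- %.2f segments (median %g, IQR %g)\n",
              s$mean_shift, s$sd_shift, s$median_shift, s$iqr_shift))
  invisible(x)
}

#' @method tidy vms_shift
#' @export
tidy.vms_shift <- function(x, ...) x$records

#' @method glance vms_shift
#' @export
glance.vms_shift <- function(x, ...) {
  dplyr::mutate(x$stats, model = x$model_name, .before = 1)
}
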