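# Exam representation.
#
# A cohort is a wide tibble, one row per exam: `patient_id`, `exam_id`,
# then per side S in {R, L} the sensory columns S_LT_<seg> / S_PP_<seg>
# for the 28 dermatomes and S_MS_<seg> for the 10 key myotomes
# (134 columns).  Scores are integers; a not-testable (NT) score is NA.
# Per-side operations work on a small long tibble built by side_scores().

exam_columns <- function() {
  side_cols <- function(s) {
    c(paste0(s, "_LT_", DERMATOME_LABELS),
      paste0(s, "_PP_", DERMATOME_LABELS),
      paste0(s, "_MS_", KEY_MYOTOME_LABELS))
  }
  c("patient_id", "exam_id", side_cols("R"), side_cols("L"))
}

#' Build per-side scores
#'
#' Constructs the long per-side score tibble used by the level functions:
#' one row per segment (C1..S45) with light touch (`lt`) and pinprick
#' (`pp`) on the 28 dermatomes and the examined motor score (`ms`) on the
#' 10 key myotomes. Defaults describe an intact side; named overrides set
#' individual segments. `NA` marks a not-testable (NT) score.
#'
#' @param lt,pp Named vectors of dermatome overrides, e.g.
#'   `c(C7 = 1, C8 = 0)`.
#' @param ms Named vector of key myotome overrides, e.g. `c(C8 = 3)`.
#' @param default_lt,default_pp,default_ms Fill values for segments not
#'   overridden (defaults: intact, 2/2/5).
#' @return Tibble with columns `segment`, `lt`, `pp`, `ms` (29 rows;
#'   non-applicable entries `NA`).
#' @examples
#' # complete lesion below C6
#' side_scores(
#'   lt = c(C7 = 0, C8 = 0), pp = c(C7 = 0, C8 = 0),
#'   ms = c(C7 = 2, C8 = 0)
#' )
#' @export
side_scores <- function(lt = NULL, pp = NULL, ms = NULL,
                        default_lt = 2L, default_pp = 2L, default_ms = 5L) {
  apply_over <- function(base, labels, over, what, range) {
    v <- rep(as.integer(base), length(labels))
    names(v) <- labels
    if (!is.null(over)) {
      bad <- setdiff(names(over), labels)
      if (length(bad)) {
        abort_validation(paste0(what, " override names are not ",
                                if (what == "ms") "key myotomes" else "dermatomes",
                                ": ", paste(bad, collapse = ", ")))
      }
      v[names(over)] <- as.integer(over)
    }
    out_of_range <- !is.na(v) & !(v %in% range)
    if (any(out_of_range)) {
      abort_validation(paste0(what, " scores outside ",
                              paste(range(range), collapse = ".."), ": ",
                              paste(labels[out_of_range], collapse = ", ")))
    }
    v
  }
  ltv <- apply_over(default_lt, DERMATOME_LABELS, lt, "lt", 0:2)
  ppv <- apply_over(default_pp, DERMATOME_LABELS, pp, "pp", 0:2)
  msv <- apply_over(default_ms, KEY_MYOTOME_LABELS, ms, "ms", 0:5)
  tibble(
    segment = SEGMENT_LABELS,
    lt = c(NA_integer_, unname(ltv))[match(SEGMENT_LABELS, c("C1", DERMATOME_LABELS))],
    pp = c(NA_integer_, unname(ppv))[match(SEGMENT_LABELS, c("C1", DERMATOME_LABELS))],
    ms = unname(msv)[match(SEGMENT_LABELS, KEY_MYOTOME_LABELS)]
  )
}

#' Extract one side of one exam from a cohort table
#'
#' @param exams Cohort tibble in the wide exam schema (see
#'   [read_exams()] / [generate_cohort()]).
#' @param side `"right"` or `"left"`.
#' @param row Row number of the exam to extract (default 1).
#' @return A per-side score tibble as returned by [side_scores()].
#' @export
exam_side <- function(exams, side = c("right", "left"), row = 1L) {
  side <- match.arg(side)
  s <- if (side == "right") "R" else "L"
  ex <- exams[row, , drop = FALSE]
  lt <- as.integer(unlist(ex[paste0(s, "_LT_", DERMATOME_LABELS)], use.names = FALSE))
  pp <- as.integer(unlist(ex[paste0(s, "_PP_", DERMATOME_LABELS)], use.names = FALSE))
  ms <- as.integer(unlist(ex[paste0(s, "_MS_", KEY_MYOTOME_LABELS)], use.names = FALSE))
  tibble(
    segment = SEGMENT_LABELS,
    lt = c(NA_integer_, lt)[match(SEGMENT_LABELS, c("C1", DERMATOME_LABELS))],
    pp = c(NA_integer_, pp)[match(SEGMENT_LABELS, c("C1", DERMATOME_LABELS))],
    ms = ms[match(SEGMENT_LABELS, KEY_MYOTOME_LABELS)]
  )
}

# internal: side tibble -> list(lt = 28-vector, pp = 28-vector, ms = 10-vector)
side_vectors <- function(side) {
  if (!all(c("segment", "lt", "pp") %in% names(side))) {
    abort_validation("a side must have columns segment, lt, pp (and ms for motor operations)")
  }
  d <- match(DERMATOME_LABELS, side$segment)
  if (anyNA(d)) abort_validation("side is missing dermatome rows")
  lt <- as.integer(side$lt[d])
  pp <- as.integer(side$pp[d])
  ms <- if ("ms" %in% names(side)) {
    k <- match(KEY_MYOTOME_LABELS, side$segment)
    as.integer(side$ms[k])
  } else {
    rep(NA_integer_, 10L)
  }
  rng_bad <- function(v, hi) any(!is.na(v) & (v < 0L | v > hi))
  if (rng_bad(lt, 2L) || rng_bad(pp, 2L)) abort_validation("sensory scores outside 0..2")
  if (rng_bad(ms, 5L)) abort_validation("motor scores outside 0..5")
  list(lt = lt, pp = pp, ms = ms)
}
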