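# Canonical spinal segment scale.
#
# ISNCSCI tests 28 dermatomes (C2..S4/5, with S4 and S5 merged into one
# "S45" dermatome) and 10 key myotomes (C5..T1 and L2..S1).  Together with
# C1 this gives 29 segments in rostral -> caudal order.  Levels are
# reported on this scale; a fully intact side gets the sentinel "INT",
# which sorts caudal to S45 (index 30) for shift arithmetic.

SEGMENT_LABELS <- c(
  paste0("C", 1:8),
  paste0("T", 1:12),
  paste0("L", 1:5),
  "S1", "S2", "S3", "S45"
)

DERMATOME_LABELS <- SEGMENT_LABELS[-1L] # C2..S45, 28 dermatomes

KEY_MYOTOME_LABELS <- c("C5", "C6", "C7", "C8", "T1",
                        "L2", "L3", "L4", "L5", "S1")

VIRTUAL_MOTOR_LABELS <- setdiff(DERMATOME_LABELS, KEY_MYOTOME_LABELS)

INT_LEVEL <- "INT"
INT_INDEX <- length(SEGMENT_LABELS) + 1L # 30

# positions of the key myotomes within the dermatome (C2..S45) order
KEY_POS_IN_DERM <- match(KEY_MYOTOME_LABELS, DERMATOME_LABELS)

#' Canonical spinal segment table
#'
#' The 29 spinal segments used throughout the package, in rostral to caudal
#' order `C1 < ... < C8 < T1 < ... < T12 < L1 < ... < L5 < S1 < S2 < S3 <
#' S45` (S4 and S5 are merged into the single dermatome `S45`, following
#' the ISNCSCI worksheet). 28 segments are dermatomes with light-touch and
#' pinprick scores; 10 are key myotomes with examined motor scores; the
#' remaining 18 (plus C1) have no clinically testable key muscle, and their
#' motor score, when needed, is a *virtual* score predicted from the
#' segment's own sensory scores.
#'
#' @return A tibble with one row per segment and columns `segment`,
#'   `index` (1-based rostral to caudal), `is_dermatome`, `is_key_myotome`
#'   and `is_virtual_motor`.
#' @examples
#' segment_table()
#' @export
segment_table <- function() {
  tibble(
    segment = SEGMENT_LABELS,
    index = seq_along(SEGMENT_LABELS),
    is_dermatome = SEGMENT_LABELS %in% DERMATOME_LABELS,
    is_key_myotome = SEGMENT_LABELS %in% KEY_MYOTOME_LABELS,
    is_virtual_motor = SEGMENT_LABELS %in% VIRTUAL_MOTOR_LABELS
  )
}

#' Segment index on the canonical scale
#'
#' Converts segment labels (including the `"INT"` sentinel for a fully
#' intact side, which sorts one past `S45`) to their 1-based rostral to
#' caudal index. Shift distances between levels are differences of these
#' indices, so e.g. `T12 -> L1` is one segment.
#'
#' @param segment Character vector of segment labels (or `"INT"`).
#' @return Integer vector of indices (`INT` maps to `r INT_INDEX`).
#' @examples
#' segment_index(c("C1", "T12", "L1", "S45", "INT"))
#' @export
segment_index <- function(segment) {
  idx <- match(segment, SEGMENT_LABELS)
  idx[segment == INT_LEVEL] <- INT_INDEX
  if (anyNA(idx) && !all(is.na(segment[is.na(idx)]))) {
    bad <- unique(segment[is.na(idx) & !is.na(segment)])
    abort(paste0("Unknown segment label(s): ", paste(bad, collapse = ", ")),
          class = "vmscore_error_validation")
  }
  idx
}
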