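# CSV / JSON / YAML input-output.
#
# The exam CSV schema is one header row plus one row per exam with the
# 134 columns of exam_columns(); cells are integers or the literal "NT".
# Every file the package writes starts with a '#' comment line carrying
# the provenance (seed and configuration hash); readers skip '#' lines.

provenance_line <- function(seed = NA, config_hash = NA) {
  sprintf("# vmscore seed=%s config=%s", as.character(seed),
          as.character(config_hash))
}

#' Read a cohort of ISNCSCI exams from CSV
#'
#' Validates the header against the exam schema (`patient_id`, `exam_id`,
#' then per side `R`/`L` the `*_LT_*`/`*_PP_*` columns for the 28
#' dermatomes and `*_MS_*` for the 10 key myotomes), parses integer
#' scores with the literal `NT` mapped to `NA`, and rejects out-of-range
#' values and duplicate `(patient_id, exam_id)` pairs with row/column
#' diagnostics. Lines starting with `#` are ignored.
#'
#' @param path CSV file path.
#' @return Cohort tibble in the wide exam schema.
#' @export
read_exams <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         comment = "#", progress = FALSE)
  want <- exam_columns()
  if (!identical(names(raw), want)) {
    missing <- setdiff(want, names(raw))
    extra <- setdiff(names(raw), want)
    abort_validation(paste0(
      "exam CSV header does not match the exam schema",
      if (length(missing)) paste0("; missing: ", paste(head(missing, 5), collapse = ", "),
                                  if (length(missing) > 5) ", ..."),
      if (length(extra)) paste0("; unexpected: ", paste(head(extra, 5), collapse = ", "),
                                if (length(extra) > 5) ", ...")
    ))
  }
  score_cols <- want[-(1:2)]
  out <- raw
  for (cn in score_cols) {
    v <- raw[[cn]]
    v[v == "NT"] <- NA_character_
    num <- suppressWarnings(as.integer(v))
    hi <- if (grepl("_MS_", cn)) 5L else 2L
    bad <- which(!is.na(v) &
                   (is.na(num) | as.character(num) != v | num < 0L | num > hi))
    if (length(bad)) {
      abort_validation(sprintf(
        "invalid value '%s' in column %s, data row %d (expected integer 0..%d or NT)",
        raw[[cn]][bad[1]], cn, bad[1], hi))
    }
    out[[cn]] <- num
  }
  dup <- duplicated(out[c("patient_id", "exam_id")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort_validation(sprintf("duplicate (patient_id, exam_id) = (%s, %s) at data row %d",
                             out$patient_id[i], out$exam_id[i], i))
  }
  out
}

#' Write a cohort of ISNCSCI exams to CSV
#'
#' Writes the wide exam schema with `NT` for not-testable scores and a
#' leading `#` provenance comment (seed and configuration hash, when the
#' cohort carries them).
#'
#' @param exams Cohort tibble.
#' @param path Output CSV path.
#' @param seed Optional seed to stamp into the provenance line (defaults
#'   to the cohort's generator seed, if any).
#' @return `path`, invisibly.
#' @export
write_exams <- function(exams, path, seed = NULL) {
  want <- exam_columns()
  if (!all(want %in% names(exams))) {
    abort_validation("exams is missing exam schema columns")
  }
  out <- exams[want]
  for (cn in want[-(1:2)]) {
    v <- as.character(out[[cn]])
    v[is.na(v)] <- "NT"
    out[[cn]] <- v
  }
  seed <- seed %||% attr(exams, "generator_seed") %||% NA
  writeLines(provenance_line(seed, string_hash(want)), path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Write a model lookup table to CSV
#'
#' @param lookup A `vms_lookup` tibble from [lookup_table()].
#' @param path Output CSV path.
#' @param seed Optional provenance seed.
#' @return `path`, invisibly.
#' @export
write_lookup_csv <- function(lookup, path, seed = NA) {
  writeLines(provenance_line(seed, string_hash(attr(lookup, "feature_set") %||% "")),
             path)
  readr::write_csv(as_tibble(lookup), path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Serialize the published model registry to JSON
#'
#' Writes every registry entry (name, feature set, rule or intercept and
#' coefficients) plus the published random forest reference importances.
#'
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_registry <- function(path) {
  reg <- published_models()
  entries <- purrr::imap(reg, function(m, name) {
    e <- list(name = name, feature_set = m$feature_set,
              model = class(m)[1])
    if (inherits(m, "vms_linear")) {
      e$intercept <- m$intercept
      e$coefficients <- as.list(m$coefficients)
      if (!is.null(m$coef_sd)) e$coef_sd <- as.list(m$coef_sd)
    } else {
      e$rule <- "5 if all features normal; 0 if both absent (ISens); else 1"
    }
    e
  })
  jsonlite::write_json(
    list(models = unname(entries),
         rfr_reference_importances = published_rfr_importances()),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Write / read a generator configuration as YAML
#'
#' @param config A [generator_config()].
#' @param path YAML file path.
#' @return `write_generator_config()` returns `path` invisibly;
#'   `read_generator_config()` returns a validated
#'   [generator_config()].
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "vms_generator_config"))
  x <- unclass(config)
  m <- x$ms_given_sens
  x$ms_given_sens <- setNames(lapply(rownames(m), function(r) unname(m[r, ])),
                              rownames(m))
  # named atomic vectors must become lists to serialize as YAML maps
  for (v in c("nli_band_probs", "severity_probs", "transition_len_probs")) {
    x[[v]] <- as.list(x[[v]])
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$ms_given_sens)) {
    m <- do.call(rbind, x$ms_given_sens)
    colnames(m) <- as.character(0:5)
    x$ms_given_sens <- m
  }
  vecs <- c("nli_band_probs", "severity_probs", "transition_len_probs")
  for (v in vecs) if (!is.null(x[[v]])) x[[v]] <- unlist(x[[v]])
  do.call(generator_config, x)
}

#' Export shift analysis results
#'
#' Writes the per-side shift records as CSV and the summary statistics
#' (with model name and inclusion counts) as JSON.
#'
#' @param analysis A `vms_shift` object from [analyze_shift()].
#' @param records_path,stats_path Output paths (either may be `NULL` to
#'   skip).
#' @param seed Optional provenance seed.
#' @return Invisibly, a list of the written paths.
#' @export
write_shift_results <- function(analysis, records_path = NULL,
                                stats_path = NULL, seed = NA) {
  stopifnot(inherits(analysis, "vms_shift"))
  if (!is.null(records_path)) {
    writeLines(provenance_line(seed, string_hash(analysis$model_name)),
               records_path)
    readr::write_csv(analysis$records, records_path, append = TRUE,
                     col_names = TRUE, progress = FALSE)
  }
  if (!is.null(stats_path)) {
    jsonlite::write_json(
      c(list(model = analysis$model_name,
             n_sides = analysis$n_sides,
             n_indeterminate = analysis$n_indeterminate),
        as.list(analysis$stats)),
      stats_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(list(records = records_path, stats = stats_path))
}
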