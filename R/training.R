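# Model fitting and cross-validated benchmarking.
#
# Training data are segmental triplets: for each exam, side and key
# myotome (C5-T1, L2-S1), the examined motor score together with the
# segment's ipsilateral and contralateral sensory scores.  Rows with any
# not-testable value among the five scores are dropped at extraction.

#' Extract segmental training triplets from a cohort
#'
#' One row per (exam, side, key myotome) with the examined motor score
#' `ms`, the same-segment ipsilateral sensory scores `ilt`, `ipp` and the
#' contralateral `clt`, `cpp`. Rows with any not-testable (`NA`) value
#' among the five scores are excluded.
#'
#' @param exams Cohort tibble in the wide exam schema.
#' @return Tibble with columns `patient_id`, `exam_id`, `side`, `segment`,
#'   `ilt`, `clt`, `ipp`, `cpp`, `ms`.
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 5, seed = 1))
#' extract_triplets(cohort)
#' @export
extract_triplets <- function(exams) {
  grab <- function(s, kind, seg) as.integer(exams[[paste0(s, "_", kind, "_", seg)]])
  out <- vector("list", 20L)
  k <- 0L
  for (side in c("right", "left")) {
    s <- if (side == "right") "R" else "L"
    o <- if (side == "right") "L" else "R"
    for (seg in KEY_MYOTOME_LABELS) {
      k <- k + 1L
      out[[k]] <- tibble(
        patient_id = exams$patient_id,
        exam_id = exams$exam_id,
        side = side,
        segment = seg,
        ilt = grab(s, "LT", seg), clt = grab(o, "LT", seg),
        ipp = grab(s, "PP", seg), cpp = grab(o, "PP", seg),
        ms = grab(s, "MS", seg)
      )
    }
  }
  out <- dplyr::bind_rows(out)
  out <- out[stats::complete.cases(out[c("ilt", "clt", "ipp", "cpp", "ms")]), ]
  dplyr::arrange(out, .data$patient_id, .data$exam_id,
                 dplyr::desc(.data$side), segment_index(.data$segment))
}

#' Fit a (multiple) linear regression virtual score model
#'
#' Ordinary least squares of the motor score on the chosen sensory feature
#' set. The fitted model carries coefficient standard errors and p-values.
#'
#' @param rows Triplet tibble from [extract_triplets()].
#' @param feature_set Feature set name, see [feature_set()].
#' @return A `vms_linear` model.
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 30, seed = 2))
#' fit_mlr(extract_triplets(cohort), "ISens")
#' @export
fit_mlr <- function(rows, feature_set = "ISens") {
  fs_name <- match.arg(feature_set, FEATURE_SET_NAMES)
  feats <- FEATURE_SETS[[fs_name]]
  X <- rows[feats]
  if (nrow(unique(X)) < 2L) {
    abort("singular fit: fewer than 2 distinct feature tuples",
          class = "vmscore_error_singular_fit")
  }
  fml <- stats::as.formula(paste("ms ~", paste(feats, collapse = " + ")))
  fit <- lm(fml, data = rows)
  if (fit$rank < length(feats) + 1L) {
    abort("singular fit: rank-deficient design matrix",
          class = "vmscore_error_singular_fit")
  }
  cf <- summary(fit)$coefficients
  linear_model(
    fs_name,
    intercept = cf["(Intercept)", "Estimate"],
    coefficients = setNames(cf[feats, "Estimate"], feats),
    coef_sd = setNames(cf[feats, "Std. Error"], feats),
    p_values = setNames(cf[feats, "Pr(>|t|)"], feats)
  )
}

#' Fit a random forest regression virtual score model
#'
#' Seeded random forest regression of the motor score on the chosen
#' sensory feature set, with impurity-based feature importances
#' normalized to sum to 1.
#'
#' @param rows Triplet tibble from [extract_triplets()].
#' @param feature_set Feature set name, see [feature_set()].
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed; fixed rows and seed give identical forests.
#' @return A `vms_forest` model.
#' @export
fit_rfr <- function(rows, feature_set = "ISens", n_trees = 100L, seed = 1L) {
  fs_name <- match.arg(feature_set, FEATURE_SET_NAMES)
  feats <- FEATURE_SETS[[fs_name]]
  if (nrow(rows) == 0L) abort_validation("cannot fit a forest on zero rows")
  fml <- stats::as.formula(paste("ms ~", paste(feats, collapse = " + ")))
  fit <- ranger::ranger(
    fml, data = rows[c(feats, "ms")],
    num.trees = n_trees, importance = "impurity",
    seed = seed, num.threads = 1L
  )
  imp <- fit$variable.importance[feats]
  tot <- sum(imp)
  imp <- if (tot > 0) imp / tot else setNames(rep(1 / length(imp), length(imp)), feats)
  new_vms_model(
    list(feature_set = fs_name, n_trees = as.integer(n_trees),
         seed = as.integer(seed), fit = fit, importances = imp),
    "vms_forest"
  )
}

#' Cross-validation configuration
#'
#' Grouped, repeated K-fold cross-validation. Grouping by `patient` keeps
#' all rows of one patient (who may contribute several longitudinal exams)
#' in a single fold, preventing leakage across repeated exams of the same
#' person; `exam` groups by exam and `none` splits rows freely.
#'
#' @param n_folds Number of folds (>= 2; default 5).
#' @param n_repeats Number of repeats (default 5).
#' @param grouping `"patient"`, `"exam"` or `"none"`.
#' @param seed Integer seed driving all fold assignments.
#' @return A `vms_cv_config` list.
#' @export
cv_config <- function(n_folds = 5L, n_repeats = 5L,
                      grouping = c("patient", "exam", "none"), seed = 1L) {
  grouping <- match.arg(grouping)
  if (n_folds < 2L) abort_config("n_folds must be >= 2")
  if (n_repeats < 1L) abort_config("n_repeats must be >= 1")
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 grouping = grouping, seed = as.integer(seed)),
            class = "vms_cv_config")
}

cv_group_ids <- function(rows, grouping) {
  switch(grouping,
         patient = rows$patient_id,
         exam = paste(rows$patient_id, rows$exam_id, sep = "\x1f"),
         none = as.character(seq_len(nrow(rows))))
}

#' Cross-validated evaluation of a virtual score predictor
#'
#' Repeated grouped K-fold cross-validation: per held-out fold, the model
#' is fitted on the training rows (`MLR`, `RFR`) or applied as a fixed
#' rule without fitting (`CLM`), and the coefficient of determination
#' (R-squared) and root mean square error of its raw predictions against
#' the examined motor scores are computed on the held-out rows. R-squared
#' uses the held-out fold's variance as reference.
#'
#' @param rows Triplet tibble from [extract_triplets()].
#' @param model_kind `"CLM"`, `"MLR"` or `"RFR"`.
#' @param feature_set Feature set name (CLM supports ipsilateral sets only).
#' @param cv A [cv_config()].
#' @param n_trees Trees for `RFR`.
#' @return A `vms_cv` tibble with one row per fold x repeat: `repeat_`,
#'   `fold`, `n_test`, `r2`, `rmse`. Summarize with [glance()] /
#'   [eval_metrics()].
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 30, seed = 3))
#' rows <- extract_triplets(cohort)
#' glance(cv_evaluate(rows, "MLR", "ISens", cv_config(seed = 9)))
#' @export
cv_evaluate <- function(rows, model_kind = c("MLR", "RFR", "CLM"),
                        feature_set = "ISens", cv = cv_config(),
                        n_trees = 100L) {
  model_kind <- match.arg(model_kind)
  fs_name <- match.arg(feature_set, FEATURE_SET_NAMES)
  gid <- cv_group_ids(rows, cv$grouping)
  groups <- sort(unique(gid)) # row-order invariance of fold assignment
  if (length(groups) < cv$n_folds) {
    abort_config(sprintf("only %d %s group(s) for %d folds",
                         length(groups), cv$grouping, cv$n_folds))
  }
  res <- withr::with_seed(cv$seed, {
    out <- list()
    for (r in seq_len(cv$n_repeats)) {
      shuffled <- sample(groups)
      fold_of <- setNames(rep(seq_len(cv$n_folds), length.out = length(groups)),
                          shuffled)
      row_fold <- unname(fold_of[gid])
      for (f in seq_len(cv$n_folds)) {
        test <- rows[row_fold == f, ]
        train <- rows[row_fold != f, ]
        model <- switch(model_kind,
          CLM = clinical_model(fs_name),
          MLR = fit_mlr(train, fs_name),
          RFR = fit_rfr(train, fs_name, n_trees = n_trees,
                        seed = (cv$seed %% 100000L) * 1000L + r * 10L + f)
        )
        pred <- predict(model, test)
        err <- test$ms - pred
        sse <- sum(err^2)
        ss_tot <- sum((test$ms - mean(test$ms))^2)
        # a zero-variance held-out fold scores 1 when predicted exactly
        r2 <- if (ss_tot > 0) 1 - sse / ss_tot else if (sse == 0) 1 else NA_real_
        out[[length(out) + 1L]] <- tibble(
          repeat_ = r, fold = f, n_test = nrow(test),
          r2 = r2,
          rmse = sqrt(mean(err^2))
        )
      }
    }
    dplyr::bind_rows(out)
  })
  structure(res, class = c("vms_cv", class(res)),
            model_kind = model_kind, feature_set = fs_name, cv = cv)
}

#' Summarize cross-validation folds into mean +/- SD metrics
#'
#' @param folds A `vms_cv` tibble from [cv_evaluate()].
#' @return One-row tibble: `model`, `feature_set`, `r2_mean`, `r2_sd`,
#'   `rmse_mean`, `rmse_sd`, `n_folds`.
#' @export
eval_metrics <- function(folds) {
  tibble(
    model = attr(folds, "model_kind") %||% NA_character_,
    feature_set = attr(folds, "feature_set") %||% NA_character_,
    r2_mean = mean(folds$r2), r2_sd = sd(folds$r2),
    rmse_mean = mean(folds$rmse), rmse_sd = sd(folds$rmse),
    n_folds = nrow(folds)
  )
}

#' @method glance vms_cv
#' @export
glance.vms_cv <- function(x, ...) eval_metrics(x)

#' Benchmark all model/feature-set combinations on one triplet set
#'
#' Evaluates the clinical model (ipsilateral sets), multiple linear
#' regression and random forest regression on every applicable feature
#' set under one cross-validation design, mirroring the published
#' benchmarking layout.
#'
#' @inheritParams cv_evaluate
#' @return Tibble with one row per model x feature set (metrics as in
#'   [eval_metrics()]).
#' @export
benchmark_models <- function(rows, cv = cv_config(), n_trees = 100L) {
  combos <- dplyr::bind_rows(
    tidyr::expand_grid(model = "CLM", fs = IPSILATERAL_SETS),
    tidyr::expand_grid(model = c("MLR", "RFR"), fs = FEATURE_SET_NAMES)
  )
  purrr::pmap_dfr(combos, function(model, fs) {
    eval_metrics(cv_evaluate(rows, model, fs, cv = cv, n_trees = n_trees))
  })
}

#' Simulate triplets with a known linear conditional mean
#'
#' Generates sensory features uniformly over the integer grid and a motor
#' response `intercept + b_lt*ilt + b_pp*ipp` plus Gaussian noise —
#' the ground-truth recovery benchmark for [fit_mlr()]. `clip` controls
#' how the 0..5 motor range is enforced: `"mean"` clips the conditional
#' mean before noise is added (a no-op when the mean already lies in
#' range, so OLS recovers the generating coefficients), `"response"`
#' censors the noisy response at 0 and 5 (which attenuates fitted slopes
#' — see the methods vignette), `"none"` leaves the response unbounded.
#'
#' @param n Number of rows.
#' @param intercept,b_lt,b_pp Generating parameters.
#' @param sigma Gaussian noise standard deviation.
#' @param clip `"mean"`, `"response"` or `"none"`.
#' @param seed Integer seed.
#' @return Triplet tibble usable with [fit_mlr()] (contralateral columns
#'   mirror the ipsilateral ones; `ms` is continuous).
#' @export
simulate_linear_triplets <- function(n, intercept = 0.2, b_lt = 1.2,
                                     b_pp = 1.0, sigma = 1,
                                     clip = c("mean", "response", "none"),
                                     seed = 1L) {
  clip <- match.arg(clip)
  withr::with_seed(seed, {
    ilt <- sample(0:2, n, replace = TRUE)
    ipp <- sample(0:2, n, replace = TRUE)
    mu <- intercept + b_lt * ilt + b_pp * ipp
    if (clip == "mean") mu <- pmin(pmax(mu, 0), 5)
    ms <- mu + rnorm(n, sd = sigma)
    if (clip == "response") ms <- pmin(pmax(ms, 0), 5)
    tibble(
      patient_id = sprintf("SIM%06d", seq_len(n)),
      exam_id = "E1", side = "right", segment = "C5",
      ilt = ilt, clt = ilt, ipp = ipp, cpp = ipp, ms = ms
    )
  })
}
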