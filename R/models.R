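# Virtual motor score predictors.
#
# Three model families share one small interface: given a segment's integer
# sensory scores they return a raw (possibly non-integer) motor score
# estimate, which is then mathematically rounded and clamped to the 0..5
# motor grade scale.  Because sensory inputs are integers in 0..2, every
# model can be enumerated exhaustively as a lookup table.

FEATURE_SET_NAMES <- c("ILT", "IPP", "ISens", "ICSens")

FEATURE_SETS <- list(
  ILT    = "ilt",
  IPP    = "ipp",
  ISens  = c("ilt", "ipp"),
  ICSens = c("ilt", "clt", "ipp", "cpp")
)

IPSILATERAL_SETS <- c("ILT", "IPP", "ISens")

#' Sensory feature sets for virtual motor score models
#'
#' The four input-variable sets used by the predictors: `ILT` (ipsilateral
#' light touch alone), `IPP` (ipsilateral pinprick alone), `ISens`
#' (ipsilateral light touch and pinprick) and `ICSens` (ipsilateral and
#' contralateral light touch and pinprick).
#'
#' @param name One of `"ILT"`, `"IPP"`, `"ISens"`, `"ICSens"`.
#' @return Character vector of feature column names, in order
#'   (`ilt`, `clt`, `ipp`, `cpp` subset).
#' @examples
#' feature_set("ISens")
#' @export
feature_set <- function(name) {
  name <- match.arg(name, FEATURE_SET_NAMES)
  FEATURE_SETS[[name]]
}

new_vms_model <- function(x, class) {
  structure(x, class = c(class, "vms_model"))
}

#' Consensus clinical model (CLM) for virtual motor scores
#'
#' The rule-based transfer function generalized from the ISNCSCI
#' transition-zone convention: with both light touch and pinprick scores
#' (`ISens`) the virtual motor score is 5 if both are normal, 0 if both
#' are absent, and 1 otherwise. The single-modality variants score 5 for a
#' normal, 1 for an impaired and 0 for an absent sensory score.
#'
#' @param feature_set `"ISens"`, `"ILT"` or `"IPP"` (the rule is
#'   ipsilateral by construction; `"ICSens"` is not supported).
#' @return A `vms_clm` model object.
#' @examples
#' clm <- clinical_model("ISens")
#' predict(clm, data.frame(ilt = c(2, 0, 1), ipp = c(2, 0, 2)))
#' @export
clinical_model <- function(feature_set = "ISens") {
  feature_set <- match.arg(feature_set, FEATURE_SET_NAMES)
  if (!feature_set %in% IPSILATERAL_SETS) {
    abort("the clinical model is defined for ipsilateral feature sets only (ILT, IPP, ISens)",
          class = "vmscore_error_unsupported")
  }
  new_vms_model(list(feature_set = feature_set), "vms_clm")
}

#' Linear virtual motor score model from explicit coefficients
#'
#' Builds a (multiple) linear regression predictor `intercept + sum(coef *
#' feature)` over one of the sensory feature sets. Used both for the
#' published formulas (see [published_models()]) and for models fitted with
#' [fit_mlr()].
#'
#' @param feature_set Feature set name, see [feature_set()].
#' @param intercept Numeric intercept.
#' @param coefficients Named numeric vector, names exactly the feature set's
#'   features (`ilt`, `clt`, `ipp`, `cpp` subset).
#' @param coef_sd,p_values Optional named numeric vectors of coefficient
#'   standard errors / p-values (carried along for reporting).
#' @return A `vms_linear` model object.
#' @examples
#' m <- linear_model("ISens", 0.18, c(ilt = 1.22, ipp = 0.96))
#' predict(m, data.frame(ilt = 0, ipp = 1))
#' @export
linear_model <- function(feature_set, intercept, coefficients,
                         coef_sd = NULL, p_values = NULL) {
  feature_set <- match.arg(feature_set, FEATURE_SET_NAMES)
  feats <- FEATURE_SETS[[feature_set]]
  if (!setequal(names(coefficients), feats)) {
    abort(paste0("coefficients must be named exactly by the ", feature_set,
                 " features: ", paste(feats, collapse = ", ")),
          class = "vmscore_error_spec")
  }
  new_vms_model(
    list(feature_set = feature_set,
         intercept = as.numeric(intercept),
         coefficients = coefficients[feats],
         coef_sd = coef_sd, p_values = p_values),
    "vms_linear"
  )
}

#' @export
print.vms_model <- function(x, ...) {
  cat("<", class(x)[1], "> feature set: ", x$feature_set, "\n", sep = "")
  if (inherits(x, "vms_linear")) {
    terms <- paste(sprintf("%.4g*%s", x$coefficients, names(x$coefficients)),
                   collapse = " + ")
    cat("  ms_hat =", sprintf("%.4g", x$intercept), "+", terms, "\n")
  }
  if (inherits(x, "vms_forest")) {
    cat("  trees:", x$n_trees, " seed:", x$seed, "\n")
    cat("  importances:",
        paste(sprintf("%s=%.3f", names(x$importances), x$importances),
              collapse = ", "), "\n")
  }
  invisible(x)
}

check_features <- function(object, newdata) {
  feats <- FEATURE_SETS[[object$feature_set]]
  missing <- setdiff(feats, names(newdata))
  if (length(missing)) {
    abort(paste0("newdata lacks feature column(s): ",
                 paste(missing, collapse = ", ")),
          class = "vmscore_error_spec")
  }
  for (f in feats) {
    v <- newdata[[f]]
    if (any(!is.na(v) & !(v %in% 0:2))) {
      abort_validation(paste0("sensory feature '", f, "' outside 0..2"))
    }
  }
  newdata[feats]
}

#' Predict raw virtual motor scores
#'
#' `predict()` methods for the three model families. Predictions are *raw*
#' (not rounded, not clamped); use [round_half_up()] or [lookup_table()]
#' for the integer motor grades used in level determination. `NA` feature
#' values (not-testable scores) yield `NA` predictions.
#'
#' @param object A `vms_clm`, `vms_linear` or `vms_forest` model.
#' @param newdata Data frame with the model's feature columns
#'   (integer scores 0..2).
#' @param ... Unused.
#' @return Numeric vector of raw predicted motor scores.
#' @name predict-vms
NULL

#' @rdname predict-vms
#' @export
predict.vms_clm <- function(object, newdata, ...) {
  nd <- check_features(object, newdata)
  out <- switch(
    object$feature_set,
    ISens = ifelse(nd$ilt == 2 & nd$ipp == 2, 5,
                   ifelse(nd$ilt == 0 & nd$ipp == 0, 0, 1)),
    ILT = ifelse(nd$ilt == 2, 5, ifelse(nd$ilt == 1, 1, 0)),
    IPP = ifelse(nd$ipp == 2, 5, ifelse(nd$ipp == 1, 1, 0))
  )
  as.numeric(out)
}

#' @rdname predict-vms
#' @export
predict.vms_linear <- function(object, newdata, ...) {
  nd <- check_features(object, newdata)
  out <- rep(object$intercept, nrow(nd))
  for (f in names(object$coefficients)) {
    out <- out + object$coefficients[[f]] * nd[[f]]
  }
  as.numeric(out)
}

#' @rdname predict-vms
#' @export
predict.vms_forest <- function(object, newdata, ...) {
  nd <- check_features(object, newdata)
  out <- rep(NA_real_, nrow(nd))
  ok <- stats::complete.cases(nd)
  if (any(ok)) {
    out[ok] <- predict(object$fit, data = nd[ok, , drop = FALSE])$predictions
  }
  out
}

#' Mathematical (half-up) rounding
#'
#' Rounds a non-negative raw motor score to the nearest integer with ties
#' going up: `floor(x + 0.5)`. The threshold between grades 4 and 5 is
#' therefore exactly 4.5 — the single-modality linear models top out near
#' 4.4 and so can never produce a rounded 5, which is what disqualifies
#' them for motor level determination.
#'
#' @param x Numeric vector, `x >= 0`.
#' @return Integer vector.
#' @examples
#' round_half_up(c(4.53, 2.35, 2.5))
#' @export
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

#' Enumerate a model as an integer lookup table
#'
#' Because sensory scores are integers in 0..2, each predictor is fully
#' described by a small table: 3 rows for a single-modality feature set,
#' 9 for `ISens`, 81 for `ICSens`. The `rounded` column is
#' `round_half_up(raw)` clamped to the motor grade range 0..5 and is what
#' enters motor level recalculation; `raw` is reported unclamped.
#'
#' @param model A `vms_model`.
#' @return A `vms_lookup` tibble with one column per feature plus `raw`
#'   and `rounded`.
#' @examples
#' lookup_table(published_models()$MLR_ISens)
#' @export
lookup_table <- function(model) {
  stopifnot(inherits(model, "vms_model"))
  feats <- FEATURE_SETS[[model$feature_set]]
  grid <- rev(expand.grid(rev(setNames(rep(list(0:2), length(feats)), feats))))
  grid <- as_tibble(grid)
  raw <- predict(model, grid)
  out <- dplyr::mutate(
    grid,
    raw = raw,
    rounded = pmin(pmax(round_half_up(raw), 0L), 5L)
  )
  structure(out,
            class = c("vms_lookup", class(out)),
            feature_set = model$feature_set,
            model_class = class(model)[1])
}

# fast vectorized (lt, pp) -> rounded virtual score closure for one model;
# NA sensory input (NT) maps to NA (indeterminate virtual score)
virtual_score_fun <- function(model) {
  if (!model$feature_set %in% IPSILATERAL_SETS) {
    abort("virtual motor scores require an ipsilateral model (ILT, IPP or ISens)",
          class = "vmscore_error_unsupported")
  }
  tbl <- lookup_table(model)
  if (model$feature_set == "ISens") {
    rounded <- tbl$rounded[order(tbl$ilt * 3L + tbl$ipp)]
    function(lt, pp) rounded[lt * 3L + pp + 1L]
  } else if (model$feature_set == "ILT") {
    rounded <- tbl$rounded[order(tbl$ilt)]
    function(lt, pp) rounded[lt + 1L]
  } else {
    rounded <- tbl$rounded[order(tbl$ipp)]
    function(lt, pp) rounded[pp + 1L]
  }
}

#' Published virtual motor score models
#'
#' The model registry: the consensus clinical rule for each ipsilateral
#' feature set, and the published linear regression formulas for all four
#' feature sets —
#' `0.14 + 2.10*ILT`; `0.61 + 1.92*IPP`; `0.18 + 1.22*ILT + 0.96*IPP`;
#' `0.14 + 0.76*ILT + 0.39*CLT + 0.50*IPP + 0.56*CPP`.
#' Random forest models are characterized by feature importances rather
#' than a formula and depend on fitting; the published importances are
#' available as reference metadata via [published_rfr_importances()], and
#' fitted forests come from [fit_rfr()].
#'
#' @return Named list of `vms_model` objects: `CLM_ILT`, `CLM_IPP`,
#'   `CLM_ISens`, `MLR_ILT`, `MLR_IPP`, `MLR_ISens`, `MLR_ICSens`.
#' @examples
#' published_models()$MLR_ISens
#' @export
published_models <- function() {
  sd2 <- function(feats) setNames(rep(0.02, length(feats)), feats)
  sd1 <- function(feats) setNames(rep(0.01, length(feats)), feats)
  list(
    CLM_ILT   = clinical_model("ILT"),
    CLM_IPP   = clinical_model("IPP"),
    CLM_ISens = clinical_model("ISens"),
    MLR_ILT   = linear_model("ILT", 0.14, c(ilt = 2.10), coef_sd = sd2("ilt")),
    MLR_IPP   = linear_model("IPP", 0.61, c(ipp = 1.92), coef_sd = sd1("ipp")),
    MLR_ISens = linear_model("ISens", 0.18, c(ilt = 1.22, ipp = 0.96),
                             coef_sd = sd2(c("ilt", "ipp"))),
    MLR_ICSens = linear_model(
      "ICSens", 0.14,
      c(ilt = 0.76, clt = 0.39, ipp = 0.50, cpp = 0.56),
      coef_sd = sd1(c("ilt", "clt", "ipp", "cpp"))
    )
  )
}

#' Published random forest feature importances (reference metadata)
#'
#' Impurity-based feature importances of the published random forest
#' regressors, per feature set. These are reference values only: exact
#' forest predictions depend on hyperparameters and training data, so the
#' package never hard-codes a forest — fitted forests come from
#' [fit_rfr()].
#'
#' @return Tibble with columns `feature_set`, `feature`, `importance`,
#'   `importance_sd`.
#' @export
published_rfr_importances <- function() {
  tibble(
    feature_set = c("ILT", "IPP", "ISens", "ISens",
                    "ICSens", "ICSens", "ICSens", "ICSens"),
    feature = c("ilt", "ipp", "ilt", "ipp", "ilt", "ipp", "clt", "cpp"),
    importance = c(1.00, 1.00, 0.72, 0.28, 0.25, 0.03, 0.00, 0.72),
    importance_sd = c(0.00, 0.00, 0.34, 0.34, 0.19, 0.04, 0.00, 0.18)
  )
}

#' @method tidy vms_linear
#' @export
tidy.vms_linear <- function(x, ...) {
  tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients)),
    std.error = c(NA_real_,
                  if (is.null(x$coef_sd)) rep(NA_real_, length(x$coefficients))
                  else unname(x$coef_sd[names(x$coefficients)])),
    p.value = c(NA_real_,
                if (is.null(x$p_values)) rep(NA_real_, length(x$coefficients))
                else unname(x$p_values[names(x$coefficients)]))
  )
}

#' @method tidy vms_forest
#' @export
tidy.vms_forest <- function(x, ...) {
  tibble(
    term = names(x$importances),
    importance = unname(x$importances)
  )
}

#' @method tidy vms_clm
#' @export
tidy.vms_clm <- function(x, ...) {
  lookup_table(x) %>% dplyr::select(-"raw") %>% as_tibble()
}

#' @method glance vms_model
#' @export
glance.vms_model <- function(x, ...) {
  tibble(
    model = class(x)[1],
    feature_set = x$feature_set,
    n_features = length(FEATURE_SETS[[x$feature_set]]),
    n_lookup = 3L^length(FEATURE_SETS[[x$feature_set]])
  )
}
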