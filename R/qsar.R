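#' Construct a linear QSAR model
#'
#' A fitted (or frozen) linear model of the form
#' `log k = intercept + sum(coefficient * descriptor)`.
#'
#' @param enm_id Nanomaterial identifier the model predicts for.
#' @param intercept Numeric intercept.
#' @param terms Named numeric vector of descriptor coefficients.
#' @param meta Optional named list of metadata (split ratio, seed, training
#'   size, reported fit statistics, ...).
#' @return An object of class `qsar_model`.
#' @export
qsar_model <- function(enm_id, intercept, terms, meta = list()) {
  terms <- terms %||% stats::setNames(numeric(0), character(0))
  if (length(terms) > 0 && (is.null(names(terms)) || any(!nzchar(names(terms))))) {
    abort_validation("`terms` must be a fully named numeric vector.")
  }
  check_finite(intercept, "intercept")
  check_finite(unname(terms), "coefficients")
  structure(list(enm_id = as.character(enm_id),
                 intercept = as.numeric(intercept),
                 terms = vapply(terms, as.numeric, 1.0),
                 meta = meta),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  rhs <- paste(sprintf("%+.4g*%s", unname(x$terms), names(x$terms)), collapse = " ")
  cat(sprintf("<qsar_model %s> log k = %.4g %s\n", x$enm_id, x$intercept, rhs))
  invisible(x)
}

#' @rdname qsar_model
#' @param x A `qsar_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qsar_model <- function(x, ...) {
  tibble::tibble(enm_id = x$enm_id,
                 term = c("(Intercept)", names(x$terms)),
                 estimate = c(x$intercept, unname(x$terms)))
}

#' @rdname qsar_model
#' @exportS3Method generics::glance
glance.qsar_model <- function(x, ...) {
  tibble::tibble(enm_id = x$enm_id,
                 n_terms = length(x$terms),
                 r2_train = x$meta$r2_train %||% NA_real_,
                 r2_validate = x$meta$r2_validate %||% NA_real_,
                 ad_fraction = x$meta$ad_fraction %||% NA_real_)
}

#' Evaluate a linear QSAR model on a descriptor table
#'
#' @param model A [qsar_model()].
#' @param table Data frame holding every descriptor the model uses.
#' @return Numeric vector of predicted log k, one per row of `table`.
#' @export
evaluate_model <- function(model, table) {
  stopifnot(inherits(model, "qsar_model"))
  missing <- setdiff(names(model$terms), names(table))
  if (length(missing) > 0) {
    abort(sprintf("descriptor column(s) required by model '%s' are missing: %s.",
                  model$enm_id, paste0("`", missing, "`", collapse = ", ")),
          class = "nanosorb_format_error")
  }
  pred <- rep(model$intercept, nrow(as.data.frame(table)))
  for (d in names(model$terms)) {
    check_finite(table[[d]], d)
    pred <- pred + model$terms[[d]] * table[[d]]
  }
  pred
}

#' @export
predict.qsar_model <- function(object, newdata, ...) {
  evaluate_model(object, newdata)
}

#' Load the frozen per-nanomaterial QSAR equations
#'
#' The package ships the 19 published descriptor-based equations (one per
#' nanomaterial: 13 metal particles, 5 multiwalled carbon nanotubes, 1
#' fullerene), each with an intercept and exactly five descriptor terms,
#' together with their reported adjusted R-squared values (80/20
#' training/validation split) and Williams-plot applicability-domain
#' fractions.
#'
#' @return A named list of 19 [qsar_model()] objects, names = nanomaterial
#'   ids.
#' @export
#' @examples
#' models <- load_frozen_models()
#' evaluate_model(models[["AlOOH"]], data.frame(ALogP = 0, nHBDon = 0,
#'   Fsp3 = 0, ATSm1 = 0, nBase = 0))  # the intercept, 1.79
load_frozen_models <- function() {
  reg <- jsonlite::fromJSON(nanosorb_file("cdk_models.json"),
                            simplifyDataFrame = FALSE)
  models <- purrr::map(reg$models, function(m) {
    qsar_model(m$enm_id, m$intercept, unlist(m$terms),
               meta = list(type = m$type, r2_train = m$r2_train,
                           r2_validate = m$r2_validate,
                           ad_fraction = m$ad_fraction, frozen = TRUE))
  })
  names(models) <- purrr::map_chr(models, "enm_id")
  if (length(models) != 19 || anyDuplicated(names(models))) {
    abort("frozen model registry is corrupt: expected 19 uniquely named models.")
  }
  bad <- names(models)[purrr::map_int(models, ~ length(.x$terms)) != 5]
  if (length(bad) > 0) {
    abort(sprintf("frozen model(s) without exactly 5 terms: %s.",
                  paste(bad, collapse = ", ")))
  }
  models
}

#' Overview table of the frozen models
#'
#' @return A tibble with one row per frozen model term (long form), plus the
#'   reported fit statistics, convenient for joins and plotting.
#' @export
frozen_model_table <- function() {
  models <- load_frozen_models()
  purrr::map_dfr(models, function(m) {
    dplyr::mutate(tidy(m),
                  r2_train = m$meta$r2_train,
                  r2_validate = m$meta$r2_validate,
                  ad_fraction = m$meta$ad_fraction)
  })
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)`, the penalised goodness of fit used
#' to score models across cross-validation ratios.
#'
#' @param observed Observed response values.
#' @param predicted Predicted values, same length.
#' @param p Number of predictors (excluding the intercept).
#' @return The adjusted R-squared (equals plain R-squared when `p = 0`).
#' @export
adjusted_r2 <- function(observed, predicted, p) {
  n <- length(observed)
  stopifnot(length(predicted) == n)
  if (n <= p + 1) abort_validation("need n > p + 1 observations (n=%d, p=%d).", n, p)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) abort_validation("observed values have zero variance.")
  r2 <- 1 - sum((observed - predicted)^2) / ss_tot
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Variance-inflation factor
#'
#' VIF of a column is `1 / (1 - R2)` from regressing that column on all other
#' columns of the design; it quantifies collinearity. Perfectly collinear
#' columns report `Inf` rather than raising an error.
#'
#' @param data Data frame of numeric candidate columns (at least two).
#' @param column Optional single column name; default computes all VIFs.
#' @return Named numeric vector of VIFs (or a single value when `column` is
#'   given).
#' @export
vif <- function(data, column = NULL) {
  data <- as.data.frame(data)
  num <- vapply(data, is.numeric, TRUE)
  data <- data[num]
  if (ncol(data) < 2) abort_validation("VIF needs at least two columns.")
  if (nrow(data) <= ncol(data)) {
    abort_validation("VIF needs more rows (%d) than columns (%d).",
                     nrow(data), ncol(data))
  }
  one <- function(col) {
    y <- data[[col]]
    x <- as.matrix(data[setdiff(names(data), col)])
    fit <- stats::lm.fit(cbind(1, x), y)
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot == 0) return(Inf)
    r2 <- 1 - sum(fit$residuals^2) / ss_tot
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  if (!is.null(column)) {
    if (!column %in% names(data)) abort_validation("column `%s` not in design.", column)
    return(one(column))
  }
  vapply(stats::setNames(names(data), names(data)), one, 1.0)
}

#' Split compounds into training and validation sets
#'
#' Response-stratified partitioning for QSAR model building. The compounds
#' with the global minimum and maximum response are always placed in the
#' training set, so the model never extrapolates beyond its training range.
#' The remaining compounds are binned into `n_quantiles` response quantiles
#' and each bin is split at the requested ratio uniformly at random.
#'
#' @param data Data frame with a `compound_id` column and the response column.
#' @param response Name of the response column (default `"log_k"`).
#' @param ratio Training fraction; the published pipeline examined 0.9, 0.8,
#'   0.7 and 0.6 and settled on 0.8 as default.
#' @param seed Integer seed; identical seeds give identical partitions.
#' @param n_quantiles Number of response bins (default 5). Reduced, with a
#'   warning, when bins would be too small.
#' @return The input tibble with an added `set` column
#'   (`"train"`/`"validate"`).
#' @export
partition_dataset <- function(data, response = "log_k", ratio = 0.8,
                              seed = 1L, n_quantiles = 5L) {
  data <- tibble::as_tibble(data)
  check_columns(data, c("compound_id", response), "compound table")
  y <- data[[response]]
  check_finite(y, response)
  if (ratio <= 0 || ratio >= 1) abort_validation("`ratio` must be in (0, 1).")
  n <- nrow(data)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  set <- rep("train", n)
  extremes <- c(which.min(y), which.max(y))
  rest <- setdiff(seq_len(n), extremes)
  if (length(rest) == 0) {
    warn("too few compounds: all placed in the training set, validation empty.")
  } else {
    k <- n_quantiles
    while (k > 1 && length(rest) / k < 2) k <- k - 1
    if (k < n_quantiles) {
      warn(sprintf("too few compounds per bin: using %d quantile bins instead of %d.",
                   k, n_quantiles))
    }
    bins <- if (k == 1) rep(1L, length(rest)) else {
      brk <- stats::quantile(y[rest], probs = seq(0, 1, length.out = k + 1))
      as.integer(cut(y[rest], breaks = unique(brk), include.lowest = TRUE))
    }
    for (b in unique(bins)) {
      idx <- rest[bins == b]
      n_train <- round(ratio * length(idx))
      train_idx <- if (n_train >= length(idx)) idx else sample(idx, n_train)
      set[setdiff(idx, train_idx)] <- "validate"
    }
  }
  dplyr::mutate(data, set = set)
}

#' Forward-selection multiple linear regression with a VIF guard
#'
#' Builds a linear QSAR model by forward selection: at each step the candidate
#' descriptor giving the largest coefficient of determination is added,
#' provided its inclusion keeps the variance-inflation factor of every
#' included descriptor at or below `vif_max` (the collinearity guard).
#' Selection stops after `max_terms` descriptors or as soon as no admissible
#' candidate improves the fit; the final model is refit by ordinary least
#' squares on the selected columns. Ties in R-squared gain are broken by
#' lexicographic descriptor name, so selection is deterministic.
#'
#' @param data Data frame of numeric candidate descriptor columns (a
#'   `compound_id` column, if present, is ignored as a candidate).
#' @param response Numeric response vector (log k), aligned with `data` rows.
#' @param max_terms Maximum number of descriptors (default 5).
#' @param vif_max Largest admissible VIF (default 2).
#' @param enm_id Label stored on the resulting model.
#' @return An object of class `qsar_fit`: a list with the fitted `model`
#'   ([qsar_model()]), the selection `trace` (step, descriptor, r2, max_vif),
#'   `r2_train_adj`, and the `lm` object `fit`.
#' @export
forward_select <- function(data, response, max_terms = 5L, vif_max = 2,
                           enm_id = "model") {
  data <- as.data.frame(data)
  data$compound_id <- NULL
  keep <- vapply(data, is.numeric, TRUE)
  data <- data[keep]
  n <- nrow(data)
  if (length(response) != n) abort_validation("`response` must align with `data` rows.")
  if (n < max_terms + 2) abort_validation("need at least max_terms + 2 rows.")
  if (ncol(data) == 0) abort_validation("no candidate descriptor columns.")
  check_finite(response, "response")

  selected <- character()
  trace <- list()
  r2_of <- function(cols) {
    fit <- stats::lm.fit(cbind(1, as.matrix(data[cols])), response)
    ss_tot <- sum((response - mean(response))^2)
    if (ss_tot == 0) return(0)
    1 - sum(fit$residuals^2) / ss_tot
  }
  best_r2 <- 0
  constant_response <- stats::var(response) == 0

  while (!constant_response && length(selected) < max_terms) {
    candidates <- sort(setdiff(names(data), selected))
    admissible <- candidates[vapply(candidates, function(cand) {
      cols <- c(selected, cand)
      if (length(cols) < 2) return(TRUE)
      all(vif(data[cols]) <= vif_max)
    }, TRUE)]
    if (length(admissible) == 0) {
      if (length(selected) == 0) {
        abort_validation("no admissible first descriptor under the VIF constraint.")
      }
      break
    }
    gains <- vapply(admissible, function(cand) r2_of(c(selected, cand)), 1.0)
    best <- admissible[which.max(gains)]   # which.max on sorted names: lexicographic ties
    if (gains[best] <= best_r2 + 1e-12) break
    selected <- c(selected, best)
    max_vif <- if (length(selected) >= 2) max(vif(data[selected])) else NA_real_
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = length(selected), descriptor = best,
      r2 = unname(gains[best]), max_vif = max_vif)
    best_r2 <- gains[best]
  }

  if (length(selected) == 0) {
    fit <- stats::lm(response ~ 1)
    coefs <- numeric(0)
  } else {
    df_fit <- data.frame(.y = response, data[selected], check.names = FALSE)
    fit <- stats::lm(.y ~ ., data = df_fit)
    coefs <- stats::coef(fit)[-1]
    names(coefs) <- selected
  }
  r2_adj <- if (length(selected) == 0 || constant_response) NA_real_ else
    adjusted_r2(response, stats::fitted(fit), length(selected))

  structure(list(
    model = qsar_model(enm_id, unname(stats::coef(fit)[1]), coefs,
                       meta = list(n_train = n)),
    trace = if (length(trace)) dplyr::bind_rows(trace) else
      tibble::tibble(step = integer(), descriptor = character(),
                     r2 = numeric(), max_vif = numeric()),
    r2_train_adj = r2_adj,
    r2_validate_adj = NA_real_,
    fit = fit
  ), class = "qsar_fit")
}

#' Train a QSAR model with a response-stratified split
#'
#' Convenience pipeline: partition the compounds with [partition_dataset()],
#' run [forward_select()] on the training portion, and score the held-out
#' validation portion with the adjusted R-squared (computed with n =
#' validation size and p = number of selected descriptors).
#'
#' @inheritParams partition_dataset
#' @inheritParams forward_select
#' @param descriptors Data frame of candidate descriptor columns aligned with
#'   `data`.
#' @return A `qsar_fit` with `r2_validate_adj` filled in and the split stored
#'   in the model metadata.
#' @export
train_qsar <- function(descriptors, data, response = "log_k", ratio = 0.8,
                       seed = 1L, n_quantiles = 5L, max_terms = 5L,
                       vif_max = 2, enm_id = "model") {
  part <- partition_dataset(data, response = response, ratio = ratio,
                            seed = seed, n_quantiles = n_quantiles)
  train <- part$set == "train"
  fit <- forward_select(descriptors[train, , drop = FALSE],
                        data[[response]][train],
                        max_terms = max_terms, vif_max = vif_max,
                        enm_id = enm_id)
  fit$model$meta <- c(fit$model$meta,
                      list(ratio = ratio, seed = seed, n_validate = sum(!train)))
  if (sum(!train) > length(fit$model$terms) + 1) {
    pred <- evaluate_model(fit$model, descriptors[!train, , drop = FALSE])
    fit$r2_validate_adj <- adjusted_r2(data[[response]][!train], pred,
                                       length(fit$model$terms))
  }
  fit$partition <- part
  fit
}

#' @export
print.qsar_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  adj. R2 (train) = %.3f, adj. R2 (validate) = %.3f\n",
              x$r2_train_adj, x$r2_validate_adj))
  invisible(x)
}

#' @rdname forward_select
#' @param x A `qsar_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qsar_fit <- function(x, ...) tidy(x$model)

#' @rdname forward_select
#' @exportS3Method generics::glance
glance.qsar_fit <- function(x, ...) {
  tibble::tibble(enm_id = x$model$enm_id,
                 n_terms = length(x$model$terms),
                 r2_train_adj = x$r2_train_adj,
                 r2_validate_adj = x$r2_validate_adj,
                 n_train = x$model$meta$n_train %||% NA_integer_,
                 ratio = x$model$meta$ratio %||% NA_real_,
                 seed = x$model$meta$seed %||% NA_integer_)
}

#' Regression-diagnostic quantities for a fitted QSAR model
#'
#' The raw numbers behind the usual diagnostic plots (residuals vs fitted,
#' normal Q-Q, scale-location, Cook's distance), exported as data so they can
#' be inspected or written to CSV rather than rendered.
#'
#' @param fit A `qsar_fit`.
#' @return A tibble with `fitted`, `residual`, `std_residual`,
#'   `theoretical_quantile`, `sqrt_abs_std_residual`, `leverage` and
#'   `cooks_distance`.
#' @export
qsar_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "qsar_fit"))
  lmfit <- fit$fit
  std <- stats::rstandard(lmfit)
  tibble::tibble(
    fitted = stats::fitted(lmfit),
    residual = stats::residuals(lmfit),
    std_residual = std,
    theoretical_quantile = stats::qnorm(stats::ppoints(length(std)))[order(order(std))],
    sqrt_abs_std_residual = sqrt(abs(std)),
    leverage = stats::hatvalues(lmfit),
    cooks_distance = stats::cooks.distance(lmfit)
  )
}
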