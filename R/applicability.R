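#' Leverages (diagonal hat values) of a design matrix
#'
#' The leverage of a compound is the corresponding diagonal element of the
#' projection ("hat") matrix `X (X'X)^-1 X'` of the model design; it measures
#' the compound's distance from the centre of the training design. Leverages
#' lie in \[0, 1\] and sum to the number of design columns (including the
#' intercept).
#'
#' @param design Data frame or matrix of numeric descriptor columns.
#' @param add_intercept Prepend an intercept column (default `TRUE`). Pass
#'   `FALSE` when `design` already contains one.
#' @return Numeric vector of hat values, one per row.
#' @export
leverages <- function(design, add_intercept = TRUE) {
  x <- as.matrix(as.data.frame(design))
  storage.mode(x) <- "double"
  check_finite(as.vector(x), "design")
  if (add_intercept) x <- cbind(`(Intercept)` = 1, x)
  if (nrow(x) < ncol(x)) abort_validation("design needs n >= p rows.")
  qx <- qr(x)
  if (qx$rank < ncol(x)) abort_validation("design matrix is rank deficient.")
  q <- qr.Q(qx)
  rowSums(q^2)
}

#' Critical hat value
#'
#' The conventional leverage cut-off `3 * (N + 1) / n`, where `N` is the
#' number of molecule descriptors in the model and `n` the size of the
#' reference (probe or training) set. Compounds above it sit far from the
#' descriptor-space centre of the reference compounds.
#'
#' @param n_descriptors Number of descriptors, N.
#' @param n_reference Reference-set size, n (> 0).
#' @return `3 * (N + 1) / n` (may exceed 1 for tiny reference sets).
#' @export
#' @examples
#' critical_hat(5, 23)  # 0.78 to two decimals
critical_hat <- function(n_descriptors, n_reference) {
  if (n_reference <= 0) abort_validation("`n_reference` must be positive.")
  3 * (n_descriptors + 1) / n_reference
}

#' Insubria applicability-domain filter
#'
#' Insubria graphs assess where predictions for compounds *without* measured
#' responses may be trusted: leverage on the x-axis, prediction on the
#' y-axis. Three threshold modes are supported:
#' `"both_thresholds"` (leverage below the critical hat AND prediction inside
#' the probe band mean +/- 3 sd), `"hat_only"` (leverage criterion alone) and
#' `"none"` (every compound in the domain). The leverage criterion is strict
#' (`h < h*`: a compound exactly at the critical hat is out), matching the
#' convention that only compounds *smaller* than the critical value are
#' retained; the band uses the sample (n-1) standard deviation of the probe
#' predictions.
#'
#' @param predictions Predicted log k per compound.
#' @param hats Leverage per compound, aligned with `predictions`.
#' @param h_star Critical hat value, see [critical_hat()].
#' @param probe_predictions Predictions for the probe compounds defining the
#'   log k band; required for mode `"both_thresholds"`.
#' @param mode One of `"both_thresholds"`, `"hat_only"`, `"none"`.
#' @param ids Optional compound ids.
#' @return An `ad_report` tibble: `compound_id`, `h`, `pred`, `in_domain`,
#'   with attributes `mode`, `h_star` and (when applicable) `thresholds`.
#' @export
insubria_filter <- function(predictions, hats, h_star,
                            probe_predictions = NULL,
                            mode = c("both_thresholds", "hat_only", "none"),
                            ids = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(predictions) == length(hats))
  check_finite(predictions, "predictions")
  check_finite(hats, "hats")
  thresholds <- c(low = -Inf, high = Inf)
  if (mode == "both_thresholds") {
    if (is.null(probe_predictions) || length(probe_predictions) == 0) {
      abort_validation("mode 'both_thresholds' needs non-empty `probe_predictions`.")
    }
    m <- mean(probe_predictions)
    s <- stats::sd(probe_predictions)
    thresholds <- c(low = m - 3 * s, high = m + 3 * s)
  }
  in_domain <- switch(mode,
    none = rep(TRUE, length(predictions)),
    hat_only = hats < h_star,
    both_thresholds = hats < h_star &
      predictions >= thresholds[["low"]] & predictions <= thresholds[["high"]]
  )
  out <- tibble::tibble(
    compound_id = as.character(ids %||% seq_along(predictions)),
    h = hats, pred = predictions, in_domain = in_domain)
  attr(out, "mode") <- mode
  attr(out, "h_star") <- h_star
  if (mode == "both_thresholds") attr(out, "thresholds") <- thresholds
  class(out) <- c("ad_report", class(out))
  out
}

#' Williams-plot applicability-domain flags
#'
#' Williams plots assess training/validation compounds with measured (or
#' surrogate) responses: standardized cross-validated residual vs leverage.
#' A compound is outside the domain if its residual falls below -3 or above 3
#' or if its leverage exceeds the critical hat value; note the boundary
#' convention differs from the Insubria filter (`h = h*` is still *in* here,
#' because only values strictly larger are excluded).
#'
#' @param std_residuals Standardized cross-validated (leave-one-out)
#'   residuals; see [loo_residuals()].
#' @param hats Leverages aligned with the residuals.
#' @param h_star Critical hat value.
#' @param ids Optional compound ids.
#' @return An `ad_report` tibble: `compound_id`, `h`, `residual`,
#'   `in_domain`.
#' @export
williams_flags <- function(std_residuals, hats, h_star, ids = NULL) {
  stopifnot(length(std_residuals) == length(hats))
  out <- tibble::tibble(
    compound_id = as.character(ids %||% seq_along(hats)),
    h = hats, residual = std_residuals,
    in_domain = abs(std_residuals) <= 3 & hats <= h_star)
  attr(out, "h_star") <- h_star
  attr(out, "mode") <- "williams"
  class(out) <- c("ad_report", class(out))
  out
}

#' Leave-one-out standardized residuals of a linear fit
#'
#' Externally studentized residuals: each compound's residual is scaled by an
#' error estimate computed with that compound left out, which is the
#' cross-validated quantity Williams plots call for.
#'
#' @param design Descriptor data frame (intercept added internally).
#' @param response Numeric response vector.
#' @return Numeric vector of studentized residuals.
#' @export
loo_residuals <- function(design, response) {
  df <- data.frame(.y = response, as.data.frame(design), check.names = FALSE)
  stats::rstudent(stats::lm(.y ~ ., data = df))
}

#' Ordination-centroid applicability domain
#'
#' A distance-based domain: all compounds are embedded in two dimensions by
#' non-metric multidimensional scaling (NMDS) of their pairwise Mahalanobis
#' distances (pooled covariance of the full compound set); a compound is in
#' the domain if its distance to the centroid of the probe compounds is no
#' larger than the domain radius. The radius defaults to the largest
#' probe-to-centroid distance, so every probe is inside its own domain.
#'
#' @param descriptors Data frame of numeric descriptor columns with a
#'   `compound_id` column (or rownames used as ids).
#' @param probe_ids Ids of the (>= 3) probe compounds.
#' @param k Embedding dimension (default 2).
#' @param trymax Random restarts for NMDS (default 20).
#' @param seed Integer seed for the NMDS starts.
#' @return A tibble `compound_id`, `axis1`, `axis2`, `dist_to_centroid`,
#'   `in_domain`, with attributes `radius` and `stress`.
#' @export
ordination_centroid_ad <- function(descriptors, probe_ids, k = 2,
                                   trymax = 20, seed = 1L) {
  descriptors <- tibble::as_tibble(descriptors)
  if (!"compound_id" %in% names(descriptors)) {
    descriptors$compound_id <- as.character(seq_len(nrow(descriptors)))
  }
  ids <- as.character(descriptors$compound_id)
  probe_ids <- as.character(probe_ids)
  if (length(probe_ids) < 3) abort_validation("need at least 3 probe compounds.")
  if (!all(probe_ids %in% ids)) {
    abort_validation("probe id(s) not present: %s.",
                     paste(setdiff(probe_ids, ids), collapse = ", "))
  }
  x <- as.matrix(dplyr::select(descriptors, -"compound_id"))
  storage.mode(x) <- "double"

  d <- vegan::vegdist(x, method = "mahalanobis")
  if (all(d < .Machine$double.eps^0.5)) {
    # degenerate cloud: every compound coincides with the probes
    out <- tibble::tibble(compound_id = ids, axis1 = 0, axis2 = 0,
                          dist_to_centroid = 0, in_domain = TRUE)
    attr(out, "radius") <- 0
    attr(out, "stress") <- 0
    return(out)
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  mds <- try(vegan::metaMDS(d, k = k, trymax = trymax, trace = 0,
                            autotransform = FALSE, wascores = FALSE),
             silent = TRUE)
  if (inherits(mds, "try-error") || !is.finite(mds$stress)) {
    abort(sprintf("NMDS did not converge%s.",
                  if (inherits(mds, "try-error")) "" else
                    sprintf(" (stress = %.4f)", mds$stress)))
  }
  pts <- vegan::scores(mds, display = "sites")
  centroid <- colMeans(pts[ids %in% probe_ids, , drop = FALSE])
  dist_c <- sqrt(rowSums(sweep(pts, 2, centroid)^2))
  radius <- max(dist_c[ids %in% probe_ids])
  out <- tibble::tibble(compound_id = ids,
                        axis1 = pts[, 1], axis2 = pts[, 2],
                        dist_to_centroid = unname(dist_c),
                        in_domain = unname(dist_c <= radius))
  attr(out, "radius") <- radius
  attr(out, "stress") <- mds$stress
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.ad_report <- function(object, ...) {
  h_star <- attr(object, "h_star")
  yvar <- if ("pred" %in% names(object)) "pred" else "residual"
  p <- ggplot2::ggplot(object,
         ggplot2::aes(x = .data$h, y = .data[[yvar]],
                      colour = .data$in_domain)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = h_star, linetype = "dashed") +
    ggplot2::labs(x = "leverage (h)",
                  y = if (yvar == "pred") "predicted log k" else
                    "standardized LOO residual",
                  colour = "in domain") +
    ggplot2::theme_minimal()
  if (yvar == "residual") {
    p <- p + ggplot2::geom_hline(yintercept = c(-3, 3), linetype = "dotted")
  }
  thr <- attr(object, "thresholds")
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = unname(thr), linetype = "dotted")
  }
  p
}
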