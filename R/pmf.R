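# molar gas constant in kJ/(mol K); w(z) is a per-mole free energy
GAS_CONSTANT_KJ <- 8.3144621e-3

#' Construct a potential-of-mean-force profile
#'
#' A PMF profile holds the free energy `w(z)` (kJ/mol) of a molecule as a
#' function of its distance `z` (nm) from a surface, at a given temperature,
#' as produced by constrained molecular-dynamics simulation.
#'
#' @param z Strictly increasing distances (nm), at least 4 points.
#' @param w Free energy values (kJ/mol), same length.
#' @param temperature Simulation temperature in Kelvin (default 310, body
#'   temperature).
#' @return A tibble of class `pmf_profile` with columns `z`, `w` and a
#'   `temperature` attribute.
#' @export
pmf_profile <- function(z, w, temperature = 310) {
  check_finite(z, "z")
  check_finite(w, "w")
  if (length(z) != length(w)) abort_validation("`z` and `w` must have equal length.")
  if (length(z) < 4) abort_validation("a PMF profile needs at least 4 points.")
  if (any(diff(z) <= 0)) abort_validation("`z` must be strictly increasing.")
  if (temperature <= 0) abort_validation("`temperature` must be positive (Kelvin).")
  out <- tibble::tibble(z = as.numeric(z), w = as.numeric(w))
  attr(out, "temperature") <- temperature
  class(out) <- c("pmf_profile", class(out))
  out
}

#' Read a PMF profile from a two-column text file
#'
#' Accepts whitespace- or comma-separated files with two numeric columns
#' (distance in nm, free energy in kJ/mol) and an optional header row.
#'
#' @param path File path.
#' @param temperature Temperature in Kelvin attached to the profile.
#' @return A [pmf_profile()].
#' @export
read_pmf <- function(path, temperature = 310) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^\\s*[-+0-9.eE]+[\\s,]+[-+0-9.eE]+\\s*$", first)
  delim <- if (grepl(",", first)) "," else NULL
  tab <- if (is.null(delim)) {
    utils::read.table(path, header = has_header)
  } else {
    utils::read.csv(path, header = has_header)
  }
  if (ncol(tab) < 2) abort("PMF file needs two columns (z, w).",
                           class = "nanosorb_format_error")
  pmf_profile(tab[[1]], tab[[2]], temperature = temperature)
}

#' Adsorption affinity from a PMF profile
#'
#' Integrates the Boltzmann factor of the PMF over the adsorbed region,
#'
#' `k = integral from z_min to c of exp(-beta * w(z)) dz`,
#'
#' with `beta = 1 / (R T)` (R in kJ/(mol K) because `w` is per mole), using
#' the composite trapezoid rule on the exponential-transformed values. The
#' material-dependent prefactor is omitted, so `k` carries units of length
#' (nm) and absolute values are comparable only within one surface; the
#' reported affinity is `log10(k)`, matching the QSAR log k convention. To
#' standardize the zero of free energy, `w` is first shifted so that the
#' plateau (bulk) level -- the mean over the trailing `plateau_window`
#' fraction of the profile -- is zero; the shift is a multiplicative constant
#' on `k` and can be disabled with `reference = "none"`. Deep attractive
#' wells are handled in log-sum-exp form, so `exp(-beta w)` never overflows.
#'
#' @param profile A [pmf_profile()].
#' @param cutoff Integration cutoff `c` in nm (the onset of the bulk
#'   plateau); `NULL` means [detect_plateau()] is used.
#' @param reference `"plateau"` (default) shifts `w` so the bulk level is
#'   zero; `"none"` integrates `w` as given.
#' @param plateau_window Trailing fraction of points defining the bulk level
#'   (default 0.1, at least 3 points).
#' @return A tibble of class `affinity_result` with `k_calc` (nm), `log10_k`,
#'   `cutoff` (nm) and `temperature` (K).
#' @export
#' @examples
#' flat <- pmf_profile(seq(0, 2, length.out = 50), rep(0, 50))
#' logk_from_pmf(flat, cutoff = 2)  # k = 2 nm, log10 k = 0.301
logk_from_pmf <- function(profile, cutoff = NULL,
                          reference = c("plateau", "none"),
                          plateau_window = 0.1) {
  stopifnot(inherits(profile, "pmf_profile"))
  reference <- match.arg(reference)
  z <- profile$z
  w <- profile$w
  temperature <- attr(profile, "temperature")
  if (is.null(cutoff)) cutoff <- detect_plateau(profile)
  if (cutoff <= min(z) || cutoff > max(z) + 1e-9) {
    abort_validation("cutoff %.4g nm is outside the profile range (%.4g, %.4g].",
                     cutoff, min(z), max(z))
  }
  if (reference == "plateau") {
    m <- max(3L, ceiling(plateau_window * length(w)))
    w <- w - mean(utils::tail(w, m))
  }
  keep <- z <= cutoff + 1e-12
  z <- z[keep]
  w <- w[keep]
  beta <- 1 / (GAS_CONSTANT_KJ * temperature)

  # trapezoid of exp(-beta w) in log space: stable for deep wells
  a <- -beta * w
  m0 <- max(a)
  log_k <- m0 + log(sum(diff(z) * (exp(a[-length(a)] - m0) + exp(a[-1] - m0)) / 2))
  out <- tibble::tibble(k_calc = exp(log_k), log10_k = log_k / log(10),
                        cutoff = cutoff, temperature = temperature)
  class(out) <- c("affinity_result", class(out))
  out
}

#' Detect the onset of the bulk plateau in a PMF profile
#'
#' The integration cutoff for [logk_from_pmf()] is the distance where the
#' profile has relaxed to its bulk level. Scanning outward from the global
#' minimum, the plateau onset is the smallest `z` where (a) a linear fit over
#' the next `window` points has |slope| at most `slope_tol` and (b) the local
#' value is within `value_tol` of the bulk level, estimated as the mean of
#' the last `window` points.
#'
#' @param profile A [pmf_profile()].
#' @param window Number of points in the trailing fit window (default 5).
#' @param slope_tol Largest plateau slope, kJ/(mol nm) (default 2).
#' @param value_tol Largest deviation from the bulk level, kJ/mol (default 1).
#' @return The cutoff distance (nm), with the bulk level in attribute
#'   `w_bulk`.
#' @export
detect_plateau <- function(profile, window = 5L, slope_tol = 2,
                           value_tol = 1) {
  stopifnot(inherits(profile, "pmf_profile"))
  z <- profile$z
  w <- profile$w
  n <- length(z)
  if (n < window + 1) abort_validation("profile too short for a %d-point window.", window)
  w_bulk <- mean(utils::tail(w, window))
  start <- which.min(w)
  for (i in start:(n - window + 1)) {
    idx <- i:(i + window - 1)
    slope <- stats::coef(stats::lm.fit(cbind(1, z[idx]), w[idx]))[2]
    if (abs(slope) <= slope_tol && abs(w[i] - w_bulk) <= value_tol) {
      return(structure(z[i], w_bulk = w_bulk))
    }
  }
  abort(sprintf(paste0("no plateau found (bulk level %.3g kJ/mol); ",
                       "extend the profile to larger distances."), w_bulk))
}

#' Correlate MD-derived and QSAR-predicted affinities
#'
#' Pearson correlation between per-molecule log k values obtained from
#' molecular dynamics (PMF integration) and from QSAR prediction, optionally
#' after excluding named molecules (e.g. charged species the force field
#' handles poorly).
#'
#' @param data Data frame with columns `compound_id`, `log_k_md`,
#'   `log_k_qsar`.
#' @param exclude Character vector of compound ids to drop before
#'   correlating.
#' @return A tibble with `r`, `p_value`, `n` (molecules used) and
#'   `n_excluded`.
#' @export
compare_md_qsar <- function(data, exclude = character()) {
  data <- tibble::as_tibble(data)
  check_columns(data, c("compound_id", "log_k_md", "log_k_qsar"),
                "comparison table")
  kept <- dplyr::filter(data, !.data$compound_id %in% exclude)
  if (nrow(kept) < 3) {
    abort_validation("need at least 3 molecules after exclusion (have %d).", nrow(kept))
  }
  ct <- stats::cor.test(kept$log_k_md, kept$log_k_qsar, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(kept), n_excluded = nrow(data) - nrow(kept))
}

#' @exportS3Method ggplot2::autoplot
autoplot.pmf_profile <- function(object, cutoff = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$w)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance z (nm)", y = "w(z) (kJ/mol)") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed")
  }
  p
}
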