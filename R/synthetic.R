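# run code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Default Abraham descriptor ranges for synthetic compounds
#'
#' Ranges bracketing typical small-organic values of the five Abraham
#' solvation descriptors; plumbing defaults for the generator, not claims
#' about any measured dataset.
#'
#' @return Named list of `c(low, high)` ranges for `E`, `S`, `A`, `B`, `V`.
#' @export
abraham_ranges <- function() {
  list(E = c(-0.5, 3), S = c(0, 3), A = c(0, 2), B = c(0, 3), V = c(0.3, 3))
}

#' Generate a synthetic Abraham-descriptor compound table
#'
#' Draws `n` synthetic compounds with descriptors uniform on the given
#' ranges; an optional pairwise correlation is imposed through a Gaussian
#' copula (the marginals stay uniform on their ranges). Identical
#' configurations produce identical tables.
#'
#' @param n Number of compounds.
#' @param seed Integer seed.
#' @param ranges Named list of `c(low, high)` per descriptor; see
#'   [abraham_ranges()].
#' @param correlation `NULL` for independent columns, a single value in
#'   (-1, 1) applied to every descriptor pair, or a 5x5 positive-definite
#'   correlation matrix.
#' @return A tibble with `compound_id` ("cpd_0001", ...) and numeric `E`,
#'   `S`, `A`, `B`, `V`.
#' @export
gen_abraham_compounds <- function(n, seed = 1L, ranges = abraham_ranges(),
                                  correlation = NULL) {
  vars <- c("E", "S", "A", "B", "V")
  if (!all(vars %in% names(ranges))) {
    abort_validation("`ranges` must name all of E, S, A, B, V.")
  }
  for (v in vars) {
    r <- ranges[[v]]
    if (length(r) != 2 || !all(is.finite(r)) || r[1] >= r[2]) {
      abort_validation("invalid range for %s.", v)
    }
  }
  if (n == 0) {
    out <- tibble::as_tibble(stats::setNames(rep(list(numeric()), 5), vars))
    return(dplyr::bind_cols(tibble::tibble(compound_id = character()), out))
  }
  u <- with_seed(seed, {
    if (is.null(correlation)) {
      matrix(stats::runif(n * 5), n, 5)
    } else {
      rho <- if (is.matrix(correlation)) correlation else {
        m <- matrix(correlation, 5, 5); diag(m) <- 1; m
      }
      z <- matrix(stats::rnorm(n * 5), n, 5) %*% chol(rho)
      stats::pnorm(z)
    }
  })
  out <- tibble::tibble(compound_id = sprintf("cpd_%04d", seq_len(n)))
  for (i in seq_along(vars)) {
    r <- ranges[[vars[i]]]
    out[[vars[i]]] <- r[1] + u[, i] * (r[2] - r[1])
  }
  out
}

# per-descriptor synthetic marginals, chosen to mimic the magnitude and type
# (count vs continuous) of each descriptor family
descriptor_generator <- function(name, n) {
  if (name == "Fsp3") return(stats::runif(n))
  if (name %in% c("ALogP", "XLogP")) return(stats::runif(n, -2, 6))
  if (name == "AMR") return(stats::runif(n, 10, 150))
  if (grepl("^ATS", name)) return(stats::runif(n, 50, 800))
  if (name == "TopoPSA") return(stats::runif(n, 0, 200))
  if (name == "WTPT.4") return(stats::runif(n, 0, 20))
  if (name == "WPATH") return(stats::runif(n, 50, 5000))
  if (grepl("^Kier", name)) return(stats::runif(n, 1, 15))
  if (name == "fragC") return(stats::runif(n, 0, 2000))
  if (name == "ECCEN") return(stats::runif(n, 10, 500))
  if (name == "MDEO.11") return(stats::runif(n, 0, 3))
  if (name == "SCH.7") return(stats::runif(n, 0, 2))
  if (name == "nAtom") return(as.numeric(sample(5:60, n, replace = TRUE)))
  if (name == "nAtomP") return(stats::rpois(n, 8))
  if (name == "nHBDon") return(stats::rpois(n, 2))
  if (name == "nRotB") return(stats::rpois(n, 3))
  if (name == "C1SP3") return(stats::rpois(n, 2))
  if (grepl("^(n|khs\\.)", name)) return(stats::rpois(n, 1))
  stats::runif(n, 0, 10)
}

#' Generate a descriptor table consistent with a linear model
#'
#' Produces a synthetic descriptor table whose response is generated exactly
#' by the given linear model (plus optional Gaussian noise), together with
#' independent decoy descriptor columns that carry no signal. Useful for
#' testing whether a selection pipeline recovers the generating equation.
#'
#' @param model A [qsar_model()] whose term names decide which descriptor
#'   columns are generated (marginals are matched to the descriptor family:
#'   counts for `n*`/`khs.*` names, a fraction for `Fsp3`, continuous ranges
#'   otherwise).
#' @param n Number of compounds.
#' @param seed Integer seed.
#' @param noise_sd Standard deviation of additive Gaussian response noise
#'   (0 = noise-free).
#' @param n_decoys Number of standard-normal decoy columns (`decoy_01`, ...)
#'   independent of the response.
#' @return A list with `data` (tibble: `compound_id`, model descriptors,
#'   decoys), `response` (numeric log k) and `model`.
#' @export
gen_table_from_model <- function(model, n, seed = 1L, noise_sd = 0,
                                 n_decoys = 10L) {
  stopifnot(inherits(model, "qsar_model"))
  if (noise_sd < 0) abort_validation("`noise_sd` must be >= 0.")
  with_seed(seed, {
    data <- tibble::tibble(compound_id = sprintf("cpd_%04d", seq_len(n)))
    for (d in names(model$terms)) data[[d]] <- descriptor_generator(d, n)
    for (j in seq_len(n_decoys)) {
      data[[sprintf("decoy_%02d", j)]] <- stats::rnorm(n)
    }
    response <- evaluate_model(model, data) +
      if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    list(data = data, response = response, model = model)
  })
}

#' Generate a synthetic PMF profile with known ground truth
#'
#' Three profile families, each with a closed-form or constructed truth so
#' integration and plateau detection can be tested against known answers:
#'
#' * `"flat"`: `w = 0` on `[0, z_max]`; the affinity equals the integration
#'   length (`k = cutoff`).
#' * `"square_well"`: `w = -depth` for `z <= width`, 0 beyond; for a cutoff
#'   `c`, `k = width * exp(beta * depth) + (c - width)` exactly.
#' * `"smooth_well"`: a C1 cosine-squared well
#'   `w = -depth * cos^2(pi (z - center) / (2 halfwidth))` on
#'   `|z - center| <= halfwidth`, 0 elsewhere; the plateau begins exactly at
#'   `center + halfwidth`.
#'
#' @param kind One of `"flat"`, `"square_well"`, `"smooth_well"`.
#' @param n Number of grid points.
#' @param z_max Largest distance (nm).
#' @param depth Well depth (kJ/mol, positive).
#' @param width Square-well width (nm).
#' @param center,halfwidth Smooth-well location and half-width (nm).
#' @param noise_sd Gaussian noise added to `w` (kJ/mol).
#' @param temperature Kelvin.
#' @param seed Integer seed (relevant only when `noise_sd > 0`).
#' @return A [pmf_profile()] with attributes `truth` (list: `kind`,
#'   parameters, `c_plateau`, and `k_true` -- the closed-form affinity at
#'   cutoff `z_max` where one exists, otherwise `NA`).
#' @export
gen_pmf <- function(kind = c("flat", "square_well", "smooth_well"),
                    n = 200L, z_max = 2, depth = 5, width = 0.5,
                    center = 0.5, halfwidth = 0.4, noise_sd = 0,
                    temperature = 310, seed = 1L) {
  kind <- match.arg(kind)
  z <- seq(0, z_max, length.out = n)
  beta <- 1 / (GAS_CONSTANT_KJ * temperature)
  truth <- list(kind = kind, z_max = z_max, temperature = temperature)
  w <- switch(kind,
    flat = {
      truth$c_plateau <- 0
      truth$k_true <- z_max
      rep(0, n)
    },
    square_well = {
      if (width <= 0 || width >= z_max) abort_validation("need 0 < width < z_max.")
      truth$depth <- depth; truth$width <- width
      truth$c_plateau <- width
      truth$k_true <- width * exp(beta * depth) + (z_max - width)
      ifelse(z <= width, -depth, 0)
    },
    smooth_well = {
      if (center - halfwidth < 0 || center + halfwidth >= z_max) {
        abort_validation("smooth well must fit inside [0, z_max).")
      }
      truth$depth <- depth; truth$center <- center; truth$halfwidth <- halfwidth
      truth$c_plateau <- center + halfwidth
      truth$k_true <- NA_real_
      ifelse(abs(z - center) <= halfwidth,
             -depth * cos(pi * (z - center) / (2 * halfwidth))^2, 0)
    })
  if (noise_sd > 0) w <- w + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  out <- pmf_profile(z, w, temperature = temperature)
  attr(out, "truth") <- truth
  out
}

#' Generate a synthetic metabolite inventory
#'
#' Random inventory with the same shape as [enteric_inventory()]: unique
#' names, one or occasionally two categories per record, and non-empty
#' source-review sets. Intended for exercising the inventory operations at
#' arbitrary scale.
#'
#' @param n Number of records.
#' @param seed Integer seed.
#' @param n_reviews Number of available reviews (indices 1..n_reviews).
#' @param path Optional CSV path; when given, the inventory is also written
#'   in the on-disk format [read_inventory()] expects.
#' @return An inventory tibble.
#' @export
gen_inventory <- function(n, seed = 1L, n_reviews = 10L, path = NULL) {
  vocab <- setdiff(metabolite_categories(), "other")
  inv <- with_seed(seed, {
    cats <- lapply(seq_len(n), function(i) {
      k <- if (stats::runif(1) < 0.05) 2 else 1
      sample(vocab, k)
    })
    revs <- lapply(seq_len(n), function(i) {
      sort(sample(seq_len(n_reviews), sample(1:3, 1)))
    })
    tibble::tibble(
      name = sprintf("met_%04d", seq_len(n)),
      category = cats,
      smiles = NA_character_,
      source_reviews = revs
    )
  })
  if (!is.null(path)) {
    flat <- tibble::tibble(
      name = inv$name,
      category = vapply(inv$category, paste, "", collapse = ";"),
      smiles = dplyr::coalesce(inv$smiles, ""),
      source_reviews = vapply(inv$source_reviews, paste, "", collapse = ";")
    )
    readr::write_csv(flat, path)
  }
  inv
}
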