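#' Predict log k from the BSAI linear free-energy relationship
#'
#' The biological surface adsorption index (BSAI) relates the base-10 log
#' adsorption affinity of a molecule to a nanomaterial surface to the
#' molecule's Abraham solvation descriptors:
#'
#' log k = c + E * r_e + S * p_s + A * a + B * b + V * v
#'
#' where `E` is the excess molar refraction, `S` the dipolarity/
#' polarizability, `A` and `B` the hydrogen-bond acidity and basicity, and `V`
#' the McGowan characteristic volume of the molecule. The nanomaterial-side
#' weights (nanodescriptors) measure the surface's response to lone-pair
#' electrons (`r_e`), polarity/polarizability (`p_s`), hydrogen-bond acidity
#' (`a`) and basicity (`b`), and hydrophobicity (`v`); `c` is the adsorption
#' constant (intercept). log k is treated as base-10 throughout, following
#' QSAR convention.
#'
#' @param compound A named list or one/multi-row data frame with numeric
#'   columns `E`, `S`, `A`, `B`, `V`.
#' @param nano A named list or one-row data frame with numeric entries `c`,
#'   `r_e`, `p_s`, `a`, `b`, `v`.
#' @return Numeric vector of predicted log k, one value per compound row.
#' @export
#' @examples
#' nano <- list(c = 1, r_e = 1, p_s = 1, a = 1, b = 1, v = 1)
#' predict_bsai(list(E = 1, S = 1, A = 1, B = 1, V = 1), nano)  # 6
predict_bsai <- function(compound, nano) {
  compound <- as.data.frame(compound)
  nano <- as.list(nano)
  check_columns(compound, c("E", "S", "A", "B", "V"), "compound table")
  need <- c("c", "r_e", "p_s", "a", "b", "v")
  miss <- setdiff(need, names(nano))
  if (length(miss) > 0) {
    abort_validation("nanodescriptor set is missing %s.",
                     paste0("`", miss, "`", collapse = ", "))
  }
  w <- vapply(nano[need], as.numeric, 1.0)
  check_finite(w, "nanodescriptors")
  for (col in c("E", "S", "A", "B", "V")) check_finite(compound[[col]], col)
  w[["c"]] + compound$E * w[["r_e"]] + compound$S * w[["p_s"]] +
    compound$A * w[["a"]] + compound$B * w[["b"]] + compound$V * w[["v"]]
}

#' Predict log k for every compound x nanomaterial pair
#'
#' Applies [predict_bsai()] over a compound table and a registry of
#' nanodescriptor sets, producing the complete log k matrix in wide form.
#'
#' @param compounds Data frame with a `compound_id` column (unique) and the
#'   Abraham descriptor columns `E`, `S`, `A`, `B`, `V`.
#' @param registry Data frame with one row per nanomaterial: `enm_id`
#'   (unique), `c`, `r_e`, `p_s`, `a`, `b`, `v`. See [read_nanodescriptors()].
#' @return A tibble with `compound_id` and one numeric log k column per
#'   `enm_id`, in registry order.
#' @export
batch_predict <- function(compounds, registry) {
  check_columns(registry, c("enm_id", "c", "r_e", "p_s", "a", "b", "v"),
                "nanodescriptor registry")
  if (nrow(registry) == 0) abort_validation("nanodescriptor registry is empty.")
  if (anyDuplicated(registry$enm_id)) {
    abort_validation("duplicate enm_id in registry: %s.",
                     paste(unique(registry$enm_id[duplicated(registry$enm_id)]),
                           collapse = ", "))
  }
  compounds <- tibble::as_tibble(compounds)
  check_columns(compounds, c("compound_id", "E", "S", "A", "B", "V"),
                "compound table")
  out <- tibble::tibble(compound_id = compounds$compound_id)
  for (i in seq_len(nrow(registry))) {
    out[[registry$enm_id[i]]] <-
      predict_bsai(compounds, as.list(registry[i, , drop = FALSE]))
  }
  out
}

#' Read a nanodescriptor registry from YAML or JSON
#'
#' The packaged pipeline does not ship measured nanodescriptor values (they
#' are adopted from external adsorption experiments and belong to their
#' authors); users supply them in a small config file. YAML files hold a list
#' of maps, JSON an array of objects; each entry needs `enm_id`, `c`, `r_e`,
#' `p_s`, `a`, `b`, `v`. A synthetic example registry (random coefficients,
#' real nanomaterial names) ships as `extdata/nanodescriptors_synthetic.yaml`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A tibble with one validated row per nanomaterial.
#' @export
read_nanodescriptors <- function(path) {
  ext <- tolower(tools::file_ext(path))
  entries <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    abort(sprintf("unsupported registry format '.%s' (use YAML or JSON).", ext),
          class = "nanosorb_format_error")
  )
  reg <- purrr::map_dfr(entries, function(e) {
    tibble::tibble(enm_id = as.character(e$enm_id),
                   c = as.numeric(e$c), r_e = as.numeric(e$r_e),
                   p_s = as.numeric(e$p_s), a = as.numeric(e$a),
                   b = as.numeric(e$b), v = as.numeric(e$v))
  })
  if (anyDuplicated(reg$enm_id)) {
    abort_validation("duplicate enm_id in registry file: %s.",
                     paste(unique(reg$enm_id[duplicated(reg$enm_id)]), collapse = ", "))
  }
  for (col in c("c", "r_e", "p_s", "a", "b", "v")) check_finite(reg[[col]], col)
  reg
}

#' Clean a raw Abraham-descriptor compound dataset
#'
#' Prepares an experimentally curated compound table for BSAI prediction in
#' three steps: (1) replace the SMILES of known-bad entries with corrected
#' structures; (2) drop compounds flagged for exclusion (poor data quality,
#' metals, salts); (3) collapse replicate entries of the same compound to a
#' single row -- first replicate measurement entries sharing a compound name
#' (one retained at random under `seed`), then descriptor-level isomers, i.e.
#' groups of rows with identical values of all five Abraham descriptors
#' (again one random representative). The operation is idempotent: cleaning a
#' cleaned table changes nothing.
#'
#' @param raw Data frame with unique `key`, a `name` column identifying the
#'   compound, a `smiles` column and numeric `E`, `S`, `A`, `B`, `V`.
#' @param corrections Named character vector mapping keys to corrected SMILES.
#'   Keys absent from `raw` raise a warning and are skipped.
#' @param exclusions Character vector of keys to drop.
#' @param seed Integer seed controlling which replicate is retained.
#' @return The cleaned tibble, in stable (key) order.
#' @export
clean_compound_dataset <- function(raw, corrections = character(),
                                   exclusions = character(), seed = 1L) {
  raw <- tibble::as_tibble(raw)
  check_columns(raw, c("key", "name", "smiles", "E", "S", "A", "B", "V"),
                "compound table")
  if (anyDuplicated(raw$key)) abort_validation("`key` must be unique.")
  raw$key <- as.character(raw$key)

  if (length(corrections) > 0) {
    hit <- names(corrections) %in% raw$key
    if (any(!hit)) {
      warn(sprintf("correction key(s) not present, skipped: %s",
                   paste(names(corrections)[!hit], collapse = ", ")))
    }
    idx <- match(names(corrections)[hit], raw$key)
    raw$smiles[idx] <- unname(corrections[hit])
  }

  out <- raw[!(raw$key %in% as.character(exclusions)), , drop = FALSE]

  # seeded random representative per duplicate group, stable across reruns
  pick_one <- function(data, group) {
    keep <- unlist(lapply(split(seq_len(nrow(data)), group), function(idx) {
      if (length(idx) == 1) idx else sample(idx, 1)
    }), use.names = FALSE)
    data[sort(keep), , drop = FALSE]
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  out <- pick_one(out, out$name)
  iso_group <- paste(format(out$E, digits = 15), format(out$S, digits = 15),
                     format(out$A, digits = 15), format(out$B, digits = 15),
                     format(out$V, digits = 15))
  out <- pick_one(out, iso_group)
  out
}
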