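#' Registered molecular-descriptor vocabulary
#'
#' Descriptor names the QSAR layer knows about: the identifiers used by the
#' frozen per-nanomaterial equations plus the subset the native calculator
#' produces. Any `khs.`-prefixed E-state fragment count is also accepted.
#'
#' @return Character vector of descriptor names.
#' @export
descriptor_vocabulary <- function() {
  c("ALogP", "XLogP", "AMR", "Fsp3", "nHBDon", "nAtom", "nAcid", "nBase",
    "nRotB", "nSmallRings", "nAtomP", "C1SP3", "TopoPSA",
    "ATSm1", "ATSm4", "ATSp1", "ATSp5", "WTPT.4", "WPATH", "Kier1", "Kier2",
    "fragC", "ECCEN", "MDEO.11", "SCH.7",
    "khs.sOH", "khs.aasC", "khs.sssSiH", "khs.aasN", "khs.ssssC", "khs.sBr",
    "khs.aaaC", "khs.ssNH", "khs.ssssSi")
}

is_known_descriptor <- function(x) {
  x %in% descriptor_vocabulary() | startsWith(x, "khs.")
}

#' Ingest an externally computed descriptor table
#'
#' Molecular descriptors for QSAR modelling are typically computed with a
#' cheminformatics toolkit and exchanged as CSV. This reader validates the
#' table: compound ids must be unique, every descriptor cell numeric, and
#' header names are checked against [descriptor_vocabulary()] (unknown names
#' are kept, with a warning, so vendor-specific columns pass through).
#'
#' @param x Path to a CSV file with a `compound_id` column, or a data frame.
#' @return A typed tibble with `compound_id` (character) and numeric
#'   descriptor columns.
#' @export
ingest_descriptor_table <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- readr::read_csv(x, col_types = readr::cols(), progress = FALSE)
  }
  x <- tibble::as_tibble(x)
  check_columns(x, "compound_id", "descriptor table")
  x$compound_id <- as.character(x$compound_id)
  if (anyDuplicated(x$compound_id)) {
    abort_validation("duplicate compound_id: %s.",
                     paste(unique(x$compound_id[duplicated(x$compound_id)]),
                           collapse = ", "))
  }
  desc_cols <- setdiff(names(x), "compound_id")
  unknown <- desc_cols[!is_known_descriptor(desc_cols)]
  if (length(unknown) > 0) {
    warn(sprintf("descriptor name(s) not in the registered vocabulary: %s",
                 paste(unknown, collapse = ", ")))
  }
  for (col in desc_cols) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num) && !all(is.na(v) == is.na(num))) {
        bad <- which(is.na(num) & !is.na(v))[1]
        abort(sprintf("non-numeric value '%s' in row %d, column `%s`.",
                      v[bad], bad, col), class = "nanosorb_format_error")
      }
      x[[col]] <- num
    }
  }
  x
}

# SMARTS definitions behind the native descriptor subset; counts are of
# matching atoms (uniqueMatches), not of embeddings
basic_descriptor_smarts <- list(
  nHBDon = "[#7,#8;!H0]",                                    # N/O bearing >= 1 H
  nRotB  = "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]",                  # acyclic single bonds, non-terminal
  nAcid  = "[$([O;H1]-[C,S,P]=O),$([*;-;!$(*~[*;+])]),$(n1nnnc1)]",
  nBase  = "[$([NH2]-[CX4]),$([NH](-[CX4])-[CX4]),$(N(-[CX4])(-[CX4])-[CX4]),$([*;+;!$(*~[*;-])])]",
  sp3C   = "[CX4]",
  anyC   = "[#6]",
  C1SP3  = "[CX4;$([CX4]~[#6]);!$([CX4](~[#6])~[#6])]"
)

#' Compute a basic subset of molecular descriptors from SMILES
#'
#' A native calculator for the unambiguous count-type descriptors, so that
#' small pipelines need not round-trip through an external toolkit. SMILES are
#' parsed with OpenBabel (via ChemmineR/ChemmineOB); implicit hydrogens are
#' made explicit for atom counting and aromaticity is perceived on parse.
#' Definitions:
#'
#' * `nAtom`: all atoms including hydrogens (from the molecular formula).
#' * `nHBDon`: N or O atoms bearing at least one hydrogen.
#' * `nRotB`: non-terminal acyclic single bonds not adjacent to a triple bond
#'   (terminal bonds such as the C-C bond of ethane are not rotatable).
#' * `nAcid`: acidic groups (O-H of carboxylic/sulfonic/phosphonic acids,
#'   uncompensated anionic atoms, tetrazole NH).
#' * `nBase`: basic groups (primary/secondary/tertiary aliphatic amines,
#'   uncompensated cationic atoms).
#' * `nSmallRings`: rings of size <= 6.
#' * `Fsp3`: sp3-hybridised carbons / all carbons (0 for carbon-free
#'   molecules); always in \[0, 1\].
#' * `C1SP3`: sp3 carbons bonded to exactly one other carbon.
#'
#' Unparseable SMILES do not stop the batch: the affected row keeps `NA`
#' descriptors and carries the failure message in `parse_error`.
#'
#' @param smiles Character vector of SMILES strings.
#' @param ids Optional compound ids (default `smiles` themselves).
#' @return A tibble with `compound_id`, `smiles`, the eight descriptor
#'   columns, and `parse_error` (NA for clean rows).
#' @export
#' @examples
#' \donttest{
#' compute_basic_descriptors(c("CCO", "c1ccccc1", "CC"))
#' }
compute_basic_descriptors <- function(smiles, ids = NULL) {
  for (pkg in c("ChemmineR", "ChemmineOB")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      abort(sprintf("package '%s' is required for native descriptor calculation.", pkg))
    }
  }
  ids <- ids %||% smiles
  stopifnot(length(ids) == length(smiles))

  one <- function(smi) {
    res <- tryCatch({
      mol <- ChemmineOB::forEachMol("SMILES", smi, identity)
      n_heavy <- ChemmineOB::smartsSearch_OB(mol, "[*]", uniqueMatches = TRUE)
      if (n_heavy == 0) stop("SMILES could not be parsed")
      counts <- vapply(basic_descriptor_smarts, function(s)
        as.numeric(ChemmineOB::smartsSearch_OB(mol, s, uniqueMatches = TRUE)), 1.0)
      formula <- ChemmineOB::prop_OB(mol)$formula[1]
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(smi))
      ring <- ChemmineR::rings(sdf[1], upper = 6, type = "count", arom = TRUE)
      ring_n <- if (is.matrix(ring)) ring[1, "RINGS"] else ring[["RINGS"]]
      list(
        nAtom = formula_atom_count(formula),
        nHBDon = counts[["nHBDon"]],
        nRotB = counts[["nRotB"]],
        nAcid = counts[["nAcid"]],
        nBase = counts[["nBase"]],
        nSmallRings = as.numeric(ring_n),
        Fsp3 = if (counts[["anyC"]] == 0) 0 else counts[["sp3C"]] / counts[["anyC"]],
        C1SP3 = counts[["C1SP3"]],
        parse_error = NA_character_
      )
    }, error = function(e) {
      list(nAtom = NA_real_, nHBDon = NA_real_, nRotB = NA_real_,
           nAcid = NA_real_, nBase = NA_real_, nSmallRings = NA_real_,
           Fsp3 = NA_real_, C1SP3 = NA_real_,
           parse_error = conditionMessage(e))
    })
    tibble::as_tibble(res)
  }

  out <- purrr::map_dfr(smiles, one)
  dplyr::bind_cols(tibble::tibble(compound_id = as.character(ids),
                                  smiles = smiles), out)
}

# total atom count from a Hill-notation molecular formula, charges ignored
formula_atom_count <- function(formula) {
  formula <- gsub("[+-]+[0-9]*$", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (length(parts) == 0) return(NA_real_)
  sum(vapply(parts, function(p) {
    n <- gsub("[A-Za-z]", "", p)
    if (nzchar(n)) as.numeric(n) else 1
  }, 1.0))
}
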