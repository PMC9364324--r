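# internal helpers shared across modules

# stop unless all values are finite numerics
check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite numeric values.", what),
          class = "nanosorb_validation_error")
  }
  invisible(x)
}

# columns that must be present in a data frame
check_columns <- function(data, cols, where) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s.",
                  where, paste0("`", missing, "`", collapse = ", ")),
          class = "nanosorb_format_error")
  }
  invisible(data)
}

abort_validation <- function(...) {
  abort(sprintf(...), class = "nanosorb_validation_error")
}

# path to a packaged data file
nanosorb_file <- function(...) {
  path <- system.file("extdata", ..., package = "nanosorb", mustWork = FALSE)
  if (!nzchar(path)) {
    abort(sprintf("packaged file %s not found.", file.path(...)))
  }
  path
}
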