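#' Read a flat key-value configuration file
#'
#' Parses `key = value` lines (one per line; `#` comments and blank lines
#' ignored). Values are converted to numeric or logical where possible,
#' otherwise kept as strings; comma-separated values become vectors.
#' Keys mirror the fields of [cohort_spec()] / [compositional_spec()],
#' plus sweep settings such as `p_grid` or `gamma_grid`.
#'
#' @param path configuration file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2)
      stop("malformed config line (expected key = value): ", ln,
           call. = FALSE)
    key <- trimws(kv[1])
    raw <- trimws(paste(kv[-1], collapse = "="))
    vals <- trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(num)) num
      else if (all(toupper(vals) %in% c("TRUE", "FALSE")))
        as.logical(toupper(vals))
      else if (length(vals) == 1) vals else vals
  }
  out
}

# Build a cohort_spec from a config list, ignoring non-spec keys.
spec_from_config <- function(config) {
  known <- names(formals(cohort_spec))
  do.call(cohort_spec, config[intersect(names(config), known)])
}

compositional_spec_from_config <- function(config) {
  known <- names(formals(compositional_spec))
  do.call(compositional_spec, config[intersect(names(config), known)])
}
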