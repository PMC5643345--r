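# Flat key-value config files with optional [section] headers; '#' comments.
# Values are parsed as logical, numeric (comma-separated -> vector) or string.
# Section names are ignored for lookup (keys are globally unique, mirroring
# pipeline_config fields), but kept for readability.

#' Read a flat key-value configuration file
#'
#' @param path Text file with `key = value` lines, optional `[section]`
#'   headers and `#` comments.
#' @return Named list of parsed values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("read_config: no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stopf("read_config: cannot parse line: '%s'", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    out[[key]] <- parse_config_value(val)
  }
  out
}

parse_config_value <- function(val) {
  if (toupper(val) %in% c("TRUE", "FALSE")) return(as.logical(toupper(val)))
  if (toupper(val) %in% c("INF", "INFINITY")) return(Inf)
  parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
  nums <- suppressWarnings(as.numeric(parts))
  if (!anyNA(nums)) return(if (length(nums) == 1L) nums[1] else nums)
  val
}

#' Build a pipeline configuration from a config file
#'
#' File keys mirror [pipeline_config()] fields; unknown keys are rejected.
#' Integer-valued fields are coerced.
#'
#' @param path Config file path.
#' @param ... Further overrides applied after the file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, ...) {
  vals <- read_config(path)
  int_fields <- c("grid_n", "n_canals", "seed", "n_projections",
                  "min_extent_vox", "n_slices")
  for (f in intersect(names(vals), int_fields))
    vals[[f]] <- as.integer(vals[[f]])
  cfg <- do.call(pipeline_config, vals)
  over <- list(...)
  if (length(over)) {
    fields <- unclass(cfg)
    fields[names(over)] <- over
    cfg <- do.call(pipeline_config, fields)
  }
  cfg
}
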