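#' Load a configuration from a flat key-value file
#'
#' Reads a flat `key: value` file (the flat subset of YAML; `#` comments
#' and blank lines ignored), applies documented defaults for absent keys,
#' and overlays any explicit overrides (e.g. parsed CLI flags), which take
#' precedence over file values. Unknown keys are rejected by name;
#' out-of-range values error naming the key, value and allowed range.
#'
#' @param path Path to the config file, or `NULL` for defaults only.
#' @param overrides Named list of values that win over the file.
#' @param type `"unit"` for an [unit_config()], `"timeseries"` for a
#'   [time_series_config()] (accepts the extra key `n_ticks`).
#' @return An `ol_config` or `ol_ts_config`.
#' @export
load_config <- function(path = NULL, overrides = list(),
                        type = c("unit", "timeseries")) {
  type <- match.arg(type)
  values <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (line in lines) {
      if (!grepl("^[A-Za-z_][A-Za-z0-9_]*[[:space:]]*:", line))
        stop("config parse error (expected `key: value`): ", line,
             call. = FALSE)
      key <- trimws(sub(":.*$", "", line))
      val <- trimws(sub("^[^:]*:", "", line))
      if (!nzchar(val))
        stop("config parse error: no value for key `", key,
             "` (nested structures are not supported)", call. = FALSE)
      num <- suppressWarnings(as.numeric(val))
      values[[key]] <- if (is.na(num)) val else num
    }
  }
  for (key in names(overrides)) values[[key]] <- overrides[[key]]
  allowed <- setdiff(names(formals(unit_config)), "...")
  if (type == "timeseries") allowed <- c(allowed, "n_ticks")
  unknown <- setdiff(names(values), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (type == "unit") {
    do.call(unit_config, values)
  } else {
    do.call(time_series_config, values)
  }
}

signif_cols <- function(df, digits = 6) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  df
}

#' Write simulation outputs with a reproducibility manifest
#'
#' Writes the supplied tables under `out_dir`: comma-delimited UTF-8 CSV
#' with a header row and no index column for tables, tab-delimited TSV for
#' the advice edge list, plus a `manifest.json` recording the
#' configuration snapshot, master seed, package version and the row count
#' of every file — enough to regenerate each file byte-for-byte.
#'
#' Doubles are written with 6 significant digits. An empty edge list
#' yields a header-only TSV.
#'
#' @param out_dir Output directory (created if needed; must be writable).
#' @param sweep,timeseries,records Optional data frames, written as
#'   `sweep.csv`, `timeseries.csv`, `tick_records.csv`.
#' @param edges Optional advice edge list, written as `edges.tsv`.
#' @param config Configuration object to snapshot in the manifest.
#' @param master_seed Master seed to record.
#' @param extra Named list merged into the manifest.
#' @return Named character vector of written file paths, invisibly.
#' @export
write_outputs <- function(out_dir, sweep = NULL, timeseries = NULL,
                          records = NULL, edges = NULL, config = NULL,
                          master_seed = NULL, extra = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                 error = function(e) FALSE)
  if (!isTRUE(ok))
    stop("I/O error: output directory not writable: ", out_dir,
         call. = FALSE)
  unlink(probe)

  files <- character(0)
  counts <- list()
  emit <- function(df, name, sep = ",") {
    path <- file.path(out_dir, name)
    data.table::fwrite(signif_cols(as.data.frame(df)), path, sep = sep,
                       quote = FALSE)
    files[[name]] <<- path
    counts[[name]] <<- nrow(df)
  }
  if (!is.null(sweep)) emit(sweep, "sweep.csv")
  if (!is.null(timeseries)) emit(timeseries, "timeseries.csv")
  if (!is.null(records)) emit(records, "tick_records.csv")
  if (!is.null(edges)) {
    if (nrow(edges) == 0L)
      edges <- data.frame(tick = integer(0), seeker_id = integer(0),
                          advisor_id = integer(0))
    emit(edges, "edges.tsv", sep = "\t")
  }
  manifest <- c(list(
    package = "olsim",
    version = as.character(utils::packageVersion("olsim")),
    master_seed = master_seed,
    config = if (!is.null(config)) unclass_config(config),
    seed_derivation = "derive_seed(master, labels) per substream",
    files = lapply(names(files), function(f)
      list(name = f, rows = counts[[f]]))
  ), extra)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  files[["manifest.json"]] <- manifest_path
  invisible(unlist(files))
}

unclass_config <- function(config) {
  if (inherits(config, "ol_ts_config"))
    list(unit = unclass(config$unit), n_ticks = config$n_ticks)
  else unclass(config)
}
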