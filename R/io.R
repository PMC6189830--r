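#' Event-table and configuration IO
#'
#' Event tables travel as plain CSV (comma-separated, UTF-8, LF endings,
#' header required) with a fixed column order; configurations and reports as
#' JSON. Read/write round-trips are exact for valid tables, and readers
#' validate the droplet-event invariants row by row, reporting the offending
#' row on failure.
#'
#' @name cli_io
NULL

EVENT_COLUMNS <- c("droplet_id", "clone", "n_cells", "n_apoptotic",
                   "sorted_positive", "n_colonies_recovered",
                   "n_positive_colonies")

#' Validate a droplet event table
#'
#' Checks the column schema and the per-row invariants: counts are
#' non-negative integers, `n_apoptotic <= n_cells`, `n_positive_colonies <=
#' n_colonies_recovered`, `clone` is `"hit"` or `"null"`, `sorted_positive`
#' is logical. Errors name the first offending row and column.
#'
#' @param events A data frame.
#' @return The table, invisibly, if valid.
#' @export
validate_events <- function(events) {
  if (!is.data.frame(events)) stop("event table must be a data frame", call. = FALSE)
  missing <- setdiff(EVENT_COLUMNS, names(events))
  if (length(missing)) {
    stop("event table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  .bad_row <- function(cond, what) {
    if (any(cond)) {
      stop(sprintf("invalid event table: %s (first at row %d)",
                   what, which(cond)[1]), call. = FALSE)
    }
  }
  for (col in c("n_cells", "n_apoptotic", "n_colonies_recovered",
                "n_positive_colonies")) {
    v <- events[[col]]
    if (!is.numeric(v)) stop("column `", col, "` must be numeric", call. = FALSE)
    .bad_row(is.na(v) | v < 0 | v != round(v),
             paste0("`", col, "` must be a non-negative integer"))
  }
  if (!is.logical(events$sorted_positive)) {
    stop("column `sorted_positive` must be logical", call. = FALSE)
  }
  .bad_row(!events$clone %in% c("hit", "null"),
           "`clone` must be \"hit\" or \"null\"")
  .bad_row(events$n_apoptotic > events$n_cells, "n_apoptotic > n_cells")
  .bad_row(events$n_positive_colonies > events$n_colonies_recovered,
           "n_positive_colonies > n_colonies_recovered")
  invisible(events)
}

#' Write a droplet event table to CSV
#'
#' @param events A valid event table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  events <- events[, EVENT_COLUMNS]
  con <- file(path, open = "wb")  # binary: LF endings on every platform
  on.exit(close(con))
  utils::write.csv(events, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a droplet event table from CSV
#'
#' @param path CSV file written by [write_events()] (header required).
#' @return A validated event table.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  events <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(
                              droplet_id = "integer", clone = "character",
                              n_cells = "integer", n_apoptotic = "integer",
                              sorted_positive = "logical",
                              n_colonies_recovered = "integer",
                              n_positive_colonies = "integer"))
  validate_events(events)
  events
}

# serialise a screen_config to a plain list for JSON
config_to_list <- function(config) {
  a <- config$assay
  list(
    schema_version = 1L,
    assay = list(hit_fraction = a$hit_fraction,
                 p_background = a$p_background,
                 p_hit = a$p_hit,
                 aggregate_size = a$aggregate_size,
                 count_model = a$count_model,
                 threshold = a$threshold,
                 threshold_rule = a$threshold_rule),
    loading = list(mean_per_droplet = config$loading$mean_per_droplet,
                   particle_kind = config$loading$particle_kind),
    n_droplets = config$n_droplets,
    cell_count_model = config$cell_count_model,
    merge_pairing_efficiency = config$merge_pairing_efficiency,
    colony_recovery_rate = config$colony_recovery_rate,
    sorter_rate = config$sorter_rate,
    seed = config$seed
  )
}

#' Write a screen configuration as JSON
#'
#' @param config A [screen_config()].
#' @param path Output path.
#' @param extra Optional named list merged into the JSON (e.g. provenance
#'   notes on calibrated parameters).
#' @return `path`, invisibly.
#' @export
write_screen_config <- function(config, path, extra = NULL) {
  lst <- config_to_list(config)
  if (!is.null(extra)) lst <- c(lst, extra)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a screen configuration from JSON
#'
#' Rejects unknown top-level keys other than documentation fields
#' (`name`, `calibrated_parameters`, `notes`), and requires
#' `schema_version` 1.
#'
#' @param path JSON file written by [write_screen_config()].
#' @return A [screen_config()].
#' @export
read_screen_config <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("schema_version", "assay", "loading", "n_droplets",
             "cell_count_model", "merge_pairing_efficiency",
             "colony_recovery_rate", "sorter_rate", "seed",
             "name", "calibrated_parameters", "notes")
  unknown <- setdiff(names(lst), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(lst$schema_version) || lst$schema_version != 1L) {
    stop("unsupported config schema_version", call. = FALSE)
  }
  a <- lst$assay
  assay <- assay_params(a$hit_fraction, a$p_background, a$p_hit,
                        a$aggregate_size, a$count_model,
                        threshold = if (identical(a$threshold_rule, "midsize"))
                          "midsize" else a$threshold)
  screen_config(assay,
                loading_model(lst$loading$mean_per_droplet,
                              lst$loading$particle_kind),
                n_droplets = lst$n_droplets,
                cell_count_model = lst$cell_count_model,
                merge_pairing_efficiency = lst$merge_pairing_efficiency,
                colony_recovery_rate = lst$colony_recovery_rate,
                sorter_rate = if (is.null(lst$sorter_rate) ||
                                  is.na(lst$sorter_rate)) NA_real_
                              else lst$sorter_rate,
                seed = lst$seed)
}

#' Write a run manifest
#'
#' Records the command, seed, a hash of the configuration JSON, package
#' version and timestamp, so a run directory documents how to reproduce
#' itself.
#'
#' @param dir Output directory (one manifest per directory).
#' @param command Character description of the command run.
#' @param seed Seed used.
#' @param config_path Path of the config JSON the run used (hashed into the
#'   manifest), or `NULL`.
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(dir, command, seed, config_path = NULL) {
  hash <- if (!is.null(config_path) && file.exists(config_path)) {
    unname(tools::md5sum(config_path))
  } else NA_character_
  manifest <- list(command = command,
                   seed = seed,
                   config_md5 = hash,
                   package = "dropscreen",
                   version = as.character(utils::packageVersion("dropscreen")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  invisible(path)
}
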