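#' Load an experiment configuration
#'
#' Reads a YAML configuration document describing either a single run
#' (`mode: run`, the default) or a sweep (`mode: sweep`).  Model constants
#' omitted from the file take their defaults; `n` (and `omega`, for
#' voluntary runs) must be given explicitly since they are the swept
#' quantities.  Unknown keys are rejected with an error naming the key.
#'
#' Run-mode keys: every [param_set()] field.  Sweep-mode keys: `scenarios`,
#' `n`, `omega`, `replicates`, `periods`, `burn_in`, `seed`, `scale`, plus
#' model-constant overrides (`N`, `b`, `c`, `p`, `k`, `m`, `mu`, `s`, `e`).
#'
#' @param path path to a YAML file.
#' @return A `pgg_params` (run mode) or `pgg_grid` (sweep mode) object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  # identity handlers keep YAML-1.1 boolean tokens (notably the key "n")
  # as literal strings; the schema has no boolean fields
  cfg <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) x,
    "bool#no" = function(x) x
  ))
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  mode <- cfg$mode %||% "run"
  cfg$mode <- NULL
  if (identical(mode, "run")) {
    unknown <- setdiff(names(cfg), params_fields())
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    do.call(param_set, cfg)
  } else if (identical(mode, "sweep")) {
    ok <- c("scenarios", "n", "omega", "replicates", "periods", "burn_in",
            "seed", "scale", "N", "b", "c", "p", "k", "m", "mu", "s", "e")
    unknown <- setdiff(names(cfg), ok)
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    do.call(sweep_grid, cfg)
  } else {
    stop(sprintf("unknown config mode '%s' (use 'run' or 'sweep')", mode),
         call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: serialisable echo of a ParamSet or grid for metadata sidecars
meta_list <- function(x, seed = NULL) {
  base <- list(package = "pggsel",
               version = as.character(packageVersion("pggsel")),
               created = format(Sys.time(), tz = "UTC",
                                format = "%Y-%m-%dT%H:%M:%SZ"))
  if (inherits(x, "pgg_params")) {
    base$params <- unclass(x)
  } else if (inherits(x, "pgg_grid")) {
    base$grid <- unclass(x)
  }
  if (!is.null(seed)) base$seed <- seed
  base
}

#' Write simulation results to disk
#'
#' Serialises a run or summary table as CSV (UTF-8, `.` decimal, header
#' row) with a JSON metadata sidecar carrying the full parameter set, seed
#' and package version — enough to reproduce the output exactly.
#'
#' For a `pgg_run`, writes `<prefix>_timeseries.csv` (columns `period`,
#' `freq_defector`, `freq_contributor`, `freq_punisher`,
#' `freq_nonparticipant`, `freq_cooperation`) and `<prefix>_meta.json`.
#' For a summary/difference data frame, writes `<prefix>_summary.csv` and,
#' when `params` is supplied, `<prefix>_meta.json`.
#'
#' @param x a `pgg_run` or a data frame.
#' @param out_dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param params optional `pgg_params`/`pgg_grid` recorded in the metadata
#'   of data-frame outputs.
#' @return Character vector of the paths written, invisibly.
#' @export
write_results <- function(x, out_dir, prefix = "pggsel", params = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop(sprintf("cannot create output directory: %s", out_dir),
           call. = FALSE)
    }
  }
  paths <- character()
  if (inherits(x, "pgg_run")) {
    csv <- file.path(out_dir, paste0(prefix, "_timeseries.csv"))
    write.csv(x$records, csv, row.names = FALSE, quote = FALSE)
    meta <- file.path(out_dir, paste0(prefix, "_meta.json"))
    jsonlite::write_json(meta_list(x$params, seed = x$seed), meta,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(csv, meta)
  } else if (is.data.frame(x)) {
    csv <- file.path(out_dir, paste0(prefix, "_summary.csv"))
    write.csv(x, csv, row.names = FALSE, quote = FALSE)
    paths <- csv
    if (!is.null(params)) {
      meta <- file.path(out_dir, paste0(prefix, "_meta.json"))
      jsonlite::write_json(meta_list(params), meta,
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      paths <- c(csv, meta)
    }
  } else {
    stop("write_results: x must be a pgg_run or a data frame", call. = FALSE)
  }
  invisible(paths)
}

#' Read back a results CSV
#'
#' Lossless counterpart of [write_results()] for both time-series and
#' summary tables.
#'
#' @param path a CSV written by [write_results()].
#' @return Data frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("results file not found: %s", path), call. = FALSE)
  }
  read.csv(path, stringsAsFactors = FALSE)
}
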