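#' Read EEG trials from CSV
#'
#' Reads either dialect the package writes and consumes:
#' * **long** — columns `trial`, `channel`, `sample`, `value` and
#'   optionally `label` (one row per sample);
#' * **wide** — one row per channel with a `channel` column, optional
#'   `trial` / `label` columns, and the remaining columns holding samples
#'   in temporal order.
#' The dialect is auto-detected from the header unless forced. Comma
#' separator, '.' decimal, UTF-8, header required.
#'
#' @param path CSV file path.
#' @param format `"auto"`, `"long"` or `"wide"`.
#' @return A long-format trial tibble (see [crop_trials()]).
#' @export
read_trials_csv <- function(path, format = c("auto", "long", "wide")) {
  format <- match.arg(format)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  long_cols <- c("trial", "channel", "sample", "value")
  if (format == "auto") {
    format <- if (all(long_cols %in% names(df))) "long" else "wide"
  }
  if (format == "long") {
    missing <- setdiff(long_cols, names(df))
    if (length(missing)) {
      abort(sprintf("%s: missing column(s) %s", path,
                    paste(missing, collapse = ", ")))
    }
    out <- df
  } else {
    if (!"channel" %in% names(df)) {
      abort(sprintf("%s: wide format requires a 'channel' column", path))
    }
    meta <- intersect(c("trial", "label", "channel"), names(df))
    samp_cols <- setdiff(names(df), meta)
    if (length(samp_cols) == 0) abort(sprintf("%s: no sample columns", path))
    if (!"trial" %in% names(df)) df$trial <- 1L
    out <- df |>
      tidyr::pivot_longer(dplyr::all_of(samp_cols), names_to = ".col",
                          values_to = "value") |>
      dplyr::group_by(.data$trial, .data$channel) |>
      dplyr::mutate(sample = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::select(-".col")
  }
  keep <- intersect(c("trial", "label", "channel", "sample", "value"),
                    names(out))
  out <- dplyr::select(out, dplyr::all_of(keep))
  if ("label" %in% names(out)) out$label <- as.factor(out$label)
  check_trials(out)
  out
}

#' Write EEG trials to a long-format CSV
#'
#' @param trials A long-format trial tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  check_trials(trials)
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}

#' Write a feature table to CSV
#'
#' @param features Output of [extract_features()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  if (!is.data.frame(features)) abort("features must be a data frame")
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features_csv()]
#'
#' @param path CSV file path.
#' @return A tibble; a `label` column, if present, becomes a factor.
#' @export
read_features_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("label" %in% names(df)) df$label <- as.factor(df$label)
  df
}

#' Default run configuration
#'
#' All pipeline parameters with their defaults: `tau_max = 7`, `m = 2`,
#' `n = 2`, `r = 0.15`, `h = 3`, crop interval `[450, 900]`, a 6-unit
#' hidden layer, 10 x 10-fold CV. Any field can be overridden by a JSON or
#' YAML config file ([read_run_config()]) or per-call arguments.
#'
#' @return A named list of defaults.
#' @export
default_config <- function() {
  list(
    tau_max = 7, m = 2, n = 2, r = 0.15, h = 3,
    interval = c(450, 900),
    fs = 128, duration_s = 9, channels = c("C3", "C4"),
    mu_band = c(8, 12), mu_amp = 1, erd_depth = 0.5,
    erd_onset_s = 3.5, erd_offset_s = 7, noise_sd = 1,
    n_trials_per_class = 140,
    hidden = 6, learning_rate = 0.05, max_epochs = 2000,
    k = 10, repeats = 10, seed = 0, alpha = 0.05
  )
}

#' Read a run configuration file
#'
#' Reads a JSON (or YAML, by extension) configuration and merges it over
#' [default_config()]; unknown fields are rejected.
#'
#' @param path Config file, or `NULL` for pure defaults.
#' @return A complete configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    requireNamespace("yaml", quietly = TRUE) || abort("yaml not available")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown config field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  utils::modifyList(cfg, user)
}
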