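#' Read a delimited series table
#'
#' Comma- or tab-separated text with a mandatory header row; `#` lines
#' are comments; decimal point only.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_series_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) {
    abort("table needs a header row and at least one data row",
          class = "micellr_validation_error")
  }
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  tbl <- utils::read.table(text = paste(lines, collapse = "\n"), sep = sep,
                           header = TRUE, stringsAsFactors = FALSE)
  tibble::as_tibble(tbl)
}

.require_cols <- function(tbl, cols, path) {
  miss <- setdiff(cols, names(tbl))
  if (length(miss) > 0) {
    abort(paste0("missing column(s) ", paste(miss, collapse = ", "),
                 " in ", path), class = "micellr_validation_error")
  }
  invisible(tbl)
}

#' Read a PGSE echo series
#'
#' Expects an `amplitude` column and a gradient column whose header
#' carries the unit: `gradient_T_per_m` or `gradient_G_per_cm`
#' (1 G/cm = 0.01 T/m). Optional `amplitude_error`.
#'
#' @param path File path.
#' @return Tibble with `gradient` (T/m), `amplitude`, optional
#'   `amplitude_error`.
#' @export
read_echo_series <- function(path) {
  tbl <- read_series_table(path)
  .require_cols(tbl, "amplitude", path)
  if ("gradient_T_per_m" %in% names(tbl)) {
    tbl$gradient <- tbl$gradient_T_per_m
  } else if ("gradient_G_per_cm" %in% names(tbl)) {
    tbl$gradient <- tbl$gradient_G_per_cm * 1e-2
  } else {
    abort(paste0("missing column(s) gradient_T_per_m or gradient_G_per_cm in ", path),
          class = "micellr_validation_error")
  }
  dplyr::select(tbl, "gradient", "amplitude",
                dplyr::any_of("amplitude_error"))
}

#' Read a relaxation series
#'
#' Columns `time_s`, `amplitude`, optional `error`.
#'
#' @param path File path.
#' @return Tibble with `time` (s), `amplitude`, optional `error`.
#' @export
read_decay_series <- function(path) {
  tbl <- read_series_table(path)
  .require_cols(tbl, c("time_s", "amplitude"), path)
  out <- tibble::tibble(time = tbl$time_s, amplitude = tbl$amplitude)
  if ("error" %in% names(tbl)) out$error <- tbl$error
  out
}

#' Read a CPMG dispersion curve
#'
#' Columns `tau_cp_s` or `tau_cp_us` (microseconds), `r2_eff_s`,
#' optional `error`.
#'
#' @param path File path.
#' @return Tibble with `tau_cp` (s), `r2_eff` (s^-1), optional `error`.
#' @export
read_dispersion <- function(path) {
  tbl <- read_series_table(path)
  .require_cols(tbl, "r2_eff_s", path)
  tau <- if ("tau_cp_s" %in% names(tbl)) {
    tbl$tau_cp_s
  } else if ("tau_cp_us" %in% names(tbl)) {
    tbl$tau_cp_us * 1e-6
  } else {
    abort(paste0("missing column(s) tau_cp_s or tau_cp_us in ", path),
          class = "micellr_validation_error")
  }
  out <- tibble::tibble(tau_cp = tau, r2_eff = tbl$r2_eff_s)
  if ("error" %in% names(tbl)) out$error <- tbl$error
  out
}

#' Read a per-residue chemical-shift table
#'
#' Columns `residue_number`, `residue_type`, `atom`, `shift_ppm`.
#'
#' @param path File path.
#' @return Tibble with `residue_number`, `residue_type`, `atom`, `shift`.
#' @export
read_shift_table <- function(path) {
  tbl <- read_series_table(path)
  .require_cols(tbl, c("residue_number", "residue_type", "atom", "shift_ppm"), path)
  tibble::tibble(residue_number = as.integer(tbl$residue_number),
                 residue_type = tbl$residue_type,
                 atom = tbl$atom,
                 shift = tbl$shift_ppm)
}

#' Read a peptide sequence
#'
#' Accepts either a plain one-letter string or a path to a FASTA file
#' (first record used).
#'
#' @param x Sequence string or file path.
#' @return One-letter sequence string.
#' @export
read_sequence <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  if (file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    if (length(lines) == 0) abort("empty sequence file", class = "micellr_parse_error")
    if (startsWith(lines[1], ">")) {
      body <- lines[-1]
      nxt <- which(startsWith(body, ">"))
      if (length(nxt) > 0) body <- body[seq_len(nxt[1] - 1)]
      return(toupper(gsub("\\s", "", paste(body, collapse = ""))))
    }
    return(toupper(gsub("\\s", "", paste(lines, collapse = ""))))
  }
  toupper(gsub("\\s", "", x))
}

#' Serialise an analysis result to JSON with provenance
#'
#' Writes the result's tidy parameter table together with package
#' version, a hash of the input data, the settings used and any seed, so
#' the stage can be re-run identically.
#'
#' @param x A fitted object (`st_fit`, `relax_fit`, `dispersion_fit`,
#'   `tauc_result`) or a plain list.
#' @param path Output path.
#' @param settings Optional named list recorded verbatim.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path, settings = list()) {
  payload <- list(
    schema_version = 1L,
    package = "micellr",
    version = as.character(utils::packageVersion("micellr")),
    class = class(x)[1],
    settings = settings
  )
  if (inherits(x, c("st_fit", "relax_fit", "dispersion_fit"))) {
    payload$parameters <- tidy(x)
    payload$input_hash <- rlang::hash(x$data)
    if (!is.null(x$covariance)) payload$covariance <- as.vector(t(x$covariance))
    if (!is.null(x$seed)) payload$seed <- x$seed
  } else if (inherits(x, "tauc_result")) {
    payload$parameters <- list(tau_c = x$tau_c, uncertainty = x$uncertainty,
                               method = x$method)
  } else {
    payload$parameters <- x
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Run configuration serialisable to JSON
#'
#' Bundles the field, solvent, interaction constants and fit options a
#' full analysis needs; [write_run_config()] / [read_run_config()] round
#' trip it through JSON exactly.
#'
#' @param field A [field_spec()].
#' @param solvent A [solvent_spec()].
#' @param constants A [model_free_constants()].
#' @param n_starts,seed,alpha Fit options.
#' @return An object of class `run_config`.
#' @export
run_config <- function(field = field_spec(proton_frequency = 599.98e6),
                       solvent = solvent_spec(303),
                       constants = model_free_constants(),
                       n_starts = 32, seed = 1, alpha = 0.05) {
  structure(list(field = unclass(field), solvent = unclass(solvent),
                 constants = unclass(constants),
                 n_starts = n_starts, seed = seed, alpha = alpha),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(field = as.list(raw$field), solvent = as.list(raw$solvent),
                 constants = as.list(raw$constants),
                 n_starts = raw$n_starts, seed = raw$seed, alpha = raw$alpha),
            class = "run_config")
}
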