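# Waveform CSV schema: units are embedded in the column names so that files
# are self-describing and unit mismatches are caught on read.
WAVEFORM_COLUMNS <- c("time_s", "p_lv_mmHg", "p_ao_mmHg", "q_ao_mL_s",
                      "pdva_cm2", "cycle_index")

#' Write a synthetic dataset to CSV with a JSON metadata sidecar
#'
#' The CSV carries the waveform schema (`time_s`, `p_lv_mmHg`, `p_ao_mmHg`,
#' `q_ao_mL_s`, `pdva_cm2`, `cycle_index`); the sidecar `<path>.meta.json`
#' records the preset targets, the seed and the generator version so every
#' artifact is reproducible.
#'
#' @param dataset A `synthetic_dataset` from [gen_experiment()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveforms <- function(dataset, path) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  df <- dataset$cycles[, WAVEFORM_COLUMNS]
  num <- setdiff(WAVEFORM_COLUMNS, "cycle_index")
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  p <- dataset$preset
  meta <- list(
    schema = "valvetwin-waveforms-1",
    valve = p$valve,
    hr_bpm = p$hr_bpm,
    targets = list(sv_mean_ml = p$sv_mean, sv_sd_ml = p$sv_sd,
                   dp_mean_mmhg = p$dp_mean, dp_sd_mmhg = p$dp_sd,
                   q_peak_ml_s = p$q_peak),
    filter = list(cutoff_hz = p$filter_cutoff,
                  pressure = p$filter_pressure, flow = p$filter_flow),
    seed = dataset$seed,
    generator_version = dataset$version
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a waveform CSV written by [write_waveforms()]
#'
#' Validates the schema (all required columns present, units as named, a
#' uniform time grid within each cycle) and returns an object usable by the
#' dataset accessors and metrics.
#'
#' @param path CSV path; the sidecar `<path>.meta.json` is read if present.
#' @return An object of class `synthetic_dataset` (without the embedded
#'   calibration object; `meta` holds the sidecar contents).
#' @export
read_waveforms <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(WAVEFORM_COLUMNS, names(df))
  if (length(miss)) {
    hint <- ""
    bad_units <- grep("^(time|p_lv|p_ao|q_ao|pdva)", names(df), value = TRUE)
    bad_units <- setdiff(bad_units, WAVEFORM_COLUMNS)
    if (length(bad_units)) {
      hint <- paste0("; found column(s) with unexpected units: ",
                     paste(bad_units, collapse = ", "))
    }
    stop("waveform file is missing column(s): ",
         paste(miss, collapse = ", "), hint)
  }
  for (nm in setdiff(WAVEFORM_COLUMNS, "cycle_index")) {
    if (!is.numeric(df[[nm]]) || anyNA(df[[nm]])) {
      stop("waveform column '", nm, "' is not fully numeric")
    }
  }
  idx <- unique(df$cycle_index)
  tt <- df$time_s[df$cycle_index == idx[1]]
  for (i in idx) {
    ti <- df$time_s[df$cycle_index == i]
    if (length(ti) != length(tt) || max(abs(ti - tt)) > 1e-9) {
      stop("cycle ", i, " is not on the common time grid")
    }
  }
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
  structure(list(
    time = tt,
    cycles = df,
    mean = NULL,
    preset = NULL,
    meta = meta,
    seed = if (!is.null(meta$seed)) meta$seed else NA_integer_,
    version = if (!is.null(meta$generator_version)) meta$generator_version
  ), class = "synthetic_dataset")
}
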