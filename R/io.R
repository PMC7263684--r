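# Trace-dataset file I/O and pipeline configuration.
#
# Trace datasets are long-format CSV (one row per sample) plus a JSON
# manifest; the CSV dialect throughout the package is comma-separated,
# UTF-8, '.' decimal, mandatory header. Voltages and times are written
# with 17 significant digits so that write -> read is bit-identical;
# derived result tables use 9 significant digits.

TRACE_COLUMNS <- c("fly_id", "genotype_label", "rab_id", "contrast",
                   "repeat", "time_s", "voltage_uv")

#' Write a trace set to disk
#'
#' Writes `traces.csv` (long format, columns `fly_id`, `genotype_label`,
#' `rab_id`, `contrast`, `repeat`, `time_s`, `voltage_uv`) and
#' `manifest.json` (design parameters, stimulus spec, seed) into a
#' directory.
#'
#' @param ts A `"trace_set"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trace_dataset <- function(ts, dir) {
  abort_if(!inherits(ts, "trace_set"), "'ts' must be a trace_set")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_samp <- nrow(ts$voltage)
  t <- (seq_len(n_samp) - 1) / ts$stimulus$sample_rate
  long <- data.frame(
    fly_id = rep(ts$meta$fly_id, each = n_samp),
    genotype_label = rep(ts$meta$genotype_label, each = n_samp),
    rab_id = rep(ts$meta$rab_id, each = n_samp),
    contrast = rep(ts$meta$contrast, each = n_samp),
    rep = rep(ts$meta$rep, each = n_samp),
    time_s = rep(t, times = ncol(ts$voltage)),
    voltage_uv = as.vector(ts$voltage),
    stringsAsFactors = FALSE
  )
  long$contrast <- sprintf("%.17g", long$contrast)
  long$time_s <- sprintf("%.17g", long$time_s)
  long$voltage_uv <- sprintf("%.17g", long$voltage_uv)
  names(long)[names(long) == "rep"] <- "repeat"
  utils::write.csv(long, file.path(dir, "traces.csv"), row.names = FALSE,
                   quote = FALSE)
  d <- ts$design
  manifest <- list(
    stimulus = unclass(ts$stimulus),
    design = if (!is.null(d)) list(
      rab_ids = d$rab_ids, n_flies_per_arm = d$n_flies_per_arm,
      contrasts = d$contrasts, n_repeats = d$n_repeats,
      cv = d$cv, seed = d$seed,
      population = unclass(d$population)
    ) else NULL,
    n_traces = ncol(ts$voltage), n_samples = n_samp
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a trace dataset from disk
#'
#' Reads `traces.csv` and `manifest.json` written by
#' [write_trace_dataset()], validating the schema: required columns
#' present, numeric voltage, and a consistent uniform time grid within
#' each trace. Violations are reported with the offending column or row
#' numbers.
#'
#' @param dir Directory holding `traces.csv` and `manifest.json`.
#' @return A `"trace_set"` (without a `design` element when the manifest
#'   carries none).
#' @export
read_trace_dataset <- function(dir) {
  csv <- file.path(dir, "traces.csv")
  mjs <- file.path(dir, "manifest.json")
  abort_if(!file.exists(csv), "no traces.csv in ", dir)
  abort_if(!file.exists(mjs), "no manifest.json in ", dir)
  abort_if(file.size(csv) == 0L, "empty dataset: traces.csv has no content")
  long <- utils::read.csv(csv, stringsAsFactors = FALSE, check.names = FALSE)
  abort_if(nrow(long) == 0L, "empty dataset: traces.csv has no rows")
  missing <- setdiff(TRACE_COLUMNS, names(long))
  abort_if(length(missing) > 0L,
           "parse error: missing column(s) ", paste(missing, collapse = ", "))
  for (col in c("contrast", "repeat", "time_s", "voltage_uv")) {
    if (!is.numeric(long[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(long[[col]]))))
      abort_if(TRUE, sprintf("parse error: non-numeric '%s' at row(s) %s",
                             col, paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  manifest <- jsonlite::fromJSON(mjs)
  st <- do.call(stimulus_spec, manifest$stimulus[
    c("f1", "mean_level", "contrast", "duration", "sample_rate")])
  key <- paste(long$fly_id, long$genotype_label, long$contrast, long$`repeat`,
               sep = "\r")
  key <- factor(key, levels = unique(key))
  n_per <- table(key)
  abort_if(length(unique(n_per)) != 1L,
           "parse error: traces differ in sample count")
  n_samp <- as.integer(n_per[1L])
  dt <- diff(long$time_s[seq_len(min(n_samp, nrow(long)))])
  abort_if(n_samp > 1L && (any(dt <= 0) || diff(range(dt)) > 1e-9 * mean(dt)),
           "parse error: inconsistent sample spacing in first trace")
  idx <- split(seq_len(nrow(long)), key)
  vmat <- vapply(idx, function(i) long$voltage_uv[i], numeric(n_samp))
  first <- vapply(idx, `[`, integer(1), 1L)
  meta <- data.frame(
    trace_id = seq_along(idx),
    fly_id = long$fly_id[first],
    genotype_label = long$genotype_label[first],
    rab_id = ifelse(long$rab_id[first] %in% c("", "NA"), NA_character_,
                    as.character(long$rab_id[first])),
    contrast = long$contrast[first],
    rep = long$`repeat`[first],
    stringsAsFactors = FALSE
  )
  dimnames(vmat) <- NULL
  structure(list(voltage = vmat, meta = meta, stimulus = st,
                 design = NULL, truth = NULL),
            class = "trace_set")
}

#' Pipeline configuration
#'
#' Collects every tunable option of the four-stage pipeline with its
#' default. The configuration serializes losslessly to JSON via
#' [config_to_json()] / [config_from_json()].
#'
#' @param scenario `"recovery"` (the 23-Rab reference screen) or `"null"`
#'   (small all-multipliers-1 screen).
#' @param seed Global integer seed; all stage seeds derive from it.
#' @param n_flies_per_arm Flies per arm (recovery scenario only).
#' @param avg_mode Repeat-averaging mode (`"incoherent"` or `"coherent"`).
#' @param k_noise Noise-floor bins per side.
#' @param snr_min Optional SNR gate on best responses (`NULL`: no gate).
#' @param weighted_spectrum Inverse-variance weighting of the spectrum
#'   regression.
#' @param outlier_threshold Studentized-residual threshold for
#'   [detect_outliers()].
#' @param dunnett_draws Monte-Carlo draws for [anova_dunnett()].
#' @param annotations Optional path to an annotation CSV (column `rab_id`
#'   plus logical/0-1 annotation columns) for enrichment tests.
#' @param out_dir Output directory for [run_pipeline()].
#' @param write_traces Also write the simulated traces as CSV (default
#'   `FALSE`; trace CSVs are large).
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(scenario = c("recovery", "null"),
                            seed = 1L,
                            n_flies_per_arm = 10,
                            avg_mode = c("incoherent", "coherent"),
                            k_noise = 5L,
                            snr_min = NULL,
                            weighted_spectrum = FALSE,
                            outlier_threshold = 3,
                            dunnett_draws = 1e5,
                            annotations = NULL,
                            out_dir = "ssvep_out",
                            write_traces = FALSE) {
  structure(list(scenario = match.arg(scenario), seed = as.integer(seed),
                 n_flies_per_arm = n_flies_per_arm,
                 avg_mode = match.arg(avg_mode), k_noise = k_noise,
                 snr_min = snr_min, weighted_spectrum = weighted_spectrum,
                 outlier_threshold = outlier_threshold,
                 dunnett_draws = dunnett_draws, annotations = annotations,
                 out_dir = out_dir, write_traces = write_traces),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `"pipeline_config"`.
#' @param path Optional file path for the JSON.
#' @export
config_to_json <- function(config, path = NULL) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname pipeline_config
#' @param x JSON string or file path written by [config_to_json()].
#' @export
config_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  do.call(pipeline_config, obj[!vapply(obj, is.null, logical(1))])
}
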