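# End-to-end pipeline: simulate -> extract -> crf -> screen.

log_msg <- function(con, level, ...) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, paste0(...))
  message(line)
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}

read_annotation_table <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  abort_if(!"rab_id" %in% names(ann), "annotation CSV needs a 'rab_id' column")
  for (col in setdiff(names(ann), "rab_id")) {
    v <- ann[[col]]
    if (is.character(v)) v <- toupper(v) %in% c("TRUE", "T", "YES", "1")
    ann[[col]] <- as.logical(v)
  }
  ann
}

#' Run the full screen-analysis pipeline
#'
#' Executes the four stages on a simulated screen: (1) simulate the trace
#' set for the configured scenario, (2) extract per-(fly, contrast)
#' harmonic amplitudes, (3) reduce to per-fly best responses, (4) compute
#' the screen statistics (arm summaries, synergy points, the
#' synergy-spectrum regression per harmonic, optional annotation
#' enrichment, signaling points with leave-one-out outlier detection, and
#' per-Rab ANOVA/Dunnett comparisons against the control arm). All result
#' tables are written to the output directory together with a manifest
#' (seed, config hash) and a timestamped run log; numeric outputs are
#' formatted with 9 significant digits, so identical config + seed gives
#' byte-identical files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @param quiet Suppress console log messages.
#' @return An object of class `"ssvep_screen"` holding every intermediate
#'   and final table, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  abort_if(!inherits(config, "pipeline_config"),
           "'config' must be a pipeline_config")
  if (is.null(out_dir)) out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  say <- function(...) {
    if (quiet) {
      writeLines(sprintf("%s [info] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                         paste0(...)), logf)
    } else {
      log_msg(logf, "info", ...)
    }
  }
  cfg_json <- as.character(config_to_json(config))
  say("config hash ", hash_string(cfg_json), ", seed ", config$seed)

  stage <- "simulate"
  result <- tryCatch({
    design <- switch(config$scenario,
      recovery = recovery_screen_design(seed = config$seed,
                                        n_flies_per_arm = config$n_flies_per_arm),
      null = null_screen_design(seed = config$seed))
    effects <- switch(config$scenario,
      recovery = recovery_screen_effects(),
      null = null_screen_effects(design$rab_ids))
    ts <- simulate_screen(design, effects)
    say("simulated ", ncol(ts$voltage), " traces for ",
        length(design$rab_ids), " Rab(s)")
    if (isTRUE(config$write_traces)) write_trace_dataset(ts, out_dir)

    stage <- "extract"
    harmonics <- extract_harmonic_table(ts, mode = config$avg_mode,
                                        k_noise = config$k_noise)
    write_result_csv(harmonics, file.path(out_dir, "harmonics.csv"))

    stage <- "crf"
    flies <- fly_results(harmonics, snr_min = config$snr_min)
    write_result_csv(flies, file.path(out_dir, "fly_results.csv"))

    stage <- "screen"
    agg <- screen_summaries(flies)
    write_result_csv(agg$summaries, file.path(out_dir, "summaries.csv"))
    write_result_csv(agg$synergy, file.path(out_dir, "synergy_points.csv"))

    fits <- lapply(stats::setNames(c("1F1", "2F1"), c("1F1", "2F1")),
                   function(h) {
                     pts <- agg$synergy[agg$synergy$harmonic == h, ]
                     fit_spectrum(pts, weighted = config$weighted_spectrum)
                   })
    fit_json <- lapply(fits, function(f) {
      list(slope = f$slope, intercept = f$intercept,
           r_squared = f$r_squared,
           residuals = as.list(stats::setNames(f$residuals, f$rab_id)),
           above_line = as.list(stats::setNames(f$above_line, f$rab_id)))
    })
    writeLines(jsonlite::toJSON(fit_json, auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "spectrum_fit.json"))

    enrichment <- NULL
    if (!is.null(config$annotations)) {
      ann <- read_annotation_table(config$annotations)
      rows <- list()
      for (h in names(fits)) {
        for (col in setdiff(names(ann), "rab_id")) {
          flag <- stats::setNames(ann[[col]], ann$rab_id)
          er <- enrichment_test(fits[[h]], flag)
          rows <- c(rows, list(data.frame(
            harmonic = h, annotation = col,
            n_annot_above = er$table[1, 1], n_annot_below = er$table[1, 2],
            n_other_above = er$table[2, 1], n_other_below = er$table[2, 2],
            odds_ratio = er$odds_ratio, p_two_sided = er$p_two_sided,
            stringsAsFactors = FALSE)))
        }
      }
      enrichment <- do.call(rbind, rows)
      write_result_csv(enrichment, file.path(out_dir, "enrichment.csv"))
    }

    sig <- signaling_points(flies)
    outliers <- detect_outliers(sig, threshold = config$outlier_threshold)
    write_result_csv(as.data.frame(outliers),
                     file.path(out_dir, "signaling.csv"))

    dun_rows <- list()
    for (h in c("1F1", "2F1")) {
      col <- paste0("best_", h)
      for (r in design$rab_ids) {
        sel <- is.na(flies$rab_id) | flies$rab_id %in% r
        d <- flies[sel, ]
        ad <- anova_dunnett(d[[col]], d$genotype_label, control = "control",
                            n_draws = config$dunnett_draws,
                            seed = derive_seed(config$seed,
                                               paste0("dunnett/", h, "/", r)))
        dun_rows <- c(dun_rows, list(cbind(
          data.frame(rab_id = r, harmonic = h,
                     F = ad$anova$F, p_anova = ad$anova$p,
                     stringsAsFactors = FALSE),
          ad$comparisons)))
      }
    }
    dunnett <- do.call(rbind, dun_rows)
    write_result_csv(dunnett, file.path(out_dir, "anova_dunnett.csv"))

    manifest <- list(seed = config$seed, config = unclass(config),
                     config_hash = hash_string(cfg_json),
                     package_version = as.character(utils::packageVersion("ssvepscreen")),
                     r_version = paste(R.version$major, R.version$minor, sep = "."))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE),
               file.path(out_dir, "manifest.json"))
    say("pipeline complete: ", out_dir)

    structure(list(config = config, design = design, truth = ts$truth,
                   harmonics = harmonics, flies = flies,
                   summaries = agg$summaries, synergy = agg$synergy,
                   fits = fits, enrichment = enrichment,
                   signaling = sig, outliers = outliers, dunnett = dunnett,
                   out_dir = out_dir),
              class = "ssvep_screen")
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(result)
}

#' @export
print.ssvep_screen <- function(x, ...) {
  cat(sprintf(
    "SSVEP screen analysis (%s scenario, seed %d): %d Rabs, %d flies\n",
    x$config$scenario, x$config$seed, length(x$design$rab_ids),
    nrow(x$flies)))
  for (h in names(x$fits)) {
    f <- x$fits[[h]]
    cat(sprintf("  %s spectrum: slope %.4g, R^2 %.3f, above line: %s\n",
                h, f$slope, f$r_squared,
                paste(f$rab_id[f$above_line], collapse = ", ")))
  }
  fl <- x$outliers$rab_id[x$outliers$flagged]
  cat("  signaling outliers: ",
      if (length(fl)) paste(fl, collapse = ", ") else "none", "\n", sep = "")
  invisible(x)
}

#' @export
summary.ssvep_screen <- function(object, ...) {
  print(object)
  cat("\nPer-arm summaries (2F1):\n")
  print(utils::head(object$summaries[object$summaries$harmonic == "2F1", ], 12),
        digits = 4, row.names = FALSE)
  invisible(object)
}

#' @export
plot.ssvep_screen <- function(x, harmonic = "2F1", ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op), add = TRUE)
  plot(x$fits[[harmonic]], main = sprintf("%s synergy spectrum", harmonic))
  graphics::plot(x$signaling$x, x$signaling$y,
                 xlab = "G2019S effect on 1F1 (µV)",
                 ylab = "G2019S effect on 2F1 (µV)",
                 main = "Lamina vs photoreceptor")
  flag <- x$outliers$flagged
  if (any(flag)) {
    graphics::points(x$signaling$x[flag], x$signaling$y[flag], pch = 19)
    graphics::text(x$signaling$x[flag], x$signaling$y[flag],
                   x$signaling$rab_id[flag], pos = 2, cex = 0.8)
  }
  invisible(x)
}
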