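#' Run the full image-to-kinetics analysis on a stack on disk
#'
#' Orchestrates the analysis chain the package implements: load the stack and
#' schedule, collapse camera frames to one per imaging epoch, build the
#' baseline signal mask, extract per-ROI delta-F/F traces, subtract the
#' control-population photoartifact (when control ROIs are present), convert
#' to pH through the piecewise-linear calibration, and compute per-ROI
#' kinetics. Writes `trace_<label>.csv`, `kinetics.csv`, `comparison.json`
#' (expressing vs control final pH, when both exist) and `analysis_log.txt`
#' into `out_dir`.
#'
#' @param stack_path multi-page TIFF written by [write_stack()].
#' @param sidecar_path its JSON schedule sidecar.
#' @param roi_path 16-bit label-mask TIFF ([write_label_mask()]).
#' @param calib_path calibration CSV with columns `pH`, `dff`.
#' @param config a [read_config()] object or path; must contain the
#'   `protocol` section, and optionally `pipeline` (threshold rule, analysis
#'   windows, initial pH).
#' @param out_dir output directory (created if needed).
#' @param roi_categories optional data frame (`label`, `category`, `parent`)
#'   or CSV path; defaults to every ROI being a soma.
#' @return Invisibly, a list with the collapsed traces, per-ROI kinetics and
#'   the comparison (if any).
#' @export
analyze_stack <- function(stack_path, sidecar_path, roi_path, calib_path,
                          config, out_dir, roi_categories = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$protocol)) {
    stop("config must contain a protocol section", call. = FALSE)
  }
  protocol <- config$protocol
  pipe <- config$raw$pipeline
  f0_rule <- if (!is.null(pipe$f0_rule)) pipe$f0_rule else "quantile"
  f0_value <- if (!is.null(pipe$f0_value)) pipe$f0_value else 0.5
  initial_pH <- if (!is.null(pipe$initial_pH)) pipe$initial_pH else 7.3
  active <- attr(protocol, "active_s")
  total <- attr(protocol, "total_s")
  stim_win <- if (!is.null(pipe$stim_window)) unlist(pipe$stim_window)
              else c(0, active)
  rec_win <- if (!is.null(pipe$recovery_window)) unlist(pipe$recovery_window)
             else c(active, total)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stack <- read_stack(stack_path, sidecar_path)
  mask <- read_label_mask(roi_path)
  labels <- sort(setdiff(unique(as.vector(mask)), 0))
  cats <- if (is.null(roi_categories)) {
    data.frame(label = labels, category = "soma", parent = NA_integer_)
  } else if (is.character(roi_categories)) {
    read.csv(roi_categories)
  } else roi_categories
  rois <- roi_set(mask, cats)
  calib <- build_calibration(read.csv(calib_path))

  collapsed <- collapse_epochs(stack, protocol)
  sig <- f0_mask(collapsed$data[1, , ], f0_rule, f0_value)

  traces <- lapply(labels, function(lb) {
    extract_trace(collapsed, rois, lb, signal_mask = sig)
  })
  names(traces) <- labels

  ctrl_labels <- cats$label[cats$category == "control"]
  controls <- traces[as.character(ctrl_labels)]
  signal_labels <- setdiff(labels, ctrl_labels)
  corrected <- lapply(as.character(signal_labels), function(lb) {
    if (length(controls) > 0) subtract_artifact(traces[[lb]], controls)
    else traces[[lb]]
  })
  names(corrected) <- signal_labels

  kin <- list(); ph_final <- c()
  for (lb in as.character(signal_labels)) {
    ph <- dff_to_ph(corrected[[lb]], calib, initial_pH = initial_pH,
                    waive_correction = TRUE)
    kin[[lb]] <- roi_kinetics(ph, stim_win, rec_win)
    ph_final[lb] <- ph$pH[nrow(ph)]
    df <- data.frame(epoch_t_s = corrected[[lb]]$t,
                     dff_raw = traces[[lb]]$dff,
                     dff_corrected = corrected[[lb]]$dff,
                     pH = ph$pH, clamped = ph$clamped)
    write.csv(df, file.path(out_dir, paste0("trace_", lb, ".csv")),
              row.names = FALSE)
  }

  kin_df <- data.frame(
    label = as.integer(names(kin)),
    category = cats$category[match(as.integer(names(kin)), cats$label)],
    pH_min = vapply(kin, `[[`, numeric(1), "pH_min"),
    pH_final = unname(ph_final),
    t_half_acid = vapply(kin, `[[`, numeric(1), "t_half_acid"),
    tau_rec = vapply(kin, `[[`, numeric(1), "tau_rec"),
    t_half_rec = vapply(kin, `[[`, numeric(1), "t_half_rec"),
    row.names = NULL)
  write.csv(kin_df, file.path(out_dir, "kinetics.csv"), row.names = FALSE)

  comparison <- NULL
  if (length(controls) > 0 && length(signal_labels) > 0) {
    ctrl_final <- vapply(controls, function(tr) {
      ph <- dff_to_ph(tr, calib, initial_pH = initial_pH,
                      waive_correction = TRUE)
      ph$pH[nrow(ph)]
    }, numeric(1))
    if (length(ctrl_final) >= 1 && length(ph_final) >= 1) {
      comparison <- tryCatch(
        compare_groups(unname(ph_final), unname(ctrl_final)),
        error = function(e) NULL)
      if (!is.null(comparison)) {
        jsonlite::write_json(
          list(test = comparison$test, statistic = comparison$statistic,
               p_value = comparison$p_value, n = comparison$n,
               exact = comparison$exact),
          file.path(out_dir, "comparison.json"), auto_unbox = TRUE,
          digits = NA)
      }
    }
  }

  writeLines(c(
    paste("f0 rule:", f0_rule, f0_value, "threshold:",
          format(attr(sig, "threshold"))),
    paste("initial pH:", initial_pH),
    paste("stim window:", paste(stim_win, collapse = "-")),
    paste("recovery window:", paste(rec_win, collapse = "-")),
    paste("seed:", if (is.null(config$seed)) "none" else config$seed)),
    file.path(out_dir, "analysis_log.txt"))

  invisible(list(traces = corrected, kinetics = kin_df,
                 comparison = comparison))
}
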