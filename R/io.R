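# Atomic file writes: write to a temp file in the target directory, then
# rename, so interrupted runs never leave truncated outputs.
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".tmp.",
                                                           basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("atomic rename failed for ", path,
                                    call. = FALSE)
  invisible(path)
}

#' Write a frame stack as multi-page TIFF with a JSON schedule sidecar
#'
#' Pixel data are stored as 32-bit TIFF pages scaled to \[0, 1\]; the scale
#' factor and the per-frame schedule (index, time, epoch label, wavelength,
#' intensity) go in the sidecar. Writes are atomic.
#'
#' @param stack a [frame_stack()].
#' @param path_tiff,path_sidecar output paths.
#' @param protocol optional [build_protocol()] used to annotate per-frame
#'   wavelength/intensity in the sidecar.
#' @return Invisibly, the TIFF path.
#' @export
write_stack <- function(stack, path_tiff, path_sidecar, protocol = NULL) {
  d <- dim(stack$data)
  lo <- min(stack$data); hi <- max(stack$data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[1]), function(k) {
    (stack$data[k, , ] - lo) / scale
  })
  write_atomic(path_tiff, function(p) {
    tiff::writeTIFF(pages, p, bits.per.sample = 32)
  })
  wl <- rep(NA_real_, d[1]); it <- rep(NA_real_, d[1])
  if (!is.null(protocol)) {
    ep <- epoch_at(protocol, stack$t)
    wl <- protocol$wavelength[ep]
    it <- protocol$intensity[ep]
  }
  sidecar <- list(
    scale = scale, offset = lo,
    frames = data.frame(index = seq_len(d[1]), t_s = stack$t,
                        epoch = stack$epoch, wavelength_nm = wl,
                        intensity_mW_cm2 = it))
  write_atomic(path_sidecar, function(p) {
    jsonlite::write_json(sidecar, p, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  })
  invisible(path_tiff)
}

#' Read a frame stack written by [write_stack()]
#'
#' @param path_tiff multi-page TIFF.
#' @param path_sidecar JSON schedule sidecar; its entry count must match the
#'   TIFF page count.
#' @return A [frame_stack()].
#' @export
read_stack <- function(path_tiff, path_sidecar) {
  pages <- tryCatch(tiff::readTIFF(path_tiff, all = TRUE),
                    error = function(e) {
                      stop("unreadable TIFF ", path_tiff, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
  sc <- jsonlite::read_json(path_sidecar, simplifyVector = TRUE)
  frames <- sc$frames
  if (length(pages) != nrow(frames)) {
    stop("sidecar/TIFF mismatch: ", nrow(frames), " sidecar entries vs ",
         length(pages), " TIFF pages (first unmatched index ",
         min(length(pages), nrow(frames)) + 1, ")", call. = FALSE)
  }
  arr <- array(NA_real_, dim = c(length(pages), nrow(pages[[1]]),
                                 ncol(pages[[1]])))
  for (k in seq_along(pages)) {
    arr[k, , ] <- pages[[k]] * sc$scale + sc$offset
  }
  frame_stack(arr, frames$t_s, frames$epoch)
}

#' Write / read a 16-bit integer label mask TIFF
#'
#' @param mask integer matrix (labels 0..65535).
#' @param path output path.
#' @return Invisibly the path / the integer matrix.
#' @export
write_label_mask <- function(mask, path) {
  write_atomic(path, function(p) {
    tiff::writeTIFF(mask / 65535, p, bits.per.sample = 16)
  })
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  storage.mode(m) <- "double"
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write a simulated trace as CSV
#'
#' Columns `t_s`, `V_mV`, `pH`, `F`, `epoch`. Atomic.
#'
#' @param trace a [simulate_cell()] trace.
#' @param path output path.
#' @param every write every n-th sample (thinning for long simulations).
#' @return Invisibly the path.
#' @export
write_sim_trace <- function(trace, path, every = 1) {
  rows <- seq(1, nrow(trace), by = every)
  df <- data.frame(t_s = trace$t[rows], V_mV = trace$V_mV[rows],
                   pH = trace$pH[rows], F = trace$F[rows],
                   epoch = trace$epoch[rows])
  write_atomic(path, function(p) write.csv(df, p, row.names = FALSE))
  invisible(path)
}

# known config sections and their known keys
.config_schema <- list(
  geometry = c("shape", "radius_um", "length_um"),
  opsin = c("preset", "g_max_nS", "E_ops_mV", "f_H", "EPD50_mW_cm2",
            "tau_on_sat_ms", "tau_off_ms", "desensitization_ratio",
            "spectrum"),
  sensor = c("pKa", "hill_n", "F_max", "artifact_rate", "noise_sd", "pH_ref"),
  physiology = c("C_m_pF", "g_leak_nS", "E_K_mV", "beta_buff", "k_rec",
                 "pH_rest", "temperature_K"),
  protocol = c("stim_s", "image_s", "active_total", "recovery_total",
               "stim_wavelength", "stim_intensity", "image_wavelength",
               "image_intensity"),
  pipeline = c("f0_rule", "f0_value", "initial_pH", "stim_window",
               "recovery_window"),
  monolayer = c("nx", "ny", "pitch_um", "g_gap_nS", "cell_volume_L",
                "on_width_um", "gap_um", "t_stim_s", "duty", "k_gapH"),
  seed = NULL, out = NULL, log_level = NULL
)

#' Read and validate a JSON/YAML run configuration
#'
#' Unknown sections or keys are rejected (typo protection); recognized
#' sections are converted to the package's parameter objects.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return A `run_config`: list with the raw config plus resolved `geom`,
#'   `opsin`, `sensor`, `phys`, `protocol` objects where those sections are
#'   present.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format: .", ext, call. = FALSE))
  unknown_sec <- setdiff(names(raw), names(.config_schema))
  if (length(unknown_sec) > 0) {
    stop("unknown config section(s): ", paste(unknown_sec, collapse = ", "),
         call. = FALSE)
  }
  for (sec in intersect(names(raw), names(.config_schema))) {
    keys <- .config_schema[[sec]]
    if (is.null(keys)) next
    bad <- setdiff(names(raw[[sec]]), keys)
    if (length(bad) > 0) {
      stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  cfg <- list(raw = raw)
  if (!is.null(raw$geometry)) {
    cfg$geom <- do.call(compartment_geometry, raw$geometry)
  }
  if (!is.null(raw$opsin)) {
    op <- raw$opsin
    cfg$opsin <- if (!is.null(op$preset)) {
      base <- opsin_preset(op$preset)
      op$preset <- NULL
      if (length(op) > 0) {
        fields <- unclass(base)
        fields[names(op)] <- op
        do.call(opsin_params, setNames(fields, sub("^spectrum$", "spectrum",
                                                   names(fields))))
      } else base
    } else do.call(opsin_params, op)
  }
  if (!is.null(raw$sensor)) cfg$sensor <- do.call(sensor_params, raw$sensor)
  if (!is.null(raw$physiology)) {
    cfg$phys <- do.call(physiology_params, raw$physiology)
  }
  if (!is.null(raw$protocol)) cfg$protocol <- do.call(build_protocol,
                                                      raw$protocol)
  cfg$seed <- raw$seed
  structure(cfg, class = "run_config")
}

#' Write the fully resolved configuration beside a run's outputs
#'
#' @param cfg a [read_config()] result or plain list.
#' @param path output YAML path.
#' @return Invisibly the path.
#' @export
write_resolved_config <- function(cfg, path) {
  raw <- if (inherits(cfg, "run_config")) cfg$raw else cfg
  write_atomic(path, function(p) yaml::write_yaml(raw, p))
  invisible(path)
}

#' Generate a named synthetic fixture dataset on disk
#'
#' Deterministic, seed-controlled datasets mirroring the package's study
#' designs, each with a ground-truth JSON for every generated quantity:
#'
#' * `"neurons-interleaved"`: a small movie of soma ROIs (proton-permeable
#'   opsin) plus an opsin-negative control ROI under an interleaved
#'   stimulation/imaging protocol, with label mask, schedule sidecar and a
#'   calibration table sampled from the sensor model.
#' * `"monolayer-stripes"`: a striped-illumination monolayer run; per-cell
#'   CSV plus V and pH maps.
#' * `"three-opsins"`: three simulated populations (proton fraction 0.5, 0,
#'   0) of compartment traces.
#'
#' @param scenario scenario name (see above).
#' @param seed RNG seed.
#' @param dir output directory (created if needed).
#' @return Invisibly, a list of the written file paths.
#' @export
make_fixtures <- function(scenario, seed, dir) {
  known <- c("neurons-interleaved", "monolayer-stripes", "three-opsins")
  if (!scenario %in% known) {
    stop("unknown scenario '", scenario, "'; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(dir, f)
  paths <- list()
  truth <- list(scenario = scenario, seed = seed)

  if (scenario == "neurons-interleaved") {
    protocol <- build_protocol(0.5, 1, 30, 30)
    sensor <- sensor_params(noise_sd = 0.004)
    cells <- list(
      simulate_cell(opsin = opsin_preset("cheriff"), sensor = sensor,
                    protocol = protocol, seed = seed),
      simulate_cell(opsin = opsin_preset("cheriff"), sensor = sensor,
                    protocol = protocol, seed = seed + 1),
      simulate_cell(opsin = opsin_preset("pscatch2"), sensor = sensor,
                    protocol = protocol, seed = seed + 2))
    layout <- list(list(cx = 12, cy = 12, r = 6),
                   list(cx = 34, cy = 14, r = 6),
                   list(cx = 22, cy = 34, r = 6))
    mov <- render_movie(cells, layout, ny = 48, nx = 48, protocol = protocol,
                        frame_rate = 4, background = 2, noise_sd = 1,
                        seed = seed + 10)
    write_stack(mov$stack, pth("stack.tif"), pth("schedule.json"), protocol)
    write_label_mask(mov$mask, pth("rois.tif"))
    knots <- c(6.4, 6.7, 7.0, 7.3)
    Fk <- render_fluorescence(knots, sensor_params())
    F0 <- render_fluorescence(7.3, sensor_params())
    calib <- data.frame(pH = knots, dff = (Fk - F0) / F0)
    write_atomic(pth("calibration.csv"), function(p) {
      write.csv(calib, p, row.names = FALSE)
    })
    write_resolved_config(list(
      protocol = list(stim_s = 0.5, image_s = 1, active_total = 30,
                      recovery_total = 30),
      pipeline = list(initial_pH = 7.3, stim_window = c(0, 30),
                      recovery_window = c(30, 60)),
      seed = seed), pth("config.yaml"))
    truth$cells <- lapply(seq_along(cells), function(i) {
      list(label = i, f_H = attr(cells[[i]], "params")$opsin$f_H,
           pH_final = cells[[i]]$pH[nrow(cells[[i]])],
           pH_min = min(cells[[i]]$pH))
    })
    paths <- lapply(c("stack.tif", "schedule.json", "rois.tif",
                      "calibration.csv", "config.yaml"), pth)
  }

  if (scenario == "monolayer-stripes") {
    grid <- monolayer_grid(nx = 40, ny = 20)
    pat <- stripe_pattern(grid, 95, 95)
    sim <- simulate_monolayer(grid, pat, t_stim_s = 13.5)
    cells <- data.frame(which(grid$express, arr.ind = TRUE),
                        V_mV = as.vector(sim$V), dpH = as.vector(sim$dpH),
                        illuminated = as.vector(unclass(pat)))
    write_atomic(pth("cells.csv"), function(p) {
      write.csv(cells, p, row.names = FALSE)
    })
    maps <- frame_stack(array(c(sim$V, sim$pH),
                              dim = c(1, nrow(sim$V), 2 * ncol(sim$V))),
                        t = 13.5, epoch = "image")
    vstack <- frame_stack(array(sim$V, dim = c(1, dim(sim$V))), 13.5, "image")
    pstack <- frame_stack(array(sim$pH, dim = c(1, dim(sim$pH))), 13.5,
                          "image")
    write_stack(vstack, pth("vmap.tif"), pth("vmap.json"))
    write_stack(pstack, pth("phmap.tif"), pth("phmap.json"))
    ctr <- acidification_contrast(sim)
    truth$contrast <- ctr[c("dpH_on", "dpH_off", "ratio")]
    truth$mask_on_columns <- which(unclass(pat)[1, ])
    paths <- lapply(c("cells.csv", "vmap.tif", "phmap.tif"), pth)
  }

  if (scenario == "three-opsins") {
    protocol <- build_protocol(0.5, 1, 20, 0)
    groups <- list(cheriff = opsin_preset("cheriff"),
                   chr2_3m = opsin_preset("chr2_3m"),
                   pscatch2 = opsin_preset("pscatch2"))
    n_per <- 4
    truth$groups <- list()
    k <- 0
    for (g in names(groups)) {
      finals <- numeric(n_per)
      for (i in seq_len(n_per)) {
        k <- k + 1
        tr <- simulate_cell(opsin = groups[[g]],
                            sensor = sensor_params(noise_sd = 0.004),
                            protocol = protocol, seed = seed + k)
        write_sim_trace(tr, pth(sprintf("%s_%02d.csv", g, i)), every = 20)
        finals[i] <- tr$pH[nrow(tr)]
        paths <- c(paths, pth(sprintf("%s_%02d.csv", g, i)))
      }
      truth$groups[[g]] <- list(f_H = groups[[g]]$f_H, pH_final = finals)
    }
  }

  write_atomic(pth("truth.json"), function(p) {
    jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  paths <- c(paths, pth("truth.json"))
  invisible(paths)
}

#' Summarize a results directory
#'
#' Collects per-ROI kinetics (`kinetics.csv`) and group comparisons
#' (`comparison.json`) written by an analysis run into a single summary with
#' a machine-readable JSON twin (`report.json`); reruns on identical inputs
#' produce identical JSON.
#'
#' @param results_dir directory containing `kinetics.csv` and/or
#'   `comparison.json`.
#' @param plot also write `traces.pdf` if per-ROI trace CSVs are present.
#' @return The summary list, invisibly; `report.json` is written into
#'   `results_dir`.
#' @export
run_report <- function(results_dir, plot = FALSE) {
  kin_path <- file.path(results_dir, "kinetics.csv")
  cmp_path <- file.path(results_dir, "comparison.json")
  if (!file.exists(kin_path) && !file.exists(cmp_path)) {
    stop("no analysis outputs (kinetics.csv / comparison.json) in ",
         results_dir, call. = FALSE)
  }
  summary <- list()
  if (file.exists(kin_path)) {
    kin <- read.csv(kin_path)
    summary$kinetics <- kin
    num <- kin[vapply(kin, is.numeric, logical(1))]
    summary$kinetics_medians <- as.list(vapply(num, median,
                                               numeric(1), na.rm = TRUE))
  }
  if (file.exists(cmp_path)) {
    summary$comparison <- jsonlite::read_json(cmp_path, simplifyVector = TRUE)
  }
  if (plot) {
    traces <- list.files(results_dir, pattern = "^trace_.*\\.csv$",
                         full.names = TRUE)
    if (length(traces) > 0) {
      pdf(file.path(results_dir, "traces.pdf"), width = 6, height = 4)
      for (f in traces) {
        tr <- read.csv(f)
        graphics::plot(tr[[1]], tr[[2]], type = "l", xlab = "t (s)",
                       ylab = names(tr)[2], main = basename(f))
      }
      dev.off()
    }
  }
  write_atomic(file.path(results_dir, "report.json"), function(p) {
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  })
  invisible(summary)
}
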