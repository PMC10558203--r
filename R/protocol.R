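#' Build an interleaved stimulation/imaging protocol
#'
#' Constructs the timed epoch schedule used throughout the package: an active
#' phase of alternating blue-light stimulation epochs and imaging epochs,
#' followed by a recovery phase with the same cadence but dark epochs in
#' place of stimulation (so the collapsed-trace time resolution is uniform).
#' The standard acidification protocol interleaves 0.5-s stimulation with
#' 1-s imaging for 150 s and then records recovery for a further 150 s.
#'
#' @param stim_s duration of one stimulation epoch (s); 0 disables stimulation.
#' @param image_s duration of one imaging epoch (s); 0 disables imaging during
#'   the active phase.
#' @param active_total total duration (s) of the interleaved active phase.
#' @param recovery_total total duration (s) of the imaging-only recovery phase.
#' @param stim_wavelength,stim_intensity stimulation light (nm, mW cm^-2).
#' @param image_wavelength,image_intensity imaging light (nm, mW cm^-2).
#'
#' @return A `stim_protocol`: data frame with columns `t_start`, `duration`,
#'   `channel` (one of `"stim"`, `"image"`, `"dark"`), `wavelength`,
#'   `intensity`; epochs are sorted, non-overlapping, and their durations sum
#'   to the total duration (attribute `total_s`).
#' @examples
#' p <- build_protocol(0.5, 1.0, 150, 150)
#' sum(p$channel == "stim")   # 100 stimulation epochs
#' @export
build_protocol <- function(stim_s, image_s, active_total, recovery_total,
                           stim_wavelength = 488, stim_intensity = 500,
                           image_wavelength = 561, image_intensity = 150) {
  args <- c(stim_s = stim_s, image_s = image_s,
            active_total = active_total, recovery_total = recovery_total)
  if (any(!is.finite(args)) || any(args < 0)) {
    stop("invalid protocol: all durations must be finite and >= 0 (got ",
         paste(names(args)[!is.finite(args) | args < 0], collapse = ", "), ")",
         call. = FALSE)
  }
  if (stim_s + image_s <= 0) {
    stop("invalid protocol: stim_s + image_s must be > 0", call. = FALSE)
  }

  t_start <- numeric(0); duration <- numeric(0); channel <- character(0)
  t <- 0
  add <- function(dur, ch) {
    t_start  <<- c(t_start, t)
    duration <<- c(duration, dur)
    channel  <<- c(channel, ch)
    t <<- t + dur
  }

  # active phase: alternate stim then image, truncating the final epoch
  eps <- 1e-9
  while (t < active_total - eps) {
    if (stim_s > 0) add(min(stim_s, active_total - t), "stim")
    if (t >= active_total - eps) break
    if (image_s > 0) add(min(image_s, active_total - t), "image")
  }

  # recovery phase: same cadence, dark epochs replacing stimulation, so the
  # epoch-time resolution of the collapsed trace is uniform across phases
  t_rec_end <- active_total + recovery_total
  while (t < t_rec_end - eps) {
    if (stim_s > 0) add(min(stim_s, t_rec_end - t), "dark")
    if (t >= t_rec_end - eps) break
    if (image_s > 0) {
      add(min(image_s, t_rec_end - t), "image")
    } else if (stim_s == 0) {
      add(t_rec_end - t, "dark")
    }
  }

  epochs <- data.frame(
    t_start = t_start, duration = duration, channel = channel,
    wavelength = ifelse(channel == "stim", stim_wavelength,
                        ifelse(channel == "image", image_wavelength, NA_real_)),
    intensity = ifelse(channel == "stim", stim_intensity,
                       ifelse(channel == "image", image_intensity, 0)),
    stringsAsFactors = FALSE
  )
  structure(epochs,
            total_s = active_total + recovery_total,
            active_s = active_total,
            class = c("stim_protocol", "data.frame"))
}

#' @export
print.stim_protocol <- function(x, ...) {
  tab <- table(x$channel)
  cat("Stimulation/imaging protocol: ", nrow(x), " epochs, ",
      attr(x, "total_s"), " s total (active ", attr(x, "active_s"), " s)\n",
      sep = "")
  for (ch in names(tab)) {
    cat(sprintf("  %-6s %4d epochs, %.5g s\n", ch, tab[[ch]],
                sum(x$duration[x$channel == ch])))
  }
  invisible(x)
}

#' Map time points to protocol epochs
#'
#' @param protocol a [build_protocol()] object.
#' @param t numeric vector of times (s).
#' @return Integer vector of epoch row indices; `NA` for times outside the
#'   protocol span.
#' @export
epoch_at <- function(protocol, t) {
  idx <- findInterval(t, protocol$t_start)
  ends <- protocol$t_start + protocol$duration
  idx[idx == 0] <- NA
  out_of <- !is.na(idx) & (t >= ends[pmin(idx, nrow(protocol))] + 1e-9)
  idx[out_of] <- NA
  idx
}

#' Cumulative blue-light dose delivered by a protocol
#'
#' Integrates stimulation-light exposure (wavelengths below `blue_max_nm`)
#' up to each requested time; this drives the sensor's blue-light
#' photoactivation artifact.
#'
#' @param protocol a [build_protocol()] object.
#' @param t times (s) at which to evaluate the cumulative dose.
#' @param blue_max_nm wavelengths at or below this count as blue (default 500).
#' @return Dose in J cm^-2 at each `t`.
#' @export
blue_dose <- function(protocol, t, blue_max_nm = 500) {
  blue <- !is.na(protocol$wavelength) & protocol$wavelength <= blue_max_nm &
    protocol$intensity > 0
  if (!any(blue)) return(numeric(length(t)))
  starts <- protocol$t_start[blue]
  durs <- protocol$duration[blue]
  rate <- protocol$intensity[blue] / 1000  # mW cm^-2 -> W cm^-2 = J cm^-2 s^-1
  vapply(t, function(tt) {
    sum(rate * pmax(0, pmin(tt - starts, durs)))
  }, numeric(1))
}
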