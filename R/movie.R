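#' Frame stack container
#'
#' A time-lapse image stack: a T x Y x X intensity array with per-frame
#' timestamps and stimulation/imaging epoch labels.
#'
#' @param data numeric array, dimensions T x Y x X.
#' @param t per-frame timestamps (s), strictly increasing.
#' @param epoch per-frame labels from `"stim"`, `"image"`, `"dark"`.
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(data, t, epoch) {
  if (length(dim(data)) != 3) stop("data must be a T x Y x X array", call. = FALSE)
  if (dim(data)[1] != length(t) || length(t) != length(epoch)) {
    stop("t and epoch must have one entry per frame", call. = FALSE)
  }
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  bad <- !epoch %in% c("stim", "image", "dark")
  if (any(bad)) {
    stop("unknown epoch labels: ", paste(unique(epoch[bad]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(data = data, t = t, epoch = epoch), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("Frame stack:", d[1], "frames of", d[2], "x", d[3], "pixels,",
      "t in [", min(x$t), ",", max(x$t), "] s\n")
  print(table(x$epoch))
  invisible(x)
}

#' Render a synthetic fluorescence movie from simulated traces
#'
#' Builds a camera-like image stack in which each circular ROI's pixels carry
#' that trace's fluorescence value (plus pixel noise) and the background is
#' near zero, together with the ground-truth label mask. This is the fixture
#' generator that lets the analysis pipeline be tested against known truth.
#'
#' @param traces list of [simulate_cell()] traces (or data frames with `t`
#'   and `F` columns) sharing a common time base.
#' @param layout list of ROI discs, each `list(cx=, cy=, r=)` in pixel units;
#'   ROIs must not overlap. May be empty (all-background movie).
#' @param ny,nx frame dimensions in pixels.
#' @param protocol the [build_protocol()] the traces were simulated under
#'   (used for frame epoch labels); defaults to the protocol attached to the
#'   first trace.
#' @param frame_rate camera frame rate (Hz).
#' @param background background intensity.
#' @param noise_sd per-pixel Gaussian noise sd (intensity units).
#' @param seed RNG seed.
#' @return A list with `stack` (a [frame_stack()]), `mask` (integer label
#'   matrix, 0 = background; label i corresponds to `traces[[i]]`), and the
#'   frame `protocol`.
#' @export
render_movie <- function(traces, layout, ny = 48, nx = 48, protocol = NULL,
                         frame_rate = 4, background = 0, noise_sd = 0,
                         seed = NULL) {
  if (is.null(protocol) && length(traces) > 0) {
    protocol <- attr(traces[[1]], "params")$protocol
  }
  if (is.null(protocol)) stop("protocol is required", call. = FALSE)
  if (length(layout) > length(traces)) {
    stop("more ROIs than traces", call. = FALSE)
  }

  mask <- matrix(0L, ny, nx)
  for (i in seq_along(layout)) {
    roi <- layout[[i]]
    yy <- matrix(seq_len(ny), ny, nx)
    xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    inside <- (yy - roi$cy)^2 + (xx - roi$cx)^2 <= roi$r^2
    if (!any(inside)) stop("ROI ", i, " contains no pixels", call. = FALSE)
    if (any(mask[inside] != 0)) {
      stop("overlapping ROIs: ", i, " intersects ", mask[inside][1],
           call. = FALSE)
    }
    mask[inside] <- i
  }

  total <- attr(protocol, "total_s")
  t_frames <- seq(1 / (2 * frame_rate), total, by = 1 / frame_rate)
  ep <- epoch_at(protocol, t_frames)
  epoch <- ifelse(is.na(ep), "dark", protocol$channel[ep])

  vals <- vapply(seq_along(layout), function(i) {
    tr <- traces[[i]]
    approx(tr$t, tr$F, xout = t_frames, rule = 2)$y
  }, numeric(length(t_frames)))
  if (length(layout) == 0) vals <- matrix(0, length(t_frames), 0)

  stack <- array(background, dim = c(length(t_frames), ny, nx))
  with_seed(seed, {
    for (k in seq_along(t_frames)) {
      fr <- matrix(background, ny, nx)
      for (i in seq_along(layout)) fr[mask == i] <- vals[k, i]
      if (noise_sd > 0) fr <- fr + rnorm(ny * nx, 0, noise_sd)
      stack[k, , ] <- fr
    }
  })

  list(stack = frame_stack(stack, t_frames, epoch), mask = mask,
       protocol = protocol)
}
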