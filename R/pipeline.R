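#' Collapse camera frames to one frame per imaging epoch
#'
#' Frames acquired during stimulation (or dark) epochs are discarded; frames
#' within each imaging epoch are pixel-wise averaged into a single frame
#' timestamped at the epoch midpoint.
#'
#' @param stack a [frame_stack()].
#' @param protocol the [build_protocol()] the stack was acquired under.
#' @return A [frame_stack()] with one `"image"` frame per imaging epoch that
#'   contained at least one camera frame.
#' @export
collapse_epochs <- function(stack, protocol) {
  ep <- epoch_at(protocol, stack$t)
  if (anyNA(ep)) {
    stop("frames outside all protocol epochs: indices ",
         paste(which(is.na(ep)), collapse = ", "), call. = FALSE)
  }
  img_epochs <- which(protocol$channel == "image")
  if (length(img_epochs) == 0) {
    stop("protocol contains no imaging epochs", call. = FALSE)
  }
  keep <- img_epochs[img_epochs %in% ep]
  if (length(keep) == 0) {
    stop("no camera frames fall inside imaging epochs", call. = FALSE)
  }
  d <- dim(stack$data)
  out <- array(NA_real_, dim = c(length(keep), d[2], d[3]))
  for (j in seq_along(keep)) {
    rows <- which(ep == keep[j])
    sub <- stack$data[rows, , , drop = FALSE]
    out[j, , ] <- apply(sub, c(2, 3), mean)
  }
  mid <- protocol$t_start[keep] + protocol$duration[keep] / 2
  frame_stack(out, mid, rep("image", length(keep)))
}

#' Baseline-fluorescence signal mask
#'
#' Thresholds the baseline frame so that delta-F/F is only computed over
#' signal-bearing pixels. Rules: `"quantile"` (default: the given quantile of
#' the nonzero pixels), `"absolute"` (a fixed intensity), or `"otsu"`
#' (requires the EBImage package). The mask keeps pixels `>=` the threshold,
#' so a uniform frame under the quantile rule keeps every pixel.
#'
#' @param frame baseline (F0) image matrix.
#' @param rule threshold rule.
#' @param value quantile (for `"quantile"`, default 0.5) or absolute
#'   threshold (for `"absolute"`).
#' @return Logical mask matrix with the threshold as attribute `threshold`;
#'   warns and returns an empty mask if no pixel passes.
#' @export
f0_mask <- function(frame, rule = c("quantile", "absolute", "otsu"),
                    value = 0.5) {
  rule <- match.arg(rule)
  if (length(frame) == 0) stop("empty frame", call. = FALSE)
  thr <- switch(rule,
    quantile = {
      nz <- frame[frame != 0]
      if (length(nz) == 0) Inf else unname(quantile(nz, value))
    },
    absolute = value,
    otsu = {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        stop("rule = 'otsu' requires the EBImage package", call. = FALSE)
      }
      rng <- range(frame)
      if (diff(rng) == 0) rng[1] else {
        scaled <- (frame - rng[1]) / diff(rng)
        EBImage::otsu(EBImage::Image(scaled)) * diff(rng) + rng[1]
      }
    })
  mask <- frame >= thr
  if (!any(mask)) {
    warning("all pixels below threshold; empty mask", call. = FALSE)
  }
  structure(mask, threshold = thr)
}

#' ROI set
#'
#' @param mask integer label matrix (0 = background).
#' @param categories data frame with columns `label`, `category` (one of
#'   `"soma"`, `"dendrite"`, `"control"`) and optional `parent` (the soma
#'   label a dendrite belongs to).
#' @return An `roi_set`.
#' @export
roi_set <- function(mask, categories) {
  stopifnot(is.matrix(mask), all(c("label", "category") %in% names(categories)))
  if (anyDuplicated(categories$label)) {
    stop("ROI labels must be unique", call. = FALSE)
  }
  if (!"parent" %in% names(categories)) categories$parent <- NA_integer_
  dend <- categories$category == "dendrite" & !is.na(categories$parent)
  missing_parent <- dend & !(categories$parent %in%
                               categories$label[categories$category == "soma"])
  if (any(missing_parent)) {
    stop("dendrite parent soma not in ROI set: label ",
         paste(categories$label[missing_parent], collapse = ", "),
         call. = FALSE)
  }
  structure(list(mask = mask, categories = categories), class = "roi_set")
}

#' Extract an ROI delta-F/F trace from a collapsed stack
#'
#' Averages, per collapsed frame, the pixels belonging to the ROI (optionally
#' intersected with a baseline signal mask from [f0_mask()]); delta-F/F is
#' computed against the first collapsed frame's ROI mean.
#'
#' @param stack a collapsed [frame_stack()] (one frame per imaging epoch).
#' @param rois an [roi_set()].
#' @param label which ROI to extract.
#' @param signal_mask optional logical matrix from [f0_mask()].
#' @return An `roi_trace`: data frame with `t` and `dff`, plus attributes
#'   `F0`, `category`, `corrected` (FALSE).
#' @export
extract_trace <- function(stack, rois, label, signal_mask = NULL) {
  row <- rois$categories[rois$categories$label == label, ]
  if (nrow(row) == 0) stop("unknown ROI label ", label, call. = FALSE)
  sel <- rois$mask == label
  if (!is.null(signal_mask)) sel <- sel & signal_mask
  if (!any(sel)) {
    stop("ROI ", label, " has no pixels after masking", call. = FALSE)
  }
  nT <- dim(stack$data)[1]
  Fm <- vapply(seq_len(nT), function(k) mean(stack$data[k, , ][sel]),
               numeric(1))
  F0 <- Fm[1]
  if (F0 == 0) stop("ROI ", label, " has zero baseline fluorescence",
                    call. = FALSE)
  structure(data.frame(t = stack$t, dff = (Fm - F0) / F0),
            F0 = F0, label = label, category = row$category,
            corrected = FALSE, class = c("roi_trace", "data.frame"))
}

#' Subtract the population-average photoartifact
#'
#' The blue-light photoactivation artifact measured in opsin-negative control
#' cells is averaged epoch-wise and subtracted from the signal trace. The
#' operation is linear: subtracting controls then averaging across cells
#' equals averaging then subtracting.
#'
#' @param trace an [extract_trace()] result (or data frame with `t`, `dff`).
#' @param controls list of control traces on the identical epoch grid.
#' @return The corrected `roi_trace` (attribute `corrected = TRUE`).
#' @export
subtract_artifact <- function(trace, controls) {
  if (length(controls) == 0) {
    stop("at least one control trace is required", call. = FALSE)
  }
  for (ctl in controls) {
    if (length(ctl$t) != length(trace$t) ||
        max(abs(ctl$t - trace$t)) > 1e-9) {
      stop("control trace epoch grid does not match the signal trace",
           call. = FALSE)
    }
  }
  ctrl_mean <- rowMeans(vapply(controls, function(ctl) ctl$dff,
                               numeric(length(trace$t))))
  out <- trace
  out$dff <- trace$dff - ctrl_mean
  attr(out, "corrected") <- TRUE
  attr(out, "control_mean") <- ctrl_mean
  out
}
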