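#' Burst imaging schedule
#'
#' Describes the snapshot design of a dispersal assay: short bursts of frames
#' shot at fixed intervals. The default reproduces the assay design: one
#' 10 s burst of 75 frames at 7.5 frames/s every 12 min, from t = 24 min to
#' t = 396 min (32 imaging cycles per landscape).
#'
#' @param first_min time of the first burst (min).
#' @param last_min time of the last burst (min).
#' @param interval_min interval between bursts (min).
#' @param frames frames per burst.
#' @param fps frames per second within a burst.
#' @return an object of class `burst_schedule` with fields `times_min`,
#'   `frames`, `fps`, `dt_fine` (s) and `burst_duration` (s).
#' @export
#' @examples
#' sch <- burst_schedule()
#' length(sch$times_min) # 32 cycles
burst_schedule <- function(first_min = 24, last_min = 396, interval_min = 12,
                           frames = 75, fps = 7.5) {
  stopifnot(first_min > 0, last_min >= first_min, interval_min > 0,
            frames >= 1, fps > 0)
  structure(
    list(
      times_min = seq(first_min, last_min, by = interval_min),
      frames = as.integer(frames),
      fps = fps,
      dt_fine = 1 / fps,
      burst_duration = (frames - 1) / fps
    ),
    class = "burst_schedule"
  )
}

#' @export
print.burst_schedule <- function(x, ...) {
  iv <- if (length(x$times_min) > 1) diff(x$times_min[1:2]) else NA
  cat(sprintf(
    "<burst_schedule> %d bursts every %g min (t = %g..%g min), %d frames at %g fps\n",
    length(x$times_min), iv, min(x$times_min), max(x$times_min), x$frames, x$fps
  ))
  invisible(x)
}
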