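#' Feeding-trial collection schedules
#'
#' A sampling scheme is the ordered set of collection times (breakpoints,
#' in hours) of a feeding trial; successive breakpoints delimit the
#' censoring intervals into which retention times are binned. The first
#' breakpoint is always 0 and the last one is the sampling horizon.
#'
#' `make_scheme()` builds the schedule shapes commonly used in retention
#' trials:
#'
#' * `regular(width, horizon)`: equal intervals over the whole period;
#' * `mode_varied(first_width, switch, tail_width, horizon)`: intervals of
#'   `first_width` hours around the distribution mode (up to `switch`,
#'   default 8 h), then `tail_width` (default 4 h) to the horizon;
#' * `tail_varied(tail_width, mode_width, switch, horizon)`: fine
#'   intervals (default 1 h) up to `switch`, then `tail_width` afterwards
#'   (a shorter final interval is appended when `tail_width` does not
#'   divide the remaining span);
#' * `last_interval(stop_time, horizon)`: 1 h intervals to 8 h, 4 h
#'   intervals until `stop_time`, then a single final collection at the
#'   horizon (sampling "paused" between `stop_time` and the horizon);
#' * `breakpoints`: an explicit vector of collection times.
#'
#' @param type Scheme shape; see Details.
#' @param width Interval width (hours) for `type = "regular"`.
#' @param horizon Final collection time in hours (default 52).
#' @param first_width,switch,tail_width,mode_width,stop_time Shape
#'   parameters, in hours; see Details.
#' @param breakpoints Explicit collection times for
#'   `type = "breakpoints"`, starting at 0, strictly increasing.
#' @return An object of class `sampling_scheme` with fields
#'   `breakpoints` and `horizon`.
#' @examples
#' make_scheme("regular", width = 4)            # 0, 4, ..., 52
#' make_scheme("last_interval", stop_time = 12) # 0, 1, ..., 8, 12, 52
#' @export
make_scheme <- function(type = c("regular", "mode_varied", "tail_varied",
                                 "last_interval", "breakpoints"),
                        width = NULL, horizon = 52,
                        first_width = NULL, switch = 8, tail_width = 4,
                        mode_width = 1, stop_time = NULL,
                        breakpoints = NULL) {
  type <- match.arg(type)
  bp <- switch(type,
    regular = {
      stopifnot(!is.null(width), width > 0)
      if (abs(horizon / width - round(horizon / width)) > 1e-8)
        stop("`width` must divide `horizon` for a regular scheme",
             call. = FALSE)
      seq(0, horizon, by = width)
    },
    mode_varied = {
      stopifnot(!is.null(first_width), first_width > 0, tail_width > 0)
      if (abs(switch / first_width - round(switch / first_width)) > 1e-8)
        stop("`first_width` must divide `switch`", call. = FALSE)
      if (abs((horizon - switch) / tail_width -
              round((horizon - switch) / tail_width)) > 1e-8)
        stop("`tail_width` must divide `horizon - switch`", call. = FALSE)
      c(seq(0, switch, by = first_width),
        seq(switch + tail_width, horizon, by = tail_width))
    },
    tail_varied = {
      stopifnot(tail_width > 0, mode_width > 0)
      tail_bp <- seq(switch, horizon, by = tail_width)
      # allow a shorter closing interval when tail_width does not divide
      if (max(tail_bp) < horizon) tail_bp <- c(tail_bp, horizon)
      c(seq(0, switch, by = mode_width), tail_bp[-1L])
    },
    last_interval = {
      stopifnot(!is.null(stop_time), stop_time > 8, stop_time < horizon)
      c(seq(0, 8, by = 1), seq(12, stop_time, by = 4), horizon)
    },
    breakpoints = {
      stopifnot(!is.null(breakpoints))
      breakpoints
    })
  new_sampling_scheme(bp)
}

new_sampling_scheme <- function(breakpoints) {
  breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints) < 2L)
    stop("a scheme needs at least 2 breakpoints", call. = FALSE)
  if (breakpoints[1L] != 0)
    stop("breakpoints must start at 0", call. = FALSE)
  if (any(diff(breakpoints) <= 0))
    stop("breakpoints must be strictly increasing", call. = FALSE)
  structure(list(breakpoints = breakpoints,
                 horizon = breakpoints[length(breakpoints)]),
            class = "sampling_scheme")
}

#' @export
print.sampling_scheme <- function(x, ...) {
  cat(sprintf("<sampling_scheme> %d intervals over (0, %g] h\n",
              length(x$breakpoints) - 1L, x$horizon))
  cat("breakpoints:", paste(x$breakpoints, collapse = " "), "\n")
  invisible(x)
}

is_sampling_scheme <- function(x) inherits(x, "sampling_scheme")

check_scheme <- function(scheme) {
  if (!is_sampling_scheme(scheme))
    stop("expected a `sampling_scheme` object", call. = FALSE)
  scheme
}

#' The ten canonical interval-variation schemes
#'
#' The named set of collection schedules used by [run_interval_study()]:
#' regular 1/2/4 h intervals over the whole 52 h period; wider intervals
#' around the mode (2 h to 8 h then 4 h); wider intervals in the tail
#' (1 h to 8 h then 2, 4 or 8 h); and truncated designs that pause
#' sampling at 36, 24 or 12 h with a single final collection at 52 h.
#' Schemes that coincide under different descriptions (e.g. 1 h to 8 h
#' then 4 h is both the finest mode variant and the 4 h tail variant)
#' appear once.
#'
#' @return A named list of [make_scheme()] objects.
#' @export
default_interval_schemes <- function() {
  list(
    regular_1h = make_scheme("regular", width = 1),
    regular_2h = make_scheme("regular", width = 2),
    regular_4h = make_scheme("regular", width = 4),
    mode_2h    = make_scheme("mode_varied", first_width = 2),
    tail_2h    = make_scheme("tail_varied", tail_width = 2),
    tail_4h    = make_scheme("tail_varied", tail_width = 4),
    tail_8h    = make_scheme("tail_varied", tail_width = 8),
    last_36h   = make_scheme("last_interval", stop_time = 36),
    last_24h   = make_scheme("last_interval", stop_time = 24),
    last_12h   = make_scheme("last_interval", stop_time = 12)
  )
}
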